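# Synthetic tissue-optics generator: spectral structure, anchor
# interpolation, cohort noise model and determinism.

test_that("optical_spectrum validates its invariants", {
  expect_s3_class(optical_spectrum(c(400, 500), c(0.1, 0.2), c(1, 1)),
                  "optical_spectrum")
  expect_error(optical_spectrum(c(500, 400), c(0.1, 0.2), c(1, 1)),
               "strictly increasing")
  expect_error(optical_spectrum(c(400, 500), c(-0.1, 0.2), c(1, 1)),
               "non-negative")
  expect_error(optical_spectrum(c(400, 500), c(0.1, 0.2), c(1, 1), g = 1),
               "g must be")
  expect_error(optical_spectrum(400, c(0.1, 0.2), c(1, 1)), "equal length")
})

test_that("group mean spectra pass exactly through the pinned anchors", {
  anc <- default_anchors()
  for (grp in c("healthy", "blackhearted")) {
    sp <- generate_group_spectrum(grp)
    v <- spectrum_at(sp, c(490, 805))
    ref <- anc[anc$group == grp, ]
    ref <- ref[order(ref$wavelength_nm), ]
    expect_equal(v$mu_a_per_mm, ref$mu_a, tolerance = 1e-9)
    expect_equal(v$mu_s_prime_per_mm, ref$mu_s_prime, tolerance = 1e-9)
  }
  # slight group is the midpoint mixture of the two mean spectra
  h <- healthy_mean(); b <- blackhearted_mean()
  s <- generate_group_spectrum("slight")
  expect_equal(s$mu_a, (h$mu_a + b$mu_a) / 2, tolerance = 1e-12)
  expect_equal(s$mu_s_prime, (h$mu_s_prime + b$mu_s_prime) / 2,
               tolerance = 1e-12)
})

test_that("healthy absorption shows pigment and water bands; blackhearted does not", {
  h <- healthy_mean(); b <- blackhearted_mean()
  wl <- h$wavelengths_nm
  win <- wl >= 450 & wl <= 550
  expect_equal(wl[win][which.max(h$mu_a[win])], 490)
  # water band: a local maximum within 980 +/- 10 nm
  win9 <- wl >= 940 & wl <= 1000
  peak9 <- wl[win9][which.max(h$mu_a[win9])]
  expect_lte(abs(peak9 - 980), 10)
  # blackhearted mu_a decreases monotonically through the pigment region:
  # no distinct 490 nm local maximum
  bwin <- b$mu_a[wl >= 450 & wl <= 550]
  expect_true(all(diff(bwin) < 0))
})

test_that("blackhearted tissue has elevated absorption and the stated scattering shape", {
  h <- healthy_mean(); b <- blackhearted_mean()
  wl <- h$wavelengths_nm
  mid <- wl >= 550 & wl <= 850
  expect_true(all(b$mu_a[mid] > h$mu_a[mid]))
  expect_true(all(b$mu_s_prime[wl >= 550] > h$mu_s_prime[wl >= 550]))
  d <- diff(b$mu_s_prime)
  expect_true(all(d[wl[-1] > 450 & wl[-1] <= 550] > 0))
  expect_true(all(d[wl[-1] > 550] < 0))
})

test_that("generator rejects unknown groups and out-of-range grids", {
  expect_error(generate_group_spectrum("rotten"))
  expect_error(generate_group_spectrum("healthy", wavelengths = c(350, 500)),
               "range")
  expect_error(generate_group_spectrum("healthy", wavelengths = c(900, 1100)),
               "range")
})

test_that("noise-free cohort records equal the slab forward model of the group mean", {
  co <- generate_cohort(cohort_spec(n_per_group = 2, cv = 0, noise = 0,
                                    seed = 3, wavelengths = c(490, 805)))
  mean_sp <- co$group_means[["healthy"]]
  s <- co$samples[[1]]
  expect_identical(s$group, "healthy")
  expect_equal(s$spectrum$mu_a, mean_sp$mu_a)
  for (i in 1:2) {
    fwd <- slab_rt(mean_sp$mu_a[i], mean_sp$mu_s_prime[i], 2, n_slab = 1.34)
    expect_equal(s$record$R_t[i], fwd$R_t)
    expect_equal(s$record$T_t[i], fwd$T_t)
  }
})

test_that("cohorts are bit-identical under a fixed seed and differ across seeds", {
  spec <- cohort_spec(n_per_group = 3, seed = 11, wavelengths = c(490, 805))
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1, co2)
  co3 <- generate_cohort(cohort_spec(n_per_group = 3, seed = 12,
                                     wavelengths = c(490, 805)))
  expect_false(identical(co1$samples[[1]]$spectrum$mu_a,
                         co3$samples[[1]]$spectrum$mu_a))
})

test_that("cohort spec validates", {
  expect_error(cohort_spec(n_per_group = 1), ">= 2")
  expect_error(cohort_spec(cv = -0.1), ">= 0")
  expect_error(cohort_spec(groups = character(0)))
})

test_that("recovered absorption separates the groups by many standard errors", {
  # single-wavelength cohort at 805 nm; invert each noisy record and compare
  # group means of the recovered mu_a
  co <- generate_cohort(cohort_spec(n_per_group = 40, seed = 21,
                                    wavelengths = 805))
  rec <- vapply(co$samples, function(s) {
    invert_rt(s$record$R_t, s$record$T_t, 2, n_slab = 1.34,
              start = c(0.05, 1))$mu_a
  }, 0)
  grp <- vapply(co$samples, `[[`, "", "group")
  mh <- rec[grp == "healthy"]; mb <- rec[grp == "blackhearted"]
  se <- sqrt(stats::var(mh) / length(mh) + stats::var(mb) / length(mb))
  expect_gt(abs(mean(mb) - mean(mh)) / se, 5)
})

test_that("spectrum and measurement CSV round-trips preserve the data", {
  sp <- generate_group_spectrum("healthy", wavelengths = seq(500, 900, 100))
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, p)
  sp2 <- read_spectrum_csv(p)
  expect_equal(sp2$mu_a, sp$mu_a)
  expect_equal(sp2$wavelengths_nm, sp$wavelengths_nm)

  co <- generate_cohort(cohort_spec(n_per_group = 2, seed = 5,
                                    wavelengths = c(490, 805)))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(co, p2)
  d <- read_measurements_csv(p2)
  expect_setequal(names(d), c("sample_id", "group", "wavelength_nm",
                              "R_t", "T_t", "thickness_mm", "n"))
  expect_equal(nrow(d), 4 * 2)
})
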