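# Forward adding-doubling solver and the inverse (IAD) search.

test_that("Fresnel reflectance matches closed forms", {
  expect_equal(fresnel_unpolarized(1, 1.34, 1), (0.34 / 2.34)^2,
               tolerance = 1e-12)
  expect_equal(fresnel_unpolarized(1, 1, 0.3), 0)
  # beyond the critical angle (critical cosine ~ 0.6652 for 1.34 -> 1)
  expect_equal(fresnel_unpolarized(1.34, 1, 0.5), 1)
  expect_error(fresnel_unpolarized(1, 1.34, 1.2), "cos_incidence")
  expect_error(fresnel_unpolarized(0.9, 1.34, 0.5), ">= 1")
})

test_that("Radau quadrature integrates polynomials exactly and contains mu = 1", {
  q <- tuberlight:::radau_mu(16)
  expect_true(any(q$mu == 1))
  expect_equal(sum(q$w), 1, tolerance = 1e-14)
  for (k in c(1, 5, 20, 30))
    expect_equal(sum(q$w * q$mu^k), 1 / (k + 1), tolerance = 1e-12)
})

test_that("slab_rt reproduces vacuum, Beer-Lambert and etalon limits", {
  v <- slab_rt(0, 0, 1, n_slab = 1, n_outside = 1)
  expect_equal(v$R_t, 0); expect_equal(v$T_t, 1)

  b <- slab_rt(1, 0, 1, n_slab = 1, n_outside = 1)
  expect_equal(b$T_t, exp(-1), tolerance = 1e-9)
  expect_equal(b$R_t, 0, tolerance = 1e-12)

  # transparent slab with index mismatch: incoherent etalon
  r0 <- fresnel_unpolarized(1, 1.34, 1)
  e <- slab_rt(0, 0, 1, n_slab = 1.34, n_outside = 1)
  expect_equal(e$T_t, (1 - r0) / (1 + r0), tolerance = 1e-12)
  expect_equal(e$R_t, 2 * r0 / (1 + r0), tolerance = 1e-12)
})

test_that("slab_rt conserves energy and is monotone in the coefficients", {
  for (mua in c(0.01, 0.3)) for (mus in c(0.2, 2)) for (d in c(0.5, 3)) {
    v <- slab_rt(mua, mus, d)
    expect_gte(v$R_t, 0); expect_gte(v$T_t, 0)
    expect_lte(v$R_t + v$T_t, 1 + 1e-12)
  }
  # T strictly decreasing in mu_a and in d; R increasing in mu_s
  t_mua <- vapply(c(0.01, 0.1, 0.5, 1), function(m)
    slab_rt(m, 1, 2)$T_t, 0)
  expect_true(all(diff(t_mua) < 0))
  t_d <- vapply(c(0.5, 1, 2, 4), function(d) slab_rt(0.1, 1, d)$T_t, 0)
  expect_true(all(diff(t_d) < 0))
  r_mus <- vapply(c(0.2, 0.5, 1, 2), function(m) slab_rt(0.05, m, 2)$R_t, 0)
  expect_true(all(diff(r_mus) > 0))
})

test_that("layer composition is associative and reciprocal", {
  quad <- tuberlight:::radau_mu(16)
  L <- tuberlight:::ad_slab_operators(0.05, 1, 0.5, 0, quad)
  L2a <- tuberlight:::ad_double(L$R, L$T)
  L3a <- tuberlight:::ad_add(L2a, L)          # (1+1)+1
  L3b <- tuberlight:::ad_add(L, tuberlight:::ad_double(L$R, L$T))  # 1+(1+1)
  expect_lt(max(abs(L3a$R - L3b$R)), 1e-9)
  expect_lt(max(abs(L3a$T - L3b$T)), 1e-9)
  # doubling twice equals stacking four identical layers one by one
  L4a <- tuberlight:::ad_double(L2a$R, L2a$T)
  L4b <- tuberlight:::ad_add(L, tuberlight:::ad_add(L, L2a))
  expect_lt(max(abs(L4a$R - L4b$R)), 1e-9)
  expect_lt(max(abs(L4a$T - L4b$T)), 1e-9)
  # reciprocity: mu_j R[i,j] / w_i is symmetric in the flux representation
  S <- sweep(sweep(L2a$R, 2, quad$mu, "*"), 1, quad$w, "/")
  expect_lt(max(abs(S - t(S))), 1e-9)
})

test_that("inversion round-trips the forward model within 1 percent", {
  for (mua in c(0.01, 0.1, 1)) for (mus in c(0.1, 1, 3)) {
    fwd <- slab_rt(mua, mus, 2, n_slab = 1.34)
    inv <- invert_rt(fwd$R_t, fwd$T_t, 2, n_slab = 1.34)
    expect_true(inv$converged)
    expect_lt(abs(inv$mu_a - mua) / mua, 0.01)
    expect_lt(abs(inv$mu_s_prime - mus) / mus, 0.01)
  }
})

test_that("a pure absorber inverts to negligible scattering", {
  fwd <- slab_rt(0.5, 0, 2, n_slab = 1.34)
  inv <- invert_rt(fwd$R_t, fwd$T_t, 2, n_slab = 1.34)
  expect_lt(inv$mu_s_prime, 1e-3)
  expect_equal(inv$mu_a, 0.5, tolerance = 1e-3)
})

test_that("unphysical measurements raise an explicit error", {
  expect_error(invert_rt(0.7, 0.5, 2), "unphysical")
  expect_error(invert_rt(-0.1, 0.5, 2), "non-negative")
})

test_that("spectrum extraction round-trips and isolates failures", {
  wl <- seq(500, 900, 80)
  sp <- generate_group_spectrum("healthy", wavelengths = wl)
  rec <- do.call(rbind, lapply(seq_along(wl), function(i) {
    v <- slab_rt(sp$mu_a[i], sp$mu_s_prime[i], 2, n_slab = 1.34)
    data.frame(wavelength_nm = wl[i], R_t = v$R_t, T_t = v$T_t)
  }))
  out <- extract_op_spectrum(rec, 2, n_slab = 1.34)
  expect_equal(attr(out, "n_masked"), 0)
  expect_true(all(abs(out$mu_a - sp$mu_a) / sp$mu_a < 0.01))
  expect_true(all(abs(out$mu_s_prime - sp$mu_s_prime) / sp$mu_s_prime < 0.01))

  # single-wavelength input
  one <- extract_op_spectrum(rec[3, ], 2, n_slab = 1.34)
  expect_length(one$mu_a, 1)
  expect_equal(one$mu_a, sp$mu_a[3], tolerance = 0.01)

  # one unphysical wavelength is masked, the rest recovered
  rec_bad <- rec
  rec_bad$R_t[2] <- 0.8; rec_bad$T_t[2] <- 0.5
  out2 <- extract_op_spectrum(rec_bad, 2, n_slab = 1.34)
  expect_equal(attr(out2, "n_masked"), 1)
  expect_true(is.na(out2$mu_a[2]))
  expect_true(all(abs(out2$mu_a[-2] - sp$mu_a[-2]) / sp$mu_a[-2] < 0.01))
})
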