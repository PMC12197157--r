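# Voxel Monte Carlo engine: sampling primitives, geometry builders,
# transport limits, conservation and cross-validation against the
# adding-doubling solver.

test_that("free-path sampling follows the exponential law", {
  expect_equal(sample_step(exp(-1), 1), 1)
  expect_equal(sample_step(1, 5), 0)
  set.seed(31)
  m <- mean(sample_step(runif(1e5, .Machine$double.eps, 1), 2))
  expect_lt(abs(m - 0.5) / 0.5, 0.01)
  expect_error(sample_step(0.5, 0), "positive")
})

test_that("Henyey-Greenstein cosine sampling has mean g and a continuous g->0 limit", {
  expect_equal(sample_hg_cos(0.75, 0), 0.5)
  set.seed(13)
  u <- runif(1e6)
  expect_lt(abs(mean(sample_hg_cos(u, 0.9)) - 0.9), 0.002)
  expect_equal(sample_hg_cos(u[1:100], 1e-13), 2 * u[1:100] - 1,
               tolerance = 1e-9)
  expect_error(sample_hg_cos(0.5, 1), "g must be")
})

test_that("Russian roulette is a thresholded, unbiased termination", {
  expect_equal(roulette(0.5, 1e-4, 10, 0.99), 0.5)
  expect_equal(roulette(1e-5, 1e-4, 10, 0.05), 1e-4)
  expect_equal(roulette(1e-5, 1e-4, 10, 0.5), 0)
  set.seed(42)
  w <- roulette(rep(1e-5, 1e6), 1e-4, 10, runif(1e6))
  expect_lt(abs(mean(w) / 1e-5 - 1), 0.01)
})

test_that("geometry builders produce the three layered models", {
  h <- healthy_mean(); b <- blackhearted_mean()
  slice <- build_geometry("slice", 805, b, h, lateral_voxels = 10)
  expect_equal(dim(slice$medium)[3] * slice$voxel_size, 2)
  half <- build_geometry("half", 805, b, h, lateral_voxels = 10)
  expect_equal(dim(half$medium)[3] * half$voxel_size, 30.5)
  # beam side first: test layer, then healthy flesh, then peel
  col <- half$medium[5, 5, ]
  expect_equal(col[1:4], rep(1L, 4))
  expect_equal(col[5:60], rep(2L, 56))
  expect_equal(col[61], 3L)
  whole <- build_geometry("whole", 805, b, h, lateral_voxels = 10)
  expect_equal(dim(whole$medium)[3] * whole$voxel_size, 61)
  colw <- whole$medium[5, 5, ]
  expect_equal(colw, c(3L, rep(2L, 56), rep(1L, 8), rep(2L, 56), 3L))
  # media evaluated at the requested wavelength
  v <- spectrum_at(b, 805)
  expect_equal(whole$media$mu_a[1], v$mu_a_per_mm)
  expect_equal(whole$media$mu_s[1], v$mu_s_prime_per_mm)
})

test_that("off-grid layer thicknesses snap with an explicit report", {
  h <- healthy_mean()
  expect_warning(build_geometry("slice", 805, h, voxel_size = 0.8,
                                lateral_voxels = 4),
                 "snapped")
  expect_error(suppressWarnings(
    build_geometry("half", 805, h, voxel_size = 1, lateral_voxels = 4)),
    "thinner")
})

test_that("transport reproduces the vacuum and Beer-Lambert limits", {
  vac <- homogeneous_geometry(0, 0, n = 1, depth_mm = 2, voxel_size = 0.5,
                              lateral_voxels = 4, n_outside = 1)
  r <- run_mc(vac, mc_config(n_photons = 1e3, seed = 1))
  expect_equal(r$specular, 0)
  expect_equal(r$T, 1)
  expect_equal(r$A, 0)

  abs1 <- homogeneous_geometry(1, 0, n = 1, depth_mm = 1, voxel_size = 0.5,
                               lateral_voxels = 4, n_outside = 1)
  n <- 1e5
  r <- run_mc(abs1, mc_config(n_photons = n, seed = 4))
  expect_lt(abs(r$T - exp(-1)), 3 * mc_se(exp(-1), n))
  expect_equal(r$R_d, 0)
  expect_equal(r$specular + r$R_d + r$T + r$A, 1, tolerance = 1e-6)
})

test_that("zero-attenuation voxels are traversed ballistically", {
  med <- array(1L, c(4, 4, 8)); med[, , 3:6] <- 2L   # 1mm abs | 2mm air | 1mm abs
  media <- data.frame(id = 1:2, name = c("absorber", "air"),
                      mu_a = c(1, 0), mu_s = c(0, 0), g = 0, n = 1)
  geo <- voxel_geometry(med, media, voxel_size = 0.5,
                        lateral_boundary = "mirror")
  r <- run_mc(geo, mc_config(n_photons = 5e4, seed = 2))
  expect_lt(abs(r$T - exp(-2)), 3 * mc_se(exp(-2), 5e4))
  expect_equal(r$specular + r$R_d + r$T + r$A, 1, tolerance = 1e-6)
})

test_that("slab escape fractions agree with adding-doubling within 3 sigma", {
  n <- 1e5
  for (s in list(c(0.05, 1), c(0.5, 0.5), c(0.01, 2), c(1, 1), c(0.1, 3))) {
    ad <- slab_rt(s[1], s[2], 2, n_slab = 1.34)
    geo <- homogeneous_geometry(s[1], s[2], g = 0, n = 1.34, depth_mm = 2,
                                voxel_size = 0.5, lateral_voxels = 8,
                                lateral_boundary = "mirror")
    mc <- run_mc(geo, mc_config(n_photons = n, seed = 3))
    ad_rd <- ad$R_t - fresnel_unpolarized(1, 1.34, 1)
    expect_lt(abs(mc$R_d - ad_rd), 3 * mc_se(ad_rd, n))
    expect_lt(abs(mc$T - ad$T_t), 3 * mc_se(ad$T_t, n))
    expect_equal(mc$specular + mc$R_d + mc$T + mc$A, 1, tolerance = 1e-6)
  }
})

test_that("tallies are reproducible under a fixed seed", {
  geo <- homogeneous_geometry(0.05, 1, depth_mm = 2, voxel_size = 0.5,
                              lateral_voxels = 8)
  r1 <- run_mc(geo, mc_config(n_photons = 2e4, seed = 17))
  r2 <- run_mc(geo, mc_config(n_photons = 2e4, seed = 17))
  expect_identical(r1$deposited, r2$deposited)
  expect_identical(r1$R_d, r2$R_d)
  r3 <- run_mc(geo, mc_config(n_photons = 2e4, seed = 18))
  expect_false(identical(r1$R_d, r3$R_d))
})

test_that("escapes are azimuthally symmetric for a homogeneous medium", {
  geo <- homogeneous_geometry(0.05, 1, depth_mm = 10, voxel_size = 0.5,
                              lateral_voxels = 41, lateral_boundary = "open")
  mc <- run_mc(geo, mc_config(n_photons = 2e4, seed = 2))
  cnt <- mc$escape_top_counts
  ic <- 21   # beam column
  q <- c(sum(cnt[1:(ic - 1), 1:(ic - 1)]), sum(cnt[(ic + 1):41, 1:(ic - 1)]),
         sum(cnt[1:(ic - 1), (ic + 1):41]), sum(cnt[(ic + 1):41, (ic + 1):41]))
  expect_gt(stats::chisq.test(q)$p.value, 0.01)
})

test_that("fluence decay matches diffusion theory in the scattering-dominated regime", {
  # fitted asymptotic decay length at the healthy 805 nm working point
  geo <- homogeneous_geometry(0.0110, 0.6581, depth_mm = 50, voxel_size = 0.5,
                              lateral_voxels = 10, lateral_boundary = "mirror")
  mc <- run_mc(geo, mc_config(n_photons = 5e4, seed = 11))
  prof <- axial_fluence_profile(mc)
  sub <- prof[prof$depth_mm > 5 & prof$depth_mm < 25, ]
  fit <- stats::lm(log(fluence) ~ depth_mm, data = sub)
  decay <- -1 / stats::coef(fit)[[2]]
  sigma <- penetration_depth(0.0110, 0.6581)
  expect_lt(abs(decay - sigma) / sigma, 0.15)
  expect_equal(mc$specular + mc$R_d + mc$T + mc$A, 1, tolerance = 1e-6)

  # 1/e-crossing depth deep in the diffusion regime (mu_s'/mu_a = 500)
  geo2 <- homogeneous_geometry(0.002, 1.0, depth_mm = 80, voxel_size = 0.5,
                               lateral_voxels = 6, lateral_boundary = "mirror")
  mc2 <- run_mc(geo2, mc_config(n_photons = 2e4, seed = 11))
  ratio <- fluence_1e_depth(mc2) / penetration_depth(0.002, 1.0)
  expect_gte(ratio, 0.85)
  expect_lte(ratio, 1.15)
})

test_that("a blackhearted core screens light from the distal half of the tuber", {
  h <- healthy_mean(); b <- blackhearted_mean()
  distal <- function(sp) {
    geo <- build_geometry("whole", 805, op_test = sp, op_healthy = h,
                          lateral_voxels = 40)
    r <- run_mc(geo, mc_config(n_photons = 5e4, seed = 5))
    expect_equal(r$specular + r$R_d + r$T + r$A, 1, tolerance = 1e-6)
    # energy immediately distal to the central test layers (z in 32.5-37.5 mm)
    sum(r$absorbed_energy[, , 66:75])
  }
  expect_gt(distal(h), distal(b))
})

test_that("energy_budget closes and mc_config validates", {
  geo <- homogeneous_geometry(0.1, 1, depth_mm = 2, voxel_size = 0.5,
                              lateral_voxels = 6)
  r <- run_mc(geo, mc_config(n_photons = 5e3, seed = 1))
  b <- energy_budget(r)
  expect_named(b, c("specular", "R_d", "T", "A"))
  expect_equal(sum(b), 1, tolerance = 1e-6)
  expect_error(mc_config(n_photons = 0), ">= 1")
  expect_error(mc_config(w_threshold = 2), "w_threshold")
  expect_error(mc_config(roulette_m = 1), "roulette_m")
})
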