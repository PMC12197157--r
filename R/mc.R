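# Monte Carlo driver, sampling primitives and energy-budget summaries.

#' Monte Carlo run configuration
#'
#' @param n_photons Photon packets to launch (>= 1).  The reference
#'   configuration uses 1e8; desk-scale runs default to 1e6.
#' @param seed Integer seed; each photon derives its own counter-based RNG
#'   stream from `(seed, photon index)`, so results do not depend on
#'   execution order.
#' @param w_threshold Russian-roulette weight threshold, in (0, 1).
#' @param roulette_m Roulette survival factor m (> 1): survive with
#'   probability 1/m at weight m*W.
#' @param max_events Scattering-event cap per photon; on reaching it the
#'   remaining weight is deposited locally (conservative termination).
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_photons = 1e6, seed = 1, w_threshold = 1e-4,
                      roulette_m = 10, max_events = 1e6) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (w_threshold <= 0 || w_threshold >= 1) stop("w_threshold must be in (0,1)")
  if (roulette_m <= 1) stop("roulette_m must be > 1")
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 w_threshold = w_threshold, roulette_m = roulette_m,
                 max_events = max_events),
            class = "mc_config")
}

#' Sample an exponential free path
#'
#' @param u Uniform variates in (0, 1].
#' @param mu_t Total interaction coefficient, mm^-1 (> 0).
#' @return Step lengths `-log(u) / mu_t`, mm.
#' @export
sample_step <- function(u, mu_t) {
  if (any(mu_t <= 0)) stop("mu_t must be positive")
  if (any(u <= 0 | u > 1)) stop("u must be in (0, 1]")
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF sampling; the `g = 0` branch reduces continuously to the
#' isotropic `2u - 1`.
#'
#' @param u Uniform variates in `[0, 1)`.
#' @param g Anisotropy factor in `[0, 1)`.
#' @return Cosines in `[-1, 1]` with mean `g`.
#' @export
sample_hg_cos <- function(u, g) {
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (g < 1e-12) return(2 * u - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - t^2) / (2 * g)))
}

#' Russian-roulette termination
#'
#' Weights at or above the threshold pass unchanged; below it the packet
#' survives with probability `1/m` at weight `m * W` and dies otherwise.
#' Unbiased: the expected weight is preserved.
#'
#' @param W Packet weight(s).
#' @param W_th Threshold.
#' @param m Survival factor (> 1).
#' @param u Uniform variates in `[0, 1)`.
#' @return Updated weights (0 for terminated packets).
#' @export
roulette <- function(W, W_th, m, u) {
  ifelse(W >= W_th, W, ifelse(u < 1 / m, m * W, 0))
}

#' Run the voxel Monte Carlo photon transport simulation
#'
#' Launches photon packets at the top face (pencil beam at the centre voxel
#' by default), applies the specular Fresnel split on entry, transports them
#' with exponential stepping clipped at voxel faces, deposits `W*mu_a/mu_t`
#' per interaction, scatters by Henyey-Greenstein, performs Fresnel
#' reflection/refraction at any face where the refractive index changes
#' (including escape into the ambient medium) and terminates by Russian
#' roulette.
#'
#' The scalar absorbed fraction `A` folds in the net roulette residual
#' (killed weight minus survivor boosts, zero in expectation), so
#' `specular + R_d + T + A = 1` holds exactly on every run; the absorbed
#' energy map contains the deposited weight only.
#'
#' @param geometry A [voxel_geometry()].
#' @param config An [mc_config()].
#' @return An `mc_result` with escape fractions (`specular`, `R_d`, `T`),
#'   absorbed fraction `A`, `absorbed_energy` (deposited weight per voxel
#'   volume, mm^-3), `fluence` (absorbed energy / mu_a, `NA` where
#'   `mu_a = 0`), top-face escape counts, photon count and seed.
#' @export
run_mc <- function(geometry, config = mc_config()) {
  stopifnot(inherits(geometry, "voxel_geometry"), inherits(config, "mc_config"))
  d <- dim(geometry$medium)
  beam_sigma <- if (identical(geometry$beam$profile, "gaussian"))
    geometry$beam$sigma_mm else 0
  entry <- as.integer(geometry$beam$entry) - 1L
  out <- mc_run_cpp(
    medium = as.integer(geometry$medium), dims = d,
    voxel = geometry$voxel_size,
    med_mua = geometry$media$mu_a, med_mus = geometry$media$mu_s,
    med_g = geometry$media$g, med_n = geometry$media$n,
    n_out = geometry$n_outside,
    lateral_mirror = identical(geometry$lateral_boundary, "mirror"),
    beam_sigma = beam_sigma, entry_ix = entry[1], entry_iy = entry[2],
    n_photons = config$n_photons, seed = config$seed,
    w_th = config$w_threshold, rm = config$roulette_m,
    max_events = config$max_events)
  vol <- geometry$voxel_size^3
  dep <- array(out$deposited, dim = d)
  mua_vox <- array(geometry$media$mu_a[as.integer(geometry$medium)], dim = d)
  flu <- dep / vol / mua_vox
  flu[mua_vox == 0] <- NA_real_
  structure(list(
    specular = out$specular, R_d = out$R_d, T = out$T, A = out$A,
    absorbed_energy = dep / vol, fluence = flu,
    deposited = dep,
    roulette_residual = out$roulette_residual,
    escape_top_counts = out$escape_top_counts,
    n_capped = out$n_capped,
    n_photons = config$n_photons, seed = config$seed,
    voxel_size = geometry$voxel_size, dims = d,
    wavelength_nm = geometry$wavelength_nm %||% NA_real_,
    model = geometry$model %||% "custom"),
    class = "mc_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result (%s, %g photons, seed %d)\n", x$model,
              x$n_photons, x$seed))
  b <- energy_budget(x)
  cat(sprintf("  specular %.4f | R_d %.4f | T %.6f | A %.4f (sum %.6f)\n",
              b["specular"], b["R_d"], b["T"], b["A"], sum(b)))
  invisible(x)
}

#' Energy budget of a Monte Carlo run
#'
#' @param result An `mc_result`.
#' @return Named vector `c(specular, R_d, T, A)`; the fractions sum to 1
#'   within 1e-6 by construction.
#' @export
energy_budget <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  b <- c(specular = result$specular, R_d = result$R_d, T = result$T,
         A = result$A)
  if (abs(sum(b) - 1) > 1e-6)
    warning("energy budget does not close: sum = ", sum(b))
  b
}

#' Wavelength-resolved energy budget of a homogeneous medium
#'
#' Runs the Monte Carlo engine on a deep homogeneous block (laterally
#' mirrored, i.e. semi-infinite in practice) at each requested wavelength of
#' a tissue spectrum and collects the escape/absorption fractions.  This is
#' the model used for the tissue-level energy distribution summaries, where
#' transmittance is negligible by construction.
#'
#' @param spectrum An [optical_spectrum()].
#' @param wavelengths Wavelengths to simulate (default: every grid point).
#' @param n_photons Photons per wavelength.
#' @param seed Base seed (offset per wavelength).
#' @param depth_mm,voxel_size,lateral_voxels Geometry of the block.
#' @return Data frame with `wavelength_nm`, `specular`, `R_d`, `T`, `A`.
#' @export
energy_budget_spectrum <- function(spectrum, wavelengths = NULL,
                                   n_photons = 1e4, seed = 1,
                                   depth_mm = 60, voxel_size = 1,
                                   lateral_voxels = 8) {
  if (is.null(wavelengths)) wavelengths <- spectrum$wavelengths_nm
  rows <- lapply(seq_along(wavelengths), function(i) {
    wl <- wavelengths[i]
    v <- spectrum_at(spectrum, wl)
    geo <- homogeneous_geometry(v$mu_a_per_mm, v$mu_s_prime_per_mm,
                                g = 0, n = 1.34, depth_mm = depth_mm,
                                voxel_size = voxel_size,
                                lateral_voxels = lateral_voxels)
    r <- run_mc(geo, mc_config(n_photons = n_photons, seed = seed + i))
    data.frame(wavelength_nm = wl, specular = r$specular, R_d = r$R_d,
               T = r$T, A = r$A)
  })
  do.call(rbind, rows)
}
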