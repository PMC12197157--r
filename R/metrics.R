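# Diffusion-approximation penetration depth, wavelength selection,
# simulation-vs-measurement error and fluence-derived depth metrics.

#' Diffusion-approximation light penetration depth
#'
#' Depth at which irradiance falls to 1/e (~37%) of its incident value:
#' `sigma = 1 / sqrt(3 * mu_a * (mu_a + mu_s'))`, valid in the
#' scattering-dominated regime.
#'
#' @param mu_a Absorption coefficient(s), mm^-1.
#' @param mu_s_prime Reduced scattering coefficient(s), mm^-1.
#' @return Penetration depth(s) in mm; `NA` where `mu_a <= 0` (vectorized
#'   use masks rather than errors).
#' @export
penetration_depth <- function(mu_a, mu_s_prime) {
  if (any(mu_s_prime < 0, na.rm = TRUE)) stop("mu_s_prime must be >= 0")
  out <- 1 / sqrt(3 * mu_a * (mu_a + mu_s_prime))
  out[!is.na(mu_a) & mu_a <= 0] <- NA_real_
  out
}

#' Penetration-depth profile of a spectrum
#'
#' Element-wise [penetration_depth()] over an [optical_spectrum()].
#'
#' @param spectrum An [optical_spectrum()].
#' @return Data frame `wavelength_nm`, `sigma_mm` (class
#'   `penetration_profile`).
#' @export
penetration_profile <- function(spectrum) {
  out <- data.frame(wavelength_nm = spectrum$wavelengths_nm,
                    sigma_mm = penetration_depth(spectrum$mu_a,
                                                 spectrum$mu_s_prime))
  class(out) <- c("penetration_profile", "data.frame")
  out
}

#' Select wavelengths of extreme penetration-depth difference
#'
#' Returns the wavelengths at which `|sigma_a - sigma_b|` is largest and
#' smallest over a shared grid; ties break toward the smaller wavelength.
#'
#' @param profile_a,profile_b Profiles from [penetration_profile()] on the
#'   same wavelength grid.
#' @return List with `lambda_max_diff`, `lambda_min_diff` (nm) and the
#'   difference values.
#' @export
select_wavelengths <- function(profile_a, profile_b) {
  if (!identical(profile_a$wavelength_nm, profile_b$wavelength_nm))
    stop("profiles must share a wavelength grid")
  d <- abs(profile_a$sigma_mm - profile_b$sigma_mm)
  if (all(is.na(d)) || max(d, na.rm = TRUE) - min(d, na.rm = TRUE) < 1e-12)
    stop("degenerate difference: profiles are identical")
  wl <- profile_a$wavelength_nm
  # which.max/min return the first (smallest-wavelength) index on ties
  list(lambda_max_diff = wl[which.max(d)],
       lambda_min_diff = wl[which.min(d)],
       max_diff_mm = max(d, na.rm = TRUE),
       min_diff_mm = min(d, na.rm = TRUE))
}

#' Mean relative error between simulated and reference series, percent
#'
#' `100 * mean(|sim - ref| / ref)` over a shared grid.
#'
#' @param simulated,reference Numeric series; `reference` strictly positive.
#' @return Percent error (scalar, >= 0; scale-invariant under common
#'   positive rescaling).
#' @export
mean_relative_error_pct <- function(simulated, reference) {
  if (length(simulated) != length(reference))
    stop("series must share a grid")
  if (any(reference <= 0)) stop("reference values must be positive")
  100 * mean(abs(simulated - reference) / reference)
}

#' Depth at which fluence falls to 1/e of its sub-surface maximum
#'
#' For volumetric input the default profile is the laterally integrated
#' fluence per depth slab, which by superposition equals the on-axis fluence
#' of an equivalent broad beam — the quantity the diffusion penetration
#' depth describes.  (`lateral = "axis"` takes the beam-axis voxel column
#' instead; it decays faster for a pencil beam because of geometric
#' spreading.)  The returned depth is measured from the location of the
#' sub-surface maximum, with linear interpolation between voxel centres,
#' and is the first crossing below `max/e`.
#'
#' @param x An `mc_result`, a 3-D fluence array, or a numeric depth profile.
#' @param depths_mm Depth coordinates of the profile (voxel centres); derived
#'   automatically for `mc_result` input.
#' @param lateral `"integrated"` or `"axis"` (volumetric input only).
#' @return Depth in mm.
#' @export
fluence_1e_depth <- function(x, depths_mm = NULL,
                             lateral = c("integrated", "axis")) {
  lateral <- match.arg(lateral)
  if (inherits(x, "mc_result")) {
    if (is.null(depths_mm))
      depths_mm <- (seq_len(x$dims[3]) - 0.5) * x$voxel_size
    prof <- if (lateral == "integrated")
      apply(x$fluence, 3, sum, na.rm = TRUE)
    else {
      d <- x$dims
      x$fluence[d[1] %/% 2 + 1, d[2] %/% 2 + 1, ]
    }
  } else if (length(dim(x)) == 3) {
    if (is.null(depths_mm)) stop("depths_mm required for array input")
    prof <- if (lateral == "integrated") apply(x, 3, sum, na.rm = TRUE)
    else x[dim(x)[1] %/% 2 + 1, dim(x)[2] %/% 2 + 1, ]
  } else {
    prof <- as.numeric(x)
    if (is.null(depths_mm)) stop("depths_mm required for profile input")
  }
  if (length(prof) != length(depths_mm)) stop("profile/depth length mismatch")
  ok <- is.finite(prof)
  prof <- prof[ok]; depths_mm <- depths_mm[ok]
  imax <- which.max(prof)
  target <- prof[imax] / exp(1)
  below <- which(prof[imax:length(prof)] < target)
  if (length(below) == 0) stop("fluence never falls below 1/e of its maximum")
  j <- imax + below[1] - 1
  # linear interpolation between the bracketing voxel centres
  z1 <- depths_mm[j - 1]; z2 <- depths_mm[j]
  f1 <- prof[j - 1]; f2 <- prof[j]
  z_cross <- z1 + (f1 - target) / (f1 - f2) * (z2 - z1)
  z_cross - depths_mm[imax]
}

#' Laterally integrated (planar) fluence-depth profile
#'
#' @param result An `mc_result`.
#' @return Data frame `depth_mm`, `fluence` (arbitrary units).
#' @export
axial_fluence_profile <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  data.frame(depth_mm = (seq_len(result$dims[3]) - 0.5) * result$voxel_size,
             fluence = apply(result$fluence, 3, sum, na.rm = TRUE))
}
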