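# Optical-property spectra for potato tissue classes.
#
# Spectra carry the absorption coefficient mu_a and the reduced scattering
# coefficient mu_s' (both mm^-1) on an ascending wavelength grid, plus an
# anisotropy factor g.  Group mean spectra are parametric shapes pinned
# exactly through per-group anchor values at 490 and 805 nm.

TISSUE_GROUPS <- c("healthy", "slight", "blackhearted")

# Fixed shape constants of the generator (see the methods vignette).
.shape <- list(
  carotenoid_center = 490, carotenoid_sd = 45,   # pigment band, healthy only
  water_center = 980, water_sd = 30, water_amp = 0.04,  # water overtone band
  nir_rise_scale = 145, nir_rise_amp = 0.012,    # healthy mu_a rise above 805 nm
  bh_mua_decay = 150,                            # blackhearted mu_a exp decay, nm
  bh_musp_peak = 550, bh_musp_peak_ratio = 1.30 / 1.1649  # peak over 805 anchor
)

#' Construct an optical-property spectrum
#'
#' @param wavelengths_nm Strictly increasing wavelength grid in nm.
#' @param mu_a Absorption coefficient per wavelength, mm^-1, non-negative.
#' @param mu_s_prime Reduced scattering coefficient per wavelength, mm^-1,
#'   non-negative.
#' @param g Anisotropy factor in `[0, 1)`.  Default 0: the package works in
#'   reduced (similarity-relation) properties, `mu_s = mu_s'`.
#' @param allow_na Permit `NA` entries (used for masked inversion failures).
#' @return An object of class `optical_spectrum`: a list with the validated
#'   fields above.
#' @export
optical_spectrum <- function(wavelengths_nm, mu_a, mu_s_prime, g = 0,
                             allow_na = FALSE) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  mu_a <- as.numeric(mu_a)
  mu_s_prime <- as.numeric(mu_s_prime)
  n <- length(wavelengths_nm)
  if (length(mu_a) != n || length(mu_s_prime) != n)
    stop("wavelengths_nm, mu_a and mu_s_prime must have equal length")
  if (n == 0) stop("empty spectrum")
  if (any(!is.finite(wavelengths_nm)) || is.unsorted(wavelengths_nm, strictly = TRUE))
    stop("wavelengths must be finite and strictly increasing")
  chk <- function(x, nm) {
    bad <- if (allow_na) !is.na(x) & (!is.finite(x) | x < 0) else !is.finite(x) | x < 0
    if (any(bad)) stop(nm, " must be finite and non-negative")
  }
  chk(mu_a, "mu_a"); chk(mu_s_prime, "mu_s_prime")
  if (!is.numeric(g) || length(g) != 1 || g < 0 || g >= 1)
    stop("g must be a single value in [0, 1)")
  structure(list(wavelengths_nm = wavelengths_nm, mu_a = mu_a,
                 mu_s_prime = mu_s_prime, g = g),
            class = "optical_spectrum")
}

#' @export
print.optical_spectrum <- function(x, ...) {
  cat(sprintf("optical_spectrum: %d wavelengths (%g-%g nm), g = %g\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$g))
  cat(sprintf("  mu_a  : %.4g-%.4g mm^-1\n",
              min(x$mu_a, na.rm = TRUE), max(x$mu_a, na.rm = TRUE)))
  cat(sprintf("  mu_s' : %.4g-%.4g mm^-1\n",
              min(x$mu_s_prime, na.rm = TRUE), max(x$mu_s_prime, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.optical_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths_nm, mu_a_per_mm = x$mu_a,
             mu_s_prime_per_mm = x$mu_s_prime, g = x$g)
}

#' Interpolate a spectrum at given wavelengths
#'
#' Linear interpolation within the grid; exact at grid points.
#'
#' @param spectrum An [optical_spectrum()].
#' @param wavelengths_nm Query wavelengths (within the grid range).
#' @return A data frame with `wavelength_nm`, `mu_a_per_mm`, `mu_s_prime_per_mm`.
#' @export
spectrum_at <- function(spectrum, wavelengths_nm) {
  rng <- range(spectrum$wavelengths_nm)
  if (any(wavelengths_nm < rng[1] | wavelengths_nm > rng[2]))
    stop("query wavelength outside the spectrum grid")
  data.frame(
    wavelength_nm = wavelengths_nm,
    mu_a_per_mm = stats::approx(spectrum$wavelengths_nm, spectrum$mu_a,
                                wavelengths_nm)$y,
    mu_s_prime_per_mm = stats::approx(spectrum$wavelengths_nm, spectrum$mu_s_prime,
                                      wavelengths_nm)$y)
}

#' Default optical-property anchors per tissue group
#'
#' Pinned (mu_a, mu_s') pairs at 490 and 805 nm for healthy and blackhearted
#' medulla tissue.  Group mean spectra interpolate exactly through these
#' values; under the diffusion approximation they yield penetration depths of
#' 2.17 / 6.73 mm (healthy, 490 / 805 nm) and 0.45 / 1.30 mm (blackhearted).
#'
#' @return Data frame with columns `group`, `wavelength_nm`, `mu_a`, `mu_s_prime`.
#' @export
default_anchors <- function() {
  data.frame(
    group = rep(c("healthy", "blackhearted"), each = 2),
    wavelength_nm = c(490, 805, 490, 805),
    mu_a = c(0.0500, 0.0110, 0.9000, 0.1500),
    mu_s_prime = c(1.3658, 0.6581, 0.9290, 1.1649))
}

.anchor_row <- function(anchors, group, wl) {
  r <- anchors[anchors$group == group & anchors$wavelength_nm == wl, , drop = FALSE]
  if (nrow(r) != 1)
    stop("anchor table must contain exactly one row for group '", group,
         "' at ", wl, " nm")
  r
}

.gauss <- function(x, center, sd) exp(-0.5 * ((x - center) / sd)^2)

# Healthy mu_a: flat baseline + carotenoid Gaussian + water band + a
# quadratic rise above 805 nm (water absorption edge).  Baseline level and
# carotenoid amplitude solved exactly through the two anchors.
.healthy_mua <- function(wl, a490, a805) {
  s <- .shape
  water <- s$water_amp * .gauss(wl, s$water_center, s$water_sd)
  rise <- s$nir_rise_amp * pmax(0, (wl - 805) / s$nir_rise_scale)^2
  car <- .gauss(wl, s$carotenoid_center, s$carotenoid_sd)
  # [1 car(805); 1 car(490)] %*% c(a0, A) = anchors minus fixed terms
  c805 <- .gauss(805, s$carotenoid_center, s$carotenoid_sd)
  rhs1 <- a805 - s$water_amp * .gauss(805, s$water_center, s$water_sd)
  rhs2 <- a490 - s$water_amp * .gauss(490, s$water_center, s$water_sd)
  A <- (rhs2 - rhs1) / (1 - c805)
  a0 <- rhs1 - A * c805
  if (A <= 0)
    warning("anchors give a non-positive pigment band; 490 nm peak absent")
  a0 + A * car + water + rise
}

# Blackhearted mu_a: declining exponential + water band, no pigment peak.
.bh_mua <- function(wl, a490, a805) {
  s <- .shape
  water <- s$water_amp * .gauss(wl, s$water_center, s$water_sd)
  e490 <- exp(-490 / s$bh_mua_decay); e805 <- exp(-805 / s$bh_mua_decay)
  w490 <- s$water_amp * .gauss(490, s$water_center, s$water_sd)
  w805 <- s$water_amp * .gauss(805, s$water_center, s$water_sd)
  p1 <- ((a490 - w490) - (a805 - w805)) / (e490 - e805)
  p0 <- (a805 - w805) - p1 * e805
  p0 + p1 * exp(-wl / s$bh_mua_decay) + water
}

# Healthy mu_s': decreasing power law through the two anchors.
.healthy_musp <- function(wl, s490, s805) {
  b <- log(s490 / s805) / log(805 / 490)
  s490 * (490 / wl)^b
}

# Blackhearted mu_s': asymmetric Gaussian peaked at 550 nm — rises over
# 450-550 nm, decreases over 550-1000 nm; flank widths solved through the
# anchors given the fixed peak/805-anchor ratio.
.bh_musp <- function(wl, s490, s805) {
  s <- .shape
  P <- s$bh_musp_peak_ratio * s805
  if (P <= s490 || P <= s805)
    stop("blackhearted mu_s' anchors incompatible with a 550 nm peak")
  pk <- s$bh_musp_peak
  sd_l <- (pk - 490) / sqrt(2 * log(P / s490))
  sd_r <- (805 - pk) / sqrt(2 * log(P / s805))
  ifelse(wl < pk, P * .gauss(wl, pk, sd_l), P * .gauss(wl, pk, sd_r))
}

#' Generate a group mean optical-property spectrum
#'
#' Builds the parametric mean spectrum of a tissue class on the given grid.
#' Healthy absorption shows a carotenoid band at 490 nm and a water band at
#' 980 nm; blackhearted absorption is elevated (notably over 550-850 nm) with
#' no pigment peak; blackhearted reduced scattering rises over 450-550 nm and
#' falls beyond.  Mean spectra pass exactly through the anchor table values.
#' The slightly blackhearted class is a convex mixture of the two.
#'
#' @param group One of `"healthy"`, `"slight"`, `"blackhearted"`.
#' @param wavelengths Ascending grid in nm within `[400, 1000]`.
#' @param anchors Anchor table as from [default_anchors()].
#' @param g Anisotropy factor attached to the spectrum.
#' @param slight_weight Mixture weight of the blackhearted mean for the
#'   `"slight"` class.
#' @return An [optical_spectrum()].
#' @export
generate_group_spectrum <- function(group, wavelengths = seq(400, 1000, by = 5),
                                    anchors = default_anchors(), g = 0,
                                    slight_weight = 0.5) {
  group <- match.arg(group, TISSUE_GROUPS)
  if (any(wavelengths < 400 | wavelengths > 1000))
    stop("wavelengths outside the supported 400-1000 nm range")
  if (group == "slight") {
    h <- generate_group_spectrum("healthy", wavelengths, anchors, g)
    b <- generate_group_spectrum("blackhearted", wavelengths, anchors, g)
    return(optical_spectrum(
      wavelengths,
      (1 - slight_weight) * h$mu_a + slight_weight * b$mu_a,
      (1 - slight_weight) * h$mu_s_prime + slight_weight * b$mu_s_prime, g))
  }
  a490 <- .anchor_row(anchors, group, 490)
  a805 <- .anchor_row(anchors, group, 805)
  if (any(c(a490$mu_a, a805$mu_a, a490$mu_s_prime, a805$mu_s_prime) < 0))
    stop("anchors must be non-negative")
  if (group == "healthy") {
    mua <- .healthy_mua(wavelengths, a490$mu_a, a805$mu_a)
    musp <- .healthy_musp(wavelengths, a490$mu_s_prime, a805$mu_s_prime)
  } else {
    mua <- .bh_mua(wavelengths, a490$mu_a, a805$mu_a)
    musp <- .bh_musp(wavelengths, a490$mu_s_prime, a805$mu_s_prime)
  }
  optical_spectrum(wavelengths, mua, musp, g)
}

#' Write / read spectrum CSV
#'
#' Columns: `wavelength_nm, mu_a_per_mm, mu_s_prime_per_mm, g`.
#'
#' @param spectrum An [optical_spectrum()].
#' @param path File path.
#' @return `read_spectrum_csv` returns an [optical_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  optical_spectrum(d$wavelength_nm, d$mu_a_per_mm, d$mu_s_prime_per_mm,
                   g = d$g[1])
}
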