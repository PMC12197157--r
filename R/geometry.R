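# Layered voxel geometries for the potato tuber simulations.

#' Construct a voxel geometry
#'
#' @param medium Integer 3-D array (nx, ny, nz) of 1-based medium ids.
#' @param media Data frame with one row per medium: `id`, `name`, `mu_a`,
#'   `mu_s`, `g`, `n`.
#' @param voxel_size Voxel edge length, mm.
#' @param n_outside Refractive index of the ambient medium (air).
#' @param lateral_boundary `"open"` (photons escape through the sides) or
#'   `"mirror"` (specular side walls; exact for laterally homogeneous media,
#'   emulating a laterally infinite medium).
#' @param beam Beam description: list with `profile` (`"pencil"` or
#'   `"gaussian"`), `sigma_mm` (Gaussian radial sd) and optional `entry`
#'   voxel (ix, iy; 1-based, defaults to the top-face centre voxel).
#' @return A `voxel_geometry` object.
#' @export
voxel_geometry <- function(medium, media, voxel_size = 0.5, n_outside = 1.0,
                           lateral_boundary = c("open", "mirror"),
                           beam = list(profile = "pencil", sigma_mm = 0)) {
  lateral_boundary <- match.arg(lateral_boundary)
  if (length(dim(medium)) != 3) stop("medium must be a 3-D array")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  need <- c("id", "mu_a", "mu_s", "g", "n")
  if (!all(need %in% names(media))) stop("media table missing columns")
  if (!all(unique(as.vector(medium)) %in% media$id))
    stop("every voxel medium id must exist in the media table")
  if (any(media$mu_a < 0 | media$mu_s < 0 | media$n < 1 |
            media$g < 0 | media$g >= 1))
    stop("invalid media optical properties")
  media <- media[order(media$id), , drop = FALSE]
  if (!identical(as.integer(media$id), seq_len(nrow(media))))
    stop("media ids must be 1..k")
  if (is.null(beam$profile)) beam$profile <- "pencil"
  if (is.null(beam$sigma_mm)) beam$sigma_mm <- 0
  if (is.null(beam$entry))
    beam$entry <- c(dim(medium)[1] %/% 2 + 1, dim(medium)[2] %/% 2 + 1)
  structure(list(medium = medium, media = media, voxel_size = voxel_size,
                 n_outside = n_outside, lateral_boundary = lateral_boundary,
                 beam = beam),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  d <- dim(x$medium)
  cat(sprintf("voxel_geometry: %d x %d x %d voxels of %g mm (depth %g mm)\n",
              d[1], d[2], d[3], x$voxel_size, d[3] * x$voxel_size))
  cat(sprintf("  media: %s; lateral boundary: %s\n",
              paste(x$media$name, collapse = ", "), x$lateral_boundary))
  invisible(x)
}

# Optical properties of one medium at a single wavelength.
.medium_at <- function(spectrum, wavelength_nm, use_reduced = TRUE) {
  v <- spectrum_at(spectrum, wavelength_nm)
  g <- if (use_reduced) 0 else spectrum$g
  mus <- if (use_reduced) v$mu_s_prime_per_mm else
    v$mu_s_prime_per_mm / (1 - spectrum$g)
  list(mu_a = v$mu_a_per_mm, mu_s = mus, g = g)
}

#' Default peel optical properties
#'
#' Peel properties are not independently characterized; the default scales
#' the healthy flesh coefficients (`mu_a` x 2, `mu_s'` x 1.5) and keeps
#' n = 1.34.  Configurable wherever a peel medium is used.
#'
#' @param healthy Healthy flesh [optical_spectrum()].
#' @return An [optical_spectrum()] for peel tissue.
#' @export
default_peel_spectrum <- function(healthy) {
  optical_spectrum(healthy$wavelengths_nm, 2 * healthy$mu_a,
                   1.5 * healthy$mu_s_prime, healthy$g)
}

.snap_layers <- function(thicknesses_mm, voxel_size) {
  nv <- round(thicknesses_mm / voxel_size)
  snapped <- nv * voxel_size
  off <- abs(snapped - thicknesses_mm) > 1e-9
  if (any(off))
    warning(sprintf(
      "layer thickness snapped to voxel planes: %s",
      paste(sprintf("%g -> %g mm", thicknesses_mm[off], snapped[off]),
            collapse = ", ")))
  if (any(nv < 1)) stop("layer thinner than one voxel")
  as.integer(nv)
}

#' Build a potato tissue simulation geometry
#'
#' Three layered models: `"slice"` is a single 2 mm layer of test tissue;
#' `"half"` stacks test (2 mm), healthy flesh (28 mm) and peel (0.5 mm),
#' beam incident on the test layer (30.5 mm total); `"whole"` stacks peel
#' (0.5), healthy (28), two 2 mm central test layers, healthy (28) and peel
#' (0.5), 61 mm total.  Layer boundaries snap to voxel planes with an
#' explicit warning when a thickness is not a voxel multiple.
#'
#' @param model `"slice"`, `"half"` or `"whole"`.
#' @param wavelength_nm Wavelength at which media are evaluated.
#' @param op_test Test-tissue [optical_spectrum()] (the healthy or
#'   blackhearted class under study).
#' @param op_healthy Healthy flesh spectrum (defaults to `op_test`).
#' @param op_peel Peel spectrum; default [default_peel_spectrum()] of the
#'   healthy flesh.
#' @param voxel_size Voxel edge, mm (default 0.5).
#' @param lateral_voxels Lateral extent in voxels for x and y (default 60).
#' @param n_outside Ambient refractive index.
#' @param use_reduced Run in reduced properties (g = 0, `mu_s = mu_s'`);
#'   otherwise `mu_s = mu_s' / (1 - g)` with the spectrum's g.
#' @param beam Beam description (see [voxel_geometry()]).
#' @return A [voxel_geometry()].
#' @export
build_geometry <- function(model = c("slice", "half", "whole"),
                           wavelength_nm, op_test, op_healthy = op_test,
                           op_peel = NULL, voxel_size = 0.5,
                           lateral_voxels = 60, n_outside = 1.0,
                           use_reduced = TRUE,
                           beam = list(profile = "pencil", sigma_mm = 0)) {
  model <- match.arg(model)
  if (is.null(op_peel)) op_peel <- default_peel_spectrum(op_healthy)
  test <- .medium_at(op_test, wavelength_nm, use_reduced)
  heal <- .medium_at(op_healthy, wavelength_nm, use_reduced)
  peel <- .medium_at(op_peel, wavelength_nm, use_reduced)
  n_tissue <- 1.34
  media <- data.frame(
    id = 1:3, name = c("test", "healthy", "peel"),
    mu_a = c(test$mu_a, heal$mu_a, peel$mu_a),
    mu_s = c(test$mu_s, heal$mu_s, peel$mu_s),
    g = c(test$g, heal$g, peel$g),
    n = rep(n_tissue, 3))
  layers <- switch(model,
    slice = data.frame(id = 1L, mm = 2),
    half = data.frame(id = c(1L, 2L, 3L), mm = c(2, 28, 0.5)),
    whole = data.frame(id = c(3L, 2L, 1L, 1L, 2L, 3L),
                       mm = c(0.5, 28, 2, 2, 28, 0.5)))
  nv <- .snap_layers(layers$mm, voxel_size)
  nz <- sum(nv)
  med <- array(rep(rep(layers$id, nv), each = lateral_voxels * lateral_voxels),
               dim = c(lateral_voxels, lateral_voxels, nz))
  g <- voxel_geometry(med, media, voxel_size, n_outside,
                      lateral_boundary = "open", beam = beam)
  g$model <- model
  g$wavelength_nm <- wavelength_nm
  g$layers <- data.frame(name = media$name[layers$id], id = layers$id,
                         thickness_mm = nv * voxel_size)
  g
}

#' Homogeneous (optionally laterally infinite) geometry
#'
#' A deep homogeneous block used for semi-infinite medium simulations, e.g.
#' diffusion-regime checks and the wavelength-resolved energy budget.  With
#' `lateral_boundary = "mirror"` the side walls are specular, which by
#' symmetry reproduces a laterally infinite medium exactly.
#'
#' @param mu_a,mu_s,g,n Optical properties of the medium.
#' @param depth_mm Block depth, mm.
#' @param voxel_size Voxel edge, mm.
#' @param lateral_voxels Lateral extent in voxels.
#' @param lateral_boundary `"mirror"` (default) or `"open"`.
#' @param n_outside Ambient index.
#' @return A [voxel_geometry()].
#' @export
homogeneous_geometry <- function(mu_a, mu_s, g = 0, n = 1.34, depth_mm = 60,
                                 voxel_size = 1, lateral_voxels = 8,
                                 lateral_boundary = "mirror",
                                 n_outside = 1.0) {
  nz <- .snap_layers(depth_mm, voxel_size)
  med <- array(1L, dim = c(lateral_voxels, lateral_voxels, nz))
  media <- data.frame(id = 1L, name = "medium", mu_a = mu_a, mu_s = mu_s,
                      g = g, n = n)
  voxel_geometry(med, media, voxel_size, n_outside,
                 lateral_boundary = lateral_boundary)
}
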