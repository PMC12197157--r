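# Synthetic cohorts: per-sample optical-property spectra plus forward-modeled
# noisy integrating-sphere measurement records.

#' Cohort specification
#'
#' @param n_per_group Samples per tissue group (>= 2 for classification use).
#' @param groups Subset of `c("healthy", "slight", "blackhearted")`.
#' @param anchors Anchor table (see [default_anchors()]).
#' @param cv Between-sample coefficient of variation of the lognormal
#'   multiplicative factors applied to each coefficient family (default 10%).
#' @param noise Multiplicative Gaussian measurement noise level on R_t/T_t
#'   (default 1%).
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @param wavelengths Spectral grid, nm (within 400-1000).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 40,
                        groups = c("healthy", "blackhearted"),
                        anchors = default_anchors(), cv = 0.10,
                        noise = 0.01, seed = 1,
                        wavelengths = seq(400, 1000, by = 5)) {
  groups <- match.arg(groups, TISSUE_GROUPS, several.ok = TRUE)
  if (length(groups) == 0) stop("empty group list")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (cv < 0 || noise < 0) stop("cv and noise must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 anchors = anchors, cv = cv, noise = noise,
                 seed = as.integer(seed), wavelengths = wavelengths),
            class = "cohort_spec")
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic measurement cohort
#'
#' For each sample the group mean spectrum is perturbed by one lognormal
#' multiplicative factor per coefficient family (spectrally smooth, mean 1,
#' coefficient of variation `spec$cv`), then the slab forward model
#' ([slab_rt()]) produces a per-wavelength (R_t, T_t) measurement record
#' with multiplicative Gaussian noise at level `spec$noise`.  A fixed seed
#' yields a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param slab_thickness_mm Sample slice thickness, mm (default 2).
#' @param n_slab,n_outside Refractive indices (defaults 1.34 / 1.0).
#' @param quadrature_order Passed to [slab_rt()].
#' @return A `tissue_cohort`: list of samples, each with `id`, `group`,
#'   `spectrum` ([optical_spectrum()]) and `record` (data frame
#'   `wavelength_nm, R_t, T_t, thickness_mm, n`).
#' @export
generate_cohort <- function(spec, slab_thickness_mm = 2, n_slab = 1.34,
                            n_outside = 1.0, quadrature_order = 16) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (slab_thickness_mm <= 0) stop("thickness must be positive")
  means <- lapply(spec$groups, generate_group_spectrum,
                  wavelengths = spec$wavelengths, anchors = spec$anchors)
  names(means) <- spec$groups
  sdlog <- sqrt(log(1 + spec$cv^2))
  samples <- with_local_seed(spec$seed, {
    out <- list()
    for (grp in spec$groups) {
      mean_sp <- means[[grp]]
      for (k in seq_len(spec$n_per_group)) {
        fa <- if (spec$cv > 0)
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        fs <- if (spec$cv > 0)
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        sp <- optical_spectrum(mean_sp$wavelengths_nm, fa * mean_sp$mu_a,
                               fs * mean_sp$mu_s_prime, mean_sp$g)
        rt <- vapply(seq_along(sp$wavelengths_nm), function(i) {
          v <- slab_rt(sp$mu_a[i], sp$mu_s_prime[i], slab_thickness_mm,
                       g = sp$g, n_slab = n_slab, n_outside = n_outside,
                       quadrature_order = quadrature_order)
          c(v$R_t, v$T_t)
        }, numeric(2))
        R_t <- rt[1, ]; T_t <- rt[2, ]
        if (spec$noise > 0) {
          R_t <- pmax(0, R_t * (1 + stats::rnorm(length(R_t), 0, spec$noise)))
          T_t <- pmax(0, T_t * (1 + stats::rnorm(length(T_t), 0, spec$noise)))
        }
        out[[length(out) + 1]] <- list(
          id = sprintf("%s_%02d", grp, k), group = grp, spectrum = sp,
          record = data.frame(wavelength_nm = sp$wavelengths_nm,
                              R_t = R_t, T_t = T_t,
                              thickness_mm = slab_thickness_mm, n = n_slab))
      }
    }
    out
  })
  structure(list(samples = samples, spec = spec,
                 group_means = means,
                 slab_thickness_mm = slab_thickness_mm, n_slab = n_slab),
            class = "tissue_cohort")
}

#' @export
print.tissue_cohort <- function(x, ...) {
  grp <- vapply(x$samples, `[[`, "", "group")
  cat("tissue_cohort:", length(x$samples), "samples (",
      paste(sprintf("%s: %d", names(table(grp)), table(grp)), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Extract an optical feature matrix from a cohort
#'
#' Builds the samples x features matrix of one optical quantity evaluated at
#' selected wavelengths (default the 490/805 nm pair), with group labels.
#'
#' @param cohort A `tissue_cohort`.
#' @param kind One of `"T_t"`, `"R_t"`, `"mu_a"`, `"mu_s_prime"`.
#' @param wavelengths Feature wavelengths, nm; `NULL` uses the full grid.
#' @return A `feature_matrix`: list with `x` (numeric matrix), `labels`
#'   (factor) and `kind`.
#' @export
cohort_features <- function(cohort, kind = c("mu_a", "mu_s_prime", "T_t", "R_t"),
                            wavelengths = c(490, 805)) {
  stopifnot(inherits(cohort, "tissue_cohort"))
  kind <- match.arg(kind)
  grid <- cohort$spec$wavelengths
  if (is.null(wavelengths)) wavelengths <- grid
  rows <- lapply(cohort$samples, function(s) {
    src <- switch(kind,
      mu_a = stats::approx(grid, s$spectrum$mu_a, wavelengths)$y,
      mu_s_prime = stats::approx(grid, s$spectrum$mu_s_prime, wavelengths)$y,
      T_t = stats::approx(grid, s$record$T_t, wavelengths)$y,
      R_t = stats::approx(grid, s$record$R_t, wavelengths)$y)
    src
  })
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("%s_%gnm", kind, wavelengths)
  rownames(x) <- vapply(cohort$samples, `[[`, "", "id")
  feature_matrix(x, factor(vapply(cohort$samples, `[[`, "", "group")), kind)
}

#' Construct a feature matrix for discrimination
#'
#' @param x Numeric matrix, samples in rows.
#' @param labels Factor of group labels (two classes, >= 2 samples each).
#' @param kind Feature kind tag.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, labels, kind = "feature") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  labels <- factor(labels)
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  if (any(!is.finite(x))) stop("feature matrix contains missing values")
  if (nlevels(droplevels(labels)) < 2) stop("need at least two classes")
  if (any(table(droplevels(labels)) < 2)) stop("need >= 2 samples per class")
  structure(list(x = x, labels = droplevels(labels), kind = kind),
            class = "feature_matrix")
}

#' Write / read cohort measurement CSV
#'
#' Long format, one row per sample x wavelength:
#' `sample_id, group, wavelength_nm, R_t, T_t, thickness_mm, n`.
#'
#' @param cohort A `tissue_cohort`.
#' @param path File path.
#' @return `read_measurements_csv` returns the long data frame.
#' @export
write_measurements_csv <- function(cohort, path) {
  rows <- lapply(cohort$samples, function(s)
    cbind(data.frame(sample_id = s$id, group = s$group), s$record))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  utils::read.csv(path)
}
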