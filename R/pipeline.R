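# End-to-end analysis pipeline: generate -> forward-measure -> invert ->
# penetration/selection -> Monte Carlo in three geometries -> energy budgets
# and maps -> classification -> manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with the package defaults.
#' Any field can be overridden; the resolved configuration is written next
#' to the outputs of each run.
#'
#' @param cohort A [cohort_spec()].
#' @param slab_thickness_mm,n_slab,n_outside Slab measurement model.
#' @param quadrature_order Adding-doubling quadrature order.
#' @param mc An [mc_config()] (desk-scale default 1e6 photons; raise
#'   `n_photons` to the reference 1e8 for production maps).
#' @param voxel_size,lateral_voxels Voxel grid for the geometry builders.
#' @param geometries Geometry models to simulate.
#' @param test_groups Tissue classes simulated as the test medium.
#' @param selected_wavelengths Override for the two analysis wavelengths;
#'   `NULL` selects them from the penetration-depth profiles
#'   ([select_wavelengths()] plus the fixed pigment-band wavelength 490 nm
#'   when the minimal-difference wavelength coincides with the maximal one).
#' @param classifier_models,classifier_features Models and feature kinds to
#'   evaluate.
#' @param pls_components,svm_cost Classifier settings.
#' @param invert_ops Recover per-sample optical properties from the noisy
#'   records at the selected wavelengths (slower; default FALSE uses the
#'   generated spectra directly).
#' @param budget_wavelengths Wavelength grid for the energy-budget spectrum.
#' @param budget_photons Photons per budget wavelength.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            slab_thickness_mm = 2, n_slab = 1.34,
                            n_outside = 1.0, quadrature_order = 16,
                            mc = mc_config(n_photons = 1e6, seed = 7),
                            voxel_size = 0.5, lateral_voxels = 60,
                            geometries = c("slice", "half", "whole"),
                            test_groups = c("healthy", "blackhearted"),
                            selected_wavelengths = NULL,
                            classifier_models = c("plsda", "svmda"),
                            classifier_features = c("T_t", "R_t", "mu_a",
                                                    "mu_s_prime"),
                            pls_components = 2, svm_cost = 1,
                            invert_ops = FALSE,
                            budget_wavelengths = seq(400, 1000, by = 50),
                            budget_photons = 5e3) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order and writes every artifact below `out_dir`:
#' group mean and per-sample optical-property spectra (CSV), measurement
#' records (CSV), penetration-depth profiles (CSV), selected wavelengths
#' (JSON), per-geometry Monte Carlo energy budgets (CSV) and absorbed-energy
#' maps (NRRD), an energy-budget spectrum (CSV), a simulated-vs-measured
#' relative-error table (CSV), classification reports (JSON + CSV), and a
#' manifest (JSON) listing every artifact with its MD5 checksum.  The run is
#' fully reproducible from the configuration and seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly (list with `artifacts`, `selected`,
#'   `budgets`, `classification`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character()
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(.serialize_config(config), cfg_path)
  keep(cfg_path)

  # 1. cohort generation (spectra + forward-modeled measurements)
  say("stage 1/6: generating cohort (%d/group: %s)",
      config$cohort$n_per_group, paste(config$cohort$groups, collapse = ", "))
  cohort <- generate_cohort(config$cohort, config$slab_thickness_mm,
                            config$n_slab, config$n_outside,
                            config$quadrature_order)
  for (grp in config$cohort$groups)
    keep(write_spectrum_csv(cohort$group_means[[grp]],
                            file.path(out_dir, sprintf("mean_ops_%s.csv", grp))))
  keep(write_measurements_csv(cohort, file.path(out_dir, "measurements.csv")))

  # 2. penetration profiles + wavelength selection
  say("stage 2/6: penetration profiles and wavelength selection")
  profiles <- lapply(cohort$group_means, penetration_profile)
  for (grp in names(profiles)) {
    p <- file.path(out_dir, sprintf("penetration_%s.csv", grp))
    utils::write.csv(profiles[[grp]], p, row.names = FALSE)
    keep(p)
  }
  if (is.null(config$selected_wavelengths)) {
    ref <- intersect(c("healthy", "blackhearted"), names(profiles))
    if (length(ref) == 2) {
      sel <- select_wavelengths(profiles[[ref[1]]], profiles[[ref[2]]])
      wls <- sort(unique(c(sel$lambda_max_diff, 490)))
    } else wls <- c(490, 805)
  } else wls <- sort(config$selected_wavelengths)
  sel_path <- file.path(out_dir, "selected_wavelengths.json")
  jsonlite::write_json(list(wavelengths_nm = wls), sel_path, auto_unbox = FALSE)
  keep(sel_path)

  # 3. optional optical-property recovery from the noisy records
  if (config$invert_ops) {
    say("stage 3/6: recovering optical properties at selected wavelengths")
    rec <- .recover_ops(cohort, wls, config)
    p <- file.path(out_dir, "recovered_ops.csv")
    utils::write.csv(rec, p, row.names = FALSE)
    keep(p)
  } else say("stage 3/6: optical-property recovery skipped (invert_ops = FALSE)")

  # 4. Monte Carlo in the requested geometries
  say("stage 4/6: Monte Carlo (%d geometries x %d tissues x %d wavelengths)",
      length(config$geometries), length(config$test_groups), length(wls))
  healthy_mean <- cohort$group_means[["healthy"]] %||%
    generate_group_spectrum("healthy", config$cohort$wavelengths,
                            config$cohort$anchors)
  budget_rows <- list()
  run_id <- 0
  for (gm in config$geometries) for (tg in config$test_groups) for (wl in wls) {
    run_id <- run_id + 1
    test_sp <- cohort$group_means[[tg]] %||%
      generate_group_spectrum(tg, config$cohort$wavelengths,
                              config$cohort$anchors)
    geo <- build_geometry(gm, wl, op_test = test_sp,
                          op_healthy = healthy_mean,
                          voxel_size = config$voxel_size,
                          lateral_voxels = config$lateral_voxels,
                          n_outside = config$n_outside)
    cfg <- config$mc
    cfg$seed <- cfg$seed + run_id
    res <- run_mc(geo, cfg)
    budget_rows[[run_id]] <- data.frame(
      geometry = gm, tissue = tg, wavelength_nm = wl,
      specular = res$specular, R_d = res$R_d, T = res$T, A = res$A,
      n_photons = cfg$n_photons, seed = cfg$seed)
    map_path <- file.path(out_dir,
                          sprintf("map_%s_%s_%gnm.nrrd", gm, tg, wl))
    keep(write_nrrd(res$absorbed_energy, map_path, config$voxel_size))
  }
  budgets <- do.call(rbind, budget_rows)
  p <- file.path(out_dir, "mc_budgets.csv")
  utils::write.csv(budgets, p, row.names = FALSE)
  keep(p)

  # wavelength-resolved semi-infinite energy budget per tissue class
  budget_spec <- do.call(rbind, lapply(config$test_groups, function(tg) {
    sp <- cohort$group_means[[tg]] %||%
      generate_group_spectrum(tg, config$cohort$wavelengths,
                              config$cohort$anchors)
    b <- energy_budget_spectrum(sp, config$budget_wavelengths,
                                n_photons = config$budget_photons,
                                seed = config$mc$seed)
    cbind(tissue = tg, b)
  }))
  p <- file.path(out_dir, "energy_budget_spectrum.csv")
  utils::write.csv(budget_spec, p, row.names = FALSE)
  keep(p)

  # 5. simulated-vs-measured validation errors (slab forward model vs the
  # noisy cohort records, per group)
  say("stage 5/6: simulation validation errors")
  val <- .validation_errors(cohort)
  p <- file.path(out_dir, "validation_errors.csv")
  utils::write.csv(val, p, row.names = FALSE)
  keep(p)

  # 6. classification
  say("stage 6/6: classification")
  cls_groups <- intersect(c("healthy", "blackhearted"), config$cohort$groups)
  reports <- list()
  if (length(cls_groups) == 2) {
    keep_samples <- vapply(cohort$samples, `[[`, "", "group") %in% cls_groups
    sub <- cohort; sub$samples <- cohort$samples[keep_samples]
    for (fk in config$classifier_features) for (md in config$classifier_models) {
      feats <- cohort_features(sub, fk, wls)
      rep <- if (md == "plsda")
        evaluate_discrimination("plsda", feats, seed = config$mc$seed,
                                n_components = config$pls_components)
      else
        evaluate_discrimination("svmda", feats, seed = config$mc$seed,
                                cost = config$svm_cost)
      reports[[sprintf("%s_%s", md, fk)]] <- rep
    }
    tbl <- do.call(rbind, lapply(reports, report_as_row))
    p <- file.path(out_dir, "classification_table.csv")
    utils::write.csv(tbl, p, row.names = FALSE)
    keep(p)
    p <- file.path(out_dir, "classification_reports.json")
    jsonlite::write_json(
      lapply(reports, function(r) r[c("model", "feature_kind", "calibration",
                                      "cross_validation", "seed")]),
      p, auto_unbox = TRUE, digits = NA)
    keep(p)
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    selected_wavelengths_nm = wls,
    n_mc_runs = run_id,
    artifacts = data.frame(path = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  say("done: %d artifacts in %s", length(artifacts), out_dir)
  invisible(list(out_dir = out_dir, manifest = manifest, budgets = budgets,
                 budget_spectrum = budget_spec, selected = wls,
                 classification = reports, validation = val))
}

.serialize_config <- function(config) {
  c(lapply(config[setdiff(names(config), c("cohort", "mc"))], function(v)
      if (is.null(v)) "auto" else v),
    list(cohort = unclass(config$cohort)[setdiff(names(config$cohort),
                                                 "anchors")],
         anchors = config$cohort$anchors,
         mc = unclass(config$mc)))
}

.recover_ops <- function(cohort, wavelengths, config) {
  rows <- lapply(cohort$samples, function(s) {
    rec <- s$record[s$record$wavelength_nm %in% wavelengths, , drop = FALSE]
    sp <- extract_op_spectrum(rec, cohort$slab_thickness_mm,
                              n_slab = cohort$n_slab,
                              n_outside = config$n_outside,
                              quadrature_order = config$quadrature_order)
    data.frame(sample_id = s$id, group = s$group,
               wavelength_nm = sp$wavelengths_nm,
               mu_a_per_mm = sp$mu_a, mu_s_prime_per_mm = sp$mu_s_prime)
  })
  do.call(rbind, rows)
}

# Mean absolute relative error between the noise-free slab forward model of
# each group mean and the group's measured (noisy) records.
.validation_errors <- function(cohort) {
  grid <- cohort$spec$wavelengths
  do.call(rbind, lapply(names(cohort$group_means), function(grp) {
    mean_sp <- cohort$group_means[[grp]]
    sim <- vapply(seq_along(grid), function(i) {
      v <- slab_rt(mean_sp$mu_a[i], mean_sp$mu_s_prime[i],
                   cohort$slab_thickness_mm, g = mean_sp$g,
                   n_slab = cohort$n_slab)
      c(v$R_t, v$T_t)
    }, numeric(2))
    grp_samples <- Filter(function(s) s$group == grp, cohort$samples)
    meas_R <- rowMeans(vapply(grp_samples, function(s) s$record$R_t,
                              numeric(length(grid))))
    meas_T <- rowMeans(vapply(grp_samples, function(s) s$record$T_t,
                              numeric(length(grid))))
    data.frame(group = grp,
               reflectance_error_pct = mean_relative_error_pct(sim[1, ], meas_R),
               transmittance_error_pct = mean_relative_error_pct(sim[2, ], meas_T))
  }))
}
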