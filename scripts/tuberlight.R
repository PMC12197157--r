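#!/usr/bin/env Rscript
# Thin command-line wrapper over the tuberlight package.
#
#   Rscript scripts/tuberlight.R <command> [options]
#
# Commands:
#   run                  full pipeline from a YAML config (or defaults)
#   simulate-cohort      write synthetic measurement records as CSV
#   extract-ops          recover optical properties from measurement CSV
#   penetration          penetration-depth profile of a spectrum CSV
#   select-wavelengths   extreme depth-difference wavelengths of two profiles
#   mc-run               Monte Carlo run in a named geometry
#   classify             fit/evaluate a discriminant model on a cohort CSV

suppressPackageStartupMessages({
  library(optparse)
  library(tuberlight)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args) >= 1) args[1] else "help"
rest <- args[-1]

op <- function(...) parse_args(OptionParser(option_list = list(...)),
                               args = rest)

group_spectrum <- function(group, wl = seq(400, 1000, 5))
  generate_group_spectrum(group, wavelengths = wl)

switch(cmd,
  "run" = {
    o <- op(make_option("--config", default = NULL),
            make_option("--out", default = "tuberlight-run"),
            make_option("--seed", type = "integer", default = 7))
    cfg <- pipeline_config(cohort = cohort_spec(seed = o$seed),
                           mc = mc_config(n_photons = 1e6, seed = o$seed))
    if (!is.null(o$config)) {
      y <- yaml::read_yaml(o$config)
      if (!is.null(y$n_photons)) cfg$mc$n_photons <- y$n_photons
      if (!is.null(y$n_per_group)) cfg$cohort$n_per_group <- y$n_per_group
      if (!is.null(y$lateral_voxels)) cfg$lateral_voxels <- y$lateral_voxels
      if (!is.null(y$selected_wavelengths))
        cfg$selected_wavelengths <- y$selected_wavelengths
    }
    run_pipeline(cfg, o$out)
  },
  "simulate-cohort" = {
    o <- op(make_option("--n-per-group", type = "integer", default = 40),
            make_option("--cv", type = "double", default = 0.10),
            make_option("--noise", type = "double", default = 0.01),
            make_option("--seed", type = "integer", default = 7),
            make_option("--out", default = "cohort.csv"))
    co <- generate_cohort(cohort_spec(n_per_group = o$`n-per-group`,
                                      cv = o$cv, noise = o$noise,
                                      seed = o$seed))
    write_measurements_csv(co, o$out)
    cat("wrote", o$out, "\n")
  },
  "extract-ops" = {
    o <- op(make_option("--measurements", type = "character"),
            make_option("--thickness-mm", type = "double", default = 2),
            make_option("--n", type = "double", default = 1.34),
            make_option("--g", type = "double", default = 0),
            make_option("--out", default = "recovered_ops.csv"))
    d <- read_measurements_csv(o$measurements)
    out <- do.call(rbind, lapply(split(d, d$sample_id), function(rec) {
      sp <- extract_op_spectrum(rec, o$`thickness-mm`, n_slab = o$n,
                                g_assumed = o$g)
      data.frame(sample_id = rec$sample_id[1], group = rec$group[1],
                 wavelength_nm = sp$wavelengths_nm, mu_a_per_mm = sp$mu_a,
                 mu_s_prime_per_mm = sp$mu_s_prime)
    }))
    utils::write.csv(out, o$out, row.names = FALSE)
    cat("wrote", o$out, "\n")
  },
  "penetration" = {
    o <- op(make_option("--spectrum", type = "character"),
            make_option("--out", default = "penetration.csv"))
    prof <- penetration_profile(read_spectrum_csv(o$spectrum))
    utils::write.csv(prof, o$out, row.names = FALSE)
    cat("wrote", o$out, "\n")
  },
  "select-wavelengths" = {
    o <- op(make_option("--a", type = "character"),
            make_option("--b", type = "character"))
    sel <- select_wavelengths(penetration_profile(read_spectrum_csv(o$a)),
                              penetration_profile(read_spectrum_csv(o$b)))
    cat(jsonlite::toJSON(sel, auto_unbox = TRUE, digits = NA), "\n")
  },
  "mc-run" = {
    o <- op(make_option("--geometry", default = "slice"),
            make_option("--tissue", default = "blackhearted"),
            make_option("--wavelength-nm", type = "double", default = 805),
            make_option("--photons", type = "double", default = 1e6),
            make_option("--seed", type = "integer", default = 7),
            make_option("--out", default = "mc-out"))
    dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
    geo <- build_geometry(o$geometry, o$`wavelength-nm`,
                          op_test = group_spectrum(o$tissue),
                          op_healthy = group_spectrum("healthy"))
    res <- run_mc(geo, mc_config(n_photons = o$photons, seed = o$seed))
    print(res)
    write_nrrd(res$absorbed_energy,
               file.path(o$out, "absorbed_energy.nrrd"), res$voxel_size)
    jsonlite::write_json(as.list(energy_budget(res)),
                         file.path(o$out, "budget.json"), auto_unbox = TRUE,
                         digits = NA)
    cat("wrote", o$out, "\n")
  },
  "classify" = {
    o <- op(make_option("--features", default = "mu_a"),
            make_option("--model", default = "svmda"),
            make_option("--n-per-group", type = "integer", default = 40),
            make_option("--seed", type = "integer", default = 7),
            make_option("--out", default = "report.json"))
    co <- generate_cohort(cohort_spec(n_per_group = o$`n-per-group`,
                                      seed = o$seed))
    f <- cohort_features(co, o$features, c(490, 805))
    rep <- evaluate_discrimination(o$model, f, seed = o$seed)
    print(rep)
    jsonlite::write_json(rep[c("model", "feature_kind", "calibration",
                               "cross_validation", "seed")],
                         o$out, auto_unbox = TRUE, digits = NA)
    cat("wrote", o$out, "\n")
  },
  {
    cat("usage: Rscript scripts/tuberlight.R <command> [options]\n",
        "commands: run | simulate-cohort | extract-ops | penetration |",
        "select-wavelengths | mc-run | classify\n")
  }
)
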