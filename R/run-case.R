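#' Configuration for a full pipeline run
#'
#' Bundles per-stage settings for [run_case()]: phantom geometry, light
#' sources, transport, dosimetry and threshold options, the output
#' directory and the master seed.  The configuration is validated before
#' any stage runs; a seed is mandatory because the transport stage is
#' stochastic.
#'
#' @param phantom list of arguments for [build_thorax_phantom()].
#' @param sources list with `n_sources`, `diameter_mm`, `total_power_mW`,
#'   `wavelength_nm` for [place_disc_sources()].
#' @param transport list with `n_packets` and optional roulette/Fresnel
#'   settings for [transport_config()].
#' @param dosimetry list with optional `detector_distances_mm`,
#'   `sampling_radius_mm`, `dvh_levels`.
#' @param threshold list with optional `mu_eff_per_cm`, `convention`,
#'   `concentration_mode`, `tissue_density`, `buildup`.
#' @param out_dir output directory for artifacts.
#' @param seed master integer seed (required).
#' @return A `run_config` object.
#' @export
run_config <- function(phantom = list(), sources = list(),
                       transport = list(), dosimetry = list(),
                       threshold = list(), out_dir = tempfile("lungpdt_"),
                       seed = NULL) {
  if (is.null(seed) || !is.finite(seed))
    stop("run_config requires an explicit integer seed for the stochastic ",
         "transport stage")
  defaults <- list(
    phantom = list(lung_volume_mL = 700, voxel_size_mm = 1,
                   bronchial_generations = 4),
    sources = list(n_sources = 3, diameter_mm = 50, total_power_mW = 2430,
                   wavelength_nm = 665),
    transport = list(n_packets = 1e5),
    dosimetry = list(detector_distances_mm = c(5, 10, 15, 20),
                     sampling_radius_mm = 1, dvh_levels = NULL),
    threshold = list(mu_eff_per_cm = 3.79, convention = "decadic-ln10",
                     concentration_mode = "mass_fraction",
                     tissue_density = 1.0, buildup = 1))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  cfg <- list(phantom = merge1(defaults$phantom, phantom),
              sources = merge1(defaults$sources, sources),
              transport = merge1(defaults$transport, transport),
              dosimetry = merge1(defaults$dosimetry, dosimetry),
              threshold = merge1(defaults$threshold, threshold),
              out_dir = out_dir, seed = as.integer(seed))
  stopifnot(cfg$transport$n_packets >= 1, cfg$sources$n_sources >= 1)
  structure(cfg, class = "run_config")
}

# small stable polynomial hash of the deparsed configuration, for provenance
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full dosimetry pipeline for one case
#'
#' Executes phantom construction, source and detector placement, Monte
#' Carlo transport, normalization, dose-volume histogram, detector
#' readouts with an effective-attenuation fit, threshold determination
#' from the bundled case table, and toxicity grading.  All artifacts are
#' written under the configured output directory together with a
#' provenance record (configuration hash, seed, package version).  Rerun
#' with the same configuration and seed is bit-identical.
#'
#' @param config a [run_config()].
#' @return A `case_report` list: `phantom`, `sources`, `fluence` paths,
#'   `dvh`, `readouts`, `attenuation_fit`, `thresholds`, `toxicity`,
#'   `provenance`.
#' @export
run_case <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  phantom <- stage("phantom", do.call(build_thorax_phantom,
    c(config$phantom, list(seed = config$seed))))
  sources <- stage("sources", do.call(place_disc_sources,
    c(list(phantom = phantom), config$sources)))
  phantom <- stage("sources", stamp_source_backing(phantom, sources))
  write_phantom(phantom, file.path(config$out_dir, "phantom"))

  tcfg <- stage("transport", do.call(transport_config,
    c(config$transport, list(seed = config$seed))))
  raw <- stage("transport", simulate_fluence(phantom, sources, tcfg))
  map <- stage("normalize", normalize_fluence(raw))
  write_fluence_map(map, file.path(config$out_dir, "fluence"))

  mask <- lung_mask(phantom)
  dvh <- stage("dvh", dose_volume_histogram(map, mask,
                                            config$dosimetry$dvh_levels))
  write_dvh_csv(dvh, file.path(config$out_dir, "dvh.csv"))

  readouts <- stage("readouts", {
    probes <- place_detectors(phantom,
                              config$dosimetry$detector_distances_mm,
                              sources[[1]],
                              config$dosimetry$sampling_radius_mm)
    data.frame(distance_mm = config$dosimetry$detector_distances_mm,
               fluence = vapply(probes,
                                function(p) detector_readout(map, p)$value,
                                0))
  })
  fit <- stage("fit", fit_effective_attenuation(readouts))

  th <- config$threshold
  thresholds <- stage("threshold", threshold_table(
    mu_eff_per_cm = th$mu_eff_per_cm, convention = th$convention,
    concentration_mode = th$concentration_mode,
    tissue_density = th$tissue_density, buildup = th$buildup))
  write.csv(thresholds, file.path(config$out_dir, "thresholds.csv"),
            row.names = FALSE)

  cases <- load_pdt_cases()
  grades <- stage("toxicity", {
    per_case <- unique(cases[, c("ps", "case", "pf_ratio_mmHg",
                                 "dynamic_compliance_mL_cmH2O",
                                 "static_compliance_mL_cmH2O",
                                 "gross_or_histology_injury")])
    per_case$toxicity <- vapply(seq_len(nrow(per_case)), function(i)
      classify_toxicity(physiology_record(
        per_case$pf_ratio_mmHg[i],
        per_case$dynamic_compliance_mL_cmH2O[i],
        per_case$static_compliance_mL_cmH2O[i],
        per_case$gross_or_histology_injury[i])), "")
    per_case
  })

  provenance <- list(config_hash = config_hash(config), seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("lungpdt")),
                     r_version = R.version.string)
  report <- list(phantom = phantom, sources = sources,
                 fluence_paths = file.path(config$out_dir,
                                           c("fluence.nii",
                                             "fluence_ledger.json")),
                 dvh = dvh, readouts = readouts, attenuation_fit = fit,
                 thresholds = thresholds, toxicity = grades,
                 provenance = provenance)
  jsonlite::write_json(
    list(provenance = provenance,
         ledger = map$ledger,
         attenuation_fit = unclass(fit),
         fraction_above_1_mW_cm2 = volume_fraction_above(map, mask, 1),
         fraction_above_10_uW_cm2 = volume_fraction_above(map, mask, 0.01)),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  class(report) <- "case_report"
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat("case_report\n")
  cat(sprintf("  lung volume: %.1f mL; sources: %d\n",
              x$phantom$lung_voxels * x$phantom$voxel_size^3 / 1000,
              length(x$sources)))
  print(x$attenuation_fit)
  cat(sprintf("  datasets with thresholds: %d\n", nrow(x$thresholds)))
  invisible(x)
}
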