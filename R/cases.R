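#' Load the bundled PDT case table
#'
#' One row per treated lobe/spot dataset of the dose-escalation study:
#' photosensitizer and administered dose, surface radiant exposure, biopsy
#' photosensitizer concentration (mass fraction with its reported spread,
#' and the study's printed molar column as a separate override), necrosis
#' depth, and the 72-h physiology used for toxicity grading.  The ALA case
#' with a reported necrosis range of 1.0-1.2 mm carries its midpoint
#' (1.1 mm); concentrations below the detection limit are `NA`.
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return A data frame with unit-suffixed column names.
#' @export
load_pdt_cases <- function(path = system.file("extdata", "pdt_cases.csv",
                                              package = "lungpdt")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$gross_or_histology_injury <- as.logical(df$gross_or_histology_injury)
  df
}

#' One case record of the escalation study
#'
#' @param photosensitizer_name text name.
#' @param admin_dose administered dose, mg/kg (>= 0).
#' @param tissue_concentration biopsy mass fraction, ug/g (>= 0).
#' @param tissue_concentration_spread reported spread of the mass
#'   fraction, ug/g.
#' @param tissue_concentration_molar concentration, uM.
#' @param surface_radiant_exposure radiant exposure(s), J/cm^2, one per
#'   treated lobe.
#' @param wavelength nm.
#' @param drug_light_interval minutes.
#' @param necrosis_depth necrosis depth(s), mm, one per lobe (0 = none).
#' @param physiology a [physiology_record()].
#' @return A `pdt_case` object.
#' @export
pdt_case <- function(photosensitizer_name, admin_dose,
                     tissue_concentration, tissue_concentration_spread,
                     tissue_concentration_molar, surface_radiant_exposure,
                     wavelength, drug_light_interval, necrosis_depth,
                     physiology) {
  stopifnot(admin_dose >= 0, all(surface_radiant_exposure >= 0),
            all(necrosis_depth >= 0),
            inherits(physiology, "physiology_record"))
  structure(list(photosensitizer_name = photosensitizer_name,
                 admin_dose = admin_dose,
                 tissue_concentration = tissue_concentration,
                 tissue_concentration_spread = tissue_concentration_spread,
                 tissue_concentration_molar = tissue_concentration_molar,
                 surface_radiant_exposure = surface_radiant_exposure,
                 wavelength = wavelength,
                 drug_light_interval = drug_light_interval,
                 necrosis_depth = necrosis_depth,
                 physiology = physiology),
            class = "pdt_case")
}

#' Forward attenuation model for synthetic case generation
#'
#' Carries everything needed to map an administered dose to a necrosis
#' depth under the 1-D exponential fluence model: the effective
#' attenuation, the photosensitizer (extinction coefficient, molecular
#' weight), a linear uptake model from administered dose to tissue
#' concentration, the multiplicative concentration measurement noise, the
#' buildup factor and the extinction convention.
#'
#' @param mu_eff_per_cm effective attenuation, per cm.
#' @param ps a [photosensitizer()].
#' @param uptake_uM_per_mg_kg tissue concentration (uM) per unit
#'   administered dose (mg/kg).
#' @param concentration_cv coefficient of variation of the (lognormal)
#'   multiplicative concentration measurement noise; 0.75 mirrors the
#'   relative spreads of the study's biopsy assays.
#' @param buildup backscatter buildup factor for [fluence_at_depth()].
#' @param convention extinction convention, see
#'   [photodynamic_threshold()].
#' @return An `attenuation_model` object.
#' @export
attenuation_model <- function(mu_eff_per_cm = 3.79, ps = ps_ppix(),
                              uptake_uM_per_mg_kg = 0.03,
                              concentration_cv = 0.75, buildup = 1,
                              convention = c("decadic-ln10",
                                             "decadic-raw")) {
  convention <- match.arg(convention)
  stopifnot(mu_eff_per_cm > 0, inherits(ps, "photosensitizer"),
            uptake_uM_per_mg_kg > 0, concentration_cv >= 0, buildup > 0)
  structure(list(mu_eff_per_cm = mu_eff_per_cm, ps = ps,
                 uptake_uM_per_mg_kg = uptake_uM_per_mg_kg,
                 concentration_cv = concentration_cv, buildup = buildup,
                 convention = convention),
            class = "attenuation_model")
}

#' Escalation design for synthetic case generation
#'
#' @param start_dose_mg_kg starting photosensitizer dose, mg/kg.
#' @param n_cases number of sequential cases.
#' @param exposures_J_cm2 surface radiant exposures delivered per case
#'   (one value per lobe dataset).
#' @param wavelength_nm treatment wavelength.
#' @param dose_doubling logical; double the dose each case (the design's
#'   no-toxicity branch).  With `FALSE` all cases use the start dose.
#' @return An `escalation_design` object.
#' @export
escalation_design <- function(start_dose_mg_kg = 15, n_cases = 4,
                              exposures_J_cm2 = c(6, 12),
                              wavelength_nm = 630, dose_doubling = TRUE) {
  stopifnot(start_dose_mg_kg > 0, n_cases >= 1, all(exposures_J_cm2 >= 0))
  structure(list(start_dose_mg_kg = start_dose_mg_kg, n_cases = n_cases,
                 exposures_J_cm2 = exposures_J_cm2,
                 wavelength_nm = wavelength_nm,
                 dose_doubling = dose_doubling),
            class = "escalation_design")
}

#' Generate synthetic escalation-study case data
#'
#' Synthesizes per-case biopsy and necrosis data from a known true
#' photodynamic threshold by inverting the 1-D exponential threshold
#' relation: the necrosis depth of each dataset is
#' `max(0, log(k eps C Phi0 / T) / mu_eff)` computed from the true tissue
#' concentration, while the reported concentration is the true value times
#' lognormal measurement noise (unit mean, CV from the model).  With zero
#' noise the generating threshold is recovered exactly by
#' [recover_threshold()]; with noise, within the propagated uncertainty.
#'
#' @param design an [escalation_design()].
#' @param true_threshold generating threshold, hv/cm^3 (> 0).
#' @param forward_model an [attenuation_model()].
#' @param noise_seed integer seed for the concentration noise.
#' @return A data frame, one row per (case, exposure) dataset, with
#'   columns `case`, `admin_dose_mg_kg`, `surface_exposure_J_cm2`,
#'   `wavelength_nm`, `conc_uM` (noisy, as measured),
#'   `conc_spread_uM` (propagated one-sigma spread), and
#'   `necrosis_depth_mm`.
#' @export
generate_case_data <- function(design, true_threshold, forward_model,
                               noise_seed = 1) {
  stopifnot(inherits(design, "escalation_design"), true_threshold > 0,
            inherits(forward_model, "attenuation_model"))
  fm <- forward_model
  k <- if (fm$convention == "decadic-ln10") log(10) else 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise_seed)

  doses <- design$start_dose_mg_kg *
    (if (design$dose_doubling) 2^(seq_len(design$n_cases) - 1)
     else rep(1, design$n_cases))
  rows <- list()
  sdlog <- sqrt(log(1 + fm$concentration_cv^2))
  for (i in seq_len(design$n_cases)) {
    c_true <- fm$uptake_uM_per_mg_kg * doses[i]
    noise <- if (fm$concentration_cv > 0)
      exp(rnorm(1, mean = -sdlog^2 / 2, sd = sdlog)) else 1
    c_obs <- c_true * noise
    for (E in design$exposures_J_cm2) {
      phi0 <- E * photons_per_joule(design$wavelength_nm) * fm$buildup
      eps_c <- k * fm$ps$molar_extinction * c_true * 1e-6  # per cm
      depth_cm <- max(0, log(eps_c * phi0 / true_threshold) /
                        fm$mu_eff_per_cm)
      rows[[length(rows) + 1]] <- data.frame(
        case = i, admin_dose_mg_kg = doses[i],
        surface_exposure_J_cm2 = E,
        wavelength_nm = design$wavelength_nm,
        conc_uM = c_obs,
        conc_spread_uM = fm$concentration_cv * c_obs,
        necrosis_depth_mm = 10 * depth_cm)
    }
  }
  do.call(rbind, rows)
}

#' Recover the photodynamic threshold from case data
#'
#' Applies the threshold relation to each dataset with visible necrosis:
#' T_i = k eps C_i Phi(depth_i), with the boundary fluence from the 1-D
#' exponential model, then aggregates across datasets (mean, with the
#' mean propagated spread).
#'
#' @param cases data frame as returned by [generate_case_data()] (columns
#'   `conc_uM`, `conc_spread_uM`, `surface_exposure_J_cm2`,
#'   `wavelength_nm`, `necrosis_depth_mm`).
#' @param model an [attenuation_model()] (same conventions used to read
#'   the data back).
#' @return A list with `per_case` (data frame with `threshold` and
#'   `spread` per dataset) and `aggregate` (a `threshold_estimate` from
#'   the across-dataset mean).
#' @export
recover_threshold <- function(cases, model) {
  stopifnot(inherits(model, "attenuation_model"))
  usable <- cases[cases$necrosis_depth_mm > 0 & !is.na(cases$conc_uM), ,
                  drop = FALSE]
  if (!nrow(usable)) stop("no dataset with visible necrosis to invert")
  ests <- lapply(seq_len(nrow(usable)), function(i) {
    row <- usable[i, ]
    phi <- fluence_at_depth(row$surface_exposure_J_cm2, model$mu_eff_per_cm,
                            row$necrosis_depth_mm / 10, model$buildup,
                            row$wavelength_nm)
    photodynamic_threshold(model$ps, row$conc_uM, phi,
                           convention = model$convention,
                           concentration_spread_uM = row$conc_spread_uM)
  })
  per_case <- data.frame(
    usable,
    threshold = vapply(ests, function(e) e$threshold, 0),
    spread = vapply(ests, function(e) e$spread, 0))
  agg <- structure(list(threshold = mean(per_case$threshold),
                        spread = mean(per_case$spread),
                        convention = model$convention,
                        fluence_source = "exponential-1D"),
                   class = "threshold_estimate")
  list(per_case = per_case, aggregate = agg)
}

#' Per-dataset thresholds from the study case table
#'
#' Applies the threshold relation to every dataset of the bundled case
#' table that has measurable necrosis and a detectable photosensitizer
#' concentration.  The concentration enters either as the biopsy mass
#' fraction converted through the molecular weight and tissue density
#' (default), or as the table's printed molar column
#' (`concentration_mode = "printed_molar"`); the two are not mutually
#' consistent in the source table and are never silently reconciled.
#'
#' @param cases case table from [load_pdt_cases()].
#' @param mu_eff_per_cm effective attenuation used for the boundary
#'   fluence, per cm.
#' @param convention extinction convention, see
#'   [photodynamic_threshold()].
#' @param concentration_mode `"mass_fraction"` or `"printed_molar"`.
#' @param tissue_density g/mL for the mass-fraction conversion.
#' @param buildup buildup factor for the boundary fluence.
#' @return Data frame with one row per usable dataset: identifiers,
#'   concentration in uM, boundary fluence (hv/cm^2), `threshold` and
#'   `spread` (hv/cm^3), plus `convention` and `fluence_source` columns.
#' @export
threshold_table <- function(cases = load_pdt_cases(), mu_eff_per_cm = 3.79,
                            convention = c("decadic-ln10", "decadic-raw"),
                            concentration_mode = c("mass_fraction",
                                                   "printed_molar"),
                            tissue_density = 1.0, buildup = 1) {
  convention <- match.arg(convention)
  concentration_mode <- match.arg(concentration_mode)
  ps_of <- function(name) if (name == "ALA") ps_ppix() else ps_chlorin_e6()
  out <- list()
  for (i in seq_len(nrow(cases))) {
    row <- cases[i, ]
    if (is.na(row$necrosis_depth_mm) || row$necrosis_depth_mm <= 0) next
    ps <- ps_of(row$ps)
    if (concentration_mode == "mass_fraction") {
      if (is.na(row$conc_ug_g)) next
      c_uM <- tissue_concentration_molar(row$conc_ug_g,
                                         ps$molecular_weight,
                                         tissue_density)
      c_sd <- tissue_concentration_molar(row$conc_spread_ug_g,
                                         ps$molecular_weight,
                                         tissue_density)
    } else {
      if (is.na(row$conc_uM_printed)) next
      c_uM <- row$conc_uM_printed
      c_sd <- if (!is.na(row$conc_ug_g) && row$conc_ug_g > 0)
        c_uM * row$conc_spread_ug_g / row$conc_ug_g else 0
    }
    phi <- fluence_at_depth(row$surface_exposure_J_cm2, mu_eff_per_cm,
                            row$necrosis_depth_mm / 10, buildup,
                            row$wavelength_nm)
    est <- photodynamic_threshold(ps, c_uM, phi, convention = convention,
                                  concentration_spread_uM = c_sd)
    out[[length(out) + 1]] <- data.frame(
      ps = row$ps, case = row$case, lobe = row$lobe,
      surface_exposure_J_cm2 = row$surface_exposure_J_cm2,
      necrosis_depth_mm = row$necrosis_depth_mm,
      conc_uM = c_uM, conc_spread_uM = c_sd,
      boundary_fluence_hv_cm2 = phi,
      threshold_hv_cm3 = est$threshold, spread_hv_cm3 = est$spread,
      convention = convention, fluence_source = "exponential-1D")
  }
  if (!length(out)) stop("no usable dataset in the case table")
  do.call(rbind, out)
}

#' Aggregate a threshold table for one photosensitizer
#'
#' @param tbl a [threshold_table()] result.
#' @param ps_name photosensitizer group to aggregate (`"ALA"` or
#'   `"Chlorin"`).
#' @return A `threshold_estimate` (across-dataset mean, spread = sd
#'   across datasets, or the single propagated spread for one dataset).
#' @export
aggregate_threshold <- function(tbl, ps_name = "ALA") {
  sel <- tbl[tbl$ps == ps_name, , drop = FALSE]
  if (!nrow(sel)) stop("no dataset for photosensitizer ", ps_name)
  spread <- if (nrow(sel) > 1) sd(sel$threshold_hv_cm3)
            else sel$spread_hv_cm3
  structure(list(threshold = mean(sel$threshold_hv_cm3), spread = spread,
                 convention = sel$convention[1],
                 fluence_source = sel$fluence_source[1]),
            class = "threshold_estimate")
}
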