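#' Photosensitizer description
#'
#' @param name photosensitizer name.
#' @param molar_extinction decadic molar extinction coefficient epsilon,
#'   M^-1 cm^-1, at `wavelength` (> 0).
#' @param wavelength nm, in (300, 1000).
#' @param molecular_weight g/mol.
#' @return A `photosensitizer` object.
#' @export
#' @examples
#' ps_ppix()
#' ps_chlorin_e6()
photosensitizer <- function(name, molar_extinction, wavelength,
                            molecular_weight) {
  stopifnot(molar_extinction > 0, wavelength > 300, wavelength < 1000,
            molecular_weight > 0)
  structure(list(name = name, molar_extinction = molar_extinction,
                 wavelength = wavelength,
                 molecular_weight = molecular_weight),
            class = "photosensitizer")
}

#' @rdname photosensitizer
#' @export
ps_ppix <- function() {
  # 5-ALA-induced protoporphyrin IX, red absorption band
  photosensitizer("PpIX", molar_extinction = 5005, wavelength = 635,
                  molecular_weight = 562.66)
}

#' @rdname photosensitizer
#' @export
ps_chlorin_e6 <- function() {
  photosensitizer("Chlorin e6", molar_extinction = 60386, wavelength = 660,
                  molecular_weight = 596.68)
}

#' Photons per joule at a given wavelength
#'
#' lambda / (h c): the photon count carried by one joule of monochromatic
#' light, used to express fluence in photons (hv) per cm^2.
#'
#' @param wavelength_nm wavelength in nm (> 0).
#' @return Photons per joule (hv/J).
#' @export
#' @examples
#' photons_per_joule(630)  # ~3.17e18
photons_per_joule <- function(wavelength_nm) {
  stopifnot(all(wavelength_nm > 0))
  wavelength_nm * 1e-9 / PLANCK_HC_JM
}

#' Tissue photosensitizer concentration: mass fraction to molarity
#'
#' C\[uM\] = mass_fraction\[ug/g\] x density\[g/mL\] x 1000 / MW\[g/mol\].
#'
#' @param mass_fraction_ug_g photosensitizer mass per tissue mass, ug/g.
#' @param molecular_weight g/mol.
#' @param tissue_density g/mL; soft tissue is close to 1.0.
#' @return Concentration in uM.
#' @export
tissue_concentration_molar <- function(mass_fraction_ug_g, molecular_weight,
                                       tissue_density = 1.0) {
  stopifnot(all(mass_fraction_ug_g >= 0), molecular_weight > 0,
            tissue_density > 0)
  mass_fraction_ug_g * tissue_density * 1000 / molecular_weight
}

#' Photon fluence at depth under the 1-D exponential model
#'
#' Surrogate for the simulated fluence at the necrotic boundary: the
#' surface radiant exposure converted to photons, attenuated exponentially
#' with the effective attenuation coefficient, with an optional
#' backscatter buildup factor.
#'
#' @param surface_exposure_J_cm2 radiant exposure at the surface, J/cm^2.
#' @param mu_eff_per_cm effective attenuation coefficient, per cm.
#' @param depth_cm depth below the illuminated surface, cm.
#' @param buildup dimensionless multiplicative buildup factor (> 0);
#'   default 1 (no backscatter buildup).
#' @param wavelength_nm wavelength, nm.
#' @return Photon fluence at depth, hv/cm^2.
#' @export
#' @examples
#' fluence_at_depth(12, 3.79, 0.17, wavelength_nm = 630)  # ~2.0e19
fluence_at_depth <- function(surface_exposure_J_cm2, mu_eff_per_cm,
                             depth_cm, buildup = 1, wavelength_nm = 630) {
  stopifnot(all(surface_exposure_J_cm2 >= 0), all(mu_eff_per_cm >= 0),
            all(depth_cm >= 0), buildup > 0)
  surface_exposure_J_cm2 * photons_per_joule(wavelength_nm) * buildup *
    exp(-mu_eff_per_cm * depth_cm)
}

#' Photodynamic threshold dose
#'
#' The photon density absorbed by the photosensitizer per unit tissue
#' volume at the necrotic boundary, T = k epsilon \[PS\] Phi in hv/cm^3,
#' with the concentration converted to mol/cm^3 and epsilon to
#' cm^3 mol^-1 cm^-1.  Convention `"decadic-ln10"` (default) multiplies by
#' k = ln 10, converting the decadic extinction coefficient into an
#' absorbed-photon density; `"decadic-raw"` uses k = 1 (the product as
#' printed).  Uncertainty is propagated linearly from the concentration
#' spread alone.
#'
#' @param ps a [photosensitizer()].
#' @param concentration_uM tissue concentration, uM (>= 0).
#' @param fluence_photon_cm2 photon fluence at the necrotic boundary,
#'   hv/cm^2 (>= 0).
#' @param convention `"decadic-ln10"` or `"decadic-raw"`.
#' @param concentration_spread_uM one-sigma spread of the concentration.
#' @param fluence_source how the boundary fluence was obtained
#'   (`"exponential-1D"` or `"mc-map"`); recorded in the estimate.
#' @return A `threshold_estimate`: `threshold`, `spread` (hv/cm^3),
#'   `convention`, `fluence_source`.
#' @export
photodynamic_threshold <- function(ps, concentration_uM, fluence_photon_cm2,
                                   convention = c("decadic-ln10",
                                                  "decadic-raw"),
                                   concentration_spread_uM = 0,
                                   fluence_source = c("exponential-1D",
                                                      "mc-map")) {
  convention <- match.arg(convention)
  fluence_source <- match.arg(fluence_source)
  stopifnot(inherits(ps, "photosensitizer"),
            concentration_uM >= 0, fluence_photon_cm2 >= 0,
            concentration_spread_uM >= 0)
  k <- if (convention == "decadic-ln10") log(10) else 1
  # epsilon [M^-1 cm^-1] x C [M] = attenuation per cm by the PS alone
  per_cm <- ps$molar_extinction * concentration_uM * 1e-6
  spread_per_cm <- ps$molar_extinction * concentration_spread_uM * 1e-6
  structure(list(threshold = k * per_cm * fluence_photon_cm2,
                 spread = k * spread_per_cm * fluence_photon_cm2,
                 convention = convention,
                 fluence_source = fluence_source),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "photodynamic threshold: %.3g +/- %.3g hv/cm^3 (%s, fluence: %s)\n",
    x$threshold, x$spread, x$convention, x$fluence_source))
  invisible(x)
}

#' Lung physiology record
#'
#' @param pf_ratio PaO2/FiO2 ratio, mmHg (>= 0).
#' @param dynamic_compliance,static_compliance treated-lung compliance,
#'   mL/cmH2O (>= 0).
#' @param gross_or_histology_injury logical; injury visible on gross, CT or
#'   histological examination.
#' @return A `physiology_record`.
#' @export
physiology_record <- function(pf_ratio, dynamic_compliance,
                              static_compliance,
                              gross_or_histology_injury = FALSE) {
  stopifnot(pf_ratio >= 0, dynamic_compliance >= 0, static_compliance >= 0,
            is.logical(gross_or_histology_injury))
  structure(list(pf_ratio = pf_ratio,
                 dynamic_compliance = dynamic_compliance,
                 static_compliance = static_compliance,
                 gross_or_histology_injury = gross_or_histology_injury),
            class = "physiology_record")
}

#' Classify lung toxicity from physiology
#'
#' Clinically significant toxicity is a P/F ratio below 300 mmHg or a
#' treated-lung compliance (dynamic or static) below 10 mL/cmH2O; visible
#' injury without functional impairment grades as mild; otherwise none.
#'
#' @param rec a [physiology_record()].
#' @return One of `"none"`, `"mild"`, `"clinically_significant"`.
#' @export
classify_toxicity <- function(rec) {
  stopifnot(inherits(rec, "physiology_record"))
  if (rec$pf_ratio < 300 || rec$dynamic_compliance < 10 ||
      rec$static_compliance < 10)
    "clinically_significant"
  else if (isTRUE(rec$gross_or_histology_injury))
    "mild"
  else
    "none"
}

#' Next photosensitizer dose in the accelerated escalation design
#'
#' Doubles the dose after a tolerated case, halves it after a
#' non-tolerated one.
#'
#' @param current_dose current dose, mg/kg (> 0).
#' @param tolerated logical; was the current dose tolerated.
#' @return Next dose, mg/kg.
#' @export
next_dose <- function(current_dose, tolerated) {
  stopifnot(current_dose > 0, is.logical(tolerated))
  if (tolerated) 2 * current_dose else current_dose / 2
}
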