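test_that("photon bookkeeping constants are right", {
  # lambda / (h c): 630 nm -> 3.171e18, 660 nm -> 3.322e18 photons/J
  expect_equal(photons_per_joule(630), 3.171e18, tolerance = 5e-4)
  expect_equal(photons_per_joule(660), 3.322e18, tolerance = 5e-4)
  expect_equal(photons_per_joule(c(400, 800)),
               2 * photons_per_joule(c(200, 400)))  # linear in wavelength
})

test_that("mass fraction converts to molarity through MW and density", {
  # 0.96 ug/g PpIX (MW 562.66), density 1.0 -> 1.706 uM
  expect_equal(tissue_concentration_molar(0.96, 562.66), 1.706,
               tolerance = 1e-3)
  expect_identical(tissue_concentration_molar(0, 562.66), 0)
  expect_equal(tissue_concentration_molar(1, 500, 2),
               2 * tissue_concentration_molar(1, 500, 1))
})

test_that("the 1-D exponential boundary fluence behaves", {
  expect_equal(fluence_at_depth(12, 3.79, 0, wavelength_nm = 630),
               12 * photons_per_joule(630))
  # 12 J/cm^2, mu_eff 3.79 /cm, 1.7 mm: 3.806e19 * exp(-0.6443) = 2.00e19
  expect_equal(fluence_at_depth(12, 3.79, 0.17, wavelength_nm = 630),
               2.00e19, tolerance = 2e-3)
  half_depth <- log(2) / 3.79
  expect_equal(fluence_at_depth(12, 3.79, 0.2 + half_depth,
                                wavelength_nm = 630),
               fluence_at_depth(12, 3.79, 0.2, wavelength_nm = 630) / 2)
})

test_that("photodynamic threshold combines eps, C, Phi with the convention", {
  est <- photodynamic_threshold(ps_ppix(), 1.71, 2.00e19)
  # ln(10) * 5005 * 1.71e-6 /cm * 2.00e19 /cm^2 = 3.94e17 /cm^3
  expect_equal(est$threshold, 3.94e17, tolerance = 2e-3)
  expect_equal(est$convention, "decadic-ln10")
  raw <- photodynamic_threshold(ps_ppix(), 1.71, 2.00e19,
                                convention = "decadic-raw")
  expect_equal(est$threshold / raw$threshold, log(10))
  expect_identical(photodynamic_threshold(ps_ppix(), 0, 1e19)$threshold, 0)
  # linearity in each factor
  expect_equal(photodynamic_threshold(ps_ppix(), 3.42, 2.00e19)$threshold,
               2 * est$threshold)
  expect_equal(photodynamic_threshold(ps_ppix(), 1.71, 4.00e19)$threshold,
               2 * est$threshold)
  # spread propagates linearly from the concentration spread
  with_sd <- photodynamic_threshold(ps_ppix(), 1.71, 2.00e19,
                                    concentration_spread_uM = 0.171)
  expect_equal(with_sd$spread, with_sd$threshold * 0.1, tolerance = 1e-9)
})

test_that("toxicity grading follows the P/F, compliance and injury rules", {
  expect_identical(classify_toxicity(physiology_record(456, 13, 12, FALSE)),
                   "none")
  expect_identical(classify_toxicity(physiology_record(97, 6, 6, TRUE)),
                   "clinically_significant")
  # preserved P/F but compliance below 10 is still significant
  expect_identical(classify_toxicity(physiology_record(440, 9, 9, TRUE)),
                   "clinically_significant")
  # visible injury with preserved function grades mild
  expect_identical(classify_toxicity(physiology_record(331, 11, 11, TRUE)),
                   "mild")
})

test_that("dose escalation doubles on tolerance and halves otherwise", {
  expect_equal(next_dose(60, FALSE), 30)
  expect_equal(next_dose(30, FALSE), 15)
  for (d in c(1, 15, 42.5))
    expect_equal(next_dose(d, TRUE), 2 * d)
})

test_that("the case generator inverts the exponential model exactly", {
  fm <- attenuation_model(concentration_cv = 0)
  design <- escalation_design(15, 3, exposures_J_cm2 = c(6, 12))
  true_T <- 5e16  # every lobe dataset above threshold at the surface
  cases <- generate_case_data(design, true_T, fm, noise_seed = 1)
  expect_equal(nrow(cases), 6)
  expect_true(all(cases$necrosis_depth_mm > 0))
  # closed form check on one dataset, by independent arithmetic
  k <- log(10)
  i <- which(cases$admin_dose_mg_kg == 30 &
               cases$surface_exposure_J_cm2 == 12)
  c_uM <- 0.03 * 30
  phi0 <- 12 * photons_per_joule(630)
  want_cm <- log(k * 5005 * c_uM * 1e-6 * phi0 / true_T) / 3.79
  expect_equal(cases$necrosis_depth_mm[i], 10 * want_cm, tolerance = 1e-12)
  # doubling the exposure deepens necrosis by ln(2)/mu_eff
  j <- which(cases$admin_dose_mg_kg == 30 &
               cases$surface_exposure_J_cm2 == 6)
  expect_equal(cases$necrosis_depth_mm[i] - cases$necrosis_depth_mm[j],
               10 * log(2) / 3.79, tolerance = 1e-10)
  # sub-threshold surface fluence yields zero depth
  quiet <- generate_case_data(design, 1e30, fm, noise_seed = 1)
  expect_true(all(quiet$necrosis_depth_mm == 0))
})

test_that("threshold recovery round-trips the generator without noise", {
  fm <- attenuation_model(concentration_cv = 0)
  design <- escalation_design(15, 4, exposures_J_cm2 = c(6, 12))
  true_T <- 2.1e17
  cases <- generate_case_data(design, true_T, fm, noise_seed = 7)
  rec <- recover_threshold(cases, fm)
  expect_lt(abs(rec$aggregate$threshold - true_T) / true_T, 1e-10)
  expect_true(all(abs(rec$per_case$threshold - true_T) / true_T < 1e-10))
})

test_that("inferred threshold is non-increasing in necrosis depth", {
  fm <- attenuation_model()
  depths <- seq(0.5, 8, by = 0.5)
  phi <- fluence_at_depth(12, fm$mu_eff_per_cm, depths / 10,
                          wavelength_nm = 630)
  thr <- vapply(phi, function(p)
    photodynamic_threshold(fm$ps, 1.7, p)$threshold, 0)
  expect_true(all(diff(thr) < 0))
})

test_that("the study case table loads with its physiology intact", {
  cases <- load_pdt_cases()
  expect_equal(nrow(cases), 10)
  expect_setequal(unique(cases$ps), c("ALA", "Chlorin"))
  expect_true(all(cases$surface_exposure_J_cm2 > 0))
  expect_true(all(cases$necrosis_depth_mm >= 0))
  tbl <- threshold_table(cases)
  # five ALA datasets with necrosis plus the vascular Chlorin case
  expect_equal(sum(tbl$ps == "ALA"), 5)
  expect_equal(sum(tbl$ps == "Chlorin"), 1)
  expect_true(all(tbl$threshold_hv_cm3 > 0))
  # printed-molar override uses the table's uM column untouched
  tbl2 <- threshold_table(cases, concentration_mode = "printed_molar")
  expect_equal(tbl2$conc_uM[tbl2$ps == "ALA" & tbl2$case == 1],
               rep(57.2, 2))
})
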