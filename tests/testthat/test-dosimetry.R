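test_that("DVH of simple maps behaves as a step function", {
  mask <- array(TRUE, dim = c(4, 4, 4))
  uni <- manual_fluence_map(array(2, dim = c(4, 4, 4)))
  dvh <- dose_volume_histogram(uni, mask, levels = c(0, 1, 2, 3))
  expect_equal(dvh$volume_fraction_at_or_above, c(1, 1, 1, 0))
  expect_equal(dvh$mask_volume_mL, 64 / 1000)

  ab <- array(c(rep(1, 32), rep(3, 32)), dim = c(4, 4, 4))
  expect_equal(volume_fraction_above(manual_fluence_map(ab), mask, 2), 0.5)
  expect_equal(volume_fraction_above(manual_fluence_map(ab), mask, 0), 1)
  expect_equal(volume_fraction_above(manual_fluence_map(ab), mask, 99), 0)

  expect_error(dose_volume_histogram(uni, mask & FALSE), "empty mask")
})

test_that("DVH is invariant to voxel ordering and joint rescaling", {
  set.seed(42)
  g <- array(rexp(125), dim = c(5, 5, 5))
  mask <- array(TRUE, dim = c(5, 5, 5))
  levels <- c(0, 0.1, 0.5, 1, 2, 5)
  d1 <- dose_volume_histogram(manual_fluence_map(g), mask, levels)
  perm <- aperm(g, c(3, 1, 2))
  d2 <- dose_volume_histogram(manual_fluence_map(perm), mask, levels)
  expect_equal(d1$volume_fraction_at_or_above, d2$volume_fraction_at_or_above)
  d3 <- dose_volume_histogram(manual_fluence_map(g * 7), mask, levels * 7)
  expect_equal(d1$volume_fraction_at_or_above, d3$volume_fraction_at_or_above)
  # monotone non-increasing, starts at 1
  expect_true(all(diff(d1$volume_fraction_at_or_above) <= 0))
  expect_equal(d1$volume_fraction_at_or_above[1], 1)
})

test_that("detector readout averages the field and applies the correction", {
  uni <- manual_fluence_map(array(3.5, dim = c(10, 10, 10)))
  p <- detector_probe(c(5, 5, 5), sampling_radius = 2)
  expect_equal(detector_readout(uni, p)$value, 3.5)
  p2 <- detector_probe(c(5, 5, 5), 2, responsivity_correction = 1.17)
  expect_equal(detector_readout(uni, p2)$value, 3.5 * 1.17)
  expect_error(detector_readout(uni, detector_probe(c(500, 5, 5), 1)),
               "no voxels")
})

test_that("readout of a diffusion field matches the point value within 5%", {
  map <- oracle_field_map(41, 1)
  for (r in c(5, 10, 15)) {
    probe <- detector_probe(map$center + c(r, 0, 0), sampling_radius = 1)
    got <- detector_readout(map, probe)$value
    want <- point_source_fluence(lung_properties(), 1000, r)
    expect_lt(abs(got - want) / want, 0.05,
              label = sprintf("readout at r = %g mm", r))
  }
})

test_that("attenuation fits recover the slope, with the known 1/r bias", {
  mu <- 0.379  # per mm
  r <- seq(5, 20, by = 2.5)
  dat <- data.frame(distance_mm = r, fluence = 8 * exp(-mu * r) / r)
  fit <- fit_effective_attenuation(dat, mode = "ln-r-times-fluence")
  expect_equal(fit$mu_eff_estimate, mu, tolerance = 1e-10)
  expect_lt(fit$stderr, 1e-10)

  raw <- fit_effective_attenuation(dat, mode = "ln-fluence")
  bias <- raw$mu_eff_estimate - mu
  expect_gt(bias, 0)  # ln-fluence overestimates for point-like geometry
  expect_lt(abs(bias - mean(1 / r)) / mean(1 / r), 0.5)

  expect_error(fit_effective_attenuation(
    data.frame(distance_mm = c(5, 10), fluence = c(1, -2))), "10")
  expect_error(fit_effective_attenuation(
    data.frame(distance_mm = c(5, 5), fluence = c(1, 2))), "distinct")
})

test_that("concordance summarizes measured-versus-simulated agreement", {
  sim <- c(1, 2, 4, 8, 16)
  ident <- concordance(sim, sim)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r_squared, 1)
  twice <- concordance(2 * sim, sim)
  expect_equal(twice$slope, 2)
  expect_equal(twice$r_squared, 1)

  set.seed(99)
  m <- rnorm(50); s <- rnorm(50)
  cc <- concordance(m, s)
  expect_lt(cc$r_squared, 0.2)
  # independent route: R^2 must equal the squared Pearson correlation
  expect_equal(cc$r_squared, cor(m, s)^2, tolerance = 1e-12)

  expect_error(concordance(c(1, 2), c(3, 3)), "zero variance")
})
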