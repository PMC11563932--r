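test_that("diffusion mu_eff reproduces the lung and muscle closed forms", {
  # lung: mu_a = 0.0473/mm with 0.965/mm reduced scattering -> 3.79 /cm
  expect_equal(10 * effective_attenuation(lung_properties()), 3.79,
               tolerance = 0.001)
  # same result from the full (mu_s, g) parameterisation
  expect_equal(effective_attenuation(lung_properties(reduced = FALSE)),
               effective_attenuation(lung_properties()), tolerance = 1e-12)
  # muscle: mu_s' = 7.356 * (1 - 0.93) = 0.51492/mm
  # sqrt(3 * 0.052 * (0.052 + 0.51492)) = 0.29739/mm by direct arithmetic
  expect_equal(effective_attenuation(muscle_properties()), 0.29739,
               tolerance = 1e-4)
  expect_warning(z <- effective_attenuation(
    material_optical_properties(0, 1, 0.9, 1.4)), "zero")
  expect_identical(z, 0)
})

test_that("penetration depth of lung tissue is 2.64 mm", {
  expect_equal(1 / effective_attenuation(lung_properties()), 2.64,
               tolerance = 0.002)
})

test_that("point-source Green's function has the right value and shape", {
  props <- lung_properties()
  # independent arithmetic: 1000 * exp(-0.37901 * 10) / (4 pi * 0.32928 * 10)
  # = 0.5460 mW/mm^2 = 54.60 mW/cm^2
  expect_equal(point_source_fluence(props, 1000, 10), 54.60,
               tolerance = 0.002)
  r <- seq(2, 30, by = 0.5)
  phi <- point_source_fluence(props, 500, r)
  expect_equal(point_source_fluence(props, 1000, r), 2 * phi)
  expect_true(all(diff(phi) < 0))
  expect_error(point_source_fluence(props, 1000, 0))
})

test_that("ln(r * Phi) is exactly linear in r with slope -mu_eff", {
  props <- lung_properties()
  r <- seq(5, 25, by = 2)
  y <- log(r * point_source_fluence(props, 1234, r))
  fit <- lm(y ~ r)
  expect_equal(unname(coef(fit)[2]), -effective_attenuation(props),
               tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})
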