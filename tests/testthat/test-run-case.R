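smoke_config <- function(out_dir, seed = 11) {
  run_config(
    phantom = list(lung_volume_mL = 50, voxel_size_mm = 2,
                   bronchial_generations = 0),
    sources = list(n_sources = 1, diameter_mm = 20, total_power_mW = 500,
                   wavelength_nm = 665),
    transport = list(n_packets = 5000),
    dosimetry = list(detector_distances_mm = c(4, 8)),
    out_dir = out_dir, seed = seed)
}

test_that("a minimal configuration runs end-to-end with all report parts", {
  out <- file.path(tempdir(), "smoke_run")
  rep <- run_case(smoke_config(out))
  expect_s3_class(rep, "case_report")
  for (part in c("phantom", "sources", "dvh", "readouts",
                 "attenuation_fit", "thresholds", "toxicity", "provenance"))
    expect_true(part %in% names(rep), label = part)
  expect_true(all(file.exists(file.path(out,
    c("phantom.nii", "phantom.yaml", "fluence.nii", "fluence_ledger.json",
      "dvh.csv", "thresholds.csv", "report.json")))))
  expect_equal(nrow(rep$toxicity), 7)  # one grade per animal case
  expect_match(rep$provenance$config_hash, "^[0-9a-f]{8}$")
  unlink(out, recursive = TRUE)
})

test_that("reruns with the same configuration and seed are identical", {
  o1 <- file.path(tempdir(), "rerun_a")
  o2 <- file.path(tempdir(), "rerun_b")
  r1 <- run_case(smoke_config(o1))
  r2 <- run_case(smoke_config(o2))
  expect_identical(r1$readouts, r2$readouts)
  expect_identical(r1$dvh$volume_fraction_at_or_above,
                   r2$dvh$volume_fraction_at_or_above)
  expect_identical(readBin(file.path(o1, "fluence.nii"), "raw", 1e6),
                   readBin(file.path(o2, "fluence.nii"), "raw", 1e6))
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("configurations without a seed are rejected before running", {
  expect_error(run_config(seed = NULL), "seed")
  expect_error(transport_config(1000), "seed")
})
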