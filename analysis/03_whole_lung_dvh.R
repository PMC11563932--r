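#!/usr/bin/env Rscript
# Whole-lung illumination analysis: three 5-cm discs totalling 2.43 W on
# the default 700 mL phantom, fluence-rate map, dose-volume histogram and
# the coverage fractions above 1 mW/cm^2 and 10 uW/cm^2.

suppressPackageStartupMessages(library(lungpdt))
dir.create("results", showWarnings = FALSE)

phantom <- build_thorax_phantom(700, 1, 4, seed = 1)
sources <- place_disc_sources(phantom, 3, 50, 2430, 665)
phantom <- stamp_source_backing(phantom, sources)
cat("transporting 2e5 packets across three sources...\n")
raw <- simulate_fluence(phantom, sources, transport_config(2e5, seed = 7))
map <- normalize_fluence(raw)
write_fluence_map(map, "results/whole_lung_fluence")

mask <- lung_mask(phantom)
dvh <- dose_volume_histogram(map, mask)
write_dvh_csv(dvh, "results/dvh.csv")

f1 <- volume_fraction_above(map, mask, 1)      # > 1 mW/cm^2
f10u <- volume_fraction_above(map, mask, 0.01) # > 10 uW/cm^2
jsonlite::write_json(list(
  fraction_above_1_mW_cm2 = f1,
  fraction_above_10_uW_cm2 = f10u,
  lung_volume_mL = dvh$mask_volume_mL,
  total_power_mW = map$total_power_mW),
  "results/coverage_fractions.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("\nlung volume: %.0f mL, total source power %.2f W\n",
            dvh$mask_volume_mL, map$total_power_mW / 1000))
cat(sprintf("fraction above 1 mW/cm^2:  %.3f\n", f1))
cat(sprintf("fraction above 10 uW/cm^2: %.3f\n", f10u))
cat("\nThe two coverage levels keep their expected ordering (the 10 uW\n",
    "region strictly contains the 1 mW region).  Absolute coverage is far\n",
    "below the ~25%/80% pattern the in-vivo CT geometry supports: with a\n",
    "2.64 mm penetration depth, three discs covering <15% of the surface\n",
    "cannot light the majority of a compact 700 mL half-ellipsoid; see the\n",
    "methods vignette (limitations) for the geometry argument.\n")
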