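# lungpdt

Light dosimetry for perfusion-assisted photodynamic therapy (PDT) of the
whole lung.

Treating an entire lung with PDT — against diffuse micrometastatic disease
— stands or falls with dosimetry: the photosensitizer–light product must
exceed the necrosis threshold in tumour tissue while staying below it in
normal lung. During acellular lung perfusion the blood is flushed out,
absorption drops, and red light penetrates far enough that large
surface-mounted LED discs plus simulation-based planning become realistic.
`lungpdt` implements that dosimetry chain as a reproducible, synthetic-scene
pipeline for physicists and engineers working on organ-scale PDT planning:

* a **voxel photon-packet Monte Carlo engine** (C++/Rcpp): Henyey–Greenstein
  scattering, exact voxel traversal, track-length fluence scoring, Russian
  roulette, a weight ledger conserved to 1e-9, per-packet RNG substreams;
* a **synthetic thorax phantom generator**: half-ellipsoid flushed lung of
  controllable volume, dichotomous bronchial air tree, tangent 5-cm
  Lambertian LED disc sources with absorbing backings, isotropic fibre
  detector probes;
* **diffusion-theory closed forms** as independent oracles:
  μ_eff = √(3 μ_a (μ_a + μ_s′)) and the infinite-medium point-source
  Green's function Φ(r) = P e^(−μ_eff r) / (4π D r);
* **dosimetric summaries**: dose-volume histograms (volume fraction at or
  above a fluence-rate level), detector readouts, effective-attenuation
  fits of ln(rΦ) or ln(Φ) against r, measured-vs-simulated concordance;
* **photodynamic thresholds** T = k ε [PS] Φ in hν/cm³ with explicit unit
  plumbing (photons per joule, µg/g ↔ µM conversion, extinction
  conventions), uncertainty propagation, a synthetic case generator with a
  tested parameter-recovery loop, and the dose-escalation / lung-toxicity
  bookkeeping (P/F ratio < 300 mmHg or compliance < 10 mL/cmH₂O ⇒
  clinically significant).

For flushed lung tissue (μ_a = 0.0473 mm⁻¹, μ_s′ = 0.965 mm⁻¹) the model's
effective attenuation is **3.79 cm⁻¹** (penetration depth 2.64 mm), and the
Monte Carlo engine recovers that value from simulated detector readouts —
the core validation loop of the package.

## Worked example

```r
library(lungpdt)

# diffusion theory for flushed lung tissue
props <- lung_properties()
cat(sprintf("mu_eff = %.2f /cm, penetration depth = %.2f mm\n",
            10 * effective_attenuation(props),
            1 / effective_attenuation(props)))

# Monte Carlo point-source run in a homogeneous lung-tissue cube
phantom <- homogeneous_phantom(160, voxel_size_mm = 1)
src <- point_source(rep(80, 3), power_mW = 1000)
map <- normalize_fluence(
  simulate_fluence(phantom, src, transport_config(2e5, seed = 42)))

r <- seq(5, 20, by = 2.5)
readouts <- data.frame(
  distance_mm = r,
  fluence = sapply(r, function(d)
    detector_readout(map, detector_probe(c(80 + d, 80, 80), 1))$value))
print(fit_effective_attenuation(readouts))

# photodynamic threshold for one dataset: 12 J/cm2, 1.7 mm necrosis,
# 0.96 ug/g PpIX
conc <- tissue_concentration_molar(0.96, ps_ppix()$molecular_weight)
phi <- fluence_at_depth(12, 3.79, 0.17, wavelength_nm = 630)
print(photodynamic_threshold(ps_ppix(), conc, phi))
```

prints

```
mu_eff = 3.79 /cm, penetration depth = 2.64 mm
attenuation_fit (ln-r-times-fluence, n = 7): mu_eff = 0.3709 /mm (3.709 /cm), se 0.0048 /mm
photodynamic threshold: 3.93e+17 +/- 0 hv/cm^3 (decadic-ln10, fluence: exponential-1D)
```

The fit recovers the diffusion-theory 3.79 cm⁻¹ to ~2% at 2×10⁵ packets
(the residual is Monte Carlo noise plus the breakdown of diffusion theory
near the source); the threshold for this dataset lands at order
10¹⁷ hν/cm³ under the decadic-ln10 convention, with the convention and
fluence model recorded in the estimate.

## Analysis workflow

Numbered drivers under `analysis/` run the full study pipeline and write
tables under `results/`:

1. `01_build_phantom.R` — the default 700 mL scene with three 5-cm discs
   totalling 2.43 W (NIfTI + YAML + summary table);
2. `02_validate_transport.R` — 10⁶-packet point-source run versus the
   diffusion oracle; radial fluence table and attenuation-fit report;
3. `03_whole_lung_dvh.R` — three-source whole-lung fluence map,
   dose-volume histogram, coverage fractions above 1 mW/cm² and 10 µW/cm²;
4. `04_thresholds.R` — per-dataset thresholds from the bundled case table
   under both extinction conventions, toxicity grades, escalation sequence;
5. `05_threshold_recovery.R` — synthetic-case parameter recovery: exact
   noise-free round trip and ≥ 90% coverage of the propagated interval
   over 100 noisy replicates.

The methods vignette (`vignettes/lung-pdt-dosimetry.Rmd`) documents the
models, conventions, parameter defaults and limitations — in particular
why absolute whole-lung coverage fractions from the compact synthetic
phantom are far below what a real thin, curved lung geometry supports.

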