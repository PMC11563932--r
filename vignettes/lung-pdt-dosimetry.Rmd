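---
title: "Light dosimetry for whole-lung photodynamic therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light dosimetry for whole-lung photodynamic therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungpdt)
```

## The problem

Photodynamic therapy (PDT) kills tissue where the product of photosensitizer
concentration and absorbed light exceeds a threshold photon density.
Treating an entire lung — for example against diffuse micrometastatic
disease — requires knowing the light fluence-rate field everywhere in the
organ, not just near a fibre tip.  During acellular lung perfusion the blood
(and with it most of the absorption) is flushed out, which extends the
optical penetration enough to make whole-organ illumination plausible: large
LED discs on the lung surface, isotropic fibre detectors inside the organ,
and Monte Carlo simulation tying the two together.

`lungpdt` implements that dosimetry chain for a synthetic, fully
reproducible scene: a voxel phantom of a flushed left lung, photon-packet
Monte Carlo transport, diffusion-theory closed forms for validation,
dose-volume histograms and attenuation fits, and photodynamic-threshold
determination with the accompanying dose-escalation and lung-toxicity
bookkeeping.

## Optical model

Each material carries an absorption coefficient $\mu_a$, a scattering
coefficient, an anisotropy $g$ (mean cosine of the Henyey–Greenstein
single-scattering deflection) and a refractive index.  The flushed-lung
tissue values used throughout are $\mu_a = 0.0473\,\mathrm{mm^{-1}}$ and a
scattering value of $0.965\,\mathrm{mm^{-1}}$ with $g = 0.93$ and
$n = 1.36$.

A deliberate modelling decision: **the lung scattering value is read as the
reduced (transport) scattering coefficient** $\mu_s' = \mu_s(1-g)$, not as
the raw $\mu_s$.  Diffusion theory gives

$$\mu_{\mathrm{eff}} = \sqrt{3\mu_a(\mu_a + \mu_s')},$$

and only the reduced reading yields the effective attenuation of
$3.79\,\mathrm{cm^{-1}}$ (penetration depth $1/\mu_{\mathrm{eff}} =
2.64\,\mathrm{mm}$) that anchors every depth calculation in this pipeline;
reading $0.965\,\mathrm{mm^{-1}}$ as a raw $\mu_s$ with $g=0.93$ would give
$\mu_s' = 0.068\,\mathrm{mm^{-1}}$ and an implausible
$\mu_{\mathrm{eff}} \approx 0.13\,\mathrm{mm^{-1}}$ for red light in flushed
lung.  Materials flagged this way are transported isotropically ($g = 0$) at
the reduced rate — the similarity relation — and the stored anisotropy has
no effect on any fluence result.  The full $(\mu_s, g)$ mode remains
available (`lung_properties(reduced = FALSE)`) and the two agree within
Monte Carlo error beyond a few transport lengths from a source.

```{r mueff}
10 * effective_attenuation(lung_properties())   # per cm
1 / effective_attenuation(lung_properties())    # penetration depth, mm
```

## The Monte Carlo engine

Transport follows the standard photon-packet scheme on a voxel grid:

* **Step sampling.**  An optical depth $\tau = -\ln U$ is consumed across
  voxels by exact axis-aligned ray marching (Amanatides–Woo traversal), so
  material boundaries are honoured exactly; there is no
  infinite-medium hop shortcut.
* **Scoring.**  Fluence uses the track-length estimator: each voxel
  accumulates packet weight times the path length traversed.  Raw maps are
  in photon-weight·mm per voxel; `normalize_fluence()` converts to
  mW/cm² via `raw * (P / N) / V_voxel` with the mm→cm conversion, and is
  exactly linear in source power.
* **Absorption.**  At each collision the weight is multiplied by the
  single-scattering albedo $\mu_s/(\mu_a+\mu_s)$ and the absorbed share is
  added to a ledger.
* **Roulette.**  Packets below weight $10^{-4}$ survive with probability
  $1/10$ and are boosted tenfold (classic multi-layer Monte Carlo values).
  The ledger identity `launched = absorbed + escaped + rouletted` holds to
  better than $10^{-9}$ relative on every run and is asserted in the tests;
  packets hitting the collision cap are folded into the roulette entry.
* **Reproducibility.**  Every packet owns a counter-based RNG substream
  derived from (seed, packet index), so results are bit-identical for a
  given seed and independent of execution order.  Seeds are mandatory.
* **Boundaries.**  Refractive-index-matched by default.  Fresnel
  reflection/refraction at voxel faces where $n$ changes is available
  behind `fresnel_at_air_interfaces`; with uniform $n$ the flag provably
  changes nothing (tested bit-for-bit).
* **Sources.**  LED discs emit uniformly over the face with a
  cosine-weighted (Lambertian) direction about the inward normal; an
  isotropic point source supports validation runs.  Packets are allocated
  to sources by largest-remainder rounding of the power shares.  The
  non-emitting housing behind each disc is represented by a slab of ideal
  absorber (`stamp_source_backing()`).

### Validation against diffusion theory

The infinite-medium Green's function
$\Phi(r) = P\,e^{-\mu_{\mathrm{eff}} r}/(4\pi D r)$ with
$D = 1/\bigl(3(\mu_a+\mu_s')\bigr)$ is the independent oracle: a $10^6$-packet
run in a homogeneous lung-tissue cube (160 mm, i.e. ≥ 60 mm padding beyond
the deepest detector) reproduces the oracle within a few percent over
5–20 mm, and the geometry-corrected attenuation fit recovers
$\mu_{\mathrm{eff}}$ to better than 3% (`analysis/02_validate_transport.R`,
`tests/testthat/test-acceptance.R`).  Diffusion theory itself is only an
approximation within a few transport lengths of the source, which is part
of the residual.

## The synthetic thorax phantom

No CT segmentations ship with this package; the scene is generated:

* **Lung shape.**  A half-ellipsoid with a flat mediastinal face — any
  convex-ish controllable-volume shape suffices for the physics; axis
  ratios default to 1 : 1 : 1.6 (cranio-caudal long axis).  The default
  volume is 700 mL, a plausible left lung for an adolescent 35–40 kg pig,
  and configurable.  The axes are calibrated iteratively so the voxelized
  parenchyma (airways excluded) matches the request to < 0.5%, well inside
  the 2% contract tested.
* **Airways.**  A symmetric dichotomous tree carved as air: generation 1
  is a 5-mm-radius main bronchus entering at the hilum; radius and length
  scale by 0.79 per generation (Weibel-like).  A strict halving rule was
  considered and rejected: halving from any anatomically plausible stem
  radius makes generation 8 — which the generator must support —
  unresolvable at any permitted voxel size, whereas 0.79 keeps
  generation-8 radii near 1.5 mm.  A generation whose diameter falls below
  one voxel raises an error naming the limiting generation.  Finer airways
  are deliberately absent: beyond the resolved tree the lung is treated as
  a homogeneous turbid medium.
* **Sources and detectors.**  Discs are placed tangent to the curved
  surface by greedy farthest-point selection over a deterministic
  candidate grid, with a non-overlap contract (pairwise centre distance ≥
  one diameter) that fails explicitly when the surface is too small.
  Detector probes sit on a source's inward axis at requested depths and
  must land in parenchyma; air-tree hits are rejected with the label
  named.  Readouts average the map over a 1-mm-radius sphere (isotropic
  probe tips are of that scale), which biases an exponential field by
  about $+2\%$ at these gradients — inside the 5% contract tested.

What the phantom does **not** emulate: the real lung's thin curved
geometry wrapped around the mediastinum, the surrounding chest wall and
its backscatter, inflation-dependent optical properties, and anatomical
airway asymmetry.  Passing tests therefore validate the physics and the
bookkeeping, not organ-scale coverage predictions for a real thorax (see
Limitations).

## Dosimetric summaries

* **Dose-volume histogram.**  "Volume fraction at or above level", over
  log-spaced levels spanning six decades by default; invariant to voxel
  ordering and to joint rescaling of map and levels.
* **Attenuation fit.**  Ordinary least squares of $\ln(r\Phi)$ on $r$
  (default; exact for point-like geometry in the diffusion limit) or of
  $\ln\Phi$ (mirroring raw measurement plots; biased above the true
  $\mu_{\mathrm{eff}}$ by roughly the mean of $1/r$ over the range — both
  modes are reported with the mode name).
* **Concordance.**  Measured-versus-simulated least-squares line plus
  $R^2$.

## Photodynamic thresholds

The threshold is $T = k\,\varepsilon\,[\mathrm{PS}]\,\Phi$ in
$h\nu/\mathrm{cm^3}$, with $\varepsilon$ the decadic molar extinction
coefficient (PpIX: $5005\,\mathrm{M^{-1}cm^{-1}}$; Chlorin e6:
$60386\,\mathrm{M^{-1}cm^{-1}}$), $[\mathrm{PS}]$ converted to
$\mathrm{mol/cm^3}$, and $\Phi$ the photon fluence at the necrotic
boundary.  Open conventions are exposed rather than silently resolved:

* **Extinction convention.**  $k = \ln 10$ (default, `decadic-ln10`)
  converts the decadic $\varepsilon$ into an absorbed-photon density;
  `decadic-raw` ($k = 1$) keeps the bare product.  Every estimate records
  its convention.
* **Boundary fluence.**  The 1-D exponential surrogate
  $\Phi = E\,\lambda/(hc)\,B\,e^{-\mu_{\mathrm{eff}} z}$ (fast,
  reproducible; buildup factor $B$ default 1) is the default; sampling an
  MC map is supported through the same readout machinery.  Estimates
  record the fluence source.
* **Concentration input.**  Biopsy mass fractions (µg/g) convert through
  the molecular weight and a tissue density of 1.0 g/mL (configurable).
  The study table's printed µM column is *not* reproducible from its own
  µg/g column (the printed values scale with administered dose, not with
  the assays), so it is accepted only as an explicit override mode and
  never reconciled.
* **Uncertainty.**  First-order propagation of the concentration spread
  only — the only per-row uncertainty the source data provide.

Applied to the bundled case table under `decadic-ln10`, the five
ALA-induced PpIX datasets with visible necrosis average
$1.45\times10^{17}\ h\nu/\mathrm{cm^3}$ — order $10^{17}$, comfortably
above the study's printed vascular-photosensitizer floor of
$6.3\times10^{15}$.  The printed per-case thresholds themselves are not
exactly derivable from the printed inputs under any single convention the
module supports (most visibly for the vascular Chlorin case, where the
computed value lands three orders above the printed bound); the package
treats the printed values as order-of-magnitude anchors and always reports
what it computed, with conventions attached.

### Synthetic case generation and recovery

`generate_case_data()` inverts the same relation: necrosis depth
$z = \max\bigl(0, \ln(k\varepsilon C\Phi_0/T)/\mu_{\mathrm{eff}}\bigr)$
from a known true threshold, with the *measured* concentration perturbed
by unit-mean lognormal noise (CV 0.75, matching the relative spreads of
the study's biopsy assays; the depth is computed from the true
concentration, so the noise is measurement error, as in the assays).
Recovery is exact without noise (round-trip error $<10^{-10}$ relative,
tested at $10^{-16}$), and with noise the two-sigma multiplicative
interval implied by the propagated spread covers the truth in ≈ 99 of 100
seeded replicates (target ≥ 90%).  The multiplicative (log-space) interval
is the natural choice for lognormal noise of this size; a symmetric ±2σ
interval would cover noticeably less on the upper tail.

## Toxicity and escalation bookkeeping

A case grades `clinically_significant` when the P/F ratio drops below
300 mmHg or either treated-lung compliance falls below 10 mL/cmH₂O;
visible gross/CT/histology injury with preserved function grades `mild`;
otherwise `none`.  The accelerated escalation rule doubles the dose after
a tolerated case and halves it otherwise.  Both reproduce the recorded
case outcomes exactly (tested per case).

## Problem sizes and numerical choices

Default analysis sizes were chosen as the smallest runs whose Monte Carlo
error is clearly inside the contracts they exercise: $10^6$ packets for
the point-source validation (slope SE ≈ 0.7% of the estimate), $2\times
10^5$ packets for the three-source whole-lung map (coverage fractions
stable to well under a percentage point), 1-mm voxels throughout.  Ties
and degenerate inputs fail loudly rather than silently: empty DVH masks,
non-positive fluences in log fits, double normalization, detectors in
air, seeds omitted, non-finite packet positions.

## Limitations

* The synthetic scene cannot reproduce organ-scale coverage numbers from
  the in-vivo CT geometry.  With $\mu_{\mathrm{eff}} = 3.79\,
  \mathrm{cm^{-1}}$, light falls three decades within ~18 mm, so three
  5-cm discs covering < 15% of a compact 700-mL half-ellipsoid light
  roughly 14% of it above 10 µW/cm² (and ~6% above 1 mW/cm²) at 2.43 W —
  the correct *ordering* but far below the ~80%/25% reported for a real
  thin, curved lung inside a reflecting thorax.  The whole-lung analysis
  states this explicitly rather than adjusting geometry until the numbers
  match.
* Infinite-medium diffusion is the only closed-form oracle; semi-infinite
  or extrapolated-boundary solutions are out of scope, so validation runs
  use padded homogeneous phantoms.
* Thresholds inherit every unit convention ambiguity of the source data;
  the package's contribution is to make each choice explicit, not to
  resolve them.
* No pharmacokinetics (drug–light intervals are carried but not
  modelled), no singlet-oxygen microdosimetry, no tumour model.
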