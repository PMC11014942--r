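---
title: "Isotope mass balance, marker-gene inventories and SIP shifts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope mass balance, marker-gene inventories and SIP shifts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrosource)
```

## The scientific problem

In nutrient-poor polar lake catchments, nitrate in sediments and soils can
come from two very different pools: atmospheric deposition (snow-borne
nitrate formed through ozone chemistry) and in-situ microbial nitrification.
The oxygen isotopes of nitrate separate the two cleanly. Atmospheric nitrate
carries a very high δ¹⁸O (around 92‰ at coastal Antarctic stations) and a
large mass-independent anomaly Δ¹⁷O (around 32‰), inherited from ozone.
Nitrification-derived nitrate instead assembles its three oxygen atoms from
ambient water and dissolved O₂, both of which sit on the mass-dependent
fractionation line, so its Δ¹⁷O is 0‰ and its δ¹⁸O is near 0.6‰.

`nitrosource` implements the quantitative side of that argument — a
two-endmember isotope mass balance with Monte-Carlo uncertainty — together
with two companion analyses used in the same kind of study: a marker-gene
inventory of nitrogen-cycle potential, and a DNA stable-isotope-probing
(SIP) readout of which nitrifiers were actively growing.

## The mixing model

For an observed tracer value $x$ (either δ¹⁸O or Δ¹⁷O) and endmember values
$x_{atm}$ and $x_{bio}$,

$$f_{atm} = \frac{x - x_{bio}}{x_{atm} - x_{bio}}, \qquad f_{bio} = 1 - f_{atm}.$$

The two tracers are always reported side by side and never averaged into a
single number: they are independent lines of evidence, and how one would
combine them into a single "~96%"-style figure is a judgement call we leave
to the analyst.

The Δ¹⁷O anomaly uses the linear definition
$\Delta^{17}O = \delta^{17}O - \lambda\,\delta^{18}O$ with $\lambda = 0.52$,
the community-standard slope for the linear form. The slope is configurable
(`lambda_mdf`); directly measured Δ¹⁷O values bypass the formula entirely and
take precedence over values derived from δ¹⁷O.

### Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| atmospheric δ¹⁸O | 92 | ‰ | coastal-station annual mean |
| atmospheric Δ¹⁷O | 32 | ‰ | coastal-station annual mean |
| biological δ¹⁸O | 0.6 | ‰ | published nitrification-product value |
| biological Δ¹⁷O | 0 | ‰ | mass-dependent by construction |
| λ (mass-dependent slope) | 0.52 | – | linear-definition standard |
| σ(δ¹⁸O), σ(Δ¹⁷O), σ(δ¹⁵N) | 0.3, 0.8, 0.6 | ‰ 1σ | denitrifier-method pooled precisions |
| `n_draws` | 10000 | – | Monte-Carlo draws per group |

A note on the biological endmember: assembling nitrate oxygen 2:1 from lake
water (−12.7‰) and atmospheric O₂ (23.9‰) gives −0.5‰
(`biological_endmember_d18O(-12.7, 23.9)`), not the 0.6‰ field value we ship
as the default constant. The field value may fold in fractionation effects
the simple 2:1 arithmetic omits. We deliberately surface both — the default
constant reproduces the published apportionment arithmetic, and the computed
value is one function call away — rather than silently substituting either.
At the observed endmember separation (~91.4‰) the 1.1‰ difference moves the
biological fraction by about 0.01.

### Uncertainty propagation

`monte_carlo_fraction()` draws the observation and both endmember values
from independent Gaussians at their 1σ values — the study provides no
covariances, so none are modelled — computes $f_{bio}$ per draw with
clipping to $[0,1]$, and reports the closed-form point estimate alongside
the Monte-Carlo median and the 2.5–97.5 percentile interval. Clipping is a
flag, never an error: measurement noise can legitimately push an observation
past an endmember. Every stochastic call takes an explicit integer seed and
restores the caller's RNG state (`withr::with_seed`), so identical inputs
and seed are bit-reproducible.

With `mode = "mean_first"` (the default, matching the published procedure of
apportioning the group mean) the uncertainty attached to the aggregated
observation is the standard error of the mean, i.e. the mean per-sample σ
divided by √n. With `mode = "per_sample"` each sample is apportioned and the
fractions averaged; no Monte-Carlo interval is produced in that mode because
the between-sample spread, not the instrument precision, then dominates.

## The marker-gene inventory

`build_inventory()` turns a sample × gene abundance table into a
process × sample potential matrix under a configurable gene→process panel.
The shipped nitrogen-cycle panel is: N₂ fixation (*nifH*); nitrification
(*amoA*, *hao*, *nxrB*); denitrification (*napA*, *narG*, *nirS*, *nirK*,
*norB*, *nosZ*); DNRA (*nrfA*); assimilatory nitrite reduction (*nasA*,
*nirA*); anammox (*hzo*, *hzs*).

Design choices, and why:

* **Aggregation is `sum` by default** (with `max` as an option): the genes of
  one process jointly evidence that process, so their abundances add.
* **Presence is aggregated abundance strictly above a threshold**, default 0
  (any positive signal counts as potential). For qPCR copies-per-ng data, 10
  copies ng⁻¹ is a conventional "relatively low quantity" yardstick and is a
  sensible stricter threshold.
* **Multi-process genes count in every mapped process.** *nirS*/*nirK* occur
  in nitrifiers as well as denitrifiers; the default panel follows the
  conventional attribution (denitrification only), and
  `ncycle_panel(dual_nir = TRUE)` adds the dual mapping.
* **Symbol matching is case-insensitive plus an explicit alias table** —
  never fuzzy. *amoA* and *amoB* must not be conflated; unmapped columns are
  retained and flagged, not dropped silently.

A process absent in every sample lands on the global absence list — the
machine-readable form of findings such as "no anammox markers anywhere".
`screen_markers()` applies the same machinery genome-wise with per-feature
any/all rules, and a small energy/carbon panel (CO oxidation via *coxL*,
uptake [NiFe]-hydrogenases, CBB and 3-hydroxypropionate carbon fixation)
ships as a starting point; the full published screening panels are larger
and user-extensible via YAML.

## The SIP density shift

DNA-SIP experiments feed microcosms a ¹³C substrate; organisms that
assimilate it build denser DNA, visible as the target gene's abundance
distribution moving to heavier fractions of a CsCl gradient. Published
studies typically demonstrate this visually as a "peak shift". We formalise
it: the primary statistic is **delta-WMD**, the difference in
abundance-weighted mean buoyant density between the ¹³C and ¹²C profiles,

$$\Delta\mathrm{WMD} = \sum_i \rho_i\, w_i^{13C} - \sum_i \rho_i\, w_i^{12C},$$

with normalised fraction weights $w_i$. The modal-fraction (peak) shift is
reported as a secondary readout. WMD is preferred because it uses every
fraction and is robust to gradient granularity, where the modal fraction
jumps in steps of the fraction spacing. This statistic is this package's
formalisation of the visual evidence, not a published definition.

Replicate microcosms (three, per the usual incubation design) are normalised
first — so gradients with different absolute qPCR yields weigh equally — and
then averaged per fraction. A pair is called *labelled* when delta-WMD
exceeds 0.005 g mL⁻¹, a threshold chosen as roughly a third of a clearly
visible shift and validated by the null calibration below. No qSIP
atom-fraction-excess conversion is attempted: that requires gradient
calibration parameters (GC content, tube-angle geometry) that the supported
input tables do not carry.

Ties in the modal fraction resolve to the lightest fraction; fewer than
three fractions is an error, not a guess.

## What the synthetic generator emulates — and what it does not

`sim_spec()` fixes the simulated study conditions; all generators flow from
its single seed through deterministic child streams, so each table
reproduces in isolation and jointly.

* **Isotope tables**: per sample type, the true tracer values are the exact
  mixing-line values for a known atmospheric fraction, plus independent
  Gaussian noise at the instrument precisions (0.3‰ δ¹⁸O, 0.8‰ Δ¹⁷O, 0.6‰
  δ¹⁵N). Defaults: six samples per type, true atmospheric fraction 0.05 in
  sediment and 0.04 in soil — the published biological fractions of 95% and
  96% read back as ground truth. Ground truth is written to a sidecar only,
  so pipeline code cannot accidentally consume it.
* **Annotation tables**: genes of present processes draw log-uniform
  abundances over 10²–10⁴ copies ng⁻¹ DNA (the magnitude range of
  environmental qPCR inventories); absent processes are exactly zero. The
  default habitat has anammox absent.
* **SIP profiles**: the ¹²C gradient is a Gaussian abundance curve (peak
  1.715 g mL⁻¹, sd 0.015) over 14 fractions spanning 1.69–1.77 g mL⁻¹ — a
  conventional gradient layout, not a published one — and the ¹³C gradient
  is the identical curve translated by the true shift (0.015 g mL⁻¹ by
  default), with 20% multiplicative log-normal noise per fraction and three
  replicates. Translating the fraction densities rather than re-evaluating
  the curve keeps the zero-noise shift exactly equal to the truth, which is
  what makes the translation property testable.

What the generator does **not** emulate: real qPCR efficiency drift,
compositionality of relative-abundance data, correlated noise between
tracers, GC-driven density offsets between taxa, or community structure of
any kind. Passing tests therefore demonstrate that the *estimators* are
correct and calibrated under the stated error model — not that the error
model exhausts real data.

## Numerical choices and degenerate inputs

* Identical endmembers are a hard error (the model is undefined), checked at
  tolerance zero.
* Observations outside the endmember interval clip with a flag (default) or
  pass through with a warning (`clip = FALSE`).
* Percentile intervals use the default quantile definition (type 7).
* Empty input tables yield empty result tables, not errors; empty abundance
  profiles and sub-3-fraction profiles are classed errors.
* All δ/Δ values are per mil throughout; fractions are unitless in $[0,1]$;
  densities are g mL⁻¹. No unit mixing anywhere.

## Problem sizes used in the test-suite calibrations

Calibration properties run at: 1000 random parameter sets for the inversion
identity; 200 replicate datasets (n = 6 samples, instrument σ) for interval
coverage and estimator error; 200 null and 100 shifted SIP replicates for
the false-positive and detection rates. These sizes give binomial standard
errors comfortably inside the asserted margins while keeping the default
suite fast.

## Known limitations

* Two endmembers only; three-source mixing and Bayesian mixing models
  (MixSIAR-style) are out of scope.
* No kinetic fractionation corrections and no δ¹⁵N-based process modelling:
  δ¹⁵N is carried through but not interpreted.
* The inventory starts from annotation counts; it performs no homology
  search and assigns no taxonomy.
* The SIP module quantifies the density shift only; converting it to atom
  fraction excess requires calibration data outside the supported inputs.
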