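# nitrosource

Who made the nitrate? In nutrient-poor polar lake catchments, sediment and
soil nitrate can come from atmospheric deposition or from in-situ microbial
nitrification, and the oxygen isotopes of nitrate tell the two apart:
atmospheric nitrate carries very high δ¹⁸O (~92‰) and a large
mass-independent anomaly Δ¹⁷O (~32‰), while nitrification-derived nitrate
sits near δ¹⁸O ≈ 0.6‰ with Δ¹⁷O = 0‰. `nitrosource` is an R package for the
quantitative workflow built on that contrast:

* **Two-endmember isotope mass balance** — for an observed tracer value
  *x* and endmembers *x*<sub>atm</sub>, *x*<sub>bio</sub>:

  *f*<sub>atm</sub> = (*x* − *x*<sub>bio</sub>) / (*x*<sub>atm</sub> − *x*<sub>bio</sub>),  *f*<sub>bio</sub> = 1 − *f*<sub>atm</sub>

  on δ¹⁸O and Δ¹⁷O (linear anomaly Δ¹⁷O = δ¹⁷O − 0.52 δ¹⁸O), with
  Monte-Carlo propagation of the measurement 1σ (0.3‰ δ¹⁸O, 0.8‰ Δ¹⁷O).
* **Nitrogen-cycle marker-gene inventory** — sample × gene tables
  (*nifH*, *amoA*, *hao*, *nxrB*, *napA*, *narG*, *nirS*, *nirK*, *norB*,
  *nosZ*, *nrfA*, *nasA*, *nirA*, *hzo*, *hzs*) aggregated into
  process × sample potential matrices with presence/absence calls.
* **DNA-SIP density shift** — the ¹³C-vs-¹²C difference in
  abundance-weighted mean buoyant density (delta-WMD, g mL⁻¹) of a target
  gene across gradient fractions, the formal version of a "peak shift".
* **Synthetic data with known ground truth** — isotope tables, annotation
  tables and SIP profiles generated from a seeded spec, so the whole
  pipeline is testable without any external downloads.

See `vignettes/methods.Rmd` for the model, its assumptions, and every
design decision.

## Worked example

Apportion the shipped summary table (sediment mean δ¹⁸O = 4.6‰,
Δ¹⁷O = 1.3‰) between atmospheric deposition and nitrification:

```r
library(nitrosource)

iso <- read_isotope_csv(system.file("extdata", "lake_catchment_isotopes.csv",
                                    package = "nitrosource"))
res <- apportion_dataset(iso, n_draws = 10000, seed = 1)
res[, c("sample_type", "tracer", "point_obs", "f_bio", "ci_low", "ci_high")]
#>   sample_type tracer point_obs  f_bio  ci_low ci_high
#> 1    sediment   d18O       4.6 0.9562 0.03738 0.05023
#> 2    sediment   D17O       1.3 0.9594 0.00000 0.08918
```

Both tracers agree: ~96% of the sediment nitrate is biological
(`f_bio`), and the 95% Monte-Carlo interval on the *atmospheric* fraction
(`ci_low`–`ci_high`) stays below ~9% even at instrument noise. The two
tracers are reported side by side, never averaged.

The other stages work the same way from R (`build_inventory()`,
`compute_shift()`, `sim_spec()` + generators) or end to end from files
(`run_mix()`, `run_inventory()`, `run_sip()`, `run_simulate()`), each
writing CSV results plus a JSON run report. A thin CLI wrapper ships at
`system.file("cli", "nitrosource.R", package = "nitrosource")`:

```sh
Rscript nitrosource.R simulate --seed 7 --out-dir sim/
Rscript nitrosource.R mix --input sim/isotopes.csv --seed 7 --out-dir mix/
```

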