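# aquametal

Heavy-metal(loid) risk assessment for surface water: pollution indices,
ecological risk, the USEPA human-health risk chain, Monte Carlo uncertainty
propagation with sensitivity analysis, and correlation/cluster source
screening — in one reproducible, seeded R pipeline.

The package is aimed at environmental scientists and public-health analysts
working with long-format water-monitoring records (site, date, analyte,
concentration in µg/L) for the eight analytes As, Cr, Cu, Fe, Mn, Ni, Pb
and Zn. It ships the per-site seasonal means of a seven-station Danube
River campaign (2013–2019) as a worked fixture and a calibrated synthetic
generator for full per-sample datasets.

## The models

**Pollution and ecological indices** (per site and pooled, per seasonal
half-year):

- HPI = Σ WᵢQᵢ / Σ Wᵢ with Qᵢ = 100·Cᵢ/Sᵢ, Wᵢ = 1/Sᵢ (low < 15, medium
  15–30, high > 30)
- MI = Σ Cᵢ/UALᵢ (six classes, cut points 0.3, 1, 2, 4, 6)
- RI = Σ Tᵣⁱ·Cᵢ/C_bgⁱ, Hakanson's potential ecological risk (low < 30)

**Health risk**, per metal × receptor (adult, child) × pathway (oral,
dermal):

- CDI_oral = C·IR·EF·ED / (BW·AT); CDI_dermal = C·ET·EF·Kp·SA·CF·ED / (BW·AT)
- HQ = CDI/RfD with RfD_dermal = RfD_oral·ABS; HI = HQ_oral + HQ_dermal
  (threshold 1)
- CR = CDI·CSF for As, Cr, Pb, against the acceptable range 10⁻⁶–10⁻⁴

**Monte Carlo**: every input of those equations can carry a point,
truncated-normal, lognormal or empirical distribution; 10,000-iteration
propagation yields mean and 5th/50th/95th percentiles plus a
rank-correlation sensitivity table (shares |ρ| normalised to 100%).

**Source screening**: Kolmogorov–Smirnov normality pre-check, Spearman
matrix with p < 0.01 / p < 0.05 flags, and average-linkage clustering on
d = 1 − ρ with Newick export.

## Worked example

```r
library(aquametal)

s <- danube_site_means()                  # packaged 7 sites x 2 seasons x 8 metals
aps <- pooled_means(s, "APR_SEP")
hpi(aps)
#> HPI [pooled] = 21.91 -> medium
metal_index(aps)$value                    #> 4.133 (heavily affected)
ecological_risk(aps)$value                #> 3.355 (low)

rt <- subset(risk_table(s), scope == "pooled" & metal == "As")
rt[, c("period", "receptor", "hi", "cr_oral", "cr_oral_class")]
#>     period receptor      hi   cr_oral cr_oral_class
#>    APR_SEP    adult 0.13049 5.844e-05    acceptable
#>    APR_SEP    child 0.49771 2.232e-04  unacceptable
#>    OCT_MAR    adult 0.14506 6.497e-05    acceptable
#>    OCT_MAR    child 0.55325 2.481e-04  unacceptable
```

Every hazard index is below 1 (no non-carcinogenic concern), but the
child's oral carcinogenic risk for arsenic (≈2.2–2.5 × 10⁻⁴) exceeds the
10⁻⁴ ceiling in both seasons — the pipeline's central finding on this
fixture. A Monte Carlo view of the same quantity:

```r
pool <- s$mean_ugL[s$period == "APR_SEP" & s$metal == "As"]
d <- c(list(C = conc_dist(ugL_to_mgL(pool))),
       mc_exposure_dists(exposure_profile("child")))
mc <- run_mc("As", "child", "oral", "HQ", d, n = 10000, seed = 1)
mc$summary
#>    mean      p5     p50     p95
#> 0.49650 0.39819 0.49245 0.60777
mc_sensitivity(mc)        # signed Spearman rho and share per input
```

End-to-end, writing a CSV bundle and a Markdown report:

```r
run_pipeline(list(generator = list(), seed = 42, output = "out"))
```

A thin CLI with the same functionality lives at `inst/cli/aquametal.R`
(subcommands `simulate`, `indices`, `risk`, `report`, …).

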