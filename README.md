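# hgrisk

Tissue-specific mercury bioaccumulation statistics and dietary risk
assessment for freshwater fish surveys.

Fish muscle is the dominant route of human exposure to methylmercury
(MeHg), and cascade reservoir systems — with long water residence times and
legacy metal contamination — are settings where mercury methylation and
trophic magnification concentrate risk. `hgrisk` takes a tidy fish-survey
table (one row per specimen × organ, with total-Hg concentration in
mg·kg⁻¹ wet weight) and provides:

* **Bioaccumulation statistics** — normality-gated log₁₀ transforms,
  one-way ANOVA with Tukey HSD across species/organs/reservoirs,
  Pearson/Spearman correlations between morphometrics (total length TL,
  total weight TW) and tissue THg, OLS size models with diagnostics, and an
  exact Mann–Whitney contrast between median-weight size classes.
* **Deterministic risk** — for consumer groups (adults 70 kg, pregnant
  women 60 kg, children 15 kg) at a weekly intake IR (baseline 140 g·week⁻¹
  ≡ 7.3 kg·year⁻¹):

  EDI = C × IR_daily / BW    (mg·kg⁻¹·day⁻¹, IR_daily = IR/7/1000)

  THQ = EDI / RfD            (RfD = 1×10⁻⁴ mg·kg⁻¹·day⁻¹; THQ < 1 ⇒ no
                              significant non-carcinogenic risk)

  HI  = Σᵢ THQᵢ              (cumulative risk over a diet basket)

  SWI = TWI × BW / C × 1000  (g·week⁻¹ at the EFSA TWI of 1.3 µg·kg⁻¹·week⁻¹,
                              evaluated at the species median and P95 muscle
                              concentration), with traffic-light advisory
                              categories red < 140 ≤ yellow < 300 ≤ green.
* **Probabilistic risk** — Monte Carlo THQ/HI (default N = 30,000) with
  weekly intake IR ~ Triangular(50, 140, 350) g·week⁻¹ sampled by the exact
  inverse CDF, concentration C resampled by species-specific empirical
  bootstrap, fixed BW per group, and summaries P50, P95 and the exceedance
  probability P(THQ > 1). The closed-form triangular CDF/quantile functions
  double as analytic oracles for validating the simulation.
* **A calibrated synthetic survey generator** — lognormal organ
  concentrations with species, reservoir and allometric size effects,
  calibrated so a default draw reproduces the structure of a 49-specimen,
  7-species, 3-reservoir cascade survey (specimen counts, organ-wise
  moments, species muscle medians, the reservoir gradient, and signed
  size–Hg slopes). Every downstream stage is therefore testable without
  field data.

## Worked example

```r
library(hgrisk)

s <- generate_survey(calibrate_defaults(), seed = 1)
s
#> <hg_survey> 49 specimens, 7 species, 441 tissue records (LOD 5e-05 mg/kg)

organ_summary(s)
#> # A tibble: 9 × 8
#>   organ      n    mean      sd  median      min    max cv_percent
#> 1 bones     49 0.0189  0.0152  0.0139  0.00304  0.0625       80.4
#> 2 gills     49 0.0114  0.0126  0.00716 0.00144  0.0647      110.
#> 3 gonads    49 0.00606 0.00566 0.00373 0.000644 0.0245       93.5
#> # ... 6 more rows

dplyr::filter(deterministic_risk(s), species == "Perca fluviatilis")
#>   species   group     n c_med_mg_kg   thq swi_med_g_week swi_p95_g_week category
#> 1 Perca fl… adul…     9       0.117 0.335            775            530 green
#> 2 Perca fl… preg…     9       0.117 0.391            664            454 green
#> 3 Perca fl… chil…     9       0.117 1.56             166            114 yellow
```

In this draw the perch muscle median is 0.117 mg·kg⁻¹: adults at
140 g·week⁻¹ carry about a third of the reference dose (THQ 0.335), while
for a 15 kg child the same meal plan exceeds it (THQ 1.56) and the
median-based safe weekly intake collapses to 166 g — a yellow advisory.
The probabilistic view for the same species and the children group:

```r
perch <- tissue_values(s, "muscle", "Perca fluviatilis")$thg_mg_kg_ww
run_mc_thq(perch, list(group = "children", bw_kg = 15),
           mc_config(n_iter = 30000, seed = 1))
#>   species group      p50   p95 p_exceed n_iter  seed
#> 1 <NA>    children  1.79  3.68    0.887  30000     1
```

i.e. under intake variability the median THQ is 1.79 and 88.7% of simulated
weeks exceed the hazard threshold. The whole chain (describe →
deterministic risk → Monte Carlo, with CSV outputs and a constants log) is
available as `run_pipeline(run_config(generator = TRUE, outdir = "out",
seed = 1))` or from the shell via `inst/scripts/hgrisk-pipeline.R`.

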