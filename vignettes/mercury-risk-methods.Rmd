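---
title: "Methods: mercury bioaccumulation statistics and dietary risk in hgrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mercury bioaccumulation statistics and dietary risk in hgrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgrisk)
```

## Scope and data model

`hgrisk` analyses total mercury (THg) measured across multiple organs of
freshwater fish and converts muscle concentrations into human dietary-risk
metrics. The survey container (`hg_survey`) holds one row per specimen
(species, trophic guild, reservoir, total length TL in cm, total weight TW
in g) and one row per specimen × organ measurement (THg in mg·kg⁻¹ wet
weight plus a below-detection flag). Nine organ tokens are accepted
(muscle, liver, kidneys, spleen, gills, bones, gonads, hearts, skin):
dissection protocols commonly list seven, but heart and skin measurements
occur in multi-tissue datasets and excluding them would silently drop data.

Two unit conventions cause most real-world errors in this domain, so both
are pinned down once:

* concentrations are mg·kg⁻¹ wet weight *everywhere* inside the package;
  files recorded in µg·kg⁻¹ are converted at the I/O boundary
  (`read_survey(conc_unit = "ug_kg")`) and never after;
* weekly intakes are g·week⁻¹ and are converted to daily intake by exact
  division by 7 (so the 140 g·week⁻¹ baseline is exactly 0.02 kg·day⁻¹,
  and 7.3 kg·year⁻¹ × 1000 / (365/7) = 140 g·week⁻¹ exactly).

Values below the limit of detection (LOD, default 5×10⁻⁵ mg·kg⁻¹) are
stored as LOD/2 with `below_lod = TRUE`. LOD/2 substitution is the standard
simple imputation for left-censored environmental data; at this LOD it is
numerically irrelevant for risk but keeps the data model total.

## Size classes and comparative statistics

Within a species, specimens are split at the median TW: strictly above the
median is `large`, at or below is `small`. The tie rule (median element
joins `small`) is a deliberate conservative choice: small fish carry lower
concentrations, so ties inflate the low class and advisories derived from
the large class are not diluted.

The comparative toolkit follows common practice in ecotoxicological
surveys, with the implementation delegated to the standard R machinery and
the contracts fixed here:

* **Normality gate** — Shapiro–Wilk at α = 0.05; rejection triggers a
  log₁₀ transform. The gate reports its decision so downstream results
  carry a `transformed` flag.
* **One-way ANOVA + Tukey HSD** (`stats::aov`, `stats::TukeyHSD`), with
  Levene's test (absolute deviations from group medians, via `car`) run
  alongside. Variance heterogeneity warns rather than aborts: in small
  unbalanced organ panels a hard abort would disable most comparisons, and
  the F test is reported with its caveat attached.
* **Correlation matrices** — Pearson and Spearman between TL or TW and
  tissue THg, per species × organ cell or pooled per organ. Cells with
  n < 3 are reported as *absent* (`estimable = FALSE`), never as zero.
  Correlations are computed on the raw concentration scale by default with
  a `log_thg` switch; the raw scale is the default because pooled
  organ-level summaries are conventionally reported that way, and the
  choice is exposed rather than hidden. Per-cell p-values are deliberately
  *not* corrected for multiplicity across the matrix; this mirrors how
  such tables are usually reported and is flagged here as liberal.
* **Mann–Whitney size contrast** — two-sided; exact null when the combined
  n ≤ 20 and there are no ties (the study-scale contrast is 4 vs 4, where
  only the exact null is defensible), normal approximation with continuity
  correction otherwise. The reported statistic is the smaller of the two U
  values. The test suite holds the implementation to a full-enumeration
  oracle over all `choose(n1+n2, n1)` label assignments for combined
  n ≤ 10.
* **OLS size models** — THg ~ TL + TW per species with residual normality,
  leverage and non-constant-variance diagnostics; a design with TL and TW
  collinear to machine precision is refit on TL alone and flagged
  degenerate rather than silently inverted.

## Deterministic risk

For consumer groups with fixed body weight BW (defaults 70/60/15 kg for
adults, pregnant women, children) and weekly intake IR:

* EDI = C × (IR/7/1000) / BW, mg·kg⁻¹·day⁻¹;
* THQ = EDI / RfD with RfD = 1×10⁻⁴ mg·kg⁻¹·day⁻¹ (MeHg oral reference
  dose); THg is used as a 1.0 proxy for MeHg by default, with a
  `mehg_fraction` knob in (0, 1] to explore the 80–95% muscle MeHg range;
* HI = Σ THQᵢ over a diet basket of species shares summing to 1;
* SWI = TWI × BW / C × 1000 g·week⁻¹ with TWI = 1.3×10⁻³ mg·kg⁻¹·week⁻¹
  (EFSA), evaluated at both the species median and the P95 of muscle
  concentrations (P95 from n < 20 warns: a tail quantile of a dozen fish is
  an unstable advisory basis).

The algebra is kept exact: `SWI × C = TWI × BW × 1000` holds to machine
precision before reporting, and consuming exactly SWI grams in a week at
concentration C delivers exactly the tolerable weekly dose. Rounding is a
reporting decision only — THQ to 3 decimals and SWI to the nearest gram in
output tables, matching how such advisory tables are printed (published
input medians are themselves rounded, so reproduced table entries can
differ by one unit in the last place).

Traffic-light categories on SWI: red < 140 g·week⁻¹ (less than one
baseline week of fish), yellow 140–299, green ≥ 300. The boundaries are
closed on the left of each upper class (140 is yellow, 300 is green).

## Monte Carlo engine

Per iteration, THQ is computed from one concentration draw and one intake
draw with BW fixed per group:

* IR ~ Triangular(50, 140, 350) g·week⁻¹, sampled through the closed-form
  inverse CDF. The triangular model is the standard data-limited choice for
  intake: minimum, most-likely and maximum are elicitable where a full
  intake distribution is not. A collapsed triangle (min = mode = max) is
  accepted so deterministic scenarios are expressible in the same engine.
* C by species-specific empirical bootstrap: one draw per iteration,
  uniformly with replacement from the observed muscle values. Drawing
  individual values (not resampled means) is what preserves the empirical
  skewness and tails in the THQ distribution.
* C and IR come from two independent uniform streams of a single seeded
  generator — independence is the transparent baseline; dependence between
  species choice and intake is out of scope.
* BW is a fixed constant per group, not a distribution (a distribution
  hook would be straightforward but is deliberately off: fixed BW keeps
  the group contrast interpretable).

Summaries per species × group: P50, P95 (type-7 quantiles, i.e. linear
interpolation of order statistics — at N = 30,000 the convention is
numerically irrelevant but tests need a fixed rule), and the exceedance
probability P(THQ > 1) reported both as a fraction and in percent. The
hazard-index variant shares one intake draw per iteration across the
basket (a consumer eats one weekly amount, split by shares) with
independent bootstrap concentration draws per species; a single-species
basket reproduces the THQ engine draw for draw under the same seed.

Because the triangular distribution has closed-form CDF and quantile
functions, the engine is validated against analytic oracles rather than
against itself: with a degenerate concentration, P(THQ > 1) must equal the
triangular survival function at the critical intake `7000·BW·RfD/C` within
binomial Monte Carlo error, and with both C and IR collapsed every draw
must equal the deterministic THQ exactly. Published Monte Carlo summary
tables for this kind of survey are *not* reproduction targets: they depend
on the unpublished per-fish concentration vectors, so the engine's
correctness surface is the analytic oracle plus degeneracy contracts.

## The synthetic survey generator

The generator exists so the full pipeline is testable end to end without
field data. It emulates a 49-specimen survey of 7 species across 3
cascade reservoirs with the following structure:

* **Design** — exact specimen counts per species × reservoir cell
  (totalling 49; e.g. 17 Prussian carp across all three reservoirs, perch
  in the upper and lower reservoirs only).
* **Morphometrics** — TL lognormal around the species median (log-scale SD
  0.18, a realistic within-species length spread); TW from a cubic
  length–weight power law through the species TL/TW medians with
  multiplicative noise (log-scale SD 0.08). Cubic allometry with a
  species-specific condition factor is the standard fish length–weight
  model.
* **Concentrations** — per organ,
  `THg = A_organ · m_species · ρ_reservoir · (TL/TL_med)^b · exp(ε)`,
  ε ~ N(0, σ²_organ). Lognormality is the natural choice for positive,
  right-skewed tissue concentrations (every organ's reference mean exceeds
  its median). The size effect is a power law in TL — equivalently linear
  in log TL — which keeps concentrations positive, is scale-invariant, and
  admits closed-form calibration; the default exponents are +2.0 for
  Prussian carp muscle (accumulation with size) and −2.5 for perch bones
  (growth-dilution-like), zero elsewhere.

Calibration is constructive, at runtime, from the embedded reference
tables:

1. reservoir multipliers ρ are fixed proportional to the reservoir muscle
   means (0.058 / 0.039 / 0.014 mg·kg⁻¹ for the upper / lower / middle
   reservoir), normalised to a count-weighted mean of 1 — fixing ρ rather
   than fitting it jointly keeps species and reservoir effects separately
   identifiable when several species occur in a single reservoir;
2. species multipliers m are then solved exactly so each species'
   count-weighted geometric mean of cell medians equals its muscle median
   target (0.107 for perch down to 0.009 for common carp);
3. per-organ residual SDs come from the organ mean/median ratio
   (σ² = 2·ln(mean/median)) net of the between-cell variance implied by
   step 1–2, floored at 0.3 so within-cell variation never collapses;
4. per-organ amplitudes A are solved in closed form so the *expected*
   pooled organ mean equals the reference mean exactly (the lognormal
   mean correction exp(σ²/2) and the size-effect variance term
   exp(b²σ²_TL/2) are both accounted for analytically).

Step 4 is what makes the replicate-mean check meaningful: the expected
grand muscle mean of a default survey is exactly 0.044 mg·kg⁻¹, so
averaging replicate surveys must converge to it with no tuning margin.

What the generator does *not* emulate: organ × reservoir interactions
(organ offsets are applied uniformly — organ-level panels in such surveys
are too unbalanced across reservoirs to support an interaction), seasonal
and MeHg-speciation structure, between-specimen correlation of organs
beyond the shared specimen effects (organ residuals are independent given
the specimen's cell and TL), and measurement error models. Tests passing
on generated data therefore demonstrate the pipeline's correctness and
calibration, not distributional claims about any real reservoir system.

## Numerical choices and degenerate inputs

* Quantiles are type 7 everywhere (R's default).
* Median-TW ties go to the small class (see above).
* `u = 0` and `u = 1` map to the triangular support endpoints; uniform
  variates are mapped to bootstrap indices by `floor(u·m)+1` clamped to
  `m`.
* Sub-LOD generator draws become LOD/2 with the flag set.
* An all-zero count table, an empty concentration sample, an empty size
  class, `c = 0` in any risk formula and a negative SWI all abort with
  specific errors; an infinite consumption allowance is never emitted.
* Pipeline stages (`input → describe → risk-det → risk-mc`) abort with
  stage-labelled diagnostics, and a run log records the seed, iteration
  count and every constant used.

## Problem sizes

The test suite and the acceptance script run at the study's native scale:
49-specimen surveys (inflated to 12–40× per cell only for
parameter-recovery checks, where the configuration itself is the oracle),
200 replicate surveys for the calibration mean, and N = 30,000 Monte Carlo
iterations. A full run of everything takes well under a minute on a single
core.

## Limitations

THg as a MeHg proxy overstates dose where the MeHg fraction is low; the
`mehg_fraction` knob explores but does not resolve this. Fixed BW ignores
within-group anthropometric variability. The correlation matrix's
uncorrected p-values will overstate significance across many cells. Exact
Mann–Whitney p-values require tie-free data; ties silently switch to the
approximation (with continuity correction), which is the standard but not
exact treatment. The generator's calibration matches first moments and
medians, not full distributions; its reservoir means follow the reference
gradient but, for species present in a single reservoir, species and
reservoir effects are confounded by design and the species target wins.
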