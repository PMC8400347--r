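---
title: "Classifying sweetened beverages in dietary recall data: methods and design"
author: "bevclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sweetened beverages in dietary recall data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bevclass)
```

## The problem

24-hour dietary recalls in national surveillance surveys attach every
reported beverage to an 8-digit foodcode in a food-composition database.
Nothing in that database states whether a foodcode's beverages contain a
low-calorie sweetener (LCS), so analyses of low-calorie sweetened beverage
(LCSB) consumption have improvised. Four families of identification
strategies recur in the literature:

1. **Database organization** — take codes under the carbonated-soft-drink
   prefix ("924...") whose descriptions read like diet drinks.
2. **Survey food categories** — take the "diet" beverage categories
   (7102, 7104, 7106).
3. **Caloric density** — call anything below an energy cut-off an LCSB.
   Published cut-offs include the FDA low-calorie (<40 kcal/8 fl oz) and
   no-calorie (<5 kcal/8 fl oz) definitions, <6.7 kcal/8 fl oz, and
   <50 kcal/240 g (a mass basis).
4. **Text search** — flag codes whose descriptions carry terms like
   "diet", "sugar-free", "light".

Each strategy both misses LCS-containing beverages and captures beverages
without any LCS. Worse, some foodcodes cover several branded products
that *disagree* on LCS content; for such **mixed** codes the sweetener
exposure of an individual report is undecidable. `bevclass` implements
all four strategies, an ingredient-based reference classifier with mixed
detection, the downstream consumer-group pipeline, design-based survey
regression, and a two-scenario sensitivity analysis that bounds the
consequences of the mixed codes.

## The ingredient-based reference classifier

For each foodcode, in each 2-year survey cycle separately:

* **LCSB** if the description explicitly indicates an LCS, or if *every*
  branded product with a known ingredient list contains at least one
  recognized LCS. A product listing both sugar and an LCS counts as
  LCS-containing.
* **SB** if no known product contains an LCS.
* **MIXED** if some but not all do.
* **NONSWEETENED** for codes in an explicitly supplied set (plain and
  unsweetened carbonated waters, plain teas and coffees); the databases
  provide no machine-readable flag for "unsweetened", so this set is an
  input, not an inference.

Several design points were genuinely open and are resolved as follows:

* **Explicit-description terms** are restricted to
  `{low-calorie sweetener, no-calorie sweetener, sugar-free, diet,
  dietetic, artificial sweetener}`. "Light", "reduced sugar", and
  "less sugar" are deliberately excluded: the packaged worked example
  contains light/reduced-sugar products with no LCS at all, so those
  labels must not override ingredient evidence.
* **Unknown ingredient lists** (archival product pages that cannot be
  located) are excluded from the all/some/none tally and noted in the
  provenance string. If they are the *only* evidence and the description
  is not explicit, classification raises an error instead of guessing;
  `build_classification_table(..., on_unclassifiable = "warn")` downgrades
  this to a warning with an `NA` class.
* **Conflicts** between an explicit description and unanimous contrary
  ingredient evidence resolve in favor of the ingredients, and the
  provenance records the conflict. Label text is marketing; ingredient
  lists are regulatory.
* **Token matching.** All text matching is whole-token with hyphen/space
  variants collapsed, so "diet" never fires on "Dietary supplement".
  Uncontrolled substring matching is precisely the failure mode that
  makes naive text strategies over-inclusive.

## Units and thresholds

Energy densities are stored as kcal/100 g with a foodcode-specific
grams-per-fluid-ounce conversion factor (plain water: 29.6 g/fl oz;
beverages span roughly 24-32 g/fl oz in recent cycles, and LCS-sweetened
drinks are measurably less dense than sugar-sweetened ones). The serving
bridges are

$$\mathrm{kcal/8\,fl\,oz} = \mathrm{kcal/100\,g} \times \frac{8 f}{100},
\qquad
\mathrm{kcal/240\,g} = \mathrm{kcal/100\,g} \times 2.4,$$

with $f$ the conversion factor; the mass-basis criterion never touches
$f$. All caloric-density comparisons are strict (`<`), as the published
criteria are printed; boundary values are excluded. When manufacturer
energies are the source and a code has several products, the minimum
known manufacturer value is used (the code counts as low-calorie if any
branded product under it qualifies).

Consumer groups use the published 4-oz day-1 rule: with effective LCSB
volume $L$ and SB volume $S$ (mixed volume joined to one side per
scenario), a participant is LCSB+SB if $L \ge 4$ and $S \ge 4$; LCSB if
$L \ge 4, S < 4$; SB if $S \ge 4, L < 4$; water if both are below 4 and
plain water (from the dietary questionnaire variable, at 29.6 g/fl oz) is
at least 4 oz; otherwise ungrouped and excluded from models — the
published analysis uses exactly four groups and is silent about the
remainder. The questionnaire-vs-recall water comparison uses a 1 g
absolute tolerance; the source material reports that mismatches exist but
states no tolerance.

## Survey estimation

`fit_survey_wls()` computes weighted least squares with a
Taylor-linearization covariance for a stratified cluster design
(with-replacement first-stage approximation): score totals per primary
sampling unit, between-PSU covariance within stratum scaled by
$n_h/(n_h-1)$, sandwiched in $(X'WX)^{-1}$, with design degrees of
freedom $\#\mathrm{PSU} - \#\mathrm{strata}$. Strata with a single PSU
are centered at the grand mean of PSU totals (switchable to a hard
error); the source material is silent on lonely-PSU handling.

Residual normality is operationalized as weighted residual skewness:
the transform ladder (identity, $\sqrt{y}$, $\log y$, $-1/\sqrt{y}$,
$-1/y$) is walked in order and the first rung with $|\mathrm{skew}| <
0.5$ is accepted. The published analysis says residuals were
"transformed until normal" without naming a test; a skewness cut-off is
deterministic, cheap, and monotone along the ladder for right-skewed
dietary outcomes. Rungs undefined for the observed outcome range
(e.g. log with non-positive values) are rejected rather than shifted.

Least-squares means are evaluated at the survey-weighted covariate
profile (weighted means of continuous covariates, weighted proportions of
factor dummies) — the evaluation point is not stated in the source
material, and the weighted profile is the natural design-consistent
choice. LSMs and standard errors are reported on the untransformed scale
while pairwise comparisons use the transformed scale, mirroring the
published reporting convention. Pairwise p-values are Tukey-Kramer
adjusted through the studentized-range distribution at the design df,
with a compact letter display (insert-and-absorb). The comparison family
is one outcome-model fit, as the published table's footnote implies.

Model 1 adjusts for age, sex, race/ethnicity, income, physical activity,
and BMI percentile; Model 2 adds total energy intake (and is therefore
skipped when energy is the outcome).

## The two-scenario sensitivity analysis

Mixed codes make individual exposure undecidable, so the pipeline is run
twice: once with all mixed volume counted as LCSB, once as SB.
`diff_scenarios()` reports per-group sample-size shifts, significance
flips at 0.05 (adjusted p-values only, matching the letter-based
presentation), and the largest LSM movement per outcome and model. Total
participant counts and classification counts must be conserved between
scenarios; violation is an error, not a warning.

Two properties of the rule are theorems and are tested as such: moving
mixed volume to the LCSB side can only grow the LCSB-side groups and
shrink the SB group, and participants on the LCSB side under the
mixed-as-SB scenario are a subset of those under mixed-as-LCSB. Water
group invariance is *not* a theorem of the rule (a participant holding
3.5 oz pure LCSB + 1.5 oz mixed + ample water would switch); it holds in
realistic data because mixed-code consumers drink their mixed beverages
in group-qualifying amounts, and the synthetic generator reproduces that
structure (see below).

## What the synthetic generator emulates — and what it does not

`gen_universe()` draws a foodcode universe with exact configured
composition (largest-remainder rounding), conversion factors in
[24, 32] g/fl oz, low energy densities for LCSB codes and sugary ones for
SB codes, and branded products realizing each code's true class; with
probability 0.1 a product's manufacturer energy is resampled from the
opposite side of the 40 kcal boundary, reproducing the large
database-vs-manufacturer discordances seen in the packaged worked
example. `gen_population()` draws intended consumer groups, places
volumes strictly on the correct side of the 4-oz thresholds (drawn in
fluid ounces, stored as grams through each code's own factor so the unit
bridge is genuinely exercised), plants a 3% questionnaire-vs-recall water
mismatch rate, attaches a stratified two-PSU-per-stratum design with
lognormal weights, and builds outcomes as group effect + age and sex
trends + Gaussian noise. Default energy effects are ordered
water < LCSB < SB < LCSB+SB (baseline 1560 kcal; +160, +320, +490),
matching the ordering and rough magnitude of published group contrasts.
Mixed-code exposure is generated by routing a configurable share of
LCSB-side consumers' LCSB volume entirely through mixed codes, which is
how mixed codes are consumed in practice and which keeps the water group
scenario-invariant by construction.

The generator does **not** emulate: day-2 (phone) recalls, item-level
nutrient composition (outcomes are drawn directly, not accumulated from
items), correlated outcomes (Model 2's energy adjustment estimates a
near-zero energy coefficient on synthetic data), cluster-level outcome
correlation, informative weights, missing covariates, or realistic brand
text. Passing tests therefore demonstrate the pipeline's correctness
and calibration under a clean design-based sampling model, not the
magnitude of misclassification effects in any real survey release.

## Numerical choices and problem sizes

Worked-example fixture energies are stored as kcal/100 g at two decimals,
chosen so the derived kcal/8 fl oz agrees with the published per-serving
figures to within 0.02 kcal and sits on the published side of every
strict threshold (exact decimal division does not round-trip in binary
floating point for several printed values, and a value of 49.999...
would silently flip the <50 criterion).

The test suite sizes its simulations for tightness per unit time: the
null family-wise error check uses 1000 simulated four-group datasets of
n = 200 under a self-representing design (measured rate 0.045); the
parameter-recovery check uses 500 replicates of an n = 400 population
under a 10-stratum, 2-PSU design, asserting unbiasedness within
Monte-Carlo error and 95% CI coverage in [0.92, 0.98]; scenario
invariants run over 100 random universes. Every empirical number quoted
anywhere in the documentation is computed by the test suite or the
acceptance script at run time.

## Known limitations

* The ingredient classifier is only as good as the product/ingredient
  records supplied; it deliberately refuses to classify a code whose only
  products have unknown ingredients.
* The lonely-PSU centering and the minimum-manufacturer-kcal rules are
  defensible conventions, not published prescriptions; both are
  documented switch points.
* The compact letter display is the standard insert-absorb construction;
  for pathological non-transitive significance patterns, letters are a
  lossy summary of the pairwise table, which is always returned
  alongside.
* Day-2 recalls, growth-chart BMI percentile computation, and native
  survey transport formats are out of scope; inputs arrive as the
  documented CSV schemas.
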