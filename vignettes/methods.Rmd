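---
title: "Dietary inflammation and antioxidant scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary inflammation and antioxidant scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflamdiet)
```

## The scores

### E-DII

The Dietary Inflammatory Index summarizes the inflammatory potential of
a whole diet as a weighted sum over food parameters.  The weights
(*effect scores*) were derived in prior literature from the effect of
each parameter on six inflammatory biomarkers (IL-1β, IL-4, IL-6, IL-10,
TNF-α, CRP); they are configuration inputs here, not something the
package computes.  The energy-adjusted variant (E-DII) scores nutrient
*densities* — amount per 1000 kcal of total energy — so that diets of
different caloric size are comparable:

$$
x_i = \frac{\text{raw intake}_i \times 1000}{\text{energy (kcal)}},\qquad
z_i = \frac{x_i - \mu_i}{\sigma_i},\qquad
\text{E-DII} = \sum_i w_i\,\bigl(2\Phi(z_i) - 1\bigr)
$$

with $\mu_i,\sigma_i$ the global reference density moments.  The
construction guarantees:

* each contribution is **zero at the global-mean density** and strictly
  bounded by $|w_i|$ at any finite intake;
* the total is **isocaloric-invariant**: scaling every intake and the
  energy by the same factor changes nothing;
* the total is monotone in each intake with the sign of $w_i$.

The test suite asserts all three as properties over randomized diets.

Two points the published method descriptions leave open, and the
conventions adopted here:

* *"Converted to a proportion"* is implemented as the standard normal
  CDF of the z-score, the referenced method's convention.  An
  alternative transform (e.g. an empirical percentile function) can be
  injected through the `percentile_fn` argument of `parameter_score()`;
  the CDF remains the default.
* Densities are formed against **total** energy including
  alcohol-derived kilocalories, and the alcohol parameter itself is
  densified the same way.  The alcohol-free energy variable appears only
  as a sensitivity-analysis covariate (`energy_nonalcohol`), not in the
  score.
* Parameters missing from a subject are **skipped, never imputed as
  zero intake** — zero consumption is a strong dietary statement,
  missing data are not.  Coverage is reported per subject
  (`n_parameters_used`, `missing_parameters`).

All arithmetic is double precision with no intermediate rounding.

### NEAC

Total dietary non-enzymatic antioxidant capacity on the TEAC scale is a
linear functional of food-item gram intakes:
$\text{NEAC} = \sum_j \text{grams}_j/1000 \times \text{TEAC}_j$, with
TEAC content in mmol Trolox equivalents per kg of edible food.  Totals
are computed with and without coffee-flagged items; the **no-coffee
total is the default exposure** in the analysis layer, matching the
descriptive convention of the studies this design follows.  Published
tables are internally inconsistent about the daily-intake unit (µmol
vs mmol TE/day next to mmol TE/kg contents); this package standardizes
on **mmol TE/day** throughout and makes no attempt to guess which unit a
given external table intended.

Unmatched food items are skipped with a count rather than an error:
FFQ/TEAC table mismatches are routine in practice.

## Quartiles, profile and combined category

Exposure quartiles are computed **on controls only** (cases never move a
cutpoint) and, for mixed-sex outcomes, **within sex**.  Numerical
choices that matter near ties:

* percentile estimator: linear interpolation between order statistics
  (`stats::quantile` type 7).  Published quartile group sizes are
  sensitive to this choice when ties exist, and the estimator is rarely
  stated; type 7 is R's default and is documented here as the package's
  convention.
* interval convention: **closed above, open below** (Q1 iff value ≤ q25,
  Q4 iff value > q75), the convention readable from printed bounds of
  the form "≤ a … > c".
* fully degenerate cutpoints (all controls identical) assign everything
  to Q1 with a warning rather than failing.

The combined inflammatory–antioxidant **profile** assigns 0–3 to
ascending E-DII quartiles and 3–0 to ascending NEAC quartiles and sums
them: 0 = least inflammatory / most antioxidant, 6 = most
inflammatory / least antioxidant.  The alternative **median-split
combined category** cross-classifies subjects by control medians of both
scores, with low-E-DII/high-NEAC as the reference level and values
exactly at a median counted as "low" (the same closed-above rule).

## The analysis layer

Associations are estimated by unconditional logistic regression
(`stats::glm`, binomial family, IRLS with relative tolerance 1e-10 and
at most 100 iterations).  Conventions:

* **Wald 95% CIs** ($\exp(\hat\beta \pm 1.96\,\mathrm{se})$) and Wald
  p-values per term.
* Categorical covariates are dummy-coded with declared reference levels;
  an explicit `"unknown"` level is retained as its own dummy, never
  treated as missing.
* The **trend test** enters the quartile index itself (1–4) as a
  continuous term in the adjusted model — not quartile medians.
* **Effect-measure modification** is tested by the likelihood-ratio
  statistic $2(\ell_{with} - \ell_{without}) \ge 0$ between nested
  models with and without exposure-by-modifier terms, against a
  chi-square with df = number of interaction terms.
* Stratified analyses drop the stratifier from the covariate set; strata
  lacking both outcome levels are skipped with a warning.
* The sensitivity suite re-fits a final model (1) excluding cases
  interviewed more than 6 months after diagnosis, (2) additionally
  adjusting for non-alcohol energy and alcohol intake, (3) restricted to
  non-drinkers (alcohol intake exactly 0 g/day).
* **No multiple-testing correction** is applied (two-sided α = 0.05),
  matching field practice for these association tables; reports state
  how many tests were run rather than adjusting them.

Separation and rank deficiency raise errors naming the offending terms;
silently dropping aliased coefficients would corrupt odds-ratio tables.
On any saturated 2×2 design the MLE odds ratio equals the cross-product
ratio; `crude_or_2x2()` (with the Woolf interval) is kept as an
independent arithmetic oracle and the equality is asserted to relative
1e-6 in the tests.

## The synthetic-study generator

`generate_intakes()`/`generate_study()` exist so that every stage —
loaders, engines, quartile machinery, model fits — can be validated
against known ground truth.  The design:

* **Marginals.** Total energy is lognormal with mean 1805 kcal/day and
  SD 535 (the control-group intake of the motivating study population);
  each nutrient density is lognormal with the reference table's global
  mean and SD, so a typical simulated diet scores near the centre of
  each parameter's range; food-item grams are lognormal with plausible
  Spanish-diet portion means calibrated so the no-coffee NEAC mean is
  ≈4–5 mmol TE/day.  Lognormal marginals guarantee non-negativity.
  30% of subjects are non-drinkers (alcohol exactly 0), which both
  exercises the zero tail and gives the non-drinker sensitivity analysis
  a non-empty population.
* **Dependence.** A Gaussian copula: each nutrient density loads
  (loading 0.65, sign-aligned with its effect score) on a latent
  *inflammatory* factor, each item's grams load (0.65) on a latent
  *antioxidant* factor, and the two factors are correlated.  Because the
  computed scores are noisy, nonlinear functions of the factors, the
  score-level correlation is attenuated relative to the factor
  correlation.  The generator therefore measures the attainable maximum
  |cor(E-DII, NEAC)| on a deterministic internal pilot (n = 4000, fixed
  internal seed, perfectly correlated factors) and scales the factor
  correlation so the **computed scores** hit the configured target —
  default **−0.32**, the inverse E-DII/NEAC association reported for the
  population this generator emulates.  A target beyond the attainable
  maximum errors out before sampling.
* **Outcome.** Case status follows
  $P(\text{case}) = \text{logit}^{-1}(\alpha + \beta\,\text{exposure} +
  \gamma'\text{covariates})$, with the exposure either the continuous
  E-DII or the 0–6 profile (computed from sex-specific quartiles of the
  pre-outcome population), optional planted quartile effects and
  interactions, and $\alpha$ solved by `uniroot` to hit the requested
  marginal case fraction (default 0.35, a typical case share in large
  case-control studies).  Default planted effect: $\beta = \log(1.14)$
  per E-DII point, the order of magnitude reported for colorectal
  cancer.  Covariates (sex, age, study area, education, smoking, BMI,
  physical activity, family history, NSAID use) have marginals loosely
  mirroring published baseline tables — calibration conveniences, not
  estimates — and are drawn **independently of diet**, so adjusted fits
  recover $\beta$ without confounding bias.  All planted coefficients
  travel in the `truth` attribute and round-trip through `truth.json`.
* **Reproducibility.** One master integer seed; each stage (calibration,
  intakes, covariates, outcome) uses a deterministically derived
  sub-stream, so identical config + seed ⇒ identical output bit for bit.

What the generator does **not** emulate: food-level dietary patterns
(nutrients and food items are linked only through the latent factors,
not through a food-composition mapping), FFQ measurement error and
recall bias, frequency matching of controls, and confounding between
diet and the covariates.  Passing recovery tests therefore demonstrate
that the scoring and modelling machinery is correct and unbiased under a
clean data-generating process — not that any real-data estimate is
unbiased.

## Problem sizes and tolerances

The test suite runs parameter-recovery fits at n = 20,000 (planted
per-unit log-ORs over the grid {log 1.04, log 1.14, log 1.22}, each
required to land within 3 standard errors), correlation calibration
checks at n = 10,000 (±0.05), and null-calibration sweeps of the trend
and LRT machinery at 1000 replicates of n = 300 (empirical type-I error
required in [0.03, 0.07] at α = 0.05).  These sizes give Monte-Carlo
noise comfortably below the assertion tolerances while keeping the whole
suite around half a minute on one CPU.

## Known limitations

* The shipped parameter reference and TEAC tables are **synthetic
  placeholders** (clearly labelled): real analyses must supply the
  energy-adjusted global DII database and published food-composition
  TEAC values, which are not redistributable here.
* Only unconditional logistic regression is provided; matched designs
  needing conditional likelihoods are out of scope.
* Profile-likelihood CIs are not implemented; Wald intervals can be
  anti-conservative in sparse strata (the separation error is the
  guardrail).
* The empirical-percentile E-DII variant is exposed as an injection
  point but has no packaged percentile database.
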