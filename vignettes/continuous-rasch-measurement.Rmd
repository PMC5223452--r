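---
title: "Rasch measurement for continuous item responses: model, estimation and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch measurement for continuous item responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschcir)
```

## The measurement problem

Healthcare and survey settings routinely produce *bounded continuous*
outcomes — percentage scores, domain means of a safety-attitude survey,
task scores — that analysts want to compare across units on a common
interval scale. Classical test theory treats the raw scores as if they were
additive; they generally are not. The Rasch family of latent-trait models
places persons (units) and items (domains) on one logit scale, but standard
Rasch software accepts only dichotomous or ordered-category responses.

`raschcir` extends the one-parameter Rasch model to continuous item
responses (CIRs). Each raw response is first rescaled affinely to the unit
interval using the instrument's per-item bounds,

$$x_{nj} = \frac{O_{nj} - \min_j}{\max_j - \min_j} \in [0, 1],$$

and then treated as a *fractional success*: its expectation is the Rasch
probability

$$E[x_{nj}] = p_{nj} = \frac{e^{\theta_n - \delta_j}}{1 + e^{\theta_n - \delta_j}},$$

with person measure $\theta_n$ and item difficulty $\delta_j$ in logits.
A 5-point Likert item with bounds (1, 5) maps onto 0, 0.25, 0.5, 0.75, 1;
binary data pass through unchanged, so the dichotomous Rasch model is the
special case $x \in \{0, 1\}$.

No full likelihood is asserted for the continuous cells. The model is a
quasi-binomial (working-variance) specification: each cell has mean
$p_{nj}$ and working variance $\mathrm{Var}_{nj} = p_{nj}(1 - p_{nj})$.
This is exactly the specification under which the estimation updates below
are Newton-Raphson steps on the score equations
$\sum_j (x_{nj} - p_{nj}) = 0$ (one per person) and
$\sum_n (x_{nj} - p_{nj}) = 0$ (one per item), and it reduces to genuine
maximum likelihood for binary data.

## Joint estimation

`cir_fit()` estimates all persons and items together:

1. all $\theta_n$ and $\delta_j$ start at 0 logits — every person equally
   able, every item equally difficult;
2. expectations $p_{nj}$, residuals $R_{nj} = x_{nj} - p_{nj}$ and
   variances $\mathrm{Var}_{nj}$ are computed for every observed cell;
3. persons are updated:
   $\theta_n \leftarrow \theta_n + \sum_j R_{nj} / \sum_j \mathrm{Var}_{nj}$
   (this *is* the Newton step, since
   $\partial \sum_j (x - p) / \partial \theta = -\sum_j p(1-p)$);
4. expectations are refreshed, items are updated with the mirrored step
   $\delta_j \leftarrow \delta_j - \sum_n R_{nj} / \sum_n \mathrm{Var}_{nj}$,
   and the difficulties are re-centered so $\sum_j \delta_j = 0$ (the
   identification constraint);
5. the loop repeats until the total absolute residual $\sum |x - p|$ drops
   below `convergence_tol`, no parameter moves by more than `change_tol`,
   or `max_iter` is reached (then a warning, never an error).

### Numerical choices

* **Iteration order.** Persons are updated before items within each outer
  iteration, with expectations refreshed between the half-steps. The order
  is a free choice of the alternating scheme; both orders converge to the
  same score-equation root (the oracle test below checks the solution, not
  the path).
* **Two stopping criteria.** The total-absolute-residual target (default
  0.01) is natural for near-noiseless data, but with real noise that total
  scales with $NL$ and never reaches a fixed small level, so a
  maximum-parameter-change criterion (default $10^{-4}$ logits) is applied
  alongside it. Which criterion fired is recorded in the result.
  The residual total is read as $\sum |O - E|$; a per-cell or squared
  reading would only relabel the same converged solution because the
  change criterion dominates on noisy data.
* **Damping and clamping.** Newton steps are truncated to `max_step`
  (1 logit) to keep early iterations stable, and estimates are confined to
  $\pm$`theta_clamp` (10 logits). Persons or items whose observed responses
  all sit on one scale bound have divergent ML estimates; they are pinned
  at the clamp, flagged `extreme`, excluded from further updates and from
  the difficulty centering.
* **Variance floor.** Denominators use
  $\max(p(1-p), 10^{-6})$ so that cells with $p \to 0, 1$ cannot produce
  division by zero.
* **Missing cells** are excluded from every row and column sum; a person or
  item with no observed responses at all is a validation error.
* **Centering cadence.** Difficulties are re-centered every iteration (not
  once at the end), so intermediate iterates stay identified; at a fixed
  point the centering shift is zero either way.

Standard errors are $1/\sqrt{\sum_j \mathrm{Var}_{nj}}$ for persons and
$1/\sqrt{\sum_n \mathrm{Var}_{nj}}$ for items — the usual Rasch information
expressions under the working variance.

```{r fit-example}
sim <- simulate_cir(n_persons = 120, n_items = 6, noise = "beta",
                    beta_precision = 12, seed = 42)
fit <- cir_fit(sim$data)
fit
```

## Fit statistics

Cell-level standardized residuals are $Z_{nj} = R_{nj}/\sqrt{Var_{nj}}$.
The sign is kept deliberately: the diagnostic maps report *direction* of
misfit (an unexpectedly strong response versus an unexpectedly weak one),
and $Z^2 = R^2/\mathrm{Var}$ is unchanged. The aggregate mean squares are

* **OUTFIT** — unweighted: $\sum Z^2 / \text{count}$ over the observed
  cells of a row or column; sensitive to outlying unexpected responses;
* **INFIT** — information-weighted: $\sum R^2 / \sum \mathrm{Var}$;
  sensitive to misfit near the parameter's own location. INFIT equals
  OUTFIT exactly wherever the variance is constant across the aggregated
  cells.

Both have expectation 1 under a correctly specified (binary) model. The
conventional screening thresholds are applied with a closed boundary:
items are flagged at INFIT $\ge 1.5$ (unidimensionality screen), persons at
OUTFIT $\ge 2.0$ (aberrant/careless response screen), and individual cells
at $|Z| \ge 2.0$.

**Normalization.** Continuous responses concentrate far more tightly around
their expectation than the binomial working variance $p(1-p)$ implies (a
beta cell with concentration $\nu$ has true variance $p(1-p)/(\nu+1)$), so
raw mean squares on CIR data sit well below 1 and the conventional
thresholds would never fire. `normalize_mnsq()` divides each mean-square
set by its mean, restoring mean 1.0 exactly for interpretation on the usual
scale; flags are recomputed on the normalized values. It is off by default
because it rescales relative, not absolute, fit.

The model-level summary is
$R^2 = \sum (E_{nj} - \bar X)^2 / \sum (X_{nj} - \bar X)^2$ with $\bar X$
the grand mean of the observed responses; a per-item-mean centering is
available as an option since the centering convention is a genuine choice
for two-way data. An accompanying regression-style F statistic uses
df $(1, n_\text{cells} - 2)$. Two estimated difficulties can be compared
with the variance-weighted test
$t = (\delta_a - \delta_b)/\sqrt{1/\Sigma\mathrm{Var}_a + 1/\Sigma\mathrm{Var}_b}$,
with a standard-normal two-sided p-value (no degrees-of-freedom convention
is imposed).

```{r stats-example}
stats <- fit_statistics(fit)
stats
```

## Diagnostic displays

Three builders return plain structured data (data frames inside a classed
list); `render_map()` writes them as deterministic JSON — the machine-readable
surface that the tests target — or renders SVG/PNG via the plot methods.
Figures are styling; the data are the contract.

* `build_wright_map()`: the person-measure histogram (default bin width
  0.25 logits — fine enough to resolve a 1-logit spread, coarse enough not
  to fragment a few hundred persons) aligned with the items on one logit
  axis, each item carrying its INFIT mean square; items below 1.5 are
  annotated as consistent with a single construct.
* `build_kidmap()`: for one focal person, each item's cohort distribution
  as a Tukey five-number summary (the box-plot convention; no whisker rule
  is imposed beyond min/max), the focal response, and the focal $Z$;
  items with $Z \ge +2$ are listed as strengths, $Z \le -2$ as weaknesses.
  The classification agrees cell-for-cell with the fit-statistics flags.
* `build_icc_overlay()`: the logistic expectation curve over the fitted
  logit range with one point per person at (measure, OUTFIT) and the 2.0
  reference line. Only OUTFIT is placed on the vertical axis — mixing a raw
  score axis with a mean-square axis in one panel distorts both.

## Adaptive testing

The CAT engine administers a calibrated Rasch bank item by item:

* **Selection** is maximum information: the unadministered item with the
  largest $p(1-p)$ at the current provisional measure, i.e. the difficulty
  nearest the measure, ties to the lowest bank index. (No selection rule is
  forced by the model; nearest-difficulty is the standard Rasch choice.)
* **Provisional measure**: damped Newton on the score equation
  $\sum_i (x_i - p_i) = 0$ over the administered items, starting from 0
  logits; all-bound response strings are pinned at $\pm 10$ logits and
  flagged.
* **Standard error**: $1/\sqrt{\sum_i p_i(1-p_i)}$ over administered items.
* **Stopping**: the residual trail is the mean of the last three absolute
  changes in the provisional measure; the session stops when it falls
  *strictly* below 0.05. The rule is undefined (hence inactive) until four
  provisional estimates exist, which imposes a 4-item minimum by
  construction. The bank running out, or an explicit item cap, also stops
  the session. The trend correlation of the last three measures against
  their step numbers is advisory display only — a flat trend signals a
  stable measure — and never a stop criterion; a zero-variance triple is
  reported as 0 with a flatness flag.
* The engine is deliberately Rasch-only: every discrimination is 1, so
  graded-response-model banks are out of scope.

## What the synthetic generator emulates — and what it does not

`simulate_cir()` draws abilities from a normal distribution on the logit
scale (default mean 0, sd 1 — a typical calibrated-survey spread),
difficulties equally spaced on $[-1, 1]$ unless supplied (supplied values
are mean-centered to match the identification constraint), and emits cells
as:

* `exact` — $x = p$: noiseless, for identifiability checks;
* `beta` — $x \sim \mathrm{Beta}(p\nu, (1-p)\nu)$: mean exactly $p$,
  support strictly inside $(0,1)$. The default concentration $\nu = 12$
  gives cell noise of roughly $\pm 0.1$–0.14 around the expectation —
  about what multi-respondent domain means show in practice;
* `binary` — $x \sim \mathrm{Bernoulli}(p)$: classical dichotomous data.

The generator reproduces the model's mean structure by construction. It
does **not** emulate multidimensionality, local dependence between items,
rater effects, floor/ceiling spikes, or systematically missing cells — so
passing recovery tests demonstrate correctness of the estimator under the
model, not robustness of the model on arbitrary real data.

`oracle_binary_jmle()` is the independent cross-check: alternating
one-dimensional derivative-free profile-likelihood searches per parameter
(with the same centering constraint), sharing no code with the Newton path.
On simulated binary data (100 persons, 11 items) the two routes agree to
well under 0.02 logits per parameter.

## Problem sizes and verification

The shipped tests exercise: oracle equivalence at 100 persons x 11 binary
items; difficulty recovery at 300 x 6 with beta noise ($\nu = 12$), where
the Pearson correlation between true and estimated difficulties exceeds
0.95 and their RMSE stays below 0.2 logits; OUTFIT calibration at
500 x 11 binary (grand mean within [0.85, 1.15], exactly 1 after
normalization); and 200 simulated CAT sessions on a 30-item bank, where
$\hat\theta \pm 1.96 \cdot \mathrm{SE}$ covers the generating ability in at
least 85% of sessions. These sizes estimate each property stably while
keeping the default suite fast.

With beta noise the interval coverage is in fact conservative (near 100%):
the SE uses the binomial working variance, which overstates the true cell
noise — the same phenomenon that motivates mean-square normalization.

## Known limitations

* The working-variance specification is an estimating-equation device, not
  a full likelihood for continuous cells; SEs and mean squares inherit its
  conservatism on low-noise data (see normalization above).
* Joint (person-and-item) estimation carries the usual small-$L$ JMLE bias
  on binary data; the package matches its own score equations, not
  conditional-ML estimates.
* Extreme response strings receive clamped measures, not finite ML
  estimates; their SEs are not meaningful.
* One scale per item: no discrimination, guessing, or rating-scale
  thresholds.
* The KIDMAP compares a person against the raw cohort distribution of each
  item; it does not adjust the cohort for ability differences.
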