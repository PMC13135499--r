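---
title: "Methods: privacy-preserving synthesis and auditing of tabular health data"
author: "tabsafe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: privacy-preserving synthesis and auditing of tabular health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabsafe)
```

# The problem

Registry and biobank tables mix continuous measurements, calendar dates,
binary indicators and free categorical codes, and routinely carry extreme
missingness — in the cohorts that motivated this package, per-column
missingness spans roughly 0.4% to 90%. Sharing such tables is legally
constrained, so a common strategy is to release *synthetic* tables drawn from
a generative model of the real data, together with quantitative evidence that
(a) the synthetic table is statistically faithful and useful for modelling,
and (b) it does not leak information about identifiable individuals. tabsafe
implements the surrounding machinery for that workflow: preprocessing that
generative models can consume and invert, auxiliary losses that keep
generators honest about correlations and distributions, a verified
k-anonymity view for exact count release, an empirical disclosure-risk
battery, model ranking, data-sufficiency analysis and constraint-driven
postprocessing. The deep generative models themselves (GANs, VAEs, diffusion
models) are deliberately out of scope; a Gaussian-copula baseline generator
and a loss-guided refinement step stand in wherever a generator is needed
end to end.

# Bidirectional preprocessing

The structured ("level-3") pipeline handles each declared column role:

* **Dates** become signed day counts from a configurable reference date
  (default 2000-01-01).
* **Continuous and date columns** are median-imputed and pushed through an
  empirical quantile transform; each column additionally emits a binary
  missingness indicator (`<name>_q_m`) equal to 1 exactly where the input was
  missing, so models can learn informative missingness instead of having it
  erased.
* **Binary/categorical columns** gain an explicit `"Unknown"` placeholder
  level for missing cells and are one-hot encoded, avoiding spurious
  ordinality.

The quantile transform is fitted *after* imputation, so the imputed median is
itself a grid point; this is what makes records imputed to the median
indistinguishable from records genuinely at the median in the encoded view,
and what lets the inverse map restore them exactly once the indicator says
which was which. The empirical CDF uses the midpoint dialect: the *i*-th of
*n* sorted observations receives level $(i - 0.5)/n$, tied values collapse to
one grid point at the mean of their constituent levels. This choice is
symmetric, strictly monotone, and never emits exactly 0 or 1, which keeps the
optional Gaussian output law (`output = "gaussian"`) finite. Between grid
points the transform interpolates linearly and outside the observed range it
clamps, so forward and inverse maps are bijective on the fitted grid.
Inversion treats an indicator value of at least 0.5 as missing (generative
output need not be binary), decodes one-hot blocks by argmax, maps the
placeholder back to missing, and rounds day counts back to calendar dates.

A simpler "level-1/2" variant replaces missing continuous/date values with a
constant −1 and skips transforms and indicators. Its inverse maps −1 back to
missing only when −1 was never an observed value; otherwise the inversion of
imputed cells is ambiguous and the package keeps the observed −1s, which is
the honest lossy behaviour. The structured pipeline exists precisely because
the constant-imputation shortcut distorts correlations and marginals on
high-missingness clinical data.

# Correlation- and distribution-aware losses

Two auxiliary losses compare a real and a generated encoded matrix with $m$
columns. The correlation loss averages squared differences of pairwise sample
correlations over the $m(m-1)/2$ unordered pairs,

$$L_{cor} = \frac{2}{m(m-1)} \sum_{j<k} (g_{jk} - \tilde g_{jk})^2,$$

and the distribution loss compares the first $H$ moments per column through a
stabilized ratio,

$$L_{dis} = \frac{1}{m} \sum_{j=1}^m \sum_{h=1}^H \frac{1}{h}
  \left(1 - \frac{\tilde S_j^{(h)} + \epsilon}{S_j^{(h)} + \epsilon}\right)^2.$$

The combined objective adds $\alpha L_{cor} + \beta L_{dis}$ to whatever base
loss a generator trains with. Design choices the formulas leave open:

* **Correlation estimator.** Pearson on the encoded matrix (including
  one-hot and indicator columns), which covers mixed types uniformly;
  Spearman is available as an option.
* **Moment convention.** Raw moments on the encoded scale. The ratio form is
  ill-behaved around zero-mean data, and encoded features are non-negative
  by construction, so raw moments keep every denominator well away from
  zero. Central moments are available as an option; should a stabilized
  real moment still be non-positive the affected term is clamped with a
  warning rather than silently exploding.
* **Defaults.** $H = 3$, $\epsilon = 10^{-8}$, $\alpha = \beta = 1$. Three
  moment orders capture location, scale and skew; the $1/h$ weights damp the
  higher, noisier orders.

`refine_synthetic()` is a desk-scale surrogate for loss-guided training:
greedy finite-difference coordinate descent over the candidate sample with
geometric step decay, accepting only strict improvements, so the monitored
objective is non-increasing by construction. It makes the losses exercisable
end to end without a neural generator; it is not a replacement for one.

# The Gaussian-copula baseline generator

`copula_baseline_sample()` maps each encoded column to normal scores through
its empirical quantile grid, estimates the normal-score correlation matrix
(ridge-repaired if not positive definite, adding `1e-8`-scaled diagonal mass
until Cholesky succeeds), samples jointly Gaussian rows, and maps back
through the inverse grids. It preserves marginals and rank correlations up
to sampling error, which is exactly the structure the evaluation suite
measures, making it a fair reference point and a useful generator for
fixtures, pipelines and sufficiency analysis.

# Adaptive binning and verified total k-anonymity

For releasing exact counts, the package treats *every* attribute as a
quasi-identifier ("total" k-anonymity): no chain of single-value filters
over distinct columns may isolate fewer than $k$ individuals, which defends
against homogeneity and background-knowledge attacks that plain k-anonymity
leaves open. Verification combines a fast greedy test — repeatedly restrict
to the globally rarest value and drop its column; any count below $k$ is a
definitive failure — with an exhaustive recursive check that filters every
column and value. Greedy false implies exhaustive false (the greedy chain is
one of the chains the exhaustive test explores); a greedy pass is always
confirmed exhaustively. The recursion memoizes on the sorted filter set and
fails loudly when a configurable state budget (default $10^6$) is exceeded,
never passing silently.

Adaptive binning starts every attribute at its finest hierarchy level and,
while verification fails, coarsens the greedy-flagged column by one level,
removing it when no coarser level exists. Ties in the greedy scan break
first by column declaration order, then by sorted bin label — determinism
matters because a released view must be reproducible. Missing values form
their own `"missing"` bin at every level; dropping those rows would bias
released counts. Intervals are half-open $[lo, hi)$ throughout, matching the
clinical BMI convention (normal is 18.5 up to but excluding 25). Built-in
hierarchies cover birth year (decades with adapted tails, then a two-bin
split at 1950) and BMI (the four clinical classes, then a two-bin split at
25); everything else is declared in configuration. The default threshold is
$k = 10$: released aggregate views never describe fewer than ten
individuals.

# Disclosure-risk metrics

Every metric carries an explicit orientation (higher-safer or lower-safer)
in its report. Distance-based metrics standardize with means and standard
deviations fitted on the real table only and use Euclidean distance on the
encoded features.

* **Cluster k-anonymity / l-diversity** cluster the table by k-means at
  several granularities (default 2, 5, 10, 15; seeded, 10 restarts) and
  report minimum cluster occupancy, respectively minimum distinct sensitive
  combinations per cluster. Granularities producing any cluster under 5
  members are skipped as unreliable and noted in the report; when no
  granularity survives, the table is scored as a single cluster.
* **k-map / Δ-presence** fit k-means on the real table only and assign
  synthetic rows to the nearest real centroid; k-map reports the smallest
  synthetic occupancy (the most vulnerable group), Δ-presence the maximum
  per-cluster fraction of distinct real sensitive combinations also present
  synthetically (set-based overlap; a frequency-based variant would weight
  common combinations more, and the set-based form is the stricter upper
  bound).
* **Identifiability / single-out** report the fraction of real records
  strictly closer to a synthetic record than to their second-nearest real
  neighbour; ties count as not closer, so duplicated rows do not inflate
  risk. The two metrics share one construction and are reported separately
  for auditability.
* **Membership inference** scores each record by inverse distance to its
  k-th nearest synthetic neighbour ($k = \lceil\sqrt{n_{synth}}\rceil$) and
  reports accuracy at the median threshold and rank-based AUC for
  member/non-member discrimination; 0.5 is chance.
* **Correct attribution probability** simulates an attacker guessing a
  sensitive attribute from key attributes: exact key matches (zero CAP) or
  nearest keys by Hamming distance (generalized CAP), guessing the modal
  sensitive value among matched synthetic rows, with tied modes sharing
  credit. Inference risk is generalized CAP for a declared known/secret
  split; with no known columns the attacker falls back to the modal class.
* **Linkability** asks whether the nearest synthetic neighbour on one
  feature subset coincides with the nearest on a disjoint subset — evidence
  that a single synthetic record stitches two attribute sets of one person.
* **Match rates** count synthetic rows approximately matching a real row on
  all variables of a configuration (absolute spans for numeric/date, exact
  for categorical, missing matches only missing), judged against a
  real-to-real baseline that excludes self-matches. Shipped span
  configurations are illustrative defaults and are configuration-driven.

# Similarity, utility, ranking

Column shapes score $1 - \mathrm{KS}$ for numeric/date columns and
$1 - \mathrm{TVD}$ for categorical ones (missing as its own category); pair
trends score $1 - |g - \tilde g|/2$ per encoded pair. The quality score is
the unweighted mean of the two aggregates; the diagnostic score the
unweighted mean of data validity (values in range/category) and structure
(names and shape). Train-synthetic-test-real fits a class-weighted linear
model, an RBF support-vector machine and gradient-boosted trees on synthetic
data and evaluates on held-out real data with frequency-weighted
precision/recall/F1 and the G-mean of per-class recalls, which stays honest
under imbalance; augmentation reports the delta of real-plus-synthetic over
real-only training.

Competing generators are compared with the Friedman test (ranks within each
dataset, ties averaged) and Nemenyi post-hoc critical differences
$CD = q_\alpha \sqrt{k(k+1)/(6N)}$, with $q_\alpha$ taken from the exact
studentized-range distribution. Failed (model, dataset) runs receive a
sentinel worst rank — one beyond the number of models by default — before
averaging, so a model that crashes is ranked behind every model that ran.

# Data sufficiency

`size_grid()` grows from 1,000 in steps of 500 to 5,000 and then in steps of
5,000 (the scheme is fully configurable), capped at the available rows.
`evaluate_at_sizes()` subsamples, fits the generator, synthesizes at the
same size and scores each replicate. Two elbow methods locate the plateau:
ranking (Nemenyi average ranks of the sizes over metrics, pooled by family
means) and composite (metrics min-max normalized within declared threshold
ranges — default $[0,1]$ for similarity scores, orientation-flipped for risk
metrics — then averaged). Both feed `detect_elbow()`: a cubic smoothing
spline with GCV-chosen smoothness, then the kneedle procedure — normalize
both axes, orient onto the concave-increasing case, take the difference to
the diagonal, and return the largest interior local maximum exceeding a
sensitivity threshold (sensitivity 1 by default, in units of the mean grid
spacing). A straight line has no interior maximum above threshold and the
elbow is declared absent rather than fabricated.

# Postprocessing by rejection sampling

Constraint rules are declarative and come from configuration, never from the
real records, so enforcing them touches no private training data. Row-level
rules are implications (e.g. males never carry cervical, placental,
endometrial or ovarian cancers; females never prostate or testicular — the
built-in oncology pack) and range rules; batch-level dependency rules bound
the deviation of a correlation from its target on the accepted batch.
Missing values satisfy row-level predicates vacuously: rejecting on missing
would silently distort missingness. Sampling over-generates each round by
the inverse of the observed acceptance rate (floored at 0.1, capped at ten
times the target) and errors out with the partial log if the target is not
reached within the iteration budget — an undersized release is never
produced silently.

# The fixture generator

Tests and examples run on synthetic biobank-like cohorts with known planted
structure: a Gaussian copula over declared continuous marginals (log-normal
for skewed lab values) with an exact target correlation matrix, a
deterministic BMI column, uniform date ranges, categorical draws, and
disease indicators with sex-specific admissibility; missingness is injected
afterwards, MCAR or MAR (per-stratum rates keyed by a conditioning column).
Defaults mirror the variable families of a population biobank —
anthropometrics around 170 cm / 78 kg, a planted height–weight correlation
of 0.5, smoking status, a cancer label at 15–20% prevalence — and
missingness rates in tests span 30–90%, inside the envelope real registries
exhibit. What the fixtures do *not* emulate: multimodal lab distributions,
informative-missingness tangles across many columns, 600-column metabolomics
panels, or longitudinal repeats. Green tests therefore demonstrate
correctness of the machinery under controllable structure, not performance
claims about any particular real cohort.

# Problem sizes and numerical choices

The shipped test-and-audit runs use deliberately modest sizes chosen to make
Monte-Carlo tolerances meaningful: correlation recovery at $n = 5000$
(tolerance 0.05, three standard errors of $r$), copula fidelity at
$n = 2000$ (tolerance 0.08), membership-inference nulls at 500 per split
(AUC tolerance 0.07), rejection calibration at $n = 1000$ (rate tolerance
0.05), round-trip checks on 100 cohorts of 30 rows, and anonymization
soundness on up to 400-row, 6-column tables where the exhaustive verifier is
cheap. Brute-force privacy verification defaults to a $10^6$-state budget;
k-means uses 10 restarts and a fixed seed; the copula ridge repair escalates
from $10^{-8}$; quantile grids collapse ties before interpolation.

# Known limitations

* The generators shipped here are reference implementations; fidelity and
  privacy numbers for neural generators must be obtained by plugging them
  into the same evaluation surface.
* Empirical disclosure metrics are attack simulations, not formal
  differential-privacy guarantees; a low score is evidence, not proof.
* Exhaustive total-k-anonymity verification is exponential in the number of
  released columns; it is intended for the handful of overview attributes a
  released view exposes, not for whole tables.
* Generalized CAP's Hamming distance treats all key columns equally; ordered
  or continuous keys should be discretized sensibly first.
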