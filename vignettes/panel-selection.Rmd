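---
title: "Two-stage discriminant selection of metabolite panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage discriminant selection of metabolite panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldapanel)
```

This vignette is the package's own account of its statistical machinery:
the discriminant model and its assumptions, the two-stage search, the
synthetic-cohort generator that stands in for patient data, and the
numerical and design choices that were genuinely open.

## 1. The classification model

`ldapanel` implements the classical shared-covariance Gaussian model.
Class $k$ has mean vector $\mu_k$ over the $p$ selected features and all
classes share the pooled within-class covariance

$$S \;=\; \frac{\sum_k (n_k - 1)\, S_k}{n - K},$$

the weighted average of the per-class sample covariances. A subject $x$ is
scored by squared Mahalanobis distances $d_k^2 = (x-\mu_k)^\top S^{-1}
(x-\mu_k)$ and classified by the Bayes posterior

$$P(k \mid x) \;\propto\; \pi_k \exp\!\left(-d_k^2/2\right),$$

normalized over classes (computed in log space with a max-shift, so
posteriors are well-behaved even when distances are hundreds of units).
With equal priors the rule reduces to the Mahalanobis-nearest centroid,
which is also how the 2-D decision-region map is defined.

Assumptions worth keeping in mind:

* **Shared covariance.** Class-specific dispersion differences are
  absorbed into the pooled estimate. On raw concentration scales this
  matters: a metabolite whose class means differ multiplicatively also
  differs in variance across classes (variance grows with the mean for
  log-normal data), which the model ignores. Section 4 describes where
  this bites.
* **Raw-scale features.** No standardization or log transform is applied.
  Discriminant coefficients then apply directly to concentrations and
  their products, which is how discriminant equations are reported in
  this field, at the cost of the heteroscedasticity above.
* **Priors.** The original analyses this package generalizes do not state
  the prior convention, and the two natural choices differ at class
  imbalance 31/8/7. The default is `proportional` (class sample shares,
  the default of standard LDA software); `equal` is a first-class option,
  and every report records which was used.

### Discriminant axes

The axes (LD1, LD2, ...) are eigenvectors of the within$^{-1}\cdot$between
scatter problem, computed through the symmetric whitened form
$S^{-1/2} B\, S^{-1/2}$. There are exactly $\min(K-1, p)$ axes — two for a
three-class problem — ordered by decreasing between/within eigenvalue.
Two conventions make results reproducible across runs and platforms:

* each axis is scaled so its pooled within-class variance is 1, making
  Euclidean geometry in the LD plane identical to Mahalanobis geometry of
  the feature space restricted to the discriminant subspace;
* each axis's sign is fixed so its largest-magnitude loading is positive
  (eigenvectors are otherwise sign-ambiguous).

Because $K - 1$ axes exhaust the between-class structure, classifying in
the LD plane agrees exactly with classifying in the full feature space for
$K = 3$; the decision-region grid exploits this.

### Leave-one-out evaluation

Every accuracy in the package is leave-one-out: for each subject the model
is refit from scratch on the other $n-1$ subjects (means, pooled
covariance, and — under proportional priors — the priors themselves are
all re-estimated) and the held-out subject is classified. Folds are
independent of subject order. A class of fewer than three subjects would
leave a one-member class inside some fold; this is refused with an
explicit error rather than silently degrading.

## 2. The two-stage search

**Stage 1** scans panel sizes $k = 1, 2, \dots$ and, for each size, finds
the metabolite subset with the best LOO accuracy. The cumulative best
accuracy over sizes is non-decreasing by construction; the *selected*
panel is the smallest size attaining the overall maximum, and the scan
stops early once `patience` (default 2) consecutive sizes bring no
cumulative improvement — the "adding a fifth or sixth metabolite did not
help" plateau rule.

**Stage 2** expands the stage-1 panel into all monomials of total degree
$\le 3$ — levels, squares, cubes, pairwise and triple products;
$\binom{m+3}{3} - 1 = 34$ terms for a four-metabolite panel — and repeats
the identical search over these term columns. Monomials are evaluated on
raw concentrations, and labels follow field notation (`C3^2*Ac-Orn`).
The term universe is deliberately built only over the stage-1 winners:
expanding all metabolites cubically would produce a search space far
beyond the information content of a 46-subject cohort.

Three search strategies share one contract (deterministic candidate
order, ties broken by higher accuracy, then smaller size, then
lexicographically smallest index set):

* `exhaustive` — all $\binom{M}{k}$ subsets in lexicographic order. It
  refuses to start a size that would exceed the evaluation `budget`
  (default $10^5$ LOO evaluations), directing the caller to a heuristic:
  an exhaustive scan of 4-subsets of 188 metabolites alone costs
  $\binom{188}{4} \approx 4.9\times10^7$ evaluations.
* `forward` (default) — grows the best subset of the previous size by one
  feature.
* `beam` — extends the `beam_width` (default 20) best subsets of the
  previous size; a good default for stage 2, where the universe is a few
  dozen terms and greedy paths can stall.

**A caveat inherited from the study design**: the LOO accuracy being
maximized is also the accuracy being reported. Selection over many
subsets inflates the winner's apparent accuracy (the no-signal tests in
the suite quantify this: the best of 12 pure-noise metabolites scores a
few points above the 31/46 majority baseline). The package reproduces
this design faithfully and reports it; it does not claim generalization
performance, which would require nested validation on data this small.

## 3. The synthetic-cohort generator

Real aqueous-humour concentration tables are not publicly deposited, so
the generator provides cohorts with the structure the analysis assumes,
with known ground truth. Per subject $i$ and metabolite $j$:

$$\log c_{ij} \;=\; \mu_j \;+\; \log s_{j,k(i)} \;+\; \sigma z_{ij},$$

* $\mu_j$: metabolite-specific log-baseline, drawn once per config from
  the seed, uniform over concentrations $\approx$ 0.05–50 µM — matching
  the orders-of-magnitude spread of a targeted panel (acyl-carnitines at
  nM–µM, amino acids up to mM).
* $s_{j,k}$: planted multiplicative marker shift for class $k$ (1 when
  unshifted). Log-normal baselines with multiplicative shifts reproduce
  the non-negative, right-skewed boxplots typical of concentration data.
* $\sigma$: log-scale noise SD, default 0.5 ($\approx$ 50% biological
  CV, a typical figure for metabolite panels).
* Correlated blocks share a per-subject latent factor:
  $z_{ij} = \sqrt{\rho}\, f_i + \sqrt{1-\rho}\, e_{ij}$, giving exactly
  the requested pairwise log-scale correlation $\rho$ (the raw-scale
  Pearson coefficient is slightly attenuated by the exponential, e.g.
  $\rho = 0.7, \sigma = 0.5 \Rightarrow r \approx 0.67$).
* Ages, when configured, are Gaussian per class truncated at 18 years;
  the study-layout defaults (`study_config()`) centre them at 56 / 67.5 /
  72 years so the age ANOVA and the age-filtered reanalysis can be
  exercised.

`study_config()` fixes one field-plausible scenario — 31/8/7 subjects,
188 metabolites, four named markers with 1.5–3-fold class shifts and a
0.45-correlation block — chosen once as realistic effect sizes for this
kind of cohort, not fitted to any dataset.

### The product-only (non-linear) mode

Stage 2 must be testable on data where stage 1 alone cannot succeed. The
`nonlinear` mode plants a signal visible only in the *product* of two
metabolites $a, b$: with a per-subject latent $h_i \sim N(0, \kappa^2)$
and per-class product shift $s_k$,

$$\log c_{ia} \mathrel{+}= \;h_i + \tfrac{1}{2}\log s_k, \qquad
  \log c_{ib} \mathrel{+}= \;-h_i + \tfrac{1}{2}\log s_k,$$

i.e. $h_i$ is added to one column and subtracted from the other, and half
the log-shift goes to each. The latent cancels in
$\log(c_{ia} c_{ib})$, so the product carries a clean multiplicative
class shift with within-class log-SD $\sqrt{2}\sigma$, while each
marginal is dominated by $\kappa$ (default 3, i.e. $\approx 6\times$ the
total shift) and is statistically uninformative at cohort-scale $n$.

Choosing the mode's stress-test condition exposed a real property of
raw-scale LDA worth recording: with large product fold-changes (e.g.
25-fold between adjacent classes) the high class's raw-scale variance
inflates the pooled covariance so much that the low classes become
indistinguishable — accuracy plateaus well below 100% even though the
log-scale gap is enormous. The shared-covariance assumption, not the
signal, is the binding constraint. The test condition therefore uses a
*moderate* fold-change with tight log-noise (4-fold shifts,
$\sigma = 0.08$, a $\approx 12$ log-SD gap), where the planted signal is
unambiguous *and* within the model's homoscedasticity tolerance.

## 4. Numerical choices

* **Singular covariance.** Stage-2 monomials can be nearly collinear at
  $n = 46$. If the pooled covariance fails a Cholesky factorization — or
  factorizes with a pivot below $10^{-12}$ of the largest, which catches
  exactly rank-deficient cases that `chol()` happens to accept — a ridge
  $\varepsilon \cdot \mathrm{tr}(S)/p$ is added, $\varepsilon$ starting
  at $10^{-8}$ and escalating tenfold to at most $10^{-2}$. The ridge
  actually used is recorded in the model and surfaced in reports; it is 0
  in the ordinary well-conditioned case.
* **Ties.** Equal posteriors predict the first class in declared class
  order; equal search accuracies prefer the smaller subset, then the
  lexicographically smallest index set. Both rules are deterministic and
  exercised by tests with duplicated columns.
* **Undefined metrics.** One-vs-rest sensitivity/specificity/PPV/NPV
  cells of the form 0/0 (a class never predicted, say) are reported as
  `NaN` with an explicit flag and *excluded* from macro-averages; silent
  zeros would corrupt them.
* **Posterior threshold.** The "posterior above 0.5" summary uses a
  strict inequality; a subject exactly at 0.5 is not counted as exceeding.
* **Quartiles.** Group summaries use linear interpolation (R's type 7),
  stated here because boxplot conventions differ between tools.
* **Serialization.** TSV outputs round floats to 12 significant digits;
  model JSON keeps full doubles. Identical configurations reproduce
  byte-identical outputs, and all generation runs under a private RNG
  stream so concurrent analyses cannot interfere.

## 5. What the tests do and do not show

The suite validates the machinery against independent oracles
(a reference LDA implementation for posteriors, per-fold refits for LOO
predictions, reference correlation/ANOVA routines to $10^{-10}$), and
validates the *pipeline* on synthetic cohorts: planted markers are
recovered ($\ge 95\%$ of seeds at an 8-fold shift among 20 noise
metabolites), class means are re-estimated within 2% at $n = 1000$ per
class, product-only cohorts are solved by stage 2 but not by degree-1
search, and no-signal cohorts stay at the 31/46 majority baseline.
Problem sizes in the tests (cohorts of 30–50 subjects, up to ~20
metabolites per search, 200 seeds for null calibration) were chosen as
the smallest scales at which these properties are statistically
unambiguous.

Passing tests demonstrate correctness of the method on data *satisfying
the generator's assumptions* — independent log-normal noise, exact
planted effects, no batch structure, no missingness beyond the load-time
policy, no measurement floor. They do not certify performance on real
cohorts, where effect sizes are unknown, correlations are not
block-structured, and the selection-bias caveat of Section 2 applies in
full.

## 6. Known limitations

* Exhaustive search is honest but budgeted; at 188 metabolites the
  default path is heuristic (forward/beam), and a globally better subset
  can in principle be missed.
* The ridge fallback stabilizes collinear term sets but shrinks the
  Mahalanobis geometry; `ridge_used` should be checked when stage 2
  selects many high-degree terms.
* Raw-scale modelling (kept for interpretability of the discriminant
  coefficients) couples class mean shifts to class variance shifts; for
  strongly multiplicative signals a log transform before analysis would
  fit the shared-covariance assumption better, and nothing in the API
  prevents passing log-transformed tables.
* Two-class problems have a single discriminant axis; the 2-D map is
  deliberately refused rather than padded.
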