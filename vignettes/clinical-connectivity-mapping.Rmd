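---
title: "Clinical connectivity mapping: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical connectivity mapping: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinCMap)
```

## The idea

Connectivity mapping matches a drug to a disease when their signatures
oppose each other. clinCMap uses routine laboratory tests as the signature
space: a drug that *lowers* glucose and LDL is complementary to a disease
that *raises* them. Both signatures are ternary vectors over a shared lab
catalog — +1 (significant increase), −1 (significant decrease), 0 — and a
drug–disease pair is scored by the negative dot product

$$TS = -\,CV_{drug}\cdot CV_{disease},$$

so every complementary lab adds one point and every adverse lab removes
one. The score is integer-valued and bounded by the number of labs on
which both vectors are nonzero.

## The drug arm: a self-controlled linear model

For one lab test, let $y_{ij}$ be the $j$-th of $J_i$ measurements of
patient $i$ and $x_{ij}\in\{0,1\}^M$ the drug-exposure indicator at that
moment. The model is

$$y_{ij} = \alpha_i + \beta^\top x_{ij} + \epsilon_{ij},\qquad
\epsilon_{ij}\overset{iid}{\sim} N(0,\sigma^2),$$

with one baseline $\alpha_i$ per patient. The self-controlled reading is
that each patient serves as their own control: $\beta_m$ is identified
from *within-patient* contrasts between exposed and unexposed
measurements, which removes all time-invariant confounding absorbed by
$\alpha_i$. Stationarity of the baseline and exchangeability of a
patient's measurements are the key assumptions: disease progression that
correlates with treatment start is *not* removed.

Solving $\partial L/\partial\alpha = 0$ gives
$\alpha = \bar y - \bar X\beta$ (per-patient means), so the baselines
never need to be estimated: subtracting each patient's mean from $y$ and
from every exposure column yields a problem whose least-squares solution
in $\beta$ equals the drug block of the full fixed-effects fit with one
explicit intercept per patient. The test suite asserts this equivalence to
1e-8 against a brute-force `lm()` oracle on a small instance; it is exact
linear algebra, not an approximation. A patient with a single measurement
centers to a zero row and silently contributes nothing — no special case
is needed.

Because only a small portion of drugs plausibly moves any given lab, the
centered problem is solved with an L1 penalty:

$$\hat\beta = \arg\min_\beta \tfrac12\|y_c - X_c\beta\|_2^2 +
\lambda\|\beta\|_1 .$$

`fitCSCCS()` delegates the penalized solve to coordinate descent
(`glmnet`, with the penalty rescaled by the sample size to match this
objective, no standardization, no intercept) and uses a minimum-norm SVD
solve at $\lambda = 0$, warning on rank deficiency.

### Choosing the penalty

The sparsity level must be tuned. The package's default is $k$-fold
cross-validation with **patients, not rows, partitioned into folds**
(default $k = 5$), over a logarithmic grid descending from
$\lambda_{max} = \|X_c^\top y_c\|_\infty$ (the smallest penalty with an
all-zero solution) down to $10^{-3}\lambda_{max}$ in 20 steps. Grouping by
patient respects the self-controlled structure: a patient's measurements
are correlated through $\alpha_i$, and row-wise folds would leak that
correlation across the split. Ties in CV error go to the larger penalty
(the sparser model). A fixed $\lambda$ can be supplied instead.

### Coefficient significance

The lasso itself has no finished p-value theory that is both simple and
assumption-light, so the package uses post-selection refitting: ordinary
least squares on the selected support over the centered data, classical
t-tests, with residual degrees of freedom reduced by the number of
patients (the intercepts the centering absorbed) as well as the support
size. Drugs off the support get $p = 1$; degenerate cases (support larger
than the residual degrees of freedom, collinear support columns) set all
p-values to 1 with a warning rather than fabricating significance. The
known cost is mild anti-conservatism on selected nulls — the selection
event is ignored — which the null-data test bounds empirically (empty
final support in at least 90% of replicates). Debiased-lasso inference
would be the principled alternative and is deliberately out of scope.

A (drug, lab) pair is called $+1$ if $p < 0.05$ and $\hat\beta > 0$,
$-1$ if $p < 0.05$ and $\hat\beta < 0$, else 0. The 0.05 cut-off is the
conventional one and is configurable (`alpha`).

## The disease arm: rank-sum tests with mean-based direction

Per lab, case and control values are compared with the Wilcoxon rank-sum
test. The implementation computes both U statistics from midranks (so
$U_1 + U_2 = n_1 n_2$ exactly, ties included) and takes the p-value from
the exact null distribution when the smaller group has at most 20
observations and there are no ties — reproducing classical U-table
look-ups — and otherwise from the normal approximation with tie and
continuity corrections. Direction is assigned by comparing the
**arithmetic means** of the two groups, not medians, even though the test
is rank-based: the mean is the quantity the downstream interpretation
("the disease raises this lab") refers to. The measure-zero corner case of
a significant p with exactly tied means is called 0 and logged.

No multiple-testing correction is applied across labs: each lab is tested
at a raw 0.05, which is the stated operating point of the procedure the
package implements. The uncorrected per-lab false-positive rate (about 1
in 20 labs under the null) is therefore a *feature of the method being
studied*, and the evaluation layer must tolerate it — see the synthetic
study design below.

Missing lab values are dropped pairwise per lab; a lab with an empty group
is called 0 with a warning. Subjects carry NA status for diseases they
were not surveyed for, so in multi-disease datasets one disease's cases
never end up in another disease's control group.

## Scoring, ranking, evaluation

`computeScoreMatrix()` applies the negative dot product over the full
harmonized catalog. Catalog harmonization (`harmonizeLabs()`) intersects
two alias maps (source name → standard lab id) and sorts the result, so a
run's catalog order is deterministic. Rankings break score ties by
ascending drug id — an arbitrary but documented and reproducible rule.

`precisionAtK()` is the fraction of the top K that is in the gold
standard; K beyond the list length is an error, never a silent
truncation. `foldEnrichment()` bins the ranking into consecutive groups
of `groupSize` from the top, the **last bin keeping the remainder**
(392 items at 80 per bin give 80/80/80/80/72), and reports
$FE = (n/m)/(N/M)$ per bin; gold drugs absent from the ranked universe
are dropped from $N$ with a logged count. `feTrend()` summarizes the
FE-vs-group relation by its least-squares slope; a sound score makes it
negative.

For the joint structure view, `biclusterScores()` implements spectral
co-clustering (normalized bipartite SVD followed by seeded k-means with
25 restarts on each side's rescaled singular-vector embedding). No
installed R package offers this algorithm, so it is implemented here and
verified on planted block matrices. Scores can be negative, so the matrix
is shifted to nonnegative by its minimum before the degree normalization;
a constant matrix has no structure and returns identity orders with a
warning. Row and column cluster counts may differ; clusters are relabeled
by first appearance so output labels are themselves deterministic.

## What the generators emulate — and what they do not

`simulateEHR()` draws data *exactly* from the model above: per-patient
baselines $N(\mu_\alpha,\sigma_\alpha^2)$, i.i.d. Bernoulli exposures per
drug per measurement, Gaussian noise. Defaults (baseline 50 ± 5, noise sd
1, exposure probability 0.3, 5–10 measurements per patient) are generic
lab-panel magnitudes; since the estimator is shift- and scale-equivariant
per lab, only effect size relative to noise matters. `simulateSurvey()`
draws cases from the control distribution plus a per-lab shift. What this
buys is a known ground truth for every downstream stage; what it does
**not** emulate: prescription intervals and exposure autocorrelation,
dosing, drug–drug interactions, non-Gaussian lab distributions, missing
data beyond unbalanced panel sizes, or treatment start correlated with
disease state. Passing tests therefore demonstrate correctness of the
estimation machinery under its own assumptions, not robustness to real
EHR pathologies.

`simulateStudy()` fixes the linked end-to-end scenario: 3 diseases each
shifting 4 of 12 labs by half a standard deviation (alternating
directions, 500 cases and 500 controls), 300 patients' EHR with unit
effects in unit noise, and per disease 5 planted drugs whose effects
oppose 3 of its labs (true score +3) plus 3 inert drugs. Five gold drugs
per disease keeps precision@5 meaningful, and the 3-lab margin keeps the
designed drugs separated from the occasional score-2 impostor that an
uncorrected per-lab false positive can create — without that headroom the
evaluation would measure tie-breaking luck rather than signal. The gold
standard is *derived from the planted truth* (a drug is indicated iff its
true score is strictly positive; ties at zero excluded), so the evaluation
closes the loop without external data.

## Numerical choices and problem sizes

* glmnet convergence threshold 1e-12 and exact (re-solved) coefficients at
  requested penalties, so support sets are stable across platforms.
* Minimum-norm SVD solve at $\lambda=0$ with tolerance
  `max(dim) * eps * max(singular value)`.
* CV tie window 1e-12 in favor of sparsity.
* Cholesky-based post-selection refit; failure of the factorization is
  treated as collinearity, not an excuse for pseudo-inverse p-values.
* Minimum-sample thresholds default to 1000 (drugs: distinct exposed
  patients; diseases: surveyed subjects), the operating point used on
  registry-scale data; synthetic runs set them low explicitly.
* The checks run at desk scale by design: sign recovery uses 200 patients
  × 20 drugs × 20 replicates; calibration uses 2000 null labs at 50 vs 50;
  the end-to-end study runs 10 seeds of the `simulateStudy()` scenario.

## Known limitations

* Post-selection p-values ignore the selection event (see above).
* Exposure is a snapshot at measurement time; duration and dose are out of
  scope.
* The disease arm is unadjusted two-group testing: no survey weights, no
  covariates, no multiplicity control.
* The score treats all labs equally; clinically salient labs (cholesterol,
  LDL, HDL, triglycerides) are not up-weighted.
* Ternary quantization discards effect magnitude by construction; two
  drugs with very different effect sizes on the same labs score
  identically.
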