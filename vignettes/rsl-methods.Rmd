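---
title: "Decoding graded multidimensional structure with representational similarity learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding graded multidimensional structure with representational similarity learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Representational similarity analysis (RSA) asks whether the pairwise
similarity structure of neural activity patterns correlates with a target
similarity structure. Its single correlation coefficient is dominated by
the leading component of the target matrix, weighs all neural features
equally, and cannot distinguish a graded multidimensional code from a
discrete unidimensional one. Representational similarity learning (RSL)
addresses this by decomposing the target similarity matrix and *decoding*
its latent components.

Let $S_{n \times n}$ be the cosine similarity matrix of mean-centered
binary feature-norm vectors for $n$ items. Its rank-$r$ eigendecomposition
gives item coordinates $U = V_r D_r^{1/2}$ (root-weighted singular
vectors), so $U U^\top$ reproduces the rank-$r$ truncation of $S$. With a
neural feature matrix $X_{n \times m}$ (items by concatenated
electrode-by-time voltages), RSL fits the multitask regression $U = X\beta$
by minimizing

$$\frac{1}{2n}\lVert U - X\beta \rVert_F^2 + \alpha H(\beta),$$

where $H$ is either the L1 norm or the group ordered-weighted LASSO
(grOWL): $H(\beta) = \sum_i w_i \,\rho_{(i)}$ with $\rho_{(1)} \ge
\rho_{(2)} \ge \dots$ the sorted row L2 norms of $\beta$ and a
nonincreasing weight sequence $w_i = \lambda + \omega\,(m-i)/(m-1)$. grOWL
encodes three assumptions about neural codes: **sparsity** (most features
carry no target information; $\lambda$ sets the pressure toward zero
rows), **redundancy** (correlated informative features should receive
similar coefficients; $\omega$ sets the decay range that couples them),
and **spanning** (an informative feature predicts *all* components — rows
are zero or dense, never partially zero).

If predicted and true coordinates of held-out items correlate reliably on
more than one component, the code is multidimensional; if they correlate
within the animate and inanimate domains separately, the code is graded
rather than categorical. The product of predicted coordinates with their
transpose reconstructs a predicted similarity matrix, directly comparable
with RSA on the same data.

## Optimization

The objective is convex but nonsmooth. We use FISTA with fixed step
$1/L$, $L = \sigma_{\max}(X)^2 / n$ (estimated by a deterministic power
iteration with a 2% safety margin), zero initialization, and a monotone
adaptive restart: if a step increases the objective, momentum is dropped
and the step retaken. Iteration stops when the relative objective change
falls below $10^{-8}$ (default; the inner tuning loop uses $10^{-5}$,
since only the candidate ranking matters there) or at `max_iter = 10000`.

The grOWL proximal operator reduces to the ordered-weighted-L1 prox on
the vector of row norms: sort descending, subtract the scaled weights,
project onto the nonincreasing cone by pool-adjacent-violators, clip at
zero, undo the sort, and rescale each row to its new norm. The PAVA and
the solver loop are compiled (Rcpp/RcppArmadillo); the prox is verified
in the test suite against a brute-force oracle that enumerates all
row-to-rank assignments and solves each assignment with base R's
`isoreg`, and the full solver against an independently written plain-ISTA
reference in Python and against glmnet for the L1 family.

The $1/(2n)$ loss normalization keeps $\alpha$ comparable across window
sizes. Predictors are z-scored and targets centered with training-fold
statistics only, recomputed on every inner split; unstandardized voltages
would make a single weight sequence meaningless across electrodes.

## Model selection and inference

Items are partitioned into 10 outer folds with exact domain balance
(5 animate + 5 inanimate per fold at $n = 100$). Within each outer fold
the remaining nine sets form the inner folds; hyperparameters
$(\lambda, \omega, \alpha)$ are sampled log-uniformly on $[10^{-4}, 10]$
and filtered by successive halving (ratio $\eta = 3$, default 27
configurations, full budget 3000 solver iterations — Hyperband-style; an
exhaustive grid mode exists for exact reproducibility). The winning
configuration refits on all non-holdout items and predicts the holdout;
ties prefer smaller $\alpha$, then smaller $\omega$. Assembled across
folds, every item has a prediction from a model never trained on it.

Cross-validated correlations are negatively biased under the null, so
significance uses permutation: the full nested-CV decode is re-run with
row-permuted targets (one permutation shared across dimensions and
subsets per run, so statistics have a coherent joint null), 100 times per
subject by default; a group-level null resamples one value per subject
and averages, 10,000 times. One-tailed $p = (b+1)/(m+1)$, adjusted by
Benjamini–Hochberg across all window × dimension × subset statistics of
an analysis (Benjamini–Yekutieli available). Reported statistics are
centered on their permutation-null mean. Hyperparameters are re-tuned
inside each permutation by default (conservative); reusing the tuned
configuration is available and is what the reduced-scale test runs use.

### Support recovery

Prediction-optimal penalties do not identify the signal support when
$m \gg n$: fits that interpolate well keep many noise rows, and with
$m = 2000$ the linear weight decay is locally flat across the active set,
so $\omega$ alone cannot bind near-duplicate groups. `recover_support()`
therefore uses standard penalized-regression machinery: an $\alpha$ path
descending from the dual-norm scale at which the model is exactly zero
(as glmnet builds its $\lambda$ sequence), inner-fold scoring, the
one-standard-error rule (sparsest configuration statistically
indistinguishable from the best), consensus across the 10 outer-fold
refits (a row must appear in 90% of them), and redundancy-group
completion — any column whose item-wise correlation with a stable column
exceeds a Bonferroni-controlled Fisher-z threshold joins the support,
since measurement noise attenuates true-duplicate correlations well below
1 and a sparse fit may keep only representatives of a redundant group.

## The synthetic data

The original-scale inputs (empirically collected feature norms, patient
ECoG recordings) are not shipped; all studies run on synthetic data with
known ground truth.

`simulate_feature_norms()` generates binary norms with the hierarchical
structure of feature-norming studies: two domains of 50 items, 30
domain-typical features each (with a graded typicality gradient across
subcategories, so the first component orders items within domains rather
than encoding a pure category indicator), five subcategories per domain
with animate subcategories more distinctive than inanimate ones, a coarse
split among inanimates, and idiosyncratic per-item features. The
resulting cosine-RSM embedding has a dominant first component separating
and grading the domains (~35% of variance) and two weaker components
(~4% each) carrying within-domain structure for both domains. These
proportions are less extreme than real norms, where the first component
can carry over 80%; the qualitative ordering and the diagnostic behavior
of the five simulated codes, not the exact split, is what the simulations
require. Because components 2 and 3 have nearby eigenvalues, which of the
two leans animate versus inanimate varies with the generator seed.

`make_condition_dataset()` builds 24-feature responses in five
conditions: `binary` (each signal feature ±1 by domain — discrete,
unidimensional), `oneD-1/2/3` (z-scored copies of one component — graded,
unidimensional), and `full` (signal features split 4/4/4 across the three
components — graded, multidimensional). Half the features carry signal;
the other half sample a uniform distribution over the signal range (the
amplitude ratio of "random" features is unspecified in norming work; we
match the signal range and note the assumption). Measurement noise is
uniform on $[-h, h]$ in signal-SD units; the default grid of 11 levels
spans $[0, 8]$, chosen so the weakest conditions (`oneD-2`, `oneD-3`)
visibly decay to null while `binary` and `oneD-1` remain robust — the
diagnostic contrast of the RSA simulation. Every generator is a pure
function of its parameters and a seed, with per-dataset substreams so
generation order is irrelevant.

`make_synthetic_ephys()` emulates trial-averaged voltages on a
20-electrode × 100-timepoint grid (1 s at 100 Hz): 40 signal columns in
ten near-duplicate groups of four (pairwise correlation ≥ 0.9 before
noise), all within a 150–700 ms latency band mirroring where reliable
decoding is typically observed, with dense 3-component mixing vectors per
group (the spanning assumption) and i.i.d. Gaussian noise scaled to a
requested SNR (default condition: SNR 4). It does not model 1/f spectra,
artifacts, autocorrelated noise, or volume conduction; passing tests on
it show the estimator recovers a planted linear code under realistic
dimensionality and noise, not that real ECoG satisfies the model.

## Preprocessing and windows

`boxcar_downsample()` averages within 10 ms boxcars (1000 → 100 Hz);
`average_repetitions()` means over stimulus repetitions; no baseline
correction and no re-referencing are applied. `censor_outliers()` removes
feature columns, then rows, whose marginal mean lies more than 5 SD from
the grand mean — columns first, with statistics recomputed before the row
pass, so a single wild cell censors its column without discarding the
item. Temporal analyses use an opening window (onset 0; widths 50 then
100–1000 ms in 100 ms steps — 11 windows) or a 100 ms moving window
advancing by 50 ms; the final onset is 900 ms, the last full window in a
1 s epoch. `run_study()` orchestrates decode → evaluate → permutation →
group aggregation (unweighted mean, SEM) per subject and window, and one
failed subject does not abort the cohort.

## Numerical choices and degenerate inputs

Cosine similarities are clipped to $[-1, 1]$ and the diagonal set to
exactly 1; eigenvalues made slightly negative by centering/rounding are
clipped to zero before the square root, and the clipped mass is recorded
on the embedding object. SVD signs are fixed by orienting each component
so the animate-domain mean coordinate is nonnegative (largest-magnitude
entry positive when no domains are given). Items whose centered feature
vector is all zero, constant activity patterns under correlation, empty
windows, fold plans that cannot be balanced, and requests for more
components than the numerical rank (warned, zero-filled) are all surfaced
as errors or warnings naming the offending item. Zero-variance subsets
yield `NA` statistics that are reported missing rather than silently
dropped; constant feature columns are retained (they contribute nothing
after centering) and flagged.

## Problem sizes in the shipped runs

The test suite and `scripts/acceptance.R` run the simulation studies at
their design scale (five conditions × 11 levels × 20 repetitions; 100
items) and the decoding studies at reduced search/permutation scale: 6–9
Hyperband configurations with iteration budgets of 300–1000 for nested
CV on the 100 × 2000 synthetic ephys, 24–39 permutations with tuned
configurations reused inside permutations, and 200 pure-noise replicates
for FDR calibration. Defaults (27 configurations, budget 3000, 100
permutations per subject, 10,000 group resamples, full re-tuning) match
the full-scale analysis workflow.

## Known limitations

- Published grOWL implementations differ in their exact weight schemes
  (linear versus spike decay); we adopt the linear OSCAR-style decay with
  exactly the $(\lambda, \omega)$ parameterization, the standard choice.
  For $m$ in the thousands the decay is locally flat, so redundancy
  grouping operates mainly through the support-completion step rather
  than the penalty itself.
- Whether the similarity decomposition should use the cosine RSM directly
  or the centered-feature cross-product is ambiguous in the source
  description; we decompose the RSM as literally described. The two differ
  by row-norm weighting and would need reconciling against the deposited
  analysis scripts for exact replication.
- The NSM pattern-similarity measure defaults to Pearson correlation
  (equivalently cosine on centered patterns); prior ECoG RSA analyses do
  not always report their measure, a replication caveat rather than a
  package option gap.
- Hyperband is concretized as single-bracket successive halving with an
  iteration-budget resource; bracket structures vary across
  implementations and none is canonical for this workflow.
- Permutation inference treats subjects as exchangeable draws and items
  as exchangeable under the null; articulation onsets late in a naming
  epoch are not modeled or censored.
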