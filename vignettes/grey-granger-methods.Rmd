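---
title: "Dynamic grey association and Granger regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic grey association and Granger regression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greynet)
```

## The inference problem

A gene regulatory network is a directed graph in which an edge
regulator → target asserts that the regulator's expression influences the
target's future expression. Given a genes × timepoints expression matrix
(possibly several replicate series), `greynet` produces a ranked list of all
ordered gene pairs, highest-confidence regulatory edges first. Ranking, not
thresholding, is the primary output: benchmark evaluation (AUROC/AUPRC
against a gold standard) and downstream prioritization both consume
rankings.

Two assumptions underlie the method. First, genes that regulate each other
have trajectories whose *shapes* agree locally in time, even when their
scales differ — the grey-relational view. Second, regulation takes effect
with a delay, so a regulator's past should improve prediction of a target's
present beyond the target's own past — the Granger view. The two stages
test these two assumptions separately, and the final score multiplies them.

## Stage 1: dynamic grey association

For each target gene the series is z-scored per replicate block, then
first-differenced. Windows are laid end to end over the difference axis:
the first window has length `L_init`, and each next length is the previous
length scaled by the ratio of the two most recent window entropies,

L_i = round(E_{i-1} / E_{i-2} × L_{i-1}),

clamped into `[L_min, L_max]`. The entropy of a window is the Shannon
entropy (bits) of the softmax of the absolute differences inside it: near
`log2(L)` when change is spread evenly, near 0 when one jump dominates.
Rising entropy therefore lengthens windows over quiet stretches and falling
entropy shortens them where dynamics concentrate.

Within a window starting at difference index *s* with length *L*, the grey
relational coefficient compares the target's z-scored values at timepoints
*s*+1 … *s*+*L* against each comparative gene, pooling the residual extrema
over all comparatives and positions in the window; the per-gene grade is the
within-window mean, and the dynamic grey association is the unweighted mean
of grades over windows, then over replicate blocks.

### Parameter choices

| parameter | default | rationale |
|---|---|---|
| `rho` | 0.5 | conventional distinguished coefficient; larger values flatten the contrast between residuals, smaller sharpen it |
| `L_init` | `max(3, round((n-1)/5))` | about five windows per series; 4 for the common 21-timepoint benchmark series |
| `L_min` | 2 | a grade needs at least two in-window positions |
| `L_max` | `n-1` | unconstrained unless the user narrows it |
| `normalization` | z-score per gene per block | grey residuals pool across genes, so genes must share a scale; z-scoring also makes the association invariant to positive affine transforms of any gene, which raw softmax entropy is not |

### Numerical and boundary conventions

These conventions are needed where the recurrence or the coefficient is
degenerate; each is the limit-consistent choice.

* **Bootstrap.** The recurrence needs two previous entropies; before the
  first window we define `E_0 = log2(L_init)`, the maximum-entropy
  baseline, so the second window adjusts only when the first window shows
  less-than-maximal entropy ("no adjustment until evidence").
* **Zero entropy.** If the reference entropy is 0 the ratio is undefined;
  the window length is kept unchanged.
* **Rounding.** Half-to-even (banker's), then clamping — so length
  sequences have no systematic upward drift from ties.
* **Remainder.** Trailing difference points too few to form a window of
  `L_min` become a final short window if at least 2 remain; a lone point is
  appended to the last window. Windows therefore tile the difference axis
  exactly, with no gaps or overlaps (stride = length; overlapping windows
  are out of scope).
* **Degenerate window.** If every residual in a window is zero, all
  coefficients are set to 1, the limit of the coefficient as residuals
  vanish; an exact copy of the target thus scores association exactly 1.
* **Window mapping.** A window `(s, L)` on the difference axis reads the
  series at timepoints `s+1 … s+L`, so grades are computed on expression
  values (not derivatives) and every window contributes `L` positions, the
  divisor in the grade.
* **Extrema pooling.** The pooled min/max of the coefficient are taken
  within each window by default (`pool_extrema = "window"`), keeping each
  window's contrast local; `"global"` pooling over all of a target's
  windows is available for sensitivity analysis, since either reading of
  the pooling scope is defensible.

## Stage 2: Granger regression

For each target a lagged design stacks, per replicate block, rows
(target at *t*; all candidate regulators at *t*−1 … *t*−*d*), never
crossing block boundaries. The default lag order *d* = 2 covers the
one-step delays a VAR(1)-like system produces plus one slack lag, while
keeping the design at 2 columns per candidate; *d* is exposed because the
right value depends on the sampling interval relative to regulatory
kinetics.

Four regressors are supported, all delegated to their standard
implementations, with importances consumed per column and summed over a
gene's lags:

* **lasso / ridge** (glmnet): predictors standardized to zero mean and unit
  variance, importance = |coefficient|. The penalty defaults to 5-fold
  cross-validation with deterministic, data-order fold assignment (so reruns
  and reseeded trials are identical); designs too short for honest folding
  fall back to a light fixed penalty of 1e-3.
* **random forest** (ranger): impurity (variance-reduction) importance,
  `mtry = max(2, p/3)` — the regression-forest convention with a floor of 2
  so that split candidates always compete; with `mtry = 1` splits are
  forced and importance degrades toward usage frequency.
* **gradient boosting** (xgboost): per-feature gain, shallow trees
  (depth 3, learning rate 0.1, row subsampling 0.8).

Stochastic regressors are averaged over `n_repeats` (default 10) reseeded
fits per target. Per-target seeds derive from the global seed plus the
target identifier's character codes, making results invariant to the input
order of genes. Candidate regulators are sorted into a canonical order
before fitting for the same reason. Autoregressive self-lags are included
in every design (standard Granger practice — a regulator must beat the
target's own history) but never appear in edge scores. Each nonzero weight
column is rescaled to sum to 1 so high-variance targets cannot dominate the
global ranking.

### Combining the stages

The way the association stage should modulate the regression stage is a
genuinely open design point. The default is the elementwise product
DGA × *w*: it is monotone in both factors, zero-preserving, and keeps the
ranking semantics of both stages. Two alternatives are retained —
`combine = "regression_only"` and `"dga_only"` — because the with/without
ablation is itself an analysis mode, and `dga_topk` offers a third reading
(association as a candidate pre-filter: only each target's top-k
association partners enter its regression). We do not claim one operator is
uniformly best; the ablation harness (`cmd_ablate`) exists to measure the
difference on a given dataset.

Direction resolution from the weight matrix uses strict support membership
(`weight > threshold`, default threshold 0, matching the sparsity-based
reading natural for the lasso): x→y alone when only x carries weight for
y, both directions when both do.

## Evaluation conventions

AUROC uses the midrank Mann–Whitney formulation (exactly the
pairwise-comparison probability with ties counted half). AUPRC is stepwise
average precision — the mean of precision at each positive hit — rather
than a trapezoidal area, which is the convention for sparse benchmark
networks where early precision matters. Gold pairs missing from a ranking
are appended below all ranked pairs as lowest-confidence rather than
dropped, matching benchmark-challenge practice; ties, including that
appended block, are broken lexicographically by (regulator, target) so
every evaluation is deterministic. Trial comparisons use the Wilcoxon
*signed-rank* (paired) test because ablation arms share trial seeds and
data; the exact null is used up to n = 25 when no zeros/ties intervene,
otherwise the continuity-corrected normal approximation.

## What the synthetic generator does and does not emulate

`sample_network` draws directed graphs without self-loops (iid ordered
pairs at the requested density, or a Zipf-hub variant for out-degree skew)
with signed edge strengths of magnitude 0.5–1. `simulate_timeseries`
defaults emulate the common in-silico benchmark shape: 10 genes,
21 timepoints, 5 replicate series. VAR(1) is the primary dynamics —
`x_t = A x_{t-1} + ε` with the adjacency rescaled to spectral radius 0.9
(nilpotent/acyclic systems, radius 0, are left unscaled) — because lagged
regression is provably consistent there, so the causal stage *must* recover
the truth and any failure is a defect, not noise. The default process noise
(sd 0.1 against unit-scale states and 0.9-magnitude dynamics) keeps lag-1
signal-to-noise around 5. Hill-kinetics ODEs (activating/repressing Hill
terms, first-order decay, RK4 integration, observation noise) provide a
nonlinear surface where the tree regressors can outrank the linear ones.

What passing on these fixtures does **not** show: robustness to
measurement-scale artifacts, unobserved confounders, non-stationary
sampling grids, heavy-tailed noise, or the feedback-rich kinetics of real
transcriptional systems. Results on real data should be read accordingly.

## Problem sizes in the shipped studies

The test suite validates the grey core against a literal loop-based
re-computation on 50 random tables of up to 5 genes and 12 timepoints
(agreement to 1e-10); exact lasso support recovery uses a noiseless
5-gene VAR(1). A *single* noiseless trajectory collapses onto the dominant
eigenspace of the dynamics and makes parent sets unidentifiable, so the
recovery study uses 50 short replicate blocks (5 timepoints each, random
initial states — 200 usable rows at lag 1), which is still noiseless VAR(1)
data but of full rank. The recovery study and the acceptance script use 20
independent 10-gene, density-0.15 networks at the default benchmark shape;
these sizes give stable means while keeping a full run in tens of seconds.

## Known limitations

* The association stage is O(m² · n) per block and the regression stage
  fits m models of m·d columns; hundreds of genes are comfortable,
  genome-wide inputs are not the target without a TF list restricting
  regulators.
* Lag order is global; gene-pair-specific delays (as addressed by
  sliding-window regression methods elsewhere) are not modeled.
* No significance is attached to individual edges; the ranking is relative.
  The Wilcoxon machinery compares method variants, not edges.
* Single-cell data violate the bulk-trajectory assumptions (dropout,
  pseudotime uncertainty) and are out of scope.
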