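---
title: "Multi-model OPLS-DA gene selection: models, assumptions and design choices"
author: "moplsda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model OPLS-DA gene selection: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moplsda)
```

## The problem

Microarray studies measure thousands of genes on a few dozen samples, and
most genes carry no information about the disease classes of interest.
When the classes number three — either genuinely parallel (three diseases)
or nested (a disease with two subtypes plus an outgroup, such as AML
against B-cell and T-cell ALL in acute leukemia) — ordinary two-class
selectors do not apply directly. This package selects marker-gene panels
for such three-class problems by decomposing them into two-class
contrasts, fitting one OPLS-DA model per contrast, ranking genes on each
model's S-plot, and merging the per-model picks into one panel whose
quality is then checked by PCA and hierarchical clustering.

## Preprocessing

Raw intensities are prepared with the classic oligonucleotide-array
recipe: clip to $[100, 16000]$; discard genes whose clipped profile has
$\max/\min \le 5$ or $\max - \min \le 500$ across samples; take
$\log_{10}$; mean-center each gene. A state machine on the
`expr_matrix` container enforces this exact order, because the filter's
fold and range criteria are defined on clipped values and would change
meaning after the log transform. Retention implements the strict logical
complement of the discard rule (both `max/min > 5` and
`max - min > 500` must hold).

Two leakage-related choices are deliberate. When a train/test split
exists, the filter is learned on the training set and the resulting gene
list is imposed on the test set with `apply_filter()`; and a test set is
centered with training-set gene means (`mean_center(reference_means=)`)
when projected into a trained model, but with its own means when analyzed
standalone. Whether the filter should instead be learned on the pooled
samples before splitting is not settled by the conventions this recipe
comes from; we chose train-only as the leak-free option.

Only centering is applied before modelling — no unit-variance scaling —
because the log transform already puts gene ranges on a comparable scale;
`opls(scale = "uv")` and `"pareto"` exist for users who want otherwise.

## The OPLS-DA model

For a two-class contrast coded as a 0/1 dummy response $y$ (centered),
and a centered samples $\times$ genes matrix $X$, the fit is the NIPALS
sequence with built-in orthogonal signal correction:

1. $w = X^T y / \lVert X^T y \rVert$ — the candidate predictive direction;
2. for each of $K$ orthogonal components: $t = Xw$,
   $p = X^T t / t^T t$, $w_o \propto p - (w^T p) w$ (unit norm),
   $t_o = X w_o$, $p_o = X^T t_o / t_o^T t_o$, and deflation
   $X \leftarrow X - t_o p_o^T$;
3. finally $t = Xw$, $p = X^T t/t^Tt$, and the inner regression
   $b = t^T y / t^T t$.

The orthogonal components absorb structured variation in $X$ that is
uncorrelated with class membership (batch-like or subtype-internal
structure), so the single predictive component concentrates the
between-class signal. The invariants $t \perp t_o$ and
$t_o \perp y$ hold by construction and are property-tested. Fit quality
is summarized by $R^2X$ (fraction of $\lVert X \rVert_F^2$ captured by
predictive plus orthogonal components), $R^2Y = 1 - \lVert y - bt
\rVert^2 / \lVert y \rVert^2$, and the cross-validated $Q^2Y$.

The score sign is fixed so that the positive class has positive mean
$t$; this makes the up/down reading of the S-plot deterministic.

### Cross-validation and significance

$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$, with PRESS accumulated from
K-fold refits (each fold re-centers $X$ and $y$ on its own training
part, again to avoid leakage) and SS the total response sum of squares.
Folds default to 7 and are assigned by venetian blinds on the stable
sample-id ordering — sample $i$ goes to fold $i \bmod 7$ — which makes
$Q^2$ reproducible without a seed. Seven folds are the convention of the
chemometrics software lineage this model family comes from; the original
sources rarely state their fold scheme, so second-decimal agreement with
published $Q^2$ values is not guaranteed.

Model significance uses CV-ANOVA:
$F = \frac{(SS - \mathrm{PRESS})/d_1}{\mathrm{PRESS}/d_2}$ with
$d_1 = 1 + K$ (one degree of freedom per extracted component) and
$d_2 = n - d_1 - 1$, referred to the upper tail of $F(d_1, d_2)$.
Commercial implementations use proprietary degrees-of-freedom
bookkeeping; ours is documented here and exact p-value parity with such
software is explicitly not promised. Negative $F$ maps to $p = 1$.

### Choosing the number of orthogonal components

No published rule fixes $K$. `select_n_ortho()` starts at zero and
accepts another component while cross-validated $Q^2$ improves by more
than `gain_threshold` (default 0.01), a deterministic stand-in for the
unpublished auto-fit rules of commercial packages. `n_ortho = "auto"`
in the selectors uses this rule per model.

## S-plot ranking

From a fitted model, each gene $g$ gets
$$\mathrm{cov}(t, X_g) = \frac{t^T X_g}{N - 1}, \qquad
  \mathrm{corr}(t, X_g) = \frac{\mathrm{cov}(t, X_g)}{s_t\, s_{X_g}},$$
with $s_t$, $s_{X_g}$ sample standard deviations ($N-1$ denominator,
matching the covariance). Correlation (the S-plot's "p(corr)" axis)
measures reliability; covariance measures contribution. Selection ranks
by $|\mathrm{corr}|$ and, within runs of genes whose $|\mathrm{corr}|$
values sit closer than `corr_tie_window` (default 0.01), prefers the
larger $|\mathrm{cov}|$; remaining ties fall back to lexicographic gene
id so results are fully deterministic. The window quantifies the informal
rule that contribution decides when correlations are not meaningfully
different; no published threshold exists, so it is exposed as a
parameter. Genes whose centered profile is numerically constant
($s_X < 10^{-12}$) are flagged and given zero correlation rather than an
indeterminate value.

A `balanced = TRUE` mode selects half the panel from the most positive
and half from the most negative correlations. It is off by default:
observed published panels mix even and uneven up/down splits, which
indicates plain top-$k$ selection, and we do not guess beyond that.

## Multi-model arrangements

**Hierarchical** (classes with subtypes): model 1 contrasts the outgroup
with the merged super-class on all samples (default 40 genes); model 2
contrasts the two subtypes using only the super-class samples, re-centered
on that subset (default 10 genes). **Parallel** (one-versus-rest): one
model per class, that class against the pooled rest, default 17 genes
each. In both, the union is deduplicated — a gene picked by two models
keeps its higher-$|\mathrm{corr}|$ occurrence, and the loser is logged —
and the hierarchical panel is topped up from model 1's deeper ranking if
deduplication leaves it short of `k_total`. The parallel panel is simply
$3k$ minus duplicates, matching how published panels of 51 picks shrink
to 50.

`ovr_ttest_select()` is the baseline: the same contrasts, ranked by
Welch two-sample p-value on log10 values (vectorized, with a $10^{-12}$
guard on the standard error so constant genes rank last instead of
erroring). Welch rather than pooled-variance was chosen because group
variances on microarrays are rarely equal; it is the safer default when
the source convention is unstated.

## Panel validation

PCA (by SVD, deterministic sign convention: the largest-magnitude
loading of each component is positive) provides score plots and the
between/within separation ratio `class_separation()`. Agglomerative
clustering of samples uses Euclidean or Pearson ($1 - r$ between sample
profiles over the panel genes) distance under Ward (`ward.D2`), average
or complete linkage. Published practice pairs Euclidean+Ward with
full-matrix trees, Euclidean+average with hierarchical top-50 panels and
Euclidean+complete with parallel panels; all combinations are exposed.

Dendrogram reading is formalized: the tree is cut into $k$ clusters
(default: the number of classes) and clusters are mapped to classes by
the injective assignment minimizing total misclassification, found
exhaustively — exact for the handful of classes this package targets.
This turns "the tree looks right" into a reproducible scalar.

## The synthetic generator

`synthetic_spec()` emulates the structure of a Golub-style training set:
38 samples in three classes of 19/8/11 (imbalance kept on purpose),
2000 genes with log10 baselines $N(2.8, 0.5)$, within-gene noise
$\sigma = 0.2$, planted markers (25 up + 25 down per contrast) shifted
by $\pm 0.6$ log10 units in the affected class, and 10% near-constant
genes ($\sigma/20$) for the variation filter to remove. Effects are
additive in log10 — hence multiplicative in raw intensity — so planted
signal is linear exactly where the model operates. Marker sets of
distinct contrasts are disjoint by construction, and generation restores
the global RNG state afterwards.

What it does not emulate: probe-level artifacts, laboratory batch
effects, heavy-tailed noise, correlated gene blocks, or
intensity-dependent variance. Passing recovery tests therefore shows the
selection machinery is correct and well-calibrated on clean log-normal
data, not that it is robust to every pathology of real arrays.

One measurement convention matters. With baselines drawn as
$N(2.8, 0.5)$, a minority of planted markers land on low baselines where
even a 4-fold shift spans less than 500 raw units, and the variation
filter removes them before any selector can see them. Marker recovery is
therefore defined over planted markers present in the filtered matrix
(the quantity that measures the selector); the fraction over all planted
markers is reported alongside by `marker_recovery()` and the acceptance
script, and the gap between the two is the filter's doing, not the
selector's.

## Numerical choices and degenerate inputs

- Degenerate contrast ($X^T y \approx 0$): refused with a clear error
  rather than returning a meaningless direction.
- Orthogonal deflation beyond the matrix rank: refused (score or weight
  norms below $10^{-10}$).
- Tolerances: unit norms and orthogonality to $10^{-10}$/$10^{-8}$;
  correlation bounds allow $10^{-9}$ of floating-point slack.
- All randomness (random CV folds, the generator) flows through explicit
  seeds; venetian-blind CV and the selectors are seed-free and fully
  deterministic.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on synthetic
data: unit tests on matrices between $4\times 3$ and $38 \times 2000$,
oracle comparisons on 50 random $10 \times 8$ matrices, recovery checks
at the generator defaults with 20 replicates per effect size in
$\{0.2, 0.4, 0.6\}$. These sizes were chosen to exercise every code path
at desk scale; the full Golub-scale reproduction (7129 probes) is a
matter of supplying the original files to `scripts/golub_check.R`.

## Known limitations

- Only single-response OPLS (one predictive component); no multi-column
  Y, O2PLS or kernel variants.
- More than three classes is allowed in parallel mode but flagged
  experimental; hierarchical mode is fixed at one outgroup and two
  subtypes.
- CV-ANOVA p-values follow the documented degrees of freedom, not any
  proprietary variant.
- The gain-threshold rule for orthogonal components is a reasoned
  stand-in, not a reconstruction of any specific software's auto-fit.
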