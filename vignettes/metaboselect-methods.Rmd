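---
title: "Methods: biomarker discovery in two-class targeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker discovery in two-class targeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Targeted serum metabolomics studies of case-control design produce a small
table — a few dozen samples, a few hundred metabolites quantified as
integrated peak areas — from which a compact panel of discriminative markers
must be extracted. At this scale (e.g. 15 cases versus 21 controls over 232
metabolites) the central risks are batch-scale artefacts, the dominance of
high-abundance analytes, and optimistic marker lists driven by chance
associations. `metaboselect` implements an end-to-end pipeline addressing
each: per-batch normalization, variance-tempering scaling, two complementary
multivariate rankings (PLS-DA VIP; random-forest backward selection), and
stability assessment by Monte Carlo cross-validation (MCCV).

# Preprocessing

Three steps, in fixed order:

1. **Batch RMS normalization.** Each marker $j$ within each analytical batch
   $b$ is divided by its root mean square in that batch,
   $x_{ij} \leftarrow x_{ij}/\sqrt{\operatorname{mean}_b(x_{\cdot j}^2)}$.
   We read "each variable of each batch" as a per-marker-per-batch divisor
   (not one scalar per batch): that is the reading under which a purely
   multiplicative batch effect on an individual metabolite cancels exactly,
   which is the point of the step. Afterwards every marker has RMS 1 within
   every batch; applying the step twice is a no-op.
2. **Log transform.** Base 10 by default (the base only rescales all
   downstream scores uniformly; 2 and $e$ are accepted). A zero intensity is
   a domain error unless a nonnegative `log_offset` is configured — silent
   pseudo-counts are a decision the analyst should make, not the package.
3. **Pareto scaling.** Columns are mean-centered and divided by the *square
   root* of their sample standard deviation ($n-1$ denominator, stated
   because unit tests are sensitive to it even though AUC and VIP are not).
   This tempers high-variance markers without flattening the variance
   structure entirely: the post-scaling column variance equals the raw
   column's standard deviation. Zero-variance columns become all-zero and
   are flagged rather than dropped, so marker indices stay stable across
   stages.

Univariate AUCs are invariant to steps 2-3 (monotone transforms); direction
calls are made on the batch-normalized, pre-log matrix, where group means are
interpretable.

# PLS-DA and VIP

The class response is coded control = 0, case = 1 and centered; components
are extracted by NIPALS with X-deflation. With a single response column the
inner iteration converges on the second pass, so the fit is exactly
deterministic (tolerance 1e-10, 500-iteration cap are kept as guards).
Weight columns are unit-norm; per-component explained response sum of
squares is $c_a^2\,t_a^\top t_a$.

The cumulative VIP through depth $a$ is
$\mathrm{VIP}_j = \sqrt{p\,\sum_{k\le a} s_k w_{jk}^2 / \sum_{k\le a} s_k}$,
whose mean square over markers is exactly 1 at every depth — the invariant
the test suite checks to 1e-10. The **global VIP is the maximum over depths
1..A** (A = 3 by default). The maximum was chosen because, in reference
marker tables of this kind, the printed "global" column equals the
component-1 value while cumulative VIPs decrease with depth; the max
reproduces that pattern without assuming which software convention produced
it. The conventional shortlist keeps markers with global VIP ≥ 2, ties
broken by marker name for a reproducible ordering.

# Univariate ROC

AUC is computed by the Mann-Whitney identity with midrank ties, and equals
exhaustive case-control pair counting exactly (an oracle the acceptance
suite checks on 1,000 random tied instances). The case group is the positive
class and AUC is reported unflipped: a marker decreased in cases shows
AUC < 0.5, with the direction carried by a separate Low/High call per class,
rather than folding to max(AUC, 1-AUC). ROC curves are threshold sweeps over
the distinct observed values; their trapezoidal area equals the
Mann-Whitney AUC, ties included.

# Sequential backward selection (SBS)

A two-class random forest (bootstrap CART, Gini splits, out-of-bag error,
permutation importance as mean decrease in OOB accuracy) is grown on the
surviving panel; each round the least important fraction (default 0.2,
ceil-based shrink, at least one marker) is dropped, and importances are
**recomputed on the surviving set each round** rather than reused from the
full model. The forest is implemented in C++ with a self-contained
splitmix64 RNG, so results are bit-reproducible for a given seed across
platforms and independent of R's RNG state. No R random-forest package is
assumed by the installation environment, and the elimination loop needs
tight control of seeds and per-round importances anyway.

The selected subset is the round minimizing OOB error; under the default
one-standard-error rule the smallest subset within one binomial standard
error ($\sqrt{e(1-e)/n_{\mathrm{oob}}}$) of the minimum is preferred. Only
the criterion (OOB) and direction (backward) are fixed; fraction, floor
(default 2), tree count (default 500) and the tie rule are configuration.
SBS runs on the full marker panel, not the VIP shortlist — selection over
the wider set can surface markers the VIP shortlist misses.

# Monte Carlo cross-validation

N = 50 iterations by default. Each iteration draws a stratified random split
(70% training); pareto centering/scaling constants are fitted on the
training rows only and applied to the test rows (the suite asserts that
perturbing test rows leaves the constants bit-identical). Batch
normalization, by contrast, is applied to the full table before splitting:
batch scale is a property of acquisition, not of the classifier, and
normalizing per-split would let split membership change a sample's values.
SBS is re-run inside every split — fractional rank frequencies are only
possible under per-split selection — and a `select = FALSE` mode validates a
fixed panel instead. A final forest on the selected subset scores the test
samples by case-class vote fraction, giving the per-iteration test ROC and
AUC.

Aggregates:

* **Rank frequency** — fraction of iterations in which a marker is selected.
* **Importance** — the final-model permutation importance, rescaled per
  iteration so the selected panel's mean square is 1 (VIP-like), then
  averaged over the iterations where the marker was selected. The reference
  analyses label this column "VIP" while describing a random-forest final
  model; since its provenance there is undocumented, this package defines
  its own importance score explicitly rather than guessing.
* **Composite ROC** — vertical averaging on a fixed 101-point FPR grid. Each
  curve is linearly interpolated after collapsing vertical segments to their
  upper TPR, and the first grid point is pinned to (0,0) (the convention of
  cross-validated mean-ROC plots), which keeps the composite monotone from
  (0,0) to (1,1). Averaging a perfect and a diagonal curve gives TPR 0.75 at
  FPR 0.5, the hand-derivable check in the suite.

Iteration seeds derive from the base seed by a fixed offset, so results are
reproducible end to end and iteration k does not change when N grows.

# The synthetic cohort generator

There is no deposited dataset for studies of this design, so the generator
is a first-class module stating the world the pipeline assumes: 15 cases, 21
controls, 232 markers, 10 informative, 2 batches by default. Intensities are
log-normal: natural-log baseline drawn once per marker from
$\log U(10^4, 10^6)$ (typical integrated peak areas), Gaussian log-scale
noise (sd 0.5), a signed group effect of $\log(2)\times$log2-fold-change on
informative markers in cases (magnitudes drawn from [1.5, 2.5]; 7 of 10
elevated, 3 decreased, mirroring the direction mix reported for serum
ceramide/sphingomyelin panels), and a purely multiplicative per-batch
per-marker factor from $U(0.5, 2)$. Noise sd is defined on the natural-log
scale because the model is log-normal; log2 effects enter as
`effect * log(2)`. Samples go to batches round-robin, so batch is *not*
confounded with class — deliberately, to isolate what normalization must do.

What the generator does **not** emulate: instrument drift within a batch, QC
pool samples, duplicate injections, internal standards, missing values, or
correlation structure between metabolites (markers are independent given
class and batch). A green recovery test therefore establishes that the
pipeline finds independent planted log-scale effects at realistic n — not
that it untangles correlated lipid families.

# Numerical choices and degenerate inputs

* Batch blocks that are entirely zero raise a degenerate-scale error naming
  batch and marker; log of a nonpositive value names sample and marker.
* Exactly equal group means withhold the direction call (flagged tie).
* Elimination ties on equal importances break by marker name, and VIP-sort
  ties by marker name, so every ordering in the package is total and
  reproducible.
* `runif(n, a, a)` in base R returns without consuming the RNG stream; the
  generator scales raw uniforms by hand so that a degenerate
  `batch_scale_range = c(1, 1)` produces the bit-exact batch-free
  counterpart of a batched cohort (the test for the multiplicative-batch
  invariant relies on this).
* Vote ties in the forest predict the control class; OOB error counts only
  samples with at least one out-of-bag tree.

# Known limitations

On null data (no planted effects) the mean MCCV test AUC is well calibrated,
but the marker table at rank-frequency threshold 0.5 is *not* reliably
empty: with 232 null markers at n = 36 the strongest chance separator has
|AUC − 0.5| ≈ 0.3 in a typical cohort, and because MCCV training sets share
~70% of samples, backward selection re-finds that same marker in more than
half the splits in roughly 40% of replicate cohorts. Rank frequency measures
selection *stability*, and stability does not imply signal at this scale —
a null-calibration run (or permutation of labels) alongside any real
analysis is the honest control, and one of the acceptance checks documents
this behavior rather than hiding it.
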