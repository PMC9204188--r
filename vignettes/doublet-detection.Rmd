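---
title: "Doublet detection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doublet detection: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A droplet that captured two cells yields one barcode whose expression
profile is a mixture of two cells' transcriptomes. Doublet prevalence grows
with loading density — close to 1% per 1,000 cells captured, so `dblkit`
models the expected doublet count of an `n`-droplet capture as
`e = n² · 10⁻⁵` unless the user supplies a rate. Homotypic doublets (same
transcriptional state twice) are nearly indistinguishable from singlets and
mostly harmless; the method therefore aims at *heterotypic* doublets and
restricts its rate expectations accordingly.

Since no labelled doublets exist at analysis time, the classifier is
trained on *artificial* doublets built from random pairs of real droplets.
The central modelling assumption is that a real doublet's expression is
approximately the sum of two cells' expressions, up to capture efficiency —
supported by the observation that real doublet library sizes track, but
fall short of, the sum of the composing cells' sizes. Three generation
methods hedge against the ways this assumption fails:

* **sum** (75% of artificial doublets): exact element-wise sum of two
  droplets' counts. Library size is conserved exactly.
* **poisson**: the sum is halved and used as the element-wise mean of
  Poisson sampling, modelling renewed sampling noise at roughly singlet
  depth.
* **reweighted** (cluster mode only, half of the non-sum share): the two
  sources' contributions are first rescaled so that source 1 contributes a
  fraction equal to the *average* of its observed library-size fraction
  `ℓ₁/(ℓ₁+ℓ₂)` and its cluster's median-size fraction `m₁/(m₁+m₂)` — a
  hedge for when the observed library size is a poor proxy for cell RNA
  content. The algebra (scale both sources to the target fractions of the
  pooled size, halve, Poisson-sample) is the simplest reading consistent
  with that averaging statement.

Only droplets inside the 5–95 library-size percentile band (linear
interpolation quantiles) serve as sources; alternatives to this quantile
definition shift the eligible set by at most one droplet on small data.

In **cluster mode** (the default) pairs are drawn from different clusters
only, proportionally to cluster sizes. This spends no artificial doublets
on modelling homotypic doublets — which would teach the classifier to call
singlets — and records each artificial doublet's origin pair for origin
inference later. In **random mode** pairs are unrestricted and the
iterative procedure instead drops "unidentifiable" artificial doublets
(those scoring below the round's threshold) from training.

## From counts to predictors

The matrix is reduced to its 1,000 most expressed features (per-cluster
top-⌈n/k⌉ union in cluster mode, so minority-cluster markers survive).
Real and artificial droplets are normalized identically — each column
scaled to the *real* droplets' median library size, then `log1p` — and
embedded by a single truncated PCA (rank 20). For every embedded droplet
the fraction of artificial doublets among its k nearest neighbours (exact
search, self excluded) is computed at k = 5, 10, 20, plus an
inverse-distance-weighted ratio at the largest k (`ε = 1e-8` stabiliser).
Computing the ratio at several scales lets the classifier pick the
informative neighbourhood size, which can differ across the expression
space. The predictor table adds the first 10 PC projections, library size,
number of detected features, and a co-expression score that counts how many
normally mutually-exclusive feature pairs a droplet co-expresses (pairs
ranked by the standardized deficit of observed co-occurrence below the
independence expectation `n·p₁·p₂`, among the 500 most expressed selected
features; 500 pairs used). Predictors known to cause overfitting — distance
to the nearest artificial doublet, whether the nearest neighbour is
artificial — are deliberately absent.

## Iterative classification and thresholding

Gradient-boosted trees (250 rounds, depth 4, learning rate 0.1, row
subsample 0.75, binary logistic objective) are fit to separate artificial
from real droplets. Every droplet is scored *out-of-fold* via 5-fold
cross-fitting so no droplet is scored by a model that saw it; rows outside
the training set are scored by the fold-model average. Because some real
droplets are true doublets mislabelled as singlets, training runs for 3
rounds by default: after each round's thresholding, real droplets at or
above the threshold ("confidently identified" — the cutoff is the round's
own threshold, a documented choice since no quantitative rule is
prescribed) are excluded from the next round's training but still scored.
Two to three rounds suffice; more mostly re-confirms the same exclusions.

The threshold scan evaluates every unique score (plus 0 and just above 1)
and minimises

```
cost_t = FNR_t + FPR_t + deviation_t²
```

with `FNR_t` the fraction of artificial doublets below `t`, `FPR_t` the
fraction of *eligible* real droplets at or above `t` (droplets called in a
previous round are ignored here, though they still count towards the
observed call count `o_t`), and

```
deviation_t = 0                                          if e_low ≤ o_t ≤ e_high
            = 2 · min(|o_t − e_low|, |o_t − e_high|) / (e_low + e_high)  otherwise
```

The bounds are `(dbr ∓ dbr_sd) · n · het_fraction`, floored at zero.
`dbr_sd = 0.015` reflects the empirical spread of observed doublet rates.
`het_fraction` is `1 − Σ pₖ²` over cluster frequencies in cluster mode. In
random mode no clusters exist; the implementation uses the fraction of
artificial doublets scoring above the median real droplet as an
identifiability proxy (clamped to at least 0.05), re-estimated each round —
an explicit approximation. Ties in the cost scan break towards the larger
threshold, i.e. fewer calls. The squared deviation keeps the term soft near
the interval and dominant far from it.

The **direct classification** variant skips embedding and kNN features and
trains on the normalized expression of the selected features directly, with
tree depth 6 for the higher-dimensional predictors. It exists mainly to
demonstrate *why* the kNN summarisation helps: the trained problem
(artificial vs real) differs subtly from the target problem (doublet vs
singlet), and a classifier with access to full expression learns artefacts
of artificial doublet construction that real doublets lack.

## Multi-sample captures

Doublets form within a capture, so for pooled captures the expected count
is the *sum of per-capture expectations*: two captures of 5,000 droplets
expect `2 · 5000² · 10⁻⁵ = 500` doublets, not `10000² · 10⁻⁵ = 1000`.
`detect_doublets_multisample()` offers `split` (independent runs per
capture — cheap, robust to batch effects) and `combined` (one run with the
summed expectation). On homogeneous captures the two agree closely.

## scATAC-seq

Accessibility reads are spread over orders of magnitude more sites than
expression over genes, so "top expressed feature" selection discards most
of the signal. `aggregate_features()` instead TF-IDF-normalizes
(`TF = x/colsum`, `IDF = log(1 + N/nᵢ)`), runs PCA with *features* as
observations, k-means the features into `n_meta` groups (1,000 by default;
use fewer than the number of sites), and sums raw counts within groups —
column totals are conserved exactly — before running the standard pipeline
on the meta-features with selection disabled.

Independently, `amulet_counts()` exploits ploidy: a diploid genome offers
each locus at most twice, so loci where one barcode's fragments stack more
than two deep indicate a doublet. Loci are maximal runs of overlap depth
> 2 under a sweep-line over each barcode's fragments per chromosome
(0-based half-open intervals; ends sort before starts at equal
coordinates). This counts fragment overlap runs rather than read start
positions — a documented divergence from the original read-based counting,
which the available description does not pin down. The null rate for the
Poisson upper-tail p-value is the trimmed mean of counts inside the 10–90%
quantile band; the statistic grows with library size, which is confounded
with doublet status, so per-barcode fragment totals are reported as a
diagnostic rather than corrected for. The expression-side score `s` and the
overlap p-value combine via Fisher's method,
`X = −2(ln p₁ + ln p₂) ~ χ²₄`, with `p₂ = 1 − s`; the overlap statistic
contributes sensitivity to homotypic doublets that the embedding side
cannot see.

## Doublet origins and enrichment

For each called doublet the modal origin pair among its 10 nearest
artificial doublets is reported (ties resolved towards the pair with
smaller summed neighbour distance). Because real doublets often contain
mostly one cell's reads, usually one of the two origins is recovered and
the second is not — expect "at least one correct" accuracy far above
"both correct".

Observed doublet counts per cluster pair are compared with the
random-pairing expectation `n · 2pₐp_b / (1 − Σpₖ²)`. Cluster stickiness is
one GLM over all pairs: cluster-membership indicators (no intercept — the
indicators sum to 2 on every row, so an intercept would be aliased), the
log random-pairing expectation as offset (count families) or an
`observed/(observed+expected)` logit response weighted by
`(observed+expected)/2` (binomial families), and optionally the log
identification difficulty — the misclassification rate of artificial
doublets of that origin at the final threshold, continuity-corrected
`(x+0.5)/(n+1)` so the log stays finite — included when at least 7 clusters
are present and estimable. The combination test first fits a global model
`log(observedᵢ) = α + log(eᵢ) + β·log(difficultyᵢ)` (negative binomial by
default; the dispersion degenerating to the Poisson limit is handled by
falling back to a Poisson fit), then evaluates each pair's single upper
tail `P(X ≥ observedᵢ)` at the fitted mean with the global dispersion, with
Benjamini–Hochberg adjustment across pairs.

Calibration caveat: across quasi-binomial, binomial, Poisson and negative
binomial variants, the quasi-binomial absorbs over-dispersion best. On
over-dispersed null simulations the parametric families are clearly
anti-conservative (empirical false-positive rates several-fold above the
nominal 0.05 in the package's own tests), so treat small p-values from the
count families with suspicion. With few clusters or very small expected
counts per pair, the weighted quasi-binomial fit itself degenerates; the
tests are meant for captures large enough to yield tens of called doublets
per common pair.

## What the simulators emulate — and what they do not

`simulate_scrnaseq()` draws per-cluster mean profiles (log-normal baseline,
disjoint marker blocks at 10× fold change covering 5% of genes per
cluster), per-cell library factors (log-normal, sd 0.3), and
negative-binomial counts (size 10 by default, ~2,000 counts per cell).
Planted doublets are a *single* NB draw from the pooled, capture-thinned
parent means (capture fraction uniform on 0.55–0.9), not a sum of two
realized cells: summing realized droplets is exactly how artificial
doublets are constructed, and a generator doing the same would make the
trained problem artificially identical to the target problem — hiding, for
instance, the direct classifier's overfitting. Parent clusters are drawn
independently, so homotypic doublets arise at rate `Σpₖ²`;
`heterotypic_only = TRUE` forces cross-cluster pairs for evaluations whose
positive class is heterotypic by construction.

`simulate_fragments()` builds a one-chromosome genome of 1 kb-spaced sites:
10% "housekeeping" sites accessible in every cluster at high capture rate,
the rest cluster-specific (60% per cluster) and sparse, with a per-cell
capture efficiency. Singlets place at most two overlapping fragments per
site — zero deep loci by construction — while doublets merge two
cross-cluster cells and stack up to four deep at shared sites. Only
cross-cluster doublets are planted: a homotypic fragment doublet carries no
accessibility signal beyond depth and library size, which is precisely the
overlap statistic's domain.

Passing tests on these generators shows the pipeline recovers doublets
whose construction matches its assumptions under realistic noise; it does
not certify performance on real data with ambient RNA, empty droplets,
batch effects, continuous trajectories (where "between-cluster" is
ill-defined), or cell-cycle structure — none of which are modelled.

## Numerical choices and problem sizes

Defaults not fixed by the method's description, chosen once to match
common single-cell practice: SVD rank 20, kNN graph k = 10, Louvain
resolution 1.0, meta-cell path above 1,000 droplets with `min(n/10, 500)`
meta-cells, singleton communities merged into the nearest centroid
cluster, k list (5, 10, 20), 10 PC predictors, feature ties broken by
ascending index, Matrix-Market 1-based indices converted internally,
fragments 0-based half-open. Artificial doublet count defaults to the
number of real droplets. The AUPRC integrates step-wise (precision held
between thresholds); the *adjusted* AUPRC — FDR rescaled so the expected
within-individual-doublet proportion maps to 0, TPR so one minus the
expected homotypic proportion maps to 1, both clamped to [0, 1] — uses the
trapezoid rule, and the two conventions can differ in the third decimal on
tiny instances.

The package's own evaluations run at desk scale, chosen so the full suite
completes in minutes on one CPU: 2,000 droplets × 500 genes for end-to-end
recovery, 600 × 400 at fold-change 3 and NB size 2 for the ten paired
kNN-vs-direct comparisons, 400 barcodes × 2,000 sites for the fragment
fixture, and 50-replicate enrichment simulations at NB size 5. The
evaluation convenience `evaluate_detection()` averages metrics over two
seeds, smoothing classifier run-to-run variability.

## Known limitations

* Scores are classifier probabilities for the artificial-vs-real problem;
  they are not calibrated posterior doublet probabilities (no base-rate
  adjustment).
* Origin inference recovers the dominant contributor far more reliably
  than the pair; downstream enrichment inherits that noise.
* The fragment-overlap statistic needs deep libraries and is confounded
  with library size; no correction is applied, only a diagnostic.
* Very small captures (< 50 droplets, or < 50 per sample in split mode)
  leave too little training data; the functions warn rather than refuse.
* Triplets and higher multiplets are not modelled, by the artificial
  generation or the simulators.
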