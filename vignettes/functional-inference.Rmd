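---
title: "Methods: phylogeny-based functional inference from 16S profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-based functional inference from 16S profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruminfer)
```

## Overview

`ruminfer` infers the KEGG-ortholog (KO) functional profile of a
microbial community from a 16S OTU table, using a custom reference of
sequenced genomes placed on a 16S phylogeny. The inference has two
halves: a *reference-side* computation that propagates observed gene
counts across the tree to unsequenced organisms, and a *query-side*
pipeline that maps each OTU onto the reference and converts abundances
into expected gene counts. This vignette documents the models, the
tunable parameters, the numerical conventions, and the choices made
where the design was genuinely open.

## The ancestral-state model

Each trait (a KO's gene copy number, or the 16S copy number) is modelled
as Brownian motion (BM) with a common rate along the reference tree:
trait change over a branch of length $t$ (substitutions/site) is
$\mathcal{N}(0, \sigma^2 t)$. Under this model the maximum-likelihood
estimate of an internal node's state given the sequenced-tip values is a
generalized-least-squares (GLS) estimate, and it can be computed without
forming covariance matrices by Gaussian message passing (Felsenstein's
pruning):

* a sequenced tip sends the message $(x, t)$ up its branch — its state
  and the branch length as effective variance;
* $k$ messages $(x_i, t_i)$ meeting at a node combine to mean
  $\sum (x_i/t_i) / \sum (1/t_i)$ with effective length
  $1/\sum(1/t_i)$, and passing through a branch adds that branch's
  length — for two children this is the familiar
  $t_{parent} + t_a t_b/(t_a+t_b)$ pruning rule;
* the *marginal* estimate at a node combines **all** messages incident
  to it — from below and from the rest of the tree through its parent
  edge — which is exactly the rerooting convention: every node is
  treated in turn as the root. One down-pass and one up-pass give all
  marginals in $O(\text{edges} \times \text{traits})$.

Unsequenced tips send no message, so they never influence the
reconstruction. Multifurcations need no special handling: the combine
step takes any number of messages. The test suite checks this engine
against an independent brute-force GLS oracle that builds the explicit
BM covariance matrix from patristic distances (shared path length from
the focal node) and solves it directly; on random trees the two agree to
machine precision, far inside the 1e-8 tolerance asserted.

Estimates are inverse-variance-weighted averages of sequenced-tip
values, so every reconstructed state lies within the min–max hull of the
observed states of that trait (a property-tested invariant).

### Tip prediction and NSTI

Sequenced tips keep their observed trait rows verbatim — predictions
must agree with direct observation where one exists. An unsequenced tip
takes the marginal state of its most proximal ancestor with a defined
state (with at least one sequenced tip in the tree, that is always its
parent). No distance-weighted blending toward the tip is applied: the
nearest-ancestor rule is the simplest scheme consistent with the
convexity invariant, and blending is left as an extension point.
Predictions are clamped to be non-negative (vacuous for the weighted
averages, but part of the output contract), and never rounded —
predicted gene counts are continuous; the command-line `--round` flag
applies half-up rounding at output time only.

Prediction reliability is summarized per tip by the
nearest-sequenced-taxon index (NSTI): the minimum patristic distance to
any sequenced tip, 0 for sequenced tips. Hold-out benchmarks
(`benchmark_trait_recovery()`) confirm the intended behavior: mean
absolute prediction error increases across NSTI terciles.

### Numerical conventions

* Branch lengths of exactly 0 are replaced by $\varepsilon = 10^{-6}$
  inside the engine only — user data are never mutated — so
  inverse-length weights stay finite. Lengths that are merely small are
  left untouched.
* Trait tables are stored as non-negative reals, not integers:
  downstream predictions are continuous.
* Predicted 16S copy numbers below 1 are clamped to 1 before use as
  divisors: a genome carries at least one rRNA operon, and the clamp
  prevents abundance inflation for poorly covered regions of the tree.
* Fewer than two sequenced tips, an all-missing trait column, or an
  empty trait/tree label intersection are fatal errors, not warnings.

## The query pipeline

**Classification.** Each OTU representative sequence is aligned globally
(Needleman–Wunsch; match 1, mismatch −1, gap open 5, gap extend 2)
against every reference 16S sequence, and identity is computed as
matches / aligned columns with terminal gap columns excluded and
internal gaps counted as mismatch columns. Ambiguous bases never count
as matches. Two points deserve emphasis because alignment dialects
differ: the *alignment* is end-to-end (so unrelated sequences cannot
score 100% over a short overhang), but terminal gap *columns* are
excluded from the identity ratio (so a clean fragment of a reference
still scores 100%). The best hit must reach the threshold — default
97.0%, inclusive, mirroring the 97% similarity grain at which OTUs are
conventionally clustered; the classification cutoff itself is a package
choice, exposed as a parameter. Ties are broken by the
lexicographically smallest reference ID under C collation, making runs
bit-reproducible. The search is exhaustive; no k-mer prescreen is
applied.

**Aggregation.** Abundances of OTUs classified to the same reference
organism are summed. Unassigned OTUs are dropped — closed-reference
semantics — and the dropped count and abundance are logged so users can
judge coverage; a query set with no classifiable OTU is a fatal error.

**Normalization and prediction.** Classified abundances are divided by
the predicted 16S copy number and multiplied through the predicted
trait table: $M[k,s] = \sum_g (A'[g,s]/\hat{C}[g]) \, \hat{T}[g,k]$.
This is linear per sample and conserves mass
($\sum_k M[k,s] = \sum_g \text{norm}[g,s] \sum_k \hat{T}[g,k]$), both
property-tested.

**Pathway collapse.** KO profiles collapse onto BRITE level-3 pathways.
A KO can belong to several pathways; `duplicated` mode credits every
membership (pathway totals may exceed KO totals — deliberately, because
ignoring multiple membership under-counts multifunctional families),
while `deduplicated` mode uses only the first-listed membership and
conserves column totals exactly. KOs absent from the map pool into
`Unclassified`. Levels 1–2 are carried as annotation on the output. The
same two conventions drive the duplicated-column variant of the trait
table builder (`build_trait_tables()`).

## Evaluation statistics

`compare_profiles()` restricts the profiles to KOs present in all
datasets, converts to relative abundance, and reports Pearson $r$,
$R^2 = r^2$ and a t-transform p-value ($n-2$ degrees of freedom,
descriptive only — nothing gates on it). Three decisions here were open
and are fixed as follows:

* *Restriction before normalization*: relative abundances are computed
  after the shared-KO subset is taken, so both profiles are
  renormalized over the same feature set.
* *"Present" means nonzero total* by default (a KO row of zeros carries
  no evidence the function was observed); `presence = "exists"` is
  available for the row-existence reading.
* *Pooled normalization* (one total per dataset, summing over samples)
  is the default, matching the one-prediction-versus-one-metagenome
  comparison; per-sample normalization is a flag.

## Synthetic data: what it emulates, and what it does not

The generators produce data with the statistical structure the method
assumes, with models chosen for closed-form checkability rather than
realism:

* **Tree**: Yule (pure birth) with exponential waiting times, birth
  rate 1/unit time. With $n$ tips the expected depth is
  $\approx \sum_{k=2}^{n} 1/k \approx \log n$ — about 5 for 100 tips —
  so BM displacements and sequence divergence are of realistic
  magnitude relative to $\sigma^2$ and $\mu$.
* **Traits**: BM from a root state, transformed to counts by
  `round(max(0, x))`. Defaults: 20 KO families at root value 10 with
  $\sigma^2 = 1$ — a small panel large enough to average per-tip error
  over, with root states large enough that the non-negativity clamp
  rarely binds (keeping the pre-rounding BM oracle exact). Tip variance
  matches the $\sigma^2 \times \text{depth}$ closed form in tests.
* **16S copy numbers**: one BM trait (root 3, rate 0.2), rounded and
  clamped to $\geq 1$ — phylogenetically autocorrelated small integers,
  as observed for rRNA operon counts.
* **Sequences**: Jukes–Cantor at rate $\mu$ per site (default 0.5),
  uniform root sequence; two-tip identity matches the
  $\tfrac14 + \tfrac34 e^{-4\mu d/3}$ closed form in tests.
* **Communities**: per-sample tip proportions from a symmetric
  Dirichlet ($\alpha = 0.5$, uneven communities), multinomial reads at
  fixed depth; one OTU per tip, representative sequence = tip sequence
  with an optional number of extra point mutations.

Every generator takes a mandatory seed; per-operation seeds are derived
as seed + a fixed small offset so each generator is deterministic both
standalone and in composition. `make_holdout_benchmark()` returns the
bundle exactly as the pipeline sees it plus the hidden truth
(pre-rounding trait values for all tips, tip of origin of each OTU).

What the fixtures do *not* model: realistic community composition,
chimeras, sequencing error beyond point mutation, within-genome 16S
divergence, horizontal gene transfer (which violates the BM assumption
for exactly the gene families where inference is hardest), or database
mislabeling. Passing benchmarks on these fixtures therefore shows the
machinery is correct and well-calibrated under its own assumptions — not
that predictions on real communities reach any particular accuracy.

## Benchmark design and problem sizes

Two benchmark replicates are packaged:

* `benchmark_trait_recovery()` — 100-tip trees, 20% of tips hidden from
  the reference, $\sigma^2 = 1$; scores pooled Pearson $r$ between
  predicted and true pre-rounding trait values of held-out tips, and
  the NSTI-tercile MAE gradient. Run at 50 replicates in the
  acceptance checks.
* `benchmark_reference_contrast()` — the same tree/trait conditions
  with a 20-tip reference, comparing a *focused* reference (tips
  sampled across the tree, low mean NSTI) against a *distant* one (a
  single 20-tip clade, high mean NSTI), scoring $R^2$ on the
  non-reference tips. The focused reference should — and in the
  packaged checks does — outpredict the distant one, the synthetic
  analog of a habitat-matched reference outperforming a generic
  database. The small-reference/large-community geometry mirrors the
  practical setting of a few hundred genomes serving a much larger 16S
  census.

These sizes (100 tips, 20 traits, 50 replicates, 1000 property trials)
were chosen as the smallest at which the stochastic properties are
stable across seeds; all complete in about a minute on one CPU.

## Known limitations

* The ASR scheme is one defensible reading of "Brownian-motion
  reconstruction with default parameters"; other implementations may
  differ numerically (e.g. in how they treat unsequenced tips or root
  the marginals), so cross-tool agreement is qualitative, not
  bitwise.
* Nearest-ancestor tip prediction ignores the branch length from
  ancestor to tip; two sister tips at very different depths below the
  same ancestor receive identical predictions (their NSTI, not their
  prediction, differs).
* Classification is alignment-identity based; it does not implement a
  naive-Bayes classifier, chimera checks, or the heuristics of mothur
  or usearch, and it is exhaustive — appropriate for references up to a
  few thousand sequences, not for hundreds of thousands.
* The BIOM support is the classic TSV dialect only, not HDF5.
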