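---
title: "Phenotype-oriented network analysis of herbal medicine"
author: "HerbPhenoNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-oriented network analysis of herbal medicine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HerbPhenoNet)
```

## The problem

Medicinal plants come with centuries of recorded *efficacy* -- lists of
phenotypes (diseases, symptoms) a plant is traditionally used for -- while
most of their constituent natural compounds lack the molecular data
(structures, protein targets) that conventional in-silico pharmacology
needs. HerbPhenoNet predicts pharmacological effects of natural compounds
from this empirical knowledge alone. The reasoning chain is: plants with
similar efficacy profiles cluster together; a compound that occurs in the
plants of such a cluster far more often than elsewhere is likely to carry
part of the cluster's shared effect; so the cluster's averaged phenotype
profile becomes the compound's predicted effect spectrum.

Efficacy annotations are heterogeneous: one plant may be annotated with a
broad concept ("inflammation"), another with a narrow descendant
("diabetic retinopathy"). Comparing raw annotation sets misses such
relatedness. The package therefore embeds all annotations in a concept
hierarchy and smooths each plant's annotations over it before any
comparison is made.

## The model, stage by stage

### Hierarchy weighting by Wu--Palmer similarity

The phenotype hierarchy is a rooted DAG parsed from broader/narrower
(RB/RN) relation pairs. Each hierarchy edge $(c_1, c_2)$ is weighted by
the Wu--Palmer semantic similarity

$$\mathrm{sim}(c_1,c_2)=\frac{2\,\mathrm{depth}(l)}
{\mathrm{path}(c_1,l)+\mathrm{path}(c_2,l)+2\,\mathrm{depth}(l)},
\qquad l = \mathrm{lcs}(c_1,c_2),$$

with the lowest common subsumer $l$ the deepest shared ancestor. Depth
counts nodes from the root (the root has depth 1) while path counts
edges below the subsumer; the node-counting depth convention prevents
zero similarity at the root (an lcs of depth 0 would annihilate the
numerator). For a parent at depth $d$ and its child the score is
$2d/(1+2d)$: edges between specific concepts (deep) carry more weight
than edges between broad ones (shallow), which is exactly the intuition
that "diabetes mellitus / diabetic retinopathy" are closer than
"inflammation / hormonal imbalance".

DAG conventions the source relations leave open are fixed as: depth is
the shortest root path; lcs ties break lexicographically; cycles in real
terminology exports are broken deterministically (the back-edge first
met in a lexicographic depth-first traversal is dropped); multiple
parentless concepts are joined under a virtual root. The RB orientation
("second concept is broader") is a config flag since terminology exports
disagree.

### Random walk with restart

A plant's annotations become a uniform seed distribution $p_0$ over its
mapped concepts, diffused by

$$p_{t+1} = (1-r)\,W p_t + r\,p_0$$

where $W$ is the column-normalized weighted adjacency of the hierarchy
(edges traversable both ways, so effect signal flows both up to broader
concepts and down to siblings), and $r = 0.7$ is the restart
probability. One convention deserves a note: with a *column*-stochastic
$W$ the propagation operator must act as $W p_t$, not $W^\top p_t$ --
the transpose form belongs to the row-oriented transition convention and
would not conserve probability mass. Iteration stops when the L1 change
drops below $10^{-8}$ (the convergence criterion is stated without a
norm in the usual formulations; L1 is chosen because the iterate is a
probability vector), with a 10,000-iteration cap that is never
approached in practice since convergence is geometric at rate $1-r$.
`rwrClosedForm()` solves the fixed point $p = r(I-(1-r)W)^{-1}p_0$
directly and doubles as both the oracle for the iterative route and the
fast path: networks up to 2,000 concepts use one factorized solve for
all plants.

The steady state is projected onto a fixed, ordered phenotype universe
without renormalization, so values stay comparable across plants; a
plant's phenotype vector is this projection. The binary *ablation*
variant (`ablationVectors()`) skips diffusion entirely -- a 0/1
indicator of direct annotations -- and exists to quantify what the
hierarchy adds.

Seeds are weighted uniformly because no efficacy-strength data exists
in the source records; unmappable annotations are skipped with a log
message, and a plant with no mappable annotation is excluded.

### Clustering with multiscale bootstrap support

Plant vectors are clustered agglomeratively (average linkage, the
pvclust default, since nothing in the problem suggests another) under
cosine distance $1 - u\cdot v/(\lVert u\rVert\,\lVert v\rVert)$, which
compares effect *profiles* regardless of total diffused mass. Cluster
support is assessed by multiscale bootstrap: for each scale
$s \in \{0.5, 0.6, \ldots, 1.4\}$, 1,000 resamples of
$\mathrm{round}(s\,P)$ phenotype columns are drawn with replacement and
reclustered, and each internal node records the fraction of resampled
trees containing its exact member set (BP). The approximately unbiased
p-value extrapolates BP across scales through
$z_s = \Phi^{-1}(1-\mathrm{bp}(s))$, the weighted least-squares fit
$z_s = v\sqrt{s} + c/\sqrt{s}$ (weights from the binomial variance of
each BP), and $\mathrm{AU} = 1-\Phi(v-c)$. BP values are clamped to
$[1/(B{+}1),\,B/(B{+}1)]$ so the quantile transform stays finite; a
curve stuck entirely at one clamp bound gets that bound's limit as its
AU, flagged. A flat $\mathrm{bp}=0.5$ curve gives $v=c=0$ and
$\mathrm{AU}=0.5$ exactly, a useful closed-form check. Note that
$\mathrm{AU}\ge\mathrm{bp}(1)$ exactly when the curvature coefficient
$c\ge 0$, the typical situation for a genuine cluster whose BP rises
with the resampling fraction.

Clusters are selected at $\mathrm{AU} \ge 0.95$, keeping only maximal
supported nodes (a supported node inside a supported ancestor is
absorbed), never the root; the result is a set of disjoint plant
clusters. Columns with zero norm can appear inside resamples (a plant
can lose all its support columns); such rows are placed at distance 1
from everything rather than aborting the resample.

### Compound enrichment and effect mapping

For each selected cluster, every compound present in at least one
member plant is tested by the one-sided Fisher's exact test on the 2x2
table of cluster membership vs compound presence -- the hypergeometric
upper tail $P(X \ge a)$ -- and kept at $p < 0.001$. The test is
one-sided because only *enrichment* is of interest, and raw p-values
are used deliberately: the threshold is a tuned selection knob (0.1 /
0.01 / 0.001 scans), not a familywise error rate. Each enriched
compound inherits the arithmetic mean of its cluster members' phenotype
vectors; a compound enriched in several clusters combines cluster means
element-wise by maximum (preserving each cluster's signal undiluted;
mean is available as a config choice). The final association list keeps
(compound, phenotype) pairs with score $\ge 0.20$, the F1-optimal
operating point of the effect-score scale, sorted deterministically.

### Evaluation

Predictions are scored against known compound--phenotype associations
by per-compound (and per-phenotype) AUROC and AUPR -- tie-corrected
Mann--Whitney for the ROC area, the non-interpolated step rule for
precision--recall -- averaged over evaluable units; units lacking a
positive or a negative are skipped and counted. Negatives are all
universe phenotypes not positive for the unit, a choice the reports
state explicitly since gold standards rarely define negatives.
Complementarity between methods is quantified by Spearman rank
correlation and the Tanimoto overlap of top-10% prediction sets. The
molecular baseline, `targetCloseness()`, scores a compound--phenotype
pair by the mean shortest-path distance from the compound's target
genes to the nearest phenotype gene on a protein-interaction network,
with a permutation p-value from uniform same-size gene draws
(degree-matched nulls are out of scope and noted as such).

## The synthetic world

Real inputs at scale (a licensed terminology graph, curated plant
databases) cannot ship with a package, so `simulateWorld()` builds
worlds with the statistical structure the pipeline assumes: a complete
rooted tree (default 4 levels, ternary; 40 concepts, 39-phenotype
universe), $K = 5$ latent efficacy themes assigned to disjoint subtrees
drawn from the shallowest level wide enough to host them, 8 plants per
theme annotated with 4 concepts sampled from their theme's subtree
(without replacement, since an efficacy record is a set of distinct
concepts), each annotation replaced by a uniform universe draw with
probability 0.1, 3 compounds per theme present in theme plants with
probability 0.9 versus 0.05 elsewhere, and 30 background compounds at
30% presence everywhere. The planted truth maps each theme compound to
its theme's phenotype set. All randomness flows from one seed through
per-stage substreams. Defaults were chosen so the full pipeline with a
1,000-resample bootstrap runs in about a minute on one CPU; the test
suite uses a reduced resample count (100--400) for routine checks,
which affects AU precision but not the structural properties under
test.

What the generator does *not* emulate matters for interpreting green
tests: real efficacy vocabularies are far larger and annotation error
is not uniform; compound occurrence correlates across related plants;
and most real plants belong to *no* tight efficacy cluster. That last
difference has a visible consequence. Because every synthetic plant
belongs to a theme, and five themes forced into a ternary tree must
share depth-2 parents, the generated truth is *hierarchically nested*:
unions of sibling themes are genuinely stable clusters, acquire high AU
support, and the maximal-node selection rule then legitimately absorbs
their member themes. Exact recovery of all individual themes is
therefore not achievable by design under the default geometry -- the
recovery report (`recoveryReport()`) measures exactly how much -- while
in sparse, background-dominated data (as in real use) top-level nodes
lose stability and small clusters surface. The two-block acceptance
fixture, which has no nested structure, is the clean positive control
for the support machinery.

Degenerate corners are handled explicitly rather than silently:
zero-degree concepts get unit self-loops in the transition matrix;
scales whose resample would have fewer than two columns are skipped;
ties in ranked outputs break lexicographically so every artifact is
byte-reproducible under a fixed seed.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `r` | 0.7 | restart probability; higher keeps diffusion local to the annotations |
| `tol` | 1e-8 | L1 convergence tolerance of the walk |
| `n_boot` | 1000 | bootstrap resamples per scale |
| `scales` | 0.5--1.4 | resampling fractions the AU fit extrapolates over |
| `au_threshold` | 0.95 | minimum AU p-value for a plant cluster |
| `fisher_alpha` | 0.001 | raw enrichment p-value threshold |
| `effect_cutoff` | 0.20 | minimum phenotype score in the association list |
| `linkage` | average | agglomeration method |

## Known limitations

Diffusion runs over the full parsed network and only the projection is
restricted to the universe; whether projected vectors should be
renormalized is genuinely open -- raw projection was chosen to keep
cross-plant values comparable, and is flagged here. The Fisher test's
sidedness, the multi-cluster combination rule, and the RB orientation
are all config switches because the underlying sources do not pin them
down. The AU machinery implements the standard two-parameter fit; the
full asymptotic standard error of AU is out of scope.
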