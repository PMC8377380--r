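---
title: "Fusing multi-property drug similarity networks: methods and design"
author: "dsnfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-property drug similarity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsnfuse)
```

## The model

`dsnfuse` rests on one working hypothesis: if two drugs are similar with
respect to some property — the side effects they cause, their chemical
structure, the proteins they bind — then the therapeutic properties of one
are plausible candidates for the other. Each property induces a drug
similarity network (DSN); no single network is sufficient, because the
properties are complementary: drugs sharing targets frequently differ in
structure, and small structural edits can change binding dramatically. The
package therefore (i) builds a unit-scale DSN per property, (ii) fuses them
non-linearly into one integrated network (iDSN), (iii) clusters the iDSN and
selects the cluster count with internal validity indices, and (iv) reads
repositioning hypotheses off the result — from high-similarity pairs with
discordant therapeutic classes and from drugs sitting in clusters enriched
for a class they do not carry.

### Similarity measures

Side-effect and chemical similarity are Tanimoto coefficients over finite
feature sets (side-effect terms, atom-pair descriptors). Two conventions
matter and are deliberate:

* `tanimoto(∅, ∅) = 0`, not 1 — absence of evidence must not assert
  maximal similarity. A drug whose profile is emptied by filtering keeps a
  row in the network; it just has zero similarity to everything.
* Feature multisets are collapsed to sets; the reader warns when it
  collapses duplicated (drug, feature) pairs.

Side-effect terms are pre-filtered: a term occurring for at most one drug
corpus-wide is removed, as is any (drug, term) pair whose reported
frequency falls below 0.1%. The frequency rule only fires for pairs that
carry frequency data; the support rule applies to every term. Emptied
profiles are retained and logged, never dropped.

Target similarity averages a normalized Smith–Waterman (SW) kernel over the
two target sets,
$$S(d,d') = \frac{1}{|P^d||P^{d'}|}\sum_i\sum_j
\frac{SW(p_i,q_j)}{\sqrt{SW(p_i,p_i)\,SW(q_j,q_j)}},$$
clipped to [0, 1]. The **geometric-mean denominator** is a design choice:
the plain product of self-scores would shrink every term quadratically in
sequence length and could never reach 1 even for identical targets, whereas
the geometric mean makes each term a proper cosine-like quantity equal to 1
exactly when the two sequences align to themselves. The product variant
remains selectable (`normalization = "product"`). Note the *mean over
pairs* means a drug's raw self-similarity is exactly 1 only when its
targets are copies of one sequence; `buildTargetDSN()` therefore forces the
network diagonal to 1, which is the contract the downstream unit-scale
machinery needs.

SW itself uses affine gaps in the EMBOSS-water convention — a gap of length
L costs `gapOpen + (L − 1) · gapExtend` — with BLOSUM62, open 10, extend
0.5 as defaults. These are the de-facto standard local-alignment settings
for protein similarity; all three are configurable through
`alignmentScoring()`, including a uniform match/mismatch scheme for
didactic examples. The scorer is compiled (Gotoh dynamic program) and is
validated in the test suite against a naive full-table reference on random
sequences.

Atom-pair tokens can be supplied precomputed (any tokenization works, the
pipeline only needs sets) or derived from SMILES via ChemmineR, the
standard R toolchain for atom-pair descriptors. A molecule with fewer than
two heavy atoms yields the empty set and flows through the empty-set
Tanimoto rule.

### Fusion

Similarity network fusion is the cross-diffusion recurrence: per view, a
full kernel \(P_v\) (half the probability mass on the diagonal, half spread
over the off-diagonal proportionally to similarity) and a sparse kernel
\(S_v\) (row-normalized restriction to the K nearest neighbors, self
excluded, ties broken by drug order), then
$$P_v \leftarrow S_v \,\bar P_{-v}\, S_v^{\top}$$
for T rounds, re-normalizing and re-symmetrizing after every round; the
fused network is the mean of the final kernels, symmetrized. The procedure
has no random element. Defaults are η = 0.5, K = 20, T = 20 — the
recommended operating point of the fusion literature; K is the only
parameter with real leverage (it sets the neighborhood scale of the
diffusion) and must be smaller than the number of drugs (degenerate n ≤ K
inputs are rejected rather than clamped). η only matters on the optional
path where raw feature distances are kernelized into affinities; the
primary path consumes the DSNs directly as affinities, since the similarity
module already produces calibrated unit-scale networks. Whether to
kernelize first was a genuinely open choice; affinity-direct was chosen
because it keeps the single-view and fused networks on comparable footing
and avoids a second bandwidth parameter.

Three linear integrators serve as baselines: elementwise maximum, weighted
average with a 0.1-step weight grid (66 weight vectors for three views),
and probability disjunction \(1-\prod_v(1-S_v)\), which requires unit-scale
inputs and dominates the maximum elementwise.

Fused networks are on an *affinity* scale (rows are kernel mass, not
bounded by 1). `unitRescale()` — division by the maximum off-diagonal
entry, diagonal pinned at 1 — is a monotone transform used whenever a fused
network must feed the distance-based validity indices.

### Clustering and model selection

Spectral clustering uses the symmetric-normalized affinity
\(D^{-1/2} W D^{-1/2}\): top-k eigenvectors, row-normalized, partitioned by
k-means. Three numerical choices make this deterministic and robust:

* k-means is seeded with a kmeans++-style initialization drawn only from
  *distinct* embedding rows, under a caller-supplied seed. On exactly
  block-structured matrices (the noiseless synthetic regime) embedding rows
  duplicate, and naive random center sampling would crash or produce empty
  clusters.
* Labels are relabeled to first-appearance order, so a fixed seed gives a
  bit-identical assignment.
* A graph with more connected components than k is rejected with advice to
  raise k, rather than silently producing an arbitrary split.

Distances for the validity indices are `d = 1 − s` on a unit-scale matrix;
the transform does not guarantee the triangle inequality, which none of the
indices used (Dunn, silhouette, connectivity) requires.

The cluster count is scanned over a range and selected by **maximum mean
silhouette, ties broken by larger Dunn index, then by smaller k**. The two
indices were stated as joint criteria without a combination rule in the
tradition this follows; silhouette is primary here because it is bounded,
averages over all samples (robust to one tight pair dominating, which Dunn
is not), and degrades smoothly. Singleton clusters contribute silhouette 0
(the standard convention), as do samples with \(a_i = b_i = 0\), which
arise when a cluster of identical points is split. Connectivity (L = 10
nearest neighbors by default, the conventional choice in the
validity-index literature) is reported for inspection but does not drive
selection. Values of k at which the spectral step cannot produce k
non-empty clusters — possible on noiseless block data, where the number of
distinct embedding rows bounds k — get NA entries and are excluded from
selection with a warning.

### Evaluation statistics

NMI is computed from the joint contingency table with base-2 logarithms and
the geometric-mean entropy normalization; when either labeling has zero
entropy the quotient is undefined and 0 is returned. When drugs carry
several ATC first-level codes and a single label vector is needed, the
first listed code is used (config-exposed; a seeded-random reduction is the
alternative). The ATC overlap rate (AOR) scores a pair 1 when the
first-level code sets intersect; the superclass overlap rate (SOR) requires
label equality. Pairs touching a drug without annotation are **excluded and
counted**, not scored 0 — scoring them as non-overlap would penalize
missing annotation rather than disagreement. The sliding-bin AOR curve
defaults to bins of 3000 pairs sliding by 100, the scale used on
database-sized networks; both are configurable so the curve is meaningful
on 120-drug synthetic universes (the tests use bins of 200 by 50).
Rogers–Tanimoto agreement is computed from the pair-counting contingency
identities rather than an O(n²) pair loop.

### Interpretation

Edge attribution reads "at least 10% higher" **relatively**
(\(S_i \ge 1.1\,S_j\)): the compared scores live on different natural
scales, so only a ratio is scale-free; an absolute-gap variant is
selectable. For three views this yields the seven contributor categories
(three single, three pairs, one all-three); the generalization to v views
walks the sorted scores and cuts at the first ratio gap reaching the
margin. Contribution summaries default to the **top 5% of fused edges** —
the same restriction the repositioning graph uses — because attribution is
a statement about edges that matter; `topFrac = 1` switches to all edges.
Which edge set underlies published pie-chart style summaries is generally
unstated; the default here is declared, not inferred.

Cluster enrichment is the hypergeometric upper tail with
ES = (k/n)/(m/N); every (cluster, term) test is BH-adjusted, and the
significance flag defaults to raw p < 0.05 (q is always reported, and the
flag can be switched to it). Multi-label drugs count once per distinct
term. Unexpected-drug flagging requires a cluster to have at least one
significant ATC term and flags members whose own codes miss the enriched
set; drugs with no ATC codes are not flagged, consistent with the
exclusion-not-penalty stance above. The property-deviation statistic is
D = (C − A)/A with a Welch t-test (the variant was unspecified in the
tradition; unequal variances are the safe default), returning NA rather
than failing on degenerate constant inputs.

## The synthetic-data generator

`simulateUniverse()` plants a ground-truth partition into every data type:

* per-cluster side-effect and atom-pair **signatures** (disjoint token
  blocks), each drug keeping a signature token with probability
  1 − dropout and adding a fixed number of background noise tokens;
* per-cluster **anchor proteins** (random 120-mers over the 20-letter
  alphabet), each drug carrying a point-mutated copy, so normalized SW is
  high within clusters and near background between;
* a dominant **ATC first-level code per cluster**, flipped to a random
  other letter with the label-noise rate — flipped drugs are the ground
  truth for unexpected-drug recovery — plus a cluster superclass label;
* per-view **informativeness**: clusters a view is declared uninformative
  about draw their features from the global background, so that view
  cannot separate them.

`complementaryBenchmark()` fixes the configuration used throughout the
tests: 120 drugs, 6 clusters, side effects separating clusters 1–3, atom
pairs 3–5, targets 5, 6 and 1, with dropout 0.25, 12 noise tokens and
mutation rate 0.08. These rates were chosen once as a moderate-noise
operating point — strong enough that no single view recovers the partition,
weak enough that the planted structure is recoverable at all — and the
problem size keeps a full multi-method comparison over 20 seeds within a
few minutes on one CPU.

What the generator does **not** emulate: the heavy-tailed degree and
annotation distributions of real drug databases, correlated noise across
views (a real drug's missing annotation is missing everywhere), multi-code
ATC profiles, shared targets between drugs, or realistic chemistry (tokens
are abstract, not derived from structures). Passing tests therefore
demonstrate that the machinery is correct and that fusion exploits
complementary signal under controlled conditions — not that any particular
database-scale result will reproduce.

Two experimental design choices worth stating: the fusion-recovery
comparison clusters every method's network at the *planted* k (the
comparison is about fusion quality, not model selection, which is assessed
separately), and unexpected-drug recovery uses the *planted* assignment
(the quantity under test is the enrichment/flagging logic; cluster recovery
is already measured elsewhere).

## Numerical conventions

* Matrices are validated symmetric within 1e-9, then symmetrized exactly as
  (M + Mᵀ)/2; on-disk matrices carry 12 significant digits and round-trip
  to that precision.
* Unit-scale invariants (entries in [0, 1], unit diagonal) are enforced by
  class validity on every constructed network.
* Nearest-neighbor ties (fusion kernel, connectivity) break by drug order —
  stable and seed-independent.
* All randomness flows through caller-supplied seeds; library code saves
  and restores the caller's RNG state.

## Limitations

Target similarity is O(n² · L²) in sequence length and drug count — fine
for hundreds of drugs with cached self-scores, but thousands of drugs with
many targets each would need a parallel or banded alignment backend.
Spectral clustering holds a dense n × n eigenproblem. The enrichment engine
tests terms independently and inherits the usual caveats of marginal
hypergeometric tests on overlapping vocabularies. And the pipeline ingests
pre-extracted TSV/FASTA — parsing native DrugBank/SIDER/PubChem dumps is
deliberately out of scope.
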