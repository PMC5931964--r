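---
title: "Methods: anatomical network analysis of limb musculoskeletal systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomical network analysis of limb musculoskeletal systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatnet)
```

## The model

Anatomical network analysis treats a body part as a simple undirected
graph.  Nodes are discrete anatomical units of three classes — bones,
cartilages, muscles — and a link records a physical contact between two
units: an articulation between skeletal elements, the attachment of a
muscle onto a bone, or blending (fibrous fusion) between two muscles.
Contacts are coded 0/1 in a labelled square adjacency matrix; the model
deliberately ignores contact geometry, strength and innervation.  Two
assumptions follow. First, the relation is symmetric and irreflexive, so
an asymmetric matrix or a non-zero diagonal is treated as a coding error,
never repaired silently (an explicit `symmetrize` option exists for data
known to be half-coded).  Second, units are identified by opaque labels:
homology decisions and nomenclature normalisation belong upstream of this
package.

When several specimens per species are coded, a structure is taken as
present when it occurs in **strictly more than half** of the specimens
(`consensusPresence()`); an even split codes as absent.  This strict
reading matters for even sample sizes and is applied uniformly to muscles
and to attachments.

Skeletal and muscular organisation can be analysed separately via induced
subgraphs (`subNetwork()`): the skeletal level keeps bones and
cartilages, the muscular level keeps muscles only.  Note that the
muscular subgraph of a real limb is usually disconnected (muscles mostly
touch bones, not each other), so path-length statistics there require the
explicit largest-component escape hatch described below.

## The six parameters

For a connected network with `N` nodes and `K` links the package computes
density `D`, mean local clustering `C`, characteristic path length `L`
and degree heterogeneity `H`.  These are standard graph descriptors; the
anatomical reading is: `D`, `C`, `L` together measure complexity and
integration (more contacts, more triangles, shorter effective distances),
while `H` measures anisomerism — how unevenly connectivity is spread over
serially similar parts.

Numerical conventions, each of which is a genuine choice the verbal
definitions leave open:

* **Low-degree nodes in `C`.**  A node of degree < 2 has no defined local
  clustering.  The default (`lowDegreeMode = "exclude"`) omits such nodes
  from the average, matching the average-local-transitivity convention of
  the common network toolkits; `"zero"` counts them as 0, which penalises
  pendant-rich networks.  Both modes are exposed and recorded in the run
  log, and the test suite pins both against a brute-force neighbour-pair
  oracle.  With no qualifying node at all, `C` is reported as 0.
* **Standard deviation in `H`.**  The sample (n−1) convention is the
  default, matching the default of the statistical environments these
  analyses are usually run in; `"population"` (n) is available.  `H = 0`
  exactly when the graph is regular.
* **`L` requires connectivity.**  Disconnected input raises an error
  naming the component sizes — silent infinite or dropped distances would
  corrupt comparisons.  `largestComponent = TRUE` computes `L` on the
  largest component and warns; the six study-scale limb networks are
  connected, so the hatch exists for subnetwork levels and exploratory
  data.
* **Rounding.**  Full precision is kept internally everywhere; report
  files round `D`, `C`, `L`, `H` to 3 decimals and percentages to 1
  decimal, using half-away-from-zero (`reportRound()`), the convention of
  the published tables these reports mirror.

## Module detection

Connectivity modules are found with a short-random-walk agglomerative
algorithm, implemented from the published method rather than delegated,
because the algorithm itself is part of what this package documents and
tests.  With `A` the adjacency matrix and `d` the degree vector, the walk
matrix is `P = D^{-1} A` and every node gets the profile `P^t[i, ]` of
its `t`-step transition probabilities (default `t = 3`: long enough to
feel module structure at the ~100-node scale of limb networks, short
enough not to mix modules).  The distance between nodes (and communities)
is the degree-weighted Euclidean distance between profiles; a community's
profile is the mean of its members' node profiles.  Starting from
singletons, only communities sharing at least one link may merge, and
each step merges the adjacent pair minimising the Ward-style cost
`|C1||C2|/(|C1|+|C2|)/N * r²` — the increase in mean squared
node-to-community distance.

Determinism is engineered, not assumed: node labels are sorted into
C-locale order before agglomeration, and exact cost ties are broken
toward the lexicographically smallest (min-label, max-label) community
pair, so the merge sequence is identical across runs and across input
node orderings.

The partition reported (`bestPartition()`) is the merge-tree level
maximising Newman–Girvan `Q = sum_s(e_ss − a_s²)`; exact `Q` ties (within
1e-12) resolve toward fewer modules.  `Q` lives in [−0.5, 1], is 0 for
the one-module partition, and falls in roughly 0.3–0.7 for strongly
modular networks.  The test suite checks the detected `Q` against an
exhaustive maximum over *all* set partitions for graphs of up to 10
nodes, and against the known planted structure of bridged cliques and
synthetic limbs.

**Jackknife error of Q.**  Every link is treated as an independent
observation: link `i` is removed, `Q` is recomputed **with the partition
held fixed**, and the usual jackknife formula aggregates the leave-one-out
values.  Holding the partition fixed is a deliberate reading: re-running
detection per deletion would conflate detection variance with score
variance, which is not what an observation-wise jackknife of a statistic
measures.  On link-transitive configurations (a cycle under the
one-module partition, the alternating bipartition of a 4-cycle) all
leave-one-out values coincide and the error is exactly 0 — a useful
sanity case because any implementation asymmetry would break it.

**Per-module significance.**  For each module, every member node
contributes its count of internal links (to the same module) and external
links (to the rest); the one-sided two-sample Wilcoxon rank-sum test asks
whether internal systematically exceeds external.  Member nodes are the
observations — this is the reading under which "the internal vs external
connections of every module" yields two equal-length samples.  The
p-value is exact — a full enumeration of the `choose(n+m, n)` rank
assignments — whenever both samples have at most 10 values and no value
occurs in both samples (within-sample ties are fine: midranks make the
enumeration exact, which matters because complete separation with tied
internal counts is the *typical* strong-module outcome).  Otherwise the
tie- and continuity-corrected normal approximation of `stats::wilcox.test`
is used.  Modules with fewer than 4 nodes are flagged unreliable: with
n = m < 4 the one-sided exact p cannot reach 0.05.  Raw p-values are
reported; the analyses this package replays apply no multiple-testing
correction, so none is applied by default (a Holm option exists).

## Comparing networks: ARD

The Average Relative Difference between two networks is the mean over
{N, K, D, C, L, H} of `|a − b| / ((a + b)/2)`, times 100.  The pair-mean
normalisation makes each term symmetric, scale-free and bounded by 2;
ARD = 0 iff all six parameters agree, and parameters equal in both
networks (including jointly zero `H` on regular graphs) contribute 0.
This reconstruction is the module's defining decision: validated by
replaying four independently published percentages (5.3, 1.3, 5.3, 8.1)
exactly at 1-decimal rounding from the shipped rounded parameter table.
Comparisons involving the *Homo sapiens* forelimb row do **not** replay
exactly from rounded inputs (recomputation gives 12.1/8.2/5.1 vs the
published 11.3/7.5/5.2): its `L` is printed at lower precision than the
other rows, so the published values evidently used unrounded parameters.
Those pairs are documented here rather than asserted.

## The synthetic generator

`generateLimbNetwork()` emulates the connectivity grammar of a tetrapod
limb: a serial chain of long bones; a mesopodial block wired as a serial
backbone plus deterministic extra articulations up to a target density;
digit rays (optional metapodial plus a phalanx chain) anchored round-robin
on the mesopod; and three muscle kinds — *intrinsic serial* muscles
confined to one ray (origin on the ray's proximal bone, insertions
fanning distally; contrahentes-like), *shared* muscles attaching to one
randomly chosen bone of each ray in a digit group, and *extrinsic*
muscles from a chain bone to two consecutive ray bones (long
flexor/extensor-like; most of their contacts lie inside the ray they
serve).  Blending links are drawn only between muscles that already share
an attachment bone — anatomically, blending occurs between muscles with
adjacent attachments — with probability 0.1 per candidate pair.
Randomness is confined to shared-muscle insertions and blending; one
integer seed governs all draws, so a spec is a complete, reproducible
description.

The four presets encode the qualitative hominid patterns: pan-like limbs
carry serial intrinsic muscles on every digit (planting one module per
ray); the homo-like forelimb replaces them with muscle groups shared
across digits 1–3 (18 muscles) and 4–5 (12), merging those rays into two
modules; the homo-like hindlimb keeps serial muscles on digits 1, 3, 4, 5
so the hallux ray forms its own module.  Preset sizes (90–95 nodes) are
within 15% of the corresponding published node counts, and the bone-only
subnetwork is identical between the pan-like and homo-like presets of a
limb, mirroring the finding that the skeletal topology is shared across
the three species.

What the generator does **not** emulate: real muscle nomenclature and
per-muscle anatomy, cartilages, sesamoids, biomechanics, and the precise
published matrices (which are not bundled).  Passing the planted-recovery
tests therefore shows the pipeline recovers known modular structure of
realistic size and wiring style — not that it reproduces any species'
actual module composition.

## Problem sizes and runtime choices

The validation suite runs at desk scale by design: exhaustive-maximum-`Q`
oracles on 100 random connected graphs of 4–10 nodes (all set partitions,
up to Bell(10) = 115{,}975 per graph), brute-force clustering/path-length
oracles on 200 random graphs of up to 12 nodes, exact rank-sum
enumeration up to `choose(20, 10)` assignments, and full pipeline runs on
the ~90-node presets.  These sizes keep the whole suite under a minute
while covering every code path at the scale the method is used at.

## Known limitations

* Unweighted, undirected networks only; no contact strength or geometry.
* One community algorithm (the random-walk agglomeration); no Louvain,
  Infomap or consensus clustering, and no overlapping modules.
* `L` (hence the full parameter bundle) is undefined on disconnected
  networks without the largest-component escape hatch; muscular-level
  subnetworks typically need it.
* ARD compares parameter vectors, not topology: two different graphs with
  equal parameters score 0.  It is a similarity of organisation
  statistics, not a graph isomorphism measure.
* The jackknife error model treats links as independent observations,
  which understates uncertainty if coding errors are correlated (e.g. a
  whole muscle miscoded).
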