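---
title: "Methods: entity-centric exploration of medical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entity-centric exploration of medical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medstars)
```

## The data model

medstars works on a two-level hierarchy. A *medical document* (MD) is one
clinical text unit — a record, note or instruction. Each document is split
into *medical paragraphs* (MPs), and the paragraph is the unit of entity
extraction: full-document embeddings let long sections (a detailed history)
drown out short but critical ones (a one-line diagnosis), so similarity is
computed where the content lives. From each paragraph we extract *medical
entities* (MEs), typed spans over nine classes — disease (`dis`), clinical
symptom (`sym`), drug (`dru`), medical equipment (`equ`), medical procedure
(`pro`), body (`bod`), examination item (`ite`), microorganism (`mic`) and
department (`dep`) — and collect the *distinct* entities of one paragraph
into its *medical entity set* (MES), with per-class counts `num_ij` and
total `num_i`.

Counting distinct keys rather than raw mentions is a deliberate choice: an
entity *set* implies deduplication, and the pole-spring weights below
should reflect a paragraph's composition, not how often one term is
repeated. Raw mentions are kept alongside for highlighting and provenance,
so nothing is lost.

Offsets are 0-based, half-open, in Unicode code points throughout; a
paragraph's text always equals the parent document slice. Paragraph
segmentation splits on runs of one or more blank lines (with a
line-per-paragraph fallback); pre-split paragraphs in the input are always
honored verbatim. Fragments whose stripped length is under `min_len`
(default 2 code points) merge into the previous segment so one-character
"paragraphs" cannot arise. Blank-line splitting is a convention of this
package — it is the least surprising rule for sectioned clinical notes —
and any corpus with authoritative paragraph boundaries should ship them
pre-split.

## Extraction and embedding are contracts, not models

Neural extractors and sentence encoders are deliberately out of scope; both
stages are pluggable interfaces with deterministic defaults so the full
pipeline runs and tests anywhere, without downloads.

The default extractor is a gazetteer matcher: case-insensitive,
whitespace-normalized, character-based (no tokenization, so Chinese and
English behave identically), leftmost-first then longest-match,
non-overlapping. Any function mapping paragraph text to valid,
non-overlapping mention spans can replace it.

The default embedder hashes tokens (letter runs; single CJK characters)
into `dim` buckets with a fixed seedless djb2 hash and L2-normalizes the
counts. It is not a semantic model — two synonyms share no buckets — but it
is deterministic, order-invariant, and exact on the synthetic corpora the
package tests itself with, where vocabulary overlap *is* the semantic
signal. Any encoder producing unit vectors (zero for empty text) can be
plugged in for real corpora.

## Topics

Documents are clustered with spherical k-means on their unit embedding
vectors: cosine assignment, mean-then-renormalize centroids, k-means++-
style seeded initialization, 50 restarts of at most 300 iterations, empty
clusters reseeded with the worst-served point. Rows are processed in
sorted-id order and labels canonicalized by first occurrence, so results
are reproducible and independent of input order. This replaces a heavier
UMAP + density-clustering stack with the same contract: every document gets
exactly one topic. `n_topics` is a configuration knob (default
`max(1, min(8, round(sqrt(n_docs))))` — a small, conventional default,
not an optimum).

Topic keywords use class-based TF-IDF: all tokens of a topic's documents
are pooled, and term t in topic c scores `tf(t, c) * log(1 + A / f(t))`
with `A` the mean token count per topic and `f(t)` the term's corpus-wide
count; ties break lexicographically. *Topic diversity* is the fraction of
unique terms among all topics' top-k lists — 1 exactly when the lists are
pairwise disjoint. Diversity on a hashed-TF embedding of synthetic notes
says nothing about diversity on a real corpus with a real encoder; the
package therefore asserts only the metric's arithmetic and its behavior
under controlled vocabulary overlap.

## Graphs, constellations and the star map

The *document graph* links every document pair whose cosine similarity
strictly exceeds `theta_doc` (default 0.5); connected components under the
threshold are the document clusters, labeled by modal topic, and node size
encodes character length.

The *paragraph graph* has two edge sets. Intra-document edges `E_d` chain
order-adjacent paragraphs of one document — a chain, not a clique, because
constellation lines imply a traversal and cliques would add quadratically
many edges with no visual counterpart. Similarity edges `E_s` connect
paragraphs of *different* documents with similarity strictly above `theta`
(default 0.5). Candidate pairs are restricted to document pairs linked in
the document graph; if the user's selection has no document edges at all,
every cross-document pair is a candidate so the view still functions.
Thresholding is strict everywhere: an edge at exactly `theta` does not
exist and exerts no force.

Constellations are blocks of a size-capped partition (default `max_size`
10) minimizing the total weight of cut edges, with `E_d` edges weighing 1
and `E_s` edges their similarity. Connected components come first; a
component over the cap is split exactly — by pruned enumeration over
capped set partitions — when it has at most `exact_threshold` (default 9)
vertices, and otherwise by recursive balanced bisection with
Kernighan–Lin refinement from seeded restarts. The exact branch exists
because components of desk scale are cheap to solve optimally and it makes
the partitioner's contract testable against brute force; the KL branch is
the standard heuristic beyond that. Ties resolve toward the smallest node
id so partitions are deterministic.

### The force model

Nine *poles*, one per entity class, sit uniformly on the boundary circle of
radius `R`, pole j at angle `2*pi*j/9` (so `dis` anchors at `(R, 0)`). Each
star (paragraph) feels:

* **Gravity** — a constant-magnitude attraction `||F||` along each `E_d`
  edge, plus `||F|| * sim_ij` along each `E_s` edge above the strict
  threshold. The similarity term's form carries no distance factor, which
  motivated making both gravity terms constant-magnitude rather than
  Hookean; there is no rest length.
* **Pole springs** — `sum_j (num_ij / num_i) * ||F||` toward pole j. The
  weights sum to one, so by the triangle inequality the spring force never
  exceeds `||F||`; a star with no entities (`num_i = 0`) feels no spring
  force at all, and a star with equal counts in all nine classes at the
  center feels exactly zero by symmetry.
* **Collision** — for any pair closer than the sum of their radii
  (uniform `r_star = R/50`), a linear-in-overlap repulsion with stiffness
  `k_c = ||F||`, equal and opposite for the two stars; coincident centers
  get a seed-deterministic direction so the simulation never stalls or
  randomizes.

The integrator is damped explicit stepping with geometric cooling:
positions start uniform in the disc of radius `R/2` (seeded), then
`position <- clamp_to_disc(position + alpha_t * F)` with
`alpha_t = max(alpha0 * rho^t, alpha_min)`, defaults `alpha0 = 0.1 R`,
`rho = 0.99`, `alpha_min = 1e-4 R`, `tol = 1e-3 R`, `max_iter = 1000`. It
stops when the largest per-star displacement falls below `tol`. Clamping
keeps every star inside the closed disc, so boundary poles remain reachable
but never exceedable. This schedule mimics conventional force-simulation
cooling; it is a design choice of this package, as is the initial
placement. With cooling floored at `alpha_min`, a lone single-class star
ends within about one step of its pole — tests allow `0.01 R`.

## The association tree

The radial dendrogram groups entity sets that share entities. The tree has
fixed depth — root, branches, MES nodes, ME leaves — and one insertion rule:
a new set is matched against every existing member; all branches and
root-level sets containing an intersecting member merge with it into a
single branch (their common ancestor), or the new set attaches to the root
if nothing intersects. Under this rule two sets share a root-level branch
exactly when they are connected through shared keys, transitively — the
branch partition equals the connected components of the bipartite MES–key
graph, which makes the outcome order-invariant and testable against an
independent union-find oracle. Unbounded nesting was rejected because the
rendered dendrogram has this depth and deeper structure would be
unobservable.

Within a branch, keys held by at least two members are promoted to shared
ME nodes (lexicographic order, before the member sets in id order). Every
MES node carries its constituent MEs as `collapsed` leaf children, so
renderers can disclose them progressively; MES node colors are the
class-palette mixture weighted by `num_ij / num_i`.

## Focused sectional profiles

A focus is a single entity key or a whole entity set. Co-occurrence is set
membership: for an entity, every MES containing the key; for an MES, the
focal set first and then every set sharing at least one key. Each
co-occurring set becomes a radial axis with per-class heights
`N_ik * h_t` (`h_t` default 1 — pure counts; renderers rescale). The donut
aggregates class counts over *all* axes, normalized to sum to one: the
aggregate reading summarizes the focus's context rather than repeating the
focal set's own composition, and for an entity focus the `focal_class`
field separately identifies the focus's own class. Whether the focal MES
should itself appear as an axis was open; it is included, first, so the
context is never shown without its anchor.

Axis order is greedy nearest-neighbor seriation on cosine similarity of the
class-count profiles, starting from the largest axis, ties by id — a
deterministic, seedless order chosen so areas of the same class tend to be
contiguous across adjacent axes. Provenance cards return the full parent
document with the set's mentions mapped to document coordinates; a class
filter keeps only that class's spans (always a subset) and reports the
earliest as the scroll anchor.

## The synthetic corpus generator

The generator defines the conditions under which the package validates
itself. Each disease gets per-class pools of fixed-length (8-letter)
pseudo-word surfaces — equal length means no surface can contain another,
so leftmost-longest matching is exact and extractor recall/precision on
planted mentions is a meaningful 0-or-1 property. A configurable
`overlap_fraction` of each pool is drawn from a common pool shared by all
diseases: at 0 the vocabularies are disjoint (so document clustering must
recover the disease labels exactly and co-occurrence components never span
diseases), at 1 they coincide (recovery degrades, by design). Documents
cycle five sections — chief complaint, medical history, examination,
diagnosis, treatment — whose sentence patterns carry the planted mentions
in natural positions, joined by commas, so segmentation, extraction and
embedding all operate on plausible text. Entity-pool roles
(enabling condition / fault / consequence) are recorded in the ground truth
for future illness-script-style evaluations; no module consumes them yet.

What the generator does *not* emulate: the statistical texture of clinical
language (abbreviations, negation, misspellings), genuinely ambiguous
surfaces, class imbalance, or any particular natural language. Passing
tests on synthetic corpora demonstrate the pipeline's arithmetic,
determinism and recovery behavior under controlled conditions — not
extraction or clustering quality on real notes, which depend entirely on
the plugged-in extractor and encoder.

Default study conditions used by the test suite and the acceptance script:
4 diseases x 5 documents, 5 sections per document, a mean of 4 planted
mentions per paragraph, overlap 0, embedding dimension 256. The heavier
oracle checks run at the scale the contracts state: exhaustive partitioner
optimality on 100 random connected graphs of up to 8 nodes, size-cap
compliance on hundreds of larger graphs, tree/bipartite equivalence
exhaustively for all 1,940 collections of up to 4 distinct non-empty
subsets of a 4-key universe plus 1,000 random 5-key collections with 20
insertion orders each, and pole affinity over all 9 classes x 20 seeds.

## Numerical and degenerate-input choices

* Zero vectors (empty text) have cosine similarity 0 to everything by
  convention; similarities are clamped to `[-1, 1]` against rounding.
* Donut fractions are exact rationals of integer counts; the sum-to-one
  invariant is asserted at `1e-12`.
* JSON serialization is canonical — documents sorted by id, fixed key
  order, no rounding — so identical inputs yield byte-identical exports.
* Luminance encodings (constellation fill by star count, star border by
  entity total) are min–max scaled to `[0.35, 0.9]`; a singleton range
  renders mid-scale (0.625). Monotonicity, the only stated requirement, is
  preserved.
* Export validation is performed by in-package structural validators
  covering required fields, types, cross-reference resolution and the
  arithmetic invariants above.

## Known limitations

* The default embedder is lexical; real deployments should plug in a
  sentence encoder honoring the unit-norm contract.
* The gazetteer extractor finds only what it is given — no nested or
  discontinuous entities, no linking to ontologies.
* The KL branch of the partitioner is a heuristic; optimality is guaranteed
  (and tested) only for components within the exact-search threshold.
* Collision handling prevents overlap pairwise per step; extremely dense
  maps can still end with small residual overlaps when the cap on step
  size binds before separation completes.
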