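---
title: "Cavity embeddings: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavity embeddings: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what is modelled,
which knobs matter, what the synthetic generator does and does not emulate,
and where the design was genuinely open. The companion test suite and
`scripts/acceptance.R` compute every empirical claim made here.

## 1. From cavity geometry to sentences

The package consumes cavities that an upstream extraction tool (a
Voronoi-based tunnel finder) has already reduced to an ordered list of
spheres along the pathway centreline, together with the surrounding atom
set. It does not construct Voronoi diagrams or search pathways itself.

Each pathway point is identified by its **four nearest lining atoms**. Two
distance readings are offered, because extraction tools differ:

* `mode = "center"` (default): plain Euclidean distance from the sphere
  centre to the atom centre. This matches a data model in which exactly four
  atoms determine a centreline vertex.
* `mode = "surface"`: centre distance minus the atom's van der Waals
  radius, so a large atom whose surface reaches closer can outrank a
  nearer-centred small one.

Ties at equal distance are broken by the lower atom serial — an arbitrary
but deterministic rule; without it, encoding would depend on sort order.
The four serials are sorted ascending and dot-joined into a canonical node
ID (`"2.3.1.4"` → `"1.2.3.4"`), making the ID invariant under the 24
orderings in which a tool might report the atoms. Degenerate quadruples
(duplicated serials) are rejected rather than repaired: a centreline vertex
needs four distinct atoms, and a duplicate signals a broken upstream file.

Consecutive duplicate node IDs are **kept**, not collapsed. Two adjacent
spheres nearest to the same four atoms yield two identical tokens; their
frequency is information the embedding model can use, and collapsing runs
would silently reweight the corpus.

Node IDs are built from atom serials, not residue numbers. Serials are the
finest stable key an extraction tool exports; residue-level IDs would merge
genuinely different nodes within large residues.

## 2. The embedding model

Node vectors are learned with a skip-gram objective: maximise the average
log probability of context tokens within a window `c` around each token,
where the conditional probability is a softmax over the vocabulary using
separate input (`v`) and output (`u`) vector tables. Cavity vectors are the
**unweighted mean of the input vectors** of the cavity's tokens — input
vectors because they are the learned word-representation table in the
word2vec convention; the mean is plain, with no radius or length weighting,
because the cavity representation is defined as an average of node
embeddings and any reweighting would be a different (untested) model.

Two training regimes share initialisation and vocabulary handling:

* **Exact softmax** (`negative = 0`): full-batch gradient ascent on the
  exact objective. Cost O(W²) per iteration, so it is the reference
  implementation — its gradients are verified against central differences
  and its iterates must never decrease the objective. It is what the
  package means by "the objective"; the test suite holds the practical
  regime accountable to it.
* **Negative sampling** (`negative = k > 0`, default 5): per-pair SGD with
  k noise tokens drawn from the unigram distribution raised to 3/4. This is
  the standard remedy for the softmax's O(W) gradient cost. The inner loop
  is compiled (C++) with a private xorshift RNG seeded from the
  configuration, so training is bit-reproducible and independent of R's
  RNG state; training is single-threaded for the same reason.

Numerical choices: softmax probabilities are computed with max-subtraction
(no overflow for large dot products); input vectors initialise uniformly in
[−0.5/d, 0.5/d] and output vectors at zero (the word2vec convention — a
zero output table makes the first updates purely data-driven); the learning
rate decays linearly from `lr = 0.025` to `lr_min = 1e-4`; sigmoid inputs
are clamped at ±30 in the compiled path. A non-finite vector after an
update aborts with the iteration reported rather than propagating NaNs.

Hyperparameter defaults and why:

| parameter | default | rationale |
|---|---|---|
| `dim` | 128 | cavity representations beyond 100 dimensions; tests use 8–32 where geometry, not capacity, is under test |
| `window` | 5 | word2vec convention; cavity sentences are short, so tests use 2 |
| `negative` | 5 | standard k for small corpora; 0 switches to the exact regime |
| `epochs` | 15 | small vocabularies converge quickly; recovery experiments use 50 |
| `min_count` | 1 | cavity vocabularies are small; discarding singletons would delete real nodes |
| subsampling of frequent tokens | off | frequent nodes are structurally meaningful here, unlike stop words |

Tokens dropped by `min_count` are removed from sentences with no
placeholder, and cavity averaging skips them under the default
`oov = "skip"` policy (counting how many tokens were used); `oov =
"strict"` raises instead. A cavity with zero in-vocabulary tokens has no
defined vector and errors with its ID.

## 3. Similarity, clustering and profiles

Cavity similarity is cosine similarity, clamped to [−1, 1] against
rounding; a zero-norm vector raises rather than returning 0, since a
direction-free vector has no meaningful similarity. Threshold queries use
the interval convention **open below, closed above**: "larger than 0.9" is
(0.9, 1] and "between 0 and 0.1" is (0, 0.1]. Both bounds are explicit
arguments, so the alternative closed-below reading is expressible.

Hierarchical clustering is average-link agglomeration on 1 − cosine
(`stats::hclust`), with both cut criteria exposed (`n_clusters` or height
`h`), and the dendrogram attached to the result. K-means runs Lloyd's
algorithm (`stats::kmeans`) on L2-normalised vectors so Euclidean geometry
matches cosine geometry, with hand-seeded k-means++ centres and the best of
`n_init` restarts by inertia. Cluster labels are dense integers starting at
1 (the R indexing convention), relabelled by first appearance so the
contract does not depend on `cutree`'s internal numbering.

t-SNE (via Rtsne, exact gradient for these problem sizes) is provided for
**visual inspection of the number of patterns only**. Cluster assignments
are always computed on the full-dimensional vectors: a 2-D t-SNE layout
distorts densities and distances, and clustering in projection space would
inherit those artifacts, so the package deliberately does not support it.

Length–width profiles accumulate arc length along sphere centres (starting
at 0 at the active-site end) against sphere radius; the bottleneck is the
radius minimum, first index on ties. Amino-acid profiles count **distinct
residues** (chain + residue number) among a cavity's lining atoms, tallied
by 3-letter code with HID kept distinct from HIS (protonation states are
real distinctions in simulation topologies); atom-level counting is
available behind `level = "atom"`. Cluster profiles are arithmetic means of
member-cavity counts, zero-filled so a residue type absent from a member
counts as 0 in the mean.

## 4. The synthetic generator

No public per-snapshot cavity corpus with ground-truth pattern labels
exists at package scale, so the generator emulates the *statistical shape*
of such data: a fixed atom set, a few recurring channels, and per-snapshot
variation.

* **Molecule**: `n_atoms` (default 300) hard spheres uniform in a 40 Å box,
  grouped into 8-atom residues named from the 20 standard amino acids plus
  HID; van der Waals radii from the Bondi table (H 1.20, C 1.70, N 1.55,
  O 1.52, S 1.80 Å; unknown elements default to 1.70 Å).
* **Channels**: smooth random walks from near the box centre (the "active
  site"), step 1.2 Å, 10–40 waypoints (sequence lengths are a free choice,
  exposed as `n_waypoints`), radii 0.9–2.5 Å lightly smoothed. Walks
  reflect off the box walls at an 8 Å margin so every waypoint keeps a full
  shell of candidate lining atoms; a waypoint with fewer than four atoms
  within `search_radius` (12 Å) aborts naming the template.
* **Noise**: per-node dropout and swap-with-a-random-pooled-node, both
  token-level, because the similarity notion being modelled is contextual —
  similar cavities share lining atoms. Sphere geometry stays attached to
  the original waypoint on a swap, emulating extraction jitter. If dropout
  removes every node, one random node is kept (a cavity must have ≥ 1
  node). Acceptance conditions fix dropout at 0.10 and swap at 0.05.

What the generator does **not** emulate: real protein packing (atoms are
uniform, residues are not spatially coherent), solvent, conformational
drift between snapshots (noise is i.i.d. per snapshot rather than
autocorrelated), branched channels, and channel birth/death over a
trajectory. Passing the recovery tests therefore shows that the
representation separates recurring token patterns under token noise — not
that it handles every artifact of real MD cavity extraction.

## 5. Reproducibility and problem sizes

Everything is seeded: dataset generation, training initialisation, the
compiled SGD stream, k-means restarts and t-SNE all derive from explicit
integer seeds, and `run_pipeline()` derives per-stage seeds from one global
seed, writing an artifact manifest with MD5 hashes so a re-run can be
checked for bit-identity. The recovery experiments in the test suite and
acceptance script use 3 templates × 50 trajectories (150 cavities, d = 16,
window 2, 5 negatives, 50 epochs, 10 seeds) — sizes at which the exact and
sampled regimes are cheap to cross-check while leaving the clustering
problem non-trivial; the generator and trainer scale to much larger corpora
linearly in total tokens.

## 6. Known limitations

* Spatial position is deliberately ignored: two cavities with the same
  lining-atom topology in different parts of the structure embed close
  together. This is a property of the representation, not a bug; position-
  aware analysis needs the geometric artifacts (profiles, PDB coordinates)
  this package also emits.
* The exact-softmax regime is O(W²) per iteration and is not intended for
  vocabularies beyond a few thousand nodes.
* Average-link merge heights are only verified against the brute-force
  oracle up to n = 12; beyond that, correctness rests on `stats::hclust`.
* PDB support is the fixed-column v3.3 coordinate subset (ATOM/HETATM); no
  mmCIF, no trajectory formats, no compressed files.
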