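---
title: "Methods: annotation transfer, consensus tracks and compaction labels for IDRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation transfer, consensus tracks and compaction labels for IDRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idranno)
```

# The problem

Intrinsically disordered regions (IDRs) lack a stable fold but carry
functions of their own — entropic chains, flexible linkers, display sites,
binding segments — that whole-protein annotation practice largely misses.
Curated resources annotate only a small set of regions with GO Molecular
Function (MF) and IDPO Disorder Function (DF) terms; the vast majority of
predicted IDRs have no functional label. `idranno` implements the transfer
of those curated region annotations to unannotated IDRs through protein
language-model embeddings, together with the two bookkeeping procedures any
disorder resource needs: per-residue consensus over heterogeneous annotation
sources, and ensemble-compaction labels from the apparent Flory scaling
exponent.

# Annotation transfer model

## Region representation

A region embedding is the arithmetic mean of the per-residue embedding
vectors inside the region (`pool_region()`). The package consumes L×D
matrices from files (TSV; D = 1024 for ProtT5-class models) and never runs
a language model itself — the embedder is a pluggable input, and a
deterministic `mock_embedder()` exists purely for tests. Coordinates are
1-based inclusive everywhere (UniProt convention); a region extending past
its matrix is a hard error rather than a silent truncation, because in
practice that signals a sequence-version mismatch.

## Weighted-KNN vote

Given a query embedding and a reference index of annotated regions, the
transfer (`transfer()`) proceeds in fixed order:

1. cosine distance from the query to every reference entry;
2. entries with d > 0.8 (the `distance_cutoff`) are discarded — comparisons
   beyond that distance carry no usable signal;
3. the k nearest survivors are kept, ties at the k-th distance broken by the
   index's stable (accession, start, end) ordering so results are
   reproducible;
4. raw weights w_i = 1 − d_i / cutoff map distances into [0, 1);
5. weights are normalised to sum to 1;
6. each term's score is the weighted fraction of neighbours annotated with
   it — a convex combination, so scores always lie in [0, 1];
7. scores are made hierarchy-consistent (`enforce_hierarchy()`): every
   term's score is raised to the maximum over its scored descendants, so a
   parent is never scored below a child;
8. thresholds: terms below the namespace score threshold are dropped, and
   the generic binding terms (GO:0005488, GO:0005515 by default) must
   additionally reach a stricter 0.9 threshold.

The published tuning on a DisProt release split (reference 2023_12, test
2024_06) fixed K = 10, τ = 0.44 for MF and K = 5, τ = 0.59 for DF; these
are `transfer_config()`'s defaults. Two points in the procedure are design
choices of this package, because the functional form was not published:

* **Weight function.** "Weights from normalised distances with the cutoff
  applied before normalisation" is realised as the linear ramp
  w = 1 − d/cutoff followed by sum-normalisation. Any monotone-decreasing
  alternative would slot into the same step; the linear ramp is the
  simplest form consistent with the description and is kept behind a single
  function.
* **Order of the strict filter.** The stricter 0.9 binding filter is applied
  *after* hierarchy enforcement and only to the listed terms; descendants of
  binding keep the ordinary namespace threshold. This matches the filter's
  purpose — damping label imbalance from generic binding annotations without
  suppressing specific functions.

Two further conventions: fewer than k survivors simply all vote (no
padding), and if every survivor sits exactly at the cutoff all raw weights
are zero, in which case the result is empty with a warning rather than a
division by zero.

Biological Process and Cellular Component are refused by `transfer()` by
default: they describe whole-protein functions too abstract for
region-level transfer. An override (`allowed_namespaces`) exists for
experimentation.

## Ontology handling

`load_obo()` reads the minimal OBO subset the transfer needs ([Term]
stanzas, is_a, alt_id, is_obsolete, default-namespace). Only is_a edges are
used — the conventional choice for MF evaluation; part_of and other
relations are ignored. Obsolete terms are dropped with a warning: real-world
OBO dialects are messy and robustness beats strictness here. Reference term
sets are true-path propagated at index build (a flag, on by default):
CAFA-style evaluation assumes propagated gold sets, and propagating the
references makes neighbour votes hierarchy-complete. Namespace roots are
excluded from propagated sets — they carry no information — but note that
GO:0005488 "binding" is an ordinary term, not a root, and is retained and
scored.

## Evaluation

`fmax_evaluate()` is the CAFA protein-centric metric applied at the region
level: at each threshold t, precision averages |pred ∩ gold|/|pred| over
regions with at least one surviving prediction, recall averages
|pred ∩ gold|/|gold| over *all* gold regions (a region with no prediction
contributes zero recall), and f-max is the maximum harmonic mean over the
grid (0–1, step 0.01 by default). Precision over an empty prediction set is
defined as 0, and the optimal threshold reported is the smallest grid point
attaining the maximum. Namespaces are evaluated separately. Region matching
is by exact (accession, start, end) key; when predicted and curated regions
do not share coordinates, `map_regions()` offers an overlap mapping with an
explicit Jaccard threshold (default 0.5) — a toolkit convenience, not a
published rule.

`grid_search()` reproduces the tuning protocol: one transfer pass per K
with no score threshold, then τ swept by the evaluator; ties prefer smaller
K, then smaller τ (simpler models first). The strict binding filter is
disabled during the search — it is a post-hoc label-imbalance damper, not
part of the (K, τ) objective.

# Consensus tracks

Sources report per-residue ternary calls: annotated (1), not annotated (0),
no coverage (−). `consensus()` aggregates per residue: *merge* is the
union; *majority* and *strict* annotate when the fraction of agreeing votes
reaches 50 % and 90 % respectively. The vote denominator is, by default,
the number of sources **covering** the residue: predictors and PDB-derived
tracks have very different coverage, and counting absence as a negative
vote would conflate missingness with disagreement. This is a package
decision (the published description is silent) and is exposed as
`denominator = "covered" | "all"`. Residues covered by nothing stay
no-coverage in every mode, which gives the subset chain
strict ⊆ majority ⊆ merge residue-wise. `min_region_length` optionally
erases short annotated runs after thresholding; the default is 1 (no
erasure) — no morphological smoothing of the kind disorder predictors apply
internally is reproduced here.

Content statistics (`content_fraction()`) follow the convention of
reporting the annotated-residue fraction over annotated proteins only:
proteins without a single annotated residue for a feature are excluded from
that feature's denominator.

# Compaction labels

The apparent Flory scaling exponent ν relates intramolecular distances to
sequence separation in a disordered chain; low ν means a compact ensemble,
high ν an expanded, well-solvated one. ν values are *inputs* (TSV rows per
region) — the sequence-based predictor that produces them is a separate
published model and is not reimplemented. `label_region()` applies the
printed rule literally: regions of ≥ 30 residues with ν ≤ 0.475 are
*compact*, ν > 0.55 *expanded*, the band between is unlabeled, as are all
shorter regions (the length gate is measured on the input region as given).
Values outside (0, 1) are errors; outside [0.3, 0.8] they warn, since
realistic IDR ensembles do not reach them.

# Synthetic fixtures: what they emulate, and what they do not

`fixture_spec()` drives seeded generators for every input:

* `sim_ontology()` — a rooted per-namespace DAG (depth 3, branching 5 by
  default: 31 terms, 25 leaves) with optional cross-links toward shallower
  levels, which preserves acyclicity by construction.
* `sim_embeddings()` — each planted leaf term gets a cluster centre of norm
  `cluster_separation × noise_sd` in a uniformly random direction; region
  embeddings are the centre plus isotropic noise. In 16 dimensions random
  directions are nearly orthogonal, so at the default separation of 10
  within-cluster spreads the clusters are cleanly separable under cosine
  distance, and at separation 0 the terms are exchangeable. Defaults (20
  terms × 30 references, 200 queries, dim 16) give a transfer problem the
  package solves at f-max ≈ 1 and a degenerate control at f-max ≈ 0.25 —
  dim 16 keeps the suite fast, with a smoke path at 1024 available through
  the same spec.
* `sim_tracks()` — a hidden binary track per protein; each source copies a
  residue's hidden call with probability `agreement`, flips it otherwise,
  and covers it with probability `coverage`. Majority-vote accuracy against
  the hidden truth then has a closed binomial form the tests check.
* `sim_nu_table()` — ν from a three-component Gaussian mixture whose
  defaults sit on the compact side (2 %), inside the unlabeled band (53 %)
  and on the expanded side (45 %), echoing the reported proteome-scale
  fractions; region lengths straddle the 30-residue gate.

What passing on these fixtures shows: the algorithms implement their
definitions exactly (oracle equivalence), recover planted structure when it
exists, and degrade to baseline when it does not. What it does **not**
show: performance on real embeddings. Genuine language-model embedding
geometry is anisotropic, cluster overlap between related functions is
substantial, and curated term frequencies are heavily imbalanced — the
published f-max values (0.72 MF, 0.83 DF) live in that regime and depend on
specific database snapshots and a multi-gigabyte model, so they are not
reproducible at desk scale and are not asserted by any test here.

# Numerical and reproducibility choices

* Cosine distances in double precision; the cutoff comparison is an exact
  `<=` on the computed double, no epsilon.
* Computed distances are clamped to [0, 2] and vote scores to [0, 1] to
  absorb last-bit floating-point spill; the oracle tests agree to 1e-12.
* Zero-norm embeddings are hard errors (degenerate input), except inside
  the separation-0 generator where a zero draw is perturbed minimally.
* All generator randomness derives from one integer seed via fixed
  per-stage offsets; `run_pipeline()` writes TSVs with fixed 6-decimal
  formatting and LF endings and a manifest without timestamps, so a rerun
  from the same seed is bit-identical file-for-file.
* Test problem sizes (≤ 50 references, D ≤ 8 for oracle equivalence;
  exhaustive ternary columns for ≤ 4 tracks, which is exact because the
  consensus rule is per-residue; 200/1000-instance property sweeps) were
  chosen so the whole suite runs in well under a minute per file while
  still covering every code path.

# Known limitations

* Exact nearest-neighbour search only — reference sets of curated IDRs are
  thousands of entries, where brute force is faster than any index.
* No BLAST-based homology propagation (a separate method wrapping an
  external aligner) and no protein-level CAFA evaluation, S-min, or
  bootstrap intervals.
* The OBO reader covers the is_a fragment only; OWL, relationship types and
  cross-ontology links are out of scope.
* Whether curated reference annotations should be propagated before
  indexing is not settled by the published description; the package
  defaults to propagating (flag `propagate` on `knn_index()`).
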