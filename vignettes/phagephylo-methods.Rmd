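---
title: "Methods: whole-genome phage comparison, genome structure and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-genome phage comparison, genome structure and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagephylo)
```

`phagephylo` turns raw phage genome sequences, read-coverage profiles and
plate-assay titre series into comparative and descriptive statistics. This
vignette documents the methods behind each module and the simulators used to
validate them. Every stochastic function takes a `seed` argument and is fully
reproducible.

## 1. The alignment engine

All sequence comparison in the package rests on `local_hsps()`, a seeded
ungapped local aligner.

**Nucleotide mode.** Exact word matches of length 7 between query and subject
seed candidate diagonals. Each seed is extended in both directions without
gaps under a +1 match / −2 mismatch score, stopping when the running score
drops more than `xdrop` below the best score seen (X-drop termination). Both
strands of the subject are searched; overlapping extensions on a diagonal are
deduplicated to the highest-scoring segment pair (HSP).

**Translated mode.** Both sequences are translated in all six reading frames
and compared frame-against-frame. Seeds are exact 3-mer amino-acid word
matches; words containing a stop or ambiguity code never seed (a seed is
always included whole in the extension, so a forced negative residue inside
the first seed on a diagonal could lock in a sub-optimal window), but
extensions cross stop codons freely. Extension uses BLOSUM62 scores with the
same X-drop rule.

**Significance.** Raw scores are converted to expect values with the
Karlin–Altschul formula \(E = K m n e^{-\lambda S}\), with the standard
ungapped parameters (nucleotide \(\lambda = 1.28\), \(K = 0.46\); BLOSUM62
\(\lambda = 0.3176\), \(K = 0.134\)). Because \(E\) underflows double
precision for long, strong matches, the engine also reports
\(\log_{10} E\), and p-values are computed as \(p = 1 - e^{-E}\) via
`-expm1(-E)` for accuracy at small \(E\).

The extension core is implemented in C++ (via Rcpp). Its correctness is
checked in the test suite against an exhaustive dynamic-programming oracle
that computes the best ungapped local score over every diagonal of both
strands — the engine must reproduce the oracle score exactly on homologous
pairs.

```{r engine}
a <- simulate_phage_community(community_config(1, 2, seed = 1))$genomes[[1]]
hits <- local_hsps(a, a)
hits[1, c("q_start", "q_end", "raw_score", "log10_e")]
```

## 2. Fragmented whole-genome similarity

`fragmented_similarity()` measures how much of one genome is recognizably
present in another, in protein space. The query genome is cut into 50 bp
fragments every 25 bp; each fragment is aligned to the whole subject with the
translated engine and contributes its best HSP score, capped at the
fragment's self-alignment score. Fragment scores below a per-target
significance floor count as zero. The similarity from genome *A* to *B* is
the summed capped scores as a percentage of the summed self-scores, so the
diagonal is 100 by construction and the measure is asymmetric (a small genome
can be fully contained in a larger one but not vice versa). `to_distance()`
symmetrizes the matrix and converts it to a distance,
\(d = 100 - (S + S^\top)/2\), suitable for tree building.

## 3. Similarity networks and layout

`build_attraction_graph()` connects two genomes whenever the best HSP in
either direction has an expect value at or below `e_ceiling` (default
`1e-5`). Each edge carries an attraction in \([0, 1]\) derived from the
better of the two directional p-values:
\(a = \min(1, -\log_{10} p / 200)\), with \(p\) floored at \(10^{-200}\).

`layout_fr()` embeds the network in two or three dimensions with a
Fruchterman–Reingold force simulation: attractive forces act along edges in
proportion to attraction, repulsive forces between all node pairs, with a
linearly cooling temperature. The returned layout records the energy trace so
convergence can be inspected; `extract_clusters()` reports connected
components of the thresholded graph, flagging singletons.

## 4. Trees, group separation and congruence

`nj_tree()` builds a neighbor-joining tree from any distance matrix
(delegating to `ape::nj()`); tiny negative branch lengths that NJ can produce
are clamped to zero, with the deficit transferred to the adjacent branch so
path lengths are preserved. `patristic_matrix()` returns tree path distances.

`group_separation()` formalizes "the groups are distinct on the tree": for
every pair of groups it compares the *smallest* between-group patristic
distance with the *largest* within-group distance on each side; a pair is
separated when the smallest between exceeds both. Singleton groups have no
within-group distance and compare against the other group's spread only.

`mast_size()` computes the number of leaves in the maximum agreement subtree
of two binary trees — the largest leaf set on which both trees induce the
same topology — using the Steel–Warnow dynamic program over directed edge
pairs. The test suite verifies it against brute-force subset enumeration.
`icong()` turns the MAST size into a congruence index by dividing by the mean
MAST size between the first tree and random trees on the same labels
(proportional-to-distinguishable-arrangements null), with a Monte-Carlo
p-value \((1 + \#\{\text{null} \ge \text{observed}\})/(R + 1)\).

```{r congruence}
tr <- random_pda_tree(paste0("t", 1:12), seed = 1)
icong(tr, tr, null_reps = 199, seed = 2)
```

## 5. Terminal repeats from coverage

A linear genome whose two ends carry an identical long repeat assembles into
a circle in which the repeat appears once but receives the reads of both
copies — about twice the depth of the unique region.
`detect_elevated_segment()` finds that segment:

1. smooth the per-position depth with a circular moving average
   (`smoothing_window`, default 201 bp);
2. mark positions at or above `ratio_threshold` (default 1.5) times the
   median smoothed depth;
3. fill below-threshold gaps narrower than one smoothing window — the
   smoother cannot resolve genuine features that small, so such gaps are
   noise;
4. take the longest contiguous run in circular coordinates (runs may wrap
   the origin);
5. refine each boundary to the split minimizing the within-segment sum of
   squares of a two-level step model.

Two biases are built into the physics of the problem and handled explicitly.
Coverage ramps from one level to the other over one read length at the repeat
boundaries (the physical ends of the linear genome receive fewer overlapping
reads), so the detected segment is biased inward by up to a read length — the
accuracy target for the length is therefore quoted in read lengths. For the
same reason the `coverage_ratio` excludes positions within one smoothing
window of either boundary from both level estimates, and takes the mean depth
of the segment core against the mean of the far background.

`linearize()` rotates the circular sequence to start at the repeat and
reports the length accounting: `total_length = unique_length + ltr_length`.
`annotate_flank_repeats()` scans the boundary neighborhoods for tandem
repeats with `find_tandem_repeats()` (exact or mismatch-tolerant unit
matching, minimum unit count and total length).

```{r ltr}
asm <- simulate_collapsed_assembly(30000, 2000, 20000, 400, seed = 5)
call <- detect_elevated_segment(asm$coverage)
call
linearize(asm$sequence, call)
```

## 6. Consensus gene calls and genome statistics

`consensus_cds()` reconciles several gene-predictor tracks: candidate
features are grouped by strand and (approximate) stop coordinate, each group
is supported by the number of tracks voting for it, and groups reaching
`min_support` are reported with the boundaries of the most-voted variant
(ties broken toward the longer open reading frame). `sequence_stats()`
summarizes a genome and its features: length, GC content, coding density,
and per-strand CDS counts.

## 7. Growth kinetics

`adsorption_rate()` estimates the adsorption rate constant from a
free-phage decay series using the standard exponential-decay form
\(k = \frac{2.303}{B t} \log_{10}(P_0 / P_t)\), where \(B\) is the host cell
density. The estimate is averaged over the initial monotone-decay window
(later time points, where free phage plateaus, would bias \(k\) downward),
per replicate and then overall.

`one_step_analysis()` fits a step model to a one-step growth curve: the
baseline is the mean titre before the rise, the latent period is the first
time the titre exceeds `rise_factor` (default 3) times baseline, the plateau
is detected by relative change below `plateau_tol`, and the burst size is
plateau over baseline. If a chloroform-treated series is supplied (or
included via a `treatment` column), the eclipse period is estimated from its
rise and constrained to be at most the latent period. Fits are flagged
censored when the curve has not plateaued by the last time point.

```{r kinetics}
s <- simulate_titer_series(
  "adsorption",
  params = list(k = 6.44e-9, cell_density = 3e8, cv = 0.1),
  design = list(times = 0:10, replicates = 3), seed = 5
)
glance(adsorption_rate(s, host_density = 3e8))
```

## 8. Simulators

Every estimator above has a matching generator, so recovery can be tested
quantitatively:

- `simulate_phage_community()` builds modular genomes: groups share a module
  backbone and diverge by point mutation and module swaps, an optional
  outgroup shares nothing.
- `simulate_collapsed_assembly()` lays uniform shotgun reads over a linear
  genome with identical terminal repeats and returns the collapsed circular
  coverage profile plus the ground truth.
- `simulate_marker_families()` evolves amino-acid alignments along a given
  tree under a Jukes–Cantor-style 20-state model; `aln_distance()` converts
  alignments to p-distances or Poisson-corrected distances.
- `simulate_predictor_tracks()` perturbs a true feature set into several
  imperfect predictor tracks (missed calls, false calls, boundary jitter).
- `simulate_titer_series()` generates adsorption and one-step titre series
  with lognormal replicate noise.

## 9. The pipeline

`run_pipeline()` chains the comparative steps — fragmented similarity,
distance conversion, neighbor-joining tree, attraction graph, layout,
clusters, group separation and (optionally) marker-tree congruence — and
`write_pipeline_results()` serializes every table along with a provenance
manifest of parameters and file checksums. Reruns with the same inputs and
seed produce byte-identical outputs. The same pipeline is exposed as a
command-line script in `inst/cli/phagephylo.R`.
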