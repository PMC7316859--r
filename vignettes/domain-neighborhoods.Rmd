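---
title: "Domain neighborhoods: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain neighborhoods: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainhood)
library(dplyr)
```

## The problem

Viral genomes are hard to compare by gene content: annotation is patchy,
many proteins have no characterized homolog, and no single gene is conserved
across all viruses. Protein *domains* — conserved modules detectable by
profile hidden Markov models (pHMMs) even at extreme sequence divergence —
offer an annotation-free alternative: decompose every genome into an ordered
string of domains, then compare genomes by the *neighborhoods* those domains
form. domainhood implements that pipeline end to end:

1. six-frame translate each nucleotide genome, so unannotated reading frames
   are searched too;
2. search the translations with a pHMM database (HMMER3 `hmmsearch`), either
   whole frames, annotated genes, or overlapping windows;
3. rescale and curate the resulting domain hits, resolving the redundancy
   the windowing deliberately creates;
4. order the surviving domains along the genome and build neighborhoods
   around chosen domains of interest, with signed ordered-domain distances;
5. turn neighborhoods into clan-keyed inverse-square-distance feature
   matrices, cluster them, and compare clusters against taxonomy.

## Search modes and windowing

`hmmsearch` sensitivity depends on target sequence length, so three search
modes are supported. Whole-frame search feeds each of the six translated
frames as one target. Gene search feeds each annotated CDS translation.
Window search cuts each frame into 200-residue windows offset by 13 residues
(`make_windows()`), which markedly improves sensitivity for short domains at
the price of re-finding the same domain in many windows. No new sequence is
created by windowing: consecutive full windows overlap by 187 residues and
the truncated tail window guarantees every residue is covered (the tail rule
is our choice; coverage would otherwise silently fail for frame lengths not
on the step lattice).

Stop codons are kept in the translations as a `*` sentinel rather than
splitting frames into ORFs — the search operates on whole frames, and pHMM
alignments simply do not extend across the sentinel. Codons containing
ambiguous bases translate to `X`, which profile scores treat neutrally.

Windows, frames and gene peptides are written with structured FASTA headers
(`ACC|frame3|win12|start156`, `ACC|gene|gp2|100|400|-`). That naming scheme
is the contract that lets `parse_domtblout()` place window-relative hit
coordinates back into frame coordinates, and frame coordinates back onto the
genome (`map_to_genomic()`): forward-frame residue *i* (0-based) of frame
*k* starts at nucleotide `(k-1) + 3i + 1`; reverse frames are reflected onto
the forward axis with strand `-`, so all downstream ordering uses one
coordinate system.

## E-value adjustment

HMMER's per-domain independent E-value is calibrated to the searched target
set. Hits from the window search are therefore rescaled twice
(`adjust_evalue()`): division by the number of targets in the run normalizes
to a single-sequence search space, and multiplication by
`frame_length / searched_length` undoes the sensitivity gain of searching a
short window instead of the full frame. Whole-frame searches use a factor of
1 for the second step; gene-mode hits also use 1, since a gene is a natural
search unit rather than an arbitrary slice — that case is not pinned by the
source procedure and is our documented choice. Hits with adjusted E-value
above 1 are excluded outright, and hits found identically in several
overlapping windows (same profile, frame and alignment interval) collapse to
the copy with the smallest adjusted E-value.

## De-overlap rules

The remaining redundancy is overlapping *distinct* hits: domains from the
same PFAM clan detected over one region, and small domains nested in large
ones. `deoverlap()` resolves these per (genome, frame) — never across
frames, so genuine double coding on opposite strands survives. Hits are
sorted by *calculated start*, the alignment start extended upstream by up to
20 residues but never more than the unmatched profile prefix
(`min(hmm_from - 1, 20)`); overlap between two hits is the intersection of
their `[calc_start, ali_end]` intervals divided by the shorter hit's length.
The shorter-hit denominator is our choice (the source is silent): it makes a
small domain nested inside a large one register as ~100% overlap, which is
exactly the redundancy the rules target. For each adjacent and skip-1 pair
(A–B, B–C, A–C) in the sorted order:

* **same clan** (both non-missing and equal): overlap ≥ 33% removes the hit
  with the larger adjusted E-value;
* **different clans**: if both hits are significant (adjusted E ≤ 1e-7) both
  are kept regardless of overlap; otherwise overlap ≥ 45% removes the worse
  hit *only* when the better one is ≥ 10,000-fold better in E-value. We read
  the ratio clause as an additional requirement for removal — the
  conservative interpretation that never deletes a hit without that printed
  justification — and keep both otherwise;
* **database precedence**: a vFAM/pVOG hit overlapping a PFAM hit at all is
  kept only when `log10(E_vfam) < 5 × log10(E_pfam)` (both E-values clamped
  below 1 so the logs are negative); at exact equality the PFAM hit wins.

Removed hits drop out of later comparisons and the scan repeats to a fixed
point. A single pass would make the kept-set depend on input order; the
fixed point, together with a total tie-break (E-value, then bit score, then
calculated start, then profile name), makes curation deterministic and
permutation-invariant, which the test suite checks on 1,000 random
instances. On instances whose overlaps are confined to adjacent and skip-1
neighbours in sorted order, the scan provably examines every overlapping
pair, and the suite verifies equality with an all-pairs brute-force oracle
there; with longer-range overlap chains the windowed scan can differ from
an all-pairs pass, a known and accepted property of the neighbour-limited
rule.

The 1e-7 significance default follows the "high quality" threshold of the
source procedure; its own alternative derivation (0.01 divided by a
9,051-genome corpus ≈ 1.1e-6) differs, so the value is a parameter of
`curation_params()` rather than a constant.

## Neighborhoods and features

Kept hits are ordered along each genome by genomic start (ties by end, then
profile name), strands interleaved. Every occurrence of a *domain of
interest* becomes a neighborhood center; members are the domains within
`radius` positions, with signed distance = member rank − center rank
(upstream negative). Distances count *domains*, not nucleotides, so
neighborhoods are robust to intergenic length variation.

The feature matrix keys members by PFAM clan (profiles without a clan key by
their own name), letting related domains share a column, and weights each
occurrence by `1/d²` of its ordered distance — 1 for a nearest neighbour,
0.0625 at distance 4, 0 for an absent clan. The center contributes 1 (a
distance-0 occurrence maps to weight 1), anchoring all DOI-containing rows
in the DOI clan column and avoiding a division by zero. For clustering
features the default reduction over multiple occurrences of a clan is `max`
(the nearest occurrence dominates); mosaic summaries use `sum`, which
aggregates conserved partnership over all neighborhoods. When one row per
genome is wanted and a genome contains several DOI occurrences, the
neighborhood of the best-scoring (smallest adjusted E-value) occurrence is
used by default.

The "fuzzy" character of the comparison lives entirely in these soft
features; the clustering itself is plain agglomerative hierarchical
clustering (`stats::hclust`, average linkage, Euclidean distance by
default — the linkage/metric/cut were not pinned by the source and are
exposed as arguments). Cluster labels are compared to taxonomy families with
the Hubert–Arabie adjusted Rand index, with the cut defaulting to
k = number of observed families, and with the per-cluster-scaled
contingency matrix (`contingency_scaled()`) for inspection.

## The synthetic generator

`generate_genomes()` plants ordered domain architectures so every stage is
testable at desk scale without downloads. Each synthetic profile has a
fixed, deterministic 50-residue motif (derived from the profile name by a
seed-independent generator), long enough that a profile built from it by
`hmmbuild` recovers it unambiguously with a real `hmmsearch`, and that
string matching recovers it in ingest mode. Genomes place each
(non-dropped) motif's reverse-translated coding sequence — minus-strand
placements as the reverse complement — separated by uniform 30–150 nt
random gaps, a spacing typical of compact viral genomes. The default study
set (`demo_architectures()`) is two families of five domains sharing one
anchor domain (the natural domain of interest) with disjoint, differently
clanned flanks; 10 genomes per family. Planted hits get independent
E-values log-uniform on [1e-30, 1e-12] (comfortably significant after
window rescaling); decoy hits get E-values uniform on (0.05, 0.95), i.e.
junk that the adjusted-E-value exclusion and the significance threshold are
supposed to handle. Hit tables are emitted in HMMER3 `--domtblout` layout
with one duplicate row per covering window, exercising exactly the
redundancy the curation stage removes. All randomness flows from a single
seed and never touches the caller's RNG stream.

What the generator does *not* emulate: realistic base composition or codon
usage, sequence divergence within a family (motifs are exact), partially
overlapping true domains, splicing or ribosomal slippage (also out of scope
for the pipeline itself, whose frame-wise search would miss or fragment
such domains). Passing recovery tests therefore demonstrate the pipeline's
bookkeeping — coordinates, rescaling, de-overlap, ordering, clustering —
not the statistical sensitivity of pHMM search on diverged real sequences,
which belongs to HMMER.

## Problem sizes and numerical notes

The test suite and the acceptance script run the full pipeline on 2 × 10
synthetic genomes (~1.3 kb each), the de-overlap boundary sweep on 1,152
constructed instances plus 1,000 random ones, and ARI calibration on 1,000
Monte-Carlo replicates — sizes chosen so the whole suite completes in a few
minutes on one core while still crossing every rule boundary
(overlap 0.32/0.33/0.34 and 0.44/0.45/0.46, the 10⁴ E-value ratio, the 5×
log10 precedence line on both sides and at equality). Degenerate inputs are
defined rather than accidental: empty frames yield no windows; genomes
missing the DOI yield no neighborhoods (not an error); a single hit is
always kept; equal E-values in de-overlap resolve by bit score, position,
then name.

## Worked example

```{r example}
sim <- generate_genomes(demo_architectures(), n_per_family = 10, seed = 42)
frames <- six_frame_translate(sim$genomes)
hits <- parse_domtblout(generate_hit_table(sim, seed = 42), sim$profile_meta)

ord <- curate_hits(hits, frames) |>
  map_hits_to_genomic(sim$genomes) |>
  order_domains()

nb <- build_neighborhoods(ord, doi = "ANCHOR_HEL", radius = 10)
m  <- build_feature_matrix(nb, key = "clan", rows = "genome")
cl <- cluster_rows(m, k = 2)
glance(cl)

labels <- left_join(tidy(cl), sim$labels, by = c(row = "accession"))
adjusted_rand(labels$cluster, labels$family)
```

```{r plots, fig.width = 7, fig.height = 4, eval = FALSE}
autoplot(cl)
plot_neighborhood_tracks(nb)
plot_mosaic(mosaic_weights(nb))
```

## Known limitations

* Splicing and ribosomal slippage are not modelled; a domain split across
  frames is missed or reported twice with inflated E-values.
* The de-overlap scan is neighbour-limited (adjacent + skip-1, to a fixed
  point); pathological stacks of more than three mutually overlapping hits
  can resolve differently than an all-pairs pass would.
* `join()` GenBank locations are collapsed to their outer span.
* The hierarchical-clustering cut (and hence any ARI against taxonomy)
  depends on `k`; the default `k` = number of observed families is a
  convention, not an optimum.
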