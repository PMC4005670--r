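---
title: "Selecting genome-specific 50-mer markers and profiling strains in metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting genome-specific 50-mer markers and profiling strains in metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmark)
```

## The problem and the model

Shotgun metagenome reads are short, and closely related bacterial strains
share most of their genome, so assigning reads to strains by alignment is
both slow and ambiguous. `strainmark` takes the opposite route: find, for
every target strain (or species), a set of 50-base sequences — genome-
specific markers, GSMs — that occur in the target and, by construction,
cannot be matched by reads from any other genome in the reference
collection or from the host. Detection then reduces to exact, full-length
string matching of markers against raw reads, with no quality trimming,
assembly, or gene prediction.

A marker is accepted only if it clears two specificity criteria against
every non-target genome (including host/contaminant genomes), on both
strands:

1. **Stretch criterion.** The candidate shares no continuous exact match
   of length ≥ *k* with any non-target, for *k* between 18 and 20. This
   is implemented as a shared-*k*-mer database: every canonical *k*-mer
   (the lexicographic minimum of the word and its reverse complement)
   that occurs in two or more taxon groups, plus every *k*-mer of the
   host genomes. A candidate containing any database *k*-mer is
   discarded. A 50-mer that survives therefore has no ≥ *k* run in
   common with anything it is not supposed to detect.
2. **Identity criterion.** The candidate's best global alignment against
   any non-target window has identity < 85%, where identity is the
   number of identical aligned positions divided by the marker length
   (50); gaps and overhangs count against identity. The bound is
   inclusive: ≥ 85% is discarded.

Selection is progressive in *k*: every target is first tried at *k* = 18
(the strictest stretch filter); targets that end up with fewer than 50
markers are retried at 19, then 20; targets still short at *k* = 20 are
flagged `excluded`. Fifty markers per target is the floor because
detection uses fixed-size random panels (default 50) so that targets
with wildly different marker counts remain comparable.

Downstream, a target is called **positive** in a sample when at least
10% of its panel markers (`ceiling(min_fraction * n)`, e.g. 5 of 50, 10
of 100) are each perfectly matched by at least one read; an optional
minimum total-read count is available for noisy settings. Abundances are
total hits divided by total raw reads, rescaled to 1e7
(Illumina-style) or 1e6 (454-style) reads.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k_schedule` | 18, 19, 20 | progressive stretch lengths (bases) |
| `min_markers` | 50 | marker floor per target before exclusion |
| `identity_threshold` | 0.85 | inclusive discard bound on global identity |
| `seed_len` | 6 | exact-word seed for the identity search (see below) |
| `panel_size` | 50 | markers per target used in detection |
| `min_fraction` | 0.10 | fraction of the panel required for a positive call |
| `min_reads` | 0 | optional minimum total hits per positive call |
| `scale` | 1e7 | abundance normalisation scale (reads per library) |

## Why the identity seed is 6 bases

The identity criterion matters exactly at 43 of 50 matching positions
(0.86 is the smallest achievable identity ≥ 0.85). An ungapped window
with ≥ 43 matches has at most 7 mismatches and hence at most 8 match
runs; if its longest run were ≤ 7, the total could not exceed
7 + 7×5 = 42. Every threshold-relevant window therefore contains a match
run of length ≥ 8, or at least two runs of length ≥ 6. A 6-base exact
seed is consequently the longest seed that cannot miss such a window —
with any longer seed, a homolog whose mismatches are spread out (the
typical survivor of 18-mer stretch filtering, which has already removed
all long runs) can reach 86% identity without ever firing the seed. The
search exploits the same arithmetic in reverse to stay fast: a diagonal
is evaluated only when two seeds fall within one candidate window at
positional gap 2–44 (two distinct runs ≥ 6) or three seeds occur at
consecutive positions (one run ≥ 8); isolated gap-1 seed pairs, which
are a quarter of all random seed hits, carry no threshold-relevant
evidence and are skipped.

Gapped refinement works directly in the criterion's own currency: on a
50-mer, identity ≥ 85% means ≥ 43 identical aligned positions, which is
exactly an alignment within 7 edit operations; the refinement is a
banded (±8 around the seeded diagonal) candidate-global minimum-edit
alignment with free end gaps on the window, run only when the ungapped
count is high enough to matter but below the discard bound (above it
the candidate is already disqualified). The search is exact for
substitution-dominated similarity at the 85% bound. An ≥ 85% alignment
whose evidence is *only* gap-split segments each shorter than 7 on
diagonals that never trigger could in principle be missed; the
synthetic genomes used for validation are substitution-only, and the
brute-force oracle in the test suite (exhaustive per-offset scanning
plus unseeded full-DP alignment) is the reference the seeded search is
held to.

Identity values are reported for the markers that are *kept*; for
discarded candidates the recorded value is the first disqualifying
identity found, and windows far below the threshold may be skipped
entirely (a candidate with no triggered diagonal reports 0), so the
value is filter evidence, not a general-purpose similarity score.

## What the synthetic generator emulates — and what it does not

`evolve_strain_family()` draws a random ancestor and derives each strain
by i.i.d. per-site substitutions at rate *d* (to a uniformly chosen
different base), giving expected pairwise divergence
2*d*(1−*d*) + (2/3)*d*². `simulate_reads()` emits error-free paired-end
100-base reads from uniformly placed fragments on either strand, with
fold-coverage counting all read bases: a genome of length *L* at
coverage *c* receives `round(c·L/100)` reads. Reads are exact substrings
of the source (or its reverse complement), matching the perfect-match
detection model.

The generator deliberately omits: sequencing errors (a substitution
error mode exists for robustness checks only — perfect matching makes
errors a pure loss of sensitivity, not a specificity risk),
insertions/deletions, rearrangements, horizontal transfer, repeat
structure, and compositional bias. Passing tests on these genomes show
that the pipeline's filters are exact for substitution-type divergence
and that detection follows coverage geometry; they do not show
robustness to indel-rich or repeat-rich genomes, where the identity
filter's gap handling and the stretch filter would face structure this
generator never produces.

### Validation conditions and problem sizes

The package validates itself at desk scale, with sizes chosen so the
full suite runs in minutes on one CPU:

* **Specificity gate**: 20 randomized single-family trials (5–10
  strains of 10–12 kb, divergence spread over 1–10%, plus a 10 kb
  synthetic host); every emitted marker is re-verified by brute force
  (substring search at the marker's *k*, exhaustive-alignment identity).
  At low divergence these trials legitimately yield few or no markers —
  an 85% identity bound cannot be met between genomes that are 96%
  identical — which is itself part of the contract (the strains come
  back `excluded`).
* **Detection-limit experiments**: 36 strains (12 families of 3) of
  30 kb at 10% per-strain divergence plus a 30 kb host. Ten percent was
  chosen, rather than the few-percent divergence typical of conspecific
  isolates, because the 85% identity criterion leaves sibling strains
  with *no* markers below roughly 8% per-strain divergence — the
  detection-limit question (how coverage and panel size set the
  identification rate) is about read-sampling geometry and needs strains
  that *have* markers. Identification rates are estimated over all
  strains × read-simulation replicates (≥ 200 strain-trials): with
  100-marker panels at 0.01× coverage roughly 40% of strains show at
  least one perfectly matched marker, rising to ~90% with 50-marker
  panels at 0.1×, reproducing the coverage-geometry expectation
  1 − exp(−51·c·n/100·...) at its two calibration points.
* **Mock community**: the same 36-strain database, 16 members simulated
  at even 5× coverage, 20 non-members present only in the database;
  with 50-marker panels and the 10% threshold all members are called
  and, reads being error-free and markers oracle-specific, non-members
  collect zero hits at any threshold.
* **Coverage closed form**: for error-free reads of length *r* at
  coverage *c*, a fixed 50-mer is fully covered by at least one read
  with probability ≈ 1 − exp(−c·(r−49)/r); the simulator+matcher pair
  is checked against this within 3σ at c ∈ {0.05, 0.25, 1}.

## Numerical and design choices

* **Window count.** A clean contig of length *L* yields *L* − 49
  candidate windows (every 50-base window). Windows containing any
  non-ACGT character are dropped; IUPAC ambiguity codes are retained in
  the stored sequence but treated as ambiguous.
* **Strand handling.** All k-mer logic is canonical (strand-collapsed)
  and the identity search queries both strands: reads come from both
  strands, so a marker must be specific in both orientations.
* **Coordinates.** 0-based half-open everywhere internally; GFF3's
  1-based closed gene rows are converted on load. A marker fully inside
  a gene is `gene`, disjoint from all genes `intergenic`, partial
  `overlap`, and markers of unannotated genomes `unannotated`.
  Multi-locus markers are classified by their first occurrence in genome
  order (deterministic tie-break).
* **Duplicates.** Identical 50-mers within one target are collapsed to
  a single candidate with all occurrence positions recorded; identical
  genome submissions (same strain label) are binned into one strain
  group.
* **Degenerate statistics.** Two constant equal groups give t = 0,
  p = 1; constant unequal groups are flagged degenerate rather than
  returning infinities. Response ratios with a non-positive group mean
  are flagged incomputable per target instead of failing the batch.
* **The FDR gate.** BH correction is computed over targets with mean
  normalised hits ≥ 5 in at least one group; ungated p-values are still
  reported. "Student's t-test" is read literally as pooled-variance
  (Welch behind a flag). The response ratio is ln(mean_B/mean_A) with
  the delta-method variance s²_B/(n_B·m²_B) + s²_A/(n_A·m²_A) and an
  equal-tailed normal interval — the standard form in the ecology
  meta-analysis literature.
* **Seeding.** Every stage derives its RNG seed from the single
  top-level seed by a fixed affine map; panels record their seed, and
  identical configurations give byte-identical outputs.

## A small worked run

```{r example, eval = FALSE}
gs <- simulate_community_genomes(n_families = 3, strains_per_family = 3,
                                 genome_length = 8000, divergence = 0.10,
                                 seed = 42, host_length = 8000)
db <- select_markers_all(gs, "strain")
db[[1]]

panel <- subsample_panel(db[[1]], n = 50, seed = 7)
reads <- simulate_reads(gs, coverage = 0.5, seed = 11)
res <- detect_sample(reads, panel)
res$detection
```

## Known limitations

* The identity search is exact for ungapped (substitution-only)
  similarity at the 85% bound; gap-only borderline alignments can be
  missed (see above). The acceptance oracle, not the seeded search, is
  the reference.
* Contigs are capped at 2²⁸ bases and collections at 2¹⁸ contigs by the
  seed-index key layout — ample for bacterial collections, but a
  chromosome-scale host should be split into chromosomes.
* Species-level markers are required to occur in ≥ 1 genome of the
  species and 0 genomes of any other species; per-marker strain
  coverage within the species is recorded in the occurrence table
  rather than enforced.
* Exclusion is a statement about the reference collection: a strain
  excluded against its siblings may be perfectly identifiable in a
  collection without close relatives.
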