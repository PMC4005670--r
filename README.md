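# strainmark

Strain- and species-level identification of microbes in shotgun
metagenomes via genome-specific 50-mer markers.

## The problem

Closely related bacterial strains share most of their genomes, so
short-read metagenome data is hard to resolve below the species level.
`strainmark` sidesteps read mapping entirely: for each target strain (or
species) in a reference collection it selects **genome-specific markers
(GSMs)** — 50-base sequences that occur in the target but, by
construction, in no other genome of the collection and not in the host.
Raw reads are then screened by *exact, full-length* marker matching: no
trimming, assembly, or gene calling.

A 50-mer qualifies as a marker only if, against every non-target genome
and both strands:

* it shares **no continuous exact stretch of length ≥ k** (k = 18–20),
  enforced through a database of canonical k-mers that occur in two or
  more taxon groups plus all host k-mers ("stretch filtering"); and
* its best **global alignment identity is < 85%** (identical aligned
  positions / 50, gaps counting against; ≥ 85% is discarded).

Selection is progressive: targets with fewer than 50 markers at k = 18
are retried at 19, then 20, and flagged `excluded` if still short. In a
sample, a target is called **present** when ≥ 10% of a fixed-size random
marker panel (default 50) is perfectly hit; abundances are hits per
total reads rescaled to 1e7 (Illumina) or 1e6 (454). A statistics layer
provides pooled two-sample t-tests, Benjamini–Hochberg FDR over targets
with ≥ 5 mean normalised hits, and log response ratios with delta-method
confidence intervals for case/control comparisons.

A built-in simulator generates families of strain genomes with
controlled per-site divergence and error-free paired-end 100-base reads
at chosen fold-coverage, so sensitivity (detection limit vs coverage and
panel size) and specificity (mock communities with known membership) are
testable end to end without downloads.

## Worked example

```r
library(strainmark)

# 3 families x 3 strains of 8 kb, 10% divergence, plus a synthetic host
gs <- simulate_community_genomes(n_families = 3, strains_per_family = 3,
                                 genome_length = 8000, divergence = 0.10,
                                 seed = 42, host_length = 8000)
db <- select_markers_all(gs, "strain")
db[["Simulatus fam001 str1"]]
#> marker_set 'Simulatus fam001 str1' (strain level): 3652 GSMs at k=18

panel <- subsample_panel(db[["Simulatus fam001 str1"]], n = 50, seed = 7)
reads <- simulate_reads(gs$genomes[["Simulatus_fam001_str1"]],
                        coverage = 1, seed = 5)
res <- detect_sample(reads, panel)
res$detection
#>                  target  n distinct_gsms_hit total_hits positive normalized_abundance
#> 1 Simulatus fam001 str1 50                23         31     TRUE              3875000
```

3652 of the strain's 8 kb survive both specificity filters at k = 18
(its two 10%-diverged siblings and the host leave plenty of unique
sequence). At 1× coverage (80 reads of 100 bases), 23 of the 50 panel
markers are each hit at least once — far above the 5-marker (10%)
positive-calling threshold — for 31 total hits, i.e. a normalised
abundance of 31/80 × 1e7.

The same functions scale to the full pipeline surface: `run_select`,
`run_detect`, `run_profile` operate on manifest/reads/abundance files,
and `inst/cli/strainmark.R` wraps them as `select` / `detect` /
`profile` / `simulate` / `evaluate` subcommands for shell use.

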