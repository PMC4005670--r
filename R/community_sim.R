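BASES <- c("A", "C", "G", "T")

# i.i.d. per-site substitution at rate d; a mutated site moves to one of
# the three other bases uniformly
mutate_sites <- function(chars, d) {
  if (d <= 0) return(chars)
  pos <- which(runif(length(chars)) < d)
  if (length(pos) == 0) return(chars)
  cur <- match(chars[pos], BASES)
  shift <- sample.int(3, length(pos), replace = TRUE)
  chars[pos] <- BASES[((cur - 1 + shift) %% 4) + 1]
  chars
}

#' Simulate a family of closely related strain genomes
#'
#' Draws a random ancestor over A/C/G/T and derives each strain by
#' independent per-site substitutions at rate `divergence` (to a uniformly
#' chosen different base), the usual neutral-substitution stand-in for a
#' clade of sequenced isolates. Strain labels are generated as fake
#' binomials (`"<genus> <species> strN"`) so that species grouping logic
#' is exercised: all strains of one family share a species.
#'
#' @param ancestor_length genome length in bp.
#' @param n_strains number of strains derived from the ancestor.
#' @param divergence per-site substitution probability from the ancestor
#'   (expected pairwise difference `2d(1-d) + (2/3)d^2`).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param genus,species tokens used to build strain labels.
#' @return a [genome_set()] of `n_strains` single-contig genomes.
#' @export
evolve_strain_family <- function(ancestor_length, n_strains, divergence,
                                 seed = 1L, genus = "Simulatus",
                                 species = "familia") {
  stopifnot(divergence >= 0, divergence < 1, n_strains >= 1,
            ancestor_length >= 1)
  with_seed(seed, {
    anc <- sample(BASES, ancestor_length, replace = TRUE)
    recs <- lapply(seq_len(n_strains), function(i) {
      s <- paste(mutate_sites(anc, divergence), collapse = "")
      gid <- sprintf("%s_%s_str%d", genus, gsub("\\s+", "_", species), i)
      genome_record(gid, paste(genus, species, sprintf("str%d", i)),
                    stats::setNames(s, paste0(gid, "_c1")))
    })
    genome_set(recs)
  })
}

#' Simulate a multi-family community of strain genomes
#'
#' Convenience wrapper building several independent strain families (one
#' species per family) plus an optional unrelated synthetic host genome
#' flagged `is_host`.
#'
#' @param n_families number of families (species).
#' @param strains_per_family strains derived per ancestor.
#' @param genome_length ancestor length per family.
#' @param divergence per-site substitution rate, see
#'   [evolve_strain_family()].
#' @param seed RNG seed.
#' @param host_length length of the synthetic host genome (0 for none).
#' @return a [genome_set()].
#' @export
simulate_community_genomes <- function(n_families, strains_per_family,
                                       genome_length, divergence,
                                       seed = 1L, host_length = 0L) {
  recs <- list()
  for (f in seq_len(n_families)) {
    fam <- evolve_strain_family(genome_length, strains_per_family,
                                divergence,
                                seed = stage_seed(seed, f),
                                species = sprintf("fam%03d", f))
    recs <- c(recs, fam$genomes)
  }
  if (host_length > 0) {
    host <- with_seed(stage_seed(seed, 0), paste(
      sample(BASES, host_length, replace = TRUE), collapse = ""))
    recs <- c(recs, list(genome_record("host_1", "Hostus syntheticus",
                                       c(host_1_c1 = host),
                                       is_host = TRUE)))
  }
  genome_set(recs)
}

#' Simulate error-free shotgun reads at a given fold-coverage
#'
#' Emulates a read simulator in its simplest mode: error-free paired-end
#' reads of fixed length placed uniformly at random on either strand.
#' Fold-coverage counts all read bases (both mates), so each genome
#' receives `round(coverage * L / read_length)` reads; paired mode emits
#' them as fragments of `fragment_length` with the two mates at the
#' fragment ends (an odd read count adds one unpaired read). Error-free
#' reads are exact substrings of the source genome or its reverse
#' complement; an optional uniform substitution error mode exists for
#' robustness testing only.
#'
#' @param x a [genome_set()] or single [genome_record()].
#' @param coverage fold-coverage; a scalar applied to every genome or a
#'   named vector by genome id (ids absent or at 0 contribute no reads).
#' @param read_length read length, default 100.
#' @param paired emit mate pairs (default TRUE).
#' @param seed RNG seed; identical inputs give byte-identical reads.
#' @param fragment_length outer fragment size for pairs (clamped to the
#'   contig length), default 300.
#' @param error_rate per-base substitution probability, default 0
#'   (error-free).
#' @return a [Biostrings::DNAStringSet] with names
#'   `<genome_id>_p<i>/1|2` (pairs) and `<genome_id>_s<i>` (singletons).
#' @export
simulate_reads <- function(x, coverage, read_length = 100L, paired = TRUE,
                           seed = 1L, fragment_length = 300L,
                           error_rate = 0) {
  recs <- if (inherits(x, "genome_record")) list(x) else x$genomes
  rl <- as.integer(read_length)
  cov_of <- function(gid) {
    if (length(coverage) == 1 && is.null(names(coverage)))
      return(as.numeric(coverage))
    if (gid %in% names(coverage)) as.numeric(coverage[[gid]]) else 0
  }
  with_seed(seed, {
    out <- character(0)
    nm <- character(0)
    for (r in recs) {
      cv <- cov_of(r$genome_id)
      if (cv <= 0) next
      if (any(nchar(r$contigs) < rl))
        stop("read_length ", rl, " exceeds shortest contig of '",
             r$genome_id, "'")
      n_reads <- round(cv * r$length / rl)
      if (n_reads < 1) next
      clen <- nchar(r$contigs)
      pick_contig <- function(n, span) {
        w <- pmax(clen - span + 1, 0)
        if (n == 0) return(integer(0))
        sample.int(length(clen), n, replace = TRUE, prob = w / sum(w))
      }
      emit <- function(seqs, names) {
        if (error_rate > 0)
          seqs <- vapply(seqs, function(s)
            paste(mutate_sites(strsplit(s, "")[[1]], error_rate),
                  collapse = ""), character(1), USE.NAMES = FALSE)
        out <<- c(out, seqs); nm <<- c(nm, names)
      }
      n_pairs <- if (paired) n_reads %/% 2L else 0L
      n_single <- n_reads - 2L * n_pairs
      if (n_pairs > 0) {
        fl <- pmin(as.integer(fragment_length), clen)
        ci <- pick_contig(n_pairs, max(fl))
        fli <- fl[ci]
        starts <- floor(runif(n_pairs) * (clen[ci] - fli + 1))
        flip <- runif(n_pairs) < 0.5
        frag <- substring(r$contigs[ci], starts + 1, starts + fli)
        frag[flip] <- revcomp(frag[flip])
        r1 <- substring(frag, 1, rl)
        r2 <- revcomp(substring(frag, fli - rl + 1, fli))
        emit(c(rbind(r1, r2)),
             c(rbind(sprintf("%s_p%d/1", r$genome_id, seq_len(n_pairs)),
                     sprintf("%s_p%d/2", r$genome_id, seq_len(n_pairs)))))
      }
      if (n_single > 0) {
        ci <- pick_contig(n_single, rl)
        starts <- floor(runif(n_single) * (clen[ci] - rl + 1))
        flip <- runif(n_single) < 0.5
        rs <- substring(r$contigs[ci], starts + 1, starts + rl)
        rs[flip] <- revcomp(rs[flip])
        emit(rs, sprintf("%s_s%d", r$genome_id, seq_len(n_single)))
      }
    }
    ss <- Biostrings::DNAStringSet(out)
    names(ss) <- nm
    ss
  })
}

#' Write reads as FASTA or FASTQ
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param path output file; FASTQ gets a fixed quality of `I` per base.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(reads, path)
  } else {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
      function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = q)
  }
  invisible(path)
}

#' Sensitivity grid: identification rate by coverage and panel size
#'
#' For each combination of fold-coverage and panel size, simulates
#' error-free reads from every evaluated strain, matches them against the
#' panels and records the fraction of strains identified under
#' `detection_rule`, averaged over `replicates` independent read
#' simulations. Panels are drawn once per panel size and shared across
#' coverages.
#'
#' @param gs the [genome_set()] the markers were selected from.
#' @param marker_db named list of `marker_set` objects (one per target),
#'   e.g. from [select_markers_all()]; excluded targets are dropped.
#' @param coverages,panel_sizes grids to evaluate.
#' @param detection_rule `"at_least_one_gsm"` (a strain counts as
#'   identified when any of its panel markers is hit) or
#'   `"fraction_threshold"` (the positive-calling rule at
#'   `min_fraction`).
#' @param min_fraction threshold for `"fraction_threshold"`.
#' @param replicates read-simulation replicates per grid point.
#' @param seed RNG seed (panels and reads both derive from it).
#' @param insufficient what to do when a target has fewer markers than
#'   `panel_size`: `"allow_fewer"` uses all of them (with a warning),
#'   `"skip"` drops the target for that panel size.
#' @return data frame with columns `coverage`, `panel_size`,
#'   `detection_rule`, `fraction_identified`, `n_targets`, `replicates`.
#' @export
sensitivity_experiment <- function(gs, marker_db, coverages, panel_sizes,
                                   detection_rule = c("at_least_one_gsm",
                                                      "fraction_threshold"),
                                   min_fraction = 0.10, replicates = 1L,
                                   seed = 1L,
                                   insufficient = c("allow_fewer", "skip")) {
  detection_rule <- match.arg(detection_rule)
  insufficient <- match.arg(insufficient)
  marker_db <- Filter(function(m) !m$excluded, marker_db)
  if (length(marker_db) == 0) stop("no usable marker sets")
  rows <- list()
  for (ps in panel_sizes) {
    panels <- list()
    for (tg in names(marker_db)) {
      ms <- marker_db[[tg]]
      if (nrow(ms$gsms) < ps) {
        if (insufficient == "skip") next
        warning("target '", tg, "' has ", nrow(ms$gsms), " < ", ps,
                " GSMs; using all", call. = FALSE)
      }
      panels[[tg]] <- subsample_panel(ms, min(ps, nrow(ms$gsms)),
                                      seed = stage_seed(seed, ps),
                                      allow_fewer = TRUE)
    }
    if (length(panels) == 0) next
    target_ids <- names(panels)
    genome_ids <- unlist(lapply(gs$genomes, function(r) {
      if (r$is_host) return(NULL)
      keys <- c(r$strain_label, r$genome_id, parse_species(r$strain_label))
      if (any(keys %in% target_ids)) r$genome_id else NULL
    }))
    sub <- gs
    sub$genomes <- gs$genomes[genome_ids]
    for (cv in coverages) {
      # replicates share one exact-match pass: reads are tagged by
      # replicate and hits split afterwards
      reads <- do.call(c, lapply(seq_len(replicates), function(rep_i) {
        r <- simulate_reads(sub, cv,
                            seed = stage_seed(seed,
                                              1000 * ps + 7 * rep_i +
                                                round(1e4 * cv)))
        names(r) <- sprintf("rep%03d|%s", rep_i, names(r))
        r
      }))
      hits <- match_reads(reads, panels)
      hit_rep <- sub("\\|.*$", "", hits$read_id)
      fr <- vapply(sprintf("rep%03d", seq_len(replicates)), function(rp) {
        h <- hits[hit_rep == rp, , drop = FALSE]
        found <- if (detection_rule == "at_least_one_gsm") {
          target_ids %in% h$target
        } else {
          det <- call_positives(h, panels, min_fraction)
          det$positive[match(target_ids, det$target)]
        }
        mean(found)
      }, numeric(1))
      rows[[length(rows) + 1]] <-
        data.frame(coverage = cv, panel_size = ps,
                   detection_rule = detection_rule,
                   fraction_identified = mean(fr),
                   n_targets = length(target_ids),
                   replicates = replicates, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a mock-community read set with known composition
#'
#' Members contribute error-free reads at the chosen abundance profile;
#' non-members are in the marker database but absent from the reads, so
#' any positive call on them is a false positive by construction.
#'
#' @param gs a [genome_set()] containing members and non-members.
#' @param members,nonmembers disjoint vectors of genome ids.
#' @param profile `"even"` (all members at `coverage_base`) or
#'   `"staggered"` (log-spaced coverages spanning `span`-fold, i.e. three
#'   orders of magnitude by default, from `coverage_base` down).
#' @param coverage_base top fold-coverage.
#' @param seed RNG seed.
#' @param span staggered max/min coverage ratio, default 1000.
#' @param ... passed to [simulate_reads()].
#' @return list with `reads`, `truth` (data frame: `genome_id`, `target`
#'   strain label, `coverage`, `expected_positive`) and the coverage
#'   vector used.
#' @export
mock_community <- function(gs, members, nonmembers,
                           profile = c("even", "staggered"),
                           coverage_base = 5, seed = 1L, span = 1000, ...) {
  profile <- match.arg(profile)
  if (length(intersect(members, nonmembers)) > 0)
    stop("member and non-member sets overlap")
  stopifnot(all(c(members, nonmembers) %in% names(gs$genomes)))
  covs <- if (profile == "even") rep(coverage_base, length(members)) else
    10^seq(log10(coverage_base), log10(coverage_base / span),
           length.out = length(members))
  names(covs) <- members
  reads <- simulate_reads(gs, covs, seed = seed, ...)
  lab <- function(g) gs$genomes[[g]]$strain_label
  truth <- data.frame(
    genome_id = c(members, nonmembers),
    target = vapply(c(members, nonmembers), lab, character(1)),
    coverage = c(unname(covs), rep(0, length(nonmembers))),
    expected_positive = c(rep(TRUE, length(members)),
                          rep(FALSE, length(nonmembers))),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth, coverage = covs)
}
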