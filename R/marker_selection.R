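#' Enumerate candidate 50-mers of a genome
#'
#' Every 50-base window of every contig is a candidate (L - 49 windows for
#' a clean contig of length L); windows containing any ambiguity code are
#' dropped, and exact duplicate sequences within the genome are collapsed
#' to one candidate -- the first occurrence in genome order is kept and all
#' occurrence positions are recorded.
#'
#' @param record a [genome_record()].
#' @param width marker width (default 50).
#' @return a `candidate_set`: data frame with columns `sequence`,
#'   `genome_id`, `contig_id`, `offset` (0-based, first occurrence), with
#'   all occurrences in `attr(, "occurrences")` (column `candidate` indexes
#'   rows of the main frame).
#' @export
enumerate_candidates <- function(record, width = 50L) {
  stopifnot(inherits(record, "genome_record"))
  parts <- lapply(names(record$contigs), function(cid) {
    seq <- record$contigs[[cid]]
    offs <- cpp_stretch_survivors(seq, 1L, numeric(0), as.integer(width))
    if (length(offs) == 0) return(NULL)
    data.frame(sequence = substring(seq, offs + 1, offs + width),
               genome_id = record$genome_id, contig_id = cid,
               offset = offs, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  if (is.null(all))
    all <- data.frame(sequence = character(0), genome_id = character(0),
                      contig_id = character(0), offset = integer(0))
  first <- !duplicated(all$sequence)
  cand <- all[first, , drop = FALSE]
  rownames(cand) <- NULL
  occ <- data.frame(candidate = match(all$sequence, cand$sequence),
                    genome_id = all$genome_id, contig_id = all$contig_id,
                    offset = all$offset, stringsAsFactors = FALSE)
  attr(cand, "occurrences") <- occ
  class(cand) <- c("candidate_set", "data.frame")
  cand
}

# subset a candidate_set, keeping the occurrence table consistent
subset_candidates <- function(cand, keep) {
  idx <- which(keep)
  out <- cand[idx, , drop = FALSE]
  rownames(out) <- NULL
  occ <- attr(cand, "occurrences")
  if (!is.null(occ)) {
    occ <- occ[occ$candidate %in% idx, , drop = FALSE]
    occ$candidate <- match(occ$candidate, idx)
    rownames(occ) <- NULL
    attr(out, "occurrences") <- occ
  }
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Remove candidates sharing a k-stretch with the shared-k-mer database
#'
#' @param candidates a `candidate_set` (or data frame with a `sequence`
#'   column).
#' @param index a `kmer_index` from [build_shared_kmer_db()].
#' @return the surviving candidates (a subset of the input).
#' @export
stretch_filter <- function(candidates, index) {
  stopifnot(inherits(index, "kmer_index"))
  hit <- vapply(candidates$sequence, cpp_any_shared, logical(1),
                k = index$k, shared_sorted = index$shared,
                USE.NAMES = FALSE)
  subset_candidates(candidates, !hit)
}

# internal: batch identity of candidate sequences against an indexed
# non-target collection. `stop_at` short-circuits a candidate once a
# disqualifying window is found.
batch_max_identity <- function(sequences, cand_group, flat, sidx,
                               nw_trigger = 0.40, pad = 8L, stop_at = 2) {
  if (length(sequences) == 0) return(numeric(0))
  cpp_max_identity(sequences, as.integer(rep_len(cand_group,
                                                 length(sequences))),
                   flat$seq, as.integer(flat$group), sidx,
                   nw_trigger, as.integer(pad), stop_at)
}

#' Maximum global identity of a candidate against non-target genomes
#'
#' Seed hits of length `seed_len` (both strands) between the candidate and
#' any non-target sequence are extended along their diagonal (ungapped
#' count of identical positions) and, near the decision boundary, refined
#' by a banded candidate-global alignment minimising edit operations with
#' free end gaps on the window -- for a 50-mer, an alignment within 7
#' operations is exactly a window of >= 43 identical positions, the
#' inclusive 85% bound. Identity is identical aligned positions divided
#' by the candidate length, maximised over evaluated windows; 0 when no
#' seeded window exists -- the search is a filter against the >= 85%
#' rule, so windows far below the threshold may be skipped rather than
#' scored.
#'
#' @param candidate a 50-base string.
#' @param nontargets a [genome_set()] that excludes every genome of the
#'   candidate's own target group (host genomes may be included; they are
#'   legitimate non-targets).
#' @param seed_len exact-word seed length; the default 6 is the smallest
#'   length guaranteed to fire on every ungapped window of >= 85% identity
#'   (43 matches split by at most 7 mismatches leave a run of >= 6).
#' @return identity fraction in `[0, 1]`.
#' @export
max_nontarget_identity <- function(candidate, nontargets, seed_len = 6L) {
  if (seed_len > nchar(candidate))
    stop("seed_len exceeds candidate length")
  flat <- flatten_contigs(nontargets)
  sidx <- cpp_seed_index(flat$seq, as.integer(seed_len))
  batch_max_identity(candidate, 0L, flat, sidx, stop_at = 2)[1]
}

#' Identity-filter stretch-filtered candidates into markers
#'
#' Candidates whose maximum global identity against any non-target window
#' reaches `threshold` (inclusive: >= 85% is discarded) are removed; each
#' survivor becomes a genome-specific marker with its identity recorded.
#'
#' @param candidates a `candidate_set` (normally already stretch-filtered).
#' @param nontargets a [genome_set()] of non-target (and host) genomes.
#' @param threshold identity cutoff, default 0.85.
#' @param seed_len see [max_nontarget_identity()].
#' @return the surviving candidates with a `max_nontarget_identity` column.
#' @export
identity_filter <- function(candidates, nontargets, threshold = 0.85,
                            seed_len = 6L) {
  flat <- flatten_contigs(nontargets)
  sidx <- cpp_seed_index(flat$seq, as.integer(seed_len))
  ids <- batch_max_identity(candidates$sequence, 0L, flat, sidx,
                            stop_at = threshold)
  out <- subset_candidates(candidates, ids < threshold)
  out$max_nontarget_identity <- ids[ids < threshold]
  out
}

#' Classify a marker location against gene annotation
#'
#' @param contig_id,offset first recorded occurrence of the marker
#'   (0-based start).
#' @param gene_intervals data frame of 0-based half-open gene intervals,
#'   or `NULL` for an unannotated genome.
#' @param width marker width.
#' @return `"gene"` (fully inside a gene), `"intergenic"` (disjoint from
#'   all genes), `"overlap"` (partial), or `"unannotated"`.
#' @export
classify_location <- function(contig_id, offset, gene_intervals = NULL,
                              width = 50L) {
  if (is.null(gene_intervals)) return("unannotated")
  gi <- gene_intervals[gene_intervals$contig_id == contig_id, , drop = FALSE]
  if (nrow(gi) == 0) return("intergenic")
  s <- offset; e <- offset + width
  inside <- any(s >= gi$start & e <= gi$end)
  if (inside) return("gene")
  disjoint <- all(e <= gi$start | s >= gi$end)
  if (disjoint) "intergenic" else "overlap"
}

# internal constructor
marker_set <- function(target_group_id, level, k_used, gsms, occurrences,
                       excluded) {
  structure(list(target_group_id = target_group_id, level = level,
                 k_used = as.integer(k_used), gsms = gsms,
                 occurrences = occurrences, excluded = isTRUE(excluded)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set '%s' (%s level): %d GSMs at k=%d%s\n",
              x$target_group_id, x$level, nrow(x$gsms), x$k_used,
              if (x$excluded) " [excluded: < minimum marker count]" else ""))
  invisible(x)
}

# stretch-filtered, deduplicated candidates of one target group at one k,
# with per-candidate non-target identities computed contig-wise
group_candidates <- function(gs, gids, k, shared, gnum = NULL, flat = NULL,
                             sidx = NULL, identity_threshold = 0.85) {
  parts <- list()
  for (g in gids) {
    rec <- gs$genomes[[g]]
    for (cid in names(rec$contigs)) {
      seq <- rec$contigs[[cid]]
      offs <- cpp_stretch_survivors(seq, as.integer(k), shared, 50L)
      if (length(offs) == 0) next
      part <- data.frame(sequence = substring(seq, offs + 1, offs + 50),
                         genome_id = g, contig_id = cid, offset = offs,
                         stringsAsFactors = FALSE)
      if (!is.null(sidx))
        part$max_nontarget_identity <-
          cpp_contig_max_identity(seq, offs, 50L, as.integer(gnum),
                                  flat$seq, as.integer(flat$group), sidx,
                                  0.40, 8L, identity_threshold)
      parts[[length(parts) + 1]] <- part
    }
  }
  all <- do.call(rbind, parts)
  if (is.null(all)) return(NULL)
  first <- !duplicated(all$sequence)
  cand <- all[first, , drop = FALSE]
  rownames(cand) <- NULL
  occ <- data.frame(candidate = match(all$sequence, cand$sequence),
                    genome_id = all$genome_id, contig_id = all$contig_id,
                    offset = all$offset, stringsAsFactors = FALSE)
  list(cand = cand, occ = occ)
}

#' Select genome-specific markers for every target group
#'
#' Runs the full selection pipeline -- candidate enumeration, shared-k-mer
#' stretch filtering, global-identity filtering -- under the progressive k
#' schedule: each target is first attempted at the smallest k; targets with
#' fewer than `min_markers` markers are retried at the next k. Targets
#' still short at the last k are returned with `excluded = TRUE`. The
#' shared-k-mer database and the non-target seed index are built once per k
#' and shared across targets.
#'
#' @param gs a [genome_set()]; host genomes participate in both filters as
#'   non-targets but are never targets.
#' @param level `"strain"` or `"species"`; controls both the grouping of
#'   the shared-k-mer database and which genomes count as non-targets
#'   (species level: all genomes of other species).
#' @param k_schedule increasing stretch lengths, default `c(18, 19, 20)`.
#' @param min_markers minimum acceptable marker count per target
#'   (default 50).
#' @param identity_threshold inclusive discard threshold, default 0.85.
#' @param seed_len identity-search seed length, see
#'   [max_nontarget_identity()].
#' @param targets optional subset of group ids to process.
#' @param verbose log per-stage candidate counts.
#' @return named list of `marker_set` objects, one per target group.
#' @export
select_markers_all <- function(gs, level = c("strain", "species"),
                               k_schedule = c(18L, 19L, 20L),
                               min_markers = 50L, identity_threshold = 0.85,
                               seed_len = 6L, targets = NULL,
                               verbose = FALSE) {
  level <- match.arg(level)
  grouping <- group_by_level(gs, level)
  if (is.null(targets)) targets <- names(grouping$groups)
  missing <- setdiff(targets, names(grouping$groups))
  if (length(missing) > 0)
    stop("target group(s) not in genome set: ",
         paste(missing, collapse = ", "))
  flat <- flatten_contigs(gs, grouping)
  sidx <- cpp_seed_index(flat$seq, as.integer(seed_len))
  group_num <- match(targets, names(grouping$groups))

  res <- stats::setNames(vector("list", length(targets)), targets)
  pending <- targets
  for (k in k_schedule) {
    if (length(pending) == 0) break
    shared_db <- build_shared_kmer_db(gs, grouping, k)
    for (tg in pending) {
      gnum <- group_num[match(tg, targets)]
      cc <- group_candidates(gs, grouping$groups[[tg]], k,
                             shared_db$shared, gnum, flat, sidx,
                             identity_threshold)
      if (is.null(cc)) {
        res[[tg]] <- marker_set(tg, level, k, empty_gsms(), empty_occ(),
                                excluded = TRUE)
        next
      }
      ids <- cc$cand$max_nontarget_identity
      keep <- which(ids < identity_threshold)
      gsms <- cc$cand[keep, , drop = FALSE]
      gsms$max_nontarget_identity <- ids[keep]
      occ <- cc$occ[cc$occ$candidate %in% keep, , drop = FALSE]
      occ$candidate <- match(occ$candidate, keep)
      rownames(gsms) <- rownames(occ) <- NULL
      gsms$location <- vapply(seq_len(nrow(gsms)), function(i) {
        rec <- gs$genomes[[gsms$genome_id[i]]]
        classify_location(gsms$contig_id[i], gsms$offset[i],
                          rec$gene_intervals)
      }, character(1))
      if (verbose)
        message(sprintf("[k=%d] %s: %d candidates -> %d GSMs",
                        k, tg, nrow(cc$cand), nrow(gsms)))
      res[[tg]] <- marker_set(tg, level, k, gsms, occ,
                              excluded = nrow(gsms) < min_markers)
    }
    pending <- names(Filter(function(m) m$excluded, res[pending]))
  }
  res
}

empty_gsms <- function() {
  data.frame(sequence = character(0), genome_id = character(0),
             contig_id = character(0), offset = integer(0),
             max_nontarget_identity = numeric(0),
             location = character(0), stringsAsFactors = FALSE)
}
empty_occ <- function() {
  data.frame(candidate = integer(0), genome_id = character(0),
             contig_id = character(0), offset = integer(0),
             stringsAsFactors = FALSE)
}

#' Select markers for one target group
#'
#' Convenience wrapper around [select_markers_all()] for a single target.
#'
#' @inheritParams select_markers_all
#' @param target_group id of the target group at `level` (strain label or
#'   species name).
#' @return a `marker_set`.
#' @export
select_markers <- function(target_group, gs, level = c("strain", "species"),
                           k_schedule = c(18L, 19L, 20L), min_markers = 50L,
                           identity_threshold = 0.85, seed_len = 6L) {
  select_markers_all(gs, level, k_schedule, min_markers,
                     identity_threshold, seed_len,
                     targets = target_group)[[target_group]]
}

#' Draw a reproducible random marker panel
#'
#' Detection and normalisation use a fixed-size random subset of a
#' target's markers (default 50) so that targets with very different
#' marker counts are comparable. Uniform sampling without replacement,
#' deterministic given `seed`; the caller's RNG stream is untouched.
#'
#' @param ms a `marker_set` (must not be excluded).
#' @param n panel size, default 50.
#' @param seed integer seed recorded in the panel.
#' @param allow_fewer if TRUE, a marker set smaller than `n` yields the
#'   full set instead of an error.
#' @return an object of class `marker_panel`.
#' @export
subsample_panel <- function(ms, n = 50L, seed = 1L, allow_fewer = FALSE) {
  stopifnot(inherits(ms, "marker_set"))
  if (ms$excluded)
    stop("marker set '", ms$target_group_id, "' is excluded (",
         nrow(ms$gsms), " GSMs)")
  avail <- nrow(ms$gsms)
  if (n > avail) {
    if (!allow_fewer)
      stop("requested panel of ", n, " from ", avail, " GSMs for '",
           ms$target_group_id, "'")
    n <- avail
  }
  pick <- with_seed(seed, sort(sample.int(avail, n)))
  gsms <- ms$gsms[pick, , drop = FALSE]
  rownames(gsms) <- NULL
  gsms$gsm_id <- sprintf("%s|g%05d", ms$target_group_id, pick)
  structure(list(target_group_id = ms$target_group_id, level = ms$level,
                 k_used = ms$k_used, n = n, seed = seed, gsms = gsms,
                 rng = "base R Mersenne-Twister via sample.int"),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel '%s': %d of the target's GSMs (seed %s)\n",
              x$target_group_id, x$n, format(x$seed)))
  invisible(x)
}
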