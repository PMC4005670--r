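#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is taken from the file extension (`.fq`/`.fastq`, optionally
#' `.gz`, is FASTQ; anything else FASTA). Qualities are ignored:
#' perfect-match detection makes them irrelevant and no trimming is done.
#'
#' @param path reads file (gzip accepted).
#' @return a [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path)
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

# accept a single panel/marker_set or a list of them; marker sets become
# full panels with stable ids
as_panel_list <- function(panels) {
  if (inherits(panels, "marker_panel") || inherits(panels, "marker_set"))
    panels <- list(panels)
  lapply(panels, function(p) {
    if (inherits(p, "marker_set")) {
      gsms <- p$gsms
      gsms$gsm_id <- sprintf("%s|g%05d", p$target_group_id,
                             seq_len(nrow(gsms)))
      p <- structure(list(target_group_id = p$target_group_id,
                          level = p$level, k_used = p$k_used,
                          n = nrow(gsms), seed = NA_integer_, gsms = gsms),
                     class = "marker_panel")
    }
    stopifnot(inherits(p, "marker_panel"))
    p
  })
}

empty_hits <- function() {
  data.frame(read_id = character(0), gsm_id = character(0),
             target = character(0), strand = character(0),
             offset = integer(0), stringsAsFactors = FALSE)
}

#' Match metagenome reads against marker panels
#'
#' A hit is an exact, full-length occurrence of a panel marker -- forward
#' or reverse complement -- as a substring of a read; only perfect matches
#' count, and every occurrence is reported (a read containing two panel
#' markers yields two hits). Reads shorter than the marker length cannot
#' hit. Matching uses a `PDict` of all panel sequences and their reverse
#' complements against the reads concatenated with `N` separators, so a
#' match can never span two reads.
#'
#' @param reads a [Biostrings::DNAStringSet], a named character vector, or
#'   a path accepted by [read_sequences()].
#' @param panels a `marker_panel`, `marker_set`, or list of them. A marker
#'   shared verbatim between panels counts toward every panel containing
#'   it.
#' @return data frame of hits: `read_id`, `gsm_id`, `target`, `strand`
#'   (`+`/`-`), `offset` (0-based position in the read).
#' @export
match_reads <- function(reads, panels) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_sequences(reads)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  panels <- as_panel_list(panels)
  pat <- do.call(rbind, lapply(panels, function(p)
    data.frame(target = p$target_group_id, gsm_id = p$gsms$gsm_id,
               sequence = p$gsms$sequence, stringsAsFactors = FALSE)))
  if (is.null(pat) || nrow(pat) == 0 || length(reads) == 0)
    return(empty_hits())
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- sprintf("read%06d", seq_along(reads))

  allpat <- c(pat$sequence, revcomp(pat$sequence))
  strand <- rep(c("+", "-"), each = nrow(pat))
  src <- rep(seq_len(nrow(pat)), 2)
  upat <- unique(allpat)
  expand <- split(seq_along(allpat), match(allpat, upat))

  widths <- Biostrings::width(reads)
  starts <- cumsum(c(1L, widths + 1L))[seq_along(reads)]
  subject <- Biostrings::DNAString(paste(as.character(reads),
                                         collapse = "N"))
  pd <- Biostrings::PDict(upat)
  m <- Biostrings::matchPDict(pd, subject)

  acc_r <- list(); acc_e <- list(); acc_o <- list()
  for (j in seq_along(upat)) {
    s <- Biostrings::start(m[[j]])
    if (length(s) == 0) next
    ridx <- findInterval(s, starts)
    off <- as.integer(s - starts[ridx])
    for (e in expand[[as.character(j)]]) {
      i <- length(acc_r) + 1
      acc_r[[i]] <- ridx; acc_e[[i]] <- rep(e, length(s))
      acc_o[[i]] <- off
    }
  }
  if (length(acc_r) == 0) return(empty_hits())
  ridx <- unlist(acc_r); e <- unlist(acc_e); off <- unlist(acc_o)
  out <- data.frame(read_id = names(reads)[ridx],
                    gsm_id = pat$gsm_id[src[e]],
                    target = pat$target[src[e]],
                    strand = strand[e], offset = off,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call targets positive from marker hits
#'
#' A target is positive when at least `ceiling(min_fraction * n)` distinct
#' panel markers are hit (the recommended 10% threshold: 5 of a 50-marker
#' panel, 10 of 100) and the total hit count reaches `min_reads`. Targets
#' with zero hits are reported with `positive = FALSE`.
#'
#' @param hits data frame from [match_reads()] over the same panels.
#' @param panels the panels that were searched.
#' @param min_fraction fraction of the panel that must be hit, default
#'   0.10.
#' @param min_reads optional minimum total hit count (a cutoff of ~5 reads
#'   removes rare spurious identifications); default 0.
#' @return data frame: `target`, `n`, `distinct_gsms_hit`, `total_hits`,
#'   `positive`.
#' @export
call_positives <- function(hits, panels, min_fraction = 0.10,
                           min_reads = 0) {
  panels <- as_panel_list(panels)
  out <- do.call(rbind, lapply(panels, function(p) {
    h <- hits[hits$target == p$target_group_id, , drop = FALSE]
    n <- nrow(p$gsms)
    need <- ceiling(min_fraction * n - 1e-9)
    distinct <- length(unique(h$gsm_id))
    data.frame(target = p$target_group_id, n = n,
               distinct_gsms_hit = distinct, total_hits = nrow(h),
               positive = distinct >= need && nrow(h) >= min_reads,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalise hit counts by sequencing depth
#'
#' Hits are divided by the total number of raw reads in the sample and
#' rescaled to a fixed library size -- 1e7 for Illumina or 1e6 for 454 --
#' to avoid very small relative abundances.
#'
#' @param total_hits numeric vector of hit counts.
#' @param total_reads total raw reads in the sample (> 0).
#' @param scale normalisation scale, default 1e7.
#' @return normalised abundance(s).
#' @export
normalize_abundance <- function(total_hits, total_reads, scale = 1e7) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  total_hits / total_reads * scale
}

#' Detect targets in one sample
#'
#' Composes [match_reads()], [call_positives()] and
#' [normalize_abundance()] for a single reads file or read set.
#'
#' @inheritParams match_reads
#' @inheritParams call_positives
#' @param scale see [normalize_abundance()].
#' @return list with `hits` and `detection` (the positive-call table plus
#'   a `normalized_abundance` column; total read count in
#'   `attr(detection, "total_reads")`).
#' @export
detect_sample <- function(reads, panels, min_fraction = 0.10,
                          min_reads = 0, scale = 1e7) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_sequences(reads)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  hits <- match_reads(reads, panels)
  det <- call_positives(hits, panels, min_fraction, min_reads)
  det$normalized_abundance <-
    normalize_abundance(det$total_hits, length(reads), scale)
  attr(det, "total_reads") <- length(reads)
  list(hits = hits, detection = det)
}

#' Assemble a targets-by-samples abundance matrix
#'
#' @param detections named list (one entry per sample) of detection tables
#'   from [detect_sample()].
#' @return numeric matrix of normalised abundances, targets in rows,
#'   samples in columns; per-sample read totals in
#'   `attr(, "total_reads")`.
#' @export
abundance_matrix <- function(detections) {
  stopifnot(length(detections) > 0, !is.null(names(detections)))
  targets <- unique(unlist(lapply(detections, function(d) d$target)))
  mat <- matrix(0, nrow = length(targets), ncol = length(detections),
                dimnames = list(targets, names(detections)))
  for (s in names(detections)) {
    d <- detections[[s]]
    mat[d$target, s] <- d$normalized_abundance
  }
  attr(mat, "total_reads") <-
    vapply(detections, function(d) attr(d, "total_reads") %||% NA_integer_,
           numeric(1))
  mat
}
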