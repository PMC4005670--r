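#' Canonical k-mers of a sequence
#'
#' Enumerates all k-windows containing only A/C/G/T, collapses each to its
#' canonical form (the lexicographically smaller of the k-mer and its
#' reverse complement) and deduplicates. Windows touching an ambiguity code
#' (N or any other IUPAC code) are skipped.
#'
#' @param sequence a single DNA string.
#' @param k word size (1--26).
#' @return sorted character vector of canonical k-mers; empty when
#'   `k > nchar(sequence)`.
#' @examples
#' extract_kmers("ACGTA", 4)   # "ACGT" "CGTA"
#' extract_kmers("ACNGT", 4)   # character(0)
#' @export
extract_kmers <- function(sequence, k) {
  stopifnot(length(sequence) == 1)
  codes <- cpp_kmer_codes(toupper(sequence), as.integer(k))
  codes <- sort(unique(codes[!is.na(codes)]))
  if (length(codes) == 0) return(character(0))
  cpp_decode_kmers(codes, as.integer(k))
}

# internal constructor; `shared` is a sorted numeric vector of canonical
# 2-bit k-mer codes (exact doubles)
kmer_index <- function(k, shared, provenance = list()) {
  structure(list(k = as.integer(k), shared = shared,
                 provenance = provenance), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d shared canonical k-mers (%s level, %d groups%s)\n",
              x$k, length(x$shared),
              x$provenance$level %||% "?",
              x$provenance$n_groups %||% NA_integer_,
              if (isTRUE(x$provenance$has_host)) " + host" else ""))
  invisible(x)
}

#' Build the shared-k-mer database used for stretch filtering
#'
#' A canonical k-mer enters the database iff it occurs in two or more taxon
#' groups (strains or species, after per-group deduplication) or in any
#' host genome. Candidate markers containing any such k-mer share an exact
#' stretch of length >= k with a non-target and are discarded by
#' [stretch_filter()].
#'
#' @param gs a [genome_set()].
#' @param grouping a `taxon_grouping` at the level markers are being
#'   selected for (strain-level database for strain markers, species-level
#'   for species markers).
#' @param k word size, 18--20 in routine use.
#' @return an object of class `kmer_index`.
#' @export
build_shared_kmer_db <- function(gs, grouping, k) {
  if (length(gs$genomes) == 0) stop("empty genome set")
  k <- as.integer(k)
  per_group <- lapply(grouping$groups, function(gids) {
    seqs <- unlist(lapply(gids, function(g) unname(gs$genomes[[g]]$contigs)))
    cpp_unique_kmer_codes(seqs, k)
  })
  all_codes <- sort(unlist(per_group, use.names = FALSE))
  shared <- unique(all_codes[duplicated(all_codes)])
  hosts <- Filter(function(r) r$is_host, gs$genomes)
  if (length(hosts) > 0) {
    hseqs <- unlist(lapply(hosts, function(r) unname(r$contigs)))
    shared <- sort(unique(c(shared, cpp_unique_kmer_codes(hseqs, k))))
  }
  kmer_index(k, shared,
             provenance = list(level = grouping$level,
                               n_groups = length(grouping$groups),
                               group_sizes = lengths(grouping$groups),
                               has_host = length(hosts) > 0))
}

#' Does a candidate 50-mer share a k-stretch with the database?
#'
#' TRUE iff any canonical k-window of the candidate is in the shared set,
#' i.e. the candidate (on either strand) has a continuous exact match of
#' length >= k with a non-target or host genome.
#'
#' @param candidate a 50-base string over A/C/G/T.
#' @param index a `kmer_index` from [build_shared_kmer_db()].
#' @return logical scalar.
#' @export
has_shared_stretch <- function(candidate, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (nchar(candidate) != 50)
    stop("candidate must be exactly 50 bases, got ", nchar(candidate))
  if (!is_clean_dna(candidate))
    stop("candidate must contain only A/C/G/T")
  cpp_any_shared(candidate, index$k, index$shared)
}

#' Serialize a k-mer index to plain text
#'
#' Header line `k=<int>`, then one canonical k-mer per line in
#' lexicographic order (reproducible files).
#'
#' @param index a `kmer_index`.
#' @param path output file.
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  kmers <- if (length(index$shared) > 0)
    cpp_decode_kmers(index$shared, index$k) else character(0)
  writeLines(c(sprintf("k=%d", index$k), kmers), path)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^k=\\d+$", lines[1]))
    stop("missing 'k=<int>' header in ", path)
  k <- as.integer(sub("^k=", "", lines[1]))
  kmers <- lines[-1]
  kmers <- kmers[nzchar(kmers)]
  shared <- if (length(kmers) > 0)
    sort(unique(cpp_unique_kmer_codes(kmers, k))) else numeric(0)
  kmer_index(k, shared, provenance = list(source = path))
}
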