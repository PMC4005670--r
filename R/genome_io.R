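#' Construct a genome record
#'
#' A genome record holds the contig sequences of one reference genome
#' together with its organism label, optional gene intervals and a host
#' flag. Host (contaminant) genomes take part in marker filtering but are
#' never marker targets. Sequences are stored upper-cased; gene intervals
#' use 0-based half-open coordinates.
#'
#' @param genome_id unique identifier for the genome.
#' @param strain_label organism name, e.g. `"Escherichia coli DEC6E"`; the
#'   binomial part defines the species, the full label defines the strain.
#' @param contigs named character vector of contig sequences.
#' @param gene_intervals optional data frame with columns `contig_id`,
#'   `start`, `end` (0-based half-open). `NULL` marks the genome as
#'   annotation-absent.
#' @param is_host logical; host genomes are used only as filters.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(genome_id, strain_label, contigs,
                          gene_intervals = NULL, is_host = FALSE) {
  stopifnot(is.character(contigs), length(contigs) >= 1)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("contigs must be named by contig_id")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig_id within genome '", genome_id, "'")
  if (!nzchar(strain_label)) stop("strain_label must be non-empty")
  contigs[] <- toupper(contigs)
  if (!is.null(gene_intervals)) {
    gene_intervals <- as.data.frame(gene_intervals)
    stopifnot(all(c("contig_id", "start", "end") %in% names(gene_intervals)))
    bad <- !(gene_intervals$contig_id %in% names(contigs))
    if (any(bad)) stop("gene interval on unknown contig in '", genome_id, "'")
    clen <- nchar(contigs)[gene_intervals$contig_id]
    if (any(gene_intervals$start < 0 | gene_intervals$end > clen |
            gene_intervals$start >= gene_intervals$end))
      stop("gene interval out of contig bounds in '", genome_id, "'")
  }
  structure(list(genome_id = genome_id, strain_label = strain_label,
                 contigs = contigs, gene_intervals = gene_intervals,
                 is_host = isTRUE(is_host),
                 length = sum(nchar(contigs))),
            class = "genome_record")
}

#' Bundle genome records into a genome set
#'
#' @param records list of [genome_record()] objects with unique genome ids.
#' @return an object of class `genome_set`: a list of records indexed by
#'   genome id.
#' @export
genome_set <- function(records) {
  ids <- vapply(records, function(r) r$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome_id in genome set")
  names(records) <- ids
  structure(list(genomes = records), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  n <- length(x$genomes)
  host <- sum(vapply(x$genomes, function(r) r$is_host, logical(1)))
  bp <- sum(vapply(x$genomes, function(r) r$length, numeric(1)))
  cat(sprintf("genome_set: %d genomes (%d host), %.0f bp total\n",
              n, host, bp))
  invisible(x)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record '%s' (%s%s): %d contig(s), %d bp, %s\n",
              x$genome_id, x$strain_label, if (x$is_host) ", host" else "",
              length(x$contigs), x$length,
              if (is.null(x$gene_intervals)) "unannotated"
              else sprintf("%d gene(s)", nrow(x$gene_intervals))))
  invisible(x)
}

# GFF3 gene rows -> 0-based half-open intervals (GFF3 is 1-based closed)
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  data.frame(contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Load reference genomes from FASTA (and optional GFF3) files
#'
#' Each FASTA file becomes one genome; sequences are upper-cased on load.
#' Genomes without a GFF3 are marked annotation-absent and their markers
#' classify as `"unannotated"`.
#'
#' @param fasta_paths character vector of FASTA files (gzip accepted), one
#'   genome per file.
#' @param strain_labels organism names, one per genome.
#' @param gff3_paths optional GFF3 annotations (`NA` or `""` for none);
#'   only rows of type `gene` are used.
#' @param host_flags logical, recycled; marks host/contaminant genomes.
#' @param genome_ids optional explicit ids (default: file base names).
#' @return a [genome_set()].
#' @export
load_genomes <- function(fasta_paths, strain_labels, gff3_paths = NULL,
                         host_flags = FALSE, genome_ids = NULL) {
  n <- length(fasta_paths)
  if (n == 0) stop("no genomes to load")
  stopifnot(length(strain_labels) == n)
  if (!is.null(gff3_paths)) stopifnot(length(gff3_paths) == n)
  host_flags <- rep_len(host_flags, n)
  if (is.null(genome_ids))
    genome_ids <- make.unique(sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                                  basename(fasta_paths)), sep = "_")
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ss <- Biostrings::readDNAStringSet(fasta_paths[i])
    if (length(ss) == 0) stop("empty FASTA: ", fasta_paths[i])
    ids <- sub("\\s.*$", "", names(ss))
    contigs <- as.character(ss)
    names(contigs) <- ids
    gi <- NULL
    if (!is.null(gff3_paths) && !is.na(gff3_paths[i]) &&
        nzchar(gff3_paths[i]))
      gi <- read_gene_intervals(gff3_paths[i])
    recs[[i]] <- genome_record(genome_ids[i], strain_labels[i], contigs,
                               gi, host_flags[i])
  }
  genome_set(recs)
}

#' Read a genome manifest and load the genomes it lists
#'
#' The manifest is a TSV with columns `genome_id`, `strain_label`,
#' `fasta_path`, `gff3_path` (may be empty) and `is_host` (0/1 or
#' TRUE/FALSE). Relative paths are resolved against the manifest location.
#'
#' @param path manifest TSV.
#' @return a [genome_set()].
#' @export
read_genome_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "strain_label", "fasta_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | !nzchar(p), NA_character_,
                                ifelse(grepl("^/", p), p, file.path(base, p)))
  gff <- if ("gff3_path" %in% names(man)) resolve(man$gff3_path) else
    rep(NA_character_, nrow(man))
  host <- if ("is_host" %in% names(man)) as.logical(man$is_host) else FALSE
  load_genomes(resolve(man$fasta_path), man$strain_label, gff, host,
               man$genome_id)
}

#' Write a genome set back to FASTA files
#'
#' @param gs a [genome_set()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_genomes <- function(gs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(gs$genomes, function(r) {
    p <- file.path(dir, paste0(r$genome_id, ".fasta"))
    ss <- Biostrings::DNAStringSet(r$contigs)
    Biostrings::writeXStringSet(ss, p)
    p
  }, character(1))
  invisible(paths)
}

#' Species name from a strain label
#'
#' The first two whitespace-separated tokens form the binomial species
#' name. Labels of the form `"Genus sp. <ID>"` name unassigned isolates;
#' these stay singleton species keyed by the full label rather than being
#' lumped into a pseudo-species `"Genus sp."`.
#'
#' @param strain_label character vector of organism names.
#' @return character vector of species names.
#' @examples
#' parse_species("Escherichia coli DEC6E")       # "Escherichia coli"
#' parse_species("Bacteroides sp. 2_1_16")       # kept as-is
#' @export
parse_species <- function(strain_label) {
  vapply(strain_label, function(lab) {
    lab <- trimws(lab)
    if (!nzchar(lab)) stop("empty strain_label")
    toks <- strsplit(lab, "\\s+")[[1]]
    if (length(toks) < 2)
      stop("cannot form a binomial species name from label '", lab, "'")
    if (toks[2] %in% c("sp.", "sp")) lab else paste(toks[1], toks[2])
  }, character(1), USE.NAMES = FALSE)
}

#' Group genomes by strain or species
#'
#' Strain level: one group per distinct strain label, so duplicate
#' submissions of the same organism are binned together. Species level:
#' groups keyed by [parse_species()]. Host genomes are excluded from all
#' groups.
#'
#' @param gs a [genome_set()].
#' @param level `"strain"` or `"species"`.
#' @return an object of class `taxon_grouping`: list with `level`,
#'   `groups` (named list of genome id vectors) and `labels`.
#' @export
group_by_level <- function(gs, level = c("strain", "species")) {
  level <- match.arg(level)
  recs <- Filter(function(r) !r$is_host, gs$genomes)
  if (length(recs) == 0) stop("no non-host genomes to group")
  labs <- vapply(recs, function(r) r$strain_label, character(1))
  keys <- if (level == "strain") labs else parse_species(labs)
  ids <- vapply(recs, function(r) r$genome_id, character(1))
  groups <- split(unname(ids), keys)
  labels <- vapply(split(unname(labs), keys), `[`, character(1), 1)
  structure(list(level = level, groups = groups, labels = labels),
            class = "taxon_grouping")
}

#' @export
print.taxon_grouping <- function(x, ...) {
  cat(sprintf("taxon_grouping at %s level: %d groups over %d genomes\n",
              x$level, length(x$groups), sum(lengths(x$groups))))
  invisible(x)
}

# flat view over contigs (including host), used by the marker pipeline:
# parallel vectors over contigs plus the group index per contig at `level`
# (host contigs get group -1)
flatten_contigs <- function(gs, grouping = NULL) {
  recs <- gs$genomes
  out <- list(seq = character(0), genome_id = character(0),
              contig_id = character(0), group = integer(0))
  gid_group <- NULL
  if (!is.null(grouping)) {
    gid_group <- integer(0)
    for (j in seq_along(grouping$groups))
      gid_group[grouping$groups[[j]]] <- j
  }
  for (r in recs) {
    g <- -1L
    if (!r$is_host && !is.null(gid_group) &&
        r$genome_id %in% names(gid_group))
      g <- gid_group[[r$genome_id]]
    out$seq <- c(out$seq, unname(r$contigs))
    out$genome_id <- c(out$genome_id, rep(r$genome_id, length(r$contigs)))
    out$contig_id <- c(out$contig_id, names(r$contigs))
    out$group <- c(out$group, rep(as.integer(g), length(r$contigs)))
  }
  out
}
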