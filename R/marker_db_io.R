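#' Write a marker database
#'
#' FASTA dialect with one record per marker; the header carries the full
#' provenance:
#' `><target>|<level>|k=<k>|id=<identity 2dp>|loc=<class>|<genome>:<contig>:<offset>`
#' (first recorded occurrence). An optional TSV mirror holds one row per
#' occurrence.
#'
#' @param marker_sets a `marker_set` or named list of them.
#' @param fasta_path output FASTA path.
#' @param tsv_path optional TSV mirror path.
#' @export
write_marker_db <- function(marker_sets, fasta_path, tsv_path = NULL) {
  if (inherits(marker_sets, "marker_set")) marker_sets <- list(marker_sets)
  lines <- character(0)
  tsv <- list()
  for (ms in marker_sets) {
    g <- ms$gsms
    if (nrow(g) == 0) next
    hdr <- sprintf(">%s|%s|k=%d|id=%.2f|loc=%s|%s:%s:%d",
                   ms$target_group_id, ms$level, ms$k_used,
                   g$max_nontarget_identity, g$location,
                   g$genome_id, g$contig_id, g$offset)
    lines <- c(lines, as.vector(rbind(hdr, g$sequence)))
    occ <- ms$occurrences
    tsv[[length(tsv) + 1]] <-
      data.frame(target = ms$target_group_id, level = ms$level,
                 k_used = ms$k_used,
                 sequence = g$sequence[occ$candidate],
                 max_nontarget_identity =
                   round(g$max_nontarget_identity[occ$candidate], 2),
                 location = g$location[occ$candidate],
                 genome_id = occ$genome_id, contig_id = occ$contig_id,
                 offset = occ$offset, stringsAsFactors = FALSE)
  }
  writeLines(lines, fasta_path)
  if (!is.null(tsv_path)) {
    df <- if (length(tsv) > 0) do.call(rbind, tsv) else
      data.frame(target = character(0))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read a marker database written by [write_marker_db()]
#'
#' @param path marker-database FASTA.
#' @return named list of `marker_set` objects (identities as stored, i.e.
#'   2 decimal places; occurrences restricted to the recorded first
#'   occurrence).
#' @export
read_marker_db <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  hdr_i <- grep("^>", lines)
  recs <- lapply(seq_along(hdr_i), function(ri) {
    i <- hdr_i[ri]
    fields <- strsplit(sub("^>", "", lines[i]), "|", fixed = TRUE)[[1]]
    if (length(fields) != 6 || !grepl("^k=\\d+$", fields[3]) ||
        !grepl("^id=", fields[4]) || !grepl("^loc=", fields[5]) ||
        !grepl("^[^:]+:[^:]+:\\d+$", fields[6]))
      stop("malformed marker-db header in record ", ri, ": ", lines[i])
    locparts <- strsplit(fields[6], ":", fixed = TRUE)[[1]]
    data.frame(target = fields[1], level = fields[2],
               k_used = as.integer(sub("^k=", "", fields[3])),
               max_nontarget_identity =
                 as.numeric(sub("^id=", "", fields[4])),
               location = sub("^loc=", "", fields[5]),
               genome_id = locparts[1], contig_id = locparts[2],
               offset = as.integer(locparts[3]),
               sequence = lines[i + 1], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  out <- lapply(split(df, df$target), function(d) {
    gsms <- data.frame(sequence = d$sequence, genome_id = d$genome_id,
                       contig_id = d$contig_id, offset = d$offset,
                       max_nontarget_identity = d$max_nontarget_identity,
                       location = d$location, stringsAsFactors = FALSE)
    occ <- data.frame(candidate = seq_len(nrow(d)),
                      genome_id = d$genome_id, contig_id = d$contig_id,
                      offset = d$offset, stringsAsFactors = FALSE)
    marker_set(d$target[1], d$level[1], d$k_used[1], gsms, occ,
               excluded = FALSE)
  })
  out[unique(df$target)]
}
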