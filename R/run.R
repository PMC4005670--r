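#' Run configuration
#'
#' Bundles the pipeline's tunable constants with their routine defaults:
#' the marker level, the progressive k schedule (18-20), the minimum
#' marker count per target (50), the inclusive identity discard threshold
#' (0.85), the identity-search seed length, the detection panel size (50),
#' the positive-calling fraction (0.10), the optional minimum read count,
#' the normalisation scale (1e7 Illumina / 1e6 for 454-style data) and the
#' top-level seed from which all stage seeds derive.
#'
#' @param level marker level, `"strain"` or `"species"`.
#' @param k_schedule progressive stretch lengths.
#' @param min_markers minimum markers per target.
#' @param identity_threshold inclusive discard threshold.
#' @param seed_len identity seed length (see [max_nontarget_identity()]).
#' @param panel_size detection panel size.
#' @param min_fraction positive-calling fraction of the panel.
#' @param min_reads minimum total hits for a positive call.
#' @param scale normalisation scale.
#' @param seed top-level RNG seed.
#' @param paths named list of input/output paths (free-form).
#' @return an object of class `run_config`.
#' @export
run_config <- function(level = "strain", k_schedule = c(18L, 19L, 20L),
                       min_markers = 50L, identity_threshold = 0.85,
                       seed_len = 6L, panel_size = 50L,
                       min_fraction = 0.10, min_reads = 0L, scale = 1e7,
                       seed = 1L, paths = list()) {
  stopifnot(level %in% c("strain", "species"),
            all(k_schedule >= 1), !is.unsorted(k_schedule),
            min_markers >= 1,
            identity_threshold > 0, identity_threshold <= 1,
            seed_len >= 1, seed_len <= 12,
            panel_size >= 1, min_fraction >= 0, min_fraction <= 1,
            min_reads >= 0, scale > 0)
  structure(list(level = level, k_schedule = as.integer(k_schedule),
                 min_markers = as.integer(min_markers),
                 identity_threshold = identity_threshold,
                 seed_len = as.integer(seed_len),
                 panel_size = as.integer(panel_size),
                 min_fraction = min_fraction,
                 min_reads = as.integer(min_reads), scale = scale,
                 seed = as.integer(seed), paths = paths),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

write_run_manifest <- function(out_dir, config, extra = list()) {
  man <- c(list(package = "strainmark",
                version = as.character(utils::packageVersion("strainmark")),
                config = unclass(config)), extra)
  jsonlite::write_json(man, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Select markers end-to-end and write the marker database
#'
#' Loads the genomes listed in a manifest, runs [select_markers_all()]
#' and writes `marker_db.fasta`, `marker_db.tsv`, a per-target
#' `summary.tsv` (k used, marker count, excluded flag, location-class
#' counts) and a JSON run manifest sufficient to reproduce the outputs.
#'
#' @param config a [run_config()].
#' @param manifest genome manifest TSV (see [read_genome_manifest()]).
#' @param out_dir output directory.
#' @return the per-target summary data frame, invisibly.
#' @export
run_select <- function(config, manifest, out_dir) {
  gs <- read_genome_manifest(manifest)
  if (all(vapply(gs$genomes, function(r) r$is_host, logical(1))))
    stop("no non-host genomes in manifest")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  db <- select_markers_all(gs, config$level, config$k_schedule,
                           config$min_markers, config$identity_threshold,
                           config$seed_len, verbose = TRUE)
  write_marker_db(db, file.path(out_dir, "marker_db.fasta"),
                  file.path(out_dir, "marker_db.tsv"))
  loc_levels <- c("gene", "intergenic", "overlap", "unannotated")
  summary <- do.call(rbind, lapply(db, function(ms) {
    lc <- table(factor(ms$gsms$location, levels = loc_levels))
    row <- data.frame(target = ms$target_group_id, level = ms$level,
                      k_used = ms$k_used, n_gsms = nrow(ms$gsms),
                      excluded = ms$excluded, stringsAsFactors = FALSE)
    for (l in loc_levels) row[[l]] <- as.integer(lc[[l]])
    row
  }))
  rownames(summary) <- NULL
  utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config,
                     list(manifest = normalizePath(manifest),
                          n_targets = nrow(summary)))
  invisible(summary)
}

#' Detect targets in a metagenome against a marker database
#'
#' Reads the marker database, draws `panel_size` markers per target
#' (seeded from the config; targets with fewer markers use all of them),
#' matches the reads and writes `hits.tsv` and `detection.tsv`.
#'
#' @param config a [run_config()].
#' @param reads_path FASTA/FASTQ reads (gz accepted).
#' @param marker_db_path marker database FASTA from [run_select()].
#' @param out_dir output directory.
#' @return the detection data frame, invisibly.
#' @export
run_detect <- function(config, reads_path, marker_db_path, out_dir) {
  db <- read_marker_db(marker_db_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- lapply(db, subsample_panel, n = config$panel_size,
                   seed = config$seed, allow_fewer = TRUE)
  res <- detect_sample(reads_path, panels, config$min_fraction,
                       config$min_reads, config$scale)
  utils::write.table(res$hits, file.path(out_dir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$detection, file.path(out_dir, "detection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config,
                     list(reads = normalizePath(reads_path),
                          marker_db = normalizePath(marker_db_path),
                          total_reads = attr(res$detection,
                                             "total_reads")))
  invisible(res$detection)
}

#' Compare groups of samples from an abundance matrix on disk
#'
#' @param config a [run_config()].
#' @param matrix_path TSV of normalised abundances, first column `target`,
#'   remaining columns samples.
#' @param groups_path TSV with columns `sample` and `group`.
#' @param out_dir output directory (gets `comparison.tsv`).
#' @param method see [compare_groups()].
#' @return the comparison data frame, invisibly.
#' @export
run_profile <- function(config, matrix_path, groups_path, out_dir,
                        method = c("ttest", "response_ratio")) {
  if (!file.exists(groups_path)) stop("missing group file: ", groups_path)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  groups <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  res <- compare_groups(mat, groups, method = method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res, file.path(out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(out_dir, config,
                     list(matrix = normalizePath(matrix_path),
                          groups = normalizePath(groups_path)))
  invisible(res)
}
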