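# Independent oracles and small fixture builders shared across tests.

rc_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# a marker_panel built directly from sequences (no selection pipeline)
make_panel <- function(sequences, target = "toy") {
  gsms <- data.frame(sequence = sequences,
                     gsm_id = sprintf("%s|g%05d", target,
                                      seq_along(sequences)),
                     stringsAsFactors = FALSE)
  structure(list(target_group_id = target, level = "strain",
                 k_used = 18L, n = length(sequences), seed = NA_integer_,
                 gsms = gsms),
            class = "marker_panel")
}

# Exhaustive max-identity oracle: per-offset ungapped scan over every
# window of every sequence (both strands); windows whose ungapped count
# comes near the threshold are refined by a candidate-global unit-cost
# alignment (match 0, mismatch/gap -1 via pairwiseAlignment, so -score =
# minimum edit operations and W - ops bounds the identical positions).
# No seeding -- this is the brute-force reference for the same identity
# definition the package filters on.
oracle_max_identity <- function(cand, seqs, refine_from = 20) {
  W <- nchar(cand)
  best <- 0
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 0,
                                                     mismatch = -1)
  for (s in seqs) {
    L <- nchar(s)
    if (L < W) next
    si <- utf8ToInt(s)
    for (q in c(cand, rc_chr(cand))) {
      qi <- utf8ToInt(q)
      m <- integer(L - W + 1)
      for (j in seq_len(W)) m <- m + (si[j:(L - W + j)] == qi[j])
      best <- max(best, max(m) / W)
      for (o in which(m >= refine_from)) {
        ws <- max(1, o - 8); we <- min(L, o + W - 1 + 8)
        pa <- Biostrings::pairwiseAlignment(
          q, substr(s, ws, we), type = "global-local",
          substitutionMatrix = submat, gapOpening = 0, gapExtension = 1)
        ops <- -Biostrings::score(pa)
        best <- max(best, (W - ops) / W)
      }
    }
  }
  best
}

# Brute-force shared-stretch oracle: does `cand` share any exact substring
# of length >= k with any of `seqs`, on either strand?
oracle_shared_stretch <- function(cand, k, seqs) {
  subject <- paste(c(seqs, rc_chr(seqs)), collapse = strrep("N", k))
  wins <- substring(cand, seq_len(nchar(cand) - k + 1),
                    seq_len(nchar(cand) - k + 1) + k - 1)
  any(vapply(unique(wins), function(w) grepl(w, subject, fixed = TRUE),
             logical(1)))
}

# Naive exact-match read scanner (oracle for match_reads)
oracle_match_count <- function(reads, sequences) {
  total <- 0
  for (r in as.character(reads)) {
    for (s in sequences) {
      for (q in c(s, rc_chr(s))) {
        total <- total +
          length(gregexpr(q, r, fixed = TRUE)[[1]][
            gregexpr(q, r, fixed = TRUE)[[1]] > 0])
      }
    }
  }
  total
}

# plant `n_sub` substitutions into a 50-mer at given 1-based positions
with_substitutions <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- alt[1]
  }
  paste(chars, collapse = "")
}

# write a genome_set as FASTA + manifest in a temp dir, return manifest
write_toy_manifest <- function(gs, dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  paths <- write_genomes(gs, dir)
  man <- data.frame(
    genome_id = names(paths),
    strain_label = vapply(gs$genomes, function(r) r$strain_label,
                          character(1)),
    fasta_path = basename(paths),
    gff3_path = "",
    is_host = vapply(gs$genomes, function(r) r$is_host, logical(1)))
  mp <- file.path(dir, "manifest.tsv")
  write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  mp
}

# decode a kmer_index's shared set to strings
decode_index <- function(idx) {
  if (length(idx$shared) == 0) return(character(0))
  strainmark:::cpp_decode_kmers(idx$shared, idx$k)
}

# Batch identity oracle via edlib (bit-parallel, exhaustive infix DP, no
# seeding).  For a 50-mer, identity >= 0.85 means >= 43 identical aligned
# positions, i.e. at most 7 substitutions+deletions -- an alignment edlib
# finds within edit distance 7.  Returns, per target, how many markers
# have ANY non-target window within `max_ops` edit operations on either
# strand (which must be zero for a specific marker set).
oracle_edlib_counts <- function(gsms_by_target, nontargets_by_target,
                                max_ops = 7) {
  python <- Sys.which(c("python", "python3"))
  python <- python[nzchar(python)][1]
  dir <- tempfile("edlib_oracle_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  plan <- lapply(names(gsms_by_target), function(tg)
    list(gsms = unname(gsms_by_target[[tg]]),
         nontargets = unname(nontargets_by_target[[tg]])))
  names(plan) <- names(gsms_by_target)
  jsonlite::write_json(plan, file.path(dir, "plan.json"),
                       auto_unbox = FALSE)
  writeLines(c(
    "import sys, json",
    "import edlib",
    "comp = str.maketrans('ACGT', 'TGCA')",
    "plan = json.load(open(sys.argv[1]))",
    "k = int(sys.argv[2])",
    "out = {}",
    "for tg, spec in plan.items():",
    "    t = ('N' * 60).join(spec['nontargets'])",
    "    fails = 0",
    "    for q in spec['gsms']:",
    "        rq = q.translate(comp)[::-1]",
    "        hit = False",
    "        for qq in (q, rq):",
    "            r = edlib.align(qq, t, mode='HW', task='distance', k=k)",
    "            if r['editDistance'] != -1:",
    "                hit = True",
    "        if hit:",
    "            fails += 1",
    "    out[tg] = {'checked': len(spec['gsms']), 'fails': fails}",
    "print(json.dumps(out))"), file.path(dir, "oracle.py"))
  res <- system2(python, c(file.path(dir, "oracle.py"),
                           file.path(dir, "plan.json"), max_ops),
                 stdout = TRUE)
  jsonlite::fromJSON(paste(res, collapse = ""))
}
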