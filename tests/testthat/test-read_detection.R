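test_that("perfect-match hits on both strands, no near-matches", {
  set.seed(61)
  gsm <- random_dna(50)
  panel <- make_panel(gsm, "tA")
  reads <- c(r1 = paste0(random_dna(25), gsm, random_dna(25)),
             r2 = paste0(random_dna(10), rc_chr(gsm), random_dna(40)),
             r3 = with_substitutions(paste0(gsm, random_dna(50)), 25),
             r4 = random_dna(40))   # shorter than the marker
  hits <- match_reads(reads, panel)
  expect_equal(nrow(hits), 2)
  h1 <- hits[hits$read_id == "r1", ]
  expect_equal(h1$strand, "+")
  expect_equal(h1$offset, 25)
  h2 <- hits[hits$read_id == "r2", ]
  expect_equal(h2$strand, "-")
  expect_equal(h2$offset, 10)
  expect_false("r3" %in% hits$read_id)   # 49/50 is not a hit
})

test_that("every occurrence is reported, including two markers in one
           read and one marker twice", {
  set.seed(62)
  g1 <- random_dna(50); g2 <- random_dna(50)
  panel <- make_panel(c(g1, g2), "tA")
  reads <- c(r1 = paste0(g1, "ACGT", g2),
             r2 = paste0(g1, "TTTTT", g1))
  hits <- match_reads(reads, panel)
  expect_equal(sum(hits$read_id == "r1"), 2)
  expect_equal(sum(hits$read_id == "r2"), 2)
  expect_equal(sort(hits$offset[hits$read_id == "r2"]), c(0, 55))
})

test_that("match_reads agrees with a naive substring scan", {
  set.seed(63)
  genome <- random_dna(2000)
  panel_seqs <- substring(genome, seq(1, 1901, by = 100),
                          seq(50, 1950, by = 100))
  panel <- make_panel(panel_seqs, "tA")
  for (trial in 1:5) {
    reads <- simulate_reads(
      genome_record("g", "Toyus exampleus s1", c(c1 = genome)),
      coverage = 2, seed = trial)
    hits <- match_reads(reads, panel)
    expect_equal(nrow(hits), oracle_match_count(reads, panel_seqs))
  }
})

test_that("reverse-complementing all reads leaves per-target hit counts
           unchanged", {
  set.seed(64)
  genome <- random_dna(3000)
  panel <- make_panel(substring(genome, c(1, 301, 601), c(50, 350, 650)),
                      "tA")
  reads <- simulate_reads(genome_record("g", "Toyus exampleus s1",
                                        c(c1 = genome)),
                          coverage = 3, seed = 5)
  fwd <- match_reads(reads, panel)
  rcr <- Biostrings::reverseComplement(reads)
  rev <- match_reads(rcr, panel)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(table(rev$gsm_id), table(fwd$gsm_id))
})

test_that("positive calling applies the ceiling fraction rule", {
  mk_hits <- function(target, n_distinct, extra = 0) {
    ids <- c(sprintf("%s|g%05d", target, seq_len(n_distinct)),
             rep(sprintf("%s|g%05d", target, 1), extra))
    data.frame(read_id = sprintf("r%d", seq_along(ids)), gsm_id = ids,
               target = rep(target, length(ids)),
               strand = rep("+", length(ids)),
               offset = rep(0L, length(ids)), stringsAsFactors = FALSE)
  }
  set.seed(65)
  p50 <- make_panel(replicate(50, random_dna(50)), "t50")
  p100 <- make_panel(replicate(100, random_dna(50)), "t100")

  det <- call_positives(mk_hits("t50", 5), p50)
  expect_true(det$positive)                     # 5 of 50 at 10%
  expect_false(call_positives(mk_hits("t50", 4), p50)$positive)
  expect_true(call_positives(mk_hits("t100", 10), p100)$positive)
  expect_false(call_positives(mk_hits("t100", 9), p100)$positive)

  # zero-hit targets are reported negative
  det2 <- call_positives(empty <- mk_hits("t50", 0), list(p50, p100))
  expect_equal(det2$positive, c(FALSE, FALSE))
  expect_equal(det2$distinct_gsms_hit, c(0, 0))

  # min_reads gate and threshold monotonicity
  expect_false(call_positives(mk_hits("t50", 5), p50,
                              min_reads = 10)$positive)
  h <- mk_hits("t50", 7)
  for (f in c(0.02, 0.06, 0.10, 0.14, 0.16)) {
    pos_lo <- call_positives(h, p50, min_fraction = f)$positive
    pos_hi <- call_positives(h, p50, min_fraction = f + 0.02)$positive
    expect_true(pos_lo >= pos_hi)   # raising the threshold never flips
  }                                 # a negative to positive
})

test_that("normalisation is linear in hits and invariant to read
           duplication", {
  expect_equal(normalize_abundance(20, 4e6, 1e7), 50)
  expect_equal(normalize_abundance(0, 123, 1e7), 0)
  expect_equal(normalize_abundance(7, 1e6, 1e6), 7)
  expect_error(normalize_abundance(1, 0), "positive")

  set.seed(66)
  genome <- random_dna(2000)
  panel <- make_panel(substring(genome, c(1, 501), c(50, 550)), "tA")
  reads <- simulate_reads(genome_record("g", "Toyus exampleus s1",
                                        c(c1 = genome)),
                          coverage = 2, seed = 9)
  d1 <- detect_sample(reads, panel)$detection
  doubled <- c(reads, reads)
  names(doubled) <- sprintf("d%04d", seq_along(doubled))
  d2 <- detect_sample(doubled, panel)$detection
  expect_equal(d2$total_hits, 2 * d1$total_hits)
  expect_equal(d2$normalized_abundance, d1$normalized_abundance)
})

test_that("abundance matrices assemble by target and sample", {
  set.seed(67)
  genome <- random_dna(2000)
  panel <- make_panel(substring(genome, c(1, 501), c(50, 550)), "tA")
  rec <- genome_record("g", "Toyus exampleus s1", c(c1 = genome))
  dets <- lapply(1:3, function(i)
    detect_sample(simulate_reads(rec, 1, seed = i), panel)$detection)
  names(dets) <- paste0("s", 1:3)
  mat <- abundance_matrix(dets)
  expect_equal(dim(mat), c(1, 3))
  expect_equal(mat["tA", "s2"], dets$s2$normalized_abundance)
  expect_equal(unname(attr(mat, "total_reads")),
               unname(vapply(dets, attr, numeric(1), "total_reads")))
})

test_that("reads readers handle FASTA and FASTQ with gzip", {
  set.seed(68)
  reads <- Biostrings::DNAStringSet(c(a = random_dna(60),
                                      b = random_dna(60)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads(reads, fa, "fasta")
  write_reads(reads, fq, "fastq")
  expect_equal(as.character(read_sequences(fa)), as.character(reads))
  got <- read_sequences(fq)
  expect_equal(unname(as.character(got)), unname(as.character(reads)))
  expect_error(read_sequences("/nonexistent/reads.fq"), "cannot read")
})
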