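test_that("candidate enumeration yields L-49 windows and drops ambiguity", {
  set.seed(51)
  rec <- genome_record("g1", "Toyus exampleus s1",
                       c(c1 = random_dna(60)))
  cand <- enumerate_candidates(rec)
  expect_equal(nrow(cand), 11)        # 60 - 49
  expect_equal(cand$offset, 0:10)

  seq70 <- random_dna(70)
  substr(seq70, 11, 11) <- "N"        # 0-based position 10
  recN <- genome_record("g2", "Toyus exampleus s2", c(c1 = seq70))
  candN <- enumerate_candidates(recN)
  # windows covering 0-based position 10 (offsets 0..10) are gone
  expect_equal(candN$offset, 11:20)

  short <- genome_record("g3", "Toyus exampleus s3", c(c1 = random_dna(40)))
  expect_equal(nrow(enumerate_candidates(short)), 0)
})

test_that("duplicate 50-mers collapse to one candidate with all
           occurrences recorded", {
  set.seed(52)
  x <- random_dna(50)
  rec <- genome_record("g1", "Toyus exampleus s1",
                       c(c1 = paste0(x, random_dna(60), x)))
  cand <- enumerate_candidates(rec)
  occ <- attr(cand, "occurrences")
  i <- which(cand$sequence == x)
  expect_length(i, 1)
  expect_equal(cand$offset[i], 0)               # first occurrence kept
  expect_setequal(occ$offset[occ$candidate == i], c(0, 110))
})

test_that("stretch_filter removes exactly the candidates with shared
           stretches and nests in the input", {
  set.seed(53)
  gs <- simulate_community_genomes(2, 2, 1500, 0.05, seed = 9)
  grouping <- group_by_level(gs, "strain")
  idx <- build_shared_kmer_db(gs, grouping, 12)
  cand <- enumerate_candidates(gs$genomes[[1]])
  kept <- stretch_filter(cand, idx)
  expect_true(all(kept$sequence %in% cand$sequence))
  expect_true(all(!vapply(kept$sequence, has_shared_stretch, logical(1),
                          index = idx)))
  removed <- setdiff(cand$sequence, kept$sequence)
  expect_true(all(vapply(removed, has_shared_stretch, logical(1),
                         index = idx)))
  # empty index: everything survives
  empty_idx <- strainmark:::kmer_index(12L, numeric(0))
  expect_equal(nrow(stretch_filter(cand, empty_idx)), nrow(cand))
})

nontarget_set <- function(seqs) {
  genome_set(lapply(seq_along(seqs), function(i)
    genome_record(paste0("nt", i), paste("Genus", paste0("sp", i), "s1"),
                  stats::setNames(seqs[i], paste0("c", i)))))
}

test_that("max_nontarget_identity: exact presence, planted substitutions,
           and the no-seed sentinel", {
  set.seed(54)
  genome <- random_dna(400)
  cand_exact <- substr(genome, 101, 150)
  expect_equal(max_nontarget_identity(cand_exact, nontarget_set(genome)),
               1.0)
  # 7 substitutions spread so runs are 4,6,6,6,6,6,6,3 -> 43/50
  cand7 <- with_substitutions(cand_exact, c(5, 12, 19, 26, 33, 40, 47))
  expect_equal(max_nontarget_identity(cand7, nontarget_set(genome)),
               43 / 50)
  # 8 substitutions, all interior (no end-gap realignment ties), with
  # several match runs >= 6 so the seeded search must evaluate -> 42/50
  cand8 <- with_substitutions(cand_exact, c(6, 9, 13, 20, 27, 34, 41, 44))
  expect_equal(max_nontarget_identity(cand8, nontarget_set(genome)),
               42 / 50)
  # reverse complement presence counts
  expect_equal(max_nontarget_identity(rc_chr(cand_exact),
                                      nontarget_set(genome)), 1.0)
  # unrelated candidate, tiny genome: no seeded window at all
  expect_equal(max_nontarget_identity(random_dna(50),
                                      nontarget_set(random_dna(120))), 0)
  expect_error(max_nontarget_identity(random_dna(50),
                                      nontarget_set(random_dna(120)),
                                      seed_len = 60), "seed_len")
})

test_that("seeded identity equals the exhaustive oracle near the
           threshold on random homolog pairs", {
  set.seed(55)
  for (trial in 1:20) {
    genome <- random_dna(300)
    nsub <- sample(0:10, 1)
    cand <- with_substitutions(substr(genome, 51, 100),
                               sample(50, nsub))
    got <- max_nontarget_identity(cand, nontarget_set(genome))
    want <- oracle_max_identity(cand, genome)
    if (want >= 0.8) expect_equal(got, want) else expect_lte(got, want)
  }
})

test_that("identity_filter applies the inclusive >= threshold", {
  set.seed(56)
  genome <- random_dna(400)
  base <- substr(genome, 101, 150)
  cands <- structure(
    data.frame(sequence = c(base,
                            with_substitutions(base, c(5, 12, 19, 26, 33,
                                                       40, 47)),
                            with_substitutions(base, c(6, 9, 13, 20, 27,
                                                       34, 41, 44))),
               genome_id = "t", contig_id = "c", offset = 0:2,
               stringsAsFactors = FALSE),
    class = c("candidate_set", "data.frame"))
  kept <- identity_filter(cands, nontarget_set(genome), threshold = 0.85)
  expect_equal(kept$sequence, cands$sequence[3])     # only 42/50 = 0.84
  expect_equal(kept$max_nontarget_identity, 0.84)
  # inclusive bound: threshold equal to an achievable identity discards it
  kept2 <- identity_filter(cands, nontarget_set(genome), threshold = 0.84)
  expect_equal(nrow(kept2), 0)
  # filters nest: identity output is a subset of its input
  expect_true(all(kept$sequence %in% cands$sequence))
})

test_that("classify_location distinguishes gene, overlap, intergenic,
           unannotated", {
  gi <- data.frame(contig_id = "c1", start = c(100, 500), end = c(400, 600))
  expect_equal(classify_location("c1", 120, gi), "gene")
  expect_equal(classify_location("c1", 380, gi), "overlap")
  expect_equal(classify_location("c1", 420, gi), "intergenic")
  # [50,100) touches but does not enter [100,400): half-open disjoint
  expect_equal(classify_location("c1", 50, gi), "intergenic")
  expect_equal(classify_location("c2", 120, gi), "intergenic")
  expect_equal(classify_location("c1", 120, NULL), "unannotated")
})

test_that("progressive k schedule: first satisfying k wins, else the last
           k is kept with the excluded flag", {
  set.seed(57)
  gs <- simulate_community_genomes(2, 3, 3000, 0.08, seed = 13,
                                   host_length = 1000)
  tg <- group_by_level(gs, "strain")$groups
  target <- names(tg)[1]
  ms1 <- select_markers(target, gs, "strain", min_markers = 1)
  expect_equal(ms1$k_used, 18L)
  expect_false(ms1$excluded)
  ms_hi <- select_markers(target, gs, "strain", min_markers = 1e6)
  expect_equal(ms_hi$k_used, 20L)
  expect_true(ms_hi$excluded)
  # identical genomes share every k-mer: nothing survives at any k
  gs0 <- evolve_strain_family(2000, 3, divergence = 0, seed = 3)
  db0 <- select_markers_all(gs0, "strain")
  expect_true(all(vapply(db0, function(m) m$excluded, logical(1))))
  expect_true(all(vapply(db0, function(m) nrow(m$gsms) == 0, logical(1))))
  # absent target errors
  expect_error(select_markers("no such strain", gs, "strain"), "not in")
})

test_that("raising k never decreases the number of stretch survivors", {
  set.seed(58)
  gs <- simulate_community_genomes(2, 3, 4000, 0.06, seed = 17)
  grouping <- group_by_level(gs, "strain")
  seq <- gs$genomes[[1]]$contigs[[1]]
  counts <- vapply(c(18L, 19L, 20L), function(k) {
    idx <- build_shared_kmer_db(gs, grouping, k)
    length(strainmark:::cpp_stretch_survivors(seq, k, idx$shared, 50L))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("panel subsampling is seeded, bounded, and reproducible", {
  set.seed(59)
  gs <- simulate_community_genomes(2, 2, 3000, 0.10, seed = 19)
  db <- select_markers_all(gs, "strain", min_markers = 10)
  ms <- db[[1]]
  p1 <- subsample_panel(ms, 50, seed = 7)
  p2 <- subsample_panel(ms, 50, seed = 7)
  expect_identical(p1$gsms, p2$gsms)
  expect_false(identical(p1$gsms,
                         subsample_panel(ms, 50, seed = 8)$gsms))
  expect_true(all(p1$gsms$sequence %in% ms$gsms$sequence))
  full <- subsample_panel(ms, nrow(ms$gsms), seed = 1)
  expect_setequal(full$gsms$sequence, ms$gsms$sequence)
  expect_error(subsample_panel(ms, nrow(ms$gsms) + 1, seed = 1),
               "requested panel")
  fewer <- subsample_panel(ms, nrow(ms$gsms) + 1, seed = 1,
                           allow_fewer = TRUE)
  expect_equal(nrow(fewer$gsms), nrow(ms$gsms))
})

test_that("marker sets carry coherent location accounting and occurrence
           provenance", {
  set.seed(60)
  gs <- simulate_community_genomes(2, 2, 2500, 0.10, seed = 23)
  db <- select_markers_all(gs, "strain", min_markers = 5)
  for (ms in db) {
    expect_true(all(ms$gsms$location %in%
                      c("gene", "intergenic", "overlap", "unannotated")))
    # location classes partition the GSMs
    expect_equal(sum(table(ms$gsms$location)), nrow(ms$gsms))
    # every occurrence indexes a GSM row
    expect_true(all(ms$occurrences$candidate %in%
                      seq_len(nrow(ms$gsms))))
    # first occurrences in the GSM table appear in the occurrence list
    expect_true(all(ms$gsms$offset %in% ms$occurrences$offset))
  }
})

test_that("annotated genomes classify markers through the pipeline", {
  set.seed(61)
  seq <- random_dna(600)
  rec <- genome_record("gA", "Toyus exampleus s1", c(c1 = seq),
                       gene_intervals = data.frame(
                         contig_id = "c1", start = 100, end = 300))
  db <- select_markers_all(genome_set(list(rec)), "strain",
                           min_markers = 10)
  g <- db[[1]]$gsms
  expect_true(all(g$location[g$offset >= 100 & g$offset <= 250] ==
                    "gene"))
  expect_true(all(g$location[g$offset + 50 <= 100 | g$offset >= 300] ==
                    "intergenic"))
  expect_true(all(g$location[g$offset > 250 & g$offset < 300] ==
                    "overlap"))
  expect_equal(sort(unique(g$location)),
               c("gene", "intergenic", "overlap"))
})
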