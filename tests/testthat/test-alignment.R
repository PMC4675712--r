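sch <- scoring_scheme()

test_that("scoring scheme loads a symmetric matrix with positive diagonal", {
  expect_s3_class(sch, "scoring_scheme")
  expect_true(isTRUE(all(sch$matrix == t(sch$matrix))))
  std <- intersect(rownames(sch$matrix),
                   strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  expect_true(all(diag(sch$matrix[std, std]) > 0))
  expect_equal(sch$matrix["A", "A"], 5L)
  expect_equal(sch$matrix["W", "W"], 11L)
  expect_equal(sch$matrix["A", "T"], 0L)  # A/T off-diagonal is 0, A/V -1
})

test_that("bit scores and E-values follow the Karlin-Altschul forms", {
  unit <- scoring_scheme(lambda = log(2), K = 1)
  expect_equal(to_bit_score(30L, unit), 30)
  expect_equal(to_bit_score(0L, unit), 0)
  raws <- 1:50
  expect_true(all(diff(to_bit_score(raws, sch)) > 0))
  expect_equal(evalue(0, 1), 1)
  expect_equal(evalue(10, 102400), 100)
  expect_equal(evalue(5, 2000), 2 * evalue(5, 1000))
  # raw_score_floor is the smallest raw score reaching the bit threshold
  f <- raw_score_floor(30, sch)
  expect_gte(to_bit_score(f, sch), 30)
  expect_lt(to_bit_score(f - 1L, sch), 30)
})

test_that("self-alignment scores the diagonal sum; disjoint residues score nothing", {
  q <- "MKVLHEWRQD"
  a <- local_align(q, q, sch)
  chars <- strsplit(q, "")[[1]]
  expect_equal(a$raw_score, sum(diag(sch$matrix[chars, chars])))
  expect_equal(c(a$q_start, a$q_end), c(0L, 10L))
  expect_equal(a$n_ident, 10L)
  # A vs T scores 0 on BLOSUM90; no positive local alignment exists
  expect_equal(nrow(local_align("AAAA", "TTTT", sch)), 0L)
  expect_equal(nrow(local_align("AAAA", "VVVV", sch)), 0L)
})

test_that("engine matches an independent full-matrix DP on random pairs", {
  withr::with_seed(31, {
    for (rep in 1:200) {
      q <- rand_protein(sample(3:12, 1))
      s <- rand_protein(sample(3:12, 1))
      a <- local_align(q, s, sch)
      got <- if (nrow(a)) a$raw_score[1] else 0L
      expect_identical(got, as.integer(oracle_sw_score(q, s, sch)))
    }
  })
})

test_that("engine matches exhaustive path enumeration on tiny pairs", {
  withr::with_seed(32, {
    for (rep in 1:25) {
      q <- rand_protein(sample(2:5, 1))
      s <- rand_protein(sample(2:5, 1))
      a <- local_align(q, s, sch)
      got <- if (nrow(a)) a$raw_score[1] else 0L
      enum <- max(0L, oracle_enum_score(q, s, sch))
      expect_identical(got, as.integer(enum))
    }
  })
})

test_that("engine agrees with pairwiseAlignment local scores", {
  withr::with_seed(33, {
    for (rep in 1:25) {
      q <- rand_protein(sample(10:20, 1))
      s <- rand_protein(sample(10:20, 1))
      a <- local_align(q, s, sch)
      if (nrow(a) == 0L) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
        substitutionMatrix = sch$matrix, gapOpening = sch$gap_open,
        gapExtension = sch$gap_extend)
      expect_equal(a$raw_score[1], Biostrings::score(pa))
    }
  })
})

test_that("suboptimal alignments are query-disjoint and score-ordered", {
  core <- "MKVLHEWRQDCFYITNPW"
  q <- paste0(core, "GGGGGGGG", core)
  a <- local_align(q, core, sch, score_floor = 50L, max_alignments = 5L)
  expect_gte(nrow(a), 2L)
  expect_true(all(diff(a$raw_score) <= 0))
  ir <- IRanges::IRanges(a$q_start + 1L, a$q_end)
  expect_true(all(IRanges::countOverlaps(ir, ir) == 1L))
})

test_that("search retains, filters and caps hits deterministically", {
  db <- Biostrings::AAStringSet(c(
    T1 = "MKVLHEWRQDCFYITNPWGSARNDCQEGHILKMFPSTWYVMKVLHEWRQD",
    N1 = rand_protein(80)))
  # query translation carries an exact copy of T1 (50 residues)
  region <- data.frame(region_id = "r:0-0", chrom = "c", start = 0L,
                       end = 0L, stringsAsFactors = FALSE)
  t <- structure(list(frame_id = "r|frame1", region_id = "r", chrom = "c",
                      region_start = 0L, region_end = 300L, strand = "+",
                      frame_offset = 0L, frame_code = 1L,
                      protein = paste0(rand_protein(25),
                                       as.character(db[["T1"]]),
                                       rand_protein(25)),
                      length = 100L), class = "framed_translation")
  hits <- search_hits(t, db, sch, search_config())
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_equal(top$subject_cluster, "T1")
  expect_lte(top$q_start, 25L)
  expect_gte(top$q_end, 75L)
  expect_gte(top$bit_score, 30)

  # fully masked query yields nothing even against its own copy
  tm <- t; tm$protein <- strrep("A", 40); tm$length <- 40L
  dbm <- Biostrings::AAStringSet(c(S = strrep("A", 40)))
  expect_equal(nrow(search_hits(tm, dbm, sch, search_config())), 0L)

  # the per-query cap binds and keeps the best by bit score
  many <- Biostrings::AAStringSet(
    stats::setNames(rep(as.character(db[["T1"]]), 7), paste0("D", 1:7)))
  capped <- search_hits(t, many, sch,
                        search_config(max_hits_per_query = 5L))
  expect_equal(nrow(capped), 5L)
  full <- search_hits(t, many, sch, search_config())
  expect_equal(capped$bit_score,
               utils::head(full[order(-full$bit_score), ]$bit_score, 5L))

  # retained hit set is independent of database order
  perm <- withr::with_seed(34, sample(length(many)))
  h1 <- search_hits(t, many, sch, search_config())
  h2 <- search_hits(t, many[perm], sch, search_config())
  expect_equal(h1, h2)

  expect_error(search_hits(t, Biostrings::AAStringSet(), sch), "empty")
  dup <- Biostrings::AAStringSet(c(A = "MKVL", A = "MKVL"))
  expect_error(search_hits(t, dup, sch), "duplicate")
})

test_that("random queries rarely hit a random database at 30 bits", {
  # shuffled-translation queries vs length-matched random queries give
  # statistically indistinguishable hit counts against a random database
  withr::with_seed(35, {
    db <- Biostrings::AAStringSet(
      stats::setNames(vapply(1:30, function(i) rand_protein(120),
                             character(1)), sprintf("R%02d", 1:30)))
    mk <- function(p) structure(
      list(frame_id = "q|frame1", region_id = "q", chrom = "c",
           region_start = 0L, region_end = 3L * nchar(p), strand = "+",
           frame_offset = 0L, frame_code = 1L, protein = p,
           length = nchar(p)), class = "framed_translation")
    cfg <- search_config(bit_threshold = 20)  # permissive: count hits
    n1 <- vapply(1:50, function(i)
      nrow(search_hits(mk(rand_protein(60)), db, sch, cfg)), integer(1))
    n2 <- vapply(1:50, function(i) {
      shuf <- paste(sample(strsplit(rand_protein(60), "")[[1]]),
                    collapse = "")
      nrow(search_hits(mk(shuf), db, sch, cfg))
    }, integer(1))
    expect_gt(stats::wilcox.test(n1, n2, exact = FALSE)$p.value, 0.01)
  })
})
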