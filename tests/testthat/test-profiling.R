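test_that("profiles count distinct clusters covering each position", {
  t <- fake_translation(len = 8L)
  hits <- data.frame(query_id = t$frame_id,
                     subject_cluster = c("A", "B", "A"),
                     q_start = c(0L, 3L, 3L), q_end = c(5L, 8L, 8L),
                     stringsAsFactors = FALSE)
  p <- accumulate_profile(hits, t)
  expect_equal(p$counts, c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))

  expect_equal(accumulate_profile(hits[0, ], t)$counts, integer(8))

  # 100 overlapping HSPs of one cluster count once per position
  hsp <- data.frame(query_id = t$frame_id, subject_cluster = "A",
                    q_start = 0L, q_end = 5L)
  hsp <- hsp[rep(1, 100), ]
  expect_equal(accumulate_profile(hsp, t)$counts,
               c(rep(1L, 5), rep(0L, 3)))
  # raw-alignment switch counts every HSP
  expect_equal(accumulate_profile(hsp, t, distinct_clusters = FALSE)$counts,
               c(rep(100L, 5), rep(0L, 3)))

  bad <- data.frame(query_id = t$frame_id, subject_cluster = "A",
                    q_start = 5L, q_end = 9L)
  expect_error(accumulate_profile(bad, t), "outside")
  foreign <- hits; foreign$query_id[2] <- "other|frame1"
  expect_error(accumulate_profile(foreign, t), "foreign")
})

test_that("profiles equal the per-position brute-force recount", {
  withr::with_seed(51, {
    for (rep in 1:60) {
      len <- sample(5:60, 1)
      t <- fake_translation(len = len)
      hits <- rand_hits(t$frame_id, len, sample(0:40, 1))
      for (distinct in c(TRUE, FALSE)) {
        p <- accumulate_profile(hits, t, distinct)
        expect_identical(p$counts, oracle_profile(hits, len, distinct))
      }
    }
  })
})

test_that("peaks are maximal supra-cutoff runs with gap merging", {
  t <- fake_translation(len = 7L)
  p <- structure(list(frame_id = t$frame_id,
                      counts = c(0L, 10L, 75L, 80L, 71L, 0L, 90L)),
                 class = "anablast_profile")
  pk <- call_peaks(p, t, cutoff = 70L)
  expect_equal(pk$p_start, c(2L, 6L))
  expect_equal(pk$p_end, c(5L, 7L))
  expect_equal(pk$height, c(80L, 90L))
  expect_true(all(pk$significant))
  # genomic interval: frame 1 at region_start 0 -> 3*p
  expect_equal(pk$g_start, c(6L, 18L))
  expect_equal(pk$g_end, c(15L, 21L))

  merged <- call_peaks(p, t, cutoff = 70L, merge_gap = 1L)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$p_start, merged$p_end, merged$height),
               c(2L, 7L, 90L))

  expect_equal(nrow(call_peaks(p, t, cutoff = 95L)), 0L)
  # min_length drops short runs; strict flag excludes exact ties
  expect_equal(nrow(call_peaks(p, t, cutoff = 90L, min_length = 2L)), 0L)
  exact <- structure(list(frame_id = t$frame_id,
                          counts = c(rep(70L, 3), rep(0L, 4))),
                     class = "anablast_profile")
  expect_equal(nrow(call_peaks(exact, t, cutoff = 70L)), 1L)
  expect_equal(nrow(call_peaks(exact, t, cutoff = 70L, strict = TRUE)), 0L)
})

test_that("raising the cutoff never adds peaks nor extends any peak", {
  withr::with_seed(52, {
    for (rep in 1:40) {
      len <- sample(10:80, 1)
      t <- fake_translation(len = len)
      counts <- as.integer(round(stats::rpois(len, 3) *
                                   sample(1:30, 1) / 3))
      p <- structure(list(frame_id = t$frame_id, counts = counts),
                     class = "anablast_profile")
      cuts <- sort(sample(1:max(counts + 1L), 3))
      pks <- lapply(cuts, function(ct) call_peaks(p, t, cutoff = ct))
      for (k in 2:3) {
        lo <- IRanges::IRanges(pks[[k - 1]]$p_start + 1L,
                               pks[[k - 1]]$p_end)
        hi <- IRanges::IRanges(pks[[k]]$p_start + 1L, pks[[k]]$p_end)
        # covered positions shrink and every higher-cutoff peak lies
        # inside a lower-cutoff peak (no peak is ever extended)
        expect_lte(sum(IRanges::width(hi)), sum(IRanges::width(lo)))
        if (length(hi))
          expect_true(all(IRanges::countOverlaps(hi, lo,
                                                 type = "within") >= 1L))
      }
    }
  })
})

test_that("cutoff calibration takes the control quantile plus one", {
  expect_equal(anablastr:::cutoff_from_maxima(c(0L, 0L, 0L)), 1L)
  expect_equal(anablastr:::cutoff_from_maxima(c(10L, 40L, 69L)), 70L)
  expect_equal(anablastr:::cutoff_from_maxima(c(10L, 40L, 69L), 0.5), 41L)
  qs <- c(0.25, 0.5, 0.75, 1.0)
  withr::with_seed(53, {
    maxima <- sample(0:100, 20, TRUE)
    cuts <- vapply(qs, function(q)
      anablastr:::cutoff_from_maxima(maxima, q), integer(1))
    expect_true(all(diff(cuts) >= 0L))
  })
  # end-to-end: controls with no conceivable hit calibrate to cutoff 1
  db <- Biostrings::AAStringSet(c(Z = strrep("W", 50)))
  ctl <- data.frame(region_id = "c:0-60", chrom = "c", start = 0L,
                    end = 60L, source = "control_shuffled", origin_id = "x",
                    sequence = strrep("GCTGCA", 10),
                    stringsAsFactors = FALSE)
  expect_equal(calibrate_cutoff(ctl, db), 1L)
  expect_error(calibrate_cutoff(ctl[0, ], db), "at least one")
})

test_that("true-positive fraction compares real and shuffled counts", {
  expect_equal(estimate_true_positive_fraction(158L, 19L), 1 - 19 / 158)
  expect_gt(estimate_true_positive_fraction(158L, 19L), 0.85)
  expect_equal(estimate_true_positive_fraction(100L, 0L), 1.0)
  expect_equal(estimate_true_positive_fraction(100L, 100L), 0.0)
  expect_error(estimate_true_positive_fraction(10L, 11L), "exceeds")
  expect_error(estimate_true_positive_fraction(0L, 0L), "positive")
})

test_that("peak peptides concatenate 5'->3' with mask stripping", {
  reg <- data.frame(region_id = "c1:0-60", chrom = "c1", start = 0L,
                    end = 60L, stringsAsFactors = FALSE)
  reg$sequence <- strrep("ACGTT", 12)
  tr <- six_frame_translate(reg)
  mkpeak <- function(t, p0, p1) data.frame(
    peak_id = sprintf("%s:%d-%d", t$frame_id, p0, p1),
    frame_id = t$frame_id, frame_code = t$frame_code, strand = t$strand,
    p_start = p0, p_end = p1, height = 99L, chrom = t$chrom,
    g_start = protein_to_genomic(t, p0, p1)$start,
    g_end = protein_to_genomic(t, p0, p1)$end, significant = TRUE,
    stringsAsFactors = FALSE)

  # single peak: X characters are stripped from the peptide
  t1 <- tr$frame1
  pk <- mkpeak(t1, 0L, 10L)
  pep <- concatenate_peaks(pk, tr, "+")
  expect_equal(pep, gsub("X", "", substr(t1$protein, 1, 10)))
  expect_false(grepl("X", pep))

  # two peaks in different frames join in genomic order
  pkA <- mkpeak(tr$frame1, 0L, 4L)   # genomic [0,12)
  pkB <- mkpeak(tr$frame2, 5L, 9L)   # genomic [16,28)
  both <- rbind(pkB, pkA)            # deliberately out of order
  expect_equal(concatenate_peaks(both, tr, "+"),
               paste0(gsub("X", "", substr(tr$frame1$protein, 1, 4)),
                      gsub("X", "", substr(tr$frame2$protein, 6, 9))))

  # reverse strand: descending genomic start
  pkC <- mkpeak(tr$frame4, 0L, 4L)   # 3' end of region
  pkD <- mkpeak(tr$frame5, 10L, 14L)
  pepR <- concatenate_peaks(rbind(pkD, pkC), tr, "-")
  expect_equal(pepR,
               paste0(gsub("X", "", substr(tr$frame4$protein, 1, 4)),
                      gsub("X", "", substr(tr$frame5$protein, 11, 14))))

  # overlapping peaks are an error naming the pair
  ovl <- rbind(mkpeak(tr$frame1, 0L, 6L), mkpeak(tr$frame2, 0L, 6L))
  expect_error(concatenate_peaks(ovl, tr, "+"), "overlapping")
  # wrong-strand peaks are rejected
  expect_error(concatenate_peaks(pkC, tr, "+"), "strand")
})
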