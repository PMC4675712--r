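# Independent oracles used across the suite.  These deliberately share no
# code with the package's alignment engine or profile accumulator.

# Full-matrix affine local-alignment DP written in plain R (iterative,
# explicit matrices).  Returns the optimal raw score only.
oracle_sw_score <- function(query, subject, scheme) {
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  s <- strsplit(toupper(subject), "", fixed = TRUE)[[1]]
  res <- rownames(scheme$matrix)
  q[!q %in% res] <- "X"; s[!s %in% res] <- "X"
  m <- length(q); n <- length(s)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, E[i + 1, j] - ge)
      F[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, F[i, j + 1] - ge)
      H[i + 1, j + 1] <- max(0, H[i, j] + scheme$matrix[q[i], s[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  max(H)
}

# Exhaustive enumeration over all monotone residue matchings: every local
# alignment is a set of matched pairs (i1<...<ik, j1<...<jk) with affine
# gap runs between consecutive pairs.  Exponential; only for tiny inputs.
oracle_enum_score <- function(query, subject, scheme) {
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  s <- strsplit(toupper(subject), "", fixed = TRUE)[[1]]
  go <- scheme$gap_open; ge <- scheme$gap_extend
  gap <- function(g) if (g > 0) go + ge * g else 0
  best <- 0
  recurse <- function(i, j, score) {
    best <<- max(best, score)
    if (i > length(q) || j > length(s)) return()
    for (ii in i:length(q)) for (jj in j:length(s)) {
      sc <- scheme$matrix[q[ii], s[jj]] - gap(ii - i) - gap(jj - j)
      recurse(ii + 1L, jj + 1L, score + sc)
    }
  }
  for (i in seq_along(q)) for (j in seq_along(s))
    recurse(i, j, 0)
  best
}

# Per-position distinct-cluster recount, one position at a time.
oracle_profile <- function(hits, len, distinct = TRUE) {
  vapply(seq_len(len) - 1L, function(p) {
    cover <- hits$q_start <= p & p < hits$q_end
    if (distinct) length(unique(hits$subject_cluster[cover]))
    else sum(cover)
  }, integer(1))
}

rand_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}

rand_hits <- function(frame_id, len, n_hits, n_clusters = 5L) {
  if (n_hits == 0L)
    return(data.frame(query_id = character(), subject_cluster = character(),
                      q_start = integer(), q_end = integer()))
  qs <- sample.int(len, n_hits, replace = TRUE) - 1L
  qe <- pmin(len, qs + sample.int(max(len %/% 2L, 1L), n_hits,
                                  replace = TRUE))
  data.frame(query_id = frame_id,
             subject_cluster = paste0("C", sample.int(n_clusters, n_hits,
                                                      replace = TRUE)),
             q_start = qs, q_end = qe, stringsAsFactors = FALSE)
}

# minimal framed_translation stand-in for profile-level tests
fake_translation <- function(frame_id = "r|frame1", len = 10L,
                             region_start = 0L, frame_code = 1L) {
  structure(list(frame_id = frame_id, region_id = "r", chrom = "c",
                 region_start = region_start,
                 region_end = region_start + 3L * len +
                   (frame_code - 1L) %% 3L,
                 strand = if (frame_code <= 3L) "+" else "-",
                 frame_offset = (frame_code - 1L) %% 3L,
                 frame_code = as.integer(frame_code),
                 protein = paste(rep("A", len), collapse = ""),
                 length = as.integer(len)),
            class = "framed_translation")
}

write_gff3 <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
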