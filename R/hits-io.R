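OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Write hits in 12-column tabular search format
#'
#' The standard "outfmt 6" dialect (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`), tab-separated, with
#' 1-based inclusive coordinates, E-values in scientific notation and bit
#' scores to one decimal.
#'
#' @param hits Hit `data.frame` from [search_hits()].
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  pident <- ifelse(hits$length > 0, 100 * hits$n_ident / hits$length, 0)
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f",
                   hits$query_id, hits$subject_cluster, pident,
                   hits$length, hits$n_mismatch, hits$n_gapopen,
                   hits$q_start + 1L, hits$q_end,
                   hits$s_start + 1L, hits$s_end,
                   hits$evalue, hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}

#' Parse externally computed hits in 12-column tabular format
#'
#' Supports running the search stage at scale in an external engine
#' (query IDs must follow `<region_id>|frame<1-6>`): 1-based inclusive
#' query coordinates are converted to 0-based half-open, and the bit
#' threshold / E-value cap / per-query hit cap of `config` are applied
#' exactly as in [search_hits()], with the same deterministic ordering.
#' Lines whose query ID is not among `frame_ids` are skipped with a
#' warning; non-numeric fields are a parse error naming the line.
#'
#' @param path Tabular hit file.
#' @param frame_ids Character vector of known frame identifiers, or a
#'   (list of) `framed_translation` to take them from.
#' @param config A [search_config()].
#' @return A hit `data.frame` in the [search_hits()] schema (`raw_score`
#'   is `NA`: raw scores are not part of the tabular format).
#' @export
parse_external_hits <- function(path, frame_ids, config = search_config()) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  if (!is.character(frame_ids))
    frame_ids <- vapply(flatten_translations(frame_ids), `[[`,
                        character(1), "frame_id")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("line ", which(nf != 12L)[1], " of ", path, " has ",
         nf[nf != 12L][1], " fields (expected 12)")
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE,
              dimnames = list(NULL, OUTFMT6_COLS))
  num <- suppressWarnings(
    apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L, dimnames = list(NULL, OUTFMT6_COLS[3:12]))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop("non-numeric field on line ", bad, " of ", path)
  }
  known <- m[, "qseqid"] %in% frame_ids
  if (!all(known)) {
    warning(sum(!known), " line(s) with unknown query ID skipped (e.g. ",
            m[!known, "qseqid"][1], ")")
    m <- m[known, , drop = FALSE]
    num <- num[known, , drop = FALSE]
  }
  if (nrow(m) == 0L) return(empty_hits())
  hits <- data.frame(query_id = m[, "qseqid"],
                     subject_cluster = m[, "sseqid"],
                     q_start = as.integer(num[, "qstart"]) - 1L,
                     q_end = as.integer(num[, "qend"]),
                     s_start = as.integer(num[, "sstart"]) - 1L,
                     s_end = as.integer(num[, "send"]),
                     raw_score = NA_integer_,
                     bit_score = num[, "bitscore"],
                     evalue = num[, "evalue"],
                     length = as.integer(num[, "length"]),
                     n_ident = as.integer(round(
                       num[, "pident"] * num[, "length"] / 100)),
                     n_mismatch = as.integer(num[, "mismatch"]),
                     n_gapopen = as.integer(num[, "gapopen"]),
                     stringsAsFactors = FALSE)
  keep <- hits$bit_score >= config$bit_threshold &
    hits$evalue <= config$evalue_cap
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_hits())
  parts <- lapply(split(hits, hits$query_id), function(h) {
    h <- h[order(-h$bit_score, h$subject_cluster, h$q_start), , drop = FALSE]
    utils::head(h, config$max_hits_per_query)
  })
  res <- do.call(rbind, c(unname(parts), list(empty_hits())))
  rownames(res) <- NULL
  res
}
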