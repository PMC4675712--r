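#' Search configuration for the low-stringency alignment stage
#'
#' Defaults follow the published parameterisation of the accumulation
#' search: hits are retained from bit score 30 up to E-value 200,000, at
#' most 10,000 alignments per query, with SEG low-complexity masking of
#' the query (window 12, trigger entropy 2.2 bits, extension entropy 2.5
#' bits).
#'
#' @param bit_threshold Minimum bit score for a retained hit.
#' @param evalue_cap Maximum E-value for a retained hit.
#' @param max_hits_per_query Cap on retained hits per framed translation,
#'   best by bit score.
#' @param seg_enabled Apply SEG masking to the query.
#' @param seg_window,seg_locut,seg_hicut SEG parameters.
#' @param max_hsps_per_subject Engine bound on query-disjoint local
#'   alignments recovered per query/subject pair.
#' @return An object of class `search_config`.
#' @export
search_config <- function(bit_threshold = 30, evalue_cap = 2e5,
                          max_hits_per_query = 10000L, seg_enabled = TRUE,
                          seg_window = 12L, seg_locut = 2.2,
                          seg_hicut = 2.5, max_hsps_per_subject = 16L) {
  stopifnot(max_hits_per_query > 0L, evalue_cap > 0,
            max_hsps_per_subject > 0L)
  structure(list(bit_threshold = bit_threshold, evalue_cap = evalue_cap,
                 max_hits_per_query = as.integer(max_hits_per_query),
                 seg_enabled = isTRUE(seg_enabled),
                 seg_window = as.integer(seg_window),
                 seg_locut = seg_locut, seg_hicut = seg_hicut,
                 max_hsps_per_subject = as.integer(max_hsps_per_subject)),
            class = "search_config")
}

encode_protein <- function(protein, scheme) {
  chars <- toupper(strsplit(protein, "", fixed = TRUE)[[1]])
  idx <- match(chars, rownames(scheme$matrix))
  idx[is.na(idx)] <- match("X", rownames(scheme$matrix))
  as.integer(idx - 1L)
}

#' Local alignment of two protein sequences
#'
#' Smith--Waterman with affine gaps (the first residue of a gap costs
#' `gap_open + gap_extend`).  Returns the optimal local alignment and,
#' when `max_alignments > 1`, further query-disjoint suboptimal alignments
#' found by masking the used query residues and re-running, down to
#' `score_floor`.  `X`/`x` positions (stop masks, ambiguous codons, SEG
#' masks) score the matrix's X column.
#'
#' @param query,subject Non-empty amino-acid strings.
#' @param scheme A [scoring_scheme()].
#' @param score_floor Minimum raw score of a reported alignment.
#' @param max_alignments Maximum number of alignments per pair.
#' @return A `data.frame` with `raw_score`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open), `length`, `n_ident`, `n_mismatch`,
#'   `n_gapopen`, ordered by decreasing raw score.
#' @export
local_align <- function(query, subject, scheme, score_floor = 1L,
                        max_alignments = 1L) {
  stopifnot(nchar(query) > 0L, nchar(subject) > 0L)
  res <- sw_align_cpp(encode_protein(query, scheme),
                      encode_protein(subject, scheme),
                      scheme$matrix, scheme$gap_open, scheme$gap_extend,
                      as.integer(score_floor), as.integer(max_alignments))
  res[order(-res$raw_score, res$q_start), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_cluster = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             raw_score = integer(), bit_score = numeric(),
             evalue = numeric(), length = integer(), n_ident = integer(),
             n_mismatch = integer(), n_gapopen = integer(),
             stringsAsFactors = FALSE)
}

load_protein_db <- function(db) {
  if (is.character(db) && length(db) == 1L)
    db <- Biostrings::readAAStringSet(db)
  if (length(db) == 0L) stop("protein database is empty")
  names(db) <- sub("\\s.*$", "", names(db))
  if (anyDuplicated(names(db)))
    stop("duplicate record identifier(s) in protein database: ",
         paste(unique(names(db)[duplicated(names(db))]), collapse = ", "))
  db
}

#' Low-stringency search of framed translations against a protein database
#'
#' The engine behind self-contained runs: each (SEG-masked) framed
#' translation is aligned against every database record -- one
#' representative per cluster -- and every local alignment with bit score
#' at or above `bit_threshold` and E-value at or below `evalue_cap`
#' becomes a hit.  The effective search space for E-values is query length
#' times total database residues unless the scheme fixes it.  Hits are
#' ordered by bit score (descending), subject identifier, then query
#' start, and truncated to `max_hits_per_query`.
#'
#' @param translations A `framed_translation` or list of them (e.g. the
#'   output of [six_frame_translate()]).
#' @param db Protein FASTA path or named [Biostrings::AAStringSet]; record
#'   identifiers are cluster identifiers and must be unique.
#' @param scheme A [scoring_scheme()].
#' @param config A [search_config()].
#' @return A hit `data.frame` (see [local_align()] for coordinate
#'   conventions) with `query_id` and `subject_cluster` columns.
#' @export
search_hits <- function(translations, db, scheme = scoring_scheme(),
                        config = search_config()) {
  db <- load_protein_db(db)
  flat <- flatten_translations(translations)
  total_res <- sum(Biostrings::width(db))
  subj_enc <- lapply(as.character(db), encode_protein, scheme = scheme)
  floor <- raw_score_floor(config$bit_threshold, scheme)
  out <- lapply(flat, function(t) {
    if (t$length == 0L) return(empty_hits())
    q <- t$protein
    if (config$seg_enabled)
      q <- seg_mask(q, config$seg_window, config$seg_locut, config$seg_hicut)
    res <- sw_search_cpp(encode_protein(q, scheme), subj_enc, scheme$matrix,
                         scheme$gap_open, scheme$gap_extend, floor,
                         config$max_hsps_per_subject)
    if (nrow(res) == 0L) return(empty_hits())
    space <- if (is.null(scheme$effective_search_space))
      as.numeric(t$length) * total_res else scheme$effective_search_space
    bits <- to_bit_score(res$raw_score, scheme)
    ev <- evalue(bits, space)
    keep <- bits >= config$bit_threshold & ev <= config$evalue_cap
    res <- res[keep, , drop = FALSE]
    if (nrow(res) == 0L) return(empty_hits())
    hits <- data.frame(query_id = t$frame_id,
                       subject_cluster = names(db)[res$subject_index],
                       q_start = res$q_start, q_end = res$q_end,
                       s_start = res$s_start, s_end = res$s_end,
                       raw_score = res$raw_score,
                       bit_score = bits[keep], evalue = ev[keep],
                       length = res$length, n_ident = res$n_ident,
                       n_mismatch = res$n_mismatch,
                       n_gapopen = res$n_gapopen,
                       stringsAsFactors = FALSE)
    hits <- hits[order(-hits$bit_score, hits$subject_cluster, hits$q_start),
                 , drop = FALSE]
    utils::head(hits, config$max_hits_per_query)
  })
  res <- do.call(rbind, c(out, list(empty_hits())))
  rownames(res) <- NULL
  res
}
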