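#' Mask low-complexity protein segments (SEG-style two-pass filter)
#'
#' Windowed compositional-entropy masking in the style of the
#' Wootton--Federhen SEG filter.  A first pass finds trigger windows whose
#' Shannon entropy (bits, computed from the residue composition of a
#' sliding window) is at or below `locut`; a second pass extends each
#' triggered segment to the maximal surrounding run of positions covered
#' by windows with entropy at or below `hicut`.  Masked residues are
#' written as lowercase `x`, which the alignment engine scores with the
#' substitution matrix's X column, so masked stretches cannot seed or
#' sustain positive-scoring alignments.
#'
#' Sequences shorter than `window` are assessed as a single window.
#' Masking is idempotent: already-masked `x` residues stay masked and
#' windows containing them are not re-evaluated, so a second pass
#' reproduces the first.
#'
#' @param protein Amino-acid string (residues plus `X`).
#' @param window Window length in residues (default 12).
#' @param locut Trigger entropy in bits (default 2.2).
#' @param hicut Extension entropy in bits (default 2.5).
#' @return The input string with low-complexity residues lowercased to `x`.
#' @export
seg_mask <- function(protein, window = 12L, locut = 2.2, hicut = 2.5) {
  stopifnot(is.character(protein), length(protein) == 1L, window >= 1L)
  n <- nchar(protein)
  if (n == 0L) return(protein)
  raw <- strsplit(protein, "", fixed = TRUE)[[1]]
  pre <- raw == "x" # already masked: stays masked, not re-evaluated
  chars <- toupper(raw)
  w <- min(as.integer(window), n)
  nw <- n - w + 1L
  H <- vapply(seq_len(nw), function(i) {
    span <- i:(i + w - 1L)
    if (any(pre[span])) return(Inf)
    cnt <- table(chars[span])
    p <- cnt / w
    -sum(p * log2(p))
  }, numeric(1))
  # positions covered by >=1 window at or below each threshold
  covered <- function(thr) {
    hit <- which(H <= thr)
    pos <- logical(n)
    for (i in hit) pos[i:(i + w - 1L)] <- TRUE
    pos
  }
  core <- covered(locut)
  if (!any(core)) return(paste(raw, collapse = ""))
  cand <- covered(hicut)
  # mask maximal candidate runs that contain at least one core position
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- strsplit(protein, "", fixed = TRUE)[[1]]
  for (k in which(r$values)) {
    if (any(core[starts[k]:ends[k]])) out[starts[k]:ends[k]] <- "x"
  }
  paste(out, collapse = "")
}
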