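#' Translate a region in all six reading frames with stop masking
#'
#' Frames 1--3 read the forward sequence at offsets 0, 1, 2; frames 4--6
#' read the reverse complement at offsets 0, 1, 2 (each strand read
#' 5'->3').  The standard genetic code is used; every stop codon and every
#' codon containing an ambiguous base is rendered as a single `X`, so
#' translation length is preserved in codon units and the downstream
#' search is independent of open-reading-frame structure.  Trailing
#' partial codons are dropped.
#'
#' @param region A single region (one-row `data.frame` or list with
#'   `region_id`, `chrom`, `start`, `end`, `sequence`).
#' @return A list of six `framed_translation` objects (fields `frame_id`,
#'   `region_id`, `chrom`, `region_start`, `region_end`, `strand`,
#'   `frame_offset`, `frame_code`, `protein`, `length`), named
#'   `frame1`..`frame6`.
#' @export
six_frame_translate <- function(region) {
  region <- as.list(region)
  seq <- region$sequence
  if (nchar(seq) < 3L)
    warning("region ", region$region_id,
            " is shorter than 3 nt; translations are empty")
  dna <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(dna)
  frames <- lapply(1:6, function(code) {
    strand <- if (code <= 3L) "+" else "-"
    offset <- (code - 1L) %% 3L
    prot <- translate_frame(if (code <= 3L) dna else rc, offset)
    structure(list(frame_id = paste0(region$region_id, "|frame", code),
                   region_id = region$region_id,
                   chrom = region$chrom,
                   region_start = as.integer(region$start),
                   region_end = as.integer(region$end),
                   strand = strand,
                   frame_offset = offset,
                   frame_code = as.integer(code),
                   protein = prot,
                   length = nchar(prot)),
              class = "framed_translation")
  })
  names(frames) <- paste0("frame", 1:6)
  frames
}

translate_frame <- function(dna, offset) {
  n_codons <- (length(dna) - offset) %/% 3L
  if (n_codons < 1L) return("")
  aa <- Biostrings::translate(
    Biostrings::subseq(dna, offset + 1L, offset + 3L * n_codons),
    no.init.codon = TRUE, if.fuzzy.codon = "X")
  chartr("*", "X", as.character(aa))
}

#' @export
print.framed_translation <- function(x, ...) {
  cat(sprintf("framed translation %s (%s strand, offset %d): %d aa\n",
              x$frame_id, x$strand, x$frame_offset, x$length))
  invisible(x)
}

#' Map a protein interval of a framed translation to genome coordinates
#'
#' Forward frames: `start = region_start + frame_offset + 3*p_start`,
#' `end = region_start + frame_offset + 3*p_end`.  Reverse frames count
#' from the region's 3' end: `end = region_end - frame_offset - 3*p_start`,
#' `start = region_end - frame_offset - 3*p_end`.  All coordinates 0-based
#' half-open; residue `p` occupies exactly one codon.
#'
#' @param t A `framed_translation`.
#' @param p_start,p_end Residue interval, `0 <= p_start < p_end <= length`.
#' @return A list with `chrom`, `start`, `end`, `strand`.
#' @export
protein_to_genomic <- function(t, p_start, p_end) {
  stopifnot(p_start >= 0L, p_end > p_start, p_end <= t$length)
  if (t$strand == "+") {
    g0 <- t$region_start + t$frame_offset + 3L * p_start
    g1 <- t$region_start + t$frame_offset + 3L * p_end
  } else {
    g1 <- t$region_end - t$frame_offset - 3L * p_start
    g0 <- t$region_end - t$frame_offset - 3L * p_end
  }
  list(chrom = t$chrom, start = as.integer(g0), end = as.integer(g1),
       strand = t$strand)
}

#' Map a codon-aligned genomic interval back to protein coordinates
#'
#' Exact inverse of [protein_to_genomic()]; the interval must lie on the
#' frame's codon grid.
#'
#' @param t A `framed_translation`.
#' @param g_start,g_end Genomic interval, 0-based half-open.
#' @return A list with `p_start`, `p_end`.
#' @export
genomic_to_protein <- function(t, g_start, g_end) {
  if (t$strand == "+") {
    off0 <- g_start - t$region_start - t$frame_offset
    off1 <- g_end - t$region_start - t$frame_offset
  } else {
    off0 <- t$region_end - t$frame_offset - g_end
    off1 <- t$region_end - t$frame_offset - g_start
  }
  if (off0 %% 3L != 0L || off1 %% 3L != 0L)
    stop("interval [", g_start, ",", g_end,
         ") is not codon-aligned in frame ", t$frame_code)
  p0 <- off0 %/% 3L; p1 <- off1 %/% 3L
  stopifnot(p0 >= 0L, p1 > p0, p1 <= t$length)
  list(p_start = as.integer(p0), p_end = as.integer(p1))
}

#' Write framed translations as protein FASTA
#'
#' Record IDs follow `<region_id>|frame<1-6>`, the identifier convention
#' expected by the external-hit parser.  Empty translations are skipped.
#'
#' @param translations A list of `framed_translation` objects (possibly
#'   nested, e.g. a list of six-frame sets).
#' @param path Output FASTA file.
#' @export
write_translations_fasta <- function(translations, path) {
  flat <- flatten_translations(translations)
  flat <- flat[vapply(flat, function(t) t$length > 0L, logical(1))]
  aa <- Biostrings::AAStringSet(vapply(flat, `[[`, character(1), "protein"))
  names(aa) <- vapply(flat, `[[`, character(1), "frame_id")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

flatten_translations <- function(x) {
  if (methods::is(x, "framed_translation")) return(list(x))
  out <- list()
  for (el in x) out <- c(out, flatten_translations(el))
  out
}
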