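#' Export per-frame profiles as bedGraph tracks
#'
#' Writes one bedGraph file per frame code (1--6), track name
#' `anablast_frame<k>`, covering every region's profile in genome
#' coordinates (0-based half-open; one line per run of equal non-zero
#' counts, mapped through [protein_to_genomic()]).
#'
#' @param profiles List of `anablast_profile`s.
#' @param translations List of the matching `framed_translation`s (any
#'   nesting; matched to profiles by `frame_id`).
#' @param dir Output directory.
#' @return Character vector of the six file paths, named by frame code.
#' @export
write_profile_bedgraph <- function(profiles, translations, dir) {
  flat <- flatten_translations(translations)
  by_id <- stats::setNames(flat, vapply(flat, `[[`, character(1),
                                        "frame_id"))
  rows <- lapply(profiles, function(p) {
    t <- by_id[[p$frame_id]]
    if (is.null(t)) stop("no translation for profile ", p$frame_id)
    if (!length(p$counts)) return(NULL)
    r <- rle(p$counts)
    e <- cumsum(r$lengths); s <- e - r$lengths
    keep <- r$values > 0L
    if (!any(keep)) return(NULL)
    g <- lapply(which(keep), function(k)
      protein_to_genomic(t, s[k], e[k]))
    data.frame(frame_code = t$frame_code,
               chrom = vapply(g, `[[`, character(1), "chrom"),
               start = vapply(g, `[[`, integer(1), "start"),
               end = vapply(g, `[[`, integer(1), "end"),
               count = r$values[keep], stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, c(rows, list(data.frame(
    frame_code = integer(), chrom = character(), start = integer(),
    end = integer(), count = integer()))))
  paths <- character(6)
  for (k in 1:6) {
    path <- file.path(dir, sprintf("anablast_frame%d.bedGraph", k))
    d <- all[all$frame_code == k, , drop = FALSE]
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    con <- file(path, "w")
    writeLines(sprintf("track type=bedGraph name=\"anablast_frame%d\"", k),
               con)
    if (nrow(d))
      writeLines(sprintf("%s\t%d\t%d\t%d", d$chrom, d$start, d$end,
                         d$count), con)
    close(con)
    paths[k] <- path
  }
  stats::setNames(paths, paste0("frame", 1:6))
}

#' Write peaks as BED6
#'
#' `name` is the peak identifier, score the peak height, plus strand.
#'
#' @param peaks Peak `data.frame`.
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  o <- order(peaks$chrom, peaks$g_start)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   peaks$chrom[o], peaks$g_start[o], peaks$g_end[o],
                   peaks$peak_id[o], peaks$height[o], peaks$strand[o])
  writeLines(lines, path)
  invisible(path)
}

#' Write peaks as GFF3 `anablast_peak` features
#'
#' Coordinates are converted to GFF3's 1-based inclusive convention;
#' `frame` and `height` attributes carry the frame code and peak height.
#'
#' @param peaks Peak `data.frame`.
#' @param path Output file.
#' @export
write_peaks_gff3 <- function(peaks, path) {
  o <- order(peaks$chrom, peaks$g_start)
  attrs <- sprintf("ID=%s;frame=%d;height=%d",
                   gff3_escape(peaks$peak_id[o]), peaks$frame_code[o],
                   peaks$height[o])
  lines <- sprintf("%s\tanablastr\tanablast_peak\t%d\t%d\t%d\t%s\t.\t%s",
                   peaks$chrom[o], peaks$g_start[o] + 1L, peaks$g_end[o],
                   peaks$height[o], peaks$strand[o], attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}
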