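#' Load a genome from FASTA
#'
#' Reads all records, normalises sequences to uppercase (a property of the
#' `DNAStringSet` container) and truncates record names at the first
#' whitespace.  Duplicate identifiers are fatal.
#'
#' @param genome_file Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
load_genome <- function(genome_file) {
  if (!file.exists(genome_file)) stop("genome file not found: ", genome_file)
  first <- readLines(genome_file, n = 50L)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) && !startsWith(trimws(first[nonblank[1]]), ">"))
    stop("malformed FASTA: line ", nonblank[1], " of ", genome_file,
         " does not start a record")
  genome <- tryCatch(Biostrings::readDNAStringSet(genome_file),
                     error = function(e)
                       stop("malformed FASTA in ", genome_file, ": ",
                            conditionMessage(e)))
  names(genome) <- sub("\\s.*$", "", names(genome))
  dup <- names(genome)[duplicated(names(genome))]
  if (length(dup))
    stop("duplicate sequence identifier(s) in ", genome_file, ": ",
         paste(unique(dup), collapse = ", "))
  genome
}

empty_regions <- function() {
  data.frame(region_id = character(), chrom = character(),
             start = integer(), end = integer(),
             source = character(), origin_id = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

region_row <- function(chrom, start, end, source, sequence, origin_id = "") {
  data.frame(region_id = sprintf("%s:%d-%d", chrom, start, end),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             source = source, origin_id = origin_id,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Extract inter-exon regions from a genome annotation
#'
#' Scans every gap between two consecutive annotated exons, the substrate
#' of the accumulation-profile search.  Exon intervals are merged across
#' genes and strands before gap computation so overlapping annotations are
#' never scanned twice.  A gap fully contained within the exon span of a
#' single transcript (GFF3 `Parent` attribute) is labelled `intron`,
#' anything else `intergenic`.  Zero-length gaps are skipped.  Chromosome
#' termini (before the first exon, after the last) are excluded unless
#' `include_termini = TRUE`, in which case they are added as intergenic.
#'
#' All returned coordinates are 0-based half-open.
#'
#' @param annotation Path to a GFF3 file with `exon` features (1-based
#'   inclusive coordinates), or a [GenomicRanges::GRanges] already holding
#'   them (metadata columns `type` and `Parent`).
#' @param genome A [Biostrings::DNAStringSet] from [load_genome()].
#' @param include_termini Also emit the terminal gaps as intergenic.
#' @return A `data.frame` with columns `region_id`, `chrom`, `start`,
#'   `end`, `source`, `origin_id`, `sequence`.
#' @export
extract_inter_exon_regions <- function(annotation, genome,
                                       include_termini = FALSE) {
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation, format = "gff3")
  } else annotation
  type <- as.character(gr$type)
  ex <- gr[!is.na(type) & tolower(type) == "exon"]
  if (length(ex) == 0L) {
    warning("annotation has no exon features; no regions extracted")
    return(empty_regions())
  }
  chroms <- as.character(GenomicRanges::seqnames(ex))
  bad <- setdiff(unique(chroms), names(genome))
  if (length(bad))
    stop("exon(s) on sequence(s) absent from the genome: ",
         paste(bad, collapse = ", "))
  lens <- Biostrings::width(genome)[match(chroms, names(genome))]
  if (any(GenomicRanges::start(ex) < 1L) || any(GenomicRanges::end(ex) > lens))
    stop("exon outside chromosome bounds")

  # transcript spans (0-based half-open) for intron labelling
  parents <- gr_parents(ex)
  span <- NULL
  if (nrow(parents)) {
    sp <- split(seq_len(nrow(parents)), parents$parent)
    span <- do.call(rbind, lapply(names(sp), function(p) {
      i <- sp[[p]]
      data.frame(chrom = parents$chrom[i[1]],
                 start = min(parents$start[i]) - 1L,
                 end = max(parents$end[i]),
                 stringsAsFactors = FALSE)
    }))
  }

  out <- lapply(names(genome), function(chr) {
    exc <- IRanges::ranges(ex[chroms == chr])
    if (length(exc) == 0L) return(empty_regions())
    merged <- IRanges::reduce(exc)
    chrlen <- Biostrings::width(genome)[names(genome) == chr]
    s1 <- GenomicRanges::start(merged); e1 <- GenomicRanges::end(merged)
    gaps0 <- data.frame(start = e1[-length(e1)], end = s1[-1] - 1L)
    if (include_termini) {
      gaps0 <- rbind(data.frame(start = 0L, end = s1[1] - 1L), gaps0,
                     data.frame(start = e1[length(e1)], end = chrlen))
      term <- c(TRUE, rep(FALSE, nrow(gaps0) - 2L), TRUE)
    } else term <- rep(FALSE, nrow(gaps0))
    keep <- gaps0$end > gaps0$start
    gaps0 <- gaps0[keep, , drop = FALSE]; term <- term[keep]
    if (nrow(gaps0) == 0L) return(empty_regions())
    src <- vapply(seq_len(nrow(gaps0)), function(i) {
      if (term[i]) return("intergenic")
      if (!is.null(span) &&
          any(span$chrom == chr & span$start <= gaps0$start[i] &
              gaps0$end[i] <= span$end)) "intron" else "intergenic"
    }, character(1))
    seqs <- vapply(seq_len(nrow(gaps0)), function(i)
      as.character(Biostrings::subseq(genome[[chr]], gaps0$start[i] + 1L,
                                      gaps0$end[i])), character(1))
    do.call(rbind, lapply(seq_len(nrow(gaps0)), function(i)
      region_row(chr, gaps0$start[i], gaps0$end[i], src[i], seqs[i])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one row per (exon, parent) pair, 1-based exon coordinates
gr_parents <- function(ex) {
  p <- ex$Parent
  if (is.null(p)) return(data.frame(parent = character(), chrom = character(),
                                    start = integer(), end = integer()))
  if (methods::is(p, "List")) {
    idx <- rep(seq_along(ex), lengths(p))
    parent <- unlist(p, use.names = FALSE)
  } else {
    idx <- seq_along(ex); parent <- as.character(p)
  }
  keep <- !is.na(parent) & nzchar(parent)
  data.frame(parent = parent[keep],
             chrom = as.character(GenomicRanges::seqnames(ex))[idx][keep],
             start = GenomicRanges::start(ex)[idx][keep],
             end = GenomicRanges::end(ex)[idx][keep],
             stringsAsFactors = FALSE)
}

#' Shuffle region sequences into null controls
#'
#' Each region's nucleotides are uniformly permuted (composition and length
#' preserved exactly), producing the shuffled-sequence negative controls
#' used to calibrate the peak cutoff.  Deterministic given `seed`; row `i`
#' of a multi-row input uses `seed + i - 1`.
#'
#' @param regions Region `data.frame` (one or more rows).
#' @param seed Integer seed.
#' @return Regions with `source = "control_shuffled"`, the same
#'   coordinates, and `origin_id` pointing at the source region.
#' @export
shuffle_region <- function(regions, seed) {
  stopifnot(nrow(regions) >= 1L, all(nchar(regions$sequence) > 0L))
  out <- regions
  for (i in seq_len(nrow(regions))) {
    s <- as.integer(seed) + i - 1L
    chars <- strsplit(regions$sequence[i], "", fixed = TRUE)[[1]]
    out$sequence[i] <- withr::with_seed(s,
      paste(sample(chars), collapse = ""))
    out$origin_id[i] <- regions$region_id[i]
    out$region_id[i] <- paste0(regions$region_id[i], "|shuf", s)
  }
  out$source <- "control_shuffled"
  out
}

#' Reverse region sequences (3'->5' character reversal) into null controls
#'
#' The reversed sequence (not the reverse complement) has no biological
#' meaning as coding DNA and serves as a second negative control.
#'
#' @param regions Region `data.frame`.
#' @return Regions with `source = "control_reversed"`.
#' @export
reverse_region <- function(regions) {
  stopifnot(nrow(regions) >= 1L)
  out <- regions
  out$sequence <- vapply(regions$sequence, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
  out$origin_id <- regions$region_id
  out$region_id <- paste0(regions$region_id, "|rev")
  out$source <- "control_reversed"
  out
}

#' Write regions as BED6
#'
#' `name` carries the region source label, score is 0, strand is `.`
#' (regions are unstranded).  BED is natively 0-based half-open, matching
#' the package's coordinate convention.
#'
#' @param regions Region `data.frame`.
#' @param path Output file.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start, regions$end,
                   regions$source, 0L, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
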