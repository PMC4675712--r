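#' Generate a clustered synthetic protein database
#'
#' Emits one representative record per cluster, organised into families
#' that share exact conserved blocks embedded in divergent random flanks.
#' A query related to one family therefore accrues alignments from many
#' distinct clusters -- the minimal generator of the accumulated-alignment
#' signal that the positional profile detects.
#'
#' @param n_clusters Number of records (one per cluster).
#' @param n_families Number of families the clusters are divided into.
#' @param length_range Two-element integer range of record lengths.
#' @param block_length Length of each conserved family block.
#' @param n_blocks Conserved blocks per family.
#' @param seed Integer seed; output is fully deterministic.
#' @param fasta Optional path: write the database as FASTA.
#' @return A list with `proteins` (named [Biostrings::AAStringSet],
#'   cluster IDs `C0001`...) and `families` (`data.frame` of `cluster_id`,
#'   `family_id`).
#' @export
generate_protein_db <- function(n_clusters = 200L, n_families = 20L,
                                length_range = c(120L, 200L),
                                block_length = 18L, n_blocks = 2L,
                                seed = 1L, fasta = NULL) {
  stopifnot(n_clusters >= 1L, n_families >= 1L, n_families <= n_clusters,
            length_range[1] %/% n_blocks >= block_length)
  res <- withr::with_seed(as.integer(seed), {
    fam_of <- rep(seq_len(n_families), length.out = n_clusters)
    fam_of <- sort(fam_of)
    blocks <- lapply(seq_len(n_families), function(f)
      vapply(seq_len(n_blocks), function(b) rand_peptide(block_length),
             character(1)))
    # blocks keep their order and approximate spacing across members:
    # block b falls inside the b-th of n_blocks equal segments
    seqs <- vapply(seq_len(n_clusters), function(i) {
      len <- sample(length_range[1]:length_range[2], 1L)
      bl <- blocks[[fam_of[i]]]
      seg <- len %/% n_blocks
      starts <- vapply(seq_len(n_blocks), function(b) {
        lo <- (b - 1L) * seg
        hi <- b * seg - block_length
        lo + sample.int(hi - lo + 1L, 1L) - 1L
      }, integer(1))
      pieces <- character(0); pos <- 0L
      for (b in seq_len(n_blocks)) {
        pieces <- c(pieces, rand_peptide(starts[b] - pos), bl[b])
        pos <- starts[b] + block_length
      }
      paste0(paste(pieces, collapse = ""), rand_peptide(len - pos))
    }, character(1))
    list(seqs = seqs, fam_of = fam_of)
  })
  proteins <- Biostrings::AAStringSet(res$seqs)
  names(proteins) <- sprintf("C%04d", seq_len(n_clusters))
  if (!is.null(fasta)) Biostrings::writeXStringSet(proteins, fasta)
  list(proteins = proteins,
       families = data.frame(cluster_id = names(proteins),
                             family_id = sprintf("F%03d", res$fam_of),
                             stringsAsFactors = FALSE))
}

rand_peptide <- function(n) {
  if (n <= 0L) return("")
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Specify a coding implant for the synthetic genome
#'
#' @param kind One of `intact_gene`, `pseudogene_stops`,
#'   `pseudogene_frameshift`, `terminal_subtraction`, `foreign_fragment`.
#' @param source_protein Database cluster ID the implant derives from.
#' @param divergence Fraction of residues substituted before
#'   back-translation (default 0.2, below the 0.5 ceiling).
#' @param n_stops Stop codons injected (`pseudogene_stops`).
#' @param n_frameshifts Single-nucleotide insertions injected
#'   (`pseudogene_frameshift`).
#' @param frame Reading frame 1--6 the implant is placed in.
#' @return One-row `data.frame`.
#' @export
implant_spec <- function(kind = c("intact_gene", "pseudogene_stops",
                                  "pseudogene_frameshift",
                                  "terminal_subtraction",
                                  "foreign_fragment"),
                         source_protein, divergence = 0.2,
                         n_stops = 0L, n_frameshifts = 0L, frame = 1L) {
  kind <- match.arg(kind)
  stopifnot(divergence >= 0, divergence < 1, frame %in% 1:6)
  data.frame(kind = kind, source_protein = source_protein,
             divergence = divergence, n_stops = as.integer(n_stops),
             n_frameshifts = as.integer(n_frameshifts),
             frame = as.integer(frame), stringsAsFactors = FALSE)
}

#' Generate a synthetic genome with planted coding implants
#'
#' Builds a single synthetic chromosome of i.i.d. background DNA at the
#' stated GC content in which each implant back-translates its (mutated)
#' source protein into the requested reading frame, each hosted in its
#' own inter-exon region between dummy single-exon genes.  Pseudogene
#' kinds inject stop codons or +1 frameshifts; subtraction/fragment kinds
#' implant a truncated or internal piece of the source protein.
#' Synonymous codons are drawn uniformly (no codon-bias model: the search
#' operates at the protein level).
#'
#' @param implants `data.frame` of [implant_spec()] rows.
#' @param db Database from [generate_protein_db()].
#' @param flank Background nucleotides on each side of an implant within
#'   its region.
#' @param exon_length Length of the dummy exons separating regions.
#' @param gc Background GC fraction (default 0.36, a yeast-like genome).
#' @param seed Integer seed.
#' @param dir Optional directory: write `genome.fa`, `annotation.gff3`
#'   and `truth.bed`.
#' @return A list with `genome` (DNAStringSet), `annotation` (GRanges of
#'   exon features), `truth` (`data.frame`: implant intervals in 0-based
#'   half-open coordinates with strand, expected `frame_code`, `kind`,
#'   `source_protein`, the implanted `protein`, and the host region
#'   bounds), and `paths` when `dir` is given.
#' @export
generate_genome_with_implants <- function(implants, db, flank = 150L,
                                          exon_length = 90L, gc = 0.36,
                                          seed = 1L, dir = NULL) {
  stopifnot(nrow(implants) >= 1L,
            all(implants$source_protein %in% names(db$proteins)))
  chrom <- "synthchr"
  syn <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  stops <- syn[["*"]]
  res <- withr::with_seed(as.integer(seed), {
    parts <- character(0); cursor <- 0L
    exons <- list(); truth <- list()
    for (i in seq_len(nrow(implants))) {
      sp <- implants[i, ]
      prot <- as.character(db$proteins[[sp$source_protein]])
      prot <- switch(sp$kind,
        terminal_subtraction = substr(prot, 1L,
                                      ceiling(0.65 * nchar(prot))),
        foreign_fragment = substr(prot, floor(0.25 * nchar(prot)) + 1L,
                                  floor(0.75 * nchar(prot))),
        prot)
      prot <- mutate_protein(prot, sp$divergence)
      codons <- vapply(strsplit(prot, "", fixed = TRUE)[[1]],
                       function(a) sample(syn[[a]], 1L), character(1),
                       USE.NAMES = FALSE)
      if (sp$kind == "pseudogene_stops" && sp$n_stops > 0L) {
        at <- sample(2:(length(codons) - 1L), sp$n_stops)
        codons[at] <- sample(stops, sp$n_stops, replace = TRUE)
      }
      dna <- paste(codons, collapse = "")
      if (sp$kind == "pseudogene_frameshift" && sp$n_frameshifts > 0L) {
        # insertions at evenly spaced codon boundaries, so every
        # between-shift segment keeps part of the conserved signal
        at <- vapply(seq_len(sp$n_frameshifts), function(k) {
          b <- as.integer(round(nchar(dna) * k /
                                  (sp$n_frameshifts + 1L) / 3)) * 3L
          min(max(b, 3L), nchar(dna) - 3L)
        }, integer(1))
        for (k in rev(seq_along(at)))
          dna <- paste0(substr(dna, 1L, at[k]),
                        sample(c("A", "C", "G", "T"), 1L),
                        substr(dna, at[k] + 1L, nchar(dna)))
      }
      strand <- if (sp$frame <= 3L) "+" else "-"
      if (strand == "-")
        dna <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(dna)))
      offset <- (sp$frame - 1L) %% 3L
      adj <- (offset - flank) %% 3L
      pad_left <- flank + if (strand == "+") adj else 0L
      pad_right <- flank + if (strand == "-") adj else 0L
      # dummy exon, then the inter-exon region hosting the implant
      exons[[length(exons) + 1L]] <-
        c(start = cursor, end = cursor + exon_length)
      parts <- c(parts, rand_dna(exon_length, gc))
      rs <- cursor + exon_length
      ts <- rs + pad_left
      te <- ts + nchar(dna)
      re <- te + pad_right
      parts <- c(parts, rand_dna(pad_left, gc), dna,
                 rand_dna(pad_right, gc))
      cursor <- re
      truth[[i]] <- data.frame(
        chrom = chrom, start = ts, end = te,
        name = sprintf("implant%02d", i), score = 0L, strand = strand,
        frame_code = sp$frame, kind = sp$kind,
        source_protein = sp$source_protein, protein = prot,
        region_start = rs, region_end = re, stringsAsFactors = FALSE)
    }
    exons[[length(exons) + 1L]] <-
      c(start = cursor, end = cursor + exon_length)
    parts <- c(parts, rand_dna(exon_length, gc))
    list(seq = paste(parts, collapse = ""),
         exons = do.call(rbind, exons), truth = do.call(rbind, truth))
  })
  genome <- Biostrings::DNAStringSet(stats::setNames(res$seq, chrom))
  nex <- nrow(res$exons)
  annotation <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(res$exons[, "start"] + 1L, res$exons[, "end"]),
    strand = "+", type = "exon",
    ID = sprintf("exon%03d", seq_len(nex)),
    Parent = sprintf("gene%03d.t1", seq_len(nex)))
  out <- list(genome = genome, annotation = annotation, truth = res$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
               annotation = file.path(dir, "annotation.gff3"),
               truth = file.path(dir, "truth.bed"))
    Biostrings::writeXStringSet(genome, paths["genome"])
    writeLines(c("##gff-version 3", sprintf(
      "%s\tanablastr\texon\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
      chrom, res$exons[, "start"] + 1L, res$exons[, "end"],
      annotation$ID, annotation$Parent)), paths["annotation"])
    utils::write.table(
      res$truth[, c("chrom", "start", "end", "name", "score", "strand")],
      paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    out$paths <- paths
  }
  out
}

mutate_protein <- function(prot, divergence) {
  if (divergence <= 0) return(prot)
  chars <- strsplit(prot, "", fixed = TRUE)[[1]]
  k <- floor(divergence * length(chars))
  if (k < 1L) return(prot)
  at <- sample(length(chars), k)
  chars[at] <- vapply(chars[at], function(a)
    sample(setdiff(AA_STANDARD, a), 1L), character(1))
  paste(chars, collapse = "")
}

#' Evaluate peak calls against implanted truth intervals
#'
#' An implant counts as detected when at least one significant peak
#' overlaps its truth interval by >= 1 bp on the correct strand (and in
#' the expected frame when `check_frame = TRUE`).  A false peak is a
#' significant peak overlapping no truth interval on either strand.
#'
#' @param peaks Peak `data.frame` from [call_peaks()].
#' @param truth Truth `data.frame` (columns `chrom`, `start`, `end`,
#'   `strand`, optionally `frame_code`) as produced by
#'   [generate_genome_with_implants()], or a BED-like frame.
#' @param check_frame Require the peak's frame code to match the truth
#'   `frame_code`.
#' @return A list with `sensitivity`, `specificity` (`NA` when there are
#'   no peaks), `n_false_peaks`, and the per-implant `table`.
#' @export
evaluate_detection <- function(peaks, truth, check_frame = FALSE) {
  det <- logical(nrow(truth)); best <- rep(NA_character_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ok <- peaks$chrom == truth$chrom[i] &
      peaks$strand == truth$strand[i] &
      peaks$g_start < truth$end[i] & peaks$g_end > truth$start[i]
    if (check_frame) ok <- ok & peaks$frame_code == truth$frame_code[i]
    det[i] <- any(ok)
    if (det[i]) best[i] <- peaks$peak_id[which(ok)[1]]
  }
  false_peak <- if (nrow(peaks)) vapply(seq_len(nrow(peaks)), function(j)
    !any(peaks$chrom[j] == truth$chrom &
           peaks$g_start[j] < truth$end &
           peaks$g_end[j] > truth$start), logical(1)) else logical(0)
  list(sensitivity = if (nrow(truth)) mean(det) else NA_real_,
       specificity = if (nrow(peaks)) 1 - sum(false_peak) / nrow(peaks)
                     else NA_real_,
       n_false_peaks = sum(false_peak),
       table = cbind(truth, detected = det, peak_id = best))
}
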