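#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix layout used by NCBI BLAST and
#' related tools: a header row of residue one-letter codes followed by one
#' labelled row per residue.  Comment lines starting with `#` are ignored.
#'
#' @param path Path to a matrix file (e.g. the BLOSUM90 table shipped in
#'   `system.file("extdata", "BLOSUM90.txt", package = "anablastr")`).
#' @return An integer matrix with residue row/column names.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop("substitution matrix file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#", header = TRUE,
                           row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  colnames(m) <- rownames(m) # header may mangle '*'; rows are authoritative
  if (!identical(rownames(m), colnames(m)) || nrow(m) != ncol(m))
    stop("substitution matrix is not square")
  m
}

#' Construct a scoring scheme for low-stringency protein alignment
#'
#' Bundles the substitution matrix, affine gap penalties and the gapped
#' Karlin--Altschul parameters used to convert raw alignment scores into
#' bit scores and E-values.  The defaults are BLOSUM90 with gap open 10 /
#' gap extend 1 and the published gapped parameters for that exact scheme
#' (lambda = 0.290, K = 0.075, as reported by NCBI BLAST+).  BLOSUM90 is
#' chosen to favour short, high-identity alignments -- the "ancient
#' footprint" signal the accumulation profile is built from.
#'
#' @param matrix_name Name of a matrix file (without extension) shipped in
#'   the package's `extdata` directory; ignored when `matrix` is given.
#' @param matrix Optional integer substitution matrix with residue
#'   row/column names including `X`.
#' @param gap_open,gap_extend Positive integer penalties; the first residue
#'   of a gap costs `gap_open + gap_extend`, each further residue
#'   `gap_extend`.
#' @param lambda,K Gapped Karlin--Altschul scale and constant for the
#'   chosen matrix/gap combination.
#' @param effective_search_space Optional fixed search space m*n for
#'   E-values; by default it is computed per query as query length times
#'   total database residues.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM90", matrix = NULL,
                           gap_open = 10L, gap_extend = 1L,
                           lambda = 0.290, K = 0.075,
                           effective_search_space = NULL) {
  if (is.null(matrix)) {
    path <- system.file("extdata", paste0(matrix_name, ".txt"),
                        package = "anablastr")
    if (!nzchar(path))
      stop("no bundled matrix named '", matrix_name,
           "'; supply `matrix` directly")
    matrix <- read_substitution_matrix(path)
  }
  if (!"X" %in% rownames(matrix)) stop("matrix must include an X column")
  if (!isTRUE(all(matrix == t(matrix)))) stop("matrix must be symmetric")
  std <- intersect(rownames(matrix), AA_STANDARD)
  if (any(diag(matrix[std, std, drop = FALSE]) <= 0L))
    stop("diagonal entries for standard residues must be positive")
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  if (!is.null(effective_search_space))
    stopifnot(effective_search_space > 0)
  structure(list(matrix_name = matrix_name, matrix = matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K,
                 effective_search_space = effective_search_space),
            class = "scoring_scheme")
}

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring scheme:", x$matrix_name,
      sprintf("(gap %d/%d, lambda %.3f, K %.3f)\n",
              x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

#' Convert a raw alignment score to bits
#'
#' `bits = (lambda * raw - ln K) / ln 2` under the scheme's gapped
#' Karlin--Altschul parameters; bit scores are comparable across scoring
#' schemes and are the unit in which the hit-retention threshold is set.
#'
#' @param raw_score Integer raw score(s).
#' @param scheme A [scoring_scheme()].
#' @return Numeric bit score(s).
#' @export
to_bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Smallest raw score reaching a bit-score threshold
#'
#' @param bits Bit-score threshold.
#' @param scheme A [scoring_scheme()].
#' @return Integer raw score floor.
#' @export
raw_score_floor <- function(bits, scheme) {
  as.integer(ceiling((bits * log(2) + log(scheme$K)) / scheme$lambda))
}

#' E-value of a bit score
#'
#' `E = m * n * 2^(-bits)` where `m * n` is the effective search space.
#'
#' @param bits Bit score(s).
#' @param effective_search_space Positive search space m*n.
#' @return Expected chance hit count(s).
#' @export
evalue <- function(bits, effective_search_space) {
  stopifnot(all(is.finite(bits)), effective_search_space > 0)
  effective_search_space * 2^(-bits)
}
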