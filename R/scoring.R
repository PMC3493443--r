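# Substitution-matrix handling and Karlin-Altschul statistics.

#' Create a protein scoring scheme
#'
#' Bundles a substitution matrix, affine gap penalties and the Karlin-Altschul
#' parameters used to convert raw alignment scores to bit scores and E-values
#' (`bits = (lambda * S - ln K) / ln 2`; `E = m * n * 2^-bits`).
#'
#' The default is the published BLOSUM62 matrix (from Biostrings) with gap
#' open/extend 11/1 and the published gapped-BLOSUM62 constants
#' `lambda = 0.267`, `K = 0.041` -- the defaults of protein BLAST searches.
#' Selenocysteine (`U`) is scored like cysteine.
#'
#' @param matrix_name Label for the matrix (default `"BLOSUM62"`). Only
#'   BLOSUM62 is bundled; use [read_score_matrix()] for others.
#' @param scores Optional integer substitution matrix with residue dimnames;
#'   overrides `matrix_name`.
#' @param gap_open,gap_extend Positive integers; the first residue of a gap
#'   costs `gap_open + gap_extend`, each further residue `gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (positive reals).
#' @return An object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$scores["A", "A"]  # 4
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", scores = NULL,
                           gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(scores)) {
    if (matrix_name != "BLOSUM62")
      stop("only BLOSUM62 is bundled; pass 'scores' or use read_score_matrix()")
    scores <- blosum62_extended()
  }
  if (!isTRUE(all.equal(scores, t(scores))))
    stop("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (gap_extend <= 0L || gap_open < gap_extend)
    stop("gap penalties must satisfy gap_open >= gap_extend > 0")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix_name = matrix_name, scores = scores,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

# BLOSUM62 with a U row/column copied from C (selenocysteine convention).
blosum62_extended <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- setdiff(rownames(m), "*")
  m <- m[keep, keep]
  m <- cbind(m, U = m[, "C"])
  m <- rbind(m, U = c(m["C", keep], m["C", "C"]))
  storage.mode(m) <- "integer"
  m
}

#' Default global-alignment scheme
#'
#' Global (domain-vs-domain) identity alignments use gentler gap penalties
#' (open 10, extend 1) than the local search scheme.
#' @return A `scoring_scheme`.
#' @export
global_scheme <- function() scoring_scheme(gap_open = 10L, gap_extend = 1L)

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-separated matrix layout used by NCBI BLAST
#' matrix files (`#` comment lines, one header row of residue letters, one
#' labeled row per residue).
#'
#' @param path Path to a matrix file.
#' @return An integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path)
  cols <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[`, character(1L), 1L)
  vals <- t(vapply(body, function(x) as.integer(x[-1L]),
                   integer(length(cols))))
  dimnames(vals) <- list(rows, cols)
  vals
}

#' Bit score from a raw alignment score
#'
#' `bits = (lambda * S - ln K) / ln 2` under the scheme's Karlin-Altschul
#' parameters.
#' @param raw_score Raw alignment score (matrix units).
#' @param scheme A [scoring_scheme].
#' @return Bit score (real).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' E-value for a bit score in a search of given size
#'
#' `E = m * n * 2^-bits`: the expected number of chance hits at or above the
#' score in a search of a length-`m` query against `n` database residues.
#'
#' @param bits Bit score.
#' @param m Query length (residues), positive.
#' @param n Database length (total residues), positive.
#' @return Non-negative real.
#' @examples
#' evalue(20, 100, 1e6)  # 1e8 * 2^-20 = 95.367...
#' @export
evalue <- function(bits, m, n) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  as.numeric(m) * as.numeric(n) * 2^(-bits)
}
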