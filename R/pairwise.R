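# Pairwise protein alignment: affine-gap local (Smith-Waterman) and global
# (Needleman-Wunsch) alignment, percent identity, and the E-value-filtered
# database search that stands in for a BLASTP run at desk scale.
# The dynamic programming itself is delegated to Biostrings::pairwiseAlignment.

as_record <- function(x) {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L) {
    nm <- names(x); if (is.null(nm)) nm <- "seq"
    return(seq_record(nm, x))
  }
  stop("expected a seq_record or a single named character string")
}

alignment_result <- function(mode, aligned_a, aligned_b, raw_score, scheme,
                             a_span, b_span) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  n_columns <- nchar(aligned_a)
  if (n_columns > 0L) {
    ca <- strsplit(aligned_a, "")[[1L]]; cb <- strsplit(aligned_b, "")[[1L]]
    if (any(ca == "-" & cb == "-")) stop("internal: gap/gap column")
    n_identical <- sum(ca == cb & ca != "-")
  } else n_identical <- 0L
  structure(list(mode = mode, aligned_a = aligned_a, aligned_b = aligned_b,
                 raw_score = raw_score,
                 bit_score = bit_score(raw_score, scheme),
                 n_identical = as.integer(n_identical),
                 n_columns = as.integer(n_columns),
                 a_span = as.integer(a_span), b_span = as.integer(b_span)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment: score %d (%.1f bits), %d/%d identical (%.1f%%)\n",
              x$mode, x$raw_score, x$bit_score, x$n_identical, x$n_columns,
              if (x$n_columns) 100 * x$n_identical / x$n_columns else 0))
  invisible(x)
}

pairwise_align <- function(a, b, scheme, type) {
  a <- as_record(a); b <- as_record(b)
  if (!nzchar(a$residues) || !nzchar(b$residues)) {
    if (type == "global") stop("cannot globally align an empty sequence")
    return(alignment_result("local", "", "", 0L, scheme,
                            c(0L, -1L), c(0L, -1L)))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a$residues), Biostrings::BString(b$residues),
    type = if (type == "local") "local" else "global",
    substitutionMatrix = scheme$scores,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = FALSE)
  sc <- as.integer(round(Biostrings::score(aln)))
  if (type == "local" && sc <= 0L)
    return(alignment_result("local", "", "", 0L, scheme,
                            c(0L, -1L), c(0L, -1L)))
  pa <- Biostrings::alignedPattern(aln)
  pb <- Biostrings::alignedSubject(aln)
  alignment_result(
    if (type == "local") "local" else "global",
    as.character(pa), as.character(pb), sc, scheme,
    c(Biostrings::start(Biostrings::pattern(aln)),
      Biostrings::end(Biostrings::pattern(aln))),
    c(Biostrings::start(Biostrings::subject(aln)),
      Biostrings::end(Biostrings::subject(aln))))
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' @param a,b [seq_record] objects (or single named strings).
#' @param scheme A [scoring_scheme]; default BLOSUM62, gaps 11/1.
#' @return An `alignment_result` with elements `mode`, `aligned_a`,
#'   `aligned_b`, `raw_score`, `bit_score`, `n_identical`, `n_columns`,
#'   `a_span`, `b_span` (1-based inclusive). An empty sequence (or a pair with
#'   no positive-scoring alignment) yields an empty alignment with score 0.
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme())
  pairwise_align(a, b, scheme, "local")

#' Optimal global alignment (Needleman-Wunsch, affine gaps, end gaps charged)
#'
#' @inheritParams smith_waterman
#' @return An `alignment_result` (see [smith_waterman()]); `raw_score` may be
#'   negative. Aligning an empty sequence is an error.
#' @export
needleman_wunsch <- function(a, b, scheme = global_scheme())
  pairwise_align(a, b, scheme, "global")

#' Percent identity of an alignment
#'
#' The denominator is all alignment columns, internal and terminal gap columns
#' included.
#'
#' @param aln An `alignment_result` (or anything with `n_identical` and
#'   `n_columns`).
#' @return A length-2 named numeric: `pident` to one decimal and `rounded`
#'   (nearest integer).
#' @export
percent_identity <- function(aln) {
  if (is.null(aln$n_columns) || aln$n_columns == 0L)
    stop("empty alignment has no percent identity")
  p <- 100 * aln$n_identical / aln$n_columns
  c(pident = round(p, 1L), rounded = round(p))
}

#' Search a protein database with one query
#'
#' Aligns the query locally against every database record, converts raw scores
#' to bit scores and E-values (search space = query length times total
#' database residues), and keeps hits with `E < threshold`, sorted by
#' ascending E-value, then descending bit score, then subject id.
#'
#' @param query A [seq_record].
#' @param database List of [seq_record] (non-empty).
#' @param scheme A [scoring_scheme].
#' @param threshold E-value cutoff (default `1e-2`, the classic
#'   potential-ortholog filter).
#' @return A data.frame with columns `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `evalue`, `pident`, `length`, and a `alignments` attribute
#'   holding the `alignment_result` list (named by subject id).
#' @export
search_database <- function(query, database, scheme = scoring_scheme(),
                            threshold = 1e-2) {
  query <- as_record(query)
  if (length(database) == 0L) stop("empty database")
  n_db <- sum(vapply(database, function(r) nchar(r$residues), numeric(1L)))
  m <- nchar(query$residues)
  alns <- lapply(database, function(subj) smith_waterman(query, subj, scheme))
  rows <- mapply(function(subj, aln) {
    data.frame(query_id = query$id, subject_id = subj$id,
               raw_score = aln$raw_score, bit_score = aln$bit_score,
               evalue = evalue(aln$bit_score, m, n_db),
               pident = if (aln$n_columns)
                 unname(percent_identity(aln)["pident"]) else NA_real_,
               length = aln$n_columns, stringsAsFactors = FALSE)
  }, database, alns, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  names(alns) <- tab$subject_id
  keep <- tab$evalue < threshold & tab$raw_score > 0L
  tab <- tab[keep, , drop = FALSE]
  alns <- alns[keep]
  o <- order(tab$evalue, -tab$bit_score, tab$subject_id)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alignments") <- alns[o]
  tab
}
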