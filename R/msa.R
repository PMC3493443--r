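# Progressive multiple sequence alignment: NJ guide tree on global-alignment
# p-distances, then profile-profile merges in guide-tree order with
# average-of-pairs column scoring and affine gap penalties.

#' Construct a multiple alignment object
#'
#' @param ids Character vector of unique sequence ids.
#' @param rows Equal-length gapped residue strings (gap = `-`), one per id.
#' @return An object of class `multiple_alignment` with elements `ids`,
#'   `rows` (named by id) and `n_columns`.
#' @export
multiple_alignment <- function(ids, rows) {
  ids <- as.character(ids); rows <- as.character(rows)
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (anyDuplicated(ids)) stop("duplicate ids in alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(rows, ""))
  if (w > 0L && any(colSums(m != "-") == 0L))
    stop("alignment contains an all-gap column")
  structure(list(ids = ids, rows = stats::setNames(rows, ids),
                 n_columns = w), class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("multiple_alignment:", length(x$ids), "sequences x",
      x$n_columns, "columns\n")
  invisible(x)
}

#' @export
as.matrix.multiple_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$rows), ""))
  rownames(m) <- x$ids
  m
}

# residue frequency profile of a gapped character matrix (gaps weight 0,
# denominators count every row)
profile_freq <- function(m, residues) {
  f <- matrix(0, nrow = length(residues), ncol = ncol(m),
              dimnames = list(residues, NULL))
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    tab <- tab[names(tab) != "-"]
    if (length(tab)) f[names(tab), j] <- as.numeric(tab)
  }
  f / nrow(m)
}

merge_profiles <- function(ma, mb, scheme) {
  residues <- rownames(scheme$scores)
  fa <- profile_freq(ma, residues)
  fb <- profile_freq(mb, residues)
  S <- t(fa) %*% scheme$scores %*% fb
  res <- .profile_align_cpp(S, scheme$gap_open, scheme$gap_extend)
  path <- res$path
  out <- matrix("-", nrow = nrow(ma) + nrow(mb), ncol = length(path))
  rownames(out) <- c(rownames(ma), rownames(mb))
  ia <- 0L; ib <- 0L
  ra <- seq_len(nrow(ma)); rb <- nrow(ma) + seq_len(nrow(mb))
  for (k in seq_along(path)) {
    mv <- path[k]
    if (mv == 1L) { ia <- ia + 1L; ib <- ib + 1L
      out[ra, k] <- ma[, ia]; out[rb, k] <- mb[, ib]
    } else if (mv == 2L) { ia <- ia + 1L; out[ra, k] <- ma[, ia]
    } else { ib <- ib + 1L; out[rb, k] <- mb[, ib] }
  }
  out
}

#' Progressive multiple alignment
#'
#' Builds a guide tree by neighbor joining on p-distances from all pairwise
#' global alignments (midpoint-rooted), then merges sequence profiles in
#' postorder with average-of-pairs column scoring under the scheme's affine
#' gap penalties. Deterministic for a fixed input order; exactly two sequences
#' reduce to [needleman_wunsch()].
#'
#' @param seqs List of at least two [seq_record] objects with unique ids.
#' @param scheme A [scoring_scheme] (default [global_scheme()]).
#' @return A [multiple_alignment()] whose rows, after removing gaps, equal the
#'   input sequences; row order follows input order.
#' @export
progressive_align <- function(seqs, scheme = global_scheme()) {
  if (length(seqs) < 2L) stop("progressive alignment needs >= 2 sequences")
  seqs <- lapply(seqs, as_record)
  ids <- vapply(seqs, function(r) r$id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  if (length(seqs) == 2L) {
    aln <- needleman_wunsch(seqs[[1L]], seqs[[2L]], scheme)
    return(multiple_alignment(ids, c(aln$aligned_a, aln$aligned_b)))
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    aln <- needleman_wunsch(seqs[[i]], seqs[[j]], scheme)
    d[i, j] <- d[j, i] <- 1 - aln$n_identical / aln$n_columns
  }
  # guide-tree branch lengths are irrelevant to the merge order, so NJ's
  # negative-length clamping is not worth a user-facing warning here
  guide <- suppressWarnings(neighbor_joining(distance_matrix(ids, d)))
  guide <- tryCatch(phangorn::midpoint(guide),
                    error = function(e)
                      ape::root(guide, outgroup = ids[1L],
                                resolve.root = TRUE))
  # postorder merge of profiles
  mats <- lapply(seqs, function(r) {
    m <- matrix(strsplit(r$residues, "")[[1L]], nrow = 1L)
    rownames(m) <- r$id
    m
  })
  names(mats) <- ids
  merge_clade <- function(node) {
    if (node <= length(guide$tip.label)) return(mats[[guide$tip.label[node]]])
    children <- guide$edge[guide$edge[, 1L] == node, 2L]
    prof <- merge_clade(children[1L])
    for (ch in children[-1L])
      prof <- merge_profiles(prof, merge_clade(ch), scheme)
    prof
  }
  root <- length(guide$tip.label) + 1L
  prof <- merge_clade(root)
  prof <- prof[ids, , drop = FALSE]
  keep <- colSums(prof != "-") > 0L
  prof <- prof[, keep, drop = FALSE]
  multiple_alignment(ids, apply(prof, 1L, paste, collapse = ""))
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but rows may contain gap characters (`-` or `.`;
#' dots are converted to dashes) and must all have equal length.
#'
#' @param path Path to an aligned FASTA file.
#' @return A [multiple_alignment()].
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  rows <- gsub(".", "-", toupper(as.character(set)), fixed = TRUE)
  for (i in seq_along(rows)) check_alphabet(gsub("-", "", rows[i]), ids[i])
  multiple_alignment(ids, rows)
}

#' Write a multiple alignment
#'
#' @param msa A [multiple_alignment()].
#' @param path Output path.
#' @param format `"fasta"` (60-column wrapped, default) or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::BStringSet(unname(msa$rows))
    names(set) <- msa$ids
    Biostrings::writeXStringSet(set, path, width = 60L)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("CLUSTAL format alignment", ""), con)
    width <- max(nchar(msa$ids)) + 3L
    for (start in seq(1L, max(1L, msa$n_columns), by = 60L)) {
      for (i in seq_along(msa$ids))
        writeLines(sprintf(paste0("%-", width, "s%s"), msa$ids[i],
                           substr(msa$rows[i], start,
                                  min(start + 59L, msa$n_columns))), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Sum-of-pairs score of a multiple alignment
#'
#' For every pair of rows, strips joint-gap columns and scores the induced
#' pairwise alignment with the scheme's substitution matrix and affine gap
#' penalties; returns the sum over pairs. Used as an alignment-quality
#' diagnostic.
#'
#' @param msa A [multiple_alignment()].
#' @param scheme A [scoring_scheme].
#' @return A single numeric score.
#' @export
sum_of_pairs <- function(msa, scheme = global_scheme()) {
  m <- as.matrix(msa)
  total <- 0
  score_pair <- function(a, b) {
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    s <- 0; in_gap <- FALSE
    for (k in seq_along(a)) {
      if (a[k] == "-" || b[k] == "-") {
        s <- s - (if (in_gap) scheme$gap_extend else
          scheme$gap_open + scheme$gap_extend)
        in_gap <- TRUE
      } else {
        s <- s + scheme$scores[a[k], b[k]]
        in_gap <- FALSE
      }
    }
    s
  }
  n <- nrow(m)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n))
    total <- total + score_pair(m[i, ], m[j, ])
  total
}
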