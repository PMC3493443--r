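#' @useDynLib foxscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

# Amino-acid alphabet accepted throughout: the 20 canonical residues plus the
# ambiguity codes B/Z/X and selenocysteine U.
AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")
AA_ALLOWED <- c(AA_STANDARD, "X", "B", "Z", "U")

#' Create a protein sequence record
#'
#' A `seq_record` holds one protein (or one excised domain) with its
#' identifier, free-text description, residue string and, for excised domains,
#' the 1-based inclusive coordinates of the region in the parent sequence.
#'
#' @param id Unique identifier token (no whitespace).
#' @param residues Amino-acid string; uppercased on construction. Allowed
#'   characters are the 20 canonical residues plus `X`, `B`, `Z`, `U`.
#' @param description Optional free-text description.
#' @param region Optional integer pair `c(start, end)`, 1-based inclusive
#'   coordinates in the parent sequence; must satisfy
#'   `end - start + 1 == nchar(residues)`.
#' @param parent_id Optional identifier of the parent sequence.
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("q1", "MKT", description = "toy")
#' @export
seq_record <- function(id, residues, description = "", region = NULL,
                       parent_id = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("'id' must be a single non-empty token without whitespace")
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("record '", id, "': residues are empty")
  check_alphabet(residues, id)
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || anyNA(region) || region[1L] < 1L ||
        region[1L] > region[2L])
      stop("record '", id, "': region must be c(start, end) with 1 <= start <= end")
    if (region[2L] - region[1L] + 1L != nchar(residues))
      stop("record '", id, "': region width does not match residue length")
  }
  structure(list(id = id, description = as.character(description),
                 residues = residues, region = region, parent_id = parent_id),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("seq_record ", x$id, " (", nchar(x$residues), " aa)",
      if (!is.null(x$region))
        paste0(" region ", x$region[1L], "-", x$region[2L],
               if (!is.null(x$parent_id)) paste0(" of ", x$parent_id)),
      "\n", sep = "")
  invisible(x)
}

check_alphabet <- function(residues, id) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALLOWED))
  if (length(bad))
    stop("record '", id, "': character '", chars[bad[1L]],
         "' at position ", bad[1L], " is outside the amino-acid alphabet")
  invisible(TRUE)
}

#' Read a protein FASTA file
#'
#' Reads records in order of appearance. Residues are uppercased, whitespace
#' and line wrapping are removed, blank lines are ignored, and trailing stop
#' characters (`*`) are stripped with a warning. Duplicate identifiers and
#' characters outside the accepted alphabet are errors.
#'
#' @param path Path to a protein FASTA file.
#' @return A list of [seq_record] objects, named by id.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  if (!startsWith(lines[[1L]], ">"))
    stop("malformed FASTA: first non-blank line of '", path,
         "' does not start with '>'")
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id in '", path, "': ",
         ids[duplicated(ids)][1L])
  res <- unname(as.character(set))
  res <- toupper(gsub("[[:space:]]", "", res))
  if (any(grepl("*", res, fixed = TRUE))) {
    warning("stripped '*' (stop) characters from ",
            sum(grepl("*", res, fixed = TRUE)), " record(s) in ", path)
    res <- gsub("*", "", res, fixed = TRUE)
  }
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) out[[i]] <- seq_record(ids[i], res[i], descs[i])
  names(out) <- ids
  out
}

#' Write protein records to FASTA
#'
#' Output is wrapped at 60 columns. Headers are `>id description`.
#'
#' @param records A list of [seq_record] objects (or a single record).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  ids <- vapply(records, function(r) r$id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  set <- Biostrings::BStringSet(vapply(records, function(r) r$residues,
                                       character(1L)))
  names(set) <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id,
    character(1L))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Load a labeled reference panel
#'
#' A reference panel is the labeled set of subfamily representatives (for the
#' Fox family: one domain record per subfamily member, optionally paired with a
#' full-length record) used both as phylogenetic anchors and as the reverse
#' best-hit database. Labels come from a two-column TSV (`id<TAB>subfamily`;
#' `#` comments allowed) that must cover every domain record.
#'
#' @param domain_path FASTA of domain sequences (e.g. excised FKH domains).
#' @param labels_path Two-column TSV mapping each domain id to a subfamily.
#' @param fulllength_path Optional FASTA of matching full-length sequences
#'   (matched to domain records by id).
#' @param target_subfamily Subfamily of interest (default `"FoxJ1"`); at least
#'   one panel entry must carry this label.
#' @return An object of class `reference_panel`: a list with elements
#'   `ids`, `subfamily` (named character), `domain` (list of [seq_record]),
#'   `full_length` (list or `NULL` entries), `target_subfamily`,
#'   `target_ids` (ids labeled with the target subfamily).
#' @export
load_panel <- function(domain_path, labels_path, fulllength_path = NULL,
                       target_subfamily = "FoxJ1") {
  domains <- read_fasta(domain_path)
  lab <- utils::read.delim(labels_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("label table must have two columns: id, subfamily")
  labels <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  if (any(!nzchar(labels))) stop("empty subfamily label in ", labels_path)
  missing <- setdiff(names(domains), names(labels))
  if (length(missing))
    stop("domain id(s) missing from label table: ",
         paste(missing, collapse = ", "))
  unused <- setdiff(names(labels), names(domains))
  if (length(unused))
    warning("label table has ", length(unused),
            " id(s) with no domain record (ignored): ",
            paste(utils::head(unused, 5L), collapse = ", "))
  fl <- NULL
  if (!is.null(fulllength_path)) {
    fl_all <- read_fasta(fulllength_path)
    fl <- fl_all[intersect(names(domains), names(fl_all))]
  }
  subfam <- labels[names(domains)]
  target_ids <- names(subfam)[subfam == target_subfamily]
  if (length(target_ids) == 0L)
    stop("target subfamily '", target_subfamily, "' absent from panel")
  structure(list(ids = names(domains), subfamily = subfam, domain = domains,
                 full_length = fl, target_subfamily = target_subfamily,
                 target_ids = target_ids),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel with", length(x$ids), "entries,",
      length(unique(x$subfamily)), "subfamilies; target",
      x$target_subfamily, "(", length(x$target_ids), "entries )\n")
  invisible(x)
}
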