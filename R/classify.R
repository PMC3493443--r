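# Reverse best-hit subfamily assignment, the ortholog decision rules
# (definite / candidate / not detected) and the survey report.

#' Build one evidence record
#'
#' One row of per-candidate evidence: the reverse best-hit call, the
#' domain-phylogeny call with its bootstrap support, and (when available) the
#' full-length-phylogeny call with its support.
#'
#' @param candidate_id Unique protein id (paralogs get distinct ids).
#' @param organism Organism label.
#' @param best_evalue Best search E-value (or `NA`).
#' @param rbh_call Reverse best-hit subfamily label (or `NA`).
#' @param rbh_margin Bit-score margin to the best other-subfamily hit.
#' @param domain_grouped Did the candidate group with the target subfamily in
#'   the domain tree?
#' @param domain_support Bootstrap percentage of that grouping (or `NA`).
#' @param fulllength_grouped,fulllength_support Same for the full-length tree
#'   (`NA` when not assessed).
#' @param group Higher taxonomic group (e.g. `"Animalia"`, `"Fungi"`).
#' @param paralog_index Ordinal for multi-copy genes (default 1).
#' @return A one-row data.frame.
#' @export
evidence_record <- function(candidate_id, organism, best_evalue = NA_real_,
                            rbh_call = NA_character_, rbh_margin = NA_real_,
                            domain_grouped = FALSE,
                            domain_support = NA_real_,
                            fulllength_grouped = NA,
                            fulllength_support = NA_real_,
                            group = NA_character_, paralog_index = 1L) {
  for (s in list(domain_support, fulllength_support))
    if (!is.na(s) && (s < 0 || s > 100))
      stop("bootstrap supports must lie in [0, 100]")
  if (!is.na(rbh_margin) && rbh_margin < 0)
    stop("rbh_margin must be non-negative")
  data.frame(candidate_id = candidate_id, organism = organism,
             group = group, paralog_index = as.integer(paralog_index),
             best_evalue = as.numeric(best_evalue),
             rbh_call = as.character(rbh_call),
             rbh_margin = as.numeric(rbh_margin),
             domain_grouped = as.logical(domain_grouped),
             domain_support = as.numeric(domain_support),
             fulllength_grouped = as.logical(fulllength_grouped),
             fulllength_support = as.numeric(fulllength_support),
             stringsAsFactors = FALSE)
}

#' Reverse best-hit subfamily assignment
#'
#' Locally aligns a candidate domain against every entry of the labeled
#' reference panel and assigns the subfamily of the highest-bit-score entry.
#' The margin is the bit-score gap to the best entry of any *other*
#' subfamily; margins below `tie_threshold` (1 bit by default) are reported
#' as `"ambiguous"`.
#'
#' @param domain Candidate domain [seq_record].
#' @param panel A `reference_panel` (see [load_panel()]).
#' @param scheme A [scoring_scheme].
#' @param tie_threshold Minimum decisive margin in bits (default 1).
#' @return List with `call` (subfamily label, `"ambiguous"`, or `NA` if no
#'   positive-scoring hit), `margin` (bits), `best_id` and a `hits`
#'   data.frame (panel id, subfamily, bit score).
#' @export
reverse_best_hit <- function(domain, panel, scheme = scoring_scheme(),
                             tie_threshold = 1) {
  domain <- as_record(domain)
  bits <- vapply(panel$domain, function(ref)
    smith_waterman(domain, ref, scheme)$bit_score, numeric(1L))
  raw <- vapply(panel$domain, function(ref)
    smith_waterman(domain, ref, scheme)$raw_score, numeric(1L))
  hits <- data.frame(id = panel$ids, subfamily = unname(panel$subfamily),
                     bit_score = unname(bits), stringsAsFactors = FALSE)
  if (all(raw <= 0))
    return(list(call = NA_character_, margin = NA_real_, best_id = NA,
                hits = hits))
  best <- which.max(bits)
  best_subfam <- hits$subfamily[best]
  other <- hits$bit_score[hits$subfamily != best_subfam]
  margin <- if (length(other)) bits[best] - max(other) else Inf
  call <- if (is.finite(margin) && margin < tie_threshold) "ambiguous"
          else best_subfam
  list(call = call, margin = max(margin, 0), best_id = hits$id[best],
       hits = hits[order(-hits$bit_score), ])
}

methods_supporting <- function(ev, target = "FoxJ1") {
  out <- character(0)
  if (!is.na(ev$rbh_call) && ev$rbh_call == target)
    out <- c(out, "reverse_hit")
  if (isTRUE(ev$domain_grouped)) out <- c(out, "domain_phylogeny")
  if (isTRUE(ev$fulllength_grouped)) out <- c(out, "fulllength_phylogeny")
  out
}

#' Call the ortholog category for one evidence record
#'
#' `definite` requires grouping with the target subfamily in the domain tree
#' at bootstrap support strictly above `support_threshold`. Otherwise the
#' candidate categories: at least two of the three methods (reverse best hit,
#' domain phylogeny, full-length phylogeny) supporting gives a `candidate`;
#' exactly one supporting method gives a `candidate` flagged as weak in the
#' rationale; no method gives `not_detected`.
#'
#' @param ev A one-row evidence data.frame (see [evidence_record()]).
#' @param support_threshold Bootstrap threshold (default 95).
#' @param target Target subfamily label.
#' @return List with `category` (`"definite"`, `"candidate"`,
#'   `"not_detected"`), `methods_supporting` and `rationale`.
#' @export
call_ortholog <- function(ev, support_threshold = 95, target = "FoxJ1") {
  ms <- methods_supporting(ev, target)
  definite <- isTRUE(ev$domain_grouped) && !is.na(ev$domain_support) &&
    ev$domain_support > support_threshold
  if (definite) {
    cat_ <- "definite"
    why <- sprintf("grouped with %s in the domain tree at bootstrap %g > %g",
                   target, ev$domain_support, support_threshold)
  } else if (length(ms) >= 2L) {
    cat_ <- "candidate"
    why <- paste("supported by", length(ms), "of 3 methods:",
                 paste(ms, collapse = ", "))
  } else if (length(ms) == 1L) {
    cat_ <- "candidate"
    why <- paste("weak: single supporting method", ms)
  } else {
    cat_ <- "not_detected"
    why <- "no supporting method"
  }
  list(category = cat_, methods_supporting = ms, rationale = why)
}

#' Survey report over an evidence table
#'
#' Applies [call_ortholog()] to every record and tabulates the survey:
#' per-protein calls plus summary counts, including the organism-level
#' selections used for weak (e.g. fungal) candidates: organisms supported by
#' at least two of the three methods, and organisms supported by both the
#' reverse best hit and the domain phylogeny.
#'
#' @param evidence A data.frame of evidence records (unique `candidate_id`).
#' @param support_threshold Bootstrap threshold for `definite` (default 95).
#' @param target Target subfamily label.
#' @return List of class `survey_report`: `table` (evidence + `category`,
#'   `n_methods`, `methods`, `rationale`) and `summary` with counts
#'   `n_proteins`, `n_proteins_identified` (>= 1 method),
#'   `n_definite`, `n_candidate`, `n_not_detected`, `by_group` (data.frame)
#'   and per-group organism selections `two_of_three_organisms`,
#'   `rbh_and_domain_organisms` (named lists by group).
#' @export
survey_report <- function(evidence, support_threshold = 95,
                          target = "FoxJ1") {
  if (anyDuplicated(evidence$candidate_id))
    stop("duplicate candidate_id in evidence: ",
         evidence$candidate_id[duplicated(evidence$candidate_id)][1L])
  calls <- lapply(seq_len(nrow(evidence)), function(i)
    call_ortholog(evidence[i, ], support_threshold, target))
  tab <- evidence
  tab$category <- vapply(calls, `[[`, character(1L), "category")
  tab$n_methods <- vapply(calls, function(x)
    length(x$methods_supporting), integer(1L))
  tab$methods <- vapply(calls, function(x)
    paste(x$methods_supporting, collapse = "+"), character(1L))
  tab$rationale <- vapply(calls, `[[`, character(1L), "rationale")

  groups <- unique(tab$group[!is.na(tab$group)])
  sel_two <- lapply(groups, function(g) {
    rows <- tab[!is.na(tab$group) & tab$group == g & tab$n_methods >= 2L, ]
    sort(unique(rows$organism))
  })
  names(sel_two) <- groups
  sel_both <- lapply(groups, function(g) {
    rows <- tab[!is.na(tab$group) & tab$group == g, ]
    keep <- !is.na(rows$rbh_call) & rows$rbh_call == target &
      rows$domain_grouped %in% TRUE
    sort(unique(rows$organism[keep]))
  })
  names(sel_both) <- groups
  by_group <- do.call(rbind, lapply(groups, function(g) {
    rows <- tab[!is.na(tab$group) & tab$group == g, ]
    data.frame(group = g, n_proteins = nrow(rows),
               n_identified = sum(rows$n_methods >= 1L),
               n_definite = sum(rows$category == "definite"),
               n_candidate = sum(rows$category == "candidate"),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    table = tab,
    summary = list(
      n_proteins = nrow(tab),
      n_proteins_identified = sum(tab$n_methods >= 1L),
      n_definite = sum(tab$category == "definite"),
      n_candidate = sum(tab$category == "candidate"),
      n_not_detected = sum(tab$category == "not_detected"),
      by_group = by_group,
      two_of_three_organisms = sel_two,
      rbh_and_domain_organisms = sel_both)),
    class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  s <- x$summary
  cat("survey_report:", s$n_proteins, "proteins;",
      s$n_proteins_identified, "identified (>=1 method);",
      s$n_definite, "definite;", s$n_candidate, "candidate;",
      s$n_not_detected, "not detected\n")
  invisible(x)
}

#' Load the bundled FoxJ1 survey evidence table
#'
#' The package ships the evidence table of a published eukaryote-wide FoxJ1
#' survey: 60 candidate proteins across 56 organisms (paralogs on separate
#' rows) with reverse best-hit calls, domain-phylogeny calls with bootstrap
#' supports, and (for the fungal proteins) full-length-phylogeny calls.
#' Qualitative phylogeny cells map to grouped flags as: `FoxJ1`/`Foxj1` ->
#' `TRUE`; `Sister to ...`, `Unresolved` or blank -> `FALSE` (blank
#' full-length cells for non-fungal rows -> `NA`, not assessed).
#'
#' @param path Path to the TSV (defaults to the installed copy).
#' @return An evidence data.frame (see [evidence_record()]) with extra
#'   columns `phylum`, `domain_label`, `fulllength_label`.
#' @export
load_survey_evidence <- function(path = system.file(
  "extdata", "foxj1_survey_evidence.tsv", package = "foxscan")) {
  raw <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  grouped_from_label <- function(lbl) {
    lbl <- trimws(lbl)
    tolower(lbl) == "foxj1"
  }
  domain_grouped <- grouped_from_label(raw$domain_label)
  full_lbl <- trimws(ifelse(is.na(raw$full_label), "", raw$full_label))
  # blank full-length cells mean "not assessed" (the survey only scored
  # full-length phylogeny for the fungal proteins)
  full_assessed <- nzchar(full_lbl)
  fulllength_grouped <- ifelse(full_assessed,
                               grouped_from_label(full_lbl), NA)
  id <- ifelse(as.integer(raw$paralog) > 1L,
               paste0(gsub(" ", "_", raw$organism), ".", raw$paralog),
               gsub(" ", "_", raw$organism))
  ev <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i)
    evidence_record(
      candidate_id = id[i], organism = raw$organism[i],
      best_evalue = as.numeric(raw$evalue[i]),
      rbh_call = raw$rbh_call[i], rbh_margin = NA_real_,
      domain_grouped = domain_grouped[i],
      domain_support = suppressWarnings(as.numeric(raw$domain_support[i])),
      fulllength_grouped = fulllength_grouped[i],
      fulllength_support =
        suppressWarnings(as.numeric(raw$full_support[i])),
      group = raw$group[i], paralog_index = as.integer(raw$paralog[i]))))
  ev$phylum <- raw$phylum
  ev$domain_label <- raw$domain_label
  ev$fulllength_label <- full_lbl
  ev$group[ev$group == "fungi"] <- "Fungi"
  ev
}

#' Write / read an evidence table as TSV
#'
#' @param evidence Evidence data.frame.
#' @param path File path.
#' @return `path` invisibly (writer); evidence data.frame (reader).
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
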