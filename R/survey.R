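# Pipeline orchestration: search -> domain excision -> alignment -> NJ +
# bootstrap -> reverse best hit -> ortholog call -> report, with config,
# per-stage artifacts and run metadata.

#' Default survey configuration
#'
#' @return A named list of defaults: `evalue_threshold` 1e-2 (the classic
#'   potential-ortholog filter), `support_threshold` 95 (definite-ortholog
#'   bootstrap cutoff), `n_replicates` 100, `min_coverage` 0.70,
#'   `distance_model` "poisson" (multiple-hit-corrected distances, the
#'   standard choice for trees over alignments that include fast-evolving
#'   regions; uncorrected p-distances are non-additive at such divergences
#'   and produce long-branch attraction artifacts in NJ),
#'   `target_subfamily` "FoxJ1", `seed` 1, `run_fulllength` TRUE.
#' @export
default_config <- function() {
  list(evalue_threshold = 1e-2, support_threshold = 95,
       n_replicates = 100L, min_coverage = 0.70,
       distance_model = "poisson",
       target_subfamily = "FoxJ1", seed = 1L, run_fulllength = TRUE)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(default_config(), as.list(config))
}

#' Run the full ortholog survey
#'
#' For every proteome: (1) search it with the target-subfamily reference
#' domain and keep hits with E-value below the threshold; (2) excise the
#' domain of the best hit by local alignment; (3) align the candidate domain
#' with the panel domains, build an NJ tree with bootstrap supports and ask
#' whether the candidate groups with the target subfamily; (4) if full-length
#' sequences are available, repeat the phylogeny full-length; (5) assign a
#' reverse best-hit subfamily; (6) call the ortholog category. Writes the
#' evidence table, the calls, one newick tree per candidate per analysis, and
#' a run-metadata JSON; everything is deterministic for a fixed config seed.
#'
#' @param config A YAML file path or list. Required fields beyond
#'   [default_config()]: `proteome_paths` (named character vector or list of
#'   FASTA paths; names are organism ids), `panel_domain_path`,
#'   `panel_labels_path`, optional `panel_full_path`, `output_dir`.
#' @return A [survey_report()] (invisibly, with `evidence` attribute);
#'   artifacts written under `output_dir`.
#' @export
run_survey <- function(config) {
  cfg <- read_config(config)
  for (f in c("proteome_paths", "panel_domain_path", "panel_labels_path",
              "output_dir"))
    if (is.null(cfg[[f]])) stop("config is missing '", f, "'")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  tree_dir <- file.path(cfg$output_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  panel <- load_panel(cfg$panel_domain_path, cfg$panel_labels_path,
                      fulllength_path = cfg$panel_full_path,
                      target_subfamily = cfg$target_subfamily)
  ref_domain <- panel$domain[[panel$target_ids[1L]]]
  scheme_local <- scoring_scheme()
  scheme_global <- global_scheme()
  proteomes <- cfg$proteome_paths
  if (is.null(names(proteomes)) || any(!nzchar(names(proteomes))))
    names(proteomes) <- tools::file_path_sans_ext(basename(unlist(proteomes)))

  evidence <- list()
  for (org in names(proteomes)) {
    proteome <- read_fasta(proteomes[[org]])
    hits <- search_database(ref_domain, proteome, scheme_local,
                            cfg$evalue_threshold)
    if (nrow(hits) == 0L) {
      evidence[[org]] <- evidence_record(org, org, group = "simulated")
      next
    }
    # candidates: every distinct passing protein (paralogs kept separate)
    for (h in seq_len(nrow(hits))) {
      subject <- proteome[[hits$subject_id[h]]]
      # query leaves get a distinct prefix so that a panel organism can be
      # surveyed against a panel containing itself
      cand_id <- if (h == 1L) paste0("query|", org) else
        paste0("query|", org, ".", h)
      dom <- suppressWarnings(
        extract_domain(subject, ref_domain, scheme_local,
                       cfg$min_coverage))
      if (is.null(dom)) next
      dom$id <- cand_id
      # domain phylogeny against the panel
      dom_seqs <- c(stats::setNames(list(dom), cand_id), panel$domain)
      msa_dom <- progressive_align(unname(dom_seqs), scheme_global)
      seed_d <- (cfg$seed + 7L * h + match(org, names(proteomes))) %%
        .Machine$integer.max
      tree_dom <- bootstrap_support(msa_dom, cfg$distance_model,
                                    cfg$n_replicates, seed = seed_d)
      grp_dom <- clade_support(tree_dom, cand_id, panel$subfamily,
                               cfg$target_subfamily)
      write_newick(tree_dom, file.path(tree_dir,
                                       paste0(cand_id, "_domain.nwk")))
      # full-length phylogeny when sequences allow it
      grp_full <- list(grouped = NA, support = NA_real_)
      if (isTRUE(cfg$run_fulllength) && !is.null(panel$full_length) &&
          length(panel$full_length) >= 2L) {
        full_cand <- seq_record(cand_id, subject$residues)
        full_seqs <- c(list(full_cand), unname(panel$full_length))
        msa_full <- progressive_align(full_seqs, scheme_global)
        tree_full <- bootstrap_support(msa_full, cfg$distance_model,
                                       cfg$n_replicates,
                                       seed = seed_d + 1L)
        grp_full <- clade_support(tree_full, cand_id, panel$subfamily,
                                  cfg$target_subfamily)
        write_newick(tree_full,
                     file.path(tree_dir, paste0(cand_id, "_full.nwk")))
      }
      rbh <- reverse_best_hit(dom, panel, scheme_local)
      evidence[[cand_id]] <- evidence_record(
        candidate_id = cand_id, organism = org,
        best_evalue = hits$evalue[h],
        rbh_call = rbh$call,
        rbh_margin = if (is.na(rbh$call)) NA_real_ else rbh$margin,
        domain_grouped = grp_dom$grouped,
        domain_support = grp_dom$support,
        fulllength_grouped = grp_full$grouped,
        fulllength_support = grp_full$support,
        group = "simulated", paralog_index = h)
    }
  }
  ev <- do.call(rbind, unname(evidence))
  report <- survey_report(ev, cfg$support_threshold, cfg$target_subfamily)
  write_evidence(report$table,
                 file.path(cfg$output_dir, "ortholog_calls.tsv"))
  write_evidence(ev, file.path(cfg$output_dir, "evidence.tsv"))
  meta <- list(package = "foxscan",
               version = as.character(utils::packageVersion("foxscan")),
               seed = cfg$seed, evalue_threshold = cfg$evalue_threshold,
               support_threshold = cfg$support_threshold,
               n_replicates = cfg$n_replicates,
               distance_model = cfg$distance_model,
               target_subfamily = cfg$target_subfamily,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(cfg$output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(report, "evidence") <- ev
  invisible(report)
}

#' Score a survey against simulation truth
#'
#' Recall = fraction of true target-subfamily proteins called definite or
#' candidate; precision = fraction of definite/candidate calls whose organism
#' truly belongs to the target subfamily.
#'
#' @param report A [survey_report()] produced by [run_survey()].
#' @param truth Data.frame with columns `id`, `subfamily` (or a truth TSV
#'   path).
#' @param target Target subfamily label.
#' @param panel_ids Ids used as reference panel (excluded from scoring).
#' @return List with `recall`, `precision`, `n_true`, `n_called`.
#' @export
score_survey <- function(report, truth, target = "FoxJ1",
                         panel_ids = character()) {
  if (is.character(truth)) truth <- utils::read.delim(truth,
                                                      comment.char = "#")
  tab <- report$table
  tab <- tab[!(tab$organism %in% panel_ids), ]
  truth <- truth[!(truth$id %in% panel_ids), ]
  called <- tab$organism[tab$category %in% c("definite", "candidate")]
  true_pos <- truth$id[truth$subfamily == target]
  recall <- if (length(true_pos))
    mean(true_pos %in% called) else NA_real_
  precision <- if (length(called))
    mean(called %in% true_pos) else NA_real_
  list(recall = recall, precision = precision,
       n_true = length(true_pos), n_called = length(unique(called)))
}

#' Percent-identity report over pairs of FASTA files
#'
#' Globally aligns the first record of each pair of FASTA files (or each
#' [seq_record] pair) and reports percent identity over all alignment
#' columns, to one decimal and rounded.
#'
#' @param pairs List of 2-element items; each element is a FASTA path or a
#'   [seq_record].
#' @param scheme A [scoring_scheme] (default [global_scheme()]).
#' @return A data.frame: `id_a`, `id_b`, `pident`, `rounded`, `n_columns`,
#'   `n_gaps`.
#' @export
run_identity_report <- function(pairs, scheme = global_scheme()) {
  if (length(pairs) == 0L) stop("no pairs given")
  first_record <- function(x) {
    if (inherits(x, "seq_record")) return(x)
    recs <- read_fasta(x)
    if (length(recs) == 0L) stop("no records in ", x)
    recs[[1L]]
  }
  rows <- lapply(pairs, function(p) {
    a <- first_record(p[[1L]]); b <- first_record(p[[2L]])
    aln <- needleman_wunsch(a, b, scheme)
    pid <- percent_identity(aln)
    data.frame(id_a = a$id, id_b = b$id, pident = pid[["pident"]],
               rounded = pid[["rounded"]], n_columns = aln$n_columns,
               n_gaps = sum(strsplit(paste0(aln$aligned_a, aln$aligned_b),
                                     "")[[1L]] == "-"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
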