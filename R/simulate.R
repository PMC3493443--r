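# Synthetic multi-subfamily protein families with known trees and labels.
# Emulates the structure of the Fox family: a conserved ~100-residue
# DNA-binding domain evolving slowly, divergent flanking sequence, several
# subfamilies, and unrelated decoy proteins per proteome.

#' Simulation parameters for a synthetic gene family
#'
#' Defaults emulate a Fox-like family: five subfamilies of eight taxa, a
#' 100-residue conserved domain between 150-residue flanks, a slow domain
#' (0.25 substitutions/site per unit branch) inside fast flanks (1.0), deep
#' splits between subfamilies (depth 1.0) and shallow radiations within them
#' (depth 0.25). At those values, domains of different subfamilies end up
#' roughly 50-60% identical and domains within a subfamily 80-95% identical,
#' the regime in which forkhead-domain surveys operate. Indels default off.
#'
#' @param n_subfamilies Number of subfamilies (>= 1, default 5).
#' @param taxa_per_subfamily Taxa per subfamily (>= 1, default 8).
#' @param domain_length Conserved domain length in residues (default 100).
#' @param flank_length Flank length each side (default 150).
#' @param domain_rate,flank_rate Substitutions/site per unit branch length
#'   (`flank_rate >= domain_rate`; defaults 0.25 and 1.0).
#' @param subfamily_depth Depth of the subfamily backbone tree (default 1.0).
#' @param within_subfamily_depth Depth of each within-subfamily tree
#'   (default 0.25).
#' @param indel_rate Insertion/deletion events per site on flanks (default 0;
#'   geometric lengths, p = 0.5; the domain is never touched so its recorded
#'   coordinates stay exact).
#' @param n_decoys Unrelated random-composition proteins per proteome
#'   (default 3).
#' @param subfamily_names Optional labels; default `FoxJ1`-style names with
#'   the first subfamily as the target.
#' @param seed Integer seed (default 42).
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_subfamilies = 5L, taxa_per_subfamily = 8L,
                              domain_length = 100L, flank_length = 150L,
                              domain_rate = 0.25, flank_rate = 1.0,
                              subfamily_depth = 1.0,
                              within_subfamily_depth = 0.25,
                              indel_rate = 0, n_decoys = 3L,
                              subfamily_names = NULL, seed = 42L) {
  counts <- c(n_subfamilies, taxa_per_subfamily, domain_length, flank_length)
  if (any(counts < 1L)) stop("counts must be >= 1")
  if (domain_rate < 0 || flank_rate < 0 || indel_rate < 0)
    stop("rates must be >= 0")
  if (flank_rate < domain_rate)
    stop("flank_rate must be >= domain_rate (the domain is the slow part)")
  if (is.null(subfamily_names)) {
    pool <- c("FoxJ1", "FoxJ2", "FoxJ3", "FoxK1", "FoxN3", "FoxA1",
              "FoxD2", "FoxO1", "FoxP1", "FoxQ1")
    subfamily_names <- if (n_subfamilies <= length(pool))
      pool[seq_len(n_subfamilies)] else paste0("SF", seq_len(n_subfamilies))
  }
  if (length(subfamily_names) != n_subfamilies)
    stop("need one name per subfamily")
  structure(list(n_subfamilies = as.integer(n_subfamilies),
                 taxa_per_subfamily = as.integer(taxa_per_subfamily),
                 domain_length = as.integer(domain_length),
                 flank_length = as.integer(flank_length),
                 domain_rate = domain_rate, flank_rate = flank_rate,
                 subfamily_depth = subfamily_depth,
                 within_subfamily_depth = within_subfamily_depth,
                 indel_rate = indel_rate, n_decoys = as.integer(n_decoys),
                 subfamily_names = subfamily_names,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# Evolve a residue vector along one branch under the 20-state
# equal-exchangeability Poisson model. With rate r (expected
# substitutions/site per unit branch) and branch length t, a site keeps its
# state with probability 1/20 + (19/20) exp(-20 r t / 19) and otherwise
# moves uniformly to one of the other 19 residues.
evolve_branch <- function(res, rate, t) {
  if (rate == 0 || t == 0) return(res)
  p_same <- 1 / 20 + (19 / 20) * exp(-20 * rate * t / 19)
  change <- stats::runif(length(res)) > p_same
  if (any(change)) {
    n <- sum(change)
    cur <- res[change]
    # map draws 1..19 onto the 19 residues that differ from the current one
    idx <- match(cur, AA_STANDARD)
    draw <- sample.int(19L, n, replace = TRUE)
    new <- AA_STANDARD[ifelse(draw >= idx, draw + 1L, draw)]
    res[change] <- new
  }
  res
}

random_residues <- function(n) AA_STANDARD[sample.int(20L, n, replace = TRUE)]

# recursively evolve domain+flank sequences down a rooted tree
evolve_tree <- function(tree, root_dom, root_fl1, root_fl2, params) {
  ntip <- length(tree$tip.label)
  out <- vector("list", ntip)
  names(out) <- tree$tip.label
  recurse <- function(node, dom, fl1, fl2) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    for (k in seq_along(kids)) {
      child <- kids[k]
      t <- tree$edge.length[which(tree$edge[, 1L] == node)[k]]
      d2 <- evolve_branch(dom, params$domain_rate, t)
      f1 <- evolve_branch(fl1, params$flank_rate, t)
      f2 <- evolve_branch(fl2, params$flank_rate, t)
      if (child <= ntip)
        out[[tree$tip.label[child]]] <<- list(dom = d2, fl1 = f1, fl2 = f2)
      else recurse(child, d2, f1, f2)
    }
  }
  recurse(ntip + 1L, root_dom, root_fl1, root_fl2)
  out
}

# apply geometric-length indels (p = 0.5) to a flank residue vector
apply_indels <- function(res, rate) {
  if (rate == 0 || length(res) == 0L) return(res)
  n_events <- stats::rpois(1L, rate * length(res))
  for (e in seq_len(n_events)) {
    if (length(res) == 0L) break
    len <- stats::rgeom(1L, 0.5) + 1L
    pos <- sample.int(length(res), 1L)
    if (stats::runif(1L) < 0.5) {
      res <- res[-(pos:min(pos + len - 1L, length(res)))]
    } else {
      res <- append(res, random_residues(len), after = pos)
    }
  }
  res
}

#' Simulate a multi-subfamily protein family
#'
#' Samples a subfamily backbone tree (coalescent shape, scaled to
#' `subfamily_depth`), grafts a within-subfamily tree onto each backbone tip
#' (scaled to `within_subfamily_depth`), draws a uniform-random root protein
#' and evolves it along every branch under the 20-state equal-exchangeability
#' Poisson model -- domain and flanks at their own rates. Full-length
#' proteins are flank + domain + flank with the domain coordinates recorded
#' exactly. Byte-identical output for a fixed seed.
#'
#' @param params A [simulation_params()].
#' @return A list of class `simulated_family`: `true_tree` (phylo over all
#'   leaves, `leaf_labels` attribute = subfamily per leaf), `proteins`
#'   (full-length [seq_record]s, domain region set), `domains` (excised
#'   domain records), `labels` (id -> subfamily), `decoys` (list per leaf of
#'   decoy records), `params`.
#' @export
simulate_family <- function(params = simulation_params()) {
  if (!inherits(params, "simulation_params")) stop("invalid params")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  ns <- params$n_subfamilies; nt <- params$taxa_per_subfamily
  scale_depth <- function(tr, depth) {
    if (is.null(tr$edge.length)) tr$edge.length <-
        rep(1, nrow(tr$edge))
    h <- max(ape::node.depth.edgelength(tr))
    if (h > 0) tr$edge.length <- tr$edge.length * depth / h
    tr
  }
  backbone <- if (ns >= 2L) {
    b <- ape::rcoal(ns, tip.label = params$subfamily_names)
    scale_depth(b, params$subfamily_depth)
  } else NULL
  sub_trees <- lapply(seq_len(ns), function(s) {
    labels <- paste0(params$subfamily_names[s], "_t",
                     seq_len(nt))
    if (nt >= 2L) {
      tr <- ape::rcoal(nt, tip.label = labels)
      scale_depth(tr, params$within_subfamily_depth)
    } else labels
  })
  if (is.null(backbone)) {
    full <- if (is.character(sub_trees[[1L]]))
      NULL else sub_trees[[1L]]
  } else {
    full <- backbone
    for (s in seq_len(ns)) {
      st <- sub_trees[[s]]
      where <- which(full$tip.label == params$subfamily_names[s])
      if (is.character(st)) {
        full$tip.label[where] <- st
      } else {
        full <- ape::bind.tree(full, st, where = where)
      }
    }
  }
  root_dom <- random_residues(params$domain_length)
  root_fl1 <- random_residues(params$flank_length)
  root_fl2 <- random_residues(params$flank_length)
  if (is.null(full)) { # single subfamily, single taxon
    leaves <- list()
    leaves[[paste0(params$subfamily_names[1L], "_t1")]] <-
      list(dom = root_dom, fl1 = root_fl1, fl2 = root_fl2)
    tree <- NULL
  } else {
    leaves <- evolve_tree(full, root_dom, root_fl1, root_fl2, params)
    tree <- full
  }
  labels <- stats::setNames(sub("_t[0-9]+$", "", names(leaves)),
                            names(leaves))
  proteins <- list(); domains <- list(); decoys <- list()
  for (id in names(leaves)) {
    lf <- leaves[[id]]
    f1 <- apply_indels(lf$fl1, params$indel_rate)
    f2 <- apply_indels(lf$fl2, params$indel_rate)
    start <- length(f1) + 1L
    end <- length(f1) + length(lf$dom)
    fullres <- paste(c(f1, lf$dom, f2), collapse = "")
    prot <- seq_record(id, fullres,
                       description = paste0("simulated ", labels[[id]],
                                            " member; domain ", start, "-",
                                            end))
    attr(prot, "domain_region") <- c(start, end)
    proteins[[id]] <- prot
    domains[[id]] <- seq_record(id, paste(lf$dom, collapse = ""),
                                description = "simulated domain",
                                region = c(start, end), parent_id = id)
    decoys[[id]] <- lapply(seq_len(params$n_decoys), function(k)
      seq_record(paste0(id, "_decoy", k),
                 paste(random_residues(params$domain_length +
                                         2L * params$flank_length),
                       collapse = ""),
                 description = "random-composition decoy"))
  }
  if (!is.null(tree)) attr(tree, "leaf_labels") <- labels
  structure(list(true_tree = tree, proteins = proteins, domains = domains,
                 labels = labels, decoys = decoys, params = params),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("simulated_family:", length(x$proteins), "proteins in",
      x$params$n_subfamilies, "subfamilies (target ",
      x$params$subfamily_names[1L], ")\n")
  invisible(x)
}

#' Write a simulated survey fixture to disk
#'
#' Emits one proteome FASTA per simulated organism (its family protein plus
#' decoys), a reference panel built from the first taxon of every subfamily
#' (domain FASTA, full-length FASTA, label TSV), and a truth TSV with the
#' known subfamily of every simulated protein for scoring recall/precision.
#'
#' @param params A [simulation_params()].
#' @param dir Output directory (created; must not already contain the files).
#' @return Invisibly, a list with `family`, `proteome_paths`,
#'   `panel_domain_path`, `panel_full_path`, `labels_path`, `truth_path`,
#'   `panel_ids`.
#' @export
make_survey_fixture <- function(params = simulation_params(), dir) {
  fam <- simulate_family(params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel_ids <- paste0(params$subfamily_names, "_t1")
  paths <- list()
  proteome_dir <- file.path(dir, "proteomes")
  dir.create(proteome_dir, showWarnings = FALSE)
  proteome_paths <- character(0)
  for (id in names(fam$proteins)) {
    p <- file.path(proteome_dir, paste0(id, ".faa"))
    if (file.exists(p)) stop("output collision: ", p)
    write_fasta(c(list(fam$proteins[[id]]), fam$decoys[[id]]), p)
    proteome_paths[id] <- p
  }
  panel_domain_path <- file.path(dir, "panel_domains.faa")
  panel_full_path <- file.path(dir, "panel_full.faa")
  labels_path <- file.path(dir, "panel_labels.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  write_fasta(unname(fam$domains[panel_ids]), panel_domain_path)
  write_fasta(unname(fam$proteins[panel_ids]), panel_full_path)
  writeLines(c("# id\tsubfamily",
               paste(panel_ids, fam$labels[panel_ids], sep = "\t")),
             labels_path)
  utils::write.table(
    data.frame(id = names(fam$labels), subfamily = unname(fam$labels)),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(family = fam, proteome_paths = proteome_paths,
                 panel_domain_path = panel_domain_path,
                 panel_full_path = panel_full_path,
                 labels_path = labels_path, truth_path = truth_path,
                 panel_ids = panel_ids))
}
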