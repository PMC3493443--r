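# Distances from an alignment, neighbor joining, bootstrap bipartition
# support and the clade-support query that decides whether a candidate
# groups with the target subfamily. Trees are ape "phylo" objects; bootstrap
# supports (percentages) live in node.label.

#' Construct a distance matrix object
#'
#' @param ids Taxon ids (ordered).
#' @param d Symmetric non-negative numeric matrix with zero diagonal.
#' @return An object of class `distance_matrix` (list with `ids`, `d`).
#' @export
distance_matrix <- function(ids, d) {
  d <- as.matrix(d)
  if (nrow(d) != length(ids) || ncol(d) != length(ids))
    stop("distance matrix dimensions do not match ids")
  dimnames(d) <- list(ids, ids)
  if (any(!is.finite(d))) stop("non-finite distances")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("non-zero diagonal")
  structure(list(ids = as.character(ids), d = d), class = "distance_matrix")
}

#' Pairwise distances from a multiple alignment
#'
#' Uses pairwise deletion: for each pair, only columns where neither row is
#' gapped are compared. `model = "p"` gives the proportion of differing
#' columns; `model = "poisson"` applies the multiple-hit correction
#' `-ln(1 - p)`.
#'
#' @param msa A [multiple_alignment()] with >= 2 rows.
#' @param model `"p"` (default) or `"poisson"`.
#' @return A [distance_matrix()].
#' @export
distances <- function(msa, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- as.matrix(msa)
  if (nrow(m) < 2L) stop("need >= 2 sequences")
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    comp <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(comp))
      stop("no comparable columns between '", msa$ids[i], "' and '",
           msa$ids[j], "'")
    p <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    if (model == "poisson") {
      if (p >= 1) stop("saturated pair ('", msa$ids[i], "', '", msa$ids[j],
                       "'): p >= 1 under the Poisson correction")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  distance_matrix(msa$ids, d)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining (via ape's implementation) on a
#' validated distance matrix. Negative branch lengths, which NJ can produce,
#' are clamped to zero with a warning (topology is unaffected). Two taxa give
#' the trivial single-edge tree.
#'
#' @param dm A [distance_matrix()] (or a symmetric matrix with dimnames).
#' @return An unrooted `phylo` object (class from ape).
#' @export
neighbor_joining <- function(dm) {
  if (!inherits(dm, "distance_matrix"))
    dm <- distance_matrix(rownames(as.matrix(dm)), dm)
  n <- length(dm$ids)
  if (n < 2L) stop("need >= 2 taxa")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", dm$ids[1L],
                                        dm$d[1L, 2L] / 2, dm$ids[2L],
                                        dm$d[1L, 2L] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dm$d))
  if (any(tr$edge.length < 0)) {
    warning("clamped ", sum(tr$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# Canonical bipartitions of an unrooted tree: for every internal edge, the
# tip-label set on the side NOT containing the reference tip (first label
# alphabetically), as a sorted, "|"-collapsed key. Trivial splits excluded.
tree_splits <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1L]
  ntip <- length(labs)
  nodes <- setdiff(unique(tree$edge[, 1L]), ntip + 1L) # non-root internals
  # also the root's child internal nodes give splits via their clades
  internal <- unique(tree$edge[tree$edge[, 2L] > ntip, 2L])
  out <- character(0); sides <- list()
  for (nd in internal) {
    tips <- labs[phangorn::Descendants(tree, nd, type = "tips")[[1L]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    key <- paste(sort(side), collapse = "|")
    if (!(key %in% out)) { out <- c(out, key); sides[[key]] <- side }
  }
  sides
}

#' Bootstrap bipartition support for a neighbor-joining tree
#'
#' Computes the point-estimate NJ tree from the alignment, then resamples
#' alignment columns with replacement `n_replicates` times, rebuilds an NJ
#' tree per replicate, and attaches to each internal edge of the point tree
#' the percentage of replicate trees containing its bipartition. Fully
#' reproducible for a fixed seed.
#'
#' @param msa A [multiple_alignment()].
#' @param model Distance model passed to [distances()].
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the column resampler.
#' @return A `phylo` tree with `node.label` holding integer percentage
#'   supports for internal edges (empty for the root/trivial labels).
#' @export
bootstrap_support <- function(msa, model = "p", n_replicates = 100L,
                              seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  point <- neighbor_joining(distances(msa, model))
  target <- tree_splits(point)
  counts <- stats::setNames(numeric(length(target)), names(target))
  m <- as.matrix(msa)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rep_msa <- multiple_alignment(msa$ids,
                                  apply(m[, cols, drop = FALSE], 1L, paste,
                                        collapse = ""))
    rep_tree <- tryCatch(
      suppressWarnings(neighbor_joining(distances(rep_msa, model))),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    hits <- names(tree_splits(rep_tree))
    counts[intersect(names(counts), hits)] <-
      counts[intersect(names(counts), hits)] + 1
  }
  support <- round(100 * counts / n_replicates)
  attach_supports(point, support)
}

# write per-split supports into node.label of the point tree
attach_supports <- function(tree, support) {
  labs <- tree$tip.label; ref <- sort(labs)[1L]; ntip <- length(labs)
  nl <- character(tree$Nnode)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  for (k in seq_along(internal)) {
    nd <- internal[k]
    tips <- labs[phangorn::Descendants(tree, nd, type = "tips")[[1L]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) { nl[k] <- ""; next }
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    key <- paste(sort(side), collapse = "|")
    nl[k] <- if (key %in% names(support))
      as.character(support[[key]]) else ""
  }
  tree$node.label <- nl
  tree
}

#' Does a query leaf group with the target subfamily?
#'
#' Finds the smallest clade (bipartition side) of the tree that contains the
#' query and at least one labeled panel leaf. The query "groups" with the
#' target subfamily when every panel leaf inside that clade carries the target
#' label (unlabeled leaves are ignored). The returned support is the bootstrap
#' value of the edge defining that clade, if present.
#'
#' @param tree A `phylo` tree (node.label supports optional).
#' @param query_id A leaf of the tree.
#' @param panel_labels Named character vector: panel leaf id -> subfamily.
#' @param target Target subfamily label (default `"FoxJ1"`).
#' @return List with `grouped` (logical), `support` (percentage or `NA`) and
#'   `nearest` (subfamily labels of panel leaves in the minimal clade).
#' @export
clade_support <- function(tree, query_id, panel_labels, target = "FoxJ1") {
  if (!(query_id %in% tree$tip.label))
    stop("query '", query_id, "' is not a leaf of the tree")
  panel_ids <- intersect(names(panel_labels), tree$tip.label)
  if (length(panel_ids) == 0L) stop("no panel leaves in tree")
  labs <- tree$tip.label; ref <- sort(labs)[1L]; ntip <- length(labs)
  nl <- tree$node.label
  # enumerate both sides of every internal edge, with its support
  candidates <- list()
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  for (k in seq_along(internal)) {
    nd <- internal[k]
    tips <- labs[phangorn::Descendants(tree, nd, type = "tips")[[1L]]]
    supp <- if (!is.null(nl) && k <= length(nl) && nzchar(nl[k]))
      as.numeric(nl[k]) else NA_real_
    for (side in list(tips, setdiff(labs, tips))) {
      if (length(side) < 2L || length(side) >= ntip) next
      if (!(query_id %in% side)) next
      inside <- intersect(side, panel_ids)
      if (length(inside) == 0L) next
      candidates[[length(candidates) + 1L]] <-
        list(side = side, support = supp)
    }
  }
  if (length(candidates) == 0L)
    return(list(grouped = FALSE, support = NA_real_, nearest = character()))
  sizes <- vapply(candidates, function(x) length(x$side), integer(1L))
  best <- candidates[[which.min(sizes)]]
  inside_labels <- panel_labels[intersect(best$side, panel_ids)]
  grouped <- all(inside_labels == target) && length(inside_labels) > 0L
  list(grouped = grouped,
       support = if (grouped) best$support else NA_real_,
       nearest = unname(inside_labels))
}

#' Write a tree to a newick file
#'
#' Bootstrap supports are written as internal node labels.
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path Path to a newick file.
#' @return A `phylo` object (internal node labels preserved).
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a PHYLIP square distance matrix
#' @param dm A [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$ids)), con)
  for (i in seq_along(dm$ids))
    writeLines(paste0(sprintf("%-10s", substr(dm$ids[i], 1L, 10L)),
                      paste(sprintf("%.6f", dm$d[i, ]), collapse = "  ")),
               con)
  invisible(path)
}
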