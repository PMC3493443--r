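test_that("p and Poisson distances follow their closed forms", {
  m <- multiple_alignment(c("a", "b"),
                          c("AAAAAAAAAA", "AAAAACCCCC"))
  expect_equal(distances(m, "p")$d["a", "b"], 0.5)
  expect_equal(distances(m, "poisson")$d["a", "b"], -log(0.5),
               tolerance = 1e-6)  # 0.693147
  ident <- multiple_alignment(c("a", "b"), c("ACDE", "ACDE"))
  expect_equal(ident <- distances(ident, "p")$d["a", "b"], 0)
})

test_that("gap handling uses pairwise deletion and flags degenerate pairs", {
  m <- multiple_alignment(c("a", "b"), c("AC-E", "-CDE"))
  # comparable columns: 2 and 4; one mismatch would be 0 here
  expect_equal(distances(m, "p")$d["a", "b"], 0)
  m2 <- multiple_alignment(c("a", "b"), c("AC--", "--DE"))
  expect_error(distances(m2), "comparable")
  m3 <- multiple_alignment(c("a", "b"), c("ACDE", "WXYF"))
  expect_error(distances(m3, "poisson"), "saturated")
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  dm <- distance_matrix(c("A", "B", "C"),
                        matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3))
  tr <- neighbor_joining(dm)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
})

test_that("a four-taxon additive matrix is inverted exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(distance_matrix(LETTERS[1:4], d))
  # split AB|CD present
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  # patristic distances reproduce the input exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4],
                                                    LETTERS[1:4]], d,
               tolerance = 1e-10)
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(41)
  recovered <- vapply(1:30, function(i) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n)
    d <- ape::cophenetic.phylo(true)
    got <- neighbor_joining(distance_matrix(rownames(d), d))
    ape::dist.topo(ape::unroot(got), ape::unroot(true)) == 0
  }, logical(1))
  expect_true(all(recovered))
})

test_that("invalid distance input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(distance_matrix(c("a", "b"), m), "symmetric")
  expect_error(distance_matrix(c("a", "b"),
                               matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

make_split_alignment <- function() {
  # two clearly separated 4-leaf clusters with 200 informative columns
  ids <- paste0("t", 1:8)
  left <- matrix(rep(c(rep("A", 100), rep("C", 100)), 4), 4, 200,
                 byrow = TRUE)
  right <- matrix(rep(c(rep("A", 100), rep("W", 100)), 4), 4, 200,
                  byrow = TRUE)
  mat <- rbind(left, right)
  set.seed(5)
  for (i in 1:8) mat[i, sample(200, 5)] <- sample(c("G","H","K","R","S"), 5,
                                                  replace = TRUE)
  multiple_alignment(ids, apply(mat, 1, paste, collapse = ""))
}

test_that("bootstrap supports are percentages, deterministic per seed, and
           saturate on an unambiguous split", {
  msa <- make_split_alignment()
  bt <- bootstrap_support(msa, "p", n_replicates = 100, seed = 1)
  supports <- suppressWarnings(as.numeric(bt$node.label))
  supports <- supports[!is.na(supports)]
  expect_true(all(supports >= 0 & supports <= 100))
  # central split separates t1-t4 from t5-t8 at full support
  splits <- foxscan:::tree_splits(bt)
  key <- paste(sort(paste0("t", 5:8)), collapse = "|")
  alt <- paste(sort(paste0("t", 1:4)), collapse = "|")
  expect_true(key %in% names(splits) || alt %in% names(splits))
  labs <- bt$node.label
  expect_true("100" %in% labs)
  bt2 <- bootstrap_support(msa, "p", n_replicates = 100, seed = 1)
  expect_identical(bt$node.label, bt2$node.label)
  bt3 <- bootstrap_support(msa, "p", n_replicates = 100, seed = 2)
  expect_identical(ape::write.tree(bt3), ape::write.tree(bt3))
  expect_error(bootstrap_support(msa, "p", n_replicates = 0), ">= 1")
})

test_that("newick output round-trips topology, lengths and supports", {
  msa <- make_split_alignment()
  bt <- bootstrap_support(msa, "p", n_replicates = 50, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(back, bt), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(bt$edge.length),
               tolerance = 1e-6)
  expect_identical(sort(back$node.label), sort(bt$node.label))
})

test_that("clade support finds the nearest-reference clade and its purity", {
  # query inside the FoxJ1 pair
  tr <- ape::read.tree(
    text = "((q:1,(j1a:1,j1b:1)100:1)100:1,(j2:1,n3:1)100:2);")
  labels <- setNames(c("FoxJ1", "FoxJ1", "FoxJ2", "FoxN3"),
                     c("j1a", "j1b", "j2", "n3"))
  got <- clade_support(tr, "q", labels)
  expect_true(got$grouped)
  expect_equal(got$support, 100)
  # query nested within FoxJ2 references
  tr2 <- ape::read.tree(
    text = "((q:1,(j2a:1,j2b:1)90:1)80:1,(j1:1,n3:1)100:2);")
  labels2 <- setNames(c("FoxJ2", "FoxJ2", "FoxJ1", "FoxN3"),
                      c("j2a", "j2b", "j1", "n3"))
  got2 <- clade_support(tr2, "q", labels2)
  expect_false(got2$grouped)
  # weakly supported grouping is reported as grouped with its support;
  # the classifier, not the tree query, refuses to call it definite
  tr3 <- ape::read.tree(
    text = "((q:1,j1:1)49:1,(j2:1,(n3:1,k1:1)99:1)99:2);")
  labels3 <- setNames(c("FoxJ1", "FoxJ2", "FoxN3", "FoxK1"),
                      c("j1", "j2", "n3", "k1"))
  got3 <- clade_support(tr3, "q", labels3)
  expect_true(got3$grouped)
  expect_equal(got3$support, 49)
  call <- call_ortholog(evidence_record("q", "org", domain_grouped = TRUE,
                                        domain_support = 49,
                                        rbh_call = "FoxJ1"))
  expect_identical(call$category, "candidate")
  expect_error(clade_support(tr, "nope", labels), "not a leaf")
})
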