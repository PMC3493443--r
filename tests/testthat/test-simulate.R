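small_params <- function(...) {
  simulation_params(n_subfamilies = 3L, taxa_per_subfamily = 3L,
                    domain_length = 60L, flank_length = 40L, ...)
}

test_that("zero evolutionary rates reproduce the root everywhere", {
  fam <- simulate_family(small_params(domain_rate = 0, flank_rate = 0,
                                      seed = 61))
  res <- vapply(fam$proteins, function(p) p$residues, character(1))
  expect_identical(length(unique(res)), 1L)
})

test_that("the same seed gives byte-identical families", {
  a <- simulate_family(small_params(seed = 62))
  b <- simulate_family(small_params(seed = 62))
  expect_identical(vapply(a$proteins, `[[`, "", "residues"),
                   vapply(b$proteins, `[[`, "", "residues"))
  expect_identical(ape::write.tree(a$true_tree),
                   ape::write.tree(b$true_tree))
  c <- simulate_family(small_params(seed = 63))
  expect_false(identical(vapply(a$proteins, `[[`, "", "residues"),
                         vapply(c$proteins, `[[`, "", "residues")))
})

test_that("recorded domain regions excise the simulated domain exactly", {
  fam <- simulate_family(small_params(seed = 64, indel_rate = 0.02))
  for (id in names(fam$proteins)) {
    reg <- attr(fam$proteins[[id]], "domain_region")
    expect_identical(substr(fam$proteins[[id]]$residues, reg[1], reg[2]),
                     fam$domains[[id]]$residues)
  }
})

test_that("domain identity decays per the 20-state Poisson closed form", {
  # two leaves at total path length t: identity ~ 1/20 + (19/20) e^(-20rt/19)
  rate <- 0.25; t_total <- 1.0; n_pairs <- 200L; L <- 100L
  set.seed(65)
  idents <- vapply(seq_len(n_pairs), function(k) {
    root <- foxscan:::random_residues(L)
    a <- foxscan:::evolve_branch(root, rate, t_total / 2)
    b <- foxscan:::evolve_branch(root, rate, t_total / 2)
    mean(a == b)
  }, numeric(1))
  expected <- 1 / 20 + (19 / 20) * exp(-20 * rate * t_total / 19)
  se <- stats::sd(idents) / sqrt(n_pairs)
  expect_lt(abs(mean(idents) - expected), 3 * se)
})

test_that("mean pairwise identity is non-increasing in the domain rate", {
  mean_ident <- function(rate) {
    fam <- simulate_family(small_params(domain_rate = rate,
                                        flank_rate = max(rate, 1), seed = 66))
    doms <- vapply(fam$domains, `[[`, "", "residues")
    pairs <- utils::combn(length(doms), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      a <- strsplit(doms[pairs[1, k]], "")[[1]]
      b <- strsplit(doms[pairs[2, k]], "")[[1]]
      mean(a == b)
    }, numeric(1)))
  }
  idents <- vapply(c(0, 0.1, 0.3, 0.8), mean_ident, numeric(1))
  expect_true(all(diff(idents) <= 0))
})

test_that("generated trees are additive and subfamilies are recoverable", {
  fam <- simulate_family(small_params(domain_rate = 0.05, flank_rate = 0.05,
                                      seed = 67))
  # additivity by construction: NJ inverts the true path-length distances
  d_true <- ape::cophenetic.phylo(fam$true_tree)
  tr_add <- neighbor_joining(distance_matrix(rownames(d_true), d_true))
  expect_equal(ape::dist.topo(ape::unroot(tr_add),
                              ape::unroot(fam$true_tree)), 0,
               ignore_attr = TRUE)
  # sequence-estimated distances recover the deep structure (subfamily
  # monophyly); the shortest within-subfamily branches carry too few
  # expected substitutions for exact recovery to be a fair requirement
  seqs <- vapply(fam$proteins, `[[`, "", "residues")
  msa <- multiple_alignment(names(seqs), seqs)  # equal-length, ungapped
  tr <- suppressWarnings(neighbor_joining(distances(msa, "p")))
  splits <- names(foxscan:::tree_splits(tr))
  for (sf in fam$params$subfamily_names) {
    members <- sort(names(fam$labels)[fam$labels == sf])
    key <- paste(members, collapse = "|")
    alt <- paste(sort(setdiff(tr$tip.label, members)), collapse = "|")
    expect_true(key %in% splits || alt %in% splits,
                info = paste("subfamily", sf, "not monophyletic"))
  }
})

test_that("the survey fixture writes panel, proteomes and truth labels", {
  dir <- withr::local_tempdir()
  fx <- make_survey_fixture(small_params(seed = 68), dir)
  panel <- load_panel(fx$panel_domain_path, fx$labels_path,
                      fulllength_path = fx$panel_full_path)
  expect_length(panel$ids, 3L)
  expect_identical(sum(panel$subfamily == "FoxJ1"), 1L)
  truth <- read.delim(fx$truth_path)
  expect_identical(nrow(truth), 9L)  # n_subfamilies x taxa_per_subfamily
  expect_length(fx$proteome_paths, 9L)
  prot <- read_fasta(fx$proteome_paths[[1]])
  expect_length(prot, 1L + 3L)  # family protein + 3 decoys
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(n_subfamilies = 0), ">= 1")
  expect_error(simulation_params(domain_rate = -1), ">= 0")
  expect_error(simulation_params(domain_rate = 2, flank_rate = 1), "flank")
})
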