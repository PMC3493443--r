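toy_panel <- function() {
  set.seed(51)
  alph <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F")
  doms <- lapply(1:4, function(i)
    seq_record(paste0("ref", i), random_protein(60, alph)))
  subfams <- c("FoxJ1", "FoxJ2", "FoxN3", "FoxK1")
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_fasta(doms, file.path(dir, "p.faa"))
  writeLines(paste(paste0("ref", 1:4), subfams, sep = "\t"),
             file.path(dir, "l.tsv"))
  load_panel(file.path(dir, "p.faa"), file.path(dir, "l.tsv"))
}

test_that("a panel member reverse-hits its own subfamily with margin", {
  panel <- toy_panel()
  got <- reverse_best_hit(panel$domain$ref2, panel)
  expect_identical(got$call, "FoxJ2")
  expect_gt(got$margin, 0)
})

test_that("a moderately diverged descendant reverse-hits its source", {
  panel <- toy_panel()
  set.seed(52)
  res <- strsplit(panel$domain$ref1$residues, "")[[1]]
  flip <- sample(60, 12)  # 20% substitutions
  res[flip] <- sample(c("A","R","N","D","C"), 12, replace = TRUE)
  desc <- seq_record("desc", paste(res, collapse = ""))
  got <- reverse_best_hit(desc, panel)
  expect_identical(got$call, "FoxJ1")
})

test_that("no positive-scoring hit yields an absent call", {
  dir <- withr::local_tempdir()
  write_fasta(list(seq_record("r1", strrep("P", 40)),
                   seq_record("r2", strrep("G", 40))),
              file.path(dir, "p.faa"))
  writeLines(c("r1\tFoxJ1", "r2\tFoxJ2"), file.path(dir, "l.tsv"))
  panel <- load_panel(file.path(dir, "p.faa"), file.path(dir, "l.tsv"))
  got <- reverse_best_hit(seq_record("w", strrep("W", 30)), panel)
  expect_true(is.na(got$call))  # W scores negatively against P and G
  expect_true(is.na(got$margin))
})

test_that("ortholog categories follow the decision rules", {
  definite <- call_ortholog(evidence_record(
    "a", "Trichoplax", rbh_call = "FoxJ1", domain_grouped = TRUE,
    domain_support = 99))
  expect_identical(definite$category, "definite")

  weak_bs <- call_ortholog(evidence_record(
    "b", "Hydra", rbh_call = "FoxJ1", domain_grouped = TRUE,
    domain_support = 49))
  expect_identical(weak_bs$category, "candidate")

  two_of_three <- call_ortholog(evidence_record(
    "c", "Saccharomyces", rbh_call = "FoxJ1", domain_grouped = FALSE,
    fulllength_grouped = TRUE))
  expect_identical(two_of_three$category, "candidate")
  expect_setequal(two_of_three$methods_supporting,
                  c("reverse_hit", "fulllength_phylogeny"))

  nothing <- call_ortholog(evidence_record("d", "Drosophila"))
  expect_identical(nothing$category, "not_detected")

  single_weak <- call_ortholog(evidence_record(
    "e", "Monosiga", rbh_call = "FoxJ1"))
  expect_identical(single_weak$category, "candidate")
  expect_match(single_weak$rationale, "weak")
})

test_that("conflicting reverse-hit and phylogeny evidence is representable", {
  ev <- evidence_record("f", "Schizosaccharomyces", rbh_call = "FoxD2",
                        domain_grouped = TRUE, domain_support = 52)
  call <- call_ortholog(ev)
  expect_identical(call$category, "candidate")
  expect_identical(call$methods_supporting, "domain_phylogeny")
  expect_identical(ev$rbh_call, "FoxD2")  # conflict recorded, not resolved
})

test_that("raising the support threshold never increases definite calls", {
  ev <- do.call(rbind, lapply(1:20, function(i)
    evidence_record(paste0("p", i), paste0("org", i), rbh_call = "FoxJ1",
                    domain_grouped = TRUE, domain_support = 5 * i)))
  n_def <- vapply(c(0, 25, 50, 75, 90, 95, 99),
                  function(th) survey_report(ev, th)$summary$n_definite,
                  numeric(1))
  expect_true(all(diff(n_def) <= 0))
})

test_that("every definite record also satisfies the >= 1 method condition", {
  ev <- load_survey_evidence()
  rep <- survey_report(ev)
  tab <- rep$table
  expect_true(all(tab$n_methods[tab$category == "definite"] >= 1L))
})

test_that("survey_report rejects duplicates and handles empty evidence", {
  ev <- rbind(evidence_record("x", "o"), evidence_record("x", "o"))
  expect_error(survey_report(ev), "duplicate")
  empty <- evidence_record("x", "o")[0, ]
  rep <- survey_report(empty)
  expect_identical(rep$summary$n_proteins, 0L)
  expect_identical(rep$summary$n_definite, 0L)
})

test_that("evidence tables round-trip through TSV", {
  ev <- load_survey_evidence()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_evidence(ev, f)
  back <- read_evidence(f)
  expect_identical(nrow(back), nrow(ev))
  expect_equal(back$domain_support, ev$domain_support)
  expect_identical(back$rbh_call, ev$rbh_call)
})
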