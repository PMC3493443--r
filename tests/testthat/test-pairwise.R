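sc_local <- scoring_scheme()           # BLOSUM62, 11/1
sc_global <- global_scheme()           # BLOSUM62, 10/1

test_that("identity local alignment scores the BLOSUM62 diagonal", {
  aln <- smith_waterman(seq_record("a", "ACDE"), seq_record("b", "ACDE"))
  expect_identical(aln$raw_score, 24L)  # 4 + 9 + 6 + 5
  expect_identical(aln$n_identical, 4L)
  expect_identical(aln$n_columns, 4L)
  expect_identical(unname(percent_identity(aln)["rounded"]), 100)
})

test_that("degenerate local inputs give the empty alignment, not errors", {
  empty <- suppressWarnings(seq_record("e", "A"))
  empty$residues <- ""
  aln <- smith_waterman(seq_record("a", "ACDE"), empty)
  expect_identical(aln$raw_score, 0L)
  expect_identical(aln$n_columns, 0L)
  expect_error(percent_identity(aln), "empty")
  expect_error(needleman_wunsch(empty, empty), "empty")
})

test_that("global alignment of identical sequences has no gaps", {
  aln <- needleman_wunsch(seq_record("a", "MKTAYIAK"),
                          seq_record("b", "MKTAYIAK"))
  expect_identical(aln$n_identical, aln$n_columns)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
})

test_that("percent identity uses all alignment columns", {
  aln <- structure(list(n_identical = 5L, n_columns = 10L),
                   class = "alignment_result")
  expect_equal(unname(percent_identity(aln)), c(50, 50))
})

test_that("the R reference DP agrees with exhaustive enumeration", {
  S <- sc_local$scores
  set.seed(42)
  for (k in 1:12) {
    a <- random_protein(sample(1:4, 1)); b <- random_protein(sample(1:4, 1))
    expect_equal(oracle_dp(a, b, S, 11, 1, local = FALSE),
                 oracle_enum_global(a, b, S, 11, 1),
                 info = paste(a, b, "global"))
    expect_equal(oracle_dp(a, b, S, 11, 1, local = TRUE),
                 oracle_enum_local(a, b, S, 11, 1),
                 info = paste(a, b, "local"))
  }
})

test_that("local and global scores match the reference DP on random pairs", {
  set.seed(7)
  for (k in 1:40) {
    a <- random_protein(sample(1:8, 1), c("A", "C", "D", "E"))
    b <- random_protein(sample(1:8, 1), c("A", "C", "D", "E"))
    got <- smith_waterman(seq_record("a", a), seq_record("b", b), sc_local)
    expect_equal(got$raw_score,
                 oracle_dp(a, b, sc_local$scores, 11, 1, local = TRUE),
                 info = paste("local", a, b))
  }
  for (k in 1:40) {
    a <- random_protein(sample(1:6, 1), c("A", "C", "W", "G"))
    b <- random_protein(sample(1:6, 1), c("A", "C", "W", "G"))
    got <- needleman_wunsch(seq_record("a", a), seq_record("b", b), sc_global)
    expect_equal(got$raw_score,
                 oracle_dp(a, b, sc_global$scores, 10, 1, local = FALSE),
                 info = paste("global", a, b))
  }
})

test_that("alignment scores are symmetric and local >= 0", {
  set.seed(11)
  for (k in 1:10) {
    a <- seq_record("a", random_protein(10, c("A", "R", "N", "D", "W")))
    b <- seq_record("b", random_protein(12, c("A", "R", "N", "D", "W")))
    ab <- smith_waterman(a, b); ba <- smith_waterman(b, a)
    expect_identical(ab$raw_score, ba$raw_score)
    expect_gte(ab$raw_score, 0L)
    gab <- needleman_wunsch(a, b); gba <- needleman_wunsch(b, a)
    expect_identical(gab$raw_score, gba$raw_score)
    expect_identical(gab$n_identical, gba$n_identical)
  }
})

test_that("E-values follow the closed form and decrease in bit score", {
  expect_equal(evalue(0, 25, 4e3), 1e5)            # E = m*n at 0 bits
  expect_equal(evalue(20, 100, 1e6), 1e8 * 2^-20)  # ~95.367
  bits <- seq(0, 60, by = 5)
  expect_true(all(diff(evalue(bits, 100, 1e6)) < 0))
  expect_error(evalue(10, 0, 100), "positive")
})

test_that("search filters by E-value and ranks the self-hit first", {
  set.seed(3)
  db <- lapply(1:6, function(i)
    seq_record(paste0("s", i), random_protein(80, LETTERS[c(1, 3:5, 7)])))
  query <- db[[4]]
  hits <- search_database(query, db, threshold = 1e-2)
  expect_identical(hits$subject_id[1], "s4")
  expect_true(all(hits$evalue < 1e-2))
  expect_true(all(diff(hits$evalue) >= 0))
  none <- search_database(query, db, threshold = 0)
  expect_identical(nrow(none), 0L)
})
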