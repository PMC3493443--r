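# Independent alignment oracles used to check the package's aligners.
#
# oracle_enum_*: exhaustive enumeration of every gapped alignment (no dynamic
# programming), feasible only for very short sequences; the ground truth.
# oracle_dp_*: a plain-R three-state affine DP, itself validated against the
# enumeration at tiny sizes and then used to check the package up to the
# lengths the enumeration cannot reach.

oracle_enum_global <- function(a, b, scores, open, ext) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  rec <- function(i, j, prev) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L, "d") + scores[a[i], b[j]])
    if (i > 0L)
      best <- max(best, rec(i - 1L, j, "u") -
                    (if (prev == "u") ext else open + ext))
    if (j > 0L)
      best <- max(best, rec(i, j - 1L, "l") -
                    (if (prev == "l") ext else open + ext))
    best
  }
  rec(length(a), length(b), "d")
}

oracle_enum_local <- function(a, b, scores, open, ext) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in seq_len(na)) for (i2 in i1:na)
    for (j1 in seq_len(nb)) for (j2 in j1:nb)
      best <- max(best, oracle_enum_global(substr(a, i1, i2),
                                           substr(b, j1, j2),
                                           scores, open, ext))
  best
}

oracle_dp <- function(a, b, scores, open, ext, local = FALSE) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  na <- length(a); nb <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, na + 1L, nb + 1L)
  X <- matrix(NEG, na + 1L, nb + 1L) # gap in b (consume a)
  Y <- matrix(NEG, na + 1L, nb + 1L)
  M[1L, 1L] <- 0
  if (!local) {
    for (i in seq_len(na)) X[i + 1L, 1L] <- -open - ext * i
    for (j in seq_len(nb)) Y[1L, j + 1L] <- -open - ext * j
  }
  best_local <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d <- max(M[i, j], X[i, j], Y[i, j])
    if (local) d <- max(d, 0)
    M[i + 1L, j + 1L] <- d + scores[a[i], b[j]]
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                             Y[i, j + 1L] - open - ext,
                             X[i, j + 1L] - ext)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                             X[i + 1L, j] - open - ext,
                             Y[i + 1L, j] - ext)
    if (local) best_local <- max(best_local, M[i + 1L, j + 1L])
  }
  if (local) best_local else max(M[na + 1L, nb + 1L], X[na + 1L, nb + 1L],
                                 Y[na + 1L, nb + 1L])
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small labeled panel built in code (synthetic ids/subfamilies)
make_toy_panel <- function(dir, n = 6L, target = "FoxJ1") {
  subfams <- c(target, "FoxJ2", "FoxN3", "FoxK1", "FoxA1", "FoxD2")[seq_len(n)]
  set.seed(99)
  doms <- lapply(seq_len(n), function(i)
    seq_record(paste0("ref", i),
               paste(sample(c("A","R","N","D","C","Q","E","G","H","I"),
                            60, replace = TRUE), collapse = "")))
  dp <- file.path(dir, "panel.faa"); lp <- file.path(dir, "labels.tsv")
  write_fasta(doms, dp)
  writeLines(paste(paste0("ref", seq_len(n)), subfams, sep = "\t"), lp)
  list(domain_path = dp, labels_path = lp, subfams = subfams)
}
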