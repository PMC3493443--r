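#!/usr/bin/env Rscript
# Optional network helper (the package itself never requires network).
#
# Fetches the six public reference proteins used by the percent-identity
# checks, excises their forkhead (FKH) domains, and writes
# inst/extdata/fkh_reference_domains.faa with the record ids the tests
# expect:
#
#   Hs_FOXJ1_FKH     human FOXJ1 (UniProt Q92949), FKH domain
#   Mm_FoxJ1_FKH     mouse Foxj1 (UniProt Q61660), FKH domain
#   Mm_FoxJ2_FKH     mouse Foxj2 (UniProt Q9ES18), FKH domain
#   Mm_FoxN3_FKH     mouse Foxn3 (UniProt Q499D6), FKH domain
#   Sp_FoxJ1_FKH     Strongylocentrotus purpuratus FoxJ1, FKH domain
#   Pl_H4_FoxJ1_FKH  Placozoa sp. H4 FoxJ1 (GenBank JX569795 translation),
#                    FKH domain
#
# Domain boundaries: for the UniProt entries the annotated
# "DNA-binding region: Fork-head" feature is used; for the NCBI records the
# domain is excised by local alignment against the human FKH domain
# (extract_domain). Verify accessions before use; public annotations move.

suppressMessages(library(foxscan))

uniprot <- c(Hs_FOXJ1 = "Q92949", Mm_FoxJ1 = "Q61660",
             Mm_FoxJ2 = "Q9ES18", Mm_FoxN3 = "Q499D6")
ncbi <- c(Sp_FoxJ1 = "NP_001091801",  # check: S. purpuratus foxJ1
          Pl_H4_FoxJ1 = "AFV96069")   # JX569795 translation

`%||%` <- function(a, b) if (is.null(a)) b else a

fetch_url <- function(url) {
  tmp <- tempfile()
  utils::download.file(url, tmp, quiet = TRUE)
  tmp
}

records <- list()

for (nm in names(uniprot)) {
  acc <- uniprot[[nm]]
  fa <- fetch_url(sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", acc))
  rec <- read_fasta(fa)[[1L]]
  rec$id <- nm
  # FKH boundaries from the UniProt feature table (JSON)
  js <- jsonlite::read_json(sprintf(
    "https://rest.uniprot.org/uniprotkb/%s.json", acc))
  feats <- Filter(function(f)
    f$type %in% c("DNA binding", "DNA-binding region") &&
      grepl("Fork", f$description %||% "", ignore.case = TRUE),
    js$features)
  if (length(feats) == 0L) stop("no fork-head feature for ", acc)
  fr <- feats[[1L]]$location
  start <- fr$start$value; end <- fr$end$value
  records[[paste0(nm, "_FKH")]] <- seq_record(
    paste0(nm, "_FKH"), substr(rec$residues, start, end),
    description = paste0(acc, " ", start, "-", end),
    region = c(start, end), parent_id = acc)
}

human_fkh <- records$Hs_FOXJ1_FKH
for (nm in names(ncbi)) {
  acc <- ncbi[[nm]]
  fa <- fetch_url(sprintf(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=protein&id=%s&rettype=fasta&retmode=text",
    acc))
  rec <- read_fasta(fa)[[1L]]
  dom <- extract_domain(rec, human_fkh)
  dom$id <- paste0(nm, "_FKH")
  records[[dom$id]] <- dom
}

out <- file.path("inst", "extdata", "fkh_reference_domains.faa")
write_fasta(records, out)
cat("wrote", out, "with", length(records), "records\n")
cat("reinstall the package so system.file() finds the new file\n")
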