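# foxscan

Ortholog classification for Fox transcription-factor subfamilies.

## What this is for

Fox (forkhead-box) transcription factors share a highly conserved
~100-residue DNA-binding domain (the forkhead/FKH domain) and are divided
into subfamilies (FoxA–FoxS). Asking "does this genome encode a FoxJ1
ortholog?" — the question behind surveys of the motile-ciliogenesis master
regulator — cannot be answered by a similarity search alone, because every
Fox subfamily lights up when you search with an FKH domain. `foxscan`
implements the standard two-pronged desk procedure used by such surveys, as
a tested, reproducible pipeline:

1. **search** — affine-gap local alignment (BLOSUM62, gaps 11/1) of a
   reference FKH domain against each candidate proteome, keeping hits with
   Karlin–Altschul E-value below `1e-2`
   (`E = m·n·2^{-(λS − ln K)/ln 2}`, λ = 0.267, K = 0.041);
2. **domain excision** — the FKH-like region of each hit is cut out by local
   alignment against the reference domain;
3. **phylogeny** — progressive multiple alignment of the excised domain with
   a labeled subfamily panel, neighbor-joining tree on Poisson-corrected
   distances, bootstrap bipartition supports, and the clade query "does the
   candidate group with the target subfamily?";
4. **reverse best hit** — the candidate domain searched back against the
   labeled panel; the best-scoring subfamily (with a bit-score margin) is
   its assignment;
5. **decision rules** — *definite* ortholog iff grouped in the domain tree
   at bootstrap support > 95; *candidate* iff at least two of the three
   methods agree (or one, flagged weak); *not detected* otherwise.

A synthetic gene-family generator (known tree, conserved domain between
fast-evolving flanks, decoy proteins, truth labels) makes every stage — and
the end-to-end classifier — testable without any downloads. The package also
bundles the evidence table of a published eukaryote-wide FoxJ1 survey
(60 candidate proteins, 56 organisms) for exercising the decision rules on
real survey evidence.

## Worked example

Simulate a small family, survey it, and score the calls against the known
truth:

```r
library(foxscan)

fx <- make_survey_fixture(
  simulation_params(n_subfamilies = 3, taxa_per_subfamily = 2,
                    domain_length = 60, flank_length = 40, seed = 71),
  "fixture")

rep <- run_survey(list(
  proteome_paths    = as.list(fx$proteome_paths),
  panel_domain_path = fx$panel_domain_path,
  panel_full_path   = fx$panel_full_path,
  panel_labels_path = fx$labels_path,
  output_dir = "survey_out", n_replicates = 25, seed = 7))
rep
#> survey_report: 6 proteins; 2 identified (>=1 method); 2 definite; 0 candidate; 4 not detected

rep$table[rep$table$category != "not_detected",
          c("organism", "rbh_call", "domain_grouped", "domain_support", "category")]
#>   organism rbh_call domain_grouped domain_support category
#> 1 FoxJ1_t2    FoxJ1           TRUE            100 definite
#> 2 FoxJ1_t1    FoxJ1           TRUE            100 definite

score_survey(rep, fx$truth_path, "FoxJ1", panel_ids = fx$panel_ids)
#> $recall    [1] 1
#> $precision [1] 1
```

Both FoxJ1-subfamily organisms are recovered as definite orthologs (reverse
hit FoxJ1, grouped with the FoxJ1 panel reference at bootstrap 100); the
FoxJ2/FoxJ3 organisms, whose proteins also pass the E-value filter, are
correctly rejected by phylogeny and reverse hit. `survey_out/` contains the
evidence TSV, the per-candidate newick trees and a run-metadata JSON
(seed, thresholds, versions) so the run can be reproduced exactly.

Applying the decision rules to the bundled published survey table:

```r
rep <- survey_report(load_survey_evidence(), support_threshold = 95)
rep
#> survey_report: 60 proteins; 60 identified (>=1 method); 43 definite; 17 candidate; 0 not detected
rep$summary$two_of_three_organisms$Fungi
#> [1] "Coccidioides immitis"   "Coccidioides posadasii"
#> [3] "Eremothecium gossypii"  "Saccharomyces cerevisiae"
```

That is: 60 proteins carry at least one line of evidence, 43 are definite
orthologs (domain-tree grouping at bootstrap > 95), and exactly four fungal
species pass the two-of-three rule.

A thin command-line front end with `survey`, `simulate`, `identity`,
`search`, `extract-domain` and `tree` subcommands is installed at
`system.file("cli", "foxscan", package = "foxscan")`.

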