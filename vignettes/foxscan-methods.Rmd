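---
title: "foxscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foxscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxscan)
```

## The problem

Fox (forkhead-box) transcription factors share a highly conserved
~100-residue DNA-binding domain, the forkhead (FKH) domain, and fall into
named subfamilies (FoxA through FoxS). Deciding whether a genome encodes an
ortholog of one particular subfamily — the motivating case is FoxJ1, the
master regulator of motile ciliogenesis — is harder than finding FKH
domains: a similarity search with the FoxJ1 FKH domain retrieves members of
many subfamilies because the domain is conserved family-wide, while the
sequence outside the domain is too divergent to align reliably across phyla.

`foxscan` implements the classic two-pronged desk procedure for this
problem:

1. **Search.** Local alignment of a reference FKH domain against each
   candidate proteome; hits with E-value below `1e-2` are potential
   orthologs.
2. **Domain excision.** The FKH-like region of each hit is excised by local
   alignment against the reference domain.
3. **Phylogeny.** The excised domain is aligned with a labeled panel of
   subfamily representatives; a neighbor-joining (NJ) tree with bootstrap
   bipartition supports answers "does the candidate group with the target
   subfamily, and how strongly?". When full-length sequences exist the same
   question is asked of a full-length tree.
4. **Reverse best hit.** The candidate domain is searched back against the
   labeled panel; the subfamily of the best hit is its reverse-BLAST-style
   assignment.
5. **Decision rules.** *Definite* ortholog: grouped with the target
   subfamily in the domain tree at bootstrap support above 95.
   *Candidate*: at least two of the three methods (reverse hit, domain
   phylogeny, full-length phylogeny) agree — the rule used for weakly
   supported (e.g. fungal) hits — or a single method with the call flagged
   as weak. *Not detected* otherwise.

The package also ships the evidence table of a published eukaryote-wide
FoxJ1 survey (60 candidate proteins across 56 organisms, paralogs counted
separately). Applying the rules above to that table reproduces its headline
tallies — 60 proteins identified, 43 definite orthologs, four fungal species
supported by at least two methods, three by both reverse hit and domain
phylogeny:

```{r table1}
rep <- survey_report(load_survey_evidence(), support_threshold = 95)
rep
rep$summary$two_of_three_organisms$Fungi
rep$summary$rbh_and_domain_organisms$Fungi
```

## Alignment and search statistics

Pairwise alignment (Smith–Waterman local, Needleman–Wunsch global, both
affine-gap) is delegated to `Biostrings::pairwiseAlignment` behind the
package's interface; the first residue of a gap costs
`gap_open + gap_extend`, each further residue `gap_extend`. Defaults follow
protein-BLAST practice: BLOSUM62 with gaps 11/1 for local search, 10/1 for
global identity alignments. Raw scores convert to bit scores via the
Karlin–Altschul form $S' = (\lambda S - \ln K)/\ln 2$ with the published
gapped-BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$, and E-values are
$E = m\,n\,2^{-S'}$ for a length-$m$ query against $n$ database residues.
No heuristic seeding is used — every database sequence is aligned in full —
so at desk scale the search is exhaustive rather than BLAST-approximate.

Conventions worth making explicit:

* **Percent identity** is `100 * n_identical / n_columns` over **all**
  alignment columns of the global alignment, terminal gaps included. This is
  the most common reported convention; the alternatives (ungapped columns;
  shorter-sequence length) are easy to derive from the returned
  `alignment_result` if a published figure appears to use them.
* **Ambiguity codes**: `X`, `B`, `Z` score as in the published BLOSUM62
  rows; selenocysteine `U` is scored like cysteine. No masking is applied.
* **Ties** in the dynamic programming are broken by the library's
  deterministic traceback, so repeated runs give identical alignments.

## Multiple alignment

No installed R package provides progressive protein multiple alignment with
the contract needed here, so `progressive_align` implements it directly: a
guide tree by NJ on p-distances from all pairwise global alignments
(midpoint-rooted, as classic progressive aligners do), then postorder
profile–profile merges. Column pairs are scored by the arithmetic mean of
residue-pair substitution scores (gap residues contribute zero), with the
same affine penalties applied at profile level; the merge kernel is a small
C++ routine. Two sequences reduce exactly to the pairwise global alignment.
There is no iterative refinement, sequence weighting, or position-specific
penalty: the alignment's job in this pipeline is to support distance
estimation over a conserved domain, not to win alignment benchmarks.

## Distances, trees, supports

Distances from an alignment use **pairwise deletion** (only columns where
neither sequence is gapped are compared): domain alignments are short and
complete deletion would discard too much. Two models are available: the
p-distance, and the Poisson correction $-\ln(1-p)$.

The survey's default is the **Poisson correction**. The reason is visible in
the package's own simulations: full-length alignments are dominated by fast
flanking sequence near saturation, where the p-distance compresses large
distances, breaks additivity, and produces classic long-branch artifacts —
in an early run an out-subfamily query was pulled to the base of the tree
next to the target reference by exactly this mechanism. The correction is
the analogue of the "correct for multiple substitutions" setting of the
classic alignment GUIs. A pair with $p \ge 1$ under the correction is
reported as saturated rather than silently clamped.

Neighbor joining is the standard Saitou–Nei agglomeration (via `ape`);
negative branch lengths, which NJ can produce, are clamped to zero with a
warning (topology is unaffected). Bootstrap supports resample alignment
columns with replacement, rebuild an NJ tree per replicate, and attach to
each internal edge of the point-estimate tree the percentage of replicates
containing its bipartition; 100 replicates by default, and the seed is
recorded in the run metadata. Supports are attached by bipartition matching
against the point tree, not by majority-rule consensus.

**"Groups with the target subfamily"** is operationalized as: find the
smallest bipartition side containing the query and at least one labeled
panel leaf; the query groups iff every panel leaf inside it carries the
target label (unlabeled leaves are ignored). The support reported is the
bootstrap value of that edge. Published surveys state the grouping
qualitatively; this operationalization is one defensible reading and is
flagged as such — reports always carry the underlying tree so a reader can
disagree.

## Reverse best hit and decision rules

The reverse-hit database is the labeled panel itself, not a full
non-redundant protein database: this preserves the logic (best-subfamily
assignment with a margin) at desk scale. A margin below 1 bit between the
best and the best other-subfamily hit is reported as `ambiguous` rather than
a call — sub-bit differences are noise. Conflicts between reverse hit and
phylogeny (both occur in the bundled survey table) are recorded, never
auto-resolved.

The bundled survey's own prose applies "identified" to every protein with at
least one supporting method but reserves "identifiable" (for fungi) for at
least two; the package exposes both tallies (`n_proteins_identified` and the
per-group `two_of_three_organisms`) instead of guessing which is canonical.

## The synthetic gene family

`simulate_family` generates the structure the survey assumes: a subfamily
backbone tree (coalescent shape scaled to depth 1.0), within-subfamily trees
(depth 0.25) grafted on its tips, and a root protein of
flank–domain–flank architecture (150 + 100 + 150 residues) evolved along
every branch under a 20-state equal-exchangeability Poisson model — the
domain at 0.25 substitutions/site per unit branch, the flanks at 1.0.
Under this model the probability that a site is identical across a path of
length $t$ is $\tfrac1{20} + \tfrac{19}{20}e^{-20rt/19}$, which gives the
generator an exact closed-form oracle for its identity decay. At the default
depths this puts domains of different subfamilies at roughly 50–60% identity
and domains within a subfamily at 80–95% — the regime of real FKH-domain
surveys (where, e.g., FoxJ1 vs the closely related FoxJ2 is in the
mid-fifties). Decoys are i.i.d. uniform-composition proteins, three per
proteome. Indels are off by default; when enabled they use geometric lengths
(p = 0.5) and touch only the flanks, so recorded domain coordinates stay
exact.

What the generator deliberately does **not** emulate: empirical amino-acid
exchangeabilities, among-site rate variation, codon structure, domain
shuffling, and genome-scale decoy diversity. Passing the end-to-end checks
therefore demonstrates that the pipeline's logic is sound under a clean,
analytically tractable model — not that its thresholds are calibrated for
any particular real proteome.

One property needs care: NJ provably recovers the generating topology from
*additive* distances, and the generated trees are additive by construction
(tested by inverting the true path-length matrix). But distances *estimated
from sequences* are not additive, and coalescent-shaped trees routinely
contain internal branches carrying less than one expected substitution
across the entire simulated protein — no method can recover those. The
sequence-level test therefore asserts recovery of the deep structure
(subfamily monophyly) rather than of every cherry.

## Numerical and degenerate-input choices

* Empty sequences: local alignment returns the empty alignment with score 0;
  global alignment raises an error.
* A local search hit requires a strictly positive raw score in addition to
  the E-value cut.
* Domain excision below 70% reference coverage returns the record flagged
  `partial` (mirroring the longest-available-sequence pragmatism of
  published scans) rather than failing; no positive-scoring alignment at all
  is "domain not found".
* A bootstrap replicate whose resampled columns leave some pair with no
  comparable site (possible under pairwise deletion) contributes to no
  bipartition, while the denominator stays the requested replicate count —
  supports are conservative in that rare case.
* All stochastic stages (simulation, bootstrap, survey) restore the caller's
  RNG state and derive their streams from explicit seeds recorded in the
  run metadata.

## Problem sizes

The package's own test and acceptance runs use the generator defaults
(5 subfamilies × 8 taxa, 400-residue proteins, 3 decoys per proteome,
100 bootstrap replicates per candidate per analysis) for the end-to-end
check, and scaled-down families (3 × 2–3, shorter sequences, 25 replicates)
for the orchestration contract tests; alignment-oracle comparisons run on
exhaustively checkable lengths (≤ 8 residues for local, ≤ 6 for global).
These sizes were chosen to exercise every stage at the survey's stated
operating conditions while keeping a full run in the low minutes on one
core.

## Known limitations

* The aligner is exhaustive, so proteome-scale searches are slower than
  seeded BLAST; the intended scale is one gene family across tens of
  proteomes.
* The guide tree and profile scoring are deliberately simple; for
  publication-grade alignments of real data, export the sequences and use a
  dedicated aligner, then feed the alignment back in.
* Reverse best hit against a small labeled panel can be ambiguous where a
  full database would not be, and vice versa; margins are reported so the
  caller can tighten the tie threshold.
* The definite/candidate rules are faithful to the published survey's logic,
  including its asymmetries (full-length phylogeny only enters when
  full-length sequences exist).
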