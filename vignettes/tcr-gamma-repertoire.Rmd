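---
title: "Methods: germline modelling, amplicon simulation and repertoire analysis for the chicken TRG locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline modelling, amplicon simulation and repertoire analysis for the chicken TRG locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrgamma)
```

## Scope and model

The package analyses the expressed T cell receptor gamma (TRG) repertoire
of the chicken from 5' RACE amplicon sequencing. The chicken TRG locus has
a translocon layout: a large bank of variable (V) gene segments upstream
of three joining (J) segments and a single constant (C) gene. A mature
transcript is produced by somatic V-J recombination; the
complementarity-determining region 3 (CDR3) spans the junction, running
from the second conserved cysteine of the V segment (IMGT position 104) to
the phenylalanine of the J-encoded Phe-Gly-X-Gly motif, with both anchor
codons excluded. Junctional diversity comes from exonuclease trimming of
the recombining ends, palindromic (P) nucleotides at untrimmed ends, and
non-templated (N) insertions.

Four concerns are implemented as separate modules around this model: a
germline segment database with IMGT-style functionality classification, a
windowed-identity dot-plot operator for locus duplication structure, a
recombination/amplicon simulator with ground truth, and the read-processing
pipeline with repertoire statistics.

## Germline database and classification

A database couples a FASTA of coding sequences with a metadata table
(functionality, region boundaries, RSS annotation, locus coordinates; all
intervals 0-based half-open). Classification is three-way and total:

* **pseudo** - the reading frame across leader + V-REGION is broken
  (internal stop, or region boundaries incompatible with the frame, as
  caused by an indel);
* **ORF** - frame intact, but a conserved anchor (Cys23, Trp41, Cys104) is
  absent, or - when RSS evidence is demanded - no RSS annotation exists;
* **functional** otherwise.

Anchor positions are taken from the region map rather than re-derived:
Cys23 is the last codon of FR1, Cys104 the last codon of FR3, and Trp41 is
required within FR2. This follows the convention that region boundaries
are curated inputs; inferring IMGT numbering from raw sequence is out of
scope.

Subgroup clustering uses pairwise global-alignment nucleotide identity
over the FR1-start..FR3-end span (the span conventionally used for
phylogeny), single linkage, threshold 0.70 *inclusive* ("at least 70%").
Whether the published criterion used the full V-REGION or FR1-FR3 is not
stated; we fix FR1-FR3 and document it. Identity is matches divided by
alignment columns under end-gap-penalized global alignment (match +1,
mismatch -1, gap open 4, gap extend 1); for equal-length substitution-only
pairs this reduces to the Hamming fraction. Subgroup labels are assigned
in 3'-to-5' locus order of each cluster's first member, matching the
direction in which segments are conventionally numbered; without locus
coordinates the input order is used.

RSS scanning slides the canonical heptamer CACAGTG and nonamer ACAAAAACC
at a fixed 12- or 23-nt spacer. Defaults allow 2 heptamer and 3 nonamer
mismatches. The V-side spacer defaults to 23 - the usual configuration
for V segments joining a 12-spacer J side, adopted as a convention here -
and both the spacer and the budgets are arguments, not constants.

## The bundled germline fixture is synthetic

Real germline sequences are not redistributed. The packaged database
(`chicken-trg-synthetic.*`) reproduces the published *inventory
structure* - 44 V segments in six subgroups of 6/19/9/4/3/3 members with
28 functional, 3 ORF and 13 pseudogenes, three functional J segments, one
C gene - with generated sequences engineered to satisfy the same
classification criteria: every subgroup shares a mutated common ancestor
(within-subgroup identity about 80-90%, between-subgroup identity well
below 70%), functional members carry all anchors and a clean frame, ORF
members lack Trp41, pseudogenes carry an internal stop (one carries a 1-nt
frameshift instead). Generation is deterministic
(`synthetic_germline_db()`, fixed seed). Consequently fixture-based tests
validate the *operators*, not any real chicken sequence.

## Dot-plot operator

`windowed_dotplot()` follows the dotmatcher idiom at desk scale: ungapped
windows (default 300 bp), forward strand only, a dot where window identity
is at least the threshold (default 0.70). Numerical choices:

* windows are anchored at their midpoint; boundary windows that would be
  clipped are skipped, not padded, so every dot reflects a full-width
  comparison;
* the evaluation grid is strided (default 1 bp; 10 bp above 50 kb input),
  and self-comparisons compute only one triangle and mirror it;
* we threshold the raw identity fraction. dotmatcher thresholds a windowed
  match *score*; for unit match / zero mismatch scoring the two rules
  coincide, which is why raw identity was chosen;
* run detection (`find_homology_runs()`) merges dots on the same diagonal
  across gaps of at most twice the stride (one missing window), tolerating
  the window-level dropouts that diverged copies produce; gapped chaining
  across shifted diagonals is deliberately out of scope.

A tandemly duplicated unit of length `u` appears as off-diagonal runs at
offsets `u`, `2u`, `3u`, ... ; `unit_identity()` quantifies two spans by
global-alignment percent identity.

## Simulator: what it emulates, and what it does not

`simulate_dataset()` draws rearrangements V-J pair by configured weights
(uniform over functional segments by default; weights naming
non-functional segments are rejected), then assembles

```
UTR + leader + V[1 .. len - v_trim] + P_V + N + P_J + J[j_trim+1 ..] + C-prefix + revcomp(barcode)
```

* **Trims and inserts.** Per-end trim lengths and the N length follow
  truncated geometric distributions (defaults: trim p = 0.3 capped at 10,
  N p = 0.15 capped at 15, P length uniform on 0..2). Trimming and N/P
  insertion are pervasive at this locus but their length distributions
  are not quantified anywhere usable, so these are qualitative defaults
  chosen to give a roughly Gaussian CDR3-length spread; they are *not*
  calibrated to real thymus data, and no test treats the simulated
  length distribution as if they were.
* **P nucleotides** occur only at untrimmed ends and are the reverse
  complement of the terminal retained bases - standard hairpin-opening
  biology, adopted here as a design choice.
* **Trim caps.** A trim never removes the anchor codons (it is capped at
  the germline CDR3 contribution of its side), so every simulated read
  has a well-defined truth CDR3.
* **Anchor-spoof rejection.** Random junction bases can, with probability
  of order 1e-3, recreate a V- or J-side anchor motif inside the junction
  and make anchor-based extraction ambiguous. Such junctions are redrawn.
  This keeps truth records exact under the extraction rule at a
  negligible bias.
* **Empty junctions** (maximal trims on both sides, no inserts) are
  recorded non-productive: a CDR3 of zero amino acids is not a plausible
  receptor, and the pipeline applies the same convention.
* **Amplicon geometry.** Reads are 250 bp paired-end; the amplicon must
  be shorter than 500 bp so mates overlap and merge. Defaults (10-nt UTR
  padding, 20-nt C-primer site) give 447-489 bp amplicons - the insert
  exclusive of sequencing adapters, consistent with the 500-600 bp gel
  band of a full library molecule. The 12-nt sample barcode rides on the
  C-gene primer, so its reverse complement closes the amplicon.
* **Error model.** Substitutions only, constant Q37; indel errors, PCR
  bias, chimeras and UMIs are out of scope. Rearrangements are drawn
  before errors are applied, so the truth table at a fixed seed is
  invariant to the error rate - useful for paired clean/noisy
  comparisons.

Because the simulator is the only data source for end-to-end tests,
passing them demonstrates correct bookkeeping (merge, orientation,
demultiplexing, assignment, extraction, collapse are mutually consistent
and invertible at zero error) and robustness at the configured error
rate - not performance on real thymus libraries, which differ in error
structure, abundance skew and germline divergence.

## Pipeline decisions

* **Stage order**: merge -> demultiplex -> dereplicate full V-region
  strings -> assign V/J -> drop pseudo/ORF assignments -> extract CDR3 ->
  classify productivity -> collapse clonotypes. Dereplication before
  assignment matches the published bookkeeping (unique V-region counts
  are reported before the pseudo/ORF filter); collapse necessarily
  follows extraction since clonotypes are keyed by (V, J, CDR3). Every
  stage's drops are counted; nothing is silently discarded.
* **V/J assignment** is a seeded, gap-free local alignment: exact 12-mer
  seeds vote for segment/diagonal candidates; each candidate is scored by
  its maximal-scoring ungapped segment along the diagonal (match +1,
  mismatch -2), ties broken by higher identity then lexicographically
  smaller id; floors of 80% identity and 50 (V) / 20 (J) aligned bases.
  Gap-free extension is exact for this data model - the simulator and
  error model are substitution-only - and keeps the suite fast; the
  scoring constants are exposed for databases that need different
  stringency. J is searched strictly downstream of the V alignment end.
* **CDR3 extraction** applies the degenerate anchor patterns
  `TAC(T|C)A(T|C)TG(T|C)` (the first codon literally TAC, exactly as the
  motif is printed for this locus) and
  `TT(C|T)GG(C|A)(A/T)(C|G)(A|T)GG(A|T)`. The V-side anchor is the last
  match starting within a 54-bp window upstream of the V alignment end
  (plus 9 bp of slack); the window bounds spurious upstream matches since
  the anchor sits at the FR3 terminus. The J-side anchor is the first
  match after the V anchor. Anchor codons are excluded from the CDR3.
* **Productivity** is frame-exact: nonzero length divisible by three and
  a stop-free standard-code translation.

## Statistics conventions

* Usage and pairing frequencies are computed over **unique clonotypes** by
  default, matching an analysis of unique sequences; read-abundance
  weighting (`weighting = "abundance"`) is the estimator of generation
  probabilities and is what parameter-recovery checks use.
* CDR3 length statistics use nucleotide lengths of productive clonotypes;
  the amino-acid mean is exactly the nucleotide mean divided by three.
  The standard deviation uses the n-1 denominator by default
  (configurable). A pooled mean and per-individual means can differ in
  the second decimal; both computations are available via grouping.
* The amino-acid composition splits CDR3s into a normal band (4-22 aa)
  and an ultralong band (23-36 aa). The four-class table (hydrophobic
  A V L I P F M W G C; neutral-hydrophilic S T N Q Y; acidic D E; basic
  K R H) is a documented convention - the exact published class
  membership is not enumerated - and is replaceable via `class_table`.
* `retention_report()` implements the filter arithmetic: post-filter =
  unique - pseudo/ORF drops; productive percentage = productive /
  post-filter x 100, with the min-max range across samples.

## Problem sizes and determinism

Tests and the acceptance script run entirely on generated data at desk
scale, chosen as the smallest sizes at which the stochastic checks are
stable: 5,000 amplicons for round-trip recovery, 10,000 for parameter
recovery (tolerance 0.02 absolute), four 17-kb tandem units at 95% copy
identity for the dot-plot structure, and brute-force oracle comparisons
on inputs up to a few kb. Every stochastic path is seed-pinned; datasets
are byte-identical across runs at a fixed configuration.

## Known limitations

* The germline fixture is synthetic; nothing here validates real chicken
  germline annotation.
* Junctional-length defaults are qualitative, so simulated CDR3 length
  and productivity distributions are not comparable to published thymus
  values.
* Gap-free assignment will under-align reads with real indels
  (sequencing or somatic); gapped chaining and reverse-strand dot-plots
  are out of scope.
* Diversity indices, spectratyping and inter-individual statistics are
  intentionally not provided.
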