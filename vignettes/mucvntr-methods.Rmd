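---
title: "Methods: characterising protein-coding VNTRs with mucvntr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising protein-coding VNTRs with mucvntr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucvntr)
```

## The problem

The secreted airway mucins MUC5AC and MUC5B carry a very large central
exon encoding degenerate variable number tandem repeats (VNTRs):
serine/threonine-rich motifs of a fixed consensus period (8 aa for the
MUC5AC-type repeat, 29 aa for the MUC5B-type), interleaved with
cysteine-rich (cys) domains. Copy number and motif composition vary
between haplotypes, the loci are refractory to short reads, and the
surrounding SNP landscape carries selection and linkage signals that are
interesting in their own right. `mucvntr` implements the full desk-scale
analysis chain for such loci:

1. **Gene projection** — place a reference gene model on each phased
   haplotype assembly and predict its protein;
2. **Domain annotation** — segment the protein into cys and
   tandem-repeat (TR) domains and classify protein groups;
3. **Motif decomposition** — tile each TR domain with consensus-period
   motifs, build the cohort-wide motif catalogue, allele strings, usage
   matrices, UPGMA clusterings and position frequency matrices;
4. **Population genetics** — binned Tajima's D scans with empirical
   percentile flags, D′ confidence intervals and Gabriel haplotype
   blocks, Hardy–Weinberg and contingency chi-square tests, and
   haplogroup-tagging SNP (tSNP) discovery by squared correlation;
5. **Synthetic cohorts** — generators for haplogroup-structured VNTR
   haplotypes and coalescent SNP panels that provide ground truth for
   every stage.

## Gene projection by exon-flank anchors

Whole-genome alignment is unnecessary at locus scale. For each exon we
record the `k`-mer immediately flanking each boundary in the reference
(default `k = 30` bp) and place both anchors on the haplotype by
affine-gap local alignment (match +1, mismatch −1, gap open −2, gap
extend −1, implemented in C++). The exon maps to the span between the
left anchor's end and the right anchor's start. An anchor whose
identity (matches/k) falls below 0.9 makes the exon `missing`; a
placement whose runner-up ties within one score unit makes it
`ambiguous`. Mucin exon flanks are unique at this scale, so k = 30 with
identity 0.9 leaves a wide margin for SNPs in the flank while rejecting
spurious placements.

Mapped exons are spliced in transcript order (reverse-complemented for
minus-strand genes) and translated with the standard genetic code.
ORF classification is strict: any internal stop — including within the
final codons before the annotated stop — is `truncated`; a non-ATG
first codon is `no_start`; an N anywhere in a mapped exon makes the
prediction `unreliable` rather than guessing at bases.

## Domain annotation by template scanning

Cys domains are found by scanning a template library against the
protein with the same local aligner. A hit becomes a call when identity
(matches / template length) is at least 0.8 over at least 80% of the
template; overlapping hits are resolved by highest identity, then
leftmost start (manual curation in the literature states no tie rule,
so we fix one that is deterministic and auditable). The shipped
template library is **synthetic**: five 40-aa stand-ins with mucin-like
cysteine spacing, generated deterministically in code
(`synthetic_cys_templates()`), because the curated domain sequences of
the original references are not redistributable here.

Maximal inter-cys segments are decomposed against the repeat consensus;
a segment becomes a TR domain when it yields at least 3 tandem
instances at a mean per-position identity of at least 0.5 to the
consensus. The instance minimum suppresses spurious TR calls in short
linkers; the identity floor suppresses calls in non-repeat tails.

Protein groups (P1–P6) are a data-driven classification: the shipped
TSV rule table encodes ranges over the number of TR domains, the
number of cys domains preceding the first TR, the central TR's copy
number (the P4/P6-defining central TR of 11 copies) and the first TR's
copy number. Rules must be mutually exclusive; more than one match is a
configuration error, no match is `unclassified`. The table is a fixture
precisely because group boundaries are a curation choice, not an
algorithmic fact.

## Motif decomposition

Decomposition is period-constrained wraparound dynamic programming: the
segment is aligned globally against an unrolled tandem array of the
consensus (match +2, mismatch −2, gap open −4, gap extend −1), with the
alignment forced to end at a motif boundary. Instance boundaries fall
where the motif phase wraps, which guarantees the *tiling invariant*:
concatenating the instances reproduces the input segment byte for byte,
in every regime including indels. Substitution-only instances have
exactly the consensus length; instances touched by an insertion or
deletion are flagged `has_indel`, excluded from the motif catalogue and
the position frequency matrix, and retained in allele strings under the
reserved id `IND` — whole-motif gains and losses are thereby kept
distinct from within-motif indels. When no consensus sequence is given
it is estimated as the non-overlapping frame m-mer maximising total
identity to all frames (ties lexicographic).

The catalogue assigns stable ids ordered by descending total count,
ties lexicographic. Usage matrices offer three modes: raw counts;
`length_norm` (counts divided by the haplotype's total instance count,
so rows sum to 1 absent indels — the length-variability correction);
and `column_norm`, a per-column min–max scaling of the length-normalised
matrix (the heatmap transform; a z-score alternative was considered,
min–max is the default because it maps degenerate columns to an exact
zero rather than NaN). Haplotype clustering uses Euclidean distance on
the length-normalised matrix; allele-level clustering can use any
user-supplied distance (Levenshtein on motif-id strings is the natural
choice). UPGMA is implemented with size-weighted arithmetic-mean
linkage, merge heights equal to half the merge distance (ultrametric by
construction), and ties broken by the smallest (row, col) pair.

## Population genetics

`tajimas_d()` computes π as the mean pairwise Hamming distance, S as
the count of segregating columns, and the 1989 normalising constants
from first principles; with S = 0 the statistic is undefined and
reported as `NA` (not 0), and percentile scans simply skip such bins.
Scans use bins anchored at multiples of the bin width from coordinate 0
(the bin phase is otherwise arbitrary; anchoring at zero makes reruns
comparable), keep bins with at least 10 SNPs, and flag bins against the
genome-wide empirical distribution using inverse-ECDF (type-1)
quantiles at the two-sided 90th/95th percentiles. Stratified scans
(per haplogroup or population) restrict the haplotype rows first and
should be compared against a background computed on the same stratum.

Pairwise LD follows the standard haplotype-frequency definitions with
`r2 <= Dprime` guaranteed for biallelic sites. The D′ confidence
interval fixes allele frequencies at their MLEs and evaluates the
multinomial likelihood of the four observed haplotype counts on a D′
grid of step 0.001, normalised to unit mass, with 5% mass trimmed from
each side at 90% coverage — the Haploview-style construction. Gabriel
blocks classify pairs as strong LD (CI lower ≥ 0.70 and upper ≥ 0.98)
or strong recombination (upper < 0.90), accept intervals whose
outermost pair is strong LD and whose strong-LD share of informative
pairs is ≥ 0.95 (pairs beyond 500 kbp ignored), and resolve overlaps
greedily by span, ties leftmost. Sites are MAF-filtered (> 5%) first.

tSNP discovery encodes a haplogroup as a pseudo-site (allele 1 =
membership) and ranks every polymorphic SNP within a window of the
locus (default 50 kbp each side; 10 kbp is the tighter variant used for
gene-proximal scans — the window is a parameter) by r² against that
indicator; hits exceed r² > 0.85, and each hit also reports r² against
every *other* haplogroup as a specificity check.

HWE uses the Pearson 1-df chi-square against MLE-frequency
expectations without continuity correction (an exact test is out of
scope), reporting the direction of the heterozygote departure;
monomorphic samples return chi² = 0, p = 1.

## Synthetic cohorts: what they emulate, and what not

The VNTR generator (`simulate_vntr_cohort()`) copies founder motif
strings per haplogroup, applies whole-motif deletions/duplications
per copy (Bernoulli), then per-residue amino-acid substitutions, and
splices the mutated central exon back into the reference scaffold.
Substitutions are drawn at the amino-acid level and reverse-translated
with a fixed codon per residue, so stop codons can never arise and
nucleotide output is deterministic. Defaults are the cohort composition
of the motivating study — 206 haplotypes, H1 = 103, H2 = 78, H3 = 25 —
with rates `sub_rate = 0.002` per residue and
`dup_rate = del_rate = 0.01` per copy: order-of-magnitude choices (no
quantitative VNTR mutation rates are published for these loci) that
produce realistic within-haplogroup diversity without destroying
haplogroup structure. The three founder architectures are P1-like
(three cys before the first TR), P2-like (five) and P4-like (five TR
domains with a central TR of 11 copies).

The coalescent generator (`simulate_coalescent_panel()`) implements the
Hudson coalescent without recombination under the infinite-sites model;
`star` joins all lineages at `tau` (default 1), making every mutation a
singleton — the minimal generative model of an excess of rare
variation; `balanced` joins two neutral clades of n/2 at `tau` (default
5, chosen well beyond the expected within-clade MRCA time of ≈2 so the
deep split dominates the genealogy) — the minimal model of an excess of
intermediate-frequency variation. These are sign-level emulations of
selection signatures, not effect-size models. Recombination, demography
and sequencing error are deliberately absent: independent bins stand in
for recombination, which keeps the simulator exact and fast.

Consequently, green tests demonstrate *internal correctness* — the
statistics match their definitions and the pipeline inverts the
generator — not that real assemblies are free of alignment artefacts,
assembly collapse over homopolymers, or reference bias, none of which
the generator produces.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF (1-based) and BED
  (0-based) convert at the boundary.
* Missing or unphased genotypes cause a site to be dropped on VCF
  ingest and counted in a skip report; retained + skipped always equals
  the record total.
* Gap scoring convention: a gap of length g costs `open + g × extend`
  in both aligners.
* Min–max column normalisation maps constant columns to zero.
* Tajima's D at S = 0, LD at a monomorphic site, and usage matrices for
  empty haplotypes are respectively `NA`, an error, and an error —
  degeneracy is surfaced, never silently zeroed.
* `plant_tag_snps()` reaches a requested r² by greedy single-haplotype
  flips (lowest index on ties) and errors with the nearest achievable
  value when the group sizes cannot realise the request within 0.02.

## Problem sizes

The shipped tests and the acceptance script run at the study
conditions the package's calibration claims refer to: 2,000 coalescent
replicates at n = 50, θ = 5 for the three genealogy shapes; 5,000
replicates at n = 10 for the E[S] check; 20 seeded scans of 201 bins
for planted-bin recovery; 100 random panels of ≤ 12 SNPs for
Gabriel-block oracle equivalence; a 200-haplotype substitution-only
cohort for the decomposition round trip; and a 40-haplotype
zero-mutation cohort for the end-to-end identity run. The full suite
completes in a few minutes on one CPU.

## Known limitations

* The anchor-based projection assumes exon flanks are unique and
  co-linear; inversions or flank deletions yield `missing` statuses
  rather than split placements.
* Protein-group rules are fixtures tuned to the synthetic
  architectures; applying them to real curation requires editing the
  TSV.
* The D′ CI fixes allele frequencies at their MLEs (profile, not
  joint, likelihood), as block-calling tools conventionally do.
* No recombination within a panel: LD decay inside a simulated bin is
  not modelled, so Gabriel blocks on simulated panels test the
  definition, not recombination-rate realism.
* The pipeline configuration accepts an R list or YAML; per-stage
  sections override defaults (`read_pipeline_config()`).

## Reproducibility

Every stochastic entry point takes a seed; identical configuration and
seed give byte-identical FASTA/VCF/TSV/JSON outputs, which
`run_pipeline()` records in a MANIFEST with md5 checksums and a
parameter-hashed stage log.
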