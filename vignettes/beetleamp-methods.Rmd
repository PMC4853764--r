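---
title: "Methods: immune-effector curation, expression contrasts, and secretome detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-effector curation, expression contrasts, and secretome detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetleamp)
```

## The analysis problem

Burying beetles (*Nicrophorus vespilloides*) breed on small vertebrate
carcasses and must suppress the microbes that compete for them. Their
antimicrobial peptides (AMPs) and lysozymes are therefore expected to be
regulated by sex, by the presence of a carcass, and by the presence of
larvae. beetleamp implements the three analysis layers such a study needs:

1. **Curation** — turning an assembled transcriptome into a conservative
   list of AMP/lysozyme *genes*, which requires separating assembly
   fragments, allelic variants, and close paralogs.
2. **Expression** — RPKM quantification and per-gene t-tests over a
   2-sex × 3-context design (M: mated, no carcass; C: carcass; CL:
   carcass + larvae), with Benjamini–Hochberg (BH) correction.
3. **Secretome** — deciding which effectors are actually present in anal
   secretions from observed tryptic-peptide masses.

A seeded synthetic-data layer generates inputs with recorded ground truth
for all three, so every claim the package makes can be tested without any
raw sequencing or mass-spectrometry data.

## Curation model

Candidates are processed in the order **translate → assign family →
coverage filter → collapse/adjudicate**. The source protocol does not fix
the relative order of the coverage filter and the redundancy collapse; we
filter first so that coverage fractions are computed against full-length
members only, and record this as a package decision.

**Translation.** With CDS coordinates supplied, the given span is
translated directly. Without them, the longest open reading frame across
all six frames is used, requiring an ATG start and allowing an open 3' end
(assembled fragments often lack the stop). The minimum accepted ORF is
`min_orf_aa = 30` residues — short enough for mature AMPs, long enough to
suppress spurious ORFs. In-frame ambiguity codes translate to `X`;
transcripts with no acceptable ORF are flagged untranslatable and carried
through to the report, never silently dropped.

**Family assignment.** Each protein is aligned globally (BLOSUM62, gap
open 10, extend 0.5) against every member of a user-supplied reference
panel of insect AMP/lysozyme families; the best-scoring family wins if
alignment identity reaches `min_identity = 0.40`. The threshold is
deliberately permissive — family panels are curated proteins from related
species and AMP families diverge quickly — and is exposed as a parameter.
Ties are broken by identity, then lexicographic family label, making the
assignment deterministic.

**Coverage filter.** Within a family, each member is aligned to the
longest member and removed when it covers *less than half* of that
reference's residues; a member at exactly 50% is retained (the rule is a
strict inequality). Members at least as long as the reference trivially
cover it.

**Allele-versus-paralog adjudication.** For each retained pair the
proteins are aligned, the alignment is back-projected onto codons, and
three counts are taken over non-gap codon columns: total nucleotide
differences, nucleotide differences inside amino-acid-changing codons, and
amino-acid differences. The decision rule is:

* ≤ 1 amino-acid difference → redundant/allelic, same gene;
* 2 to `few_aa_threshold` amino-acid differences → **different genes only
  when total nucleotide differences exceed the amino-acid-changing ones**,
  i.e. when synonymous divergence exists. Synonymous changes accumulate
  between gene copies but not between alleles of one gene, so their
  presence is the signal that two similar sequences are paralogs;
* more than `few_aa_threshold` differences → different genes.

"Only few amino acid differences" is not quantified in the underlying
protocol (its one worked instance has two); we default
`few_aa_threshold = 5`, conservative and configurable. Gap columns are
excluded from all counts, so indel-only variants collapse under the
redundancy rule.

**Clustering.** Genes are connected components (single linkage) of the
same-gene relation. When linkage joins a pair that was itself judged
distinct, the union is kept — the conservative, lower gene count — and the
conflict is logged. The representative is the longest member, ties broken
by smallest id. Every transcript ends in exactly one terminal status
(`untranslatable`, `unassigned`, `removed_low_coverage`, `collapsed`,
`retained`), and statuses are conserved: they partition the input.

## Expression model

RPKM is computed as `count × 10⁹ / (length_bp × total mapped reads)`.
Zero counts would give log2 of zero, so RPKM is floored at `2⁻⁴`
(configurable) before the log — finite, and safely below the expression
filter. Group summaries are geometric means over biological replicates,
i.e. arithmetic means of log2 RPKM, and fold changes are differences of
group-mean log2 values.

**Expression filter.** Genes with group-mean log2 RPKM below 1 are
excluded. Read literally, "below 1 under any condition" would discard
genes silent in one context — including exactly the carcass-induced
effectors of interest — so the default excludes a gene only when it is
low in *all six* groups; the literal `mode = "any"` is available. The
threshold comparison is strict: a gene at exactly 1 stays.

**Housekeeping stability.** The fold range `2^(max − min)` of the six
group-mean log2 values must stay strictly below 1.3 for a housekeeping
gene to pass. The check is computed on group means (six values); a
stricter per-sample variant would flag individual outlier replicates and
can be built from the per-sample matrix the object retains.

**Testing.** Each of the seven contrasts (M-vs-C per sex, C-vs-CL per
sex, m-vs-f per context) gets a two-sided pooled-variance Student t-test
per gene on log2 RPKM (df = n₁+n₂−2); Welch is available as an option.
BH correction is applied per contrast across all filtered genes — the
family of tests is configurable because the original family is not
documented. Stars mark adjusted p below 0.05 / 0.01 / 0.001. Degenerate
genes (zero variance in both groups) get p = 1 at equal means and p = 0
with a `degenerate` flag otherwise; both conventions are visible in the
output rather than silently imputed. Reference genes (e.g. RPL7/RPS4e
style ribosomal proteins) are carried into the heat-map export unfiltered
and untested, to display normalization stability.

## Proteomics model

Trypsin is modeled with the standard specificity: cleavage C-terminal to
K or R except before P. Defaults: at most one missed cleavage, minimum
peptide length 5, no fixed modifications (carbamidomethyl-C available),
10 ppm mass tolerance. Peptide monoisotopic masses are residue-table sums
plus one water. Matching is mass-only — fragmentation spectra are out of
scope — and an observed mass matching peptides of several proteins is
credited to all of them and flagged ambiguous. A sequence mode accepts
already-identified peptides and skips mass matching.

Coverage is the fraction of a protein's residues under at least one
matched peptide, computed on the sequence as supplied (no precursor /
mature-form distinction). A protein is *present* in a group when coverage
strictly exceeds 0.5 — "more than half" — so exactly half is absent.

## What the simulators emulate — and what they do not

`simulate_family()` builds families whose confounders are exactly those
curation must resolve: allelic variants with controlled synonymous and
nonsynonymous single-codon substitutions, paralogs diverged at
gene-private codons, and 5'-anchored fragments truncated below half
length. Substitutions are placed at distinct codons; synonymous changes
use the degeneracy of the code (background codons are drawn from 4-fold
degenerate families), and the construction is re-verified post hoc by
brute-force codon comparison. It does **not** simulate assembly chimeras,
sequencing error, alternative splicing, or within-codon multiple hits.

`simulate_counts()` draws mapped-read counts from a negative binomial
with mean `RPKM × length_bp × depth / 10⁹` and variance
`μ + φμ²`. The study design default is 18 samples (2 sexes × 3 contexts ×
3 replicates) at 30 million mapped reads each, matching whole-adult
RNA-seq library sizes for this design. No distributional model for the
expression noise is documented in the underlying protocol; the negative
binomial is this package's own choice, made because the pipeline input is
counts (letting RPKM computation be exercised end to end) and because it
is the field-standard overdispersed count model. Defaults: dispersion
0.05 for ordinary genes (a typical biological-replicate value for bulk
RNA-seq), 4-fold planted effects, 12 housekeeping genes at high
expression. Library-composition effects, gene-length biases, and mapping
ambiguity are not simulated — so passing tests demonstrate correctness of
the statistics under the stated model, not robustness to normalization
artifacts.

`simulate_secretome()` subsamples the theoretical tryptic peptides of
present proteins at a detection rate, perturbs masses by Gaussian ppm
noise, and adds decoy masses rejection-sampled at least 1 Da from every
theoretical peptide, which makes matcher specificity directly testable.
Chromatography, charge states, and intensity are not modeled.

## Numerical choices

* Codon-aware difference counting takes a positional fast path when the
  two in-frame sequences have equal length and the mismatch density is
  ≤ 20%; denser mismatch patterns (e.g. compensating indels) fall back to
  the alignment-based path. Both paths are checked against a brute-force
  oracle.
* All simulator randomness flows from a single integer seed per spec via
  `withr::with_seed`, so generation never disturbs the caller's RNG and
  equal seeds give byte-identical outputs.
* Cluster ids, representatives, and tie-breaks are fully deterministic
  (length, then lexicographic id).
* The RPKM floor (2⁻⁴) keeps log2 finite; it is below the expression
  threshold, so flooring can never promote a silent gene past the filter.

## Problem sizes in the test suite

The suite verifies truth recovery over 50 seeded families (2–6 genes,
1–3 alleles, 240-nt coding sequences), type-I calibration and FDR control
on 1000-gene matrices (one fixed-seed calibration run and ten
mixed-effect replicates), detection power and housekeeping stability over
100 seeded simulations of a 68-gene study-like panel, and the
carcass-restricted secretome pattern over 20 seeds. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bounds while
keeping the suite quick to run.

## Known limitations

* Family assignment is alignment-identity based; highly divergent novel
  families below 40% identity to every panel entry are reported
  unassigned rather than discovered de novo.
* The coverage filter measures coverage against the longest member, not a
  true multiple-alignment consensus; for families whose longest member is
  itself incomplete, coverage is measured against that fragment.
* The expression layer implements the classical RPKM + t-test + BH
  workflow faithfully, including its known weaknesses at n = 3; it is not
  a shrinkage-based DE method and should not be compared against one.
* Secretome presence is a per-group qualitative call; no peptide-level
  false-discovery control is attempted beyond the mass tolerance and the
  coverage threshold.
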