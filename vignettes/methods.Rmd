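---
title: "Candidate-gene screening for salt tolerance: models and methods"
author: "saltNAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene screening for salt tolerance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltNAC)
```

## The screening problem

Hexaploid bread wheat carries three related subgenomes (A, B and D), so a
transcription-factor family such as NAC exists as hundreds of gene copies
organised into *homoeolog members*: groups of corresponding copies on the
same-numbered chromosome of different subgenomes, sometimes expanded further
by tandem duplication. `saltNAC` implements the desk side of a screen that
narrows such a family down to a handful of salt-tolerance candidate genes
by combining three orthogonal lines of evidence:

1. **Family catalogue** — which copies exist, how they group into members,
   which lie in tandem clusters, and how they are named.
2. **Expression trajectories** — which genes respond to NaCl in a
   time-course RNA-seq experiment, and with what temporal pattern.
3. **Phenotype association** — which gene-region SNPs track the relative
   salt-injury rate (RSIR) of root traits across a diversity panel.

A gene is a candidate when it shows the *successive upregulation* pattern
(trajectory Group 4) **and** its region carries at least one significant,
QC-passing SNP. Downstream, haplotypes over the candidate region are tested
against the phenotype and a KASP genotyping marker is designed so breeders
can score the favourable haplotype cheaply.

Because the underlying study data (a reference wheat genome, a breeding
line's RNA-seq, a genotyped germplasm panel) are not something a package
can ship, a first-class synthetic-data generator reproduces the
*statistical structure* of each input, with truth labels that every
downstream stage must recover.

## The catalogue stage

**Domain screen.** `scanNamDomain()` slides a fixed 30-residue consensus
(standing in for the NAM domain that defines the family) along each
protein and keeps genes whose best window matches at least 90% of the
consensus positions. This is deliberately a consensus scan, not a profile
HMM: it gives the screening step a deterministic, dependency-free signal
with the same pass/fail role the real pipeline delegates to an HMM search.

**Homoeolog grouping.** Members are connected components of a graph whose
edges join genes on the same homoeologous chromosome group with global
protein identity at or above 0.9 (identity = matches / alignment length
under unit match/mismatch scoring). Edges are allowed both across
subgenomes (homoeologs) and within one chromosome (duplicates), because a
tandem copy must belong to the member it duplicates. When an external
homoeologue annotation exists, `provided_map` bypasses inference entirely
— that is the faithful path; inference is the self-contained fallback.

**Tandem clusters.** Copies of one member on one chromosome are chained by
single linkage on start coordinates with a 10 Mb gap limit. Chaining (not
an all-pairs rule) is the deliberate reading: clusters of up to nine genes
are observed, which an all-pairs-within-10-Mb rule would make implausible.
A 1/9/18 Mb chain is therefore one cluster of three although its ends are
17 Mb apart. Strand is ignored; the gap is measured between start
coordinates.

**Naming.** Members are sorted by smallest homoeologous group, then
smallest start coordinate on that group (subgenome order A < B < D and
gene id break ties) and numbered 1..N. Every copy is named
`prefix + number + "-" + subgenome letter`; a positional rank is appended
only when the member holds more than one copy on that chromosome
(`-D3` = third copy on the D chromosome), and a dotted sub-index
(`-D3.2`) is emitted only when the input annotation distinguishes nested
duplicates. The grammar is deterministic and invariant to input order. The
dotted grammar is a package decision — the convention it mimics is not
formally defined anywhere — so exact reproduction of historical names is
not claimed.

**Expression classes.** A gene is `none` when its mean reference FPKM is
zero (below 1e-9 — "no expression" is read as numerically zero), `low`
below 1, `normal` at 1 or above. Summary percentages are rounded half-up
to two decimals, which is what makes 145/446 print as 32.51%.

## The expression stage

FPKM follows the standard definition, fragments / (mapped fragments in
millions × transcript length in kb). Differential expression against the
0 h control is called per treated time point (1, 6, 24, 48 h after
treatment) with:

* log2 fold change of time-point means with a pseudocount of 1 (so silent
  genes have a defined fold change);
* a Welch (unequal-variance) test on log2(FPKM + 1) replicate values;
* Benjamini–Hochberg FDR across genes *within each time point* (the
  stratification is a package decision; computing it across the pooled
  table would mix null distributions of different time points);
* verdict `up`/`down` at |log2FC| ≥ 1 and FDR ≤ 0.01.

The original analysis used a negative-binomial count pipeline; the
replicate-level Welch test keeps this stage self-contained, and
`ingestDETable()` accepts precomputed (log2FC, FDR) tables for users who
already have count-model output. When both replicate groups have zero
variance the p-value is defined as 1 for equal means and 0 otherwise.

A gene is *salt-responsive* when DE (either direction) at ≥ 2 treated time
points. Responsive genes fall into four trajectory groups, evaluated in
this order:

* **Group 2** — down at 1 h and log2FC non-decreasing thereafter (early
  repression, then recovery). Checked first so that a down-then-rising
  profile is Group 2 even if it never reaches an `up` verdict.
* **Group 1** — no upregulated time point (downregulation trend).
* **Group 4** — no downregulated time point and `up` at both 24 and 48 h
  (successive upregulation). Requiring significance at the two late time
  points, rather than at all four, is the package's formalisation of
  "successive upregulation"; the verbal description does not say whether
  every time point must be individually significant.
* **Group 3** — everything else (transient/specific upregulation).

The rules are total and single-valued on every verdict/fold-change
combination a responsive gene can present.

## The association stage

**RSIR.** For each accession, trait and replicate, plant values are
averaged into X~CK~ and X~NaCl~; the replicate's injury rate is
(X~CK~ − X~NaCl~)/X~CK~ × 100, and the reported RSIR is the mean over
replicates (ratio first, then averaging — the loosely stated alternative,
averaging before the ratio, differs only at second order but the
per-replicate ratio is the reading adopted). Negative values (trait
increased under NaCl) are retained; X~CK~ = 0 makes the ratio undefined
and the record is flagged and excluded.

**QC.** MAF is computed on non-missing alleles and folded to ≤ 0.5. A SNP
passes when MAF > 0.10 **strictly** and missing rate < 0.05 **strictly** —
the thresholds are read literally from their ">" and "<" statements, so
MAF exactly 0.10 fails.

**Scan.** Per SNP, ordinary least squares of RSIR on alt-allele dosage
(0/1/2) plus the top `n_pcs` genotype principal components (default 3,
configurable to 0). The named GWAS tool in the original analysis is not
reimplemented and no model variant is stated, so the simplest defensible
model is used and recorded in the manifest. Missing genotypes are dropped
per SNP with `n_used` recorded; no imputation, so the accounting is
transparent. p-values come from the dosage coefficient's t-statistic —
with `n_pcs = 0` this reproduces the correlation-t closed form to
numerical precision. q-values are Benjamini–Hochberg over the scan.
Significance is −log10 p **strictly greater than** 4.

One numerical subtlety: the PCA is computed on an LD-pruned dosage matrix
(greedy, |r| < 0.9). In a candidate-gene panel the SNP set is dominated by
tightly linked blocks; without pruning the top components simply *are* the
largest blocks, and regressing on them absorbs exactly the local signals
the scan is meant to find. Pruning restores the intended role of the
components — background structure, not foreground signal.

**Context annotation.** Strand-aware: promoter within 2000 bp 5′ of the
start codon, 3′-UTR within 500 bp 3′ of the stop codon, exon/intron by the
exon intervals; for coding positions the reference and alternative codons
are compared under the standard genetic code (`nonsense` when the
alternative codon is a stop).

## Haplotypes and KASP markers

The candidate region runs from 2000 bp upstream of the start codon to
500 bp downstream of the stop codon, strand-aware. Haplotypes are the
distinct allele strings over the region's SNPs among accessions with fully
homozygous, non-missing calls — the panel is inbred, so heterozygous or
missing accessions are excluded rather than phased. Labels Hap1, Hap2, …
descend by frequency with allele-string lexicographic order breaking ties,
making the labelling a deterministic function of the genotype matrix.
Hap1 vs Hap2 RSIR differences use a Welch t-test at α = 0.01, and the
report states which haplotype has the lower injury rate (better
tolerance).

`designKasp()` builds the two allele-specific forward primers — the
standard FAM tail `GAAGGTGACCAAGTTCATGCT` and HEX tail
`GAAGGTCGGAGTCAACGGATT`, each followed by the same 18–25 b gene-specific
window ending exactly on the SNP, differing only at the 3′-terminal base
(reference allele under FAM, alternative under HEX; the tail↔allele
pairing is a convention choice) — and a common reverse primer on the
opposite strand whose 3′ end sits 30–120 bp downstream. Windows are chosen
by closeness of a simple Tm estimate to 60 °C (Wallace rule up to 14
bases, a GC-fraction linear formula above), with ties broken toward
shorter primers and smaller gaps so the design is byte-reproducible.
Primer quality beyond length and Tm (hairpins, dimers, specificity) is out
of scope.

## The synthetic study

The generator's defaults are the study conditions, chosen once:

* 21 chromosomes named 1A..7D, 150 Mb each (a scaled-down chromosome is
  enough to express the 10 Mb clustering geometry);
* per-subgenome copy presence 0.85, which leaves about 5% of members
  single-copy, matching the observed 6 of 118;
* tandem probability 32/118 with cluster sizes 2–9 and intra-cluster gaps
  of 0.5–6 Mb;
* proteins of 250–350 residues carrying the planted motif, copies mutated
  at 1% of non-motif positions so member identity stays well above the
  0.9 grouping threshold; decoys (15%) carry no motif;
* trajectory mix 22/446 for each of Groups 1–3, 78/446 for Group 4, rest
  nonDE (only the Group 4 and total-DE proportions are reported in the
  study; the equal split of the remainder across Groups 1–3 is a package
  choice). Genes of members named in `causal_spec` are always Group 4 —
  the spiked candidates must satisfy the selection rule they are meant to
  test;
* archetype means are constructed on the pseudocount scale,
  mean~t~ = (mean~0~ + 1)·2^a^ − 1, so the classifier recovers every label
  exactly at zero replicate noise; FPKM replicates are lognormal with an
  exact mean and CV `replicate_cv` (default 0.1 — the study does not state
  replicate variance, so this is a package default);
* a panel of 114 inbred accessions; gene regions of causal (or otherwise
  configured) members are one perfectly linked block with minor-haplotype
  frequency 0.3, which yields exactly two haplotypes — the testable
  content of a "two-haplotype region"; other SNPs are independent with
  MAF uniform on (0.1, 0.5); genotype missingness 2%, heterozygosity 0;
* root traits with realistic scales (e.g. total root length 25 cm) and
  per-plant CV 0.2 over 10 plants × 3 replicates (plant-level variance is
  again unstated in the study and is a package default); NaCl values are
  CK × (1 − injury) with mean injury 0.30 and accession-level SD 0.08, so
  control traits are effect-free and RSIR carries the whole genetic
  contrast;
* the causal effect size is solved from the requested variance explained
  against the sum of the accession-level injury variance and the
  analytically propagated measurement variance of the RSIR ratio, so the
  *realised* dosage–RSIR r² matches the request (verified to ±0.1); the
  alt allele is protective, so Hap2 (minor) is the tolerant haplotype.

All randomness flows through one seeded generator per stage (seed, seed+1,
seed+2), giving byte-identical GFF3/FASTA/VCF/TSV/JSON outputs for a fixed
seed.

What the generator does **not** emulate: realistic linkage maps and decay
(regions are either one perfect block or free), population structure or
kinship (accessions are exchangeable), count overdispersion of the
negative-binomial kind, UTR-containing gene models, and genome sequence
between genes. Tests passing on this generator therefore certify the
pipeline's logic and statistics under its stated assumptions — not
robustness to structured populations or messy annotation.

## Problem sizes and numerical choices

The shipped demo (12 members, three spiked causal members at variance
explained 0.25) runs end to end in well under a minute. The recovery
suites use 200 power replicates on a 4-member genome, two 25-member null
panels (≈ 1400 null tests), and a 70-member genome (≈ 300 genes) for
trajectory recovery; these sizes keep the whole suite at a few minutes on
one CPU while leaving the Monte-Carlo margins comfortable.

Tie-breaks are fixed everywhere a choice exists (member ordering,
haplotype labels, primer windows, Manhattan ordering by chromosome,
position, then SNP id). Degenerate inputs have defined behaviour: empty
FASTA yields an empty screen, a zero-variance SNP is skipped with a log
entry, a constant phenotype refuses the scan, X~CK~ = 0 excludes the
record, and a haplotype group smaller than two refuses the t-test.

## Known limitations

* The association model is a fixed-effect GLM with PC covariates; kinship
  or mixed models are out of scope, so in a genuinely structured panel the
  null exceedance rate would exceed the nominal one.
* The domain screen is a consensus scan; divergent family members that a
  profile HMM would catch can be missed.
* Published gene names cannot be reproduced exactly because the dotted
  sub-index convention is not formally defined; `matchReferenceSequences()`
  (exact full-length identity) is the supported cross-referencing route.
* Candidate selection inherits the scan's false-positive rate: at
  p < 1e-4 over thousands of SNP × trait tests, an occasional chance hit
  lands in a Group-4 gene's region. The screen is therefore reported (and
  tested) at the member level, which is also the unit on which such
  screens report their candidates.
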