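---
title: "Core collections and SNP fingerprints: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core collections and SNP fingerprints: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingercore)
```

`fingercore` turns a multi-sample VCF of biallelic SNP genotypes, a
reference FASTA and a sample-to-population table into (i) a core
germplasm collection, (ii) a screened fingerprinting panel with KASP
assays, and (iii) population-origin calls for query accessions. This
vignette explains the statistical machinery, the defaults and their
units, the synthetic data model the tests rest on, and the choices made
where the design was genuinely open.

## Genotype model

All stages consume a `geno_matrix`: unordered allele-pair calls over
{A,C,G,T} with missing values allowed. "0/1" and "1/0" collapse to the
same het call because downstream statistics are all order-free;
multiallelic and indel records are excluded at import rather than split,
since every screening statistic below assumes a biallelic locus (MAF
≤ 0.5, PIC ≤ 0.375, He ≤ 0.5). Coordinates are 1-based and closed, as in
VCF and FASTA.

## Diversity statistics

Per locus, with `p` and `q = 1 − p` the allele frequencies over called
samples (complete cases per locus):

* `Ho` — fraction of heterozygous calls;
* `He = 1 − p² − q²` — expected heterozygosity. The plain (uncorrected)
  form is used, not the `2n/(2n−1)` small-sample correction, so the
  biallelic ceiling is exactly 0.500; Nei's gene diversity coincides with
  this for two alleles and is reported as a separate column only for
  table parity with conventional diversity reports;
* Shannon–Wiener `−(p ln p + q ln q)` on allele frequencies with the
  natural log (ceiling `ln 2 ≈ 0.693`);
* PIC, Botstein's formula restricted to two alleles,
  `He − 2p²q²` (ceiling 0.375 at `p = 0.5`);
* exact Hardy–Weinberg p-value (below);
* missing rate.

The log base and estimator variants are genuinely underdetermined in the
field's desktop tools; the choices above are the ones whose ceilings
(0.5, ln 2, 0.375) match how screened panels are usually summarized, and
they are what the screening thresholds assume.

The exact HWE test is the Levene–Haldane conditional test: given the
observed allele counts, the probability of `h` heterozygotes among `n`
individuals is `n!/(n_AA! h! n_aa!) · 2^h · n_A! n_a! / (2n)!`, and the
p-value sums the probabilities of all outcomes no more probable than the
observed one. The implementation works in log-space via `lgamma`; the
test suite checks it against an independent dynamic-programming
enumeration of allele-to-slot arrangements for every genotype triple with
`n ≤ 20`.

## Screening cascade

`screen_cascade()` evaluates six verdicts per locus, each independently
(the conjunction is order-free, so the report can show exactly which
criterion kills each locus):

| criterion   | default    | meaning |
|-------------|------------|---------|
| specificity | 401 bp     | the `2·flank+1` window occurs exactly once in the genome, both strands |
| missing     | 0          | maximum per-locus missing-call rate |
| maf         | ≥ 0.2      | minor allele frequency |
| pic         | ≥ 0.35     | polymorphism information content |
| hwe         | p > 0.01   | exact test, strictly greater |
| isolation   | ± 100 bp   | no other variant within the window |

Three readings had to be fixed:

* **Isolation is a closed window**: a neighbour at exactly 100 bp fails.
  This is the conservative reading of "within 100 bp", and it is
  configurable.
* **Specificity is exact full-window uniqueness** (both strands, via
  Aho–Corasick matching of all windows at once). A BLAST-style inexact
  aligner can be slotted in behind the same predicate, but exact
  uniqueness is deterministic, needs no external index, and is the
  conservative approximation of "uniquely aligned": any window that is
  not even exactly unique cannot be unique under an inexact aligner.
* **PIC subsumes a stricter MAF bound**: for a biallelic locus PIC
  ≥ 0.35 forces MAF ≳ 0.355, so the MAF ≥ 0.2 criterion is only binding
  when the PIC threshold is relaxed. This is why the hand-built
  screening fixture in the tests cannot contain a locus failing *only*
  the MAF criterion — such a locus does not exist.

Turning `require_specificity` off reproduces the larger
specificity-free panel variant; its survivors are always a superset of
the strict panel's (property-tested).

`chromosome_balanced_select()` is the deterministic stand-in for "pick
loci with high PIC and MAF, evenly across chromosomes", a rule that is
never fully specified in practice: quota `floor(target/n_chrom)` per
chromosome, the remainder going to chromosomes with the most survivors,
ranking within a chromosome by (PIC, MAF) descending with ties broken by
locus id, and shortfalls on thin chromosomes redistributed with a
warning. Given the same report it always returns the same panel.

## Core-collection optimization

The objective is the 0.7/0.3 blend of mean pairwise modified Rogers
distance (MR) and per-locus-normalized pooled Shannon diversity (SH).
Normalizing SH by the number of loci keeps it in `[0, ln 2]`,
commensurate with MR ∈ `[0, 1]`, so the weights mean what they say.
Missing calls are pairwise-deleted from MR and excluded from pooled
frequencies.

The search is steepest-ascent over single swaps (replace one selected
accession by one unselected) from seeded random starts, with 10 restarts
by default and a 200-sweep guard; a sweep that finds no improving swap
proves a local optimum, so the guard is rarely binding. The objective is
maintained incrementally (pair-sum and pooled dosage vectors), making a
sweep `O(k (N−k) L)`. The suite verifies the search attains the
brute-force optimum over all `C(N, k)` subsets for `N ≤ 12, k ≤ 4` and
that the reported objective always equals an independent recomputation.

`fraction_sweep()` optimizes one core per fraction of the 0.1–0.9 grid,
seeding each fraction's search from the previous core (nesting). Nesting
makes the sweep cheap (restarts are only spent on the smallest fraction)
and in practice keeps the allele-coverage curve monotone, which is how a
recommended fraction — the smallest reaching the coverage goal, default
CV ≥ 0.99 — is read off the curve. The coverage goal is a configurable
stand-in: with real collections the choice is made by eye on the CV
curve, and where the elbow falls depends on the data.

## Fingerprints, barcodes, KASP

Fingerprints keep the full two-allele call per cell but also carry a
rendering class (hom by base; all hets collapse to one class; missing
separate) matching the conventional colour scheme for fingerprint
figures — the display loses information that the barcode payload must
retain, which is why the two are separate fields. The barcode payload is
a deterministic text grammar (`sample`, panel version hash, then
`locus=call` pairs in panel order) that round-trips through
`parse_barcode_payload()`; rendering an actual QR image is left to any
external encoder.

KASP assembly places two allele-specific forward primers ending exactly
on the SNP (identical but for the 3' base; FAM tail on the ref primer,
VIC on the alt) and greedily searches downstream for the first common
reverse primer satisfying GC ∈ [30, 60] %, Tm ∈ [55, 61] °C and product
≤ 120 bp. Tm uses the basic GC-count formula
`64.9 + 41·(G+C − 16.4)/N` on the genomic segment (tails excluded) —
thermodynamic nearest-neighbour models need salt and concentration
assumptions a desk tool cannot verify, and only the constraint *ranges*
matter here. An infeasible locus yields a design-failure report rather
than an error, since panel conversion rates are themselves a result. The
1:1:3 forward:forward:reverse mix ratio is carried as annotation only.

## Population structure and origin assignment

The distance model is the call-level p-distance: the proportion of
shared called panel loci at which two accessions' unordered calls
differ, het vs hom counting as a full mismatch. This is the simplest
model consistent with the small printed distance values such panels
produce (0, 1/18 ≈ 0.0556, 1/7 ≈ 0.1429); an allele-sharing distance is
a possible refinement but is not needed by anything downstream. Trees
are Saitou–Nei neighbor joining with negative branch lengths clamped to
zero (flagged); bootstrap supports resample panel loci with replacement.
PCA runs on the column-centered dosage matrix with missing dosages
imputed to locus means, and fixes each component's sign by its
largest-magnitude loading so coordinates do not flip under reordering.

`assign_population()` calls the population with the smallest mean
distance to its references, reporting the margin to the runner-up and
"AMBIGUOUS" on exact ties. Leave-one-out assignment over the synthetic
collection reproduces the qualitative field finding the panel design
aims at: the strongly diverged plateau population is recovered
essentially perfectly from 52 markers, while the three weakly diverged
northern populations are frequently confused with one another (but not
with the plateau group).

## Synthetic data model

`simulate_genotypes()` draws, per locus, an ancestral alt-allele
frequency `p₀ ~ U(0.05, 0.5)`, then population frequencies under the
Balding–Nichols model `p_k ~ Beta(p₀(1−F)/F, (1−p₀)(1−F)/F)`, and
genotypes as `Binomial(2, p_k)` dosages. Defaults emulate the study
conditions the pipeline targets: 90 accessions (26/26/26 northern +
12 plateau), 14 chromosomes of 60 kb, 1000 loci, 1 % missing calls,
plateau `F = 0.3`, northern `F = 0.02` below a shared intermediate
ancestor with branch `F = 0.05`. The shared branch is the one parameter
with no stated analogue; 0.05 was chosen once as a realistic weak
northern clade — strong enough that the three populations drift together
away from the ancestral pool, weak enough that they remain mutually
confusable. Chromosome length is genome-scale-free: only window
uniqueness and locus spacing matter, so 60 kb per chromosome keeps exact
window matching fast while leaving room for 401 bp windows and 250 bp
spacing.

What the generator does *not* emulate: linkage disequilibrium and
recombination (loci are exchangeable draws), a realistic site-frequency
spectrum (the ancestral MAF is uniform), sequencing error, allelic
dropout, and the paralog/multi-copy windows that make specificity
filtering genuinely hard in large allopolyploid genomes (duplicated
segments can be planted, but they are exact copies). Tests passing on
this generator therefore validate the *procedures* — filters, search,
distances, assignment logic — not the field performance of any
particular marker panel on real resequencing data.

## Numerical choices and degenerate inputs

* HWE p-values are computed in log-space and compared with a `1 + 1e-9`
  relative slack when summing "no more probable" outcomes, so
  floating-point ties resolve the way exact rational enumeration would.
* Monomorphic loci: He, Shannon, PIC all 0; HWE p = 1 (single outcome).
* All-missing loci are an error in `locus_stats()`; samples sharing no
  called locus are an error in MRD and an explicit "uncomparable" flag
  (never distance 0) in p-distance and fingerprint comparison.
* Swap-search ties: an improving move must beat the incumbent by more
  than 1e-10; equal-objective moves are not taken, making the ascent
  path (and hence the result for a fixed seed) deterministic.
* Quota ties in panel selection and name ties in assignment resolve
  lexicographically.

## Problem sizes used by the test and acceptance runs

The bundled runs use the default synthetic collection (90 samples, 1000
loci) for the end-to-end checks, brute-force oracles at `N ≤ 12, k ≤ 4`
(subset search), `n ≤ 20` (HWE enumeration) and `n ≤ 8` taxa (100
additive trees), and a fraction sweep at 2 restarts. These sizes were
chosen so the whole suite exercises every oracle property at exhaustive
scale where exhaustive is feasible, and at collection scale everywhere
else.

## Known limitations

* Exact-match specificity cannot flag windows unique in sequence but
  repetitive under inexact alignment; on real polyploid genomes an
  aligner-backed predicate should replace the built-in backend.
* The He/PIC/Shannon estimator variants are fixed (uncorrected, natural
  log, biallelic Botstein); other desktop tools may apply small-sample
  corrections and will differ in the third decimal.
* p-distance treats het/hom as a full mismatch; allele-sharing distances
  would halve such mismatches and shrink all distances accordingly.
* The optimizer guarantees local optimality under single swaps, not
  global optimality beyond the exhaustively verified sizes.
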