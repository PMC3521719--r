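---
title: "Methods: pseudogene surveys from resequencing variants"
author: "psiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudogene surveys from resequencing variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Selfing plant species such as *Arabidopsis thaliana* maintain large panels
of naturally inbred accessions.  When many accessions are resequenced
against one reference genome, a substantial fraction of annotated
protein-coding genes turn out to carry loss-of-function alleles —
frameshifts or premature stop codons — in at least one accession.
`psiscan` implements the full survey that turns per-accession variant
tables into such a catalogue of pseudogene (Ψ) loci, and the population,
landscape, molecular-evolution, domain-bias and phylogenetic analyses
built on top of it.  Because the real 80-accession data set is large and
external, the package ships a synthetic-data generator that emulates its
structure, with an exact truth table, so every stage is testable offline.

## The disrupted-allele caller

Each accession is treated as a haploid genome (the accessions are selfing
lines; heterozygous genotypes are rejected at parse time).  Absence of a
variant record means the reference allele — resequencing panels report no
call in inaccessible regions, and those sites are assumed reference.

For one gene and one accession:

1. **Coding indels.**  Insertions and deletions are projected onto the
   spliced CDS of the locus's first transcript.  A deletion overhanging an
   exon boundary contributes only its coding bases.  A deletion covering
   the entire CDS is logged as a whole-gene deletion and treated as a
   frameshift at position 0.
2. **Frameshift rule.**  If the net signed length of all coding indels is
   not divisible by 3, the allele is frameshifted at the 5'-most
   frame-disrupting indel.  If the net length is divisible by 3, a window
   of three consecutive frame-disrupting indels is slid along the CDS;
   when the distance between the first and last member of any window
   exceeds `set_span_bp` (default 300 bp), the allele is still called
   frameshifted at that window's first member — widely spaced
   compensating indels leave a long out-of-frame stretch even though the
   total length is restored.  The window formalisation is one reading of
   "three adjacent indels treated as a set"; it is configurable.
3. **Premature stop.**  SNVs are substituted into the reference CDS and
   the annotated frame is translated.  A stop codon before the annotated
   terminal codon, in a codon containing at least one substituted base,
   is a premature stop.  The event position is the first base of the
   created stop codon (so a third-position change at codon 5 of a
   100-codon CDS gives relative position 12/300 = 0.04).  Start-codon
   loss and terminal-stop loss are not Ψ calls, and stops arising only
   downstream of a frameshift are regarded as consequences of the
   frameshift rather than independent events.
4. **Classification.**  When several disruptive events co-occur, the
   5'-most one (tie broken frameshift-first) classifies the allele.  Its
   relative position falls in one of three bins (0–1/3, 1/3–2/3, 2/3–1;
   ties at an edge go to the lower bin), and a locus is a Ψ locus under
   criterion `first_third` / `first_two_thirds` / `whole_orf` when at
   least one accession's primary event lies below the cutoff.  Because
   different accessions can disrupt the same locus in different bins,
   per-bin locus counts overlap and need not sum to the total.

Genes annotated as pseudogenes or transposable elements are excluded
up front; multi-transcript loci contribute only the transcript whose
identifier sorts first under natural sort (".1" before ".2" before
".10") — the annotation's notion of "first transcript" is not otherwise
machine-readable.

## Synthetic data: what it emulates and what it does not

`simulate_reference()` builds random-sequence chromosomes (GC ≈ 36%,
matching the *A. thaliana* genome-wide average) carrying non-overlapping
1–4-exon genes whose CDS start with ATG, end with a stop and contain no
internal stop.  Under the `centromere_dip` profile, placement density in
the central 30% of each chromosome is one fifth of the arm density,
mimicking pericentromeric gene deserts.  `simulate_variants()` plants at
most one disruption per gene — a frame-disrupting indel of length 1, 2, 4
or 5 (never a multiple of 3) or a nonsense SNV — shared identically by
`k` carrier accessions, with `k` drawn from a neutral-like spectrum
(P(k) ∝ 1/k) or fixed at 1 (`singleton`).  The disruption probability can
be a function of local gene density and can be multiplied per domain
family, which is how the landscape- and bias-recovery properties are
exercised.  Background SNVs are synonymous-biased inside CDS (third
positions with a synonymous alternative), so the planted truth table
remains an exact oracle for the caller even at non-zero background
rates.

Deliberately not emulated: linkage and recombination, demography,
sequencing error, heterozygosity, structural variants beyond simple
indels, and multi-hit loci.  Passing the end-to-end oracle therefore
shows the calling logic is exact under the stated conventions; it does
not validate robustness to genotyping error in real panels.

One master seed drives everything; sub-stages derive fixed child seeds,
so a simulation is reproducible byte-for-byte.

## Population summaries

* Per-accession Ψ counts with mean and sample SD.
* The disrupted-allele frequency spectrum over Ψ loci: mean carrier count
  `k`, the fraction shared by ≥2 accessions, and the fraction in the
  1–10 band.
* The accumulation curve: for each sample size `k`, the mean (over
  `reps = 100` random accession orderings; the averaging scheme is
  unspecified in the source analyses, and 100 orderings make the
  Monte-Carlo error negligible at these scales) of the number of distinct
  Ψ loci among the first `k` accessions, fitted by ordinary least squares
  as `Y = a ln X + b`.  `predict_loci()` evaluates the fitted model and
  is exactly invertible.
* The equal-probability null for shared Ψ loci: each accession redraws
  its observed Ψ count uniformly without replacement from the gene
  universe; the mean pairwise shared proportion over replicates is the
  null, and the Monte-Carlo p-value is the fraction of null replicates at
  or above the observed value.  The shared proportion is Jaccard
  (|A∩B|/|A∪B|) by default with |A∩B|/mean(|A|,|B|) as an alternative —
  the original analyses never state their denominator, so both are
  provided and the choice is recorded in the output.

## Landscape statistics

Windows are non-overlapping 1-Mb tiles (a "sliding window" with step =
width; the width is configurable).  Genes belong to the window containing
their leftmost CDS coordinate — single assignment, no fractional
overlap.  Per window: gene count, Ψ count and the Ψ/ORF ratio (undefined
without genes), optionally stratified into singleton and duplicated
genes using the family classification.  `density_correlation()` reports
Pearson r (with the two-sided t-based p-value) between Ψ/ORF and gene
count; a zero-variance input is reported as undefined rather than
guessed.  `region_compare()` contrasts centromere against telomere
regions (4 Mb around the centromere midpoint and 4 Mb per chromosome
tip) for CDS length, exon count, GC fraction and per-locus disrupted
allele frequency, separately for Ψ and non-Ψ loci, with Welch's
unequal-variance two-sided t-tests — the t-test variant is unspecified
in the source, and Welch's is the safer default.  P-values are reported
raw, without multiple-testing correction, mirroring the original
reporting style.

## Clusters and families

Two Ψ loci join a cluster when at most 9 genes of any status lie between
them on the same chromosome ("separated by less than ten genes", read
strictly); clusters are maximal chains.  Families replace an external
BLASTN + ClustalW2 pipeline with an internal, deterministic equivalent:
a shared-k-mer prefilter (k = 11, ≥3 shared k-mers, standing in for a
stringent e-value screen; disabled automatically for ≤20 genes so small
inputs are aligned all-against-all) proposes candidate pairs, which are
aligned locally with affine gaps (match +1, mismatch −2, open −5,
extend −2).  Identity is matches over aligned non-gap columns; coverage
is the aligned span over the shorter sequence — the original coverage
basis (query, subject or alignment) is unstated, and the shorter
sequence is the most conservative choice.  Pairs with identity ≥ 0.70
and coverage ≥ 0.50 become edges; families are single-linkage connected
components, the family identity is the maximum pairwise identity among
members, and a gene with no qualifying hit is a singleton.  The strand
is not searched.

## Molecular evolution

`ng_pair()` implements Nei–Gojobori (1986) counting: per codon, each
position contributes the fraction of its three possible changes that are
synonymous (changes to stop codons count as nonsynonymous); observed
differences are averaged over all mutational pathways between the two
codons, excluding pathways through stop codons (if every pathway is
blocked, all pathways are used rather than dropping the codon).  pS and
pN receive the Jukes–Cantor correction K = −(3/4) ln(1 − 4p/3);
Ka/Ks is reported as NA when Ks = 0 or a correction is undefined
(p ≥ 3/4), which keeps tabular averaging meaningful.

Alleles are materialised in the reference frame: SNVs substituted,
deleted coding bases marked `-`, insertions not represented; codons
containing gaps, ambiguity or stops in either sequence are dropped
pairwise.  π and Dxy are raw per-site proportions (no correction) over
the same compared sites; Ka/Ks are the corrected rates.  For each Ψ
locus only the disrupted haplotype with the highest carrier count is
analysed (the "representative"); low-frequency disrupted haplotypes are
excluded, following the source methods.

`tajimas_d()` is the standard Tajima (1989) statistic; D is undefined
(NaN) when there are no segregating sites, and at least four sequences
are required.  `sim_neutral_sample()` provides a plain n-coalescent with
infinite-sites mutation for calibration; over 200 replicates the mean D
is expected within ±0.15 of 0 — note that this band is about 2.3
Monte-Carlo standard errors at 200 replicates, so the check is seeded.

## Domain bias

For each domain family: PPD (the proportion of members that are Ψ loci),
FDA (the mean carrier count over the family's Ψ loci) and the
per-ecotype frequency PPD·FDA/n, which reproduces the published
per-ecotype column on every row where all three inputs are printed.  A
locus carrying several domains counts in each of its families.  The
top-1% partition takes the empirical 0.99 quantile (type-7 linear
interpolation) of PPD and of FDA across families; region I is above both
cutoffs, II above the FDA cutoff only, III above the PPD cutoff only,
IV neither (the original figure does not fix which single-parameter
region is called II versus III; the orientation here is documented and
configurable by relabeling).  Ties at a cutoff are included (≥).  The
subset randomization test reuses the shared-Ψ null restricted to a
family subset's loci.

## Phylogeny

The presence/absence matrix codes 1 for an intact allele and 0 for a
disrupted one, accessions × Ψ loci, columns sorted by locus id.  The
tree is Saitou–Nei neighbor joining on Hamming-proportion distances;
negative branch lengths are clamped to zero with the deficit moved to
the sister branch, and the unrooted tree is written as Newick.  The
source methods name neighbor joining while their discussion mentions a
parsimony program; neighbor joining is implemented as the primary method
and parsimony is out of scope.

## Numerical conventions and degenerate inputs

* All internal coordinates are 0-based half-open; GFF3, VCF and the TSV
  dialect are converted at the boundary, and indel anchor bases are
  stripped so positions point at the first changed base.
* Overlapping variants within one accession are a hard error; unsorted
  input is sorted with a warning.
* Genes whose CDS length is not a positive multiple of 3 are skipped
  with a warning at parse time.
* Relative-position ties at 1/3 or 2/3 fall in the lower bin; criterion
  cutoffs are strict (`rel < cutoff`).
* The log-curve fit requires ≥3 points; `density_correlation()` requires
  ≥3 windows; t-test cells with fewer than 2 observations are NA;
  `shared_null()` warns below 100 replicates.
* NJ tie-breaks follow the implementation's lowest-index pair order,
  making tree output deterministic.

## Problem sizes

The test suite and examples run on simulated genomes of 2 chromosomes ×
0.3–2.5 Mb with 50–1000 genes and 6–20 accessions, chosen so the full
suite exercises every stage — including a 20 000-cell exact caller
oracle — in a few minutes on one core.  Sizes are parameters of
`sim_params()`, so larger emulations are a configuration change, not a
code change.

## Known limitations

* The caller trusts the reference annotation; it does not re-annotate
  ORFs or rescue reading frames across accessions.
* Splice-site disruption and start-codon loss are detected neither as Ψ
  calls nor separately.
* The family prefilter can miss pairs hovering exactly at 70% identity
  with no conserved 11-mer run; disable it (`use_prefilter = FALSE`) for
  exhaustive small-scale runs.
* Ka/Ks is pairwise-counting (NG86), not maximum-likelihood; π and Dxy
  are uncorrected proportions.  Units differ accordingly and are named
  in every output column.
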