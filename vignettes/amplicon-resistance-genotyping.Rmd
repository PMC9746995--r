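---
title: "Dual-barcode amplicon sequencing for insecticide-resistance genotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-barcode amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliseqr)
```

## The assay this package analyses

Target-site insecticide resistance in *Aedes aegypti* is driven by point
mutations in three genes: the voltage-gated sodium channel (*vgsc*,
kdr mutations such as V1016G/I and F1534C), acetylcholinesterase
(*ace-1*, G119S) and the GABA-receptor *rdl* locus (A296S). A
cost-effective way to survey them is multiplexed amplicon sequencing:
eleven ~444–498 bp regions spanning the known mutation sites are PCR
amplified per mosquito with primers that carry a mosquito-specific 6 bp
barcode on both the forward and the reverse side. Products from 20
mosquitoes × 11 loci (220 amplicons) are pooled, sequenced as 250 bp
read pairs, and demultiplexed *in silico* by the (forward, reverse)
barcode combination.

`ampliseqr` reimplements the complete downstream analysis as a single
tested R package: panel/sample-sheet data model, pool simulator,
demultiplexer with mistag removal, per-amplicon aligner and pileup
variant caller with allele-ratio diploid genotyping, cohort retention
filters and consequence annotation, and population-genetic reporting
(allele frequencies, Hardy–Weinberg tests, Tajima's D, concordance).

## Demultiplexing and mistag removal

A read pair is assigned to a (mosquito, amplicon) when

1. the first 6 bases of each mate match a known barcode
   (`barcode_max_mismatch`, default 0 — 6-mers are short enough that a
   1-mismatch tolerance erodes the pairwise distance of realistic
   barcode sets, so exact matching is the default);
2. the (forward, reverse) combination is listed in the sample sheet;
3. the bases after the barcode match exactly one amplicon's primer
   within `primer_max_mismatch` (default 2), with degenerate primer
   positions compared through the IUPAC expansion sets.

Pairs whose two barcodes are individually valid but whose combination
is unassigned are counted **mistag** and discarded — this is the
index-hopping removal step, and the simulator models mistagging the
same way (swapping in a valid-but-unassigned combination). Everything
else is **unmatched**: unknown barcodes, failed primer matches, and
pairs whose two mates match primers of different amplicons (a
conservative guard against chimeric pairs). Both read orientations are
attempted, since amplicon orientation on the flow cell is not
guaranteed. The partition is exhaustive:
`assigned + mistag + unmatched = total`, property-tested on fuzzed
input.

Barcode and primer bases are trimmed before variant calling, qualities
in lockstep, so technical sequence never reaches the pileup.

## Alignment

Reads are aligned to their amplicon's reference insert with a glocal
(semi-global) affine-gap aligner written in C++: the read is aligned
end to end, reference end-gaps are free. Scoring is match +1,
mismatch −1, and a gap of length *L* costs `gap_open + L·gap_extend`
(−4 − L by default). Ties break deterministically: smallest end
position on the reference, diagonal-preferring traceback. The original
workflow used BWA-MEM; an internal aligner keeps the package
self-contained and is exact rather than heuristic at these read/insert
sizes. Scores are verified against an independent full-DP oracle in the
test suite. Amplicon reads are highly redundant, so each distinct
sequence in a read group is aligned once and the result reused.

Mate 2 is reverse-complemented before alignment. Because 2×250 bp pairs
overlap on ~470 bp amplicons, overlapping mate bases at the same insert
position are counted **once**, keeping the higher-quality observation —
otherwise depth in the overlap would double-count each fragment.

## Pileup, filters and allele-ratio genotyping

Pileup columns record, per insert offset, the depth of each allele
among bases with phred ≥ `min_base_quality` (default Q30); lower
quality bases count only toward the raw spanning depth. Indels are
keyed by their left-aligned, anchor-base VCF representation
(e.g. `CT>C`); a read carrying an indel supports the indel allele at
the anchor column, not additionally the anchor reference base.

Genotyping per site:

* quality-passing depth < `min_depth` (50) → `missing`;
* alleles with depth < `min_allele_depth` (10) are ignored;
* among qualifying alleles, the top two by depth (reference first on
  ties) define the **allele ratio** = major / (major + minor), 1.0 when
  a single allele qualifies;
* ratio ≥ `hom_ratio_threshold` (0.8, inclusive) → homozygous for the
  major allele, otherwise heterozygous.

The 0.8–1.0 reassignment band is the core empirical rule of the assay:
replicate and Sanger comparisons show that discordant calls concentrate
in heterozygotes with ratios of 0.8–1, and recalling them homozygous
restores full concordance. The exact allele-ratio formula of the
diploid genotyping scheme the assay cites is not restated in its
methods; major over top-two depths is the inference implemented here,
and the boundary is inclusive. `concordance(..., apply_reassignment =
TRUE)` applies the same rule when comparing call sets.

The published workflow called variants with two external callers and
took the union; this package implements one internal pileup caller
instead. At amplicon depths (hundreds-fold) with Q30-filtered bases,
pileup calling of SNPs and small indels is essentially
count-based, and the union-of-callers step is not reproduced.

## Cohort rules

Per-sample calls are merged by site key (chrom, pos, ref, alt)
regardless of how many amplicons cover the site. When overlapping
amplicons yield duplicate calls for one sample, the call with higher
quality-passing depth wins and disagreements are flagged — the
published pipeline is silent on this, so the choice is documented here
rather than hidden. Retention implements the cross-sample rule: a site
is kept iff carriers (≥1 alternate allele) number **more than one
mosquito** and span **at least two pools** (`min_mosquitoes = 2`,
`min_pools = 2`). Cohorts sequenced in a single pool therefore retain
nothing unless `min_pools` is overridden — deliberate, since the
two-pool requirement is what makes mistag artefacts unlikely to
replicate. Reports expose both *n genotyped* and *n carriers* per site,
because published per-site denominators can differ between the two.

## Consequence annotation

Panel CDS segments carry genomic interval, strand, frame and optionally
`cds_offset`, the number of coding bases preceding the segment in the
transcript. The 5-column (frame-only) format cannot place an
amplicon-local codon at an absolute amino-acid number such as rdl 296,
which is why the optional sixth column exists; frame is validated
against it when both are present. Amino-acid numbering across species
is inconsistent in the resistance literature (e.g. *rdl* 296 vs
*Drosophila* 301), so known-site labels are carried as panel metadata
rather than recomputed.

Exonic SNVs are translated strand- and frame-aware with the standard
genetic code (synonymous / missense / stop_gained). Codons that run off
the amplicon or CDS segment are reported `truncated_codon`, never
guessed. Intronic sites within 8 bases of an exon boundary are
`splice_region`; exonic sites within 3 bases keep their coding effect
and set a `near_splice` flag. The 3/8 window is the convention of the
standard consequence-calling tool this step replaces; the original
analysis does not define its window.

## Population-genetic statistics

* **HWE**: a 1-df chi-squared goodness-of-fit of observed genotype
  counts against (1−p)², 2p(1−p), p², no Yates correction and no exact
  test at small counts (the original analysis specifies only
  "chi-squared tests"); a warning is emitted when an expected count is
  below 5, and the deviation flag uses p < 0.001.
* **Tajima's D** is computed from unphased dosage matrices: the mean
  pairwise difference is `k̄ = Σ 2x(2n−x)/(2n(2n−1))` over segregating
  sites with alternate-allele count x, which equals the average over
  all chromosome pairs without phasing; constants a₁…e₂ follow the
  standard definitions and D is undefined (reported missing) at S = 0.
  Sites with any missing genotype are dropped listwise, keeping n
  constant — a per-pair treatment would break the variance formula.
  Whether the published −0.56 was computed per amplicon or pooled is
  unstated, so `cohort_tajimas_d()` supports both via `per_locus`.
* **Concordance** compares shared non-missing (sample, site) genotype
  keys, optionally after the 0.8-ratio reassignment.

The published Cabo Verde values (146 SNPs, 84.2 %/90 %/67 %
concordances, D = −0.56, ~40 % MAF < 0.1) depend on unreleased reads;
they define report shapes only and are asserted nowhere in this
package.

## What the simulator does and does not emulate

`simulate_pool()` emits pairs structured
5′-[6 bp barcode][primer][insert…]-3′ on both mates, heterozygous sites
drawing each haplotype with probability ½ per fragment, with:

* substitution errors at `base_error_rate` (default 0; indel errors are
  out of scope by default since SNP calling is the focus);
* uniform Q37 qualities, or a two-level model assigning low phred to
  erroneous bases so the Q30 filter can be exercised independently of
  the error model;
* mistagging at `mistag_rate` as barcode-combination swapping among
  valid barcodes (the published work does not quantify its mistag rate;
  the knob's conventional setting of ~1 % in our examples is a
  placeholder, not a measured value);
* optional per-locus efficiency multipliers for coverage spread
  (real panels show 120- to ~2,400-fold differences);
* either fixed per-amplicon coverage or a pool-level `total_pairs`
  budget (needed for 50,000-pairs-over-220-amplicons arithmetic);
* byte-identical output under a fixed seed.

Fragments are whole amplicons (no shearing), which matches PCR amplicon
libraries. Not modelled: PCR chimeras, polymerase stutter, quality
decay along the read, copy-number variation, or contamination between
pools. A green end-to-end test therefore establishes correctness of the
analysis logic under a faithful-but-idealised read generator, not
robustness to every laboratory artefact.

The bundled `example_panel()` uses the real assay's primers, lengths
and multiplex groups, but **synthetic** insert sequences: seeded random
bodies with the primers grafted at the ends and the four known
resistance codons planted at literature-consistent coordinates. No
genome download is required and no real reference sequence is shipped.

## Numerical and degenerate-input choices

* Phred encoding is fixed at Sanger +33.
* Degenerate IUPAC bases are legal in primers only; inserts must be
  A/C/G/T (they come from a single reference assembly).
* Panel coordinates are 1-based inclusive in files, 0-based half-open
  internally.
* Reverse primers are stored 5′→3′ in primer orientation; validation
  compares their reverse complement to the insert's 3′ end.
* Amplicon length is primer-to-primer inclusive; barcodes and
  sequencing tails are technical sequence outside the declared length.
* Multi-allelic columns keep the top two qualifying alleles; the rest
  is treated as noise.
* `missing` genotypes propagate: they are excluded from carrier counts,
  concordance and HWE, and drop a site listwise for Tajima's D.

## Known limitations

* One pileup caller, no caller-union step.
* No metabolic-resistance or CNV detection; the panel targets
  target-site mutations only.
* Cross-pool contamination is not analysed; barcode combinations
  belonging to another pool's sheet are simply unmatched.
* The aligner is exact but O(read × insert); it is sized for amplicon
  panels (hundreds of reads per group), not whole-genome data.
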