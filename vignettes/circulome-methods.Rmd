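---
title: "Methods: detecting and characterizing eccDNA from Circulome-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing eccDNA from Circulome-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circulome)
library(dplyr)
```

## The biological setting

Ciliates such as *Oxytricha* keep two genomes: a germline micronucleus (MIC)
whose long chromosomes are mostly germline-limited DNA, and a somatic
macronucleus (MAC) assembled after mating from a copy of the MIC by massive
programmed rearrangement. Gene-bearing segments (MDSs,
macronuclear-destined sequences) are stitched together in MAC order —
sometimes from a scrambled MIC order — while the intervening
internally eliminated sequences (IESs), intergenic spacers around chromosome
breakage sites, and Tc1/*mariner*-type telomere-bearing-element (TBE)
transposons are destroyed. Short direct repeats called *pointers* occur once
at the end of MDS *n* and once at the start of MDS *n + 1*; one copy is
retained at each somatic junction.

A substantial part of this eliminated DNA leaves the genome as
extrachromosomal circular DNA (eccDNA). Circle sequencing
(Circulome-seq) captures it by exonuclease-digesting linear DNA, tagmenting
what remains, and sequencing paired ends. This package implements the
bioinformatic half of such a study: the three sequencing signatures of
circularity, circle assembly and filtering, annotation against the
rearrangement map, and circle-transcription analysis — all driven by a
synthetic genome and read simulator so every claim is testable against
exhaustive ground truth at desk scale.

## The three signatures of circularity

1. **TBE junction reads.** A circularized TBE joins the telomeric end of its
   right terminal inverted repeat (TIR) to the telomeric start of its left
   TIR across a 5 bp junction `G-A-N-T-X`, whose central `ANT` is the
   target-site duplication (TSD). Reads containing the 33-mer
   `GGTTTTGGGGTTTT.A.T.AAAACCCCAAAACC` (dot = any base) on either strand are
   counted and classified by the junction's final base into GANTC, GANTG and
   GANTA (T is tallied as `other` rather than dropped). One subtlety this
   package resolves explicitly: the 33-mer is nearly reverse-complement
   symmetric, so every junction read *also* matches as its own reverse
   complement — but in that orientation position 19 always reads C, the
   complement of the junction's constant G. `count_tbe_junction_reads()`
   therefore anchors on the constant G at match position 15 to pick the true
   orientation; without this, all classes collapse toward GANTC.

2. **Split junction reads.** A read spanning a circle's ligation point maps
   to the linear MIC in *permuted* order: its prefix aligns downstream of
   its suffix, on the same contig and strand.
   `detect_split_junctions()` keeps reads with exactly one primary and one
   supplementary alignment partitioning the read, applies the standard
   filters (MAPQ ≥ 5, no duplicates or secondary records, both coordinates
   ≥ 150 bp from contig ends), and infers the circle as
   `[suffix ref_start, prefix ref_end)`.

3. **The 9 bp tagmentation duplication.** Tn5 cuts with a 9 bp stagger. A
   small circle cut exactly once linearizes into a fragment whose two ends
   are the same cut, so the resulting read pair carries identical 9-mers at
   its 5′ ends; mapped, the mates sit on opposite strands facing outward
   with their 5′ ends overlapping by exactly nine bases.
   `detect_9bp_duplications()` requires the sequence-level duplication, the
   mapped geometry (`minus ref_end − plus ref_start == 9`, exactly), and the
   standard filters.

## Junction registers and direct repeats

When a direct repeat flanks the two cuts, the cut pair is not unique: `[s,
e)` and `[s + k, e + k)` describe the same circle whenever the *k* entering
bases agree. This package canonicalizes every junction — simulator truth and
detector output alike — to the *rightmost* register
(`canonical_junction()`), which is exactly the register a maximal-prefix
split alignment reports. "Exact coordinate recovery" is well-defined only
after this choice. Two consequences worth knowing:

* `flanking_direct_repeat()` measures the maximal exact extension in both
  directions from the junction points (capped at 25 bp; observed repeats in
  vivo are far shorter). In the canonical register the rightward extension
  is zero by construction, so the repeat is read leftward — for a circle cut
  exactly at a pointer, this recovers the pointer length.
* `classify_cut_sites()` compartments (pointer / IES / MDS, with a signed
  offset from the pointer's IES-facing edge) are register-sensitive. At zero
  cut noise the biological cuts sit on the pointer copies and classify 100%
  pointer; the canonical register shifts past the pointer end and, in about
  a quarter of junctions (when the next genome base coincidentally matches),
  one base further. Offsets are reported per register; choose the register
  deliberately when comparing distributions.

## The synthetic genome and read simulator

`sim_genome()` builds MIC contigs carrying MAC loci (alternating
pointer-flanked MDS cores and IESs), intergenic spacers with chromosome
breakage sites, and TBEs with telomeric-motif TIRs and an `ANT` TSD on both
flanks. Key defaults in `sim_config()` (all changeable, none load-bearing
for correctness):

| parameter | default | meaning |
|---|---|---|
| `n_contigs`, `contig_length` | 6 × 20 kb | desk-scale MIC |
| `n_mac_loci`, `mds_per_locus` | 12, 5 | 48 eliminated IESs |
| `ies_length_range` | 80–400 bp | floor respects the smallest circularized IES (57 bp) with margin for the 78 bp minimum circle |
| `pointer_length_nonscrambled` / `_scrambled` | 3–7 / 8–14 bp | means ≈ 5 and 11 bp |
| `fraction_scrambled` | 0.15 | loci with permuted MIC order |
| `tbe_length` | 4000 bp | full-length TBE scale |
| `tbe_flank_probs` | C 19 / G 52 / A 22 / T 7 % | composition of the base immediately outside the TSD ("position −4"), copied into the junction 5-mer |
| `read_length`, `insert_size` | 75 bp, 400 ± 80 | Illumina-like |
| `cut_offset_sd` | 8 bp | truncated-normal imprecision of IES cuts around the pointer anchors, independent per side |
| `depth` | 30× | circle coverage in a mid-rearrangement library |
| `exo_linear_survival` | 0.03 | linear survival of three exonuclease rounds |

Design choices where the underlying biology is unobserved:

* **Cut imprecision** is a truncated normal per side. Only summaries of the
  real cut-distance distributions are known; the normal is a stand-in, not a
  claim.
* **TBE excision** emits one resolved strand with the junction 5-mer
  `G + TSD + X`, X copied from the position −4 base. The excision
  heteroduplex (two strands disagreeing at the junction) is not modeled;
  sequencing reads single junctions.
* **Scrambling** permutes MIC order only. Inverting an MDS block would break
  the invariant that both annotated pointer copies carry identical
  forward-strand sequence, so orientation is always `+` (the field exists
  for annotation compatibility).
* **Tagmentation** places cuts as a Poisson process (rate 1/insert mean per
  copy; circles get enough copies to approach the target depth) and retains
  fragments through a Gaussian size-selection kernel centred on the insert
  size. Insert sizes therefore *emerge* from cuts plus selection rather than
  being drawn directly — drawing them directly would destroy the single-cut
  / 9 bp duplication logic the simulator exists to produce. Coincident cut
  positions collapse to one cut. `force_single_cut = TRUE` gives every
  circle exactly one cut, placed so neither mate crosses the pre-existing
  circle junction, isolating the 9 bp signature.
* The **library grid** is fixed: asexual ×2 (no circles), early ×2,
  mid ×2 (+exo), mid ×1 (−exo), late ×1, with `circle_factor` scaling circle
  abundance; downstream filters reference exactly this grid.

What the simulator deliberately does **not** emulate: base-calling errors
and quality models, the ~2000-fold MAC polyploidy, satellite-repeat circles,
MDS paralogy, old-MAC degradation products beyond generic linear background,
and gapped alignment. Green tests therefore certify the *logic* of the
pipeline — detector geometry, filters, statistics, bookkeeping — not its
robustness to sequencing noise or repeat-rich genomes; real data should
enter through external SAM from a production aligner.

## The internal mapper

`map_reads()` is an exact-match k-mer seed (default 16) with ungapped
binary-search extension, adequate because simulated reads are error-free.
Unique full-length placements get MAPQ 60; two or more tied placements get
MAPQ 0 with a deterministic (contig, position) tie-break — the only
downstream use is the MAPQ < 5 multi-mapper cut, which this binary model
serves exactly. Chimeric reads split at the maximal prefix extension (the
canonical register above). Reverse-strand reads are mapped via reverse
complement, with read offsets stored in aligned orientation as in SAM.
Real aligners replace all of this transparently: `read_sam()` accepts any
SAM text whose CIGARs use M/=/X/I/D/N/S/H.

## Circles, coverage and the high-confidence rule

Junction calls with identical (contig, start, end) merge into one isoform —
exact-coordinate only, because boundary heterogeneity is a real phenomenon
the analysis reports (`group_isoforms()` exists for windowed summaries).
A circle is **high confidence** iff horizontal coverage (fraction of the
circle body covered by ≥ 1 read) is ≥ 25% in *both* mid-rearrangement +exo
replicates, ≤ 15% in *both* asexual replicates (thresholds inclusive), and
at least one split junction read supports the isoform. The −exo and
early/late libraries never participate in the rule. Counts are
depth-normalized as reads per million mapped (RPM), rounded to one decimal
only at report time.

## Permutation nulls and statistics

`shuffle_intervals()` places each interval, length preserved, uniformly at
random among all positions where it fits inside a domain segment (segments
weighted by their number of valid placements); overlaps between placed
intervals are permitted and everything is deterministic under a seed. The
genome-wide domain uses strict containment. The IES-restricted domain
(`ies_domain()`, padded ±25 bp for boundary imprecision) can be shorter than
the longest circle, so placement falls back per-length to anchoring the
interval *start* inside a segment — lengths are still preserved. The
Kolmogorov–Smirnov comparison of cut-distance distributions and the
chi-squared contrasts delegate to `stats::ks.test()` (asymptotic, two
sample) and `stats::chisq.test()` (Pearson, no continuity correction); both
are cross-checked against brute-force oracles in the test suite.

One reporting note: the published eliminated-site percentages (0.46% of
non-scrambled, 0.04% of scrambled, 0.10% of intergenic sites yielding
circles) reproduce exactly from the shipped census, but the Pearson 2×2
chi-squared on those counts gives p ≈ 4 × 10⁻¹⁰, not the stronger bound
sometimes quoted; `eliminated_site_summary()` reports the computed
statistic and p-value.

## Circle transcription

`sim_rnaseq()` emulates a two-timepoint RNA-seq design with three
components: genic transcription over MDS interiors (12×, kept 40 bp from
MDS boundaries — mature somatic transcripts crossing an MDS–MDS junction do
not align contiguously to the germline and pointer-duplicated ends map
ambiguously), a weak basal genome-wide component (0.5×), and, at
mid-rearrangement only, transcription of a fixed 30% subset of circles
(10×) from bidirectional TSSs placed N(0, 20 bp) around the junction, with
read-through across the circular template (those reads map as permuted
chimeras and are found by reusing the split-junction detector).

`permutation_percentile()` compares the observed mean length-normalized
read count over circles with the same statistic over shuffled interval
sets; the percentile is the fraction of replicates strictly below the
observed mean (ties count as not-below), which makes it invariant to global
scaling of counts. Two domains mirror the two questions: restricted to IES
space, circle transcription stands far above the basal floor; genome-wide,
it is swamped by genic transcription and the effect disappears.

The permutation design presumes the circle set is a *sparse subset* of the
IES universe. `transcription_study_config()` encodes those study
conditions (8 × 30 kb contigs, 32 loci of 8 MDSs, roughly a third of
non-scrambled IESs excised once): with dense excision the nulls resample
the transcribed IESs themselves and the percentile is uninformative — a
property of the statistic, not of this implementation. Counting is
unstranded by default (TSSs are bidirectional); per-read, with ≥ 1 bp
intersection as overlap.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on
genomes of 120–240 kb with a few thousand to a few tens of thousands of
read pairs, 500–1000 shuffle replicates per null, and a 100-run calibration
of the transcription percentile — sizes chosen so the whole suite completes
in a couple of minutes on one core while leaving every statistical check
well-powered. All randomness flows through explicit seeds; identical seeds
give byte-identical genomes, FASTQ and shuffle output.

## Known limitations

* Ungapped, error-free alignment only; supply external SAM for real data.
* Translocation circles (cuts on different contigs) are out of scope, as in
  the source analyses.
* Circle copy number and size-selection bias are not corrected; the
  simulator reproduces the bias (small circles are under-sequenced) rather
  than removing it.
* The eliminated-site census and library statistics shipped in
  `inst/extdata` are published aggregates used for arithmetic
  reproduction; they are not re-derived here.
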