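# circulome

Detection and characterization of extrachromosomal circular DNA (eccDNA)
produced during programmed genome rearrangement in ciliates, from
tagmentation-based circle sequencing (Circulome-seq).

During the development of a new somatic macronucleus, ciliates such as
*Oxytricha* eliminate most of their germline (MIC) genome — transposons
(TBEs), internally eliminated sequences (IESs) between the retained MDS
segments, and intergenic DNA near chromosome breakage sites — and much of it
leaves as circular molecules. This package is for researchers analysing such
circle-enriched sequencing data (and for anyone who wants a fully testable,
desk-scale model of that analysis). It implements the three sequencing
signatures of circularity:

1. **TBE junction reads** — the 33-mer circular-junction pattern
   `GGTTTTGGGGTTTT.A.T.AAAACCCCAAAACC`, classified by the junction 5-mer
   `G-A-N-T-X` into GANTC / GANTG / GANTA (central `ANT` = the target-site
   duplication);
2. **split junction reads** — reads whose prefix maps *downstream* of their
   suffix on the same contig and strand (permuted order), diagnostic of a
   circular junction, with the standard filters (MAPQ ≥ 5, duplicate and
   secondary removal, 150 bp contig-end exclusion);
3. **9 bp duplication read pairs** — the Tn5 tagmentation signature of a
   circle cut exactly once: mates sharing a genomic 9-mer at their 5′ ends,
   mapped outward with exactly nine bases of 5′ overlap.

Around these it provides circle-isoform assembly (exact-coordinate merging),
horizontal coverage, the 25%/15% two-replicate high-confidence filter,
reads-per-million normalization, annotation against MDS/pointer/IES maps
(distance bins, cut-site compartments, flanking direct repeats,
eliminated-sequence categories, interval-shuffle permutation nulls,
Kolmogorov–Smirnov and chi-squared contrasts), and quantification of circle
transcription from RNA-seq against IES-restricted and genome-wide
permutation nulls. A synthetic MIC-genome and paired-end read simulator with
exhaustive ground truth (`sim_genome()`, `excise_circles()`,
`tagment_and_read()`, `sim_rnaseq()`) drives the test suite, so nothing
needs to be downloaded.

All functions take and return tibbles (0-based half-open coordinates), chain
with the pipe, and read/write the standard formats: FASTA/FASTQ via
Biostrings, SAM text (external aligner output is accepted everywhere),
BED6+ and bedGraph.

## Worked example

```r
library(circulome)
library(dplyr)

cfg     <- sim_config()
genome  <- sim_genome(cfg, seed = 1)
genome
#> <ecc_genome> 6 contigs (120,000 bp total), 12 MAC loci (2 scrambled),
#>   60 MDSs, 54 eliminated loci, 3 TBEs

circles <- excise_circles(genome, cfg, seed = 2)
reads   <- tagment_and_read(as_molecules(circles), config = cfg,
                            library = "mid_1", seed = 3)

idx  <- build_genome_index(genome)
segs <- map_reads(tibble(read_id = rep(reads$pair_id, 2),
                         mate = rep(1:2, each = nrow(reads)),
                         seq = c(reads$mate1_seq, reads$mate2_seq)),
                  genome, index = idx)

calls    <- detect_split_junctions(segs, nchar(genome$contigs),
                                   library = "mid_1", genome = genome)
isoforms <- assemble_circles(calls)
isoforms
#> # A tibble: 62 × 7
#>   isoform_id contig start   end n_reads support          length
#> 1 iso00001   MIC_01   792  1152       9 <tibble [1 × 2]>    360
#> 2 iso00002   MIC_01   799  1152       5 <tibble [1 × 2]>    353
#> 3 iso00003   MIC_01   800  1155       9 <tibble [1 × 2]>    355
#> ...
```

349 junction reads collapse into 62 circle isoforms; the overlapping
isoforms at MIC_01:792–1155 are the boundary heterogeneity of imprecise IES
excision, which exact-coordinate merging deliberately preserves. The same
reads yield the other two signatures:

```r
detect_9bp_duplications(reads, segs, nchar(genome$contigs),
                        library = "mid_1") |> nrow()
#> [1] 858

count_tbe_junction_reads(reads) |> filter(n_reads > 0)
#> # A tibble: 3 × 3
#>   library class n_reads
#> 1 mid_1   GANTG       1
#> 2 mid_1   GANTA       6
#> 3 mid_1   other       3
```

Depth normalization reproduces published library statistics exactly from
raw counts — e.g. 649 TBE junction reads among 1,185,659 mapped reads:

```r
rpm(649, 1185659)
#> [1] 547.4
```

`horizontal_coverage()` + `call_high_confidence()` apply the
two-replicate coverage rule; `classify_cut_sites()`,
`flanking_direct_repeat()`, `classify_eliminated_type()` and
`mds_distance_bins()` annotate the result; `permutation_percentile()`
compares circle transcription with IES-restricted shuffle nulls. Result
objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
displays. The methods vignette (`vignettes/circulome-methods.Rmd`) explains
the models, defaults and their limits.

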