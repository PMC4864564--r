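# txmetagene

Metagene profiles of RNA-related genomic features on standardized
transcript coordinates.

## What it is for

Post-transcriptional RNA modifications (m⁶A, m⁵C) and other RNA-related
features are reported as genome coordinates, but their interpretation
revolves around the landmarks of the mature transcript — TSS, start codon,
stop codon, TES.  `txmetagene` is for analysts who have a gene annotation
(GTF) and feature sets (BED intervals: MeRIP-Seq peaks, single-nucleotide
modification sites, methylation calls) and want the classic metagene
picture: where does the signal sit along a standardized 5′UTR–CDS–3′UTR
axis (or along lncRNAs), summarized over the whole transcriptome?

## The method

Every non-empty transcript component (5′UTR, CDS, 3′UTR; the whole
transcript for lncRNA) of mature length *L* is cut into *B* equal-width
bins (default *B* = 100) whose mature spans are projected back to genomic
intervals through the exon structure — a bin may span introns.  On the
standardized axis each mRNA component occupies 1/3 of [0, 1] (optionally,
widths proportional to true mean component lengths), and bin *i* of a
component with axis interval [o, o+w) sits at o + (i + ½)·w/B.

A feature overlapping *n* ≥ 1 retained transcripts contributes weight
**1/n** to every bin (of those transcripts) whose genomic footprint it
touches by ≥ 1 nt, so unambiguous features count fully and isoform-shared
features are split evenly.  Ambiguity is tamed beforehand by a length
filter (per-component minimum, default 100 nt), an isoform-ambiguity
filter (drop transcripts overlapping > 3 others), and an optional
feature-ambiguity filter (drop features on > 5 transcripts).  Cell
weights are normalized per feature group and per biotype to a density
integrating to 1, optionally Gaussian-smoothed (mass-conserving, with
boundary reflection), and plotted with landmark markers.  Flanking
promoter/downstream DNA (default 1 kb) can extend the axis.

For RNA/DNA bisulfite data, per-cytosine calls with ≥ 5 reads are split
into `high` / `low` / `undetermined` methylation groups by two one-sided
exact binomial tests (α = 0.05 each) against the data set's average
methylation probability (pooled Σm / Σ(m+u)); the groups export as BED
and feed back into the profiler for stratified curves.

A seeded synthetic-data module (`simulate_annotation()`,
`simulate_features()`, `simulate_cytosines()`) generates toy genomes,
feature sets and cytosine tables with known ground truth, so the whole
pipeline is testable without downloads.

## Worked example

```r
library(txmetagene)

anno  <- simulate_annotation(n_genes = 20, isoforms = 1,
                             lncrna_fraction = 0, p_no_utr = 0, seed = 101)
sites <- simulate_features(anno, n = 2000, law = "triangle",
                           peak_center = 2/3, peak_halfwidth = 0.1,
                           seed = 102)
mg <- metagene(anno, list(m6a_like = sites), min_component_length = 10)
#> annotation: 20 transcripts parsed
#> filters: 20 transcripts retained (20 mRNA, 0 lncRNA)
#> coordinates: 6000 bins built
#> features [m6a_like]: 2000 read, 2000 retained
#> features [m6a_like]: 2000 assigned to bins
summary(mg)
#> metagene profile summary
#>     group biotype total_weight integral mode_std_pos
#>  m6a_like    mRNA         2000        1    0.6683333
plot(mg)                      # one panel per biotype, landmarks marked
export_metagene(mg, "out")    # profile + filter-report TSVs and a PDF
```

2000 single-nucleotide sites were simulated from a triangular peak at
standardized position 2/3 — the stop codon, the hallmark m⁶A pattern.
The fitted profile integrates to exactly 1 and its mode lands at
0.668 ≈ 2/3, i.e. the stop codon, recovering the planted enrichment.
`metagene()` equally accepts a GTF path and BED paths directly:
`metagene("genes.gtf", list(peaks = "peaks.bed"))`.

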