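---
title: "Metagene profiling on standardized transcript coordinates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metagene profiling on standardized transcript coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmetagene)
```

## The problem

RNA-related features — m6A peaks from MeRIP-Seq, m5C calls from RNA
bisulfite sequencing, RNA-binding-protein sites — are delivered as genome
coordinates, but their biology is organized around the landmarks of the
mature transcript: TSS, start codon, stop codon, TES.  Summarizing where
features sit relative to those landmarks across thousands of transcripts
requires (i) converting between genome and mature-RNA coordinates through
exon/intron structure, (ii) standardizing transcripts of very different
lengths onto a common axis, and (iii) dealing with the ambiguity created by
overlapping isoforms, where one genomic position belongs to several RNAs —
possibly to the CDS of one and the 3'UTR of another.

## The model

**Standardized coordinates.**  Each transcript is decomposed into
components: 5'UTR, CDS and 3'UTR for mRNA (any of the UTRs may be empty),
the whole transcript for lncRNA.  Every non-empty component of mature
length $L$ is divided into $B$ bins of near-equal width
($\lfloor L/B\rfloor$ or $\lceil L/B\rceil$ nt; the $L \bmod B$ wider bins
are placed 5'-most — a deterministic, order-preserving rule).  Bin $i$ of a
component occupying the axis interval $[o, o+w)$ sits at standardized
position $o + (i + 1/2)\,w/B$.  In the default `equal` layout each mRNA
component occupies one third of $[0,1]$, so the profile is comparable
across transcripts regardless of their component lengths; the `true_width`
layout instead makes component axis widths proportional to their mean
lengths over the retained mRNAs.  Each bin's mature span is projected back
to the genome through the exon structure, so a bin may consist of several
genomic intervals when it spans introns.  The collection of projected bins
is the genome-facing coordinate system everything else overlaps against,
and can be exported as a BED-like table (`write_guitar_coords()`).

**Ambiguity weighting.**  A feature that overlaps (by at least 1 nt of
exonic sequence) $n \ge 1$ retained transcripts is allocated weight $1/n$
on every bin of every one of those transcripts whose genomic footprint it
touches; $n = 1$ gives the full weight 1.  The hit criterion is an
indicator (any overlap), not fractional coverage: with equal-width bins a
feature covering 70% 5'UTR and 30% CDS hits 5'UTR and CDS bins in exactly
that 70/30 proportion, which is the behavior the weighting is designed to
reproduce.  A feature spanning two components of the same transcript
contributes records in both.  Features are not length-normalized: a long
peak hits many bins and therefore contributes to many cells — with peak
data the profile reflects covered axis mass, not peak counts.

**Filters.**  Three filters precede assignment.  (1) A length filter:
every non-empty mRNA component must reach `min_component_length` (default
100 nt, the conventional cutoff for peak-resolution data; ~10 nt is
appropriate for single-base data), lncRNAs must reach `min_lncrna_length`
(default 300 nt, the usual lncRNA definition); independently each
component must hold at least $B$ nt so $B$ bins are feasible.  (2) An
isoform-ambiguity filter: transcripts whose exonic footprint overlaps more
than `max_tx_overlap` (default 3) other transcripts are dropped.  Counts
are computed once on the input set — removal never changes another
transcript's count, making the filter single-pass and order-independent.
We count on the post-length-filter set (switchable via
`count_before_length_filter`).  (3) An optional feature-ambiguity filter:
features overlapping more than `max_feature_tx` (default 5) retained
transcripts are discarded.  Transcript overlap requires the same strand by
default — antisense transcripts are biologically distinct RNAs — and
features with strand `*` (BED3) match both strands.

**Density.**  Per feature group and per biotype (mRNA and lncRNA are never
cross-normalized — their axes are not commensurable), cell weights $w_i$
on cells of axis width $d_i$ are normalized to a density
$f_i = w_i / (\sum_j w_j \, d_i)$ so that $\sum_i f_i d_i = 1$ over the
displayed axis.  Because each group is normalized separately, curves show
distributional shape, not abundance, and scaling one group's feature count
leaves every other group's curve unchanged.

**Flanking DNA.**  Optionally `flank` nt of promoter DNA (5' of the TSS)
and downstream DNA (3' of the TES) are added as pure genomic bins (no
intron logic), rendered on axis extensions of width 1/3 on each side and
included in the normalization domain, so RNA- and DNA-level signal appear
on one comparable axis.  The defaults (1000 nt, `flank_bins = bins`)
follow the conventional 1-kb promoter window.  When flanks are enabled,
the $n$ of the $1/n$ weighting counts transcripts whose exonic *or* flank
footprint the feature touches; otherwise a purely promoter-resident
feature (the typical DNA-methylation or H3K4me3 case) would have $n = 0$
and silently vanish.  A flank running past the chromosome start is
truncated with a warning.

**Smoothing.**  Displayed curves are smoothed with a Gaussian kernel
(default bandwidth 0.02 axis units) applied to the cell masses with
reflection at both axis ends; the transition matrix reallocates each
source cell's mass with column sums of one, so the integral is preserved
exactly and a uniform profile stays uniform to numerical precision.
Smoothing is presentation-only: exports carry the raw weights and raw
density alongside.

**Binomial methylation grouping.**  For bisulfite data, per-cytosine
calls (methylated count $m$, unmethylated $u$) with coverage
$m + u \ge$ `min_reads` (default 5) are classified against the average
methylation probability $p$ of the data set — by default the pooled
estimator $\sum m / \sum(m+u)$, which is what "average over the entire
transcriptome" means read-weighted; a per-site mean is available — using
two one-sided exact binomial tests at level $\alpha = 0.05$ each:
`high` if $P(X \ge m) < \alpha$, `low` if $P(X \le m) < \alpha$, else
`undetermined`.  Tails are inclusive (the standard exact-test convention,
conservative), no multiple-testing correction is applied (per-site raw
$\alpha$, as is usual for this descriptive grouping), and degenerate
$p \in \{0, 1\}$ is an error.  The three groups export as BED files that
feed straight back into `metagene()` for stratified profiles.

## The synthetic-data module

`simulate_annotation()` generates coordinate-only toy genomes: genes in
disjoint windows on alternating strands; per-gene isoform counts drawn
from a user-set pool, all isoforms anchored at the gene TSS so that
same-gene isoforms mutually overlap and the per-transcript overlap count
(`isoforms - 1`) is exact ground truth; intron-containing transcripts;
mRNAs with or without UTRs; a lncRNA fraction.  Default component lengths
(5'UTR 120–400 nt, CDS 300–1500 nt, 3'UTR 150–900 nt, lncRNA 0.4–2 kb,
introns 60–600 nt) are in the range of compact mammalian genes — chosen
once as plausible desk-scale values, small enough that full test runs
finish in seconds.  `simulate_features()` draws standardized positions
from a declared law — uniform, or a uniform/triangular mixture whose peak
location and half-width emulate landmark enrichment such as the m6A
stop-codon peak — and projects them to genomic intervals through a chosen
transcript.  `simulate_cytosines()` draws per-site methylation counts
from a rate mixture with recorded true classes.  All generators are
deterministic per seed with integer-only coordinates.

What the generators do *not* emulate: expression-level imbalance between
isoforms, sequencing noise in peak boundaries, chromosome-scale gene
density, biased genomic composition.  Passing tests therefore demonstrate
the correctness of the coordinate algebra, weighting, filtering and
normalization — not robustness to every artifact of real libraries.

## Numerical and design choices

* Coordinates are 1-based closed throughout (the GRanges convention);
  transcript coordinates run 1..L from the TSS.  BED input/output is
  0-based half-open on disk, converted by `rtracklayer`.
* The CDS span is used exactly as annotated — no ±3 nt stop-codon
  adjustment; users whose annotation excludes the stop codon from the CDS
  can pre-adjust.
* Transcripts lacking CDS records are lncRNA; a biotype whitelist
  (`noncoding_biotypes`) can force coding-looking entries to noncoding.
  Unstranded transcripts are rejected (no 5'→3' direction).
* $B$ defaults to 100 bins per component (~1% resolution per component,
  matching percent-style standardized axes).  With half-open bins a
  single-nucleotide site on a bin boundary hits exactly one bin.
* Degenerate inputs: empty feature sets yield an all-zero profile with a
  warning; all-zero cell vectors stay zero rather than dividing by zero;
  empty components contribute no bins and exclude a transcript only if
  the length filter says so.
* Test and example problem sizes (tens of genes, $10^3$–$10^4$ features,
  100-instance oracle sweeps) were chosen so the full suite runs in about
  two minutes while keeping per-cell counts large enough for the
  statistical checks to be meaningful.

## A worked run

```{r example}
anno <- simulate_annotation(n_genes = 20, isoforms = 1,
                            lncrna_fraction = 0, p_no_utr = 0, seed = 101)
sites <- simulate_features(anno, n = 2000, law = "triangle",
                           peak_center = 2/3, peak_halfwidth = 0.1,
                           seed = 102)
mg <- metagene(anno, list(m6a_like = sites), min_component_length = 10,
               verbose = FALSE)
summary(mg)
plot(mg)
```

The recovered mode sits at standardized position ~2/3 — the stop codon —
as dictated by the placement law, and the printed integral equals 1.

## Known limitations

* Abundant transcripts and long features dominate profiles: every feature
  and transcript carries the same unit weight, which is appropriate for
  site-level features but not for raw read alignments; median-abundance
  weighting is out of scope.
* mRNA and lncRNA curves are not mutually comparable (separate
  normalization by design).
* When transcripts are short relative to $B$, the ±1 nt bin-width
  differences produce a slight front-loaded tilt in raw per-cell weights;
  it averages out across transcripts and is invisible after smoothing,
  but per-nucleotide resolution ($B \approx L$) is not optimized.
* The 1/n split treats all overlapping isoforms as equally likely
  carriers; fuzzy or abundance-aware allocation is not implemented.
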