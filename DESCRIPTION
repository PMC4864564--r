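Package: txmetagene
Title: Metagene Profiles of RNA-Related Genomic Features on Standardized
    Transcript Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sketches the transcriptomic distribution of genome-coordinate
    features (RNA modification sites, MeRIP-Seq peaks, methylated cytosines)
    over mRNA and lncRNA. Builds standardized transcript coordinates by
    dividing each transcript component (5'UTR, CDS, 3'UTR, or the whole
    lncRNA) into equal-width bins and projecting the bins back onto the
    genome, so that features denoted in genome coordinates can be overlapped
    with the bins and summarized as a normalized metagene density anchored at
    the transcript landmarks (TSS, start codon, stop codon, TES). Handles
    isoform ambiguity by weighting each feature 1/n across the n overlapping
    transcripts, with length and isoform-ambiguity filters, optional flanking
    DNA regions, and binomial grouping of bisulfite cytosine calls into high,
    low and undetermined methylation classes. A seeded synthetic-data module
    generates toy annotations, feature sets and cytosine tables with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
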