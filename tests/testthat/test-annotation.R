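test_that("GTF parsing builds transcript models with converted coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\ttest\tCDS\t151\t350\t.\t+\t0\tgene_id "g1"; transcript_id "tx1";'
  ), gtf)
  anno <- read_annotation(gtf)
  tx <- transcripts(anno)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$mature_length, 200L)
  expect_equal(tx$biotype, "mRNA")
  ex <- anno$exon_tab
  expect_equal(ex$gstart, c(101L, 301L))
  expect_equal(ex$gend, c(200L, 400L))

  # same transcript without CDS lines is a lncRNA
  writeLines(c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";'
  ), gtf)
  expect_equal(transcripts(read_annotation(gtf))$biotype, "lncRNA")
})

test_that("malformed GTF lines are reported with their line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\ttest\texon\t400\t300\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";'
  ), gtf)
  expect_error(read_annotation(gtf), "line 2")
  writeLines("chr1 exon 1 10", gtf)
  expect_error(read_annotation(gtf), "line 1")
})

test_that("transcripts on multiple chroms/strands or unstranded are dropped", {
  ex <- data.frame(
    tx_id = c("a", "a", "b", "b", "c", "d"), gene_id = "g",
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1", "chr1"),
    start = c(1, 1, 1, 50, 1, 100), end = c(10, 10, 10, 60, 10, 200),
    strand = c("+", "+", "+", "-", ".", "+"))
  expect_warning(anno <- tx_annotation(ex), "dropping 3")
  expect_equal(transcripts(anno)$tx_id, "d")
})

test_that("book-ended exons are merged", {
  ex <- data.frame(tx_id = "a", gene_id = "g", chrom = "chr1",
                   start = c(101, 201), end = c(200, 300), strand = "+")
  anno <- tx_annotation(ex)
  expect_equal(transcripts(anno)$n_exons, 1L)
  expect_equal(transcripts(anno)$mature_length, 200L)
})

test_that("genomic positions map to mature coordinates and back", {
  anno <- two_exon_anno("+")
  expect_equal(genomic_to_transcript(anno, "tx1", 101), 1L)   # TSS
  expect_equal(genomic_to_transcript(anno, "tx1", 301), 101L) # after exon 1
  expect_true(is.na(genomic_to_transcript(anno, "tx1", 250))) # intronic
  expect_true(is.na(genomic_to_transcript(anno, "tx1", 500))) # intergenic

  annom <- two_exon_anno("-")
  expect_equal(genomic_to_transcript(annom, "tx1", 400), 1L)  # minus TSS
  expect_equal(genomic_to_transcript(annom, "tx1", 101), 200L)
})

test_that("mature spans project to minimal genomic interval lists", {
  anno <- two_exon_anno("+")
  # expected footprint derived by brute-force per-nt mapping
  g <- mature_nt_vector(anno, "tx1")
  span <- g[51:150]
  gr <- transcript_to_genomic(anno, "tx1", 51, 150)
  expect_equal(length(gr), 2L)   # crosses the intron
  expect_equal(GenomicRanges::start(gr), c(151L, 301L))
  expect_equal(GenomicRanges::end(gr), c(200L, 350L))
  expect_setequal(unlist(lapply(seq_along(gr), function(i)
    seq.int(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))), span)

  # single-exon span stays a single interval
  gr1 <- transcript_to_genomic(anno, "tx1", 1, 100)
  expect_equal(length(gr1), 1L)
  expect_equal(c(GenomicRanges::start(gr1), GenomicRanges::end(gr1)),
               c(101L, 200L))

  expect_error(transcript_to_genomic(anno, "tx1", 0, 10), "outside")
  expect_error(transcript_to_genomic(anno, "tx1", 150, 250), "outside")
})

test_that("projection and mapping are mutually inverse on random transcripts", {
  anno <- simulate_annotation(n_genes = 8L, seed = 11L)
  for (tx in transcripts(anno)$tx_id) {
    g <- mature_nt_vector(anno, tx)
    L <- length(g)
    # per-nt round trip on a sample of positions
    for (p in unique(c(1L, L, sample.int(L, 20L)))) {
      gr <- transcript_to_genomic(anno, tx, p, p)
      expect_equal(GenomicRanges::width(gr), 1L)
      expect_equal(genomic_to_transcript(anno, tx, GenomicRanges::start(gr)),
                   p)
      expect_equal(GenomicRanges::start(gr), g[p])
    }
    # random spans have the right total width and invert per-nt
    a <- sample.int(L - 1L, 1L); b <- sample.int(L - a, 1L) + a
    gr <- transcript_to_genomic(anno, tx, a, b)
    expect_equal(sum(GenomicRanges::width(gr)), b - a + 1L)
  }
})

test_that("component decomposition partitions the mature transcript", {
  anno <- two_exon_anno("+", cds = c(151L, 350L))
  cc <- tx_components(anno)
  expect_equal(cc$component, c("utr5", "cds", "utr3"))
  # brute-force: exonic nts before/within/after the CDS
  g <- mature_nt_vector(anno, "tx1")
  expect_equal(cc$tend[1] - cc$tstart[1] + 1, sum(g < 151))
  expect_equal(cc$tend[2] - cc$tstart[2] + 1, sum(g >= 151 & g <= 350))
  expect_equal(cc$tstart, c(1L, 51L, 151L))
  expect_equal(cc$tend, c(50L, 150L, 200L))

  # lncRNA is a single whole component
  lnc <- two_exon_anno("+", cds = NULL)
  expect_equal(tx_components(lnc),
               data.frame(tx_id = "tx1", component = "whole",
                          tstart = 1L, tend = 200L))

  # CDS starting at the TSS leaves no utr5 row
  at_tss <- two_exon_anno("+", cds = c(101L, 350L))
  expect_false("utr5" %in% tx_components(at_tss)$component)

  # CDS endpoints must be exonic
  expect_error(two_exon_anno("+", cds = c(250L, 350L)), "not covered")
})

test_that("component spans are contiguous and sum to the mature length", {
  anno <- simulate_annotation(n_genes = 10L, seed = 5L)
  cc <- tx_components(anno)
  for (tx in transcripts(anno)$tx_id) {
    ci <- cc[cc$tx_id == tx, ]
    ci <- ci[order(ci$tstart), ]
    expect_equal(ci$tstart[1], 1L)
    expect_equal(ci$tend[nrow(ci)],
                 transcripts(anno)$mature_length[
                   transcripts(anno)$tx_id == tx])
    if (nrow(ci) > 1L)
      expect_equal(ci$tstart[-1], ci$tend[-nrow(ci)] + 1L)
  }
})

test_that("mirroring the genome leaves transcript coordinates unchanged", {
  anno <- simulate_annotation(n_genes = 10L, seed = 7L)
  mir <- mirror_annotation(anno)
  a <- transcripts(anno); m <- transcripts(mir)
  m <- m[match(a$tx_id, m$tx_id), ]
  expect_equal(a$mature_length, m$mature_length)
  expect_equal(a$biotype, m$biotype)
  ca <- tx_components(anno); cm <- tx_components(mir)
  ord <- function(d) {
    d <- d[order(d$tx_id, d$tstart), ]; rownames(d) <- NULL; d
  }
  expect_equal(ord(ca), ord(cm))
})

test_that("GTF round trip preserves the annotation", {
  anno <- simulate_annotation(n_genes = 6L, seed = 3L)
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(anno, gtf)
  back <- read_annotation(gtf)
  a <- transcripts(anno); b <- transcripts(back)
  b <- b[match(a$tx_id, b$tx_id), ]
  expect_equal(a$mature_length, b$mature_length)
  expect_equal(a$biotype, b$biotype)
  expect_equal(a$cds_start, b$cds_start)
  expect_equal(a$cds_end, b$cds_end)
})
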