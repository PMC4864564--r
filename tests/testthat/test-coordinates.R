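test_that("bins divide components evenly with front-loaded remainders", {
  ex <- data.frame(tx_id = "l1", gene_id = "g1", chrom = "chr1",
                   start = 1001, end = 1300, strand = "+")
  anno <- tx_annotation(ex)              # lncRNA, mature length 300
  gc <- guitar_coords(anno, bins = 3L)
  b <- gc$bins
  expect_equal(nrow(b), 3L)
  expect_equal(b$width_nt, c(100L, 100L, 100L))
  expect_equal(b$std_pos, c(1, 3, 5) / 6)
  expect_equal(b$component, rep("whole", 3L))

  # length 10, 3 bins: widths 4/3/3, tiling verified nucleotide by nucleotide
  ex$end <- 1010
  gc2 <- guitar_coords(tx_annotation(ex), bins = 3L)
  expect_equal(gc2$bins$width_nt, c(4L, 3L, 3L))
  covered <- unlist(Map(seq.int, gc2$bins$tstart, gc2$bins$tend))
  expect_equal(sort(covered), 1:10)
})

test_that("mRNA components each span one third of the equal-layout axis", {
  anno <- mono_mrna(300L, 300L, 300L)
  gc <- guitar_coords(anno, bins = 100L)
  b <- gc$bins
  expect_equal(nrow(b), 300L)
  cds <- b[b$component == "cds", ]
  expect_true(all(cds$std_pos > 1 / 3 & cds$std_pos < 2 / 3))
  expect_equal(max(cds$std_pos) - min(cds$std_pos) + 1 / 300, 1 / 3)
  # cds cells cover an axis span of exactly 1/3
  cells <- gc$cells[gc$cells$component == "cds", ]
  expect_equal(sum(cells$cell_width), 1 / 3)
})

test_that("axis layout reflects true component widths when asked", {
  eq <- axis_layout("equal")
  expect_equal(eq$offset[eq$component %in% c("utr5", "cds", "utr3")],
               c(0, 1, 2) / 3)
  tw <- axis_layout("true_width",
                    mean_lengths = c(utr5 = 150, cds = 1500, utr3 = 1350))
  expect_equal(tw$width[match(c("utr5", "cds", "utr3"), tw$component)],
               c(0.05, 0.50, 0.45))
  same <- axis_layout("true_width",
                      mean_lengths = c(utr5 = 200, cds = 200, utr3 = 200))
  expect_equal(same, eq)
  expect_error(axis_layout("true_width",
                           mean_lengths = c(utr5 = 0, cds = 0, utr3 = 0)),
               "zero")
})

test_that("bins tile components without gap or overlap and project fully", {
  anno <- simulate_annotation(n_genes = 8L, seed = 21L)
  gc <- guitar_coords(anno, bins = 50L)
  b <- gc$bins
  comp <- tx_components(anno)
  for (i in seq_len(nrow(comp))) {
    bi <- b[b$tx_id == comp$tx_id[i] & b$component == comp$component[i], ]
    bi <- bi[order(bi$bin), ]
    expect_equal(bi$tstart[1], comp$tstart[i])
    expect_equal(bi$tend[nrow(bi)], comp$tend[i])
    expect_true(all(bi$tstart[-1] == bi$tend[-nrow(bi)] + 1L))
    expect_true(max(bi$width_nt) - min(bi$width_nt) <= 1L)
  }
  # per-bin genomic footprint width equals the bin's mature width,
  # hence the per-transcript total equals the mature length
  fw <- tapply(GenomicRanges::width(gc$granges),
               S4Vectors::mcols(gc$granges)$key, sum)
  expect_equal(as.numeric(fw[as.character(b$key)]), as.numeric(b$width_nt))
  tot <- tapply(as.numeric(b$width_nt), b$tx_id, sum)
  expect_equal(as.numeric(tot[transcripts(anno)$tx_id]),
               as.numeric(transcripts(anno)$mature_length))
  # at least one bin spans an intron in this fixture
  expect_true(any(table(S4Vectors::mcols(gc$granges)$key) > 1L))
})

test_that("a too-short component triggers an instructive error", {
  ex <- data.frame(tx_id = "l1", gene_id = "g1", chrom = "chr1",
                   start = 1, end = 50, strand = "+")
  expect_error(guitar_coords(tx_annotation(ex), bins = 100L),
               "length_filter")
})

test_that("flank bins tile the promoter and tail without touching exons", {
  anno <- mono_mrna(300L, 300L, 300L, tss = 1001L)
  gc <- guitar_coords(anno, bins = 100L, flank = 1000L, flank_bins = 50L)
  pro <- gc$bins[gc$bins$component == "promoter", ]
  expect_equal(nrow(pro), 50L)
  expect_equal(unique(pro$width_nt), 20L)
  prg <- gc$granges[S4Vectors::mcols(gc$granges)$key %in% pro$key]
  expect_equal(min(GenomicRanges::start(prg)), 1L)
  expect_equal(max(GenomicRanges::end(prg)), 1000L)
  expect_true(all(pro$std_pos < 0 & pro$std_pos > -1 / 3))
  # promoter bin 0 is the farthest from the TSS
  expect_equal(GenomicRanges::start(prg)[which.min(pro$bin)], 1L)

  tail_b <- gc$bins[gc$bins$component == "tail", ]
  tlg <- gc$granges[S4Vectors::mcols(gc$granges)$key %in% tail_b$key]
  expect_equal(range(c(GenomicRanges::start(tlg), GenomicRanges::end(tlg))),
               c(1901L, 2900L))
  expect_true(all(tail_b$std_pos > 1))

  # flank bins never intersect the exonic footprint
  exgr <- unlist(anno$exons)
  expect_equal(length(GenomicRanges::findOverlaps(prg, exgr)), 0L)
  expect_equal(length(GenomicRanges::findOverlaps(tlg, exgr)), 0L)

  # minus strand: the tail tiles the genomic left of the footprint
  annom <- mono_mrna(300L, 300L, 300L, tss = 2000L, strand = "-")
  gcm <- guitar_coords(annom, bins = 100L, flank = 1000L, flank_bins = 50L)
  tb <- gcm$bins[gcm$bins$component == "tail", ]
  tg <- gcm$granges[S4Vectors::mcols(gcm$granges)$key %in% tb$key]
  expect_equal(range(c(GenomicRanges::start(tg), GenomicRanges::end(tg))),
               c(101L, 1100L))
  # tail bin 0 sits right next to the TES (rightmost of the tail block)
  expect_equal(GenomicRanges::end(tg)[which.min(tb$bin)], 1100L)

  # flank reaching below the chromosome start is truncated with a warning
  near0 <- mono_mrna(300L, 300L, 300L, tss = 501L)
  expect_warning(guitar_coords(near0, bins = 100L, flank = 1000L),
                 "truncated")
})

test_that("standardized positions are invariant under genome mirroring", {
  anno <- simulate_annotation(n_genes = 8L, seed = 33L)
  mir <- mirror_annotation(anno)
  gc <- guitar_coords(anno, bins = 40L)
  gm <- guitar_coords(mir, bins = 40L)
  key <- function(b) b[order(b$tx_id, b$component, b$bin),
                       c("tx_id", "component", "bin", "std_pos", "width_nt")]
  a <- key(gc$bins); b <- key(gm$bins)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("guitar coordinates export as a BED-like conversion table", {
  anno <- mono_mrna(120L, 150L, 130L)
  gc <- guitar_coords(anno, bins = 10L)
  f <- tempfile(fileext = ".tsv")
  write_guitar_coords(gc, f)
  d <- read.delim(f)
  expect_equal(nrow(d), length(gc$granges))
  expect_true(all(d$end > d$start))           # half-open, 0-based start
  expect_equal(sum(d$end - d$start), 400L)
})
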