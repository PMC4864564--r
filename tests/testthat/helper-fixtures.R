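# small constructors and independent oracles shared across test files

# the canonical two-exon transcript: exons [101,200],[301,400], optional CDS
two_exon_anno <- function(strand = "+", cds = c(151L, 350L)) {
  ex <- data.frame(tx_id = "tx1", gene_id = "g1", chrom = "chr1",
                   start = c(101L, 301L), end = c(200L, 400L),
                   strand = strand, stringsAsFactors = FALSE)
  cdf <- if (is.null(cds)) NULL else
    data.frame(tx_id = "tx1", start = cds[1L], end = cds[2L])
  tx_annotation(ex, cdf)
}

# single-exon mRNA with given component lengths, TSS at `tss` (plus strand)
mono_mrna <- function(u5 = 300L, cl = 300L, u3 = 300L, tss = 1001L,
                      tx_id = "tx1", gene_id = "g1", strand = "+",
                      chrom = "chr1") {
  L <- u5 + cl + u3
  if (strand == "+") {
    ex <- data.frame(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
                     start = tss, end = tss + L - 1L, strand = strand)
    cds <- data.frame(tx_id = tx_id, start = tss + u5,
                      end = tss + u5 + cl - 1L)
  } else {
    ex <- data.frame(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
                     start = tss - L + 1L, end = tss, strand = strand)
    cds <- data.frame(tx_id = tx_id, start = tss - u5 - cl + 1L,
                      end = tss - u5)
  }
  tx_annotation(ex, cds)
}

# per-nucleotide genomic vector of a transcript in 5'->3' order
# (independent of the package's interval projection)
mature_nt_vector <- function(anno, tx_id) {
  ex <- anno$exon_tab[anno$exon_tab$tx_id == tx_id, , drop = FALSE]
  ex <- ex[order(ex$gstart), , drop = FALSE]
  g <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq.int(ex$gstart[i], ex$gend[i])))
  if (ex$strand[1L] == "-") g <- rev(g)
  g
}

# mirror the genome about position M: g -> M - g + 1, strand flipped
mirror_annotation <- function(anno, M = 1e6L) {
  et <- anno$exon_tab
  ex <- data.frame(tx_id = et$tx_id,
                   gene_id = anno$tx$gene_id[match(et$tx_id, anno$tx$tx_id)],
                   chrom = et$chrom,
                   start = M - et$gend + 1L, end = M - et$gstart + 1L,
                   strand = ifelse(et$strand == "+", "-", "+"),
                   stringsAsFactors = FALSE)
  coding <- anno$tx[anno$tx$biotype == "mRNA", , drop = FALSE]
  cds <- if (nrow(coding)) data.frame(
    tx_id = coding$tx_id,
    start = M - coding$cds_end + 1L,
    end = M - coding$cds_start + 1L) else NULL
  tx_annotation(ex, cds)
}

mirror_features <- function(gr, M = 1e6L) {
  s <- as.character(GenomicRanges::strand(gr))
  s2 <- ifelse(s == "+", "-", ifelse(s == "-", "+", "*"))
  out <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(gr)),
    IRanges::IRanges(M - GenomicRanges::end(gr) + 1L,
                     M - GenomicRanges::start(gr) + 1L),
    strand = s2)
  names(out) <- names(gr)
  out
}

# brute-force per-nucleotide assignment oracle: maps every feature
# nucleotide to transcripts and bins directly, then allocates 1/n weights
oracle_assign <- function(features, gc) {
  anno <- gc$annotation
  recs <- list()
  for (fi in seq_along(features)) {
    fchr <- as.character(GenomeInfoDb::seqnames(features))[fi]
    fstr <- as.character(GenomicRanges::strand(features))[fi]
    fnt <- seq.int(GenomicRanges::start(features)[fi],
                   GenomicRanges::end(features)[fi])
    hit_tx <- character(0L)
    hit_bins <- list()
    for (tx in anno$tx$tx_id) {
      t <- anno$tx[anno$tx$tx_id == tx, ]
      if (t$chrom != fchr) next
      if (fstr != "*" && fstr != t$strand) next
      g <- mature_nt_vector(anno, tx)
      tp <- match(fnt, g)          # mature positions of feature nts
      tp <- tp[!is.na(tp)]
      if (length(tp) == 0L) next
      hit_tx <- c(hit_tx, tx)
      b <- gc$bins[gc$bins$tx_id == tx &
                     !(gc$bins$component %in% c("promoter", "tail")), ]
      sel <- vapply(seq_len(nrow(b)), function(j)
        any(tp >= b$tstart[j] & tp <= b$tend[j]), NA)
      hit_bins[[tx]] <- b[sel, , drop = FALSE]
    }
    n <- length(hit_tx)
    if (n == 0L) next
    for (tx in hit_tx) {
      b <- hit_bins[[tx]]
      if (nrow(b))
        recs[[length(recs) + 1L]] <- data.frame(
          feature_id = as.character(fi), tx_id = tx,
          component = b$component, bin = b$bin, weight = 1 / n,
          stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L)
    return(data.frame(feature_id = character(0L), tx_id = character(0L),
                      component = character(0L), bin = integer(0L),
                      weight = numeric(0L)))
  out <- do.call(rbind, recs)
  out[order(out$feature_id, out$tx_id, out$component, out$bin), ]
}

# canonical form of assignment records for record-for-record comparison
canon_records <- function(rec) {
  d <- data.frame(feature_id = as.character(rec$feature_id),
                  tx_id = rec$tx_id, component = as.character(rec$component),
                  bin = rec$bin, weight = rec$weight,
                  stringsAsFactors = FALSE)
  d <- d[order(d$feature_id, d$tx_id, d$component, d$bin), ]
  rownames(d) <- NULL
  d
}

# small random instance for oracle-equivalence checks
random_instance <- function(seed) {
  anno <- simulate_annotation(
    n_genes = 2L, isoforms = c(1L, 2L, 3L), lncrna_fraction = 0.3,
    utr5_range = c(30L, 80L), cds_range = c(90L, 300L),
    utr3_range = c(30L, 120L), lncrna_range = c(120L, 400L),
    max_exons = 3L, intron_range = c(20L, 100L), p_no_utr = 0.15,
    gene_gap = 300L, seed = seed)
  gc <- guitar_coords(anno, bins = 10L)
  span <- max(anno$exon_tab$gend) + 100L
  n_feat <- sample(1:50, 1L)
  fs <- sample.int(span, n_feat, replace = TRUE)
  fw <- sample(1:60, n_feat, replace = TRUE)
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(fs, fs + fw - 1L),
    strand = sample(c("+", "-", "*"), n_feat, replace = TRUE))
  list(anno = anno, gc = gc, features = feats)
}
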