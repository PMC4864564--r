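#' Simulate a toy transcript annotation with known ground truth
#'
#' Generates a coordinate-only toy genome (no sequence is needed anywhere
#' in the method): genes are laid out on one chromosome in disjoint
#' windows, alternating strands; each gene carries one or several isoforms
#' that all share the gene TSS (so same-gene isoforms mutually overlap and
#' the per-transcript overlap count is exactly `isoforms - 1`, recorded as
#' ground truth).  Transcripts may contain introns; mRNAs may lack a 5'
#' and/or 3'UTR with probability `p_no_utr`; a fraction of genes is
#' noncoding (lncRNA).
#'
#' @param n_genes number of genes.
#' @param isoforms integer vector sampled uniformly for the per-gene
#'   isoform count.
#' @param lncrna_fraction probability that a gene is a lncRNA gene.
#' @param utr5_range,cds_range,utr3_range,lncrna_range component length
#'   ranges (nt), sampled uniformly.
#' @param max_exons maximum exon count per transcript (>= 1).
#' @param intron_range intron length range (nt).
#' @param p_no_utr probability that an mRNA lacks its 5'UTR (and,
#'   independently, its 3'UTR).
#' @param gene_gap genomic gap between gene windows (nt).
#' @param chrom chromosome name.
#' @param seed RNG seed; fixed seeds give identical annotations.
#' @return a `tx_annotation`; attribute `"truth"` is a data.frame with one
#'   row per transcript (`tx_id`, `gene_id`, `biotype`, `utr5_len`,
#'   `cds_len`, `utr3_len`, `mature_length`, `n_isoforms`,
#'   `true_overlap`).
#' @export
simulate_annotation <- function(n_genes = 30L, isoforms = c(1L, 1L, 2L, 3L),
                                lncrna_fraction = 0.25,
                                utr5_range = c(120L, 400L),
                                cds_range = c(300L, 1500L),
                                utr3_range = c(150L, 900L),
                                lncrna_range = c(400L, 2000L),
                                max_exons = 4L,
                                intron_range = c(60L, 600L),
                                p_no_utr = 0.1,
                                gene_gap = 2000L, chrom = "chr1",
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rint <- function(r) sample(seq.int(r[1L], r[2L]), 1L)
  exon_rows <- list(); cds_rows <- list(); truth_rows <- list()
  cursor <- 1L
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_iso <- sample(isoforms, 1L)
    is_nc <- runif(1L) < lncrna_fraction
    iso <- vector("list", n_iso)
    for (k in seq_len(n_iso)) {
      if (is_nc) {
        u5 <- 0L; cl <- 0L; u3 <- 0L
        L <- rint(lncrna_range)
      } else {
        u5 <- if (runif(1L) < p_no_utr) 0L else rint(utr5_range)
        cl <- rint(cds_range)
        u3 <- if (runif(1L) < p_no_utr) 0L else rint(utr3_range)
        L <- u5 + cl + u3
      }
      n_ex <- sample(seq_len(min(max_exons, max(1L, L %/% 50L))), 1L)
      brk <- if (n_ex > 1L) sort(sample(seq_len(L - 1L), n_ex - 1L)) else integer(0L)
      widths <- diff(c(0L, brk, L))
      introns <- if (n_ex > 1L)
        vapply(seq_len(n_ex - 1L), function(i) rint(intron_range), 0L)
      else integer(0L)
      iso[[k]] <- list(u5 = u5, cl = cl, u3 = u3, L = L,
                       widths = widths, introns = introns,
                       span = L + sum(introns))
    }
    win <- max(vapply(iso, `[[`, 0L, "span"))
    anchor <- if (strand == "+") cursor else cursor + win - 1L
    for (k in seq_len(n_iso)) {
      z <- iso[[k]]
      tx_id <- sprintf("%s.t%d", gene_id, k)
      off <- cumsum(c(0L, z$widths[-length(z$widths)] +
                        z$introns))          # 5'->3' exon offsets
      if (strand == "+") {
        gs <- anchor + off
        ge <- gs + z$widths - 1L
      } else {
        ge <- anchor - off
        gs <- ge - z$widths + 1L
      }
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        tx_id = tx_id, gene_id = gene_id, chrom = chrom,
        start = gs, end = ge, strand = strand, stringsAsFactors = FALSE)
      if (!is_nc) {
        # genomic endpoints of the mature CDS span [u5+1, u5+cl]
        cum <- cumsum(z$widths)
        t2g1 <- function(tp) {
          i <- which(cum >= tp)[1L]
          within <- tp - (cum[i] - z$widths[i]) - 1L
          if (strand == "+") gs[i] + within else ge[i] - within
        }
        ga <- t2g1(z$u5 + 1L)
        gb <- t2g1(z$u5 + z$cl)
        cds_rows[[length(cds_rows) + 1L]] <- data.frame(
          tx_id = tx_id, start = min(ga, gb), end = max(ga, gb),
          stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        tx_id = tx_id, gene_id = gene_id,
        biotype = if (is_nc) "lncRNA" else "mRNA",
        utr5_len = z$u5, cds_len = z$cl, utr3_len = z$u3,
        mature_length = z$L, n_isoforms = n_iso,
        true_overlap = n_iso - 1L, stringsAsFactors = FALSE)
    }
    cursor <- cursor + win + gene_gap
  }
  anno <- tx_annotation(do.call(rbind, exon_rows),
                        if (length(cds_rows)) do.call(rbind, cds_rows))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  attr(anno, "truth") <- truth
  anno
}

# draw standardized axis positions from a placement law on [0, 1]:
# uniform, or a mixture of uniform and a symmetric triangular peak
.draw_positions <- function(n, law, center, halfwidth, peak_weight) {
  u <- runif(n)
  if (law == "uniform") return(u)
  from_peak <- runif(n) < peak_weight
  tri <- center + halfwidth * (runif(n) - runif(n))
  x <- ifelse(from_peak, tri, u)
  # reflect into [0, 1]
  x <- abs(x)
  x <- ifelse(x > 1, 2 - x, x)
  pmin(pmax(x, 0), 1)
}

#' Simulate genomic features placed by a known law on the standardized axis
#'
#' Draws standardized positions from the placement law (uniform, or a
#' uniform/triangular-peak mixture emulating e.g. stop-codon enrichment),
#' assigns each to a uniformly chosen transcript of the requested biotype,
#' converts the position to a mature-transcript nucleotide under the
#' equal-thirds layout, and projects it to the genome.  mRNA placement
#' uses transcripts with all three components present so every axis
#' position is realizable.
#'
#' @param anno a `tx_annotation` (typically the filtered one).
#' @param n number of features.
#' @param law `"uniform"` or `"triangle"`.
#' @param biotype `"mRNA"` or `"lncRNA"`.
#' @param peak_center,peak_halfwidth,peak_weight triangular-peak mixture
#'   parameters: location on the `[0, 1]` axis, half-width, and the
#'   fraction of features drawn from the peak (the rest are uniform).
#' @param width feature width in nt (a width-w feature covers mature
#'   positions p..p+w-1, clipped at the transcript end; its genomic
#'   interval is the enclosing range, so peaks may span introns).
#' @param seed RNG seed.
#' @param path optional BED output path.
#' @return GRanges of features; attribute `"truth"` is a data.frame with
#'   the generating `tx_id`, standardized position `u` and mature position.
#' @export
simulate_features <- function(anno, n = 1000L, law = c("uniform", "triangle"),
                              biotype = "mRNA", peak_center = 2 / 3,
                              peak_halfwidth = 0.1, peak_weight = 0.8,
                              width = 1L, seed = NULL, path = NULL) {
  law <- match.arg(law)
  stopifnot(inherits(anno, "tx_annotation"))
  if (!is.null(seed)) set.seed(seed)
  comp <- anno$components
  if (biotype == "mRNA") {
    full <- names(which(table(comp$tx_id[comp$tx_id %in%
                                           anno$tx$tx_id[anno$tx$biotype == "mRNA"]]) == 3L))
  } else {
    full <- anno$tx$tx_id[anno$tx$biotype == "lncRNA"]
  }
  if (length(full) == 0L) stop("no usable ", biotype, " transcripts")
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(path)) writeLines(character(0L), path)
    attr(gr, "truth") <- data.frame(tx_id = character(0L), u = numeric(0L),
                                    mature_pos = integer(0L))
    return(gr)
  }
  u <- .draw_positions(n, law, peak_center, peak_halfwidth, peak_weight)
  tx <- sample(full, n, replace = TRUE)
  comp_by_tx <- split(comp, comp$tx_id)
  ex_by_tx <- split(anno$exon_tab, anno$exon_tab$tx_id)
  chrom <- strand <- character(n)
  gstart <- gend <- mpos <- integer(n)
  for (i in seq_len(n)) {
    cc <- comp_by_tx[[tx[i]]]
    L <- max(cc$tend)
    if (biotype == "mRNA") {
      third <- min(floor(u[i] * 3), 2)
      ci <- cc[cc$component == c("utr5", "cds", "utr3")[third + 1L], ]
      f <- u[i] * 3 - third
      pos <- ci$tstart + min(floor(f * (ci$tend - ci$tstart + 1L)),
                             ci$tend - ci$tstart)
    } else {
      pos <- 1L + min(floor(u[i] * L), L - 1L)
    }
    pe <- min(pos + width - 1L, L)
    d <- .t2g(ex_by_tx[[tx[i]]], as.integer(pos), as.integer(pe))
    chrom[i] <- d$chrom[1L]
    strand[i] <- d$strand[1L]
    gstart[i] <- min(d$gstart)
    gend[i] <- max(d$gend)
    mpos[i] <- pos
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(gstart, gend),
                               strand = strand)
  names(gr) <- sprintf("feat%05d", seq_len(n))
  if (!is.null(path)) rtracklayer::export(gr, path, format = "bed")
  attr(gr, "truth") <- data.frame(tx_id = tx, u = u, mature_pos = mpos,
                                  stringsAsFactors = FALSE)
  gr
}

#' Simulate a per-cytosine bisulfite call table with known classes
#'
#' Each site is assigned a latent class (e.g. background vs highly
#' methylated) with the given mixture fractions; its methylated read count
#' is Binomial(coverage, class rate).  The true class is recorded for
#' recovery tests.
#'
#' @param n number of cytosine sites.
#' @param coverage per-site read coverage: a scalar, a length-`n` vector,
#'   or a Poisson mean when `coverage_law = "poisson"` (truncated at 1).
#' @param rates named numeric vector of per-class methylation rates.
#' @param fractions mixture fractions (same names/order as `rates`,
#'   summing to 1).
#' @param coverage_law `"fixed"` or `"poisson"`.
#' @param chrom chromosome name; sites are placed every 3 nt.
#' @param seed RNG seed.
#' @param path optional TSV output path (chrom, pos, strand, m, u).
#' @return data.frame `chrom`, `pos`, `strand`, `m`, `u`, `coverage`,
#'   `true_class`.
#' @export
simulate_cytosines <- function(n = 1000L, coverage = 50L,
                               rates = c(background = 0.0165, high = 0.5),
                               fractions = c(background = 0.9, high = 0.1),
                               coverage_law = c("fixed", "poisson"),
                               chrom = "chr1", seed = NULL, path = NULL) {
  coverage_law <- match.arg(coverage_law)
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(names(fractions) %in% names(rates)))
  if (!is.null(seed)) set.seed(seed)
  cls <- sample(names(fractions), n, replace = TRUE, prob = fractions)
  cov <- if (coverage_law == "poisson")
    pmax(1L, stats::rpois(n, coverage)) else rep_len(as.integer(coverage), n)
  m <- rbinom(n, cov, rates[cls])
  d <- data.frame(chrom = chrom, pos = seq_len(n) * 3L - 2L,
                  strand = rep_len(c("+", "-"), n),
                  m = m, u = cov - m, coverage = cov,
                  true_class = cls, stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(d[, c("chrom", "pos", "strand", "m", "u")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  d
}
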