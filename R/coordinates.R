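# split a length L into B ordered widths differing by at most 1,
# remainder front-loaded (5'->3')
.split_widths <- function(L, B) {
  base <- L %/% B
  r <- L %% B
  w <- rep.int(base, B)
  if (r > 0L) w[seq_len(r)] <- base + 1L
  w
}

#' Standardized-axis layout of transcript components
#'
#' Assigns each component a sub-interval of the standardized axis.  In
#' `equal` mode the three mRNA components each occupy 1/3 of `[0, 1]`; in
#' `true_width` mode their widths are proportional to the mean component
#' lengths over the annotated mRNAs (still summing to 1).  The lncRNA axis
#' is always the single interval `[0, 1]`.  When flanks are enabled the
#' promoter extends the axis to the left of 0 and the downstream DNA tail
#' to the right of 1, each with axis width `flank_frac`.
#'
#' @param mode `"equal"` or `"true_width"`.
#' @param mean_lengths named numeric (`utr5`, `cds`, `utr3`): mean component
#'   lengths in nt, required for `true_width`.
#' @param flank logical; include promoter/tail axis extensions?
#' @param flank_frac axis width of each flank extension (default 1/3).
#' @return data.frame with columns `biotype`, `component`, `offset`,
#'   `width` (axis units).
#' @export
axis_layout <- function(mode = c("equal", "true_width"), mean_lengths = NULL,
                        flank = FALSE, flank_frac = 1 / 3) {
  mode <- match.arg(mode)
  if (mode == "equal") {
    w <- c(utr5 = 1, cds = 1, utr3 = 1) / 3
  } else {
    if (is.null(mean_lengths) ||
        !all(c("utr5", "cds", "utr3") %in% names(mean_lengths)))
      stop("true_width mode needs mean_lengths for utr5, cds, utr3")
    m <- as.numeric(mean_lengths[c("utr5", "cds", "utr3")])
    if (sum(m) <= 0) stop("all mean component lengths are zero")
    w <- setNames(m / sum(m), c("utr5", "cds", "utr3"))
  }
  lay <- data.frame(
    biotype = c(rep("mRNA", 3L), "lncRNA"),
    component = c("utr5", "cds", "utr3", "whole"),
    offset = c(0, cumsum(w)[1:2], 0),
    width = c(unname(w), 1),
    stringsAsFactors = FALSE
  )
  if (flank) {
    fl <- data.frame(
      biotype = rep(c("mRNA", "lncRNA"), each = 2L),
      component = rep(c("promoter", "tail"), 2L),
      offset = rep(c(-flank_frac, 1), 2L),
      width = flank_frac,
      stringsAsFactors = FALSE
    )
    lay <- rbind(fl[fl$component == "promoter", ], lay,
                 fl[fl$component == "tail", ])
  }
  rownames(lay) <- NULL
  lay
}

#' Build guitar coordinates: standardized bins projected onto the genome
#'
#' Divides every non-empty component of every transcript into `bins`
#' equal-width bins (widths differ by at most 1 nt; the remainder goes to
#' the 5'-most bins), assigns each bin a standardized axis position
#' `offset + (bin + 0.5)/B * width`, and projects its mature span back to
#' genomic intervals through the exon structure — a bin spanning an intron
#' yields several genomic pieces.  Optionally adds flanking DNA bins
#' covering `flank` nt of promoter (5' of the TSS) and downstream tail
#' (3' of the TES); flank bins are plain genomic intervals with no intron
#' logic.
#'
#' Every non-empty component must be at least `bins` nt long; apply
#' [length_filter()] first (its `bins` feasibility check guarantees this).
#'
#' @param anno a `tx_annotation` (typically already filtered).
#' @param bins bins per component (default 100).
#' @param flank flank width in nt (0 disables flanks).
#' @param flank_bins number of bins per flank (default `bins`).
#' @param layout `"equal"` or `"true_width"` axis layout.
#' @return object of class `guitar_coords`: list with `bins` (one row per
#'   bin: `key`, `tx_id`, `biotype`, `component`, `bin`, `tstart`, `tend`,
#'   `width_nt`, `std_pos`), `granges` (genomic footprints, one range per
#'   piece, metadata column `key`), `cells` (the shared standardized axis
#'   grid), `layout`, `config` and the `annotation` used.
#' @export
guitar_coords <- function(anno, bins = 100L, flank = 0L, flank_bins = bins,
                          layout = c("equal", "true_width")) {
  stopifnot(inherits(anno, "tx_annotation"), bins >= 1L, flank >= 0L)
  layout <- match.arg(layout)
  comp <- anno$components
  clen <- comp$tend - comp$tstart + 1L
  short <- clen < bins
  if (any(short))
    stop("component(s) shorter than the bin count (e.g. ",
         comp$tx_id[which(short)[1L]], " ", comp$component[which(short)[1L]],
         " = ", clen[which(short)[1L]], " nt < ", bins,
         " bins); apply length_filter() first")

  ml <- NULL
  if (layout == "true_width") {
    mr <- anno$tx$tx_id[anno$tx$biotype == "mRNA"]
    if (length(mr) == 0L) stop("true_width layout requires mRNA transcripts")
    cc <- comp[comp$tx_id %in% mr, ]
    tot <- tapply(cc$tend - cc$tstart + 1, cc$component, sum)
    ml <- setNames(rep(0, 3L), c("utr5", "cds", "utr3"))
    ml[names(tot)] <- tot / length(mr)
  }
  lay <- axis_layout(layout, ml, flank = flank > 0L)

  bin_rows <- vector("list", 0L)
  gr_rows <- vector("list", 0L)
  truncated <- FALSE
  for (i in seq_len(nrow(anno$tx))) {
    t <- anno$tx[i, ]
    ex <- anno$exon_tab[anno$exon_tab$tx_id == t$tx_id, , drop = FALSE]
    cc <- comp[comp$tx_id == t$tx_id, , drop = FALSE]
    for (j in seq_len(nrow(cc))) {
      cj <- cc[j, ]
      L <- cj$tend - cj$tstart + 1L
      w <- .split_widths(L, bins)
      ends <- cj$tstart - 1L + cumsum(w)
      starts <- ends - w + 1L
      li <- lay[lay$biotype == t$biotype & lay$component == cj$component, ]
      bin_rows[[length(bin_rows) + 1L]] <- data.frame(
        tx_id = t$tx_id, biotype = t$biotype, component = cj$component,
        bin = seq_len(bins) - 1L, tstart = starts, tend = ends,
        width_nt = w,
        std_pos = li$offset + (seq_len(bins) - 0.5) / bins * li$width,
        stringsAsFactors = FALSE)
      # genomic footprints: overlap-join exon mature spans with bin spans
      ov <- IRanges::findOverlaps(IRanges::IRanges(ex$tstart, ex$tend),
                                  IRanges::IRanges(starts, ends))
      qe <- ex[queryHits(ov), , drop = FALSE]
      os <- pmax(starts[subjectHits(ov)], qe$tstart)
      oe <- pmin(ends[subjectHits(ov)], qe$tend)
      plus <- qe$strand == "+"
      gs <- ifelse(plus, qe$gstart + (os - qe$tstart),
                   qe$gend - (oe - qe$tstart))
      ge <- ifelse(plus, qe$gstart + (oe - qe$tstart),
                   qe$gend - (os - qe$tstart))
      gr_rows[[length(gr_rows) + 1L]] <- data.frame(
        chrom = qe$chrom, gstart = as.integer(gs), gend = as.integer(ge),
        strand = qe$strand, tx_id = t$tx_id, component = cj$component,
        bin = subjectHits(ov) - 1L, stringsAsFactors = FALSE)
    }
    if (flank > 0L) {
      fb <- .flank_bins(t, ex, flank, flank_bins, lay)
      truncated <- truncated || isTRUE(attr(fb, "truncated"))
      if (!is.null(fb$bins)) {
        bin_rows[[length(bin_rows) + 1L]] <- fb$bins
        gr_rows[[length(gr_rows) + 1L]] <- fb$gr
      }
    }
  }
  if (truncated)
    warning("flank(s) truncated at the chromosome start")

  bins_df <- do.call(rbind, bin_rows)
  rownames(bins_df) <- NULL
  bins_df$key <- seq_len(nrow(bins_df))
  bins_df <- bins_df[, c("key", "tx_id", "biotype", "component", "bin",
                         "tstart", "tend", "width_nt", "std_pos")]
  grd <- do.call(rbind, gr_rows)
  grd$key <- bins_df$key[match(
    paste(grd$tx_id, grd$component, grd$bin),
    paste(bins_df$tx_id, bins_df$component, bins_df$bin))]
  gr <- GenomicRanges::GRanges(grd$chrom,
                               IRanges::IRanges(grd$gstart, grd$gend),
                               strand = grd$strand)
  mcols(gr)$key <- grd$key

  cells <- .cell_grid(lay, unique(bins_df$biotype), bins,
                      if (flank > 0L) flank_bins else NULL)
  structure(list(bins = bins_df, granges = gr, cells = cells, layout = lay,
                 config = list(bins = as.integer(bins),
                               flank = as.integer(flank),
                               flank_bins = as.integer(flank_bins),
                               layout = layout),
                 annotation = anno),
            class = "guitar_coords")
}

# promoter/tail bins for one transcript; pure genomic intervals
.flank_bins <- function(t, ex, flank, flank_bins, lay) {
  g_lo <- min(ex$gstart)
  g_hi <- max(ex$gend)
  plus <- t$strand == "+"
  out_b <- list(); out_g <- list()
  truncated <- FALSE
  for (comp in c("promoter", "tail")) {
    upstream <- (comp == "promoter")
    # genomic side of this flank: left of the footprint on + for promoter,
    # right for tail; mirrored on -
    left_side <- xor(!plus, upstream)
    if (left_side) {
      lo <- g_lo - flank; hi <- g_lo - 1L
      if (lo < 1L) { lo <- 1L; truncated <- TRUE }
      if (hi < lo) next
    } else {
      lo <- g_hi + 1L; hi <- g_hi + flank
    }
    Tw <- hi - lo + 1L
    w <- .split_widths(Tw, flank_bins)
    keep <- w > 0L
    w <- w[keep]
    nb <- length(w)
    if (nb == 0L) next
    # bin 0 is the 5'-most on the axis: farthest from the TSS for the
    # promoter, nearest to the TES for the tail; genomic bin order follows
    # the transcript's reading direction
    if (plus) {
      ends <- lo - 1L + cumsum(w); starts <- ends - w + 1L
    } else {
      starts <- hi + 1L - cumsum(w); ends <- starts + w - 1L
    }
    li <- lay[lay$biotype == t$biotype & lay$component == comp, ]
    bin_idx <- seq_len(nb) - 1L
    out_b[[comp]] <- data.frame(
      tx_id = t$tx_id, biotype = t$biotype, component = comp,
      bin = bin_idx, tstart = NA_integer_, tend = NA_integer_,
      width_nt = w,
      std_pos = li$offset + (bin_idx + 0.5) / flank_bins * li$width,
      stringsAsFactors = FALSE)
    out_g[[comp]] <- data.frame(
      chrom = t$chrom, gstart = as.integer(starts), gend = as.integer(ends),
      strand = t$strand, tx_id = t$tx_id, component = comp, bin = bin_idx,
      stringsAsFactors = FALSE)
  }
  res <- list(bins = if (length(out_b)) do.call(rbind, out_b) else NULL,
              gr = if (length(out_g)) do.call(rbind, out_g) else NULL)
  attr(res, "truncated") <- truncated
  res
}

# the shared standardized grid: one cell per (biotype, component, bin)
.cell_grid <- function(lay, biotypes, bins, flank_bins) {
  rows <- list()
  for (bt in biotypes) {
    lb <- lay[lay$biotype == bt, , drop = FALSE]
    for (j in seq_len(nrow(lb))) {
      isfl <- lb$component[j] %in% c("promoter", "tail")
      if (isfl && is.null(flank_bins)) next
      B <- if (isfl) flank_bins else bins
      idx <- seq_len(B) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        biotype = bt, component = lb$component[j], bin = idx,
        std_pos = lb$offset[j] + (idx + 0.5) / B * lb$width[j],
        cell_width = lb$width[j] / B,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  d <- d[order(d$biotype, d$std_pos), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @export
print.guitar_coords <- function(x, ...) {
  cat("guitar_coords:", nrow(x$bins), "bins over",
      length(unique(x$bins$tx_id)), "transcripts;",
      x$config$bins, "bins/component,",
      if (x$config$flank > 0) paste0(x$config$flank, " nt flanks, ") else "",
      x$config$layout, "layout\n")
  invisible(x)
}

#' Export guitar coordinates as a BED-like TSV
#'
#' One row per genomic footprint piece: `chrom`, `start` (0-based),
#' `end`, `name` (`tx_id|component|bin`), `score` (standardized axis
#' position) and `strand` — the low-level transcript-to-genome conversion
#' table, usable by external tools.
#'
#' @param gc a `guitar_coords` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guitar_coords <- function(gc, path) {
  stopifnot(inherits(gc, "guitar_coords"))
  b <- gc$bins[match(mcols(gc$granges)$key, gc$bins$key), ]
  d <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gc$granges)),
    start = GenomicRanges::start(gc$granges) - 1L,
    end = GenomicRanges::end(gc$granges),
    name = paste(b$tx_id, b$component, b$bin, sep = "|"),
    score = b$std_pos,
    strand = as.character(GenomicRanges::strand(gc$granges)),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
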