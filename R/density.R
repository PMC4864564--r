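# normalize weights to a density integrating to 1 over the displayed axis,
# per (group, biotype); all-zero groups stay zero (with a warning upstream)
.normalize_cells <- function(grid) {
  grid$density <- 0
  for (g in unique(grid$group)) for (bt in unique(grid$biotype)) {
    i <- grid$group == g & grid$biotype == bt
    if (!any(i)) next
    M <- sum(grid$weight[i])
    if (M > 0)
      grid$density[i] <- grid$weight[i] / (M * grid$cell_width[i])
  }
  grid
}

# mass-conserving Gaussian smoothing on the standardized axis with
# reflection at both axis ends; operates on one group x biotype vector
.smooth_mass <- function(x, width, m, bandwidth, lo, hi) {
  if (bandwidth <= 0 || length(x) < 2L) return(m)
  K <- function(d) exp(-0.5 * (d / bandwidth)^2)
  k <- K(outer(x, x, "-")) +
    K(outer(x, 2 * lo - x, "-")) +
    K(outer(x, 2 * hi - x, "-"))
  k <- k * width               # rows scaled by destination cell width
  k <- sweep(k, 2L, colSums(k), "/")   # each source's mass fully reallocated
  as.numeric(k %*% m)
}

#' Smooth a metagene profile
#'
#' Gaussian-kernel smoothing of the binned weights on the standardized
#' axis, with reflection at the axis ends so that the integral of the
#' density is preserved (to well within 1e-9).  Smoothing is
#' presentation-only: the unsmoothed weights and density are kept.
#'
#' @param x a `metagene` object.
#' @param bandwidth kernel standard deviation in axis units; 0 disables
#'   smoothing (the smoothed density equals the raw density).
#' @return the `metagene` object with updated `density_smooth`.
#' @export
smooth_profile <- function(x, bandwidth = 0.02) {
  stopifnot(inherits(x, "metagene"), bandwidth >= 0)
  p <- x$profile
  p$density_smooth <- p$density
  if (bandwidth > 0) {
    for (g in unique(p$group)) for (bt in unique(p$biotype)) {
      i <- which(p$group == g & p$biotype == bt)
      if (length(i) < 2L) next
      o <- i[order(p$std_pos[i])]
      lo <- min(p$std_pos[o] - p$cell_width[o] / 2)
      hi <- max(p$std_pos[o] + p$cell_width[o] / 2)
      m <- .smooth_mass(p$std_pos[o], p$cell_width[o], p$weight[o],
                        bandwidth, lo, hi)
      M <- sum(m)
      p$density_smooth[o] <- if (M > 0) m / (M * p$cell_width[o]) else 0
    }
  }
  x$profile <- p
  x$config$bandwidth <- bandwidth
  x
}

#' Metagene profile of genomic features on standardized transcript coordinates
#'
#' The end-to-end pipeline: parse the annotation, derive components, apply
#' the length and isoform-ambiguity filters, build guitar coordinates,
#' overlap the feature sets with the bins under 1/n ambiguity weighting,
#' and summarize the weights as a normalized density on the standardized
#' axis, separately per feature group and per biotype (mRNA / lncRNA).
#'
#' @param annotation a `tx_annotation` or the path of a GTF file.
#' @param features a GRanges, a BED file path, or a (preferably named) list
#'   of either; list names become group labels.
#' @param bins bins per component (default 100).
#' @param layout `"equal"` (each mRNA component spans 1/3 of the axis) or
#'   `"true_width"` (axis widths proportional to mean component lengths).
#' @param flank flanking DNA width in nt (0 = no flanks); when enabled,
#'   promoter and downstream-tail bins extend the axis and are included in
#'   the normalization domain.
#' @param flank_bins bins per flank (default `bins`).
#' @param min_component_length,min_lncrna_length length-filter thresholds
#'   (nt).
#' @param max_tx_overlap isoform-ambiguity threshold: transcripts
#'   overlapping more than this many others are dropped (default 3).
#' @param max_feature_tx feature-ambiguity threshold: features overlapping
#'   more than this many retained transcripts are dropped (default 5);
#'   `Inf` disables the filter.
#' @param ignore_strand overlap transcripts/features regardless of strand?
#' @param bandwidth smoothing bandwidth in axis units (0 disables).
#' @param keep_records keep the per-record overlap table in the result?
#' @param verbose log per-stage counts via [message()]?
#' @return object of class `metagene` with elements `profile` (the per-cell
#'   table: group, biotype, component, bin, std_pos, cell_width, weight,
#'   density, density_smooth), `layout`, `counts`, `config`,
#'   `filter_report`, `coords` and optionally `records`.
#' @examples
#' anno <- simulate_annotation(n_genes = 12, seed = 1)
#' sites <- simulate_features(anno, n = 500, law = "triangle", seed = 2)
#' mg <- metagene(anno, sites, min_component_length = 10, verbose = FALSE)
#' summary(mg)
#' @export
metagene <- function(annotation, features, bins = 100L,
                     layout = c("equal", "true_width"),
                     flank = 0L, flank_bins = bins,
                     min_component_length = 100L, min_lncrna_length = 300L,
                     max_tx_overlap = 3L, max_feature_tx = 5L,
                     ignore_strand = FALSE, bandwidth = 0.02,
                     keep_records = FALSE, verbose = TRUE) {
  layout <- match.arg(layout)
  say <- function(...) if (verbose) message(...)

  anno <- if (is.character(annotation)) read_annotation(annotation)
  else annotation
  stopifnot(inherits(anno, "tx_annotation"))
  say("annotation: ", nrow(anno$tx), " transcripts parsed")

  fanno <- filter_transcripts(anno,
                              min_component_length = min_component_length,
                              min_lncrna_length = min_lncrna_length,
                              bins = bins, max_tx_overlap = max_tx_overlap,
                              ignore_strand = ignore_strand)
  say("filters: ", nrow(fanno$tx), " transcripts retained (",
      sum(fanno$tx$biotype == "mRNA"), " mRNA, ",
      sum(fanno$tx$biotype == "lncRNA"), " lncRNA)")
  if (nrow(fanno$tx) == 0L)
    stop("no transcripts retained after filtering")

  gc <- guitar_coords(fanno, bins = bins, flank = flank,
                      flank_bins = flank_bins, layout = layout)
  say("coordinates: ", nrow(gc$bins), " bins built")

  # normalize the features argument to a named list of GRanges
  if (inherits(features, "GRanges") || is.character(features) &&
      length(features) == 1L)
    features <- list(features = features)
  if (is.character(features)) features <- as.list(features)
  if (is.null(names(features)))
    names(features) <- paste0("group", seq_along(features))
  noname <- !nzchar(names(features))
  names(features)[noname] <- paste0("group", seq_along(features))[noname]
  feats <- lapply(names(features), function(g) {
    f <- features[[g]]
    gr <- if (is.character(f)) read_features(f) else f
    mcols(gr)$group <- rep(g, length(gr))
    gr
  })

  rec_list <- lapply(feats, function(gr) {
    g <- if (length(gr)) mcols(gr)$group[1L] else "features"
    n_in <- length(gr)
    if (is.finite(max_feature_tx))
      gr <- filter_features(gr, fanno, max_feature_tx = max_feature_tx,
                            ignore_strand = ignore_strand)
    say("features [", g, "]: ", n_in, " read, ", length(gr), " retained")
    r <- assign_features(gr, gc, ignore_strand = ignore_strand)
    if (nrow(r) && is.null(r$group)) r$group <- g
    say("features [", g, "]: ", length(unique(r$feature_id)),
        " assigned to bins")
    r
  })
  records <- do.call(rbind, rec_list)
  if (is.null(records) || nrow(records) == 0L) {
    warning("no feature overlaps any retained transcript; profile is zero")
    records <- data.frame(feature_id = character(0L), tx_id = character(0L),
                          biotype = character(0L), component = character(0L),
                          bin = integer(0L), std_pos = numeric(0L),
                          n = integer(0L), weight = numeric(0L),
                          group = character(0L), stringsAsFactors = FALSE)
  }

  grid <- bin_weights(records, gc)
  if (nrow(records) == 0L && length(feats))
    grid <- do.call(rbind, lapply(names(features), function(g) {
      d <- gc$cells; d <- cbind(group = g, d); d$weight <- 0; d
    }))
  grid <- .normalize_cells(grid)

  out <- structure(list(
    profile = grid,
    layout = gc$layout,
    counts = list(
      transcripts_parsed = nrow(anno$tx),
      transcripts_retained = nrow(fanno$tx),
      features_read = sum(vapply(feats, length, 0L)),
      features_assigned = length(unique(records$feature_id)),
      records = nrow(records)),
    config = list(bins = as.integer(bins), layout = layout,
                  flank = as.integer(flank),
                  flank_bins = as.integer(flank_bins),
                  min_component_length = min_component_length,
                  min_lncrna_length = min_lncrna_length,
                  max_tx_overlap = max_tx_overlap,
                  max_feature_tx = max_feature_tx,
                  ignore_strand = ignore_strand,
                  bandwidth = bandwidth),
    filter_report = attr(fanno, "filter_report"),
    coords = gc,
    records = if (keep_records) records else NULL
  ), class = "metagene")
  smooth_profile(out, bandwidth)
}

#' @export
print.metagene <- function(x, ...) {
  cat("metagene profile:",
      length(unique(x$profile$group)), "group(s) x",
      length(unique(x$profile$biotype)), "biotype(s);",
      x$config$bins, "bins/component,", x$config$layout, "layout")
  if (x$config$flank > 0) cat(",", x$config$flank, "nt flanks")
  cat("\n  transcripts retained:", x$counts$transcripts_retained,
      "/", x$counts$transcripts_parsed,
      "; features assigned:", x$counts$features_assigned, "\n")
  invisible(x)
}

#' @export
summary.metagene <- function(object, ...) {
  p <- object$profile
  s <- do.call(rbind, lapply(split(p, paste(p$group, p$biotype)), function(d) {
    data.frame(group = d$group[1L], biotype = d$biotype[1L],
               total_weight = sum(d$weight),
               integral = sum(d$density * d$cell_width),
               mode_std_pos = d$std_pos[which.max(d$density)],
               stringsAsFactors = FALSE)
  }))
  rownames(s) <- NULL
  cat("metagene profile summary\n")
  print(s, row.names = FALSE)
  invisible(s)
}

#' @export
as.data.frame.metagene <- function(x, ...) x$profile

#' Plot a metagene profile
#'
#' One panel per biotype, one curve per feature group, with vertical
#' landmark markers: TSS, start codon, stop codon and TES for mRNA; TSS
#' and TES for lncRNA.  Flanks, when present, extend the x-axis beyond the
#' TSS/TES; in `true_width` layout the component spans reflect their mean
#' true widths.
#'
#' @param x a `metagene` object.
#' @param smoothed plot the smoothed density (default) or the raw one?
#' @param col optional vector of curve colors (one per group).
#' @param lwd line width.
#' @param legend.pos position keyword for the group legend, or `NA` for
#'   none.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.metagene <- function(x, smoothed = TRUE, col = NULL, lwd = 2,
                          legend.pos = "topright", ...) {
  p <- x$profile
  if (nrow(p) == 0L) stop("empty profile")
  groups <- unique(p$group)
  biotypes <- intersect(c("mRNA", "lncRNA"), unique(p$biotype))
  if (is.null(col)) col <- grDevices::hcl.colors(max(2L, length(groups)),
                                                 "Dark 2")[seq_along(groups)]
  ycol <- if (smoothed) "density_smooth" else "density"
  op <- par(mfrow = c(1L, length(biotypes)), mar = c(6, 4, 3, 1))
  on.exit(par(op))
  for (bt in biotypes) {
    d <- p[p$biotype == bt, ]
    lay <- x$layout[x$layout$biotype == bt, ]
    ymax <- max(d[[ycol]], 1e-9)
    plot(NA, xlim = range(lay$offset, lay$offset + lay$width),
         ylim = c(0, ymax * 1.05), xlab = "", ylab = "density",
         main = bt, xaxt = "n", ...)
    marks <- sort(unique(c(lay$offset, lay$offset + lay$width)))
    abline(v = marks, col = "grey70", lty = 3)
    inner <- sort(unique(c(0, lay$offset[!lay$component %in%
                                           c("promoter", "tail")] +
                             lay$width[!lay$component %in%
                                         c("promoter", "tail")])))
    lab <- if (bt == "mRNA") {
      stats::setNames(inner, c("TSS", "start codon", "stop codon",
                               "TES")[seq_along(inner)])
    } else stats::setNames(inner, c("TSS", "TES"))
    axis(1, at = unname(lab), labels = names(lab), las = 2, cex.axis = 0.8)
    for (k in seq_along(groups)) {
      dg <- d[d$group == groups[k], ]
      dg <- dg[order(dg$std_pos), ]
      lines(dg$std_pos, dg[[ycol]], col = col[k], lwd = lwd)
    }
    if (bt == biotypes[1L] && !is.na(legend.pos) && length(groups) > 1L)
      legend(legend.pos, legend = groups, col = col, lwd = lwd, bty = "n",
             cex = 0.8)
  }
  invisible(x)
}

#' Export a metagene analysis to files
#'
#' Writes the per-cell profile TSV (`group`, `biotype`, `component`,
#' `bin`, `std_pos`, `weight`, `density`, `density_smooth` — the
#' intermediate-results hook for external plotting), the transcript filter
#' report TSV, the overlap records TSV when kept, and the figure.
#'
#' @param x a `metagene` object.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @param figure `"pdf"`, `"png"` or `"none"`.
#' @return character vector of the paths written, invisibly.
#' @export
export_metagene <- function(x, dir, prefix = "metagene",
                            figure = c("pdf", "png", "none")) {
  stopifnot(inherits(x, "metagene"))
  figure <- match.arg(figure)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  f <- file.path(dir, paste0(prefix, "_profile.tsv"))
  utils::write.table(x$profile, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, f)
  if (!is.null(x$filter_report)) {
    f <- file.path(dir, paste0(prefix, "_filter_report.tsv"))
    utils::write.table(x$filter_report, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(x$records)) {
    f <- file.path(dir, paste0(prefix, "_records.tsv"))
    utils::write.table(x$records, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
  }
  if (figure != "none") {
    f <- file.path(dir, paste0(prefix, "_profile.", figure))
    if (figure == "pdf") grDevices::pdf(f, width = 9, height = 4.5)
    else grDevices::png(f, width = 1200, height = 600, res = 120)
    plot(x)
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  invisible(paths)
}
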