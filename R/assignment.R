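#' Read genomic features from a BED file
#'
#' Reads BED3/BED6 intervals via `rtracklayer` (0-based half-open in the
#' file, 1-based closed GRanges in memory).  Features without a strand
#' column get strand `*` and match transcripts on both strands under the
#' same-strand overlap policy.
#'
#' @param path BED file path; an empty file yields an empty GRanges.
#' @param group optional group label stored in metadata column `group`.
#' @return GRanges (metadata: `name`/`score` if present, `group` if given).
#' @export
read_features <- function(path, group = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  gr <- if (length(lines) == 0L) GenomicRanges::GRanges()
  else rtracklayer::import(path, format = "bed")
  if (!is.null(group)) mcols(gr)$group <- rep(group, length(gr))
  gr
}

#' Transcripts overlapped by each feature
#'
#' A transcript is overlapped when at least one nucleotide of the feature
#' lies in its exonic footprint (or, when `flank_footprint` is supplied,
#' its flanking DNA).  The number of overlapped transcripts is the `n` of
#' the 1/n weight allocation.
#'
#' @param features GRanges.
#' @param anno a (filtered) `tx_annotation`.
#' @param ignore_strand overlap regardless of strand?
#' @param flank_footprint optional GRanges of flank regions with metadata
#'   column `tx_id` (used internally when flanks are enabled).
#' @return list (one element per feature) of overlapped `tx_id`s; its
#'   `lengths()` is the per-feature n.
#' @export
overlapping_transcripts <- function(features, anno, ignore_strand = FALSE,
                                    flank_footprint = NULL) {
  stopifnot(inherits(features, "GRanges"), inherits(anno, "tx_annotation"))
  h <- GenomicRanges::findOverlaps(features, anno$exons,
                                   ignore.strand = ignore_strand)
  pairs <- data.frame(f = queryHits(h),
                      tx = names(anno$exons)[subjectHits(h)],
                      stringsAsFactors = FALSE)
  if (!is.null(flank_footprint) && length(flank_footprint)) {
    h2 <- GenomicRanges::findOverlaps(features, flank_footprint,
                                      ignore.strand = ignore_strand)
    pairs <- rbind(pairs, data.frame(
      f = queryHits(h2),
      tx = mcols(flank_footprint)$tx_id[subjectHits(h2)],
      stringsAsFactors = FALSE))
  }
  pairs <- unique(pairs)
  out <- rep(list(character(0L)), length(features))
  if (nrow(pairs)) {
    sp <- split(pairs$tx, pairs$f)
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Overlap features with guitar bins and allocate 1/n weights
#'
#' For each feature overlapping n >= 1 retained transcripts, every guitar
#' bin whose genomic footprint intersects the feature by at least one
#' nucleotide yields one record with weight 1/n: a feature fully contained
#' in a single transcript carries weight 1; a feature shared by n isoforms
#' divides its weight equally among them.  A feature spanning two
#' components of one transcript contributes records in both.  When flanks
#' are enabled, flank bins participate identically and n counts overlap
#' with the exonic-or-flank footprint.
#'
#' @param features GRanges (optionally with metadata columns `name`,
#'   `group`).
#' @param gc a `guitar_coords` object.
#' @param ignore_strand overlap regardless of strand?  (Features with
#'   strand `*` always match both strands.)
#' @return data.frame of overlap records: `feature_id`, `group` (if
#'   present), `tx_id`, `biotype`, `component`, `bin`, `std_pos`, `n`,
#'   `weight`.
#' @export
assign_features <- function(features, gc, ignore_strand = FALSE) {
  stopifnot(inherits(features, "GRanges"), inherits(gc, "guitar_coords"))
  empty <- data.frame(feature_id = character(0L), tx_id = character(0L),
                      biotype = character(0L), component = character(0L),
                      bin = integer(0L), std_pos = numeric(0L),
                      n = integer(0L), weight = numeric(0L),
                      stringsAsFactors = FALSE)
  if (length(features) == 0L) return(empty)

  fid <- if (!is.null(names(features)) && all(nzchar(names(features))))
    names(features) else as.character(seq_along(features))

  flank_fp <- NULL
  if (gc$config$flank > 0L) {
    fl <- gc$bins$component[match(mcols(gc$granges)$key, gc$bins$key)] %in%
      c("promoter", "tail")
    flank_fp <- gc$granges[fl]
    mcols(flank_fp)$tx_id <-
      gc$bins$tx_id[match(mcols(flank_fp)$key, gc$bins$key)]
  }
  txs <- overlapping_transcripts(features, gc$annotation,
                                 ignore_strand = ignore_strand,
                                 flank_footprint = flank_fp)
  n <- lengths(txs)

  h <- GenomicRanges::findOverlaps(features, gc$granges,
                                   ignore.strand = ignore_strand)
  if (length(h) == 0L) return(empty)
  keys <- mcols(gc$granges)$key[subjectHits(h)]
  pairs <- unique(data.frame(f = queryHits(h), key = keys))
  b <- gc$bins[match(pairs$key, gc$bins$key), ]
  rec <- data.frame(feature_id = fid[pairs$f],
                    tx_id = b$tx_id, biotype = b$biotype,
                    component = b$component, bin = b$bin,
                    std_pos = b$std_pos,
                    n = as.integer(n[pairs$f]),
                    weight = 1 / n[pairs$f],
                    stringsAsFactors = FALSE)
  if (!is.null(mcols(features)$group))
    rec <- cbind(rec, group = mcols(features)$group[pairs$f])
  rec <- rec[rec$n >= 1L, , drop = FALSE]
  rec <- rec[order(match(rec$feature_id, fid), rec$std_pos), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Sum overlap-record weights on the standardized axis grid
#'
#' Aggregates record weights per standardized axis cell (biotype,
#' component, bin index), summing across transcripts, separately per group
#' (mRNA and lncRNA are never cross-normalized).  Cells with no hits get
#' weight 0, so every group covers the full displayed axis.
#'
#' @param records overlap records from [assign_features()].
#' @param gc the `guitar_coords` the records were computed on.
#' @return data.frame: `group`, `biotype`, `component`, `bin`, `std_pos`,
#'   `cell_width`, `weight`.
#' @export
bin_weights <- function(records, gc) {
  stopifnot(inherits(gc, "guitar_coords"))
  cells <- gc$cells
  groups <- if (!is.null(records$group) && nrow(records))
    unique(as.character(records$group)) else "features"
  if (is.null(records$group)) records$group <- "features"
  grid <- do.call(rbind, lapply(groups, function(g)
    cbind(group = g, cells, stringsAsFactors = FALSE)))
  if (nrow(records)) {
    agg <- stats::aggregate(weight ~ group + biotype + component + bin,
                            data = records, FUN = sum)
    key_g <- paste(grid$group, grid$biotype, grid$component, grid$bin)
    key_a <- paste(agg$group, agg$biotype, agg$component, agg$bin)
    grid$weight <- agg$weight[match(key_g, key_a)]
    grid$weight[is.na(grid$weight)] <- 0
  } else {
    grid$weight <- 0
  }
  grid <- grid[order(grid$group, grid$biotype, grid$std_pos), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}
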