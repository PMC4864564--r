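#' Transcript length filter
#'
#' Retains an mRNA only if every one of its non-empty components (5'UTR,
#' CDS, 3'UTR) is at least `min_component_length` nt, and a lncRNA only if
#' its mature length is at least `min_lncrna_length` nt.  Independently of
#' the user thresholds, each non-empty component must be at least `bins` nt
#' so that it can support `bins` bins (bin feasibility).  The appropriate
#' user threshold depends on the resolution of the assay: ~10 nt for
#' single-base techniques, ~100 nt for peak-level data.
#'
#' @param anno a `tx_annotation`.
#' @param min_component_length per-component minimum for mRNA (nt).
#' @param min_lncrna_length mature-length minimum for lncRNA (nt).
#' @param bins bins per component that the coordinates will use.
#' @return the filtered `tx_annotation`, with a data.frame attribute
#'   `"filter_report"` (tx_id, retained flag, reason).
#' @export
length_filter <- function(anno, min_component_length = 100L,
                          min_lncrna_length = 300L, bins = 100L) {
  stopifnot(inherits(anno, "tx_annotation"))
  comp <- anno$components
  clen <- comp$tend - comp$tstart + 1L
  keep <- logical(nrow(anno$tx))
  reason <- character(nrow(anno$tx))
  for (i in seq_len(nrow(anno$tx))) {
    t <- anno$tx[i, ]
    li <- clen[comp$tx_id == t$tx_id]
    thr <- if (t$biotype == "mRNA")
      max(min_component_length, bins) else max(min_lncrna_length, bins)
    keep[i] <- all(li >= thr)
    if (!keep[i]) reason[i] <- "length"
  }
  rep_df <- data.frame(tx_id = anno$tx$tx_id, retained = keep,
                       reason = reason, stringsAsFactors = FALSE)
  out <- anno[anno$tx$tx_id[keep]]
  attr(out, "filter_report") <- rep_df
  out
}

#' Count exon-sharing transcripts
#'
#' For every transcript, the number of *other* transcripts whose exonic
#' footprint shares at least one nucleotide with its own on the same
#' chromosome.  By default overlap requires the same strand (antisense
#' transcripts are distinct RNAs); set `ignore_strand = TRUE` to count
#' across strands.
#'
#' @param anno a `tx_annotation`.
#' @param ignore_strand count overlaps regardless of strand?
#' @return named integer vector (tx_id -> count).
#' @export
count_exonic_overlaps <- function(anno, ignore_strand = FALSE) {
  stopifnot(inherits(anno, "tx_annotation"))
  h <- GenomicRanges::findOverlaps(anno$exons, anno$exons,
                                   ignore.strand = ignore_strand)
  h <- h[queryHits(h) != subjectHits(h)]
  setNames(tabulate(queryHits(h), nbins = length(anno$exons)),
           names(anno$exons))
}

#' Isoform-ambiguity filter
#'
#' Removes transcripts whose exonic footprint overlaps more than
#' `max_overlap` other transcripts (default 3).  Counts are computed once
#' on the annotation as given — removal of one transcript never changes
#' another's count (a single pass, order-independent).
#'
#' @inheritParams count_exonic_overlaps
#' @param max_overlap maximum tolerated number of overlapping transcripts.
#' @return the filtered `tx_annotation` with a `"filter_report"` attribute
#'   including the overlap counts.
#' @export
ambiguity_filter <- function(anno, max_overlap = 3L, ignore_strand = FALSE) {
  stopifnot(inherits(anno, "tx_annotation"))
  cnt <- count_exonic_overlaps(anno, ignore_strand = ignore_strand)
  keep <- cnt <= max_overlap
  rep_df <- data.frame(tx_id = anno$tx$tx_id,
                       overlap_count = as.integer(cnt[anno$tx$tx_id]),
                       retained = unname(keep[anno$tx$tx_id]),
                       reason = ifelse(keep[anno$tx$tx_id], "", "ambiguity"),
                       stringsAsFactors = FALSE)
  out <- anno[names(cnt)[keep]]
  attr(out, "filter_report") <- rep_df
  out
}

#' Full transcript filter pipeline
#'
#' Applies the length filter then the isoform-ambiguity filter, as a fixed
#' order.  By default overlap counts are computed on the post-length-filter
#' set; set `count_before_length_filter = TRUE` to count on the raw input.
#'
#' @inheritParams length_filter
#' @inheritParams ambiguity_filter
#' @param max_tx_overlap maximum tolerated transcript overlap count.
#' @param count_before_length_filter compute overlap counts before the
#'   length filter?
#' @return filtered `tx_annotation`; attribute `"filter_report"` has one
#'   row per input transcript with component lengths, overlap count,
#'   retained flag and removal reason.
#' @export
filter_transcripts <- function(anno, min_component_length = 100L,
                               min_lncrna_length = 300L, bins = 100L,
                               max_tx_overlap = 3L, ignore_strand = FALSE,
                               count_before_length_filter = FALSE) {
  stopifnot(inherits(anno, "tx_annotation"))
  a1 <- length_filter(anno, min_component_length, min_lncrna_length, bins)
  r1 <- attr(a1, "filter_report")
  cnt_base <- if (count_before_length_filter) anno else a1
  cnt <- count_exonic_overlaps(cnt_base, ignore_strand = ignore_strand)
  keep2 <- names(cnt)[cnt <= max_tx_overlap]
  out <- a1[intersect(a1$tx$tx_id, keep2)]

  comp <- anno$components
  clen <- comp$tend - comp$tstart + 1L
  getlen <- function(id, cp) {
    v <- clen[comp$tx_id == id & comp$component == cp]
    if (length(v)) v else 0L
  }
  rep_df <- data.frame(
    tx_id = anno$tx$tx_id,
    biotype = anno$tx$biotype,
    mature_length = anno$tx$mature_length,
    utr5_len = vapply(anno$tx$tx_id, getlen, 0L, "utr5"),
    cds_len = vapply(anno$tx$tx_id, getlen, 0L, "cds"),
    utr3_len = vapply(anno$tx$tx_id, getlen, 0L, "utr3"),
    overlap_count = as.integer(cnt[anno$tx$tx_id]),
    retained = anno$tx$tx_id %in% out$tx$tx_id,
    stringsAsFactors = FALSE, row.names = NULL
  )
  rep_df$reason <- ifelse(rep_df$retained, "",
                          ifelse(!r1$retained[match(rep_df$tx_id, r1$tx_id)],
                                 "length", "ambiguity"))
  attr(out, "filter_report") <- rep_df
  out
}

#' Feature-ambiguity filter
#'
#' Removes genomic features overlapping (by at least one exonic
#' nucleotide, same strand policy as the transcript filters) more than
#' `max_feature_tx` retained transcripts (default 5).  Features that
#' overlap no transcript are kept — they simply contribute nothing
#' downstream.
#'
#' @param features GRanges of features (e.g. from [read_features()]).
#' @param anno the filtered `tx_annotation`.
#' @param max_feature_tx maximum tolerated number of overlapped transcripts.
#' @param ignore_strand overlap regardless of strand?
#' @return the retained subset of `features`.
#' @export
filter_features <- function(features, anno, max_feature_tx = 5L,
                            ignore_strand = FALSE) {
  stopifnot(inherits(features, "GRanges"), inherits(anno, "tx_annotation"))
  if (length(features) == 0L) return(features)
  n <- GenomicRanges::countOverlaps(features, anno$exons,
                                    ignore.strand = ignore_strand)
  features[n <= max_feature_tx]
}

#' Write the transcript filter report as TSV
#' @param anno a filtered `tx_annotation` carrying a `"filter_report"`
#'   attribute (from [filter_transcripts()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(anno, path) {
  rep_df <- attr(anno, "filter_report")
  if (is.null(rep_df)) stop("annotation carries no filter report")
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
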