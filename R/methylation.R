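#' Read a per-cytosine bisulfite call table
#'
#' Five tab-separated columns: chromosome, position (1-based), strand,
#' methylated read count, unmethylated read count — the layout of common
#' bisulfite cytosine reports after column selection.
#'
#' @param path TSV path (no header by default).
#' @param header does the file carry a header line?
#' @return data.frame with columns `chrom`, `pos`, `strand`, `m`, `u` and
#'   a derived `coverage` (= m + u).
#' @export
read_cytosine_report <- function(path, header = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos", "strand", "m", "u"))
  if (any(d$m < 0 | d$u < 0)) stop("negative read counts")
  d$coverage <- d$m + d$u
  d
}

#' Coverage filter for cytosine records
#'
#' Keeps records with at least `min_reads` aligned reads (m + u), the
#' usual call-reliability cutoff (default 5), preserving input order.
#'
#' @param records data.frame with columns `m` and `u`.
#' @param min_reads minimum total read count (>= 1).
#' @return the retained subset.
#' @export
coverage_filter <- function(records, min_reads = 5L) {
  stopifnot(min_reads >= 1L)
  records[(records$m + records$u) >= min_reads, , drop = FALSE]
}

#' Average methylation rate of a call set
#'
#' The pooled-read estimator: total methylated reads over total reads
#' (sum(m) / sum(m + u)) — the "average over the entire transcriptome".
#' `method = "mean"` instead averages the per-site fractions m/(m+u).
#'
#' @param records data.frame with columns `m` and `u`.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return the average methylation probability in `[0, 1]`.
#' @export
global_methylation_rate <- function(records, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (nrow(records) == 0L) stop("no records")
  if (method == "pooled") sum(records$m) / sum(records$m + records$u)
  else mean(records$m / (records$m + records$u))
}

#' Classify cytosines by binomial test against the average rate
#'
#' Each covered cytosine is tested with two one-sided exact binomial tests
#' against the global average methylation probability: it is labeled
#' `high` when P(X >= m | n = coverage, p) < alpha, `low` when
#' P(X <= m | n, p) < alpha, and `undetermined` otherwise (inclusive
#' tails; no multiple-testing correction, per-site raw alpha).
#'
#' @param records cytosine data.frame (`chrom`, `pos`, `strand`, `m`, `u`),
#'   e.g. from [read_cytosine_report()].
#' @param alpha per-direction significance level (default 0.05).
#' @param min_reads coverage filter applied first (default 5).
#' @param p_global average methylation probability; estimated from the
#'   coverage-filtered records when `NULL`.
#' @param rate_method estimator passed to [global_methylation_rate()].
#' @return object of class `cytosine_classes`: the filtered records with a
#'   `label` column plus attributes `p_global`, `alpha` and `counts`
#'   (labels partition the records: counts sum to the filtered size).
#' @export
classify_cytosines <- function(records, alpha = 0.05, min_reads = 5L,
                               p_global = NULL,
                               rate_method = c("pooled", "mean")) {
  stopifnot(alpha > 0, alpha < 1)
  d <- coverage_filter(records, min_reads)
  if (nrow(d) == 0L) stop("no records pass the coverage filter")
  if (is.null(p_global))
    p_global <- global_methylation_rate(d, match.arg(rate_method))
  if (p_global <= 0 || p_global >= 1)
    stop("degenerate average methylation rate (", p_global,
         "); the binomial model needs 0 < p < 1")
  cov <- d$m + d$u
  upper <- stats::pbinom(d$m - 1L, cov, p_global, lower.tail = FALSE)
  lower <- stats::pbinom(d$m, cov, p_global)
  d$label <- ifelse(upper < alpha, "high",
                    ifelse(lower < alpha, "low", "undetermined"))
  structure(d, class = c("cytosine_classes", "data.frame"),
            p_global = p_global, alpha = alpha,
            counts = c(high = sum(d$label == "high"),
                       low = sum(d$label == "low"),
                       undetermined = sum(d$label == "undetermined")))
}

#' @export
print.cytosine_classes <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("cytosine classification:", nrow(x), "sites; p_global =",
      signif(attr(x, "p_global"), 4), "; alpha =", attr(x, "alpha"), "\n")
  cat("  high:", cnt["high"], " low:", cnt["low"],
      " undetermined:", cnt["undetermined"], "\n")
  invisible(x)
}

#' Write methylation groups as BED files plus a JSON summary
#'
#' One BED6 file per label (`high`, `low`, `undetermined`) of single-
#' nucleotide intervals (name = label, score = per-mille methylation
#' level), directly usable as feature input of [metagene()], plus a JSON
#' summary with the counts, the average rate and alpha.
#'
#' @param x a `cytosine_classes` object.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return named character vector of paths, invisibly.
#' @export
write_methylation_groups <- function(x, dir, prefix = "m5c") {
  stopifnot(inherits(x, "cytosine_classes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  for (lab in c("high", "low", "undetermined")) {
    d <- x[x$label == lab, , drop = FALSE]
    gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos),
                                 strand = d$strand)
    mcols(gr)$name <- rep(lab, nrow(d))
    mcols(gr)$score <- round(1000 * d$m / pmax(1L, d$m + d$u))
    f <- file.path(dir, paste0(prefix, "_", lab, ".bed"))
    rtracklayer::export(gr, f, format = "bed")
    paths[lab] <- f
  }
  f <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(n = nrow(x),
                            counts = as.list(attr(x, "counts")),
                            p_global = attr(x, "p_global"),
                            alpha = attr(x, "alpha")),
                       f, auto_unbox = TRUE, digits = NA)
  paths["summary"] <- f
  invisible(paths)
}
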