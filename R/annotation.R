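#' Build a transcript annotation from exon and CDS tables
#'
#' Constructs the transcript models used throughout the package: per-isoform
#' ordered exons, the optional CDS span, the derived biotype (mRNA when a CDS
#' is present, lncRNA otherwise) and the component decomposition of the
#' mature transcript (5'UTR / CDS / 3'UTR for mRNA, the whole transcript for
#' lncRNA).
#'
#' All genomic coordinates are 1-based closed (the GRanges convention).
#' Transcript (mature RNA) coordinates run 1..L in 5'->3' reading order, L
#' being the mature length (sum of exon widths).  Book-ended or overlapping
#' exons of one transcript are merged.  Transcripts whose exons lie on more
#' than one chromosome or strand, or whose strand is unstranded (`*`/`.`),
#' are dropped with a warning: the 5'->3' direction would be undefined.
#'
#' @param exons data.frame with columns `tx_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (one row per exon, 1-based closed).
#' @param cds optional data.frame with columns `tx_id`, `start`, `end`
#'   giving the genomic span of the CDS (first to last coding nucleotide) of
#'   coding transcripts.  Both endpoints must be exonic.  The span is taken
#'   exactly as annotated; no stop-codon adjustment is applied.
#' @param force_noncoding optional character vector of `tx_id`s to treat as
#'   noncoding even if a CDS row is present (e.g. from a biotype whitelist).
#' @return An object of class `tx_annotation`: a list with elements
#'   `exons` (GRangesList, one element per transcript, genomic order),
#'   `tx` (data.frame of per-transcript metadata incl. `biotype` and
#'   `mature_length`), `exon_tab` (per-exon table with mature-coordinate
#'   spans, 5'->3' order) and `components` (non-empty component spans in
#'   mature coordinates).
#' @seealso [read_annotation()] to build one from a GTF file.
#' @export
tx_annotation <- function(exons, cds = NULL, force_noncoding = NULL) {
  req <- c("tx_id", "gene_id", "chrom", "start", "end", "strand")
  if (!is.data.frame(exons) || !all(req %in% names(exons)))
    stop("'exons' must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(exons) == 0L) stop("no exon records")
  exons$tx_id <- as.character(exons$tx_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  if (any(exons$start > exons$end))
    stop("exon with start > end (tx ",
         exons$tx_id[which(exons$start > exons$end)[1L]], ")")

  # drop transcripts with inconsistent chrom/strand or no defined strand
  ok_strand <- exons$strand %in% c("+", "-")
  bad_tx <- unique(exons$tx_id[!ok_strand])
  chrs <- tapply(exons$chrom, exons$tx_id, function(x) length(unique(x)))
  strs <- tapply(exons$strand, exons$tx_id, function(x) length(unique(x)))
  bad_tx <- unique(c(bad_tx, names(chrs)[chrs > 1L], names(strs)[strs > 1L]))
  if (length(bad_tx)) {
    warning("dropping ", length(bad_tx),
            " transcript(s) with undefined strand or exons on multiple ",
            "chromosomes/strands: ", paste(utils::head(bad_tx, 5L), collapse = ", "))
    exons <- exons[!(exons$tx_id %in% bad_tx), , drop = FALSE]
    if (nrow(exons) == 0L) stop("no transcripts left after validation")
  }

  gr <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start, exons$end),
                               strand = exons$strand)
  grl <- GenomicRanges::split(gr, exons$tx_id)
  grl <- GenomicRanges::reduce(grl)    # merges overlapping and book-ended exons
  tx_ids <- names(grl)

  gene_of <- vapply(split(exons$gene_id, exons$tx_id), `[`, "", 1L)[tx_ids]
  etab <- .exon_table(grl)
  ml <- tapply(etab$tend, etab$tx_id, max)[tx_ids]

  cds_tab <- NULL
  if (!is.null(cds) && nrow(cds) > 0L) {
    creq <- c("tx_id", "start", "end")
    if (!all(creq %in% names(cds)))
      stop("'cds' must have columns ", paste(creq, collapse = ", "))
    cds$tx_id <- as.character(cds$tx_id)
    cds <- cds[!(cds$tx_id %in% force_noncoding), , drop = FALSE]
    cds <- cds[cds$tx_id %in% tx_ids, , drop = FALSE]
    if (nrow(cds)) {
      cds_tab <- data.frame(tx_id = cds$tx_id,
                            cds_start = as.integer(cds$start),
                            cds_end = as.integer(cds$end))
      if (anyDuplicated(cds_tab$tx_id))
        stop("multiple CDS spans for one transcript")
    }
  }

  tx <- data.frame(
    tx_id = tx_ids,
    gene_id = unname(gene_of),
    chrom = vapply(split(etab$chrom, etab$tx_id), `[`, "", 1L)[tx_ids],
    strand = vapply(split(etab$strand, etab$tx_id), `[`, "", 1L)[tx_ids],
    n_exons = as.integer(tapply(etab$tx_id, etab$tx_id, length)[tx_ids]),
    mature_length = as.integer(ml),
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(cds_tab)) {
    i <- match(cds_tab$tx_id, tx$tx_id)
    tx$cds_start[i] <- cds_tab$cds_start
    tx$cds_end[i] <- cds_tab$cds_end
  }
  tx$biotype <- ifelse(is.na(tx$cds_start), "lncRNA", "mRNA")

  obj <- structure(list(exons = grl, tx = tx, exon_tab = etab,
                        components = NULL),
                   class = "tx_annotation")
  obj$components <- .derive_components(obj)
  obj
}

# per-exon table with mature-coordinate spans, rows in 5'->3' order per tx
.exon_table <- function(grl) {
  gr <- unlist(grl, use.names = FALSE)
  tx_id <- rep(names(grl), S4Vectors::elementNROWS(grl))
  d <- data.frame(tx_id = tx_id,
                  chrom = as.character(GenomeInfoDb::seqnames(gr)),
                  strand = as.character(GenomicRanges::strand(gr)),
                  gstart = GenomicRanges::start(gr),
                  gend = GenomicRanges::end(gr),
                  stringsAsFactors = FALSE)
  # order 5'->3': ascending gstart on +, descending on -
  d <- d[order(d$tx_id, ifelse(d$strand == "+", 1L, -1L) * d$gstart), ,
         drop = FALSE]
  w <- d$gend - d$gstart + 1L
  d$tend <- stats::ave(w, d$tx_id, FUN = cumsum)
  d$tstart <- d$tend - w + 1L
  rownames(d) <- NULL
  d
}

# derive non-empty component spans (mature coords) for every transcript
.derive_components <- function(anno) {
  out <- vector("list", nrow(anno$tx))
  for (i in seq_len(nrow(anno$tx))) {
    t <- anno$tx[i, ]
    L <- t$mature_length
    if (t$biotype == "lncRNA") {
      out[[i]] <- data.frame(tx_id = t$tx_id, component = "whole",
                             tstart = 1L, tend = L,
                             stringsAsFactors = FALSE)
      next
    }
    ex <- anno$exon_tab[anno$exon_tab$tx_id == t$tx_id, , drop = FALSE]
    g5 <- if (t$strand == "+") t$cds_start else t$cds_end
    g3 <- if (t$strand == "+") t$cds_end else t$cds_start
    ta <- .g2t(ex, g5)
    tb <- .g2t(ex, g3)
    if (is.na(ta) || is.na(tb) || ta > tb)
      stop("CDS span of transcript ", t$tx_id,
           " is not covered by its exons")
    comp <- data.frame(
      tx_id = t$tx_id,
      component = c("utr5", "cds", "utr3"),
      tstart = c(1L, ta, tb + 1L),
      tend = c(ta - 1L, tb, L),
      stringsAsFactors = FALSE
    )
    out[[i]] <- comp[comp$tstart <= comp$tend, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# map genomic positions to mature coordinates for one transcript's exon rows
.g2t <- function(ex, g) {
  res <- rep(NA_integer_, length(g))
  for (j in seq_len(nrow(ex))) {
    hit <- !is.na(g) & g >= ex$gstart[j] & g <= ex$gend[j]
    if (any(hit)) {
      res[hit] <- if (ex$strand[j] == "+")
        ex$tstart[j] + (g[hit] - ex$gstart[j])
      else
        ex$tstart[j] + (ex$gend[j] - g[hit])
    }
  }
  res
}

# map a mature-coordinate span [a,b] (1-based closed) to genomic intervals;
# returns a data.frame in 5'->3' order with gstart/gend
.t2g <- function(ex, a, b) {
  hit <- ex[ex$tend >= a & ex$tstart <= b, , drop = FALSE]
  os <- pmax(a, hit$tstart)
  oe <- pmin(b, hit$tend)
  plus <- hit$strand == "+"
  gs <- ifelse(plus, hit$gstart + (os - hit$tstart),
               hit$gend - (oe - hit$tstart))
  ge <- ifelse(plus, hit$gstart + (oe - hit$tstart),
               hit$gend - (os - hit$tstart))
  data.frame(chrom = hit$chrom, gstart = as.integer(gs),
             gend = as.integer(ge), strand = hit$strand,
             stringsAsFactors = FALSE)
}

#' Convert genomic positions to mature-transcript coordinates
#'
#' Positions are counted 1..L from the TSS in 5'->3' reading order; for
#' minus-strand transcripts position 1 is the genomically rightmost exonic
#' nucleotide.  Intronic or intergenic positions map to `NA` (they are not
#' part of the mature RNA).
#'
#' @param anno a `tx_annotation`.
#' @param tx_id single transcript identifier.
#' @param pos vector of genomic positions (1-based).
#' @return integer vector of mature positions, `NA` where unmapped.
#' @export
genomic_to_transcript <- function(anno, tx_id, pos) {
  stopifnot(inherits(anno, "tx_annotation"), length(tx_id) == 1L)
  ex <- anno$exon_tab[anno$exon_tab$tx_id == tx_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", tx_id)
  .g2t(ex, as.integer(pos))
}

#' Project a mature-transcript span onto the genome
#'
#' Returns the minimal set of genomic intervals covering the mature span
#' `[start, end]` (1-based closed).  More than one interval is returned
#' exactly when the span crosses at least one intron.
#'
#' @inheritParams genomic_to_transcript
#' @param start,end mature span bounds, `1 <= start <= end <= L`.
#' @return GRanges in 5'->3' order; total width equals `end - start + 1`.
#' @export
transcript_to_genomic <- function(anno, tx_id, start, end) {
  stopifnot(inherits(anno, "tx_annotation"), length(tx_id) == 1L)
  ex <- anno$exon_tab[anno$exon_tab$tx_id == tx_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", tx_id)
  L <- max(ex$tend)
  if (start < 1L || end > L || start > end)
    stop("span [", start, ",", end, "] outside mature transcript [1,", L, "]")
  d <- .t2g(ex, as.integer(start), as.integer(end))
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$gstart, d$gend),
                         strand = d$strand)
}

#' Per-transcript component spans in mature coordinates
#'
#' One row per non-empty component (`utr5`, `cds`, `utr3` for mRNA; `whole`
#' for lncRNA) with its mature-coordinate span.  Components partition
#' `[1, mature_length]` in 5'->3' order; an mRNA annotated with a CDS
#' starting at the TSS simply has no `utr5` row.
#'
#' @param anno a `tx_annotation`.
#' @return data.frame with columns `tx_id`, `component`, `tstart`, `tend`.
#' @export
tx_components <- function(anno) {
  stopifnot(inherits(anno, "tx_annotation"))
  anno$components
}

#' Per-transcript metadata table
#' @param anno a `tx_annotation`.
#' @return data.frame with one row per transcript (`tx_id`, `gene_id`,
#'   `chrom`, `strand`, `n_exons`, `mature_length`, `cds_start`, `cds_end`,
#'   `biotype`).
#' @export
transcripts <- function(anno) {
  stopifnot(inherits(anno, "tx_annotation"))
  anno$tx
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("tx_annotation:", nrow(x$tx), "transcripts (",
      sum(x$tx$biotype == "mRNA"), "mRNA,",
      sum(x$tx$biotype == "lncRNA"), "lncRNA ) on",
      length(unique(x$tx$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
`[.tx_annotation` <- function(x, i, ...) {
  ids <- if (is.character(i)) i else x$tx$tx_id[i]
  ids <- ids[ids %in% x$tx$tx_id]
  x$tx <- x$tx[match(ids, x$tx$tx_id), , drop = FALSE]
  rownames(x$tx) <- NULL
  x$exons <- x$exons[ids]
  x$exon_tab <- x$exon_tab[x$exon_tab$tx_id %in% ids, , drop = FALSE]
  x$components <- x$components[x$components$tx_id %in% ids, , drop = FALSE]
  rownames(x$exon_tab) <- rownames(x$components) <- NULL
  x
}

#' Read a GTF gene annotation into transcript models
#'
#' Parses a GTF (2.2) file with `rtracklayer`, after a light line-level
#' validation pass that reports malformed lines by number.  `exon` records
#' grouped by `transcript_id` define the transcripts; `CDS` records, when
#' present, define the coding span (mRNA biotype).  1-based closed GTF
#' coordinates are kept as-is (the package convention).
#'
#' @param path path to a GTF file; `transcript_id` and `gene_id` attributes
#'   are required on exon records.
#' @param noncoding_biotypes optional character vector: transcripts whose
#'   `gene_biotype`/`transcript_biotype` attribute is in this set are forced
#'   to lncRNA even if CDS records exist.
#' @return a [tx_annotation] object.
#' @export
read_annotation <- function(path, noncoding_biotypes = NULL) {
  .validate_gtf(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon/CDS records in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("GTF records lack transcript_id attributes")
  gid <- if (!is.null(gr$gene_id)) gr$gene_id else gr$transcript_id

  is_ex <- as.character(gr$type) == "exon"
  ex <- gr[is_ex]
  exons <- data.frame(tx_id = ex$transcript_id,
                      gene_id = gid[is_ex],
                      chrom = as.character(GenomeInfoDb::seqnames(ex)),
                      start = GenomicRanges::start(ex),
                      end = GenomicRanges::end(ex),
                      strand = as.character(GenomicRanges::strand(ex)),
                      stringsAsFactors = FALSE)
  exons$strand[exons$strand == "*"] <- "."

  cdsr <- gr[!is_ex]
  cds <- NULL
  if (length(cdsr)) {
    cds <- data.frame(tx_id = cdsr$transcript_id,
                      start = GenomicRanges::start(cdsr),
                      end = GenomicRanges::end(cdsr),
                      stringsAsFactors = FALSE)
    cds <- do.call(rbind, lapply(split(cds, cds$tx_id), function(d)
      data.frame(tx_id = d$tx_id[1L], start = min(d$start),
                 end = max(d$end), stringsAsFactors = FALSE)))
  }
  # transcripts that have CDS but no exon records are rejected
  if (!is.null(cds)) {
    orphan <- setdiff(cds$tx_id, exons$tx_id)
    if (length(orphan))
      warning("dropping ", length(orphan),
              " transcript(s) with CDS but no exon records")
    cds <- cds[cds$tx_id %in% exons$tx_id, , drop = FALSE]
  }

  force_nc <- NULL
  if (!is.null(noncoding_biotypes)) {
    bt <- gr$gene_biotype
    if (is.null(bt)) bt <- gr$transcript_biotype
    if (!is.null(bt))
      force_nc <- unique(gr$transcript_id[!is.na(bt) &
                                            bt %in% noncoding_biotypes])
  }
  tx_annotation(exons, cds, force_noncoding = force_nc)
}

.validate_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
    if (s > e)
      stop("malformed GTF line ", i, ": start (", s, ") > end (", e, ")")
  }
  invisible(TRUE)
}

#' Write a transcript annotation as GTF
#'
#' Emits one `exon` record per exon and, for coding transcripts, per-exon
#' `CDS` records (the CDS mature span projected back through the introns).
#' Output is deterministic for a given annotation.
#'
#' @param anno a `tx_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(anno, path) {
  stopifnot(inherits(anno, "tx_annotation"))
  rows <- list()
  for (i in seq_len(nrow(anno$tx))) {
    t <- anno$tx[i, ]
    ex <- anno$exon_tab[anno$exon_tab$tx_id == t$tx_id, , drop = FALSE]
    ex <- ex[order(ex$gstart), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ex$chrom, start = ex$gstart, end = ex$gend,
      strand = ex$strand, type = "exon",
      tx_id = t$tx_id, gene_id = t$gene_id, stringsAsFactors = FALSE)
    if (t$biotype == "mRNA") {
      cc <- anno$components[anno$components$tx_id == t$tx_id &
                              anno$components$component == "cds", ]
      cg <- .t2g(anno$exon_tab[anno$exon_tab$tx_id == t$tx_id, , drop = FALSE],
                 cc$tstart, cc$tend)
      cg <- cg[order(cg$gstart), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cg$chrom, start = cg$gstart, end = cg$gend,
        strand = cg$strand, type = "CDS",
        tx_id = t$tx_id, gene_id = t$gene_id, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  mcols(gr)$source <- "txmetagene"
  mcols(gr)$type <- d$type
  mcols(gr)$transcript_id <- d$tx_id
  mcols(gr)$gene_id <- d$gene_id
  mcols(gr)$phase <- ifelse(d$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
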