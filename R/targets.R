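# Target prediction: cis by genomic-window search around lncRNA loci,
# trans by expression correlation across samples.

spans_of <- function(x, by) {
  if (inherits(x, "transcript_models")) return(model_spans(x, by = by))
  need <- c("id", "chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("span table must have columns id, chrom, start, end")
  x[, need]
}

#' Cis target genes within a genomic window
#'
#' A (lncRNA, gene) pair is a cis edge when both loci are on the same
#' chromosome, their outer spans do not overlap, and the gap between the
#' spans `max(0, max(starts) - min(ends))` satisfies
#' `0 < gap <= window_bp`. The search is strand-agnostic and reports
#' neighbours on both sides; overlapping or touching loci are excluded
#' ("without overlap").
#'
#' @param lnc_loci lncRNA loci: a `transcript_models` table (spans taken
#'   per transcript) or a data frame with `id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param gene_loci Protein-coding gene spans, same forms (spans taken per
#'   gene for `transcript_models`).
#' @param window_bp Window size in bp; 10000 and 100000 are the
#'   conventional choices.
#' @return Edge data frame with columns `lncrna_id`, `gene_id`, `mode`
#'   ("cis"), `window`, `distance_bp`, `cor` (NA).
#' @export
cis_targets <- function(lnc_loci, gene_loci, window_bp = 10000) {
  if (window_bp <= 0) stop("window_bp must be positive")
  lnc <- spans_of(lnc_loci, by = "transcript")
  gene <- spans_of(gene_loci, by = "gene")
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      mode = character(0), window = numeric(0),
                      distance_bp = numeric(0), cor = numeric(0))
  if (nrow(lnc) == 0 || nrow(gene) == 0) return(empty)
  chroms <- union(lnc$chrom, gene$chrom)
  gr <- function(d) GenomicRanges::GRanges(
    factor(d$chrom, levels = chroms),
    IRanges::IRanges(start = d$start + 1, end = d$end))
  hits <- GenomicRanges::findOverlaps(gr(lnc), gr(gene),
                                      maxgap = window_bp,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  gap <- pmax(0, pmax(lnc$start[i], gene$start[j]) -
                 pmin(lnc$end[i], gene$end[j]))
  keep <- gap > 0 & gap <= window_bp
  if (!any(keep)) return(empty)
  out <- data.frame(
    lncrna_id = lnc$id[i][keep], gene_id = gene$id[j][keep],
    mode = "cis", window = window_bp, distance_bp = gap[keep], cor = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper around [stats::cor()]: requires equal lengths of
#' at least 3 and signals constant vectors (for which the correlation is
#' undefined) instead of returning NA.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Trans target genes by expression correlation
#'
#' Computes the Pearson correlation of every (lncRNA, gene) pair across the
#' shared samples and reports pairs with `|cor|` strictly above the
#' threshold. Constant features (zero variance) are skipped and recorded in
#' the `"skipped"` attribute. Pairs where both sides are the same feature
#' id are never reported.
#'
#' @param lnc_expr lncRNA x sample FPKM matrix.
#' @param gene_expr Gene x sample FPKM matrix with identical sample
#'   columns, in the same order.
#' @param threshold Absolute-correlation threshold (default 0.95, strict).
#' @return Edge data frame with columns `lncrna_id`, `gene_id`, `mode`
#'   ("trans"), `window` (NA), `distance_bp` (NA), `cor`.
#' @export
trans_targets <- function(lnc_expr, gene_expr, threshold = 0.95) {
  if (!identical(colnames(lnc_expr), colnames(gene_expr)))
    stop("sample columns differ between the two matrices")
  keep_l <- apply(lnc_expr, 1, stats::sd) > 0
  keep_g <- apply(gene_expr, 1, stats::sd) > 0
  skipped <- c(rownames(lnc_expr)[!keep_l], rownames(gene_expr)[!keep_g])
  if (length(skipped))
    message("skipping ", length(skipped), " constant feature(s)")
  lnc <- lnc_expr[keep_l, , drop = FALSE]
  gene <- gene_expr[keep_g, , drop = FALSE]
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      mode = character(0), window = numeric(0),
                      distance_bp = numeric(0), cor = numeric(0))
  if (nrow(lnc) == 0 || nrow(gene) == 0) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  cm <- stats::cor(t(lnc), t(gene))
  hit <- which(abs(cm) > threshold, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  out <- data.frame(
    lncrna_id = rownames(lnc)[hit[, 1]],
    gene_id = rownames(gene)[hit[, 2]],
    mode = "trans", window = NA_real_, distance_bp = NA_real_,
    cor = cm[hit],
    stringsAsFactors = FALSE
  )
  out <- out[out$lncrna_id != out$gene_id, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
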