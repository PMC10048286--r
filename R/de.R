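# Differential-expression orchestration: TMM-normalized pseudo-counts,
# per-feature NB exact test, group-mean FPKM fold changes, BH adjustment
# and up/down/ns calls.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Assign up/down/ns differential-expression calls
#'
#' A feature is `up` if its (raw or adjusted) p-value is below
#' `p_threshold` and `log2fc > lfc_threshold`, `down` if the p-value passes
#' and `log2fc < -lfc_threshold`, otherwise `ns`. The absolute-value
#' reading of the fold-change threshold is deliberate: down-regulated
#' features with large negative fold changes are differentially expressed.
#'
#' @param de_table Data frame with columns `log2fc`, `pvalue`, `padj`.
#' @param p_threshold Significance threshold (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param use_adjusted Use `padj` instead of `pvalue` for the cut.
#' @return The table with a `call` column added; up/down/ns counts are
#'   attached as attribute `"call_counts"`.
#' @export
call_de <- function(de_table, p_threshold = 0.05, lfc_threshold = 1,
                    use_adjusted = FALSE) {
  p <- if (use_adjusted) de_table$padj else de_table$pvalue
  call <- rep("ns", nrow(de_table))
  call[p < p_threshold & de_table$log2fc > lfc_threshold] <- "up"
  call[p < p_threshold & de_table$log2fc < -lfc_threshold] <- "down"
  de_table$call <- call
  attr(de_table, "call_counts") <- c(up = sum(call == "up"),
                                     down = sum(call == "down"),
                                     ns = sum(call == "ns"))
  de_table
}

#' Two-group differential expression with the NB exact test
#'
#' Full DE stage: TMM factors give effective library sizes; counts are
#' scaled to the common (geometric-mean) effective size and rounded half-up
#' into pseudo-counts; a common dispersion is estimated by method of
#' moments unless supplied; each feature is tested with the conditional NB
#' exact test; fold changes are computed on group-mean FPKM (old over
#' young) with a pseudocount applied only where a group mean is zero; BH
#' adjustment and calls complete the table.
#'
#' @param counts Feature x sample count matrix.
#' @param groups Sample -> group mapping with levels `old` and `young`
#'   (named vector or `sample_id`/`group` data frame).
#' @param lengths Named feature lengths in nt, for FPKM.
#' @param dispersion Optional fixed common dispersion; estimated from the
#'   data when `NULL`.
#' @param epsilon FPKM pseudocount used only when a group mean is 0
#'   (default 0.01).
#' @param p_threshold,lfc_threshold,use_adjusted Passed to [call_de()].
#' @return Data frame with columns `feature_id`, `mean_fpkm_old`,
#'   `mean_fpkm_young`, `log2fc`, `pvalue`, `padj`, `call`, plus attributes
#'   `dispersion`, `norm_factors` and `epsilon_applied` (logical per
#'   feature).
#' @export
run_de <- function(counts, groups, lengths, dispersion = NULL,
                   epsilon = 0.01, p_threshold = 0.05, lfc_threshold = 1,
                   use_adjusted = FALSE) {
  counts <- as_count_matrix(counts)
  groups <- normalize_groups(groups, colnames(counts))
  if (!setequal(unique(groups), c("old", "young")))
    stop("groups must be 'old' and 'young'")
  if (min(table(groups)) < 2) stop("each group needs at least two replicates")
  nf <- tmm_factors(counts)
  eff <- colSums(counts) * nf
  common <- exp(mean(log(eff)))
  pseudo <- floor(sweep(counts, 2, common / eff, "*") + 0.5)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(pseudo, stats::setNames(groups, colnames(counts)))
  old <- which(groups == "old")
  young <- which(groups == "young")
  pvalue <- apply(pseudo, 1, function(x)
    nb_exact_test(x[old], x[young], dispersion))
  fk <- fpkm(counts, lengths)
  mo <- rowMeans(fk[, old, drop = FALSE])
  my <- rowMeans(fk[, young, drop = FALSE])
  eps_applied <- mo == 0 | my == 0
  eps <- ifelse(eps_applied, epsilon, 0)
  lfc <- log2((mo + eps) / (my + eps))
  out <- data.frame(
    feature_id = rownames(counts),
    mean_fpkm_old = unname(mo), mean_fpkm_young = unname(my),
    log2fc = unname(lfc), pvalue = unname(pvalue),
    padj = bh_adjust(unname(pvalue)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- call_de(out, p_threshold, lfc_threshold, use_adjusted)
  attr(out, "dispersion") <- dispersion
  attr(out, "norm_factors") <- nf
  attr(out, "epsilon_applied") <- stats::setNames(unname(eps_applied),
                                                  rownames(counts))
  out
}
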