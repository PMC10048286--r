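# Relative qPCR quantification by the Livak 2^-ddCt method, with technical
# replicate averaging, calibrator-group centering, group statistics and
# RNA-seq direction concordance.

#' Relative quantification by 2^-ddCt
#'
#' Technical replicates are averaged per (sample, gene); then per sample
#' `dCt = mean Ct(target) - mean Ct(reference)`, per gene
#' `ddCt = dCt - mean(dCt over the calibrator group)` and `RQ = 2^-ddCt`.
#' Centering on the calibrator-group mean makes the calibrator's geometric
#' mean RQ exactly 1. Replicate SD above 0.5 cycles triggers a warning but
#' no rejection.
#'
#' @param ct Data frame with columns `sample_id`, `group`, `gene_id`, `ct`
#'   (one row per technical replicate); Ct values must lie in (0, 45).
#' @param reference_gene Internal-control gene id (e.g. beta-actin) that
#'   every sample must carry.
#' @param calibrator_group Group used as calibrator (default `"young"`).
#' @param paired Use a paired t-test for the group comparison (default
#'   unpaired; biologically independent groups are the common design).
#' @return List with `samples` (per sample x gene: `delta_ct`,
#'   `delta_delta_ct`, `rq`) and `genes` (per gene: group mean RQ and SEM,
#'   `log2_rq_ratio` of old over young means, two-tailed t-test `pvalue`,
#'   `direction`).
#' @export
delta_delta_ct <- function(ct, reference_gene = "beta_actin",
                           calibrator_group = "young", paired = FALSE) {
  need <- c("sample_id", "group", "gene_id", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0 | ct$ct >= 45)) stop("Ct values must lie in (0, 45)")
  if (!calibrator_group %in% ct$group)
    stop("calibrator group '", calibrator_group, "' not present")
  key <- interaction(ct$sample_id, ct$gene_id, drop = TRUE)
  rep_sd <- tapply(ct$ct, key, stats::sd)
  noisy <- names(rep_sd)[!is.na(rep_sd) & rep_sd > 0.5]
  if (length(noisy))
    warning("technical replicate SD > 0.5 cycles for: ",
            paste(noisy, collapse = ", "))
  agg <- stats::aggregate(ct ~ sample_id + group + gene_id, data = ct,
                          FUN = mean)
  ref <- agg[agg$gene_id == reference_gene, ]
  targets <- agg[agg$gene_id != reference_gene, ]
  missing_ref <- setdiff(unique(targets$sample_id), ref$sample_id)
  if (length(missing_ref))
    stop("no reference gene measurement for sample(s): ",
         paste(missing_ref, collapse = ", "))
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  targets$delta_ct <- targets$ct - ref_ct[targets$sample_id]
  samples <- do.call(rbind, lapply(split(targets, targets$gene_id), function(d) {
    calib_mean <- mean(d$delta_ct[d$group == calibrator_group])
    d$delta_delta_ct <- d$delta_ct - calib_mean
    d$rq <- 2^(-d$delta_delta_ct)
    d
  }))
  rownames(samples) <- NULL
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  genes <- do.call(rbind, lapply(split(samples, samples$gene_id), function(d) {
    rq_old <- d$rq[d$group == "old"]
    rq_young <- d$rq[d$group == "young"]
    mo <- mean(rq_old); my <- mean(rq_young)
    data.frame(
      gene_id = d$gene_id[1],
      mean_rq_old = mo, sem_rq_old = sem(rq_old),
      mean_rq_young = my, sem_rq_young = sem(rq_young),
      log2_rq_ratio = log2(mo / my),
      pvalue = group_test(rq_old, rq_young, paired = paired),
      direction = if (mo > my) "up" else "down",
      stringsAsFactors = FALSE
    )
  }))
  rownames(genes) <- NULL
  list(samples = samples[, c("gene_id", "sample_id", "group", "delta_ct",
                             "delta_delta_ct", "rq")],
       genes = genes)
}

#' Two-tailed t-test on relative quantities
#'
#' Standard Student's t-test (two-sided), unpaired by default; the paired
#' mode requires equal group sizes in declared pairing order. Two groups
#' with identical values (zero pooled variance, equal means) return p = 1.
#'
#' @param rq_old,rq_young Numeric vectors of per-sample RQ values.
#' @param paired Paired test flag.
#' @return Two-sided p-value.
#' @export
group_test <- function(rq_old, rq_young, paired = FALSE) {
  if (length(rq_old) < 2 || length(rq_young) < 2)
    stop("need at least two samples per group")
  if (paired && length(rq_old) != length(rq_young))
    stop("paired test needs equal group sizes")
  if (stats::sd(rq_old) == 0 && stats::sd(rq_young) == 0) {
    # degenerate noise-free input: t is 0 (equal means) or infinite
    return(if (isTRUE(all.equal(mean(rq_old), mean(rq_young)))) 1 else 0)
  }
  if (paired && stats::sd(rq_old - rq_young) == 0)
    return(if (isTRUE(all.equal(mean(rq_old), mean(rq_young)))) 1 else 0)
  stats::t.test(rq_old, rq_young, paired = paired,
                var.equal = !paired)$p.value
}

#' qPCR / RNA-seq direction concordance
#'
#' Compares, per gene, the sign of the qPCR log2 group-mean RQ ratio with
#' the sign of the RNA-seq log2 fold change, and reports the agreeing
#' fraction. Genes missing from either table are listed and excluded.
#'
#' @param qpcr_genes Per-gene table from [delta_delta_ct()] (`$genes`).
#' @param de DE table from [run_de()].
#' @return List with `table` (per shared gene: both signs and `agree`),
#'   `fraction` (agreeing fraction) and `missing` (ids excluded).
#' @export
concordance <- function(qpcr_genes, de) {
  shared <- intersect(qpcr_genes$gene_id, de$feature_id)
  missing <- setdiff(qpcr_genes$gene_id, de$feature_id)
  q <- qpcr_genes[match(shared, qpcr_genes$gene_id), ]
  d <- de[match(shared, de$feature_id), ]
  tab <- data.frame(
    gene_id = shared,
    qpcr_log2_ratio = q$log2_rq_ratio,
    rnaseq_log2fc = d$log2fc,
    agree = sign(q$log2_rq_ratio) == sign(d$log2fc),
    stringsAsFactors = FALSE
  )
  list(table = tab,
       fraction = if (nrow(tab)) mean(tab$agree) else NA_real_,
       missing = missing)
}
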