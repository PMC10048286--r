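# Negative-binomial exact test for two-group count comparisons, in the
# style of the classic conditional exact test: condition on the total
# pseudo-count of a feature and measure how extreme the observed split of
# that total between the groups is under an NB model.

#' Negative-binomial exact test on equal-library pseudo-counts
#'
#' Both groups are assumed to be on a common effective library size (see
#' [run_de()] for the scaling). Writing `r = n / dispersion` for a group of
#' `n` samples, the group sums are NB with sizes `r_a`, `r_b` and a shared
#' mean parameter that cancels on conditioning: given the total `T`, the
#' first group's sum follows the beta-binomial-type law
#' `P(S_a = s | T) = C(s + r_a - 1, s) C(T - s + r_b - 1, T - s) /
#' C(T + r_a + r_b - 1, T)`. The two-sided p-value is the total probability
#' of splits no more probable than the observed one. `dispersion = 0`
#' reduces to the conditional binomial split.
#'
#' @param counts_a,counts_b Non-negative integer pseudo-counts per sample.
#' @param dispersion Common NB dispersion (`var = m + d m^2`), >= 0.
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion = 0) {
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (dispersion < 0) stop("dispersion must be >= 0")
  sa <- sum(counts_a)
  total <- sa + sum(counts_b)
  if (total == 0) return(1)
  na <- length(counts_a)
  nb <- length(counts_b)
  s <- 0:total
  if (dispersion == 0) {
    logp <- stats::dbinom(s, total, na / (na + nb), log = TRUE)
  } else {
    ra <- na / dispersion
    rb <- nb / dispersion
    logp <- lchoose(s + ra - 1, s) + lchoose(total - s + rb - 1, total - s) -
      lchoose(total + ra + rb - 1, total)
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[sa + 1]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Common dispersion by method of moments
#'
#' Columns are first scaled to a common library size (mean of the totals);
#' for each feature the within-group sample variances are pooled across the
#' two groups and converted to a dispersion estimate
#' `max(0, (s^2 - m) / m^2)` (from `var = m + d m^2`); the common value is
#' the mean over features with positive pooled mean.
#'
#' @param counts Feature x sample count matrix.
#' @param groups Named character vector (sample -> group label) or a data
#'   frame with columns `sample_id`, `group`; exactly two groups, each with
#'   at least two samples.
#' @return Scalar common dispersion estimate (>= 0).
#' @export
estimate_dispersion <- function(counts, groups) {
  counts <- as_count_matrix(counts)
  groups <- normalize_groups(groups, colnames(counts))
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  idx <- lapply(lv, function(g) which(groups == g))
  if (any(lengths(idx) < 2)) stop("each group needs at least two replicates")
  lib <- colSums(counts)
  norm <- sweep(counts, 2, mean(lib) / lib, "*")
  gm <- matrix(unlist(lapply(idx, function(j)
    rowMeans(norm[, j, drop = FALSE]))), nrow = nrow(norm))
  gv <- matrix(unlist(lapply(idx, function(j)
    apply(norm[, j, drop = FALSE], 1, stats::var))), nrow = nrow(norm))
  df <- lengths(idx) - 1
  v <- (gv %*% df) / sum(df)
  n <- lengths(idx)
  m <- (gm %*% n) / sum(n)
  ok <- m > 0
  if (!any(ok)) return(0)
  mean(pmax(0, (v[ok] - m[ok]) / m[ok]^2))
}

normalize_groups <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    g <- as.character(groups$group)
    names(g) <- as.character(groups$sample_id)
    groups <- g
  }
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing))
    stop("no group for sample(s): ", paste(missing, collapse = ", "))
  unname(groups[sample_ids])
}
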