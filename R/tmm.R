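# Trimmed mean of M-values (TMM) between-library normalization, using the
# published default trims (30% on M, 5% on A) and precision weights.

#' TMM normalization factors
#'
#' Computes a scaling factor per library by the trimmed mean of M-values
#' against a reference library (the one whose 75th-percentile count
#' fraction is closest to the mean of those fractions). Genes expressed in
#' both libraries contribute an M-value (log2 ratio of count fractions) and
#' an A-value (average log2 abundance); after double trimming (`trim_m` on
#' M, `trim_a` on A) the factor is `2^` the precision-weighted mean of the
#' remaining M-values. Factors are rescaled to geometric mean 1.
#'
#' @param counts Feature x sample count matrix (>= 2 samples).
#' @param trim_m Fraction trimmed from each tail of the M distribution.
#' @param trim_a Fraction trimmed from each tail of the A distribution.
#' @return Named vector of normalization factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library total")
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  xr <- counts[, ref]
  Nr <- lib[ref]
  factors <- vapply(seq_len(ncol(counts)), function(s) {
    x <- counts[, s]
    N <- lib[s]
    keep <- x > 0 & xr > 0
    if (!any(keep))
      stop("sample '", colnames(counts)[s],
           "' shares no expressed genes with the reference library")
    x <- x[keep]; y <- xr[keep]
    M <- log2((x / N) / (y / Nr))
    A <- 0.5 * log2((x / N) * (y / Nr))
    if (max(abs(M)) < 1e-10) return(1)
    # double trim by rank, as in the published TMM recipe
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    k <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(k)) return(1)
    w <- (N - x) / (N * x) + (Nr - y) / (Nr * y)
    2^(sum((w * M)[k]) / sum(w[k]))
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  factors
}
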