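# FPKM quantification and group fold changes.

as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have feature rownames and sample colnames")
  if (any(counts < 0)) stop("negative counts")
  counts
}

#' Convert a fragment-count matrix to FPKM
#'
#' `FPKM[f, s] = counts[f, s] * 1e9 / (total_counts[s] * length[f])`:
#' fragments per kilobase of transcript per million mapped fragments.
#'
#' @param counts Feature x sample matrix of non-negative counts with
#'   rownames and colnames.
#' @param lengths Named vector of feature lengths in nt (> 0), covering all
#'   rows of `counts`.
#' @return Matrix of FPKM values with the same dimnames.
#' @export
fpkm <- function(counts, lengths) {
  counts <- as_count_matrix(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("no length for feature(s): ", paste(missing, collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("feature lengths must be positive")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero library total for sample(s): ",
                          paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot, "/") / len * 1e9
}

#' Gene-level FPKM by summing transcript FPKMs
#'
#' The FPKM of a gene is the sum of the FPKMs of its transcripts, per
#' sample; column sums are therefore preserved.
#'
#' @param tx_fpkm Transcript x sample FPKM matrix.
#' @param tx2gene Named character vector mapping transcript id to gene id
#'   (or a two-column data frame `transcript_id`, `gene_id`).
#' @return Gene x sample FPKM matrix.
#' @export
gene_fpkm <- function(tx_fpkm, tx2gene) {
  if (is.data.frame(tx2gene)) {
    map <- tx2gene[[2]]
    names(map) <- tx2gene[[1]]
    tx2gene <- map
  }
  unmapped <- setdiff(rownames(tx_fpkm), names(tx2gene))
  if (length(unmapped))
    stop("transcript(s) not in tx2gene: ", paste(unmapped, collapse = ", "))
  rowsum(tx_fpkm, group = tx2gene[rownames(tx_fpkm)], reorder = TRUE)
}

#' Log2 fold change between group means, old over young
#'
#' `log2((mean_old + epsilon) / (mean_young + epsilon))`. With the default
#' `epsilon = 0` a zero group mean is an error; callers handling zeros must
#' choose a pseudocount explicitly.
#'
#' @param mean_old,mean_young Non-negative group mean expression values
#'   (vectorized).
#' @param epsilon Non-negative pseudocount added to both means.
#' @return Numeric vector of log2 fold changes.
#' @examples
#' log2_fold_change(97.03, 23.58)  # 2.0409
#' @export
log2_fold_change <- function(mean_old, mean_young, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be non-negative")
  if (any(mean_old < 0) || any(mean_young < 0)) stop("group means must be non-negative")
  if (epsilon == 0 && any(mean_old == 0 | mean_young == 0))
    stop("zero group mean with epsilon = 0; set a positive epsilon")
  log2((mean_old + epsilon) / (mean_young + epsilon))
}
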