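# Hypergeometric over-representation analysis of DE / target gene sets
# against user-supplied term annotations (GMT or two-column TSV). The
# universe is a required explicit input: results depend on it, and no
# default background is assumed.

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn from a
#' universe of `N` genes of which `K` carry the term.
#'
#' @param k Annotated genes observed in the drawn set.
#' @param K Universe genes carrying the term.
#' @param n Size of the drawn (DE) set.
#' @param N Universe size.
#' @return p-value in `[0, 1]`.
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read gene-set annotations from a GMT file
#'
#' @param path GMT file: one term per line,
#'   `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' @param namespace Namespace label recorded for every term (GMT carries
#'   none); one of the GO namespaces or `"pathway"`.
#' @return Annotation data frame with columns `term_id`, `term_name`,
#'   `namespace` and list column `genes`.
#' @export
read_gmt <- function(path, namespace = "unspecified") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("GMT lines need at least term, description and one gene")
  data.frame(
    term_id = vapply(parts, `[[`, character(1), 1),
    term_name = vapply(parts, `[[`, character(1), 2),
    namespace = rep(namespace, length(parts)),
    genes = I(lapply(parts, function(p) unique(p[-(1:2)]))),
    stringsAsFactors = FALSE
  )
}

#' Write gene-set annotations to a GMT file
#'
#' @param annotations Annotation data frame as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  writeLines(vapply(seq_len(nrow(annotations)), function(i) {
    paste(c(annotations$term_id[i], annotations$term_name[i],
            annotations$genes[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Term over-representation of a DE gene set
#'
#' Tests every annotated term with the upper-tail hypergeometric test
#' against an explicit gene universe. Genes outside the universe are
#' trimmed from each term; a DE gene absent from the universe is an error.
#' Results are sorted by p-value; BH-adjusted p-values are reported
#' alongside raw p.
#'
#' @param de_genes Character vector: the differentially expressed (or
#'   target) gene set.
#' @param universe Character vector: all genes the study could have
#'   detected.
#' @param annotations Annotation data frame ([read_gmt()]) or a named list
#'   of gene vectors.
#' @return Data frame with one row per term with at least one universe
#'   gene: `term_id`, `term_name`, `namespace`, `k` (DE genes in term),
#'   `K` (universe genes in term), `n` (DE set size), `N` (universe size),
#'   `pvalue`, `padj`, `identified_genes` (comma-joined).
#' @export
enrich <- function(de_genes, universe, annotations) {
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  out_of_universe <- setdiff(de_genes, universe)
  if (length(out_of_universe))
    stop("DE gene(s) not in the universe: ",
         paste(out_of_universe, collapse = ", "))
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- data.frame(
      term_id = names(annotations), term_name = names(annotations),
      namespace = "unspecified", genes = I(unname(annotations)),
      stringsAsFactors = FALSE
    )
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    term_genes <- intersect(annotations$genes[[i]], universe)
    K <- length(term_genes)
    if (K == 0) return(NULL)
    hit <- intersect(term_genes, de_genes)
    k <- length(hit)
    data.frame(
      term_id = annotations$term_id[i], term_name = annotations$term_name[i],
      namespace = annotations$namespace[i],
      k = k, K = K, n = n, N = N,
      pvalue = hypergeom_pvalue(k, K, n, N),
      identified_genes = paste(sort(hit), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), pvalue = numeric(0),
                      padj = numeric(0), identified_genes = character(0)))
  res$padj <- bh_adjust(res$pvalue)
  res <- res[order(res$pvalue, res$term_id),
             c("term_id", "term_name", "namespace", "k", "K", "n", "N",
               "pvalue", "padj", "identified_genes")]
  rownames(res) <- NULL
  res
}

#' Filter enrichment results for reporting
#'
#' The displayed table keeps terms with `pvalue < p_threshold` and at least
#' `min_genes` DE genes (the ">3 DE genes per term" display convention).
#'
#' @param results Result table from [enrich()].
#' @param p_threshold Raw-p significance threshold (default 0.05).
#' @param min_genes Minimum DE genes per displayed term (default 4).
#' @return Filtered result table, sorted by p-value.
#' @export
enrichment_report <- function(results, p_threshold = 0.05, min_genes = 4) {
  out <- results[results$pvalue < p_threshold & results$k >= min_genes, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}
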