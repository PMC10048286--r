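# Independent brute-force / closed-form oracles used to validate the
# package's own implementations. These deliberately take a different route
# than the code under test.

rand_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# longest ORF by exhaustive scan over every ATG and its first in-frame stop
orf_oracle <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  codon <- function(i) substr(seq, i, i + 2)
  for (s in seq_len(max(0L, n - 5L))) {
    if (codon(s) != "ATG") next
    j <- s + 3L
    while (j + 2L <= n) {
      if (codon(j) %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (j - s) %/% 3L)
        break
      }
      j <- j + 3L
    }
  }
  as.integer(best)
}

# conditional split distribution by explicit numerical convolution of
# per-sample NB (or Poisson) pmfs, then tail summation
nb_exact_oracle <- function(counts_a, counts_b, dispersion) {
  total <- sum(counts_a) + sum(counts_b)
  if (total == 0) return(1)
  pm <- if (dispersion == 0) stats::dpois(0:total, 1) else
    stats::dnbinom(0:total, size = 1 / dispersion, mu = 1)
  conv <- function(a, b) {
    m <- length(a)
    out <- numeric(m)
    for (k in seq_len(m)) out[k] <- sum(a[seq_len(k)] * b[k:1])
    out
  }
  grp <- function(n) {
    out <- pm
    if (n > 1) for (i in 2:n) out <- conv(out, pm)
    out
  }
  joint <- grp(length(counts_a)) * rev(grp(length(counts_b)))
  joint <- joint / sum(joint)
  obs <- joint[sum(counts_a) + 1]
  sum(joint[joint <= obs * (1 + 1e-10)])
}

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# all-pairs O(n^2) cis scan on span tables (0-based half-open)
cis_oracle <- function(lnc, gene, window_bp) {
  grid <- expand.grid(i = seq_len(nrow(lnc)), j = seq_len(nrow(gene)))
  gap <- pmax(0, pmax(lnc$start[grid$i], gene$start[grid$j]) -
                pmin(lnc$end[grid$i], gene$end[grid$j]))
  keep <- lnc$chrom[grid$i] == gene$chrom[grid$j] & gap > 0 & gap <= window_bp
  out <- data.frame(lncrna_id = lnc$id[grid$i][keep],
                    gene_id = gene$id[grid$j][keep],
                    distance_bp = gap[keep], stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# upper-tail hypergeometric by direct combinatorial summation
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
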