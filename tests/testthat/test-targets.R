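span_df <- function(ids, chrom, start, end) {
  data.frame(id = ids, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("cis window search uses the gap between spans and excludes overlap", {
  lnc <- span_df("l1", "chr1", 1000, 2000)
  gene <- span_df("g1", "chr1", 7000, 8000)
  e <- cis_targets(lnc, gene, window_bp = 10000)
  expect_equal(nrow(e), 1)
  expect_equal(e$distance_bp, 5000)
  expect_equal(e$mode, "cis")

  # overlapping spans: no edge ("without overlap"); touching spans (gap 0) too
  expect_equal(nrow(cis_targets(span_df("l", "chr1", 1000, 2000),
                                span_df("g", "chr1", 1500, 3000), 10000)), 0)
  expect_equal(nrow(cis_targets(span_df("l", "chr1", 1000, 2000),
                                span_df("g", "chr1", 2000, 3000), 10000)), 0)
  # boundary gap exactly equal to the window is included
  expect_equal(nrow(cis_targets(span_df("l", "chr1", 0, 100),
                                span_df("g", "chr1", 10100, 10200), 10000)), 1)
  expect_equal(nrow(cis_targets(span_df("l", "chr1", 0, 100),
                                span_df("g", "chr1", 10101, 10200), 10000)), 0)
  # different chromosomes never pair
  expect_equal(nrow(cis_targets(span_df("l", "chr1", 0, 100),
                                span_df("g", "chr2", 500, 600), 10000)), 0)
})

test_that("cis search equals the all-pairs brute-force scan on random layouts", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 120
    lnc <- span_df(sprintf("l%03d", 1:n), sample(c("chr1", "chr2"), n, TRUE),
                   s <- sample(0:3e5, n), s + sample(200:3000, n, TRUE))
    gene <- span_df(sprintf("g%03d", 1:n), sample(c("chr1", "chr2"), n, TRUE),
                    s2 <- sample(0:3e5, n), s2 + sample(200:5000, n, TRUE))
    w <- sample(c(10000, 100000), 1)
    mine <- cis_targets(lnc, gene, w)
    oracle <- cis_oracle(lnc, gene, w)
    expect_equal(mine[, c("lncrna_id", "gene_id", "distance_bp")], oracle)
  }
})

test_that("cis search is symmetric and translation-invariant", {
  set.seed(43)
  n <- 60
  lnc <- span_df(sprintf("l%02d", 1:n), "chr1",
                 s <- sample(0:2e5, n), s + sample(200:2000, n, TRUE))
  gene <- span_df(sprintf("g%02d", 1:n), "chr1",
                  s2 <- sample(0:2e5, n), s2 + sample(200:2000, n, TRUE))
  e <- cis_targets(lnc, gene, 10000)
  # swapping query and subject swaps the id columns but keeps the pairs
  e_sw <- cis_targets(gene, lnc, 10000)
  expect_setequal(paste(e$lncrna_id, e$gene_id, e$distance_bp),
                  paste(e_sw$gene_id, e_sw$lncrna_id, e_sw$distance_bp))
  # translating a whole chromosome leaves every gap unchanged
  shift <- 12345
  e_tr <- cis_targets(transform(lnc, start = start + shift, end = end + shift),
                      transform(gene, start = start + shift, end = end + shift),
                      10000)
  expect_equal(e_tr, e)
})

test_that("pearson_cor validates input and matches the direct formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1), 1.0)
  expect_equal(pearson_cor(x, -x), -1.0)
  expect_error(pearson_cor(x, rep(3, 5)), "constant")
  expect_error(pearson_cor(x, x[1:4]), "equal length")
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "at least 3")
  set.seed(47)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_cor(a, b), direct, tolerance = 1e-12)
  }
})

test_that("trans targets report exactly the pairs above the threshold", {
  set.seed(53)
  z <- rlnorm(8, 0, 1.5)
  lnc <- rbind(l1 = z * exp(rnorm(8, 0, 0.01)), l2 = rnorm(8, 50, 5))
  gene <- rbind(g1 = z * exp(rnorm(8, 0, 0.01)), g2 = rnorm(8, 50, 5))
  colnames(lnc) <- colnames(gene) <- sprintf("s%d", 1:8)
  e <- trans_targets(lnc, gene, threshold = 0.95)
  expect_true("g1" %in% e$gene_id[e$lncrna_id == "l1"])
  expect_true(all(abs(e$cor) > 0.95))
  # stored correlations recompute exactly from the matrices
  for (i in seq_len(nrow(e)))
    expect_equal(e$cor[i], cor(lnc[e$lncrna_id[i], ], gene[e$gene_id[i], ]))

  # threshold 1 keeps only exactly collinear pairs
  lnc2 <- rbind(l1 = c(1, 2, 3, 4, 5, 6, 7, 8))
  gene2 <- rbind(g1 = 2 * c(1, 2, 3, 4, 5, 6, 7, 8) + 3,
                 g2 = c(1, 2, 3, 4, 5, 6, 7, 9))
  colnames(lnc2) <- colnames(gene2) <- sprintf("s%d", 1:8)
  e2 <- trans_targets(lnc2, gene2, threshold = 1)
  expect_equal(nrow(e2), 0)  # strict: |cor| must exceed 1, impossible

  expect_error(trans_targets(lnc, gene[, 8:1]), "sample columns")
  # constant features are skipped with a message
  lnc3 <- rbind(l1 = rep(5, 8), l2 = rnorm(8))
  colnames(lnc3) <- colnames(gene)
  expect_message(e3 <- trans_targets(lnc3, gene, 0.95), "constant")
  expect_equal(attr(e3, "skipped"), "l1")
})

test_that("independent features almost never exceed the 0.95 threshold at n=8", {
  set.seed(59)
  x <- matrix(rnorm(8 * 100), ncol = 8, dimnames = list(sprintf("a%d", 1:100), sprintf("s%d", 1:8)))
  y <- matrix(rnorm(8 * 100), ncol = 8, dimnames = list(sprintf("b%d", 1:100), sprintf("s%d", 1:8)))
  e <- trans_targets(x, y, 0.95)
  frac <- nrow(e) / (100 * 100)
  expect_lt(frac, 0.005)
  # consistent with the analytic t-transform null tail
  analytic <- 2 * pt(-0.95 * sqrt(6) / sqrt(1 - 0.95^2), df = 6)
  expect_lt(abs(frac - analytic), 0.003)
})
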