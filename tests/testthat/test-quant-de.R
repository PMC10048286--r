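test_that("FPKM normalizes by library depth and feature length", {
  counts <- matrix(c(10, 1e6 - 10, 0, 1e6), ncol = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  lens <- c(a = 1000, b = 2000)
  fk <- fpkm(counts, lens)
  expect_equal(fk["a", "s1"], 10)   # 10 * 1e9 / (1e6 * 1000)
  expect_equal(fk["a", "s2"], 0)

  # scale invariance: doubling every count of a sample leaves its FPKM fixed
  c2 <- counts
  c2[, "s1"] <- c2[, "s1"] * 2
  expect_equal(fpkm(c2, lens)[, "s1"], fk[, "s1"])

  expect_error(fpkm(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                    lens), "zero library")
  expect_error(fpkm(counts, c(a = 1000)), "no length")
})

test_that("gene FPKM sums transcript FPKMs and preserves column totals", {
  tx <- matrix(c(3, 7, 5, 1, 2, 9), ncol = 2,
               dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  map <- c(t1 = "gA", t2 = "gA", t3 = "gB")
  g <- gene_fpkm(tx, map)
  expect_equal(g["gA", "s1"], 10)
  expect_equal(g["gB", "s1"], 5)   # single-transcript gene unchanged
  expect_equal(colSums(g), colSums(tx))
  expect_error(gene_fpkm(tx, c(t1 = "gA")), "not in tx2gene")
})

test_that("log2 fold change is log2(old/young) with explicit zero handling", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(20, 5), 2)
  # antisymmetry under group swap
  set.seed(3)
  o <- runif(50, 0.1, 100); y <- runif(50, 0.1, 100)
  expect_equal(log2_fold_change(o, y), -log2_fold_change(y, o))
  expect_error(log2_fold_change(5, 0), "epsilon")
  expect_equal(log2_fold_change(0, 0, epsilon = 0.01), 0)
})

test_that("TMM factors are 1 for depth-only differences and permutation-stable", {
  set.seed(8)
  base <- rnbinom(400, mu = 50, size = 10) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  expect_equal(unname(tmm_factors(m)), c(1, 1, 1))

  # library B = 2 x A gene-wise: all M-values 0, depth absorbed by lib size
  m2 <- cbind(A = base, B = 2 * base)
  rownames(m2) <- rownames(m)
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2["B"] / f2["A"]), 1)

  set.seed(9)
  m3 <- matrix(rnbinom(500 * 4, mu = rlnorm(500, log(60), 1), size = 5) + 1,
               ncol = 4, dimnames = list(sprintf("g%d", 1:500), sprintf("s%d", 1:4)))
  perm <- sample(nrow(m3))
  expect_equal(tmm_factors(m3[perm, ]), tmm_factors(m3))
  expect_equal(exp(mean(log(tmm_factors(m3)))), 1)
})

test_that("TMM factors track the reference implementation on random data", {
  set.seed(11)
  m <- matrix(rnbinom(2000 * 6, mu = rlnorm(2000, log(80), 1), size = 8),
              ncol = 6, dimnames = list(sprintf("g%d", 1:2000), sprintf("s%d", 1:6)))
  m[, 3] <- m[, 3] * 3
  mine <- tmm_factors(m)
  ref <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  expect_equal(unname(mine), ref, tolerance = 0.05)
})

test_that("NB exact test matches closed forms and the enumeration oracle", {
  expect_equal(nb_exact_test(c(5, 5, 5, 5), c(5, 5, 5, 5), 0.1), 1)
  # dispersion 0 with equal group sizes is the conditional binomial split
  expect_equal(nb_exact_test(c(0, 0), c(10, 10), 0), 2 * 0.5^20)
  expect_error(nb_exact_test(c(-1, 2), c(1, 1), 0.1), "negative")
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.3), 1)

  set.seed(17)
  for (i in 1:150) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    ca <- rnbinom(na, mu = sample(1:20, 1), size = 5)
    cb <- rnbinom(nb, mu = sample(1:20, 1), size = 5)
    if (sum(ca) + sum(cb) == 0 || sum(ca) + sum(cb) > 200) next
    d <- sample(c(0, 0.05, 0.1, 0.4, 1), 1)
    expect_equal(nb_exact_test(ca, cb, d), nb_exact_oracle(ca, cb, d),
                 tolerance = 1e-9)
  }
})

test_that("moment dispersion estimate recovers simulated values", {
  const <- matrix(7, nrow = 50, ncol = 8,
                  dimnames = list(sprintf("g%d", 1:50),
                                  c(paste0("O", 1:4), paste0("Y", 1:4))))
  grp <- setNames(rep(c("old", "young"), each = 4), colnames(const))
  expect_equal(estimate_dispersion(const, grp), 0)

  set.seed(23)
  pois <- simulate_counts(2000, baseline_mean = 100, dispersion = 0)
  expect_lt(estimate_dispersion(pois$counts, pois$groups), 0.05)
  nb <- simulate_counts(2000, baseline_mean = 100, dispersion = 0.2)
  expect_equal(estimate_dispersion(nb$counts, nb$groups), 0.2, tolerance = 0.08)

  expect_error(estimate_dispersion(const[, c(1, 2, 5)],
                                   grp[c(1, 2, 5)]), "two replicates")
})

test_that("BH adjustment matches the step-up oracle and stays above p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(29)
  for (i in 1:200) {
    p <- runif(sample(1:100, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
  }
})

test_that("DE calls respect both thresholds with the absolute-value reading", {
  tab <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2fc = c(2.0, -1.5, 0.9, 1.5),
                    pvalue = c(0.01, 0.01, 0.001, 0.2),
                    padj = c(0.04, 0.04, 0.01, 0.5))
  out <- call_de(tab)
  expect_equal(out$call, c("up", "down", "ns", "ns"))
  expect_equal(unname(attr(out, "call_counts")), c(1, 1, 2))
  out2 <- call_de(tab, use_adjusted = TRUE)
  expect_equal(out2$call, c("up", "down", "ns", "ns"))
})

test_that("run_de is antisymmetric under group relabeling", {
  set.seed(37)
  s <- simulate_counts(300, baseline_mean = 80, dispersion = 0.1,
                       de_fraction = 0.2)
  de1 <- run_de(s$counts, s$groups, s$lengths)
  flipped <- setNames(ifelse(s$groups == "old", "young", "old"),
                      names(s$groups))
  de2 <- run_de(s$counts, flipped, s$lengths)
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$pvalue, de2$pvalue)
  expect_true(all(de1$padj >= de1$pvalue))
  expect_true(all(de1$log2fc[de1$call == "up"] > 0))
  expect_true(all(de1$log2fc[de1$call == "down"] < 0))
})
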