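test_that("length gate is strictly greater than the cutoff", {
  f <- data.frame(transcript_id = c("a", "b"), length_nt = c(200L, 201L))
  expect_equal(length_gate(f), "b")
  f2 <- data.frame(transcript_id = letters[1:5], length_nt = rep(1000L, 5))
  expect_equal(length_gate(f2), letters[1:5])
  expect_error(length_gate(f[0, ]), "empty")

  sim <- shared_sim()
  feats <- transcript_features(sim$models, sim$seqs)
  truth <- sim$truth$features
  expect_setequal(length_gate(feats),
                  truth$transcript_id[truth$length_nt > 200])
})

test_that("hexamer tables are smoothed probability distributions", {
  t1 <- train_hexamer_tables("ATGATGATGATG", "ATGATGATGATG")
  expect_equal(t1$coding_freq, t1$noncoding_freq)
  expect_equal(sum(t1$coding_freq), 1, tolerance = 1e-9)
  expect_true(all(t1$coding_freq > 0))

  # one AAAAAA hexamer per class, pseudocount 1: that cell gets 2/4097
  t2 <- train_hexamer_tables("AAAAAA", "AAAAAA", pseudocount = 1)
  expect_equal(unname(t2$coding_freq["AAAAAA"]), 2 / 4097)
  expect_equal(unname(t2$coding_freq["ACGTAC"]), 1 / 4097)
  expect_equal(sum(t2$noncoding_freq), 1, tolerance = 1e-9)

  expect_error(train_hexamer_tables(character(0), "AAAAAA"), "at least one")
  expect_error(train_hexamer_tables("AAA", "AAAAAA"), "at least 6")
})

test_that("hexamer score is the mean log ratio over overlapping 6-mers", {
  eq <- train_hexamer_tables("ACGTACGTACGT", "ACGTACGTACGT")
  expect_equal(hexamer_score(rand_dna(100), eq), 0)

  # single repeated hexamer whose coding frequency is twice the noncoding one
  hand <- eq
  hand$coding_freq["AAAAAA"] <- 2 * hand$noncoding_freq["AAAAAA"]
  expect_equal(hexamer_score(strrep("A", 30), hand), log(2))

  expect_error(hexamer_score("ACGTA", eq), "shorter")

  # independent re-implementation: explicit window loop
  set.seed(5)
  tabs <- train_hexamer_tables(
    vapply(1:10, function(i) rand_dna(300, c(A = .2, C = .3, G = .3, T = .2)),
           character(1)),
    vapply(1:10, function(i) rand_dna(300, c(A = .3, C = .2, G = .2, T = .3)),
           character(1)))
  llr <- log(tabs$coding_freq / tabs$noncoding_freq)
  for (i in 1:20) {
    s <- rand_dna(sample(50:150, 1))
    wins <- substring(s, 1:(nchar(s) - 5), 6:nchar(s))
    expect_equal(hexamer_score(s, tabs), mean(llr[wins]), tolerance = 1e-12)
  }
})

test_that("predicate classification applies the three thresholds", {
  f <- data.frame(transcript_id = c("x", "y"),
                  length_nt = c(500L, 900L), exon_count = c(1L, 5L),
                  orf_len_aa = c(20L, 300L), orf_coverage = c(0.1, 0.9))
  v <- classify_coding_potential(f, c(x = -1, y = 2))
  expect_true(all(unlist(v[v$transcript_id == "x", -1])))
  expect_false(v$noncoding_by_orf[v$transcript_id == "y"])
  expect_false(v$noncoding_by_coverage[v$transcript_id == "y"])
  expect_false(v$noncoding_by_hexamer[v$transcript_id == "y"])
})

test_that("consensus is the three-way intersection and Venn counts partition", {
  v <- data.frame(
    transcript_id = c("1", "2", "3"),
    noncoding_by_orf = c(TRUE, TRUE, FALSE),
    noncoding_by_coverage = c(FALSE, TRUE, TRUE),
    noncoding_by_hexamer = c(FALSE, TRUE, FALSE)
  )
  cons <- consensus_lncrnas(v)
  expect_equal(cons$lncrna_ids, "2")
  expect_equal(sum(cons$venn), 3)

  disj <- data.frame(transcript_id = c("a", "b"),
                     noncoding_by_orf = c(TRUE, FALSE),
                     noncoding_by_coverage = c(FALSE, TRUE),
                     noncoding_by_hexamer = c(FALSE, FALSE))
  expect_length(consensus_lncrnas(disj)$lncrna_ids, 0)

  # region counts vs brute-force membership enumeration on random verdicts
  set.seed(31)
  for (rep in 1:5) {
    rv <- data.frame(transcript_id = as.character(1:200),
                     noncoding_by_orf = sample(c(TRUE, FALSE), 200, TRUE),
                     noncoding_by_coverage = sample(c(TRUE, FALSE), 200, TRUE),
                     noncoding_by_hexamer = sample(c(TRUE, FALSE), 200, TRUE))
    cons <- consensus_lncrnas(rv)
    pattern <- paste0(rv$noncoding_by_orf + 0, rv$noncoding_by_coverage + 0,
                      rv$noncoding_by_hexamer + 0)
    brute <- table(factor(pattern, levels = c("100", "010", "001", "110",
                                              "101", "011", "111")))
    expect_equal(unname(cons$venn), as.vector(brute))
    expect_equal(sum(cons$venn), sum(pattern != "000"))
    # intersection property: consensus inside every per-predicate set
    for (col in names(rv)[-1])
      expect_true(all(cons$lncrna_ids %in% rv$transcript_id[rv[[col]]]))
  }
})

test_that("each predicate separates planted coding from non-coding classes", {
  sim <- shared_sim()
  res <- shared_pipeline()
  truth <- sim$truth$features
  v <- res$verdicts
  cls <- truth$class[match(v$transcript_id, truth$transcript_id)]
  for (col in c("noncoding_by_orf", "noncoding_by_coverage",
                "noncoding_by_hexamer")) {
    acc <- mean(v[[col]] == (cls == "noncoding"))
    expect_gte(acc, 0.9)
  }
  # consensus sensitivity and specificity against the planted truth
  lnc_truth <- truth$transcript_id[truth$class == "noncoding" &
                                     truth$length_nt > 200]
  coding_truth <- truth$transcript_id[truth$class == "coding"]
  expect_gte(mean(lnc_truth %in% res$lncrna_ids), 0.85)
  expect_gte(1 - mean(coding_truth %in% res$lncrna_ids), 0.85)
})

test_that("class characterization reports exact summaries and generator trends", {
  f <- data.frame(transcript_id = c("l1", "l2", "m1", "m2"),
                  length_nt = c(300L, 500L, 2000L, 3000L),
                  exon_count = c(1L, 2L, 8L, 10L),
                  orf_len_aa = c(10L, 20L, 400L, 600L),
                  orf_coverage = c(.1, .2, .7, .8))
  ch <- characterize_classes(c("l1", "l2"), c("m1", "m2"), f)
  expect_equal(ch$summary$mean_length_nt, c(400, 2500))
  expect_equal(ch$summary$mean_orf_len_aa, c(15, 500))
  expect_equal(sum(ch$histograms$length_nt$count), 4)

  ch1 <- characterize_classes("l1", "m1", f)
  expect_equal(ch1$summary$mean_length_nt, c(300, 2000))
  ch0 <- characterize_classes(character(0), c("m1", "m2"), f)
  expect_equal(ch0$summary$n, c(0, 2))
  expect_true(is.na(ch0$summary$mean_length_nt[1]))
  expect_error(characterize_classes(c("l1"), c("l1", "m1"), f), "disjoint")

  res <- shared_pipeline()
  s <- res$characterization$summary
  expect_lt(s$mean_length_nt[s$class == "lncRNA"],
            s$mean_length_nt[s$class == "mRNA"])
  expect_lt(s$mean_orf_len_aa[s$class == "lncRNA"],
            s$mean_orf_len_aa[s$class == "mRNA"])
  expect_lt(s$mean_exon_count[s$class == "lncRNA"],
            s$mean_exon_count[s$class == "mRNA"])
})
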