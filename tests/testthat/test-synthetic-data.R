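test_that("configuration is validated", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, de_fraction = 1.5), "fractions")
  expect_error(sim_config(seed = 1, n_genes = 0), "positive")
  expect_error(sim_config(seed = 1, n_validation = 30, cis_n_short = 4),
               "validation")
  expect_error(simulate_lnc_study(
    small_config(1, chrom_length_bp = 2e4)), "too short")
})

test_that("the same seed reproduces byte-identical output files", {
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulate_lnc_study(small_config(7), outdir = d1)
  simulate_lnc_study(small_config(7), outdir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 9)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the data
  d3 <- file.path(tempdir(), "simC")
  simulate_lnc_study(small_config(8), outdir = d3)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("truth verification passes in memory and through files", {
  d <- file.path(tempdir(), "simV")
  sim <- simulate_lnc_study(small_config(11), outdir = d)
  v_mem <- verify_truth(sim)
  expect_true(v_mem$ok)
  expect_equal(nrow(v_mem$checks), 6)
  v_file <- verify_truth(d)
  expect_true(v_file$ok)
  unlink(d, recursive = TRUE)
})

test_that("a corrupted annotation is caught by the gap check", {
  d <- file.path(tempdir(), "simF")
  sim <- simulate_lnc_study(small_config(13), outdir = d)
  # shift one exon of a planted cis lncRNA in the emitted GTF
  victim <- sim$truth$cis_pairs$lncrna_id[1]
  gtf <- readLines(file.path(d, "annotation.gtf"))
  i <- grep(paste0('transcript_id "', victim, '"'), gtf)[1]
  fields <- strsplit(gtf[i], "\t")[[1]]
  fields[4] <- as.integer(fields[4]) + 37
  fields[5] <- as.integer(fields[5]) + 37
  gtf[i] <- paste(fields, collapse = "\t")
  writeLines(gtf, file.path(d, "annotation.gtf"))
  v <- verify_truth(d)
  expect_false(v$ok)
  gap_row <- v$checks[v$checks$check == "cis_gaps", ]
  expect_false(gap_row$pass)
  expect_match(gap_row$detail, victim, fixed = TRUE)
  unlink(d, recursive = TRUE)
})

test_that("planted cis gaps at 5/50/150 kb are recovered per window", {
  cfg <- small_config(17, chrom_length_bp = 2e6,
                      cis_n_short = 1, cis_n_mid = 1, cis_n_long = 1,
                      cis_gap_short = c(5000, 5000),
                      cis_gap_mid = c(50000, 50000),
                      cis_gap_long = c(150000, 150000),
                      n_validation = 1)
  sim <- simulate_lnc_study(cfg)
  cis <- sim$truth$cis_pairs
  expect_setequal(cis$gap_bp, c(5000, 50000, 150000))
  lnc_models <- sim$models[sim$models$transcript_id %in% cis$lncrna_id, ]
  gene_models <- sim$models[sim$models$gene_id %in% cis$gene_id, ]
  key <- function(e) paste(e$lncrna_id, e$gene_id)
  truth_key <- paste(cis$lncrna_id, cis$gene_id)
  e10 <- cis_targets(lnc_models, gene_models, 10000)
  expect_true(truth_key[cis$gap_bp == 5000] %in% key(e10))
  expect_false(any(truth_key[cis$gap_bp > 10000] %in% key(e10)))
  e100 <- cis_targets(lnc_models, gene_models, 100000)
  expect_true(all(truth_key[cis$gap_bp <= 100000] %in% key(e100)))
  expect_false(any(truth_key[cis$gap_bp > 100000] %in% key(e100)))
  # reported distances equal the planted gaps
  m <- match(truth_key, key(e100))
  expect_equal(e100$distance_bp[m[!is.na(m)]], cis$gap_bp[!is.na(m)])
})

test_that("generated studies stay truth-consistent across seeds", {
  for (seed in c(19, 23, 29)) {
    sim <- simulate_lnc_study(small_config(seed))
    v <- verify_truth(sim)
    expect_true(v$ok, label = paste("seed", seed))
  }
})

test_that("count simulator plants the requested design", {
  set.seed(1)
  s <- simulate_counts(500, n_old = 4, n_young = 4, baseline_mean = 100,
                       dispersion = 0.1, de_fraction = 0.2, lfc_magnitude = 2)
  expect_equal(dim(s$counts), c(500, 8))
  expect_equal(sum(s$truth$is_de), 100)
  expect_setequal(unique(abs(s$truth$true_lfc[s$truth$is_de])), 2)
  expect_setequal(unname(s$groups), c("old", "young"))
  # planted effects move the group means in the planted direction
  emp <- log2((rowMeans(s$counts[, 1:4]) + 1) / (rowMeans(s$counts[, 5:8]) + 1))
  up <- s$truth$true_lfc > 0
  dn <- s$truth$true_lfc < 0
  expect_gt(mean(emp[up]), 1.5)
  expect_lt(mean(emp[dn]), -1.5)
})
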