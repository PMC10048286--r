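# Shared fixtures. The full-scale study and its pipeline run are expensive
# (~20 s together), so they are generated once per session and reused.

.fixture_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_lnc_study(sim_config(seed = 42))
  .fixture_cache$sim
}

shared_pipeline <- function() {
  if (is.null(.fixture_cache$res)) {
    t0 <- Sys.time()
    .fixture_cache$res <- run_pipeline(shared_sim())
    .fixture_cache$pipeline_secs <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  .fixture_cache$res
}

# reduced-scale configuration for tests that need several fresh studies
small_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_chroms = 2, chrom_length_bp = 1e6,
                   n_genes = 150, n_lncrnas = 40,
                   cis_n_short = 4, cis_n_mid = 4, cis_n_long = 2,
                   trans_n_pairs = 6, trans_n_negative = 2, trans_n_de = 3,
                   n_validation = 4, n_terms = 8, term_size_range = c(10, 30),
                   enriched_term_size = 15, enriched_term_de = 8,
                   n_train = 30)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(sim_config, defaults)
}

gtf_line <- function(chrom, start, end, gene, tx, strand = "+") {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, start, end, strand, gene, tx)
}

write_toy_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

toy_models <- function(spans, chrom = "chr1") {
  # spans: named list id -> c(start, end), single-exon transcripts
  new_tm <- get("new_transcript_models", asNamespace("lncgland"))
  new_tm(data.frame(
    transcript_id = names(spans),
    gene_id = names(spans),
    chrom = chrom, strand = "+",
    exons = I(lapply(spans, function(s) cbind(start = s[1], end = s[2]))),
    stringsAsFactors = FALSE
  ))
}

exact_ct <- function(gene_delta, ref_ct = 20) {
  # noise-free Ct table: gene_delta maps gene -> dCt shift applied to the
  # old group (young is the calibrator baseline)
  samples <- c(paste0("O", 1:4), paste0("Y", 1:4))
  groups <- rep(c("old", "young"), each = 4)
  rows <- list()
  for (s in seq_along(samples)) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = samples[s], group = groups[s], gene_id = "beta_actin",
      ct = ref_ct)
    for (g in names(gene_delta)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples[s], group = groups[s], gene_id = g,
        ct = 25 + if (groups[s] == "old") gene_delta[[g]] else 0)
    }
  }
  do.call(rbind, rows)
}
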