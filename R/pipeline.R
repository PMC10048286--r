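# End-to-end orchestration: identify lncRNAs, call differential expression,
# predict cis and trans targets, assemble the regulatory network, run term
# enrichment and validate against the qPCR table.

#' Run the full lncRNA analysis pipeline
#'
#' Executes every stage on a study bundle: sequence features and the
#' length gate; hexamer tables trained on the bundle's coding/non-coding
#' training split; consensus lncRNA identification; transcript FPKM and
#' gene-level FPKM; differential expression of lncRNA transcripts and of
#' protein-coding genes (transcript counts summed per gene); cis targets
#' at each window; trans targets by correlation of lncRNA FPKM with DE
#' gene FPKM; the DE-only regulatory network; term enrichment of the DE
#' gene set against the annotation; and 2^-ddCt quantification of the Ct
#' table with RNA-seq concordance.
#'
#' @param study A study bundle as returned by [simulate_lnc_study()] (or
#'   an equivalent list read from files: `models`, `seqs`, `counts`,
#'   `groups`, `lengths`, `tx2gene`, `annotations`, `ct`, `train_coding`,
#'   `train_noncoding`).
#' @param windows Cis window sizes in bp (default 10 kb and 100 kb).
#' @param cor_threshold Trans correlation threshold (default 0.95).
#' @param p_threshold,lfc_threshold DE call thresholds.
#' @param padj_threshold Network endpoint threshold on adjusted p.
#' @param min_nt Length-gate cutoff (default 200 nt).
#' @param reference_gene,calibrator_group qPCR settings.
#' @return List with the outputs of every stage: `features`, `verdicts`,
#'   `lncrna_ids`, `venn`, `characterization`, `de_lnc`, `de_gene`,
#'   `cis_edges` (one element per window), `trans_edges`, `network`,
#'   `enrichment`, `qpcr`, `concordance`.
#' @export
run_pipeline <- function(study, windows = c(10000, 100000),
                         cor_threshold = 0.95, p_threshold = 0.05,
                         lfc_threshold = 1, padj_threshold = 0.05,
                         min_nt = 200, reference_gene = "beta_actin",
                         calibrator_group = "young") {
  models <- study$models
  feats <- transcript_features(models, study$seqs)

  ## lncRNA identification
  gated <- length_gate(feats, min_nt = min_nt)
  tables <- train_hexamer_tables(study$train_coding, study$train_noncoding)
  gated_feats <- feats[feats$transcript_id %in% gated, ]
  scores <- hexamer_scores(
    stats::setNames(study$seqs[gated_feats$transcript_id],
                    gated_feats$transcript_id), tables)
  verdicts <- classify_coding_potential(gated_feats, scores)
  cons <- consensus_lncrnas(verdicts)
  lnc_ids <- cons$lncrna_ids
  mrna_tx <- setdiff(feats$transcript_id, lnc_ids)
  characterization <- characterize_classes(lnc_ids, mrna_tx, feats)

  ## quantification and differential expression
  tx2gene <- study$tx2gene
  gene_of <- stats::setNames(tx2gene$gene_id, tx2gene$transcript_id)
  lnc_counts <- study$counts[rownames(study$counts) %in% lnc_ids, , drop = FALSE]
  mrna_counts <- study$counts[rownames(study$counts) %in% mrna_tx, , drop = FALSE]
  gene_counts <- rowsum(mrna_counts, group = gene_of[rownames(mrna_counts)])
  gene_lengths <- stats::setNames(
    vapply(split(study$lengths[rownames(mrna_counts)],
                 gene_of[rownames(mrna_counts)]), max, numeric(1)),
    unique(sort(gene_of[rownames(mrna_counts)])))
  de_lnc <- run_de(lnc_counts, study$groups,
                   study$lengths[rownames(lnc_counts)],
                   p_threshold = p_threshold, lfc_threshold = lfc_threshold)
  de_gene <- run_de(gene_counts, study$groups, gene_lengths,
                    p_threshold = p_threshold, lfc_threshold = lfc_threshold)

  ## target prediction
  lnc_models <- models[models$transcript_id %in% lnc_ids, ]
  gene_models <- models[models$transcript_id %in% mrna_tx, ]
  cis_edges <- lapply(windows, function(w)
    cis_targets(lnc_models, gene_models, window_bp = w))
  names(cis_edges) <- paste0("window_", format(windows, scientific = FALSE,
                                               trim = TRUE))
  fk <- fpkm(study$counts, study$lengths)
  lnc_fpkm <- fk[rownames(fk) %in% lnc_ids, , drop = FALSE]
  deg_ids <- de_gene$feature_id[de_gene$call != "ns"]
  gene_fk <- gene_fpkm(fk[rownames(mrna_counts), , drop = FALSE],
                       tx2gene)
  deg_fpkm <- gene_fk[rownames(gene_fk) %in% deg_ids, , drop = FALSE]
  trans_edges <- trans_targets(lnc_fpkm, deg_fpkm, threshold = cor_threshold)

  ## network: widest-window cis edges (deduplicated to the smallest
  ## qualifying window) plus trans edges
  cis_all <- do.call(rbind, cis_edges)
  if (nrow(cis_all)) {
    key <- paste(cis_all$lncrna_id, cis_all$gene_id)
    cis_all <- do.call(rbind, lapply(split(cis_all, key), function(d)
      d[which.min(d$window), , drop = FALSE]))
    rownames(cis_all) <- NULL
  }
  all_edges <- rbind(cis_all, trans_edges)
  network <- build_network(de_lnc, de_gene, all_edges,
                           padj_threshold = padj_threshold)

  ## enrichment of the DE gene set
  universe <- rownames(gene_counts)
  enrichment <- enrich(intersect(deg_ids, universe), universe,
                       study$annotations)

  ## qPCR validation
  qpcr <- delta_delta_ct(study$ct, reference_gene = reference_gene,
                         calibrator_group = calibrator_group)
  conc <- concordance(qpcr$genes, rbind(de_lnc, de_gene))

  list(features = feats, verdicts = verdicts, lncrna_ids = lnc_ids,
       venn = cons$venn, characterization = characterization,
       de_lnc = de_lnc, de_gene = de_gene, cis_edges = cis_edges,
       trans_edges = trans_edges, network = network,
       enrichment = enrichment, qpcr = qpcr, concordance = conc)
}
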