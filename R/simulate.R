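# Synthetic two-group lncRNA study generator with planted truth. The
# generator emulates the statistical structure assumed by the pipeline: a
# 4 vs 4 old/young design, a mixed population of protein-coding and
# non-coding transcripts with distinct length/exon/ORF distributions,
# NB-distributed counts with a planted DE fraction, lncRNA loci placed at
# controlled genomic gaps from coding genes, latent-factor-coupled trans
# pairs, one planted enriched term and a Ct table derived from the planted
# fold changes. Every run is fully reproducible from the seed.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under:
#' 2,000 coding genes and 300 lncRNA loci on two 5-Mb chromosomes, 4 old
#' vs 4 young samples, NB counts (`var = m + d m^2`) with dispersion 0.1
#' around a baseline mean of 100 (log-normal spread across features), 10%
#' DE at |log2FC| = 2, cis pairs planted below 10 kb, between 10 and
#' 100 kb and beyond 100 kb, trans pairs coupled through a shared
#' log-normal per-sample factor, and qPCR Ct noise of 0.2 cycles.
#'
#' @param seed Integer RNG seed (mandatory: every run is reproducible).
#' @param n_chroms,chrom_length_bp Chromosome count and length.
#' @param n_genes,n_lncrnas Number of coding genes (one transcript each)
#'   and lncRNA loci.
#' @param n_old,n_young Group sizes.
#' @param de_fraction Fraction of features with a planted effect.
#' @param lfc_magnitude Absolute planted log2 fold change (old over young).
#' @param nb_dispersion Common NB dispersion.
#' @param baseline_mean,baseline_sdlog Median and log-sd of the per-feature
#'   baseline mean counts (set `baseline_sdlog = 0` for a flat profile).
#' @param cis_n_short,cis_n_mid,cis_n_long Planted cis pairs per gap class.
#' @param cis_gap_short,cis_gap_mid,cis_gap_long Gap ranges (bp) of the
#'   three classes: below 10 kb, 10-100 kb, beyond 100 kb.
#' @param trans_n_pairs,trans_n_negative,trans_n_de Planted trans pairs,
#'   how many couple negatively, and how many (taken first) are also
#'   planted DE on both sides so they can enter the network.
#' @param trans_sigma Log-sd of the shared per-sample latent factor.
#' @param n_validation Cis short-gap pairs reserved for qPCR validation
#'   (both members DE; one pair down-regulated, the rest up).
#' @param coding_orf_aa,coding_orf_coverage Planted ORF length (aa) and
#'   coverage ranges of coding transcripts.
#' @param noncoding_len_range Length range of non-coding transcripts.
#' @param noncoding_max_orf_aa,noncoding_max_orf_coverage Caps enforced on
#'   non-coding transcripts by rejection sampling.
#' @param coding_exon_range,noncoding_exon_range,intron_range Structural
#'   ranges.
#' @param n_terms,term_size_range,enriched_term_size,enriched_term_de
#'   Annotation terms: count, random term sizes, and the planted enriched
#'   term's size and number of DE member genes.
#' @param qpcr_noise_sd Gaussian noise sd (cycles) on each Ct replicate.
#' @param n_train Training sequences per class for the hexamer tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chroms = 2, chrom_length_bp = 5e6,
                       n_genes = 2000, n_lncrnas = 300,
                       n_old = 4, n_young = 4,
                       de_fraction = 0.1, lfc_magnitude = 2,
                       nb_dispersion = 0.1,
                       baseline_mean = 100, baseline_sdlog = 0.7,
                       cis_n_short = 20, cis_n_mid = 20, cis_n_long = 8,
                       cis_gap_short = c(500, 9500),
                       cis_gap_mid = c(12000, 95000),
                       cis_gap_long = c(110000, 180000),
                       trans_n_pairs = 20, trans_n_negative = 6,
                       trans_n_de = 8, trans_sigma = 1.5,
                       n_validation = 4,
                       coding_orf_aa = c(150, 500),
                       coding_orf_coverage = c(0.55, 0.85),
                       noncoding_len_range = c(180, 1200),
                       noncoding_max_orf_aa = 100,
                       noncoding_max_orf_coverage = 0.5,
                       coding_exon_range = c(4, 10),
                       noncoding_exon_range = c(1, 3),
                       intron_range = c(80, 400),
                       n_terms = 25, term_size_range = c(20, 80),
                       enriched_term_size = 50, enriched_term_de = 25,
                       qpcr_noise_sd = 0.2, n_train = 150) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  fr <- c("de_fraction")
  if (any(unlist(cfg[fr]) < 0 | unlist(cfg[fr]) > 1))
    stop("fractions must lie in [0, 1]")
  if (any(unlist(cfg[c("n_chroms", "chrom_length_bp", "n_genes", "n_lncrnas",
                       "n_old", "n_young")]) <= 0))
    stop("counts and sizes must be positive")
  if (cfg$n_validation > cfg$cis_n_short)
    stop("validation pairs must fit inside the short-gap cis pairs")
  if (cfg$trans_n_de > cfg$trans_n_pairs || cfg$trans_n_negative > cfg$trans_n_pairs)
    stop("trans pair subsets exceed trans_n_pairs")
  class(cfg) <- "sim_config"
  cfg
}

CODING_BASE_PROBS <- c(A = 0.24, C = 0.30, G = 0.30, T = 0.16)
NONCODING_BASE_PROBS <- c(A = 0.32, C = 0.17, G = 0.17, T = 0.34)

rand_seq <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

non_stop_codons <- function(probs) {
  all64 <- apply(expand.grid(b1 = names(probs), b2 = names(probs),
                             b3 = names(probs)), 1, paste, collapse = "")
  p <- apply(expand.grid(p1 = probs, p2 = probs, p3 = probs), 1, prod)
  keep <- !all64 %in% c("TAA", "TAG", "TGA")
  list(codons = all64[keep], probs = p[keep] / sum(p[keep]))
}

make_coding_seq <- function(orf_aa, coverage, codon_pool) {
  orf_nt <- orf_aa * 3 + 3
  len <- max(ceiling(orf_nt / coverage), orf_nt + 6)
  utr <- len - orf_nt
  utr5 <- floor(utr * stats::runif(1, 0.2, 0.8))
  utr3 <- utr - utr5
  orf <- paste0("ATG",
                paste(sample(codon_pool$codons, orf_aa - 1, replace = TRUE,
                             prob = codon_pool$probs), collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  paste0(rand_seq(utr5, CODING_BASE_PROBS), orf,
         rand_seq(utr3, CODING_BASE_PROBS))
}

make_noncoding_seq <- function(len, max_orf_aa, max_coverage, max_tries = 300) {
  for (i in seq_len(max_tries)) {
    s <- rand_seq(len, NONCODING_BASE_PROBS)
    o <- find_longest_orf(s)
    if (o$orf_len_aa < max_orf_aa && o$orf_coverage < max_coverage) return(s)
  }
  stop("could not draw a non-coding sequence of ", len,
       " nt within the ORF caps")
}

split_exons <- function(total_nt, k, min_exon = 30) {
  k <- max(1L, min(k, total_nt %/% min_exon))
  extra <- total_nt - k * min_exon
  add <- if (k > 1) as.vector(stats::rmultinom(1, extra, rep(1, k))) else extra
  min_exon + add
}

#' Simulate an NB count matrix with planted differential expression
#'
#' Minimal count simulator for calibration and power studies: every
#' feature has the same baseline mean; a `de_fraction` of features gets a
#' `lfc_magnitude` effect (random sign) applied to the old group.
#'
#' @param n_features Number of features.
#' @param n_old,n_young Group sizes (columns `O1..`, `Y1..`).
#' @param baseline_mean Scalar mean, or vector of per-feature means.
#' @param dispersion NB dispersion (`var = m + d m^2`); 0 gives Poisson.
#' @param de_fraction Fraction of features with a planted effect.
#' @param lfc_magnitude Absolute planted log2 fold change.
#' @param feature_length Transcript length in nt assigned to every feature
#'   (for FPKM downstream).
#' @return List with `counts` (matrix), `groups` (named vector), `lengths`
#'   (named vector) and `truth` (data frame `feature_id`, `is_de`,
#'   `true_lfc`).
#' @export
simulate_counts <- function(n_features, n_old = 4, n_young = 4,
                            baseline_mean = 100, dispersion = 0.1,
                            de_fraction = 0, lfc_magnitude = 2,
                            feature_length = 1000) {
  ids <- sprintf("F%05d", seq_len(n_features))
  samples <- c(sprintf("O%d", seq_len(n_old)), sprintf("Y%d", seq_len(n_young)))
  groups <- stats::setNames(rep(c("old", "young"), c(n_old, n_young)), samples)
  base <- rep_len(baseline_mean, n_features)
  lfc <- numeric(n_features)
  n_de <- round(de_fraction * n_features)
  if (n_de > 0) {
    de_idx <- sample(n_features, n_de)
    lfc[de_idx] <- lfc_magnitude * sample(c(-1, 1), n_de, replace = TRUE)
  }
  mu <- outer(base, rep(1, n_old + n_young)) *
    2^outer(lfc, as.numeric(groups == "old"))
  counts <- if (dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = n_features)
  } else {
    matrix(stats::rpois(length(mu), mu), nrow = n_features)
  }
  dimnames(counts) <- list(ids, samples)
  list(counts = counts, groups = groups,
       lengths = stats::setNames(rep(feature_length, n_features), ids),
       truth = data.frame(feature_id = ids, is_de = lfc != 0, true_lfc = lfc,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic lncRNA study
#'
#' Produces annotation (GTF), transcript sequences (FASTA), a two-group
#' count matrix, sample groups, a transcript-to-gene map, hexamer training
#' sequences, term annotations with one planted enriched term, a qPCR Ct
#' table for the validation features, and a truth table tying everything
#' together. With `outdir` set, all components are written as plain-text
#' files consumable by the rest of the package with no adapters.
#'
#' @param config A `sim_config`.
#' @param outdir Optional output directory (created if missing).
#' @return Invisible list with `models`, `seqs`, `counts`, `groups`,
#'   `lengths`, `tx2gene`, `annotations`, `ct`, `train_coding`,
#'   `train_noncoding`, `truth` and `config`.
#' @export
simulate_lnc_study <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  codon_pool <- non_stop_codons(CODING_BASE_PROBS)

  ## --- transcripts -------------------------------------------------------
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  gene_tx <- paste0(gene_ids, ".1")
  lnc_genes <- sprintf("L%04d", seq_len(cfg$n_lncrnas))
  lnc_tx <- paste0(lnc_genes, ".1")

  coding_seqs <- vapply(seq_len(cfg$n_genes), function(i) {
    make_coding_seq(sample(cfg$coding_orf_aa[1]:cfg$coding_orf_aa[2], 1),
                    stats::runif(1, cfg$coding_orf_coverage[1],
                                 cfg$coding_orf_coverage[2]),
                    codon_pool)
  }, character(1))
  noncoding_seqs <- vapply(seq_len(cfg$n_lncrnas), function(i) {
    make_noncoding_seq(sample(cfg$noncoding_len_range[1]:cfg$noncoding_len_range[2], 1),
                       cfg$noncoding_max_orf_aa,
                       cfg$noncoding_max_orf_coverage)
  }, character(1))
  seqs <- stats::setNames(c(coding_seqs, noncoding_seqs), c(gene_tx, lnc_tx))

  exon_lengths <- c(
    lapply(nchar(coding_seqs), function(L)
      split_exons(L, sample(cfg$coding_exon_range[1]:cfg$coding_exon_range[2], 1))),
    lapply(nchar(noncoding_seqs), function(L)
      split_exons(L, sample(cfg$noncoding_exon_range[1]:cfg$noncoding_exon_range[2], 1)))
  )
  intron_lengths <- lapply(exon_lengths, function(e)
    if (length(e) > 1) sample(cfg$intron_range[1]:cfg$intron_range[2],
                              length(e) - 1, replace = TRUE) else integer(0))
  span_len <- vapply(seq_along(exon_lengths), function(i)
    sum(exon_lengths[[i]]) + sum(intron_lengths[[i]]), numeric(1))
  tx_ids <- c(gene_tx, lnc_tx)
  tx_gene <- c(gene_ids, lnc_genes)
  is_coding <- c(rep(TRUE, cfg$n_genes), rep(FALSE, cfg$n_lncrnas))

  ## --- planted cis pairs and genomic placement ---------------------------
  n_cis <- cfg$cis_n_short + cfg$cis_n_mid + cfg$cis_n_long
  if (n_cis > min(cfg$n_lncrnas, cfg$n_genes))
    stop("more planted cis pairs than available loci")
  cis_lnc <- sample(cfg$n_lncrnas, n_cis)
  cis_gene <- sample(cfg$n_genes, n_cis)
  gap_of <- function(n, range) {
    if (n == 0) return(integer(0))
    if (range[1] == range[2]) return(rep(range[1], n))
    sample(range[1]:range[2], n, replace = TRUE)
  }
  cis_gaps <- c(gap_of(cfg$cis_n_short, cfg$cis_gap_short),
                gap_of(cfg$cis_n_mid, cfg$cis_gap_mid),
                gap_of(cfg$cis_n_long, cfg$cis_gap_long))
  cis_cat <- rep(c("lt10k", "10to100k", "gt100k"),
                 c(cfg$cis_n_short, cfg$cis_n_mid, cfg$cis_n_long))

  # units: paired gene+lnc loci keep their planted gap; everything else is
  # a standalone locus; units are shuffled and packed chromosome by
  # chromosome with a small random intergenic gap
  units <- list()
  for (p in seq_len(n_cis)) {
    gi <- cis_gene[p]; li <- cfg$n_genes + cis_lnc[p]
    units[[length(units) + 1]] <-
      list(tx = c(gi, li), offsets = c(0, span_len[gi] + cis_gaps[p]))
  }
  for (gi in setdiff(seq_len(cfg$n_genes), cis_gene))
    units[[length(units) + 1]] <- list(tx = gi, offsets = 0)
  for (li in setdiff(seq_len(cfg$n_lncrnas), cis_lnc))
    units[[length(units) + 1]] <-
      list(tx = cfg$n_genes + li, offsets = 0)
  units <- units[sample(length(units))]

  tx_start <- numeric(length(tx_ids))
  tx_chrom <- character(length(tx_ids))
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  cur_chrom <- 1L
  cursor <- 0
  for (u in units) {
    width <- max(u$offsets + span_len[u$tx])
    pad <- sample(300:800, 1)
    if (cursor + pad + width > cfg$chrom_length_bp) {
      cur_chrom <- cur_chrom + 1L
      cursor <- 0
      pad <- sample(300:800, 1)
      if (cur_chrom > cfg$n_chroms || pad + width > cfg$chrom_length_bp)
        stop("chromosome too short for the requested loci")
    }
    start <- cursor + pad
    tx_start[u$tx] <- start + u$offsets
    tx_chrom[u$tx] <- chrom_names[cur_chrom]
    cursor <- start + width
  }
  strand <- sample(c("+", "-"), length(tx_ids), replace = TRUE)
  exons <- lapply(seq_along(tx_ids), function(i) {
    e <- exon_lengths[[i]]
    ir <- intron_lengths[[i]]
    starts <- tx_start[i] + cumsum(c(0, (e + c(ir, 0))[-length(e)]))
    cbind(start = starts, end = starts + e)
  })
  ord <- order(tx_ids)
  models <- new_transcript_models(data.frame(
    transcript_id = tx_ids[ord], gene_id = tx_gene[ord],
    chrom = tx_chrom[ord], strand = strand[ord],
    exons = I(exons[ord]), stringsAsFactors = FALSE
  ))

  ## --- expression: planted DE, trans coupling, NB counts -----------------
  n_feat <- length(tx_ids)
  samples <- c(sprintf("O%d", seq_len(cfg$n_old)),
               sprintf("Y%d", seq_len(cfg$n_young)))
  groups <- stats::setNames(rep(c("old", "young"), c(cfg$n_old, cfg$n_young)),
                            samples)
  is_old <- as.numeric(groups == "old")
  base <- stats::rlnorm(n_feat, meanlog = log(cfg$baseline_mean),
                        sdlog = cfg$baseline_sdlog)
  base <- pmax(base, 2)

  # validation pairs: first n_validation short-gap cis pairs; one pair down
  val_pairs <- seq_len(cfg$n_validation)
  val_lnc_idx <- cfg$n_genes + cis_lnc[val_pairs]
  val_gene_idx <- cis_gene[val_pairs]
  val_sign <- c(rep(1, cfg$n_validation - 1), -1)

  # trans pairs: features not already used for validation
  avail_lnc <- setdiff(seq_len(cfg$n_lncrnas), cis_lnc[val_pairs])
  avail_gene <- setdiff(seq_len(cfg$n_genes), cis_gene[val_pairs])
  trans_lnc <- cfg$n_genes + sample(avail_lnc, cfg$trans_n_pairs)
  trans_gene <- sample(avail_gene, cfg$trans_n_pairs)
  trans_neg <- seq_len(cfg$trans_n_pairs) %in%
    sample(cfg$trans_n_pairs, cfg$trans_n_negative)

  lfc <- numeric(n_feat)
  forced <- c(val_lnc_idx, val_gene_idx)
  lfc[val_lnc_idx] <- cfg$lfc_magnitude * val_sign
  lfc[val_gene_idx] <- cfg$lfc_magnitude * val_sign
  trans_de <- seq_len(cfg$trans_n_de)
  for (p in trans_de) {
    s <- sample(c(-1, 1), 1)
    lfc[trans_lnc[p]] <- cfg$lfc_magnitude * s
    lfc[trans_gene[p]] <- cfg$lfc_magnitude * s * (if (trans_neg[p]) -1 else 1)
    forced <- c(forced, trans_lnc[p], trans_gene[p])
  }
  n_de_target <- round(cfg$de_fraction * n_feat)
  free <- setdiff(seq_len(n_feat), c(forced, trans_lnc, trans_gene))
  n_fill <- max(0, n_de_target - length(unique(forced)))
  fill <- sample(free, min(n_fill, length(free)))
  lfc[fill] <- cfg$lfc_magnitude * sample(c(-1, 1), length(fill), replace = TRUE)

  mu <- outer(base, rep(1, length(samples))) * 2^outer(lfc, is_old)
  for (p in seq_len(cfg$trans_n_pairs)) {
    z <- stats::rnorm(length(samples))
    fac <- exp(cfg$trans_sigma * z - cfg$trans_sigma^2 / 2)
    mu[trans_lnc[p], ] <- mu[trans_lnc[p], ] * fac
    mu[trans_gene[p], ] <- mu[trans_gene[p], ] *
      (if (trans_neg[p]) 1 / fac else fac)
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = n_feat, dimnames = list(tx_ids, samples))
  counts <- counts[order(rownames(counts)), ]
  lengths <- stats::setNames(nchar(seqs), names(seqs))

  ## --- hexamer training split -------------------------------------------
  train_coding <- stats::setNames(vapply(seq_len(cfg$n_train), function(i)
    make_coding_seq(sample(100:300, 1), stats::runif(1, 0.6, 0.9), codon_pool),
    character(1)), sprintf("TRC%04d", seq_len(cfg$n_train)))
  train_noncoding <- stats::setNames(vapply(seq_len(cfg$n_train), function(i)
    rand_seq(sample(300:800, 1), NONCODING_BASE_PROBS), character(1)),
    sprintf("TRN%04d", seq_len(cfg$n_train)))

  ## --- term annotations with one planted enriched term -------------------
  de_genes <- gene_ids[lfc[seq_len(cfg$n_genes)] != 0]
  n_from_de <- min(cfg$enriched_term_de, length(de_genes))
  planted_genes <- c(sample(de_genes, n_from_de),
                     sample(setdiff(gene_ids, de_genes),
                            cfg$enriched_term_size - n_from_de))
  terms <- vector("list", cfg$n_terms)
  terms[[1]] <- sort(planted_genes)
  for (i in seq_len(cfg$n_terms)[-1]) {
    sz <- sample(cfg$term_size_range[1]:cfg$term_size_range[2], 1)
    terms[[i]] <- sort(sample(gene_ids, sz))
  }
  annotations <- data.frame(
    term_id = sprintf("term%02d", seq_len(cfg$n_terms)),
    term_name = c("planted enriched process",
                  sprintf("random gene set %d", seq_len(cfg$n_terms)[-1])),
    namespace = sample(c("BP", "MF", "CC", "pathway"), cfg$n_terms,
                       replace = TRUE),
    genes = I(terms), stringsAsFactors = FALSE
  )

  ## --- qPCR Ct table for the validation features -------------------------
  val_feature <- c(tx_ids[val_lnc_idx], tx_gene[val_gene_idx])
  val_lfc <- c(lfc[val_lnc_idx], lfc[val_gene_idx])
  ct_rows <- list()
  sample_shift <- stats::runif(length(samples), -0.5, 0.5)
  for (s in seq_along(samples)) {
    for (r in 1:3) {
      ct_rows[[length(ct_rows) + 1]] <- data.frame(
        sample_id = samples[s], group = unname(groups[s]),
        gene_id = "beta_actin", replicate = r,
        ct = 19 + sample_shift[s] + stats::rnorm(1, 0, cfg$qpcr_noise_sd),
        stringsAsFactors = FALSE
      )
    }
  }
  base_ct <- stats::runif(length(val_feature), 22, 26)
  for (f in seq_along(val_feature)) {
    for (s in seq_along(samples)) {
      for (r in 1:3) {
        ct_rows[[length(ct_rows) + 1]] <- data.frame(
          sample_id = samples[s], group = unname(groups[s]),
          gene_id = val_feature[f], replicate = r,
          ct = base_ct[f] - val_lfc[f] * is_old[s] + sample_shift[s] +
            stats::rnorm(1, 0, cfg$qpcr_noise_sd),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  ct <- do.call(rbind, ct_rows)

  ## --- truth table --------------------------------------------------------
  measured_orf <- lapply(seqs, find_longest_orf)
  fk <- fpkm(counts, lengths)
  r_emp <- vapply(seq_len(cfg$trans_n_pairs), function(p)
    stats::cor(fk[tx_ids[trans_lnc[p]], ], fk[tx_ids[trans_gene[p]], ]),
    numeric(1))
  truth <- list(
    features = data.frame(
      transcript_id = tx_ids, gene_id = tx_gene,
      class = ifelse(is_coding, "coding", "noncoding"),
      length_nt = unname(nchar(seqs)[tx_ids]),
      orf_len_aa = vapply(measured_orf, `[[`, integer(1), "orf_len_aa")[tx_ids],
      orf_coverage = vapply(measured_orf, `[[`, numeric(1), "orf_coverage")[tx_ids],
      base_mean = base, is_de = lfc != 0, true_lfc = lfc,
      in_trans_pair = seq_len(n_feat) %in% c(trans_lnc, trans_gene),
      stringsAsFactors = FALSE
    ),
    cis_pairs = data.frame(
      lncrna_id = tx_ids[cfg$n_genes + cis_lnc],
      gene_id = gene_ids[cis_gene],
      gap_bp = cis_gaps, category = cis_cat, stringsAsFactors = FALSE
    ),
    trans_pairs = data.frame(
      lncrna_id = tx_ids[trans_lnc], gene_id = tx_gene[trans_gene],
      negative = trans_neg, both_de = seq_len(cfg$trans_n_pairs) %in% trans_de,
      r_empirical = r_emp, stringsAsFactors = FALSE
    ),
    enriched_term = list(term_id = "term01", genes = sort(planted_genes),
                         n_de_members = n_from_de),
    qpcr = data.frame(feature_id = val_feature, true_lfc = val_lfc,
                      stringsAsFactors = FALSE),
    samples = data.frame(sample_id = samples, group = unname(groups),
                         stringsAsFactors = FALSE),
    config = list(seed = cfg$seed,
                  noncoding_max_orf_aa = cfg$noncoding_max_orf_aa,
                  noncoding_max_orf_coverage = cfg$noncoding_max_orf_coverage,
                  nb_dispersion = cfg$nb_dispersion,
                  lfc_magnitude = cfg$lfc_magnitude)
  )

  sim <- list(models = models, seqs = seqs, counts = counts, groups = groups,
              lengths = lengths,
              tx2gene = data.frame(transcript_id = tx_ids[ord],
                                   gene_id = tx_gene[ord],
                                   stringsAsFactors = FALSE),
              annotations = annotations, ct = ct,
              train_coding = train_coding, train_noncoding = train_noncoding,
              truth = truth, config = cfg)
  if (!is.null(outdir)) write_sim(sim, outdir)
  invisible(sim)
}

write_sim <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_gtf(sim$models, fp("annotation.gtf"))
  write_fasta_seqs(sim$seqs, fp("transcripts.fa"))
  write_fasta_seqs(sim$train_coding, fp("train_coding.fa"))
  write_fasta_seqs(sim$train_noncoding, fp("train_noncoding.fa"))
  counts_df <- data.frame(feature_id = rownames(sim$counts), sim$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, fp("counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$samples, fp("groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$tx2gene, fp("tx2gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(sim$annotations, fp("annotations.gmt"))
  utils::write.table(sim$ct, fp("ct.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

read_sim <- function(outdir) {
  fp <- function(f) file.path(outdir, f)
  counts_df <- utils::read.delim(fp("counts.tsv"), check.names = FALSE)
  counts <- as.matrix(counts_df[, -1])
  rownames(counts) <- counts_df$feature_id
  groups_df <- utils::read.delim(fp("groups.tsv"))
  truth <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  seqs <- read_fasta_seqs(fp("transcripts.fa"))
  list(models = parse_gtf(fp("annotation.gtf")), seqs = seqs,
       counts = counts,
       groups = stats::setNames(groups_df$group, groups_df$sample_id),
       lengths = stats::setNames(nchar(seqs), names(seqs)),
       tx2gene = utils::read.delim(fp("tx2gene.tsv")),
       annotations = read_gmt(fp("annotations.gmt")),
       ct = utils::read.delim(fp("ct.tsv")),
       train_coding = read_fasta_seqs(fp("train_coding.fa")),
       train_noncoding = read_fasta_seqs(fp("train_noncoding.fa")),
       truth = truth)
}

#' Verify a simulated study against its truth table
#'
#' Re-derives features from the emitted components and checks that the
#' truth table is consistent with them: transcript lengths match exon sums
#' and FASTA lengths, ORF caps hold per class, planted cis gaps are
#' reproduced exactly from the annotation, empirical group fold changes of
#' planted DE features are near their planted values, trans-pair
#' correlations recompute to the recorded values and the qPCR table
#' recovers the planted fold changes.
#'
#' @param x A simulation object from [simulate_lnc_study()] or the output
#'   directory it was written to.
#' @return List with `ok` (all checks passed) and `checks` (data frame
#'   `check`, `pass`, `detail`).
#' @export
verify_truth <- function(x) {
  sim <- if (is.character(x)) read_sim(x) else x
  truth <- sim$truth
  feats <- truth$features
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  exon_len <- stats::setNames(
    vapply(sim$models$exons, function(e) sum(e[, 2] - e[, 1]), numeric(1)),
    sim$models$transcript_id)
  seq_len_ <- nchar(sim$seqs)[feats$transcript_id]
  ok_len <- feats$length_nt == unname(seq_len_) &
    feats$length_nt == unname(exon_len[feats$transcript_id])
  add("transcript_lengths", all(ok_len),
      if (all(ok_len)) "" else paste("mismatch:",
        paste(feats$transcript_id[!ok_len][1:min(3, sum(!ok_len))], collapse = ", ")))

  orf <- lapply(sim$seqs[feats$transcript_id], find_longest_orf)
  aa <- vapply(orf, `[[`, integer(1), "orf_len_aa")
  cov <- vapply(orf, `[[`, numeric(1), "orf_coverage")
  cap_aa <- truth$config$noncoding_max_orf_aa
  cap_cov <- truth$config$noncoding_max_orf_coverage
  coding <- feats$class == "coding"
  ok_orf <- (coding & aa >= cap_aa & cov >= cap_cov) |
    (!coding & aa < cap_aa & cov < cap_cov)
  add("orf_constraints", all(ok_orf),
      if (all(ok_orf)) "" else paste("violations:",
        paste(feats$transcript_id[!ok_orf][1:min(3, sum(!ok_orf))], collapse = ", ")))

  tx_span <- model_spans(sim$models, by = "transcript")
  gene_span <- model_spans(sim$models, by = "gene")
  cis <- truth$cis_pairs
  gaps <- vapply(seq_len(nrow(cis)), function(i) {
    l <- tx_span[tx_span$id == cis$lncrna_id[i], ]
    g <- gene_span[gene_span$id == cis$gene_id[i], ]
    if (l$chrom != g$chrom) return(NA_real_)
    max(0, max(l$start, g$start) - min(l$end, g$end))
  }, numeric(1))
  ok_gap <- !is.na(gaps) & gaps == cis$gap_bp
  add("cis_gaps", all(ok_gap),
      if (all(ok_gap)) "" else paste("gap mismatch for pair(s):",
        paste(paste(cis$lncrna_id[!ok_gap], cis$gene_id[!ok_gap])[1:min(3, sum(!ok_gap))],
              collapse = "; ")))

  old <- names(sim$groups)[sim$groups == "old"]
  young <- names(sim$groups)[sim$groups == "young"]
  mo <- rowMeans(sim$counts[, old, drop = FALSE])
  my <- rowMeans(sim$counts[, young, drop = FALSE])
  emp_lfc <- log2((mo + 1) / (my + 1))
  sel <- feats$is_de & !feats$in_trans_pair & feats$base_mean >= 20
  ids <- feats$transcript_id[sel]
  ok_mean <- abs(emp_lfc[ids] - feats$true_lfc[sel]) < 1.5
  add("group_means", all(ok_mean),
      if (all(ok_mean)) "" else paste("deviating feature(s):",
        paste(ids[!ok_mean][1:min(3, sum(!ok_mean))], collapse = ", ")))

  fk <- fpkm(sim$counts, sim$lengths)
  tx_of_gene <- stats::setNames(sim$tx2gene$transcript_id, sim$tx2gene$gene_id)
  tp <- truth$trans_pairs
  r_now <- vapply(seq_len(nrow(tp)), function(p)
    stats::cor(fk[tp$lncrna_id[p], ], fk[tx_of_gene[tp$gene_id[p]], ]),
    numeric(1))
  ok_r <- abs(r_now - tp$r_empirical) < 1e-6
  add("trans_correlations", all(ok_r),
      if (all(ok_r)) "" else "recorded correlation does not recompute")

  q <- delta_delta_ct(sim$ct, reference_gene = "beta_actin",
                      calibrator_group = "young")
  qt <- truth$qpcr
  got <- q$genes$log2_rq_ratio[match(qt$feature_id, q$genes$gene_id)]
  ok_q <- abs(got - qt$true_lfc) < 0.5
  add("qpcr_fold_changes", all(ok_q),
      if (all(ok_q)) "" else paste("deviating feature(s):",
        paste(qt$feature_id[!ok_q], collapse = ", ")))

  checks <- do.call(rbind, checks)
  list(ok = all(checks$pass), checks = checks)
}
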