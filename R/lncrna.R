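# Consensus lncRNA identification: three in-repo coding-potential predicates
# (longest-ORF length, ORF coverage, hexamer usage) combined by intersection,
# mirroring the consensus-of-three logic of CPC/CNCI/PFAM-style filters.

#' Minimum-length gate for lncRNA candidates
#'
#' lncRNAs are by definition longer than 200 nt; the gate is strict
#' (`length_nt > min_nt`).
#'
#' @param features Feature table from [transcript_features()].
#' @param min_nt Minimum length in nucleotides (default 200).
#' @return Character vector of retained transcript ids.
#' @export
length_gate <- function(features, min_nt = 200) {
  if (nrow(features) == 0) stop("empty feature table")
  features$transcript_id[features$length_nt > min_nt]
}

#' Train hexamer frequency tables from coding and non-coding sequences
#'
#' Counts overlapping 6-mers (windows containing N are skipped) in each
#' training class, adds a pseudocount to every one of the 4096 hexamers and
#' normalizes to probabilities. The tables feed [hexamer_score()], the
#' in-repo stand-in for an external coding-potential classifier.
#'
#' @param coding_seqs,noncoding_seqs Character vectors of training
#'   sequences, each at least 6 nt.
#' @param pseudocount Positive smoothing count added to every hexamer cell.
#' @return A `hexamer_tables` list with `coding_freq`, `noncoding_freq`
#'   (named probability vectors over the 4096 hexamers, each summing to 1)
#'   and `pseudocount`.
#' @export
train_hexamer_tables <- function(coding_seqs, noncoding_seqs, pseudocount = 1) {
  if (length(coding_seqs) == 0 || length(noncoding_seqs) == 0)
    stop("both training classes must contain at least one sequence")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  count6 <- function(seqs) {
    if (any(nchar(seqs) < 6)) stop("training sequences must be at least 6 nt")
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(toupper(seqs)), width = 6L)
    colSums(m)
  }
  norm <- function(cnt) {
    p <- cnt + pseudocount
    p / sum(p)
  }
  out <- list(coding_freq = norm(count6(coding_seqs)),
              noncoding_freq = norm(count6(noncoding_seqs)),
              pseudocount = pseudocount)
  class(out) <- "hexamer_tables"
  out
}

#' Hexamer usage score of a sequence
#'
#' Mean, over the sequence's overlapping 6-mers, of
#' `log(coding_freq / noncoding_freq)`. Positive scores are coding-like,
#' negative scores non-coding-like. Natural logarithm.
#'
#' @param seq Nucleotide string of length >= 6.
#' @param tables A `hexamer_tables` object from [train_hexamer_tables()].
#' @return Scalar score.
#' @export
hexamer_score <- function(seq, tables) {
  if (nchar(seq) < 6) stop("sequence shorter than 6 nt")
  unname(hexamer_scores(seq, tables))
}

#' Hexamer usage scores for many sequences
#'
#' Vectorized form of [hexamer_score()].
#'
#' @param seqs Character vector of sequences (length >= 6 each).
#' @param tables A `hexamer_tables` object.
#' @return Named numeric vector of scores (NA for sequences with no
#'   N-free 6-mer window).
#' @export
hexamer_scores <- function(seqs, tables) {
  if (any(nchar(seqs) < 6)) stop("sequence shorter than 6 nt")
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(toupper(seqs)), width = 6L)
  llr <- log(tables$coding_freq / tables$noncoding_freq)
  llr <- llr[colnames(m)]
  tot <- rowSums(m)
  out <- as.vector(m %*% llr) / ifelse(tot > 0, tot, NA_real_)
  names(out) <- names(seqs)
  out
}

#' Apply the three coding-potential predicates
#'
#' Each transcript receives three boolean non-coding verdicts:
#' `noncoding_by_orf` (longest ORF shorter than `max_orf_aa`),
#' `noncoding_by_coverage` (ORF coverage below `max_orf_coverage`) and
#' `noncoding_by_hexamer` (hexamer score below `hexamer_cutoff`). The
#' defaults are conventional lncRNA heuristics, not reproductions of any
#' external tool's cutoff.
#'
#' @param features Feature table from [transcript_features()].
#' @param scores Named numeric vector of hexamer scores covering
#'   `features$transcript_id`.
#' @param max_orf_aa ORF length cutoff in amino acids (default 100).
#' @param max_orf_coverage ORF coverage cutoff (default 0.5).
#' @param hexamer_cutoff Hexamer score cutoff (default 0).
#' @return Data frame of per-transcript verdicts.
#' @export
classify_coding_potential <- function(features, scores, max_orf_aa = 100,
                                      max_orf_coverage = 0.5,
                                      hexamer_cutoff = 0) {
  missing <- setdiff(features$transcript_id, names(scores))
  if (length(missing))
    stop("no hexamer score for: ", paste(missing, collapse = ", "))
  s <- scores[features$transcript_id]
  data.frame(
    transcript_id = features$transcript_id,
    noncoding_by_orf = features$orf_len_aa < max_orf_aa,
    noncoding_by_coverage = features$orf_coverage < max_orf_coverage,
    noncoding_by_hexamer = unname(s < hexamer_cutoff),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Consensus lncRNA set and Venn region counts
#'
#' The consensus set contains transcripts flagged non-coding by all three
#' predicates (intersection logic). Venn counts cover the seven regions of
#' the three per-predicate non-coding sets and sum to the number of
#' transcripts flagged by at least one predicate.
#'
#' @param verdicts Verdict table from [classify_coding_potential()].
#' @return List with `lncrna_ids` (consensus set, sorted) and `venn`
#'   (named integer vector over the seven regions).
#' @export
consensus_lncrnas <- function(verdicts) {
  a <- verdicts$noncoding_by_orf
  b <- verdicts$noncoding_by_coverage
  c_ <- verdicts$noncoding_by_hexamer
  venn <- c(
    "orf" = sum(a & !b & !c_),
    "coverage" = sum(!a & b & !c_),
    "hexamer" = sum(!a & !b & c_),
    "orf+coverage" = sum(a & b & !c_),
    "orf+hexamer" = sum(a & !b & c_),
    "coverage+hexamer" = sum(!a & b & c_),
    "orf+coverage+hexamer" = sum(a & b & c_)
  )
  list(lncrna_ids = sort(verdicts$transcript_id[a & b & c_]), venn = venn)
}

#' Characterize lncRNA and mRNA classes
#'
#' Per-class summaries of transcript length, exon count and ORF length,
#' plus histogram counts on shared bin edges -- the standard comparison
#' showing that lncRNAs are shorter, have fewer exons and shorter ORFs than
#' protein-coding transcripts.
#'
#' @param lnc_ids,mrna_ids Disjoint transcript id sets.
#' @param features Feature table covering both sets.
#' @param length_breaks,orf_breaks Histogram bin edges (defaults span the
#'   data).
#' @return List with `summary` (one row per class; `NA` means for empty
#'   classes) and `histograms` (per metric, counts per class and bin).
#' @export
characterize_classes <- function(lnc_ids, mrna_ids, features,
                                 length_breaks = NULL, orf_breaks = NULL) {
  if (length(intersect(lnc_ids, mrna_ids)))
    stop("lncRNA and mRNA id sets must be disjoint")
  rows <- function(ids, cls) {
    f <- features[features$transcript_id %in% ids, ]
    data.frame(
      class = cls, n = nrow(f),
      mean_length_nt = if (nrow(f)) mean(f$length_nt) else NA_real_,
      median_length_nt = if (nrow(f)) stats::median(f$length_nt) else NA_real_,
      mean_exon_count = if (nrow(f)) mean(f$exon_count) else NA_real_,
      mean_orf_len_aa = if (nrow(f)) mean(f$orf_len_aa) else NA_real_,
      median_orf_len_aa = if (nrow(f)) stats::median(f$orf_len_aa) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  summary <- rbind(rows(lnc_ids, "lncRNA"), rows(mrna_ids, "mRNA"))
  hist_of <- function(values_by_class, breaks) {
    do.call(rbind, lapply(names(values_by_class), function(cls) {
      v <- values_by_class[[cls]]
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      data.frame(class = cls, bin_lower = h$breaks[-length(h$breaks)],
                 bin_upper = h$breaks[-1], count = h$counts,
                 stringsAsFactors = FALSE)
    }))
  }
  f_lnc <- features[features$transcript_id %in% lnc_ids, ]
  f_mrna <- features[features$transcript_id %in% mrna_ids, ]
  all_f <- rbind(f_lnc, f_mrna)
  histograms <- NULL
  if (nrow(all_f)) {
    if (is.null(length_breaks))
      length_breaks <- pretty(range(all_f$length_nt), n = 20)
    if (is.null(orf_breaks))
      orf_breaks <- pretty(range(all_f$orf_len_aa), n = 20)
    exon_breaks <- seq(0.5, max(all_f$exon_count) + 0.5)
    vals <- function(col) {
      out <- list()
      if (nrow(f_lnc)) out$lncRNA <- f_lnc[[col]]
      if (nrow(f_mrna)) out$mRNA <- f_mrna[[col]]
      out
    }
    histograms <- list(
      length_nt = hist_of(vals("length_nt"), length_breaks),
      exon_count = hist_of(vals("exon_count"), exon_breaks),
      orf_len_aa = hist_of(vals("orf_len_aa"), orf_breaks)
    )
  }
  list(summary = summary, histograms = histograms)
}
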