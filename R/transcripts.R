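#' @import Biostrings
#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# Internal coordinates are 0-based half-open throughout the package; GTF
# (1-based inclusive) is converted only at the file boundary so that all
# interval arithmetic (gaps, cis windows) stays unambiguous.

new_transcript_models <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

empty_transcript_models <- function() {
  new_transcript_models(data.frame(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0),
    exons = I(list())
  ))
}

validate_exons <- function(ex, id) {
  if (nrow(ex) == 0) stop("transcript '", id, "' has no exons")
  if (is.unsorted(ex[, 1])) ex <- ex[order(ex[, 1]), , drop = FALSE]
  if (any(ex[, 2] <= ex[, 1]))
    stop("transcript '", id, "' has an empty or inverted exon")
  if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
    stop("transcript '", id, "' has overlapping exons")
  ex
}

#' Read transcript models from a GTF annotation
#'
#' Parses exon records of an Ensembl-dialect GTF (attributes
#' `gene_id "..."; transcript_id "...";`) into a `transcript_models` table,
#' one row per transcript, with exons stored as a two-column matrix of
#' 0-based half-open intervals sorted by start.
#'
#' @param path Path to a GTF file.
#' @return A `transcript_models` data frame with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand` and a list column `exons` (n x 2 integer
#'   matrices, columns `start`, `end`, 0-based half-open).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
#'                   'gene_id "g1"; transcript_id "t1";'), gtf)
#' parse_gtf(gtf)$exons[[1]]  # (100, 200) internally
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  content <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(content)) return(empty_transcript_models())
  nfield <- lengths(strsplit(lines[content], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(content)[nfield < 9][1]
    stop("malformed GTF line ", bad, " in '", path,
         "': expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(empty_transcript_models())
  if (is.null(gr$transcript_id))
    stop("exon record without a transcript_id attribute in '", path, "'")
  if (is.null(gr$gene_id))
    stop("exon record without a gene_id attribute in '", path, "'")
  tid <- as.character(gr$transcript_id)
  gid <- as.character(gr$gene_id)
  if (any(is.na(tid)) || any(!nzchar(tid)))
    stop("exon record without a transcript_id attribute in '", path, "'")
  if (any(is.na(gid)) || any(!nzchar(gid)))
    stop("exon record without a gene_id attribute in '", path, "'")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  # GTF 1-based inclusive -> 0-based half-open
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  ord <- order(tid, s0)
  tid <- tid[ord]; gid <- gid[ord]; chrom <- chrom[ord]
  strand <- strand[ord]; s0 <- s0[ord]; e0 <- e0[ord]
  idx <- split(seq_along(tid), tid)
  ids <- names(idx)
  exons <- vector("list", length(ids))
  gene <- chr <- str <- character(length(ids))
  for (i in seq_along(ids)) {
    j <- idx[[i]]
    if (length(unique(chrom[j])) > 1 || length(unique(strand[j])) > 1)
      stop("transcript '", ids[i], "' has exons on multiple chromosomes or strands")
    gene[i] <- gid[j[1]]; chr[i] <- chrom[j[1]]; str[i] <- strand[j[1]]
    ex <- cbind(start = s0[j], end = e0[j])
    exons[[i]] <- validate_exons(ex, ids[i])
  }
  new_transcript_models(data.frame(
    transcript_id = ids, gene_id = gene, chrom = chr, strand = str,
    exons = I(exons), stringsAsFactors = FALSE
  ))
}

#' Write transcript models as GTF exon records
#'
#' Inverse of [parse_gtf()]: emits one `exon` line per exon, converting the
#' internal 0-based half-open coordinates back to GTF 1-based inclusive.
#' Round-tripping through `write_gtf()` then `parse_gtf()` is lossless.
#'
#' @param models A `transcript_models` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  if (nrow(models) > 0) {
    n_ex <- vapply(models$exons, nrow, integer(1))
    ex <- do.call(rbind, models$exons)
    lines <- sprintf(
      '%s\tlncgland\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      rep(models$chrom, n_ex), ex[, 1] + 1L, ex[, 2],
      rep(models$strand, n_ex), rep(models$gene_id, n_ex),
      rep(models$transcript_id, n_ex)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file keyed by transcript id.
#' @return Named uppercase character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

check_alphabet <- function(seq) {
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
}

#' Find the longest open reading frame in a transcript sequence
#'
#' Scans the three forward frames of the sense-strand sequence for the
#' longest ATG-initiated, in-frame, stop-terminated ORF. The peptide length
#' excludes the stop codon; coverage counts the full ORF including the stop
#' codon as a fraction of the transcript length. Codons containing N never
#' match ATG or a stop.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}` (case-insensitive),
#'   given in sense orientation.
#' @return List with `orf_len_aa` (0 if no complete ORF), `orf_start`
#'   (0-based offset of the ATG, `NA` if none) and `orf_coverage`
#'   (ORF nt including stop / transcript nt).
#' @examples
#' find_longest_orf("ATGAAATAG")  # 2 aa, coverage 1
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  check_alphabet(seq)
  n <- nchar(seq)
  best_len <- 0L
  best_start <- NA_integer_
  if (n >= 6) {
    for (frame in 0:2) {
      pos <- seq.int(frame + 1L, by = 3L, length.out = (n - frame) %/% 3L)
      if (length(pos) < 2) next
      codons <- substring(seq, pos, pos + 2L)
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      if (!any(is_start) || !any(is_stop)) next
      # segment = stretch between consecutive stop codons; the longest ORF
      # ending at a given stop starts at the first ATG in its segment
      seg <- cumsum(is_stop) - is_stop
      atg <- which(is_start)
      first_atg <- vapply(split(atg, seg[atg]), min, numeric(1))
      stop_idx <- which(is_stop)
      fa <- first_atg[as.character(seg[stop_idx])]
      ok <- !is.na(fa)
      if (!any(ok)) next
      lens <- stop_idx[ok] - fa[ok]
      i <- which.max(lens)
      if (lens[i] > best_len) {
        best_len <- as.integer(lens[i])
        best_start <- as.integer(pos[fa[ok][i]] - 1L)
      }
    }
  }
  list(
    orf_len_aa = best_len,
    orf_start = if (best_len > 0) best_start else NA_integer_,
    orf_coverage = if (best_len > 0 && n > 0) (best_len * 3 + 3) / n else 0
  )
}

#' Compute per-transcript sequence features
#'
#' Builds the feature table driving lncRNA identification: transcript length
#' (sum of exon lengths), exon count, longest-ORF peptide length and ORF
#' coverage.
#'
#' @param models A `transcript_models` data frame.
#' @param seqs Named character vector of transcript sequences; each sequence
#'   length must equal the sum of the model's exon lengths.
#' @return Data frame with columns `transcript_id`, `length_nt`,
#'   `exon_count`, `orf_len_aa`, `orf_coverage`.
#' @export
transcript_features <- function(models, seqs) {
  missing <- setdiff(models$transcript_id, names(seqs))
  if (length(missing))
    stop("no sequence for transcript(s): ", paste(missing, collapse = ", "))
  seqs <- seqs[models$transcript_id]
  len_model <- vapply(models$exons, function(e) sum(e[, 2] - e[, 1]), numeric(1))
  len_seq <- nchar(seqs)
  bad <- which(len_model != len_seq)
  if (length(bad))
    stop("sequence length does not match exon lengths for: ",
         paste(models$transcript_id[bad], collapse = ", "))
  orf <- lapply(seqs, find_longest_orf)
  data.frame(
    transcript_id = models$transcript_id,
    length_nt = as.integer(len_seq),
    exon_count = vapply(models$exons, nrow, integer(1)),
    orf_len_aa = vapply(orf, `[[`, integer(1), "orf_len_aa"),
    orf_coverage = vapply(orf, `[[`, numeric(1), "orf_coverage"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Outer genomic spans of transcripts or genes
#'
#' @param models A `transcript_models` data frame.
#' @param by Aggregate spans per `"transcript"` or per `"gene"` (union of
#'   the gene's transcript spans; all transcripts of a gene must share a
#'   chromosome).
#' @return Data frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
model_spans <- function(models, by = c("transcript", "gene")) {
  by <- match.arg(by)
  sp <- data.frame(
    id = models$transcript_id,
    gene_id = models$gene_id,
    chrom = models$chrom,
    start = vapply(models$exons, function(e) min(e[, 1]), numeric(1)),
    end = vapply(models$exons, function(e) max(e[, 2]), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (by == "transcript") return(sp[, c("id", "chrom", "start", "end")])
  out <- do.call(rbind, lapply(split(sp, sp$gene_id), function(d) {
    if (length(unique(d$chrom)) > 1)
      stop("gene '", d$gene_id[1], "' has transcripts on multiple chromosomes")
    data.frame(id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
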