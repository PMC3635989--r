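#' Mappability-corrected effective transcript lengths
#'
#' A 50-nt window of a transcript is uniquely mappable when its sequence
#' occurs nowhere else in the transcript set (neither in another
#' transcript nor at another position of the same one). The effective
#' length is the number of uniquely mappable windows, i.e. (L - 49) minus
#' the multimapping windows; transcripts shorter than the window have
#' effective length 0.
#'
#' @param transcripts Named character vector of nucleotide sequences
#'   (A/C/G/T), names are transcript ids.
#' @param window Window size in nt (default 50).
#' @return Named integer vector of effective lengths.
#' @export
effective_lengths <- function(transcripts, window = 50L) {
  if (window < 1L) stop("window must be >= 1")
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts)))
    stop("transcripts must carry unique names")
  lens <- nchar(transcripts)
  wins <- lapply(seq_along(transcripts), function(i) {
    l <- lens[i]
    if (l < window) return(character(0))
    substring(transcripts[i], 1:(l - window + 1L), window:l)
  })
  all_wins <- unlist(wins, use.names = FALSE)
  counts <- table(all_wins)
  eff <- vapply(wins, function(w) {
    if (length(w) == 0L) return(0L)
    sum(counts[w] == 1L)
  }, integer(1))
  setNames(eff, names(transcripts))
}

#' Effective length of one transcript
#'
#' @param transcript_id Transcript id present in `transcripts`.
#' @inheritParams effective_lengths
#' @export
effective_length <- function(transcript_id, transcripts, window = 50L) {
  if (!transcript_id %in% names(transcripts))
    stop("unknown transcript id: ", transcript_id)
  unname(effective_lengths(transcripts, window)[transcript_id])
}

#' Corrected RPKM
#'
#' Raw read count per million mapped reads divided by the effective
#' length in kilobases.
#'
#' @param raw_count Reads assigned to the gene in one tissue.
#' @param total_mapped_reads Library size (mapped reads) for the tissue.
#' @param effective_length_nt Mappability-corrected length in nt.
#' @return cRPKM value; `NA` where the effective length is 0 (the gene is
#'   unmeasurable in that tissue).
#' @export
crpkm <- function(raw_count, total_mapped_reads, effective_length_nt) {
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  out <- (raw_count / (total_mapped_reads / 1e6)) / (effective_length_nt / 1e3)
  out[effective_length_nt == 0] <- NA_real_
  out
}

#' Expressed call from cRPKM
#'
#' @param crpkm cRPKM values.
#' @param cutoff Threshold (default 10); a gene is expressed when
#'   `crpkm >= cutoff`.
#' @return Logical vector (`NA` propagates from unmeasurable genes).
#' @export
call_expressed <- function(crpkm, cutoff = 10) {
  crpkm >= cutoff
}

#' Tissue-specificity score
#'
#' `(T - t) / (T - 1)`: 1 for a gene expressed in a single tissue, 0 for a
#' gene expressed in all `T` tissues. Genes expressed nowhere (t = 0) get
#' `NA` and are excluded from tissue-specificity analyses.
#'
#' @param t Number of tissues the gene is expressed in.
#' @param n_tissues Total number of tissues considered (default 16).
#' @return Score in `[0, 1]`, or `NA` for `t = 0`.
#' @export
tissue_specificity <- function(t, n_tissues = 16L) {
  if (any(t < 0 | t > n_tissues)) stop("t must lie in [0, n_tissues]")
  out <- (n_tissues - t) / (n_tissues - 1)
  out[t == 0] <- NA_real_
  out
}

#' Per-gene, per-tissue expression table
#'
#' @param counts Data frame with columns `gene_id`, `tissue`, `raw_count`.
#' @param totals Data frame with columns `tissue`, `total_mapped_reads`.
#' @param eff_lengths Named vector of per-gene effective lengths (nt).
#' @param cutoff cRPKM expressed cutoff (default 10).
#' @return `counts` augmented with `crpkm` and `expressed`.
#' @export
expression_table <- function(counts, totals, eff_lengths, cutoff = 10) {
  tot <- setNames(totals$total_mapped_reads, totals$tissue)
  if (any(!counts$tissue %in% names(tot)))
    stop("tissue without a library-size total")
  if (any(!counts$gene_id %in% names(eff_lengths)))
    stop("gene without an effective length")
  counts$crpkm <- crpkm(counts$raw_count, tot[counts$tissue],
                        eff_lengths[counts$gene_id])
  counts$expressed <- call_expressed(counts$crpkm, cutoff)
  counts
}

#' Tissue-specificity scores from an expression table
#'
#' @param expression Output of [expression_table()].
#' @param n_tissues Total number of tissues (default 16).
#' @return Data frame: `gene_id`, `t` (expressing tissues), `score`.
#' @export
ts_scores <- function(expression, n_tissues = 16L) {
  t_per_gene <- tapply(expression$expressed, expression$gene_id,
                       function(e) sum(e, na.rm = TRUE))
  data.frame(gene_id = names(t_per_gene),
             t = as.integer(t_per_gene),
             score = tissue_specificity(as.integer(t_per_gene), n_tissues),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlation of tissue specificity with disorder composition
#'
#' Spearman rank correlation between the tissue-specificity score and the
#' per-protein proportion of a disorder class, plus per-bin medians over
#' equal-width score bins.
#'
#' @param scores Data frame from [ts_scores()] (genes with `t = 0` are
#'   dropped).
#' @param composition Data frame from [protein_composition()]; gene ids
#'   must match protein ids.
#' @param class Disorder class (`"flexible"` or `"constrained"`).
#' @param n_bins Number of equal-width score bins (default 5).
#' @return List with `rho`, `p`, `n`, and a `bins` data frame
#'   (`bin`, `score_lo`, `score_hi`, `n`, `median_proportion`).
#' @export
ts_disorder_correlation <- function(scores, composition, class = "flexible",
                                    n_bins = 5L) {
  col <- paste0("p_", class)
  m <- merge(scores[!is.na(scores$score), c("gene_id", "score")],
             composition[, c("protein_id", col)],
             by.x = "gene_id", by.y = "protein_id")
  if (nrow(m) < 3L) stop("need at least 3 genes with scores and compositions")
  ct <- suppressWarnings(
    stats::cor.test(m$score, m[[col]], method = "spearman", exact = FALSE))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(m$score, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  bins <- data.frame(
    bin = seq_len(n_bins),
    score_lo = breaks[-length(breaks)],
    score_hi = breaks[-1L],
    n = as.integer(tabulate(bin, n_bins)),
    median_proportion = vapply(seq_len(n_bins), function(b) {
      v <- m[[col]][bin == b]
      if (length(v) == 0L) NA_real_ else stats::median(v)
    }, numeric(1)))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m), bins = bins)
}
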