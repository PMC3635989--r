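#' Residue interval of an exon from CDS nucleotide coordinates
#'
#' A residue whose codon is split across two exons is assigned to the exon
#' containing the codon's first nucleotide. For an exon covering CDS
#' nucleotides `[nt_start, nt_end]` (1-based) this is residues
#' `ceiling((nt_start + 2) / 3)` through `floor((nt_end + 2) / 3)`.
#'
#' @param nt_start,nt_end 1-based CDS nucleotide coordinates of the exon.
#' @return List with `start_res`, `end_res` (1-based inclusive).
#' @export
codon_interval <- function(nt_start, nt_end) {
  if (any(nt_start < 1L) || any(nt_end < nt_start))
    stop("require 1 <= nt_start <= nt_end")
  list(start_res = as.integer(ceiling((nt_start + 2) / 3)),
       end_res = as.integer(floor((nt_end + 2) / 3)))
}

#' Per-column gap fractions of an alignment
#'
#' @param group An `aligned_group`.
#' @return Numeric vector: gap rows / total rows, per column.
#' @keywords internal
gap_fractions <- function(group) {
  colMeans(group$aln == GAP)
}

#' Per-exon disorder summaries
#'
#' For each exon, the proportions of the four residue categories over the
#' exon's classified residues, the combined disorder rate (all disordered
#' categories), and the mean per-column gap fraction over the exon's
#' alignment columns. Exons with no classified residues are dropped with a
#' warning.
#'
#' @param exons Exon model data frame: `exon_id`, `event_id`,
#'   `protein_id`, `role` (`C1`/`A`/`C2`/`distal_C`), `label`
#'   (`tissue_specific`/`general`/`not_applicable`), `start_res`,
#'   `end_res`, `nt_length`.
#' @param residues Per-residue classification table (see
#'   [classify_group()]).
#' @param groups Optional named list of `aligned_group` objects (names =
#'   protein ids) used to compute `gap_rate`; `NA` when absent.
#' @return Data frame with one row per retained exon: exon fields plus
#'   `n_residues`, `p_constrained`, `p_flexible`, `p_nonconserved`,
#'   `p_ordered`, `p_disorder`, `gap_rate`.
#' @export
exon_summaries <- function(exons, residues, groups = NULL) {
  if (any(exons$start_res > exons$end_res))
    stop("malformed exon interval (start_res > end_res)")
  res_split <- split(residues, residues$protein_id)
  gapf <- if (!is.null(groups))
    lapply(groups, gap_fractions) else NULL
  short <- c("constrained", "flexible", "nonconserved", "ordered")
  rows <- lapply(seq_len(nrow(exons)), function(i) {
    e <- exons[i, ]
    r <- res_split[[e$protein_id]]
    if (!is.null(r))
      r <- r[r$residue_pos >= e$start_res & r$residue_pos <= e$end_res, ]
    if (is.null(r) || nrow(r) == 0L) return(NULL)
    n <- nrow(r)
    cnt <- table(factor(r$category, levels = DISORDER_CATEGORIES))
    props <- as.numeric(cnt) / n
    gr <- NA_real_
    if (!is.null(gapf) && !is.null(gapf[[e$protein_id]]))
      gr <- mean(gapf[[e$protein_id]][r$column_index])
    cbind(e, data.frame(n_residues = n,
                        p_constrained = props[1L], p_flexible = props[2L],
                        p_nonconserved = props[3L], p_ordered = props[4L],
                        p_disorder = sum(props[1:3]), gap_rate = gr))
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " exon(s) with no classified residues dropped: ",
            paste(utils::head(exons$exon_id[dropped], 5L), collapse = ", "))
  out <- do.call(rbind, rows[!dropped])
  rownames(out) <- NULL
  out
}

#' Residue-weighted proteome background proportions
#'
#' The background level of each disorder category over all classified
#' residues of the run.
#'
#' @param residues Per-residue classification table.
#' @return Named numeric vector: `constrained`, `flexible`,
#'   `nonconserved`, `ordered`, `disorder` (sum of the first three).
#' @export
proteome_background <- function(residues) {
  p <- as.numeric(table(factor(residues$category,
                               levels = DISORDER_CATEGORIES))) / nrow(residues)
  c(constrained = p[1L], flexible = p[2L], nonconserved = p[3L],
    ordered = p[4L], disorder = sum(p[1:3]))
}

#' Select exon summaries by role and label
#' @keywords internal
select_exons <- function(summaries, role, label = NULL) {
  keep <- summaries$role == role
  if (!is.null(label) && !is.na(label)) keep <- keep & summaries$label == label
  summaries[keep, , drop = FALSE]
}

#' Compare exon groups on a per-exon disorder metric
#'
#' Runs the requested two-group (Wilcoxon rank-sum) or group-versus-
#' background (one-sample Wilcoxon signed-rank against the residue-
#' weighted background scalar) contrasts on per-exon proportions and
#' BH-adjusts the p-values across the contrast family.
#'
#' @param summaries Data frame from [exon_summaries()].
#' @param contrasts List of contrast descriptors, each a list with
#'   `name`, `metric` (a `p_*` column of `summaries`), `role1`, `label1`,
#'   and either `role2`/`label2` or `background = TRUE`.
#' @param background Named background vector from [proteome_background()]
#'   (required when any contrast uses the background).
#' @param alternative Test sidedness (default two-sided).
#' @return Data frame: `contrast`, `metric`, `n1`, `n2`, `statistic`,
#'   `p`, `p_adj`, `direction`.
#' @export
compare_exon_groups <- function(summaries, contrasts = default_contrasts(),
                                background = NULL,
                                alternative = "two.sided") {
  rows <- lapply(contrasts, function(ct) {
    g1 <- select_exons(summaries, ct$role1, ct$label1)
    if (nrow(g1) == 0L)
      stop("empty exon group: ", ct$role1, "/", ct$label1)
    x <- g1[[ct$metric]]
    if (isTRUE(ct$background)) {
      if (is.null(background)) stop("background vector required")
      mu <- background[[sub("^p_", "", ct$metric)]]
      ht <- suppressWarnings(stats::wilcox.test(
        x, mu = mu, alternative = alternative, exact = FALSE,
        correct = FALSE))
      dir <- if (ht$p.value < 0.05)
        (if (stats::median(x) > mu) "up" else "down") else "none"
      data.frame(contrast = ct$name, metric = ct$metric,
                 n1 = length(x), n2 = NA_integer_,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 direction = dir, stringsAsFactors = FALSE)
    } else {
      g2 <- select_exons(summaries, ct$role2, ct$label2)
      if (nrow(g2) == 0L)
        stop("empty exon group: ", ct$role2, "/", ct$label2)
      if (nrow(g1) < 2L || nrow(g2) < 2L)
        stop("each group needs >= 2 exons for contrast '", ct$name, "'")
      y <- g2[[ct$metric]]
      w <- wilcoxon_rank_sum(x, y, alternative = alternative)
      data.frame(contrast = ct$name, metric = ct$metric,
                 n1 = length(x), n2 = length(y),
                 statistic = w$statistic, p = w$p,
                 direction = contrast_direction(w$statistic, length(x),
                                                length(y), w$p),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  out[, c("contrast", "metric", "n1", "n2", "statistic", "p", "p_adj",
          "direction")]
}

#' Default exon-group contrast family
#'
#' Tissue-specific versus general exons per role for the flexible and
#' constrained classes, and alternative-exon disorder versus the proteome
#' background.
#'
#' @return List of contrast descriptors for [compare_exon_groups()].
#' @export
default_contrasts <- function() {
  two <- function(name, metric, role)
    list(name = name, metric = metric, role1 = role,
         label1 = "tissue_specific", role2 = role, label2 = "general")
  bg <- function(name, metric, role, label)
    list(name = name, metric = metric, role1 = role, label1 = label,
         background = TRUE)
  list(
    two("flexible_TS_A_vs_general_A", "p_flexible", "A"),
    two("flexible_TS_C1_vs_general_C1", "p_flexible", "C1"),
    two("flexible_TS_C2_vs_general_C2", "p_flexible", "C2"),
    two("constrained_TS_A_vs_general_A", "p_constrained", "A"),
    two("constrained_TS_C1_vs_general_C1", "p_constrained", "C1"),
    two("constrained_TS_C2_vs_general_C2", "p_constrained", "C2"),
    bg("disorder_TS_A_vs_background", "p_disorder", "A", "tissue_specific"),
    bg("disorder_general_A_vs_background", "p_disorder", "A", "general"))
}

#' Functional-protein contrasts for alternative exons
#'
#' (1) Chi-squared test (2x2, no continuity correction) of the bona-fide
#' protein flag against hosting a tissue-specific versus general
#' alternative exon, over proteins hosting at least one A exon. (2)
#' Wilcoxon rank-sum of the flexible-disorder proportion in A exons of
#' bona-fide versus other proteins.
#'
#' @param flags Data frame with columns `protein_id`, `bona_fide`
#'   (logical).
#' @param summaries Exon summaries (see [exon_summaries()]).
#' @return List with `table` (the 2x2 contingency table), `chi2`
#'   (statistic + p), and `wilcoxon` (statistic + p + group sizes).
#' @export
functional_protein_contrast <- function(flags, summaries) {
  a_ex <- summaries[summaries$role == "A", , drop = FALSE]
  host <- tapply(a_ex$label == "tissue_specific", a_ex$protein_id, any)
  bf <- setNames(flags$bona_fide, flags$protein_id)[names(host)]
  if (anyNA(bf)) stop("bona-fide flag missing for some A-exon host proteins")
  tab <- table(factor(bf, levels = c(TRUE, FALSE)),
               factor(host, levels = c(TRUE, FALSE)),
               dnn = c("bona_fide", "hosts_TS"))
  chi2 <- chi_squared_2x2(tab)
  bf_exon <- setNames(flags$bona_fide, flags$protein_id)[a_ex$protein_id]
  x <- a_ex$p_flexible[bf_exon]
  y <- a_ex$p_flexible[!bf_exon]
  wil <- if (length(x) >= 2L && length(y) >= 2L) {
    w <- wilcoxon_rank_sum(x, y)
    list(statistic = w$statistic, p = w$p, n1 = length(x), n2 = length(y))
  } else list(statistic = NA_real_, p = NA_real_,
              n1 = length(x), n2 = length(y))
  list(table = tab, chi2 = chi2, wilcoxon = wil)
}
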