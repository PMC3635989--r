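#' Per-protein feature residue sets
#'
#' Expands feature annotations into residue sets per protein (set
#' semantics: overlapping features count a residue once), optionally with
#' a symmetric halo.
#'
#' @param sites Feature table: `protein_id`, `kind`, `start_res`,
#'   `end_res`.
#' @param halo Residues added on each side of every feature (default 0).
#' @return Named list: protein id -> sorted integer vector of residues.
#' @keywords internal
feature_residue_sets <- function(sites, halo = 0L) {
  if (nrow(sites) == 0L) return(list())
  per <- split(sites, sites$protein_id)
  lapply(per, function(d) {
    sort(unique(unlist(mapply(
      function(s, e) seq(max(1L, s - halo), e + halo),
      d$start_res, d$end_res, SIMPLIFY = FALSE))))
  })
}

#' Positional category profile around feature sites
#'
#' For each offset d in `-window..window`, the fraction of residues at
#' position (site + d) carrying each disorder category, pooled over
#' sites. Offsets falling outside the protein (or outside the classified
#' region) are excluded from both numerator and denominator.
#'
#' @param sites Feature table (typically phosphosites; `start_res` is
#'   used as the site position).
#' @param residues Per-residue classification table.
#' @param window Half-width of the profile (default 10).
#' @return Data frame: `offset`, `category`, `rate`, `n` (residues
#'   contributing at that offset).
#' @export
positional_profile <- function(sites, residues, window = 10L) {
  if (window < 1L) stop("window must be >= 1")
  if (nrow(sites) == 0L) stop("no sites to profile")
  cat_by_prot <- lapply(split(residues, residues$protein_id), function(r)
    setNames(r$category, r$residue_pos))
  offsets <- seq(-window, window)
  sites <- sites[sites$protein_id %in% names(cat_by_prot), , drop = FALSE]
  if (nrow(sites) == 0L) stop("no sites on classified proteins")
  counts <- matrix(0L, length(offsets), length(DISORDER_CATEGORIES),
                   dimnames = list(offsets, DISORDER_CATEGORIES))
  totals <- integer(length(offsets))
  for (i in seq_len(nrow(sites))) {
    cats <- cat_by_prot[[sites$protein_id[i]]]
    pos <- sites$start_res[i] + offsets
    hit <- cats[as.character(pos)]
    ok <- !is.na(hit)
    totals <- totals + ok
    for (j in which(ok))
      counts[j, hit[j]] <- counts[j, hit[j]] + 1L
  }
  out <- expand.grid(offset = offsets, category = DISORDER_CATEGORIES,
                     stringsAsFactors = FALSE)
  out$rate <- as.vector(counts) / rep(pmax(totals, 1L),
                                      length(DISORDER_CATEGORIES))
  out$rate[rep(totals, length(DISORDER_CATEGORIES)) == 0L] <- NA_real_
  out$n <- rep(totals, length(DISORDER_CATEGORIES))
  out
}

#' Feature density per exon with role contrasts
#'
#' Per-exon feature density (feature residues within the exon divided by
#' exon residue count), and Wilcoxon rank-sum contrasts of each
#' neighborhood role (C1, A, C2) against distal constitutive exons,
#' BH-adjusted.
#'
#' @param exons Exon model data frame.
#' @param sites Feature table (filter by `kind` beforehand to test
#'   phosphosites or motifs separately).
#' @param halo Optional halo around features (default 0).
#' @return List with `densities` (exon fields + `n_feature_residues`,
#'   `density`) and `contrasts` (`contrast`, `n1`, `n2`, `statistic`,
#'   `p`, `p_adj`, `direction`).
#' @export
feature_rate_by_exon <- function(exons, sites, halo = 0L) {
  fr <- feature_residue_sets(sites, halo)
  dens <- exons
  dens$n_feature_residues <- vapply(seq_len(nrow(exons)), function(i) {
    s <- fr[[exons$protein_id[i]]]
    if (is.null(s)) return(0L)
    sum(s >= exons$start_res[i] & s <= exons$end_res[i])
  }, integer(1))
  dens$density <- dens$n_feature_residues /
    (dens$end_res - dens$start_res + 1L)
  base <- dens$density[dens$role == "distal_C"]
  rows <- lapply(c("C1", "A", "C2"), function(role) {
    x <- dens$density[dens$role == role]
    if (length(x) < 2L || length(base) < 2L)
      return(data.frame(contrast = paste0(role, "_vs_distal"),
                        n1 = length(x), n2 = length(base),
                        statistic = NA_real_, p = NA_real_,
                        direction = "none", stringsAsFactors = FALSE))
    w <- wilcoxon_rank_sum(x, base)
    data.frame(contrast = paste0(role, "_vs_distal"),
               n1 = length(x), n2 = length(base),
               statistic = w$statistic, p = w$p,
               direction = contrast_direction(w$statistic, length(x),
                                              length(base), w$p),
               stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, rows)
  contrasts$p_adj <- bh_fdr(contrasts$p)
  list(densities = dens, contrasts = contrasts)
}

#' Disorder rates inside versus outside features, by event label
#'
#' Stratifies the residues of labelled exons by (label x inside/outside
#' feature) and reports residue-level rates of combined disorder,
#' constrained and flexible disorder per stratum, plus pairwise Wilcoxon
#' contrasts (on the per-residue indicators) of inside versus outside
#' within each label and of equal strata across labels.
#'
#' @param exons Exon model data frame.
#' @param sites Feature table.
#' @param residues Per-residue classification table.
#' @param roles Exon roles whose residues enter the analysis (default
#'   `"A"`).
#' @param halo Halo around features defining "inside" (default 0: the
#'   modified residue itself).
#' @return List with `rates` (`label`, `where`, `category`, `rate`, `n`)
#'   and `contrasts` (`contrast`, `category`, `n1`, `n2`, `p`, `p_adj`).
#'   Empty strata are reported with `n = 0` and `rate = NA`.
#' @export
rates_within_outside <- function(exons, sites, residues, roles = "A",
                                 halo = 0L) {
  ex <- exons[exons$role %in% roles &
              exons$label %in% c("tissue_specific", "general"), , drop = FALSE]
  if (nrow(ex) == 0L) stop("no labelled exons with the requested roles")
  fr <- feature_residue_sets(sites, halo)
  res_split <- split(residues, residues$protein_id)
  recs <- lapply(seq_len(nrow(ex)), function(i) {
    r <- res_split[[ex$protein_id[i]]]
    if (is.null(r)) return(NULL)
    r <- r[r$residue_pos >= ex$start_res[i] & r$residue_pos <= ex$end_res[i], ]
    if (nrow(r) == 0L) return(NULL)
    s <- fr[[ex$protein_id[i]]]
    data.frame(label = ex$label[i],
               inside = if (is.null(s)) rep(FALSE, nrow(r))
                        else r$residue_pos %in% s,
               category = r$category, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, recs)
  ind <- cbind(disorder = d$category != "ordered",
               constrained = d$category == "constrained_disorder",
               flexible = d$category == "flexible_disorder")
  strata <- expand.grid(label = c("general", "tissue_specific"),
                        where = c("inside", "outside"),
                        stringsAsFactors = FALSE)
  rates <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- d$label == strata$label[i] &
      (d$inside == (strata$where[i] == "inside"))
    data.frame(label = strata$label[i], where = strata$where[i],
               category = colnames(ind),
               rate = if (sum(sel) == 0L) NA_real_ else colMeans(ind[sel, , drop = FALSE]),
               n = sum(sel), stringsAsFactors = FALSE, row.names = NULL)
  }))
  pair <- function(sel1, sel2, name, cat) {
    x <- ind[sel1, cat]; y <- ind[sel2, cat]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(contrast = name, category = cat,
                        n1 = length(x), n2 = length(y), p = NA_real_,
                        stringsAsFactors = FALSE))
    w <- wilcoxon_rank_sum(x, y)
    data.frame(contrast = name, category = cat, n1 = length(x),
               n2 = length(y), p = w$p, stringsAsFactors = FALSE)
  }
  cons <- list()
  for (cat in colnames(ind)) {
    for (lab in c("general", "tissue_specific"))
      cons[[length(cons) + 1L]] <-
        pair(d$label == lab & d$inside, d$label == lab & !d$inside,
             paste0(lab, "_inside_vs_outside"), cat)
    for (wh in c(TRUE, FALSE))
      cons[[length(cons) + 1L]] <-
        pair(d$label == "tissue_specific" & d$inside == wh,
             d$label == "general" & d$inside == wh,
             paste0("TS_vs_general_", if (wh) "inside" else "outside"), cat)
  }
  contrasts <- do.call(rbind, cons)
  contrasts$p_adj <- bh_fdr(contrasts$p)
  list(rates = rates, contrasts = contrasts)
}
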