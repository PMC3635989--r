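#' Pipeline run configuration
#'
#' All analysis thresholds in one place.
#'
#' @param disorder_threshold Column disorder-conservation threshold
#'   (default 0.30).
#' @param identity_threshold Column identity threshold (default 0.80).
#' @param crpkm_cutoff Expressed call cutoff (default 10).
#' @param min_samples,min_studies,min_wgs_samples Driver recurrence
#'   thresholds (defaults 5, 3, 3).
#' @param overlap_cutoff Enrichment-map edge cutoff (default 0.4).
#' @param alpha Significance level for directions/reports (default 0.05).
#' @param profile_window Positional profile half-width (default 10).
#' @param feature_halo Halo around features for the inside/outside
#'   stratification (default 0).
#' @param n_tissues Total tissues for the TS score (default 16).
#' @return List of class `run_config`.
#' @export
run_config <- function(disorder_threshold = 0.30, identity_threshold = 0.80,
                       crpkm_cutoff = 10, min_samples = 5L, min_studies = 3L,
                       min_wgs_samples = 3L, overlap_cutoff = 0.4,
                       alpha = 0.05, profile_window = 10L, feature_halo = 0L,
                       n_tissues = 16L) {
  stopifnot(disorder_threshold >= 0, disorder_threshold <= 1,
            identity_threshold >= 0, identity_threshold <= 1,
            crpkm_cutoff >= 0, overlap_cutoff >= 0, overlap_cutoff <= 1,
            alpha > 0, alpha < 1)
  structure(list(disorder_threshold = disorder_threshold,
                 identity_threshold = identity_threshold,
                 crpkm_cutoff = crpkm_cutoff, min_samples = min_samples,
                 min_studies = min_studies,
                 min_wgs_samples = min_wgs_samples,
                 overlap_cutoff = overlap_cutoff, alpha = alpha,
                 profile_window = profile_window,
                 feature_halo = feature_halo, n_tissues = n_tissues),
            class = "run_config")
}

#' Cross-reference the inputs of a run
#' @keywords internal
check_cross_references <- function(data) {
  prot_ids <- names(data$groups)
  bad <- setdiff(unique(data$exons$protein_id), prot_ids)
  if (length(bad))
    stop("exon protein(s) without a classified alignment group: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- setdiff(unique(data$mutations$gene_id), prot_ids)
  if (length(bad))
    stop("mutation gene(s) without a protein: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- setdiff(unique(data$features$protein_id), prot_ids)
  if (length(bad))
    stop("feature protein(s) without a protein: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(TRUE)
}

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

#' Run the full comparative-disorder pipeline
#'
#' Executes conservation -> expression -> splicing -> features ->
#' mutations -> enrichment over a dataset (a `disord_sim` or the list
#' returned by [read_sim_dataset()]), writes every stage table and a
#' six-section summary report under `out_dir`, and returns all results.
#' Reruns with the same inputs produce byte-identical outputs.
#'
#' @param data Input bundle: `groups`, `exons`, `features`, `mutations`,
#'   `rest_exome_nt`, `expression`, `annotations`, `bona_fide`.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(data, out_dir, config = run_config()) {
  check_cross_references(data)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(config)
  logf <- file.path(out_dir, "run.log")
  log_lines <- c(paste0("disordAS ", utils::packageVersion("disordAS"),
                        " config=", h),
                 paste0("thresholds: disorder=", config$disorder_threshold,
                        " identity=", config$identity_threshold,
                        " crpkm=", config$crpkm_cutoff,
                        " driver=", config$min_samples, "/",
                        config$min_studies, "/", config$min_wgs_samples,
                        " overlap=", config$overlap_cutoff,
                        " alpha=", config$alpha))
  emit <- function(df, name) {
    write_tsv(df, file.path(out_dir, name), h)
    log_lines <<- c(log_lines, paste0(name, ": ", nrow(df), " rows"))
  }

  ## stage 1: conservation
  residues <- do.call(rbind, lapply(data$groups, function(g)
    classify_group(g, disorder_threshold = config$disorder_threshold,
                   identity_threshold = config$identity_threshold)))
  rownames(residues) <- NULL
  composition <- protein_composition(residues)
  background <- proteome_background(residues)
  emit(residues, "residue_classification.tsv")
  emit(composition, "protein_composition.tsv")

  ## stage 2: expression and tissue specificity
  ex <- data$expression
  eff_tx <- effective_lengths(ex$transcripts)
  eff_gene <- stats::setNames(eff_tx, ex$tx2gene[names(eff_tx)])
  expr <- expression_table(ex$counts, ex$totals, eff_gene,
                           cutoff = config$crpkm_cutoff)
  tss <- ts_scores(expr, n_tissues = config$n_tissues)
  corr_flex <- ts_disorder_correlation(tss, composition, "flexible")
  corr_cons <- ts_disorder_correlation(tss, composition, "constrained")
  emit(expr, "expression.tsv")
  emit(tss, "ts_scores.tsv")

  ## stage 3: splicing
  summaries <- exon_summaries(data$exons, residues, data$groups)
  contrasts <- compare_exon_groups(summaries, background = background)
  func <- functional_protein_contrast(data$bona_fide, summaries)
  emit(summaries, "exon_summaries.tsv")
  emit(contrasts, "exon_contrasts.tsv")

  ## stage 4: features
  phospho <- data$features[data$features$kind == "phosphosite", , drop = FALSE]
  motifs <- data$features[data$features$kind == "motif", , drop = FALSE]
  profile <- if (nrow(phospho)) positional_profile(
    phospho, residues, window = config$profile_window) else NULL
  phospho_rate <- feature_rate_by_exon(data$exons, phospho)
  motif_rate <- feature_rate_by_exon(data$exons, motifs)
  strata <- rates_within_outside(data$exons, phospho, residues,
                                 halo = config$feature_halo)
  if (!is.null(profile)) emit(profile, "positional_profile.tsv")
  emit(phospho_rate$contrasts, "phospho_exon_contrasts.tsv")
  emit(motif_rate$contrasts, "motif_exon_contrasts.tsv")
  emit(strata$rates, "feature_strata.tsv")

  ## stage 5: mutations
  sites <- classify_sites(data$mutations, min_samples = config$min_samples,
                          min_studies = config$min_studies,
                          min_wgs_samples = config$min_wgs_samples)
  sites <- assign_region(sites, data$exons)
  region_summary <- mutation_region_summary(sites, data$exons,
                                            data$rest_exome_nt)
  test_rest <- neighborhood_ratio_test(sites, "rest")
  test_distal <- neighborhood_ratio_test(sites, "distal_C")
  emit(sites, "mutation_sites.tsv")
  emit(region_summary, "mutation_region_summary.tsv")

  ## stage 6: GO enrichment and map
  go_flex <- go_term_enrichment(composition, data$annotations, "flexible")
  go_cons <- go_term_enrichment(composition, data$annotations, "constrained")
  sig <- go_flex$term_id[go_flex$p_adjusted < config$alpha]
  members <- split(data$annotations$protein_id, data$annotations$term_id)
  map <- if (length(sig) >= 1L)
    build_enrichment_map(members[sig],
                         stats::setNames(go_flex$p_adjusted, go_flex$term_id),
                         cutoff = config$overlap_cutoff)
  else list(nodes = data.frame(), edges = data.frame())
  emit(go_flex, "go_enrichment_flexible.tsv")
  emit(go_cons, "go_enrichment_constrained.tsv")
  if (nrow(map$nodes)) {
    emit(map$nodes, "enrichment_map_nodes.tsv")
    emit(map$edges, "enrichment_map_edges.tsv")
  }

  ## report
  rep <- c(
    paste0("# disordAS pipeline report (config=", h, ")"),
    "",
    "## 1. Disorder category proportions",
    paste0("residues classified: ", nrow(residues)),
    paste0("background proportions: ",
           paste(names(background), fmt_num(background),
                 sep = "=", collapse = " ")),
    paste0("dominant-category protein counts: ",
           paste(names(table(composition$dominant_category)),
                 table(composition$dominant_category),
                 sep = "=", collapse = " ")),
    "",
    "## 2. Exon-group contrasts (alternative splicing)",
    utils::capture.output(print(contrasts, digits = 4)),
    paste0("functional-protein chi-squared p = ", fmt_num(func$chi2$p),
           "; flexible-in-A Wilcoxon p = ", fmt_num(func$wilcoxon$p)),
    "",
    "## 3. Tissue specificity vs disorder",
    paste0("Spearman rho (flexible) = ", fmt_num(corr_flex$rho),
           ", p = ", fmt_num(corr_flex$p), ", n = ", corr_flex$n),
    paste0("Spearman rho (constrained) = ", fmt_num(corr_cons$rho),
           ", p = ", fmt_num(corr_cons$p)),
    "",
    "## 4. Phosphosites and linear motifs",
    if (!is.null(profile)) {
      peak <- profile[profile$category == "constrained_disorder", ]
      paste0("constrained profile peak at offset ",
             peak$offset[which.max(peak$rate)])
    } else "no phosphosites",
    utils::capture.output(print(phospho_rate$contrasts, digits = 4)),
    utils::capture.output(print(motif_rate$contrasts, digits = 4)),
    "",
    "## 5. Disorder within/outside features",
    utils::capture.output(print(strata$rates, digits = 4)),
    "",
    "## 6. Cancer mutations",
    utils::capture.output(print(region_summary, digits = 4)),
    paste0("neighborhood vs rest: ratio-of-ratios = ",
           fmt_num(test_rest$ratio_of_ratios), ", chi2 = ",
           fmt_num(test_rest$statistic), ", p = ", fmt_num(test_rest$p)),
    paste0("neighborhood vs distal: ratio-of-ratios = ",
           fmt_num(test_distal$ratio_of_ratios), ", chi2 = ",
           fmt_num(test_distal$statistic), ", p = ",
           fmt_num(test_distal$p)))
  writeLines(rep, file.path(out_dir, "report.txt"))
  writeLines(log_lines, logf)

  invisible(list(residues = residues, composition = composition,
                 background = background, expression = expr,
                 ts_scores = tss, ts_correlation = list(flexible = corr_flex,
                                                        constrained = corr_cons),
                 exon_summaries = summaries, exon_contrasts = contrasts,
                 functional = func, profile = profile,
                 phospho_rate = phospho_rate, motif_rate = motif_rate,
                 strata = strata, mutation_sites = sites,
                 mutation_region_summary = region_summary,
                 mutation_tests = list(rest = test_rest,
                                       distal = test_distal),
                 go = list(flexible = go_flex, constrained = go_cons),
                 enrichment_map = map))
}
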