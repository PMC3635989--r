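small_cfg <- function(seed = 1,
                      mutation_model = list(
                        n_sites = 150L, driver_site_fraction = 0.2,
                        neighborhood_rel_rate = 5,
                        wgs_study_fraction = 0.3, n_studies = 10L,
                        wgs_path_fraction = 0.4,
                        driver_samples_range = c(5L, 9L),
                        driver_studies_range = c(3L, 4L),
                        wgs_driver_samples_range = c(3L, 5L)), ...) {
  sim_config(seed = seed, n_groups = 6L, n_species = 8L,
             protein_length_range = c(250L, 300L),
             exon_model = list(n_ts_events = 2L, n_general_events = 4L,
                               n_distal_per_protein = 1L,
                               exon_length_range = c(20L, 40L),
                               max_events_per_protein = 1L),
             mutation_model = mutation_model,
             ...)
}

test_that("configuration validation rejects invalid settings", {
  expect_error(sim_config(n_species = 1L), "invalid-config")
  expect_error(sim_config(gap_rate = 1.5), "invalid-config")
  expect_error(sim_config(background_rates = c(constrained = 0.9,
                                               flexible = 0.9,
                                               nonconserved = 0)),
               "invalid-config")
  fm <- sim_config()$feature_model
  fm$phospho_density["C1"] <- 1.2  # more than one feature per residue
  expect_error(sim_config(feature_model = fm), "invalid-config")
})

test_that("identical seed and config reproduce identical datasets", {
  a <- suppressWarnings(simulate_dataset(small_cfg(11)))
  b <- suppressWarnings(simulate_dataset(small_cfg(11)))
  expect_identical(a$groups, b$groups)
  expect_identical(a$features, b$features)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$expression, b$expression)
  c2 <- suppressWarnings(simulate_dataset(small_cfg(12)))
  expect_false(identical(a$groups, c2$groups))
})

test_that("degenerate probabilities give perfectly conserved columns", {
  dsm <- sim_config()$disorder_segment_model
  dsm$constrained$identity <- 1.0
  dsm$constrained$cons_of_disorder <- 1.0
  cfg <- small_cfg(21, disorder_segment_model = dsm, gap_rate = 0,
                   background_rates = c(constrained = 1, flexible = 0,
                                        nonconserved = 0))
  out <- generate_alignment_group(cfg, 1)
  cs <- column_scores(out$group)
  planted <- out$truth$category == "constrained_disorder"
  expect_true(all(cs$identity_fraction[planted] == 1))
  expect_true(all(cs$disorder_fraction[planted] == 1))
})

test_that("planted per-column identity is recovered on average", {
  dsm <- sim_config()$disorder_segment_model
  dsm$flexible$identity <- 0.5
  means <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, n_groups = 1L, n_species = 22L,
                      protein_length_range = c(50L, 50L), gap_rate = 0,
                      disorder_segment_model = dsm,
                      background_rates = c(constrained = 0, flexible = 1,
                                           nonconserved = 0),
                      exon_model = list(n_ts_events = 0L,
                                        n_general_events = 0L,
                                        n_distal_per_protein = 0L,
                                        exon_length_range = c(20L, 40L),
                                        max_events_per_protein = 1L))
    out <- generate_alignment_group(cfg, 1)
    mean(column_scores(out$group)$identity_fraction)
  }, numeric(1))
  expect_true(all(means > 0.4 & means < 0.6))
  expect_true(abs(mean(means) - 0.5) < 0.05)
})

test_that("exon models are structurally sound and respect requested counts", {
  cfg <- small_cfg(31)
  exons <- suppressWarnings(generate_exon_models(cfg))
  ev <- split(exons$role[!is.na(exons$event_id)],
              exons$event_id[!is.na(exons$event_id)])
  # no orphan A exons: every event carries exactly C1, A, C2
  expect_true(all(vapply(ev, function(r)
    identical(sort(r), c("A", "C1", "C2")), logical(1))))
  # adjacency and disjointness within each event
  for (e in unique(stats::na.omit(exons$event_id))) {
    trio <- exons[!is.na(exons$event_id) & exons$event_id == e, ]
    trio <- trio[match(c("C1", "A", "C2"), trio$role), ]
    expect_equal(trio$start_res[2], trio$end_res[1] + 1L)
    expect_equal(trio$start_res[3], trio$end_res[2] + 1L)
  }
  n_ts <- length(unique(exons$event_id[exons$label == "tissue_specific"]))
  n_gen <- length(unique(exons$event_id[exons$label == "general"]))
  expect_lte(n_ts, 2L); expect_lte(n_gen, 4L)
  # nt length permits split codons at both ends
  expect_true(all(exons$nt_length >=
                    3L * (exons$end_res - exons$start_res + 1L) - 2L))
  # a config whose events cannot fit warns and skips
  tiny <- sim_config(seed = 32, n_groups = 2L,
                     protein_length_range = c(60L, 60L),
                     exon_model = list(n_ts_events = 5L,
                                       n_general_events = 5L,
                                       n_distal_per_protein = 0L,
                                       exon_length_range = c(20L, 40L),
                                       max_events_per_protein = 3L))
  expect_warning(sim_plan(tiny), "skipped")
})

test_that("ground truth covers every generated entity exactly once", {
  sim <- suppressWarnings(simulate_dataset(small_cfg(41)))
  expect_equal(nrow(sim$truth$residues),
               sum(sim$plan$proteins$length))
  expect_equal(nrow(sim$truth$genes), length(sim$groups))
  # one truth row per distinct mutation site
  key_t <- paste(sim$truth$mutation_sites$gene_id,
                 sim$truth$mutation_sites$protein_pos)
  expect_false(anyDuplicated(key_t) > 0)
  key_r <- unique(paste(sim$mutations$gene_id, sim$mutations$protein_pos))
  expect_setequal(key_r, key_t)
  # disorder tracks cover every species' ungapped sequence exactly
  for (g in sim$groups[1:2]) {
    ungapped <- rowSums(g$aln != "-")
    expect_equal(vapply(g$tracks, length, 1L), unname(ungapped))
  }
})

test_that("feature generation respects densities, bounds and empty configs", {
  cfg <- small_cfg(51)
  feats <- suppressWarnings(generate_features(cfg))
  lens <- setNames(sim_plan(cfg)$proteins$length,
                   sim_plan(cfg)$proteins$protein_id)
  expect_true(all(feats$start_res >= 1))
  expect_true(all(feats$end_res <= lens[feats$protein_id]))
  expect_true(all(feats$end_res >= feats$start_res))
  fm <- cfg$feature_model
  fm$phospho_density[] <- 0; fm$motif_density[] <- 0
  cfg0 <- small_cfg(51, feature_model = fm)
  expect_equal(nrow(suppressWarnings(generate_features(cfg0))), 0L)
})

test_that("planted recurrence round-trips through the driver classifier", {
  cfg <- small_cfg(61)
  mut <- suppressWarnings(generate_mutations(cfg))
  sites <- classify_sites(mut$records)
  key <- paste(sites$gene_id, sites$protein_pos)
  truth <- setNames(mut$truth$planted_call,
                    paste(mut$truth$gene_id, mut$truth$protein_pos))
  expect_equal(unname(truth[key]), sites$call)
  # zero mutations: empty table
  mm <- cfg$mutation_model; mm$n_sites <- 0L
  cfg0 <- small_cfg(61, mutation_model = mm)
  expect_equal(nrow(suppressWarnings(generate_mutations(cfg0))$records), 0L)
})

test_that("expression round-trips planted tissue breadth through the cRPKM call", {
  cfg <- small_cfg(71)
  expr <- suppressWarnings(generate_expression(cfg))
  eff <- effective_lengths(expr$transcripts)
  eff_gene <- setNames(eff, expr$tx2gene[names(eff)])
  tab <- expression_table(expr$counts, expr$totals, eff_gene)
  tss <- ts_scores(tab)
  m <- merge(tss, expr$truth, by = "gene_id")
  expect_gte(mean(m$t == m$t_true), 0.95)
  if (any(m$t_true == 1 & m$t == 1))
    expect_true(all(m$score[m$t_true == 1 & m$t == 1] == 1))
})

test_that("duplicated transcript blocks reduce effective length", {
  em <- sim_config()$expression_model
  em$duplicate_pair_fraction <- 1
  cfg <- small_cfg(81, expression_model = em)
  expr <- suppressWarnings(generate_expression(cfg))
  eff <- effective_lengths(expr$transcripts)
  tl <- nchar(expr$transcripts[1])
  expect_true(all(eff < tl - 49L))
  # full duplication: every window multimaps
  tx <- expr$transcripts[1]
  expect_equal(unname(effective_lengths(c(a = unname(tx), b = unname(tx)))),
               c(0L, 0L))
})

test_that("planted exon class-rate differences are recovered from the alignments", {
  cfg <- sim_config(seed = 91, n_groups = 30L, n_species = 12L,
                    protein_length_range = c(260L, 300L),
                    exon_model = list(n_ts_events = 15L,
                                      n_general_events = 15L,
                                      n_distal_per_protein = 0L,
                                      exon_length_range = c(20L, 40L),
                                      max_events_per_protein = 1L))
  sim <- suppressWarnings(simulate_dataset(cfg))
  residues <- do.call(rbind, lapply(sim$groups, classify_group))
  summaries <- exon_summaries(sim$exons, residues)
  flex_ts <- mean(summaries$p_flexible[summaries$role == "A" &
                                       summaries$label == "tissue_specific"])
  flex_gen <- mean(summaries$p_flexible[summaries$role == "A" &
                                        summaries$label == "general"])
  expect_gte(flex_ts - flex_gen, 0.2)  # planted 0.5 vs 0.2
})
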