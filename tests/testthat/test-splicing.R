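# Minimal classified fixture: one protein, hand-set categories.
fixture_residues <- function(categories, protein_id = "P1") {
  data.frame(protein_id = protein_id,
             residue_pos = seq_along(categories),
             column_index = seq_along(categories),
             category = categories, stringsAsFactors = FALSE)
}

exon_row <- function(exon_id, start, end, role = "A", label = "general",
                     protein_id = "P1", event_id = "EV1") {
  data.frame(exon_id = exon_id, event_id = event_id,
             protein_id = protein_id, role = role, label = label,
             start_res = start, end_res = end,
             nt_length = 3L * (end - start + 1L), stringsAsFactors = FALSE)
}

test_that("split codons go to the exon holding the first nucleotide", {
  expect_equal(codon_interval(1, 90), list(start_res = 1L, end_res = 30L))
  # nt 91 starts codon 31, so a 91-nt exon gains residue 31
  expect_equal(codon_interval(1, 91), list(start_res = 1L, end_res = 31L))
  expect_equal(codon_interval(92, 180), list(start_res = 32L, end_res = 60L))
  # any exon of >= 3 nt owns at least one codon start
  for (s in 1:9) {
    iv <- codon_interval(s, s + 2)
    expect_gte(iv$end_res, iv$start_res)
  }
})

test_that("exon summaries report category proportions and gap rates", {
  cats <- c(rep("flexible_disorder", 10), rep("ordered", 10))
  res <- fixture_residues(cats)
  ex <- exon_row("E1", 1, 20)
  s <- exon_summaries(ex, res)
  expect_equal(s$p_flexible, 0.5)
  expect_equal(s$p_ordered, 0.5)
  expect_equal(s$p_disorder, 0.5)
  expect_equal(s$n_residues, 20L)
  expect_true(is.na(s$gap_rate))

  # gap rate: mean of per-column gap fractions over the exon's columns
  g <- make_group(c("AD", "A-", "AC", "AW"),
                  c("DD", "D", "DD", "DD"), group_id = "P1")
  res2 <- classify_group(g, protein_id = "P1")
  ex2 <- exon_row("E2", 1, 2)
  s2 <- exon_summaries(ex2, res2, groups = list(P1 = g))
  expect_equal(s2$gap_rate, mean(c(0, 0.25)))

  # an exon with no classified residues is dropped with a warning
  ex3 <- rbind(ex, exon_row("E9", 100, 120))
  expect_warning(out <- exon_summaries(ex3, res), "E9")
  expect_equal(out$exon_id, "E1")
})

test_that("proteome background is residue-weighted over all proteins", {
  res <- rbind(fixture_residues(rep("flexible_disorder", 30), "P1"),
               fixture_residues(rep("ordered", 70), "P2"))
  bg <- proteome_background(res)
  expect_equal(unname(bg["flexible"]), 0.3)
  expect_equal(unname(bg["disorder"]), 0.3)
  expect_equal(unname(bg["ordered"]), 0.7)
})

test_that("group contrasts are symmetric and recover a planted difference", {
  set.seed(77)
  mk_sum <- function(n, p, role, label) {
    data.frame(exon_id = sprintf("%s_%s_%d", role, label, 1:n), role = role,
               label = label, p_flexible = rbinom(n, 40, p) / 40,
               stringsAsFactors = FALSE)
  }
  summaries <- rbind(mk_sum(60, 0.5, "A", "tissue_specific"),
                     mk_sum(60, 0.2, "A", "general"))
  ct <- list(list(name = "ts_vs_gen", metric = "p_flexible",
                  role1 = "A", label1 = "tissue_specific",
                  role2 = "A", label2 = "general"))
  res <- compare_exon_groups(summaries, ct)
  expect_lt(res$p, 1e-4)
  expect_equal(res$direction, "up")
  # swapped groups: mirrored statistic, identical p
  ct_sw <- list(list(name = "gen_vs_ts", metric = "p_flexible",
                     role1 = "A", label1 = "general",
                     role2 = "A", label2 = "tissue_specific"))
  res_sw <- compare_exon_groups(summaries, ct_sw)
  expect_equal(res$p, res_sw$p)
  expect_equal(res$statistic + res_sw$statistic, 60 * 60)
  # an empty group is a named error
  ct_bad <- list(list(name = "x", metric = "p_flexible", role1 = "C1",
                      label1 = "tissue_specific", role2 = "A",
                      label2 = "general"))
  expect_error(compare_exon_groups(summaries, ct_bad), "C1")
})

test_that("background contrasts use the one-sample signed-rank route", {
  set.seed(78)
  summaries <- data.frame(exon_id = sprintf("e%d", 1:50), role = "A",
                          label = "tissue_specific",
                          p_disorder = rbinom(50, 40, 0.6) / 40,
                          stringsAsFactors = FALSE)
  bg <- c(disorder = 0.25)
  ct <- list(list(name = "vs_bg", metric = "p_disorder", role1 = "A",
                  label1 = "tissue_specific", background = TRUE))
  res <- compare_exon_groups(summaries, ct, background = bg)
  expect_lt(res$p, 1e-6)
  expect_equal(res$direction, "up")
})

test_that("functional-protein contrast preserves contingency totals", {
  set.seed(79)
  n <- 40
  summaries <- data.frame(
    exon_id = sprintf("e%d", 1:n), role = "A",
    label = rep(c("tissue_specific", "general"), each = n / 2),
    protein_id = sprintf("P%02d", 1:n),
    p_flexible = runif(n), stringsAsFactors = FALSE)
  flags <- data.frame(protein_id = sprintf("P%02d", 1:n),
                      bona_fide = rep(c(TRUE, FALSE), n / 2),
                      stringsAsFactors = FALSE)
  out <- functional_protein_contrast(flags, summaries)
  expect_equal(sum(out$table), n)
  expect_equal(out$wilcoxon$n1 + out$wilcoxon$n2, n)
  expect_true(out$chi2$p >= 0 && out$chi2$p <= 1)
})

test_that("null and planted functional contrasts behave as expected", {
  set.seed(80)
  rej_null <- 0; rej_planted <- 0
  n_runs <- 40
  for (r in 1:n_runs) {
    n <- 300
    hosts_ts <- rep(c(TRUE, FALSE), each = n / 2)
    # null: flag independent of hosting a TS event
    flag_null <- runif(n) < 0.3
    tab <- table(factor(flag_null, levels = c(TRUE, FALSE)),
                 factor(hosts_ts, levels = c(TRUE, FALSE)))
    if (chi_squared_2x2(tab)$p < 0.05) rej_null <- rej_null + 1
    # planted: 2-fold enrichment of the flag among TS hosts
    flag_pl <- runif(n) < ifelse(hosts_ts, 0.5, 0.25)
    tab2 <- table(factor(flag_pl, levels = c(TRUE, FALSE)),
                  factor(hosts_ts, levels = c(TRUE, FALSE)))
    if (chi_squared_2x2(tab2)$p < 0.05) rej_planted <- rej_planted + 1
  }
  expect_lte(rej_null / n_runs, 0.15)
  expect_gte(rej_planted / n_runs, 0.9)
})
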