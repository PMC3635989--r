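test_that("identity fraction counts the modal amino acid over all rows", {
  expect_equal(identity_fraction(c("A", "A", "A", "A")), 1.0)
  expect_equal(identity_fraction(c("A", "A", "A", "G")), 0.75)
  # gaps stay in the denominator but are never a type
  expect_equal(identity_fraction(c("A", "A", "-", "G")), 0.5)
  expect_equal(identity_fraction(c("-", "-", "-")), 0)
  expect_error(identity_fraction(character(0)), "non-empty")
})

test_that("disorder fraction is reference-anchored and gap-free", {
  expect_equal(disorder_fraction(c("A", "A", "A", "A"),
                                 c("D", "D", "O", "D")), 0.75)
  expect_equal(disorder_fraction(c("A", "A", "A"), c("D", "D", "D")), 1.0)
  # an ordered reference counts rows sharing the ordered state
  expect_equal(disorder_fraction(c("A", "A", "A", "A"),
                                 c("O", "O", "O", "D")), 0.75)
  # gap rows drop out of numerator and denominator
  expect_equal(disorder_fraction(c("A", "-", "A", "A"),
                                 c("D", NA, "O", "D")), 2 / 3)
  expect_error(disorder_fraction(c("-", "A"), c(NA, "D")),
               "reference")
})

test_that("bin maps reproduce the verbal thresholds", {
  expect_identical(bin_scores(0.80, 0.30), list(A_bin = 9L, D_bin = 3L))
  expect_identical(bin_scores(0.79, 0.29), list(A_bin = 8L, D_bin = 2L))
  expect_identical(bin_scores(1.0, 1.0), list(A_bin = 10L, D_bin = 10L))
  expect_identical(bin_scores(0, 0), list(A_bin = 1L, D_bin = 0L))
  expect_error(bin_scores(1.2, 0.5), "\\[0, 1\\]")
})

test_that("residue classification follows the four-way rule", {
  expect_equal(classify_residue(TRUE, 0.85, 0.35), "constrained_disorder")
  expect_equal(classify_residue(TRUE, 0.50, 0.35), "flexible_disorder")
  expect_equal(classify_residue(TRUE, 0.95, 0.10), "nonconserved_disorder")
  expect_equal(classify_residue(FALSE, 0.95, 0.95), "ordered")
  # boundaries are inclusive
  expect_equal(classify_residue(TRUE, 0.80, 0.30), "constrained_disorder")
  expect_equal(classify_residue(TRUE, 0.7999, 0.30), "flexible_disorder")
})

test_that("classify_group matches the naive column-recount oracle", {
  set.seed(42)
  for (i in 1:20) {
    g <- random_group(sample(2:12, 1), sample(10:40, 1))
    got <- classify_group(g)
    want <- oracle_classify(g)
    expect_equal(got$category, want$category)
    expect_equal(got$identity_fraction, want$identity_fraction)
    expect_equal(got$disorder_fraction, want$disorder_fraction)
    expect_equal(got$column_index, want$column_index)
  }
})

test_that("every reference residue gets exactly one category", {
  g <- random_group(8, 60, seed = 7)
  res <- classify_group(g)
  ref_len <- sum(g$aln[1, ] != "-")
  expect_equal(nrow(res), ref_len)
  expect_true(all(res$category %in% c("constrained_disorder",
                                      "flexible_disorder",
                                      "nonconserved_disorder", "ordered")))
  comp <- protein_composition(res)
  expect_equal(comp$length, ref_len)
  expect_equal(comp$n_constrained + comp$n_flexible + comp$n_nonconserved +
                 comp$n_ordered, ref_len)
  expect_equal(comp$p_constrained + comp$p_flexible + comp$p_nonconserved +
                 comp$p_ordered, 1, tolerance = 1e-9)
})

test_that("raising thresholds moves counts monotonically", {
  g <- random_group(15, 120, gap_p = 0.05, seed = 11)
  count <- function(a_th, d_th) {
    r <- classify_group(g, identity_threshold = a_th,
                        disorder_threshold = d_th)
    c(con = sum(r$category == "constrained_disorder"),
      fle = sum(r$category == "flexible_disorder"))
  }
  a_grid <- seq(0.2, 1, by = 0.1)
  prev <- count(a_grid[1], 0.3)
  for (a in a_grid[-1]) {
    cur <- count(a, 0.3)
    expect_lte(cur["con"], prev["con"])
    expect_gte(cur["fle"], prev["fle"])
    prev <- cur
  }
  d_grid <- seq(0.1, 1, by = 0.1)
  prev_cd <- sum(count(0.8, d_grid[1]))
  for (d in d_grid[-1]) {
    cur_cd <- sum(count(0.8, d))
    expect_lte(cur_cd, prev_cd)
    prev_cd <- cur_cd
  }
})

test_that("an all-gap row leaves disorder fractions unchanged and can only lower identity", {
  g <- make_group(c("ADKL", "ADRL", "AGKL"),
                  c("DDOO", "DDOO", "DOOO"))
  base <- column_scores(g)
  g2 <- make_group(c("ADKL", "ADRL", "AGKL", "----"),
                   c("DDOO", "DDOO", "DOOO", ""))
  aug <- column_scores(g2)
  expect_equal(aug$disorder_fraction, base$disorder_fraction)
  expect_true(all(aug$identity_fraction <= base$identity_fraction))
})

test_that("dominant category ties break constrained > flexible > nonconserved > ordered", {
  res <- data.frame(protein_id = "P1", residue_pos = 1:4,
                    category = c("constrained_disorder", "flexible_disorder",
                                 "constrained_disorder", "flexible_disorder"),
                    stringsAsFactors = FALSE)
  expect_equal(protein_composition(res)$dominant_category,
               "constrained_disorder")
  res_all_ord <- data.frame(protein_id = "P2", residue_pos = 1:5,
                            category = rep("ordered", 5),
                            stringsAsFactors = FALSE)
  comp <- protein_composition(res_all_ord)
  expect_equal(comp$p_ordered, 1)
  expect_equal(comp$dominant_category, "ordered")
})

test_that("ortholog filtering applies the CCDS and >15-eukaryote rules", {
  mk <- function(pid, n_orth) {
    data.frame(protein_id = pid,
               ortholog_id = sprintf("o%02d", seq_len(n_orth)),
               species = sprintf("sp%02d", seq_len(n_orth)),
               e_value = 1e-40, eukaryote = TRUE, stringsAsFactors = FALSE)
  }
  cand <- rbind(mk("P15", 15), mk("P16", 16), mk("PnoCCDS", 20))
  ccds <- c(P15 = TRUE, P16 = TRUE, PnoCCDS = FALSE)
  out <- filter_orthologs(cand, ccds)
  expect_identical(out$proteins, "P16")

  # lowest e-value wins a many-mapping; ties go lexicographic
  many <- data.frame(protein_id = "P1", ortholog_id = c("oB", "oA", "oC"),
                     species = "sp01", e_value = c(1e-50, 1e-30, 1e-50),
                     eukaryote = TRUE, stringsAsFactors = FALSE)
  res <- filter_orthologs(many, c(P1 = TRUE), min_orthologs = 0L)
  expect_equal(res$orthologs$ortholog_id, "oB")
  many$e_value[1] <- NA
  expect_error(filter_orthologs(many, c(P1 = TRUE)), "e-value")
})

test_that("cross-species agreement counts jointly disordered aligned pairs", {
  dis <- "flexible_disorder"; ord <- "ordered"
  expect_equal(cross_species_agreement(c(dis, dis, ord), c(dis, dis, ord)), 1)
  expect_equal(cross_species_agreement(c(dis, ord), c(ord, dis)), 0)
  # brute-force check on random toys
  set.seed(3)
  cats <- c("constrained_disorder", "flexible_disorder",
            "nonconserved_disorder", "ordered")
  for (i in 1:25) {
    n <- sample(5:30, 1)
    a <- sample(c(cats, NA), n, replace = TRUE)
    b <- sample(c(cats, NA), n, replace = TRUE)
    both <- !is.na(a) & !is.na(b)
    da <- both & a != "ordered"
    db <- both & b != "ordered"
    denom <- sum(da | db)
    if (denom == 0) next
    expect_equal(cross_species_agreement(a, b), sum(da & db) / denom)
  }
})
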