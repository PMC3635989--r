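fixture_res <- function(categories, protein_id = "P1") {
  data.frame(protein_id = protein_id,
             residue_pos = seq_along(categories),
             column_index = seq_along(categories),
             category = categories, stringsAsFactors = FALSE)
}

site_row <- function(pos, protein_id = "P1", kind = "phosphosite",
                     end = pos) {
  data.frame(protein_id = protein_id, kind = kind, start_res = pos,
             end_res = end, source = "synthetic", stringsAsFactors = FALSE)
}

test_that("positional profile peaks where the planted class sits", {
  # constrained exactly at site positions, flexible in the +/-3 flanks
  cats <- rep("ordered", 60)
  sites_at <- c(10, 25, 40)
  for (p in sites_at) {
    cats[p] <- "constrained_disorder"
    cats[setdiff((p - 3):(p + 3), p)] <- "flexible_disorder"
  }
  res <- fixture_res(cats)
  sites <- do.call(rbind, lapply(sites_at, site_row))
  prof <- positional_profile(sites, res, window = 5)
  con <- prof[prof$category == "constrained_disorder", ]
  expect_equal(con$offset[which.max(con$rate)], 0)
  expect_equal(con$rate[con$offset == 0], 1)
  fle <- prof[prof$category == "flexible_disorder", ]
  expect_true(all(fle$rate[abs(fle$offset) %in% 1:3] == 1))
  expect_equal(fle$rate[fle$offset == 0], 0)
  expect_error(positional_profile(sites[0, ], res), "no sites")
})

test_that("profile offsets outside the protein drop from numerator and denominator", {
  res <- fixture_res(rep("flexible_disorder", 10))
  prof <- positional_profile(site_row(2), res, window = 4)
  n <- prof$n[prof$category == "ordered"]  # same n for all categories
  expect_equal(n[prof$offset[prof$category == "ordered"] == -4], 0L)
  expect_equal(n[prof$offset[prof$category == "ordered"] == -1], 1L)
  fle <- prof[prof$category == "flexible_disorder", ]
  expect_true(all(fle$rate[fle$n > 0] == 1))
  expect_true(all(is.na(fle$rate[fle$n == 0])))
})

test_that("feature density per exon is bounded and contrasts detect planted ratios", {
  set.seed(55)
  # 60 exons per role on one long protein, planted 3x density in C1
  n_per <- 60; elen <- 30L
  mk <- function(role, offset) {
    data.frame(exon_id = sprintf("%s_%d", role, 1:n_per),
               event_id = NA_character_, protein_id = "P1", role = role,
               label = "general",
               start_res = offset + (0:(n_per - 1)) * elen + 1L,
               end_res = offset + (1:n_per) * elen,
               nt_length = 3L * elen, stringsAsFactors = FALSE)
  }
  exons <- rbind(mk("C1", 0L), mk("A", n_per * elen),
                 mk("C2", 2L * n_per * elen), mk("distal_C", 3L * n_per * elen))
  l <- 4L * n_per * elen
  dens <- ifelse(seq_len(l) <= n_per * elen, 0.15, 0.05)
  pos <- which(runif(l) < dens)
  sites <- do.call(rbind, lapply(pos, site_row))
  out <- feature_rate_by_exon(exons, sites)
  expect_true(all(out$densities$density >= 0 & out$densities$density <= 1))
  c1 <- out$contrasts[out$contrasts$contrast == "C1_vs_distal", ]
  a <- out$contrasts[out$contrasts$contrast == "A_vs_distal", ]
  expect_lt(c1$p, 0.01)
  expect_equal(c1$direction, "up")
  expect_gt(a$p, 0.01)  # A planted at the distal rate
  # realized count ratio C1 : A near the planted 3x
  ratio <- sum(out$densities$n_feature_residues[out$densities$role == "C1"]) /
    sum(out$densities$n_feature_residues[out$densities$role == "A"])
  expect_gt(ratio, 2); expect_lt(ratio, 4)
  # zero features: all densities zero
  out0 <- feature_rate_by_exon(exons, sites[0, ])
  expect_true(all(out0$densities$density == 0))
})

test_that("within/outside strata partition exon residues", {
  set.seed(56)
  cats <- sample(c("constrained_disorder", "flexible_disorder", "ordered"),
                 200, replace = TRUE)
  res <- fixture_res(cats)
  exons <- rbind(
    data.frame(exon_id = "a1", event_id = "E1", protein_id = "P1",
               role = "A", label = "tissue_specific", start_res = 1L,
               end_res = 100L, nt_length = 300L, stringsAsFactors = FALSE),
    data.frame(exon_id = "a2", event_id = "E2", protein_id = "P1",
               role = "A", label = "general", start_res = 101L,
               end_res = 200L, nt_length = 300L, stringsAsFactors = FALSE))
  sites <- do.call(rbind, lapply(c(5, 20, 60, 110, 150), site_row))
  out <- rates_within_outside(exons, sites, res)
  tot <- tapply(out$rates$n[out$rates$category == "disorder"],
                out$rates$label[out$rates$category == "disorder"], sum)
  expect_equal(as.integer(tot[c("tissue_specific", "general")]),
               c(100L, 100L))
  ins <- out$rates[out$rates$where == "inside" &
                   out$rates$category == "disorder", ]
  expect_equal(sum(ins$n), 5L)
  # planted recovery: inside rate follows the categories at site residues
  inside_cats <- cats[c(5, 20, 60, 110, 150)]
  expect_equal(sum(ins$rate * ins$n) / sum(ins$n),
               mean(inside_cats != "ordered"))
})

test_that("pooled profile at offset zero equals the inside-feature rate", {
  set.seed(57)
  cats <- sample(c("constrained_disorder", "flexible_disorder",
                   "nonconserved_disorder", "ordered"), 300, replace = TRUE)
  res <- fixture_res(cats)
  exons <- data.frame(exon_id = c("a1", "a2"), event_id = c("E1", "E2"),
                      protein_id = "P1", role = "A",
                      label = c("tissue_specific", "general"),
                      start_res = c(1L, 151L), end_res = c(150L, 300L),
                      nt_length = 450L, stringsAsFactors = FALSE)
  pos <- sample(300, 25)
  sites <- do.call(rbind, lapply(pos, site_row))
  prof <- positional_profile(sites, res, window = 3)
  out <- rates_within_outside(exons, sites, res)
  ins <- out$rates[out$rates$where == "inside", ]
  for (catname in c("constrained", "flexible")) {
    full <- paste0(ifelse(catname == "constrained", "constrained_disorder",
                          "flexible_disorder"))
    p0 <- prof$rate[prof$offset == 0 & prof$category == full]
    sub <- ins[ins$category == catname, ]
    expect_equal(p0, sum(sub$rate * sub$n) / sum(sub$n))
  }
})
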