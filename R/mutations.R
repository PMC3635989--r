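#' Aggregate mutation records and call driver versus passenger sites
#'
#' Records are collapsed to one per (sample, site); a site is keyed by
#' (gene, protein position, alternate amino acid) by default, or by
#' (gene, position) when `key_by_alt = FALSE`. A site is a driver when it
#' recurs in at least `min_samples` distinct samples from at least
#' `min_studies` distinct studies, or in at least `min_wgs_samples`
#' distinct samples from whole-genome screening studies; every other site
#' is a passenger, so the two calls partition all sites.
#'
#' @param records Data frame: `gene_id`, `protein_pos`, `aa_ref`,
#'   `aa_alt`, `sample_id`, `study_id`, `screen_type`
#'   (`whole_genome`/`targeted`).
#' @param min_samples,min_studies,min_wgs_samples Recurrence thresholds
#'   (defaults 5, 3, 3).
#' @param key_by_alt Keep distinct substitutions at one codon as distinct
#'   sites (default TRUE).
#' @return Data frame with one row per site: `gene_id`, `protein_pos`,
#'   `aa_alt` (NA when `key_by_alt = FALSE`), `n_samples`, `n_studies`,
#'   `n_wgs_samples`, `call`.
#' @export
classify_sites <- function(records, min_samples = 5L, min_studies = 3L,
                           min_wgs_samples = 3L, key_by_alt = TRUE) {
  if (nrow(records) == 0L)
    return(data.frame(gene_id = character(), protein_pos = integer(),
                      aa_alt = character(), n_samples = integer(),
                      n_studies = integer(), n_wgs_samples = integer(),
                      call = character(), stringsAsFactors = FALSE))
  stopifnot(all(records$screen_type %in% c("whole_genome", "targeted")),
            all(records$protein_pos >= 1L),
            all(records$aa_ref != records$aa_alt))
  key <- if (key_by_alt)
    paste(records$gene_id, records$protein_pos, records$aa_alt, sep = "\r")
  else paste(records$gene_id, records$protein_pos, sep = "\r")
  keep <- !duplicated(paste(key, records$sample_id, sep = "\r"))
  records <- records[keep, , drop = FALSE]
  key <- key[keep]
  first <- !duplicated(key)
  sites <- data.frame(gene_id = records$gene_id[first],
                      protein_pos = records$protein_pos[first],
                      aa_alt = if (key_by_alt) records$aa_alt[first]
                               else NA_character_,
                      stringsAsFactors = FALSE)
  o <- order(sites$gene_id, sites$protein_pos, sites$aa_alt,
             method = "radix")
  sites <- sites[o, , drop = FALSE]
  f <- factor(key, levels = key[first][o])
  # one row per (site, sample) after collapsing, so samples are row counts
  sites$n_samples <- as.integer(table(f))
  study_first <- !duplicated(paste(key, records$study_id, sep = "\r"))
  sites$n_studies <- as.integer(table(f[study_first]))
  sites$n_wgs_samples <-
    as.integer(table(f[records$screen_type == "whole_genome"]))
  rownames(sites) <- NULL
  out <- sites
  out$call <- ifelse(
    (out$n_samples >= min_samples & out$n_studies >= min_studies) |
      out$n_wgs_samples >= min_wgs_samples, "driver", "passenger")
  out
}

#' Assign each mutation site to an exon-region class
#'
#' Containment of the protein position in an exon interval, with priority
#' A > C1 > C2 > distal_C when models overlap; positions in no exon fall
#' in `rest`.
#'
#' @param sites Site table from [classify_sites()].
#' @param exons Exon model data frame (protein ids match the sites'
#'   gene ids).
#' @return `sites` with an added `region` column.
#' @export
assign_region <- function(sites, exons) {
  prio <- c("A", "C1", "C2", "distal_C")
  ex_split <- split(exons, exons$protein_id)
  sites$region <- vapply(seq_len(nrow(sites)), function(i) {
    e <- ex_split[[sites$gene_id[i]]]
    if (is.null(e)) return("rest")
    hit <- e$role[sites$protein_pos[i] >= e$start_res &
                  sites$protein_pos[i] <= e$end_res]
    if (length(hit) == 0L) return("rest")
    prio[min(match(hit, prio))]
  }, character(1))
  sites
}

#' Mutation density per 10 kb
#'
#' @param count Number of sites of the relevant call in the region class.
#' @param nt_length Total nucleotide length of the region class.
#' @return Sites per 10,000 nt.
#' @export
density_per_10kb <- function(count, nt_length) {
  if (any(nt_length <= 0)) stop("region nt length must be > 0")
  count / nt_length * 1e4
}

#' Per-region driver/passenger summary
#'
#' @param sites Region-assigned site table (see [assign_region()]).
#' @param exons Exon model data frame (provides per-role nt lengths).
#' @param rest_exome_nt Nucleotide length of the exome outside all exon
#'   models.
#' @return Data frame per region (`C1`, `A`, `C2`, `distal_C`, `rest`):
#'   `n_driver`, `n_passenger`, `nt_length`, `density_driver_per_10kb`,
#'   `driver_passenger_ratio`.
#' @export
mutation_region_summary <- function(sites, exons, rest_exome_nt) {
  regions <- c("C1", "A", "C2", "distal_C", "rest")
  nt <- c(tapply(exons$nt_length, factor(exons$role, levels = regions[1:4]),
                 sum), rest = rest_exome_nt)
  nt[is.na(nt)] <- 0
  data.frame(
    region = regions,
    n_driver = vapply(regions, function(r)
      sum(sites$region == r & sites$call == "driver"), integer(1)),
    n_passenger = vapply(regions, function(r)
      sum(sites$region == r & sites$call == "passenger"), integer(1)),
    nt_length = as.numeric(nt[regions]),
    stringsAsFactors = FALSE, row.names = NULL) -> out
  out$density_driver_per_10kb <- ifelse(
    out$nt_length > 0, out$n_driver / out$nt_length * 1e4, NA_real_)
  out$driver_passenger_ratio <- ifelse(
    out$n_passenger > 0, out$n_driver / out$n_passenger, NA_real_)
  out
}

#' Driver enrichment in alternative-splicing neighborhoods
#'
#' Builds the 2x2 table of call (driver/passenger) by location (inside
#' the C1/A/C2 neighborhood versus a comparison region) and returns the
#' driver:passenger ratio in each region, their quotient (the
#' ratio-of-ratios), and a Pearson chi-squared test without continuity
#' correction.
#'
#' @param sites Region-assigned site table.
#' @param comparison `"rest"` (rest of the exome) or `"distal_C"`
#'   (distal constitutive exons of the same proteins).
#' @return List with `table`, `ratio_neighborhood`, `ratio_comparison`,
#'   `ratio_of_ratios`, `statistic`, `p`, and `skipped` (TRUE when a
#'   table margin is empty, in which case the test is not run).
#' @export
neighborhood_ratio_test <- function(sites, comparison = c("rest", "distal_C")) {
  comparison <- match.arg(comparison)
  nb <- sites$region %in% c("C1", "A", "C2")
  cmp <- sites$region == comparison
  tab <- rbind(
    neighborhood = c(driver = sum(nb & sites$call == "driver"),
                     passenger = sum(nb & sites$call == "passenger")),
    comparison = c(driver = sum(cmp & sites$call == "driver"),
                   passenger = sum(cmp & sites$call == "passenger")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, ratio_neighborhood = NA_real_,
                ratio_comparison = NA_real_, ratio_of_ratios = NA_real_,
                statistic = NA_real_, p = NA_real_, skipped = TRUE))
  r_nb <- tab["neighborhood", "driver"] / tab["neighborhood", "passenger"]
  r_cmp <- tab["comparison", "driver"] / tab["comparison", "passenger"]
  ht <- chi_squared_2x2(tab)
  list(table = tab, ratio_neighborhood = r_nb, ratio_comparison = r_cmp,
       ratio_of_ratios = r_nb / r_cmp, statistic = ht$statistic, p = ht$p,
       skipped = FALSE)
}
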