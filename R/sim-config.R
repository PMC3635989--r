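#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data
#' generator. Defaults emulate the data regime the pipeline is designed
#' for: ortholog alignments of 22 species, cassette-exon neighborhoods
#' with tissue-specific and general events, planted disorder-class rates
#' per exon role, feature densities concentrated in flanking exons,
#' recurrence-planted mutation tables, and 16-tissue expression counts.
#'
#' @param seed Integer seed; identical (seed, config) pairs reproduce
#'   byte-identical outputs.
#' @param n_groups Number of ortholog groups (= reference proteins/genes).
#' @param n_species Sequences per alignment (default 22).
#' @param protein_length_range Reference protein length range (residues).
#' @param gap_rate Expected fraction of columns gapped per non-reference
#'   species (indel segments; default 0.05).
#' @param indel_mean_len Mean indel segment length in columns.
#' @param disorder_segment_model Per-category column parameters: for each
#'   of `constrained`, `flexible`, `nonconserved`, `ordered`, a list with
#'   `disordered` (reference state), `cons_of_disorder` (probability a
#'   non-reference row shares the reference's disorder state) and
#'   `identity` (probability a non-reference row carries the reference
#'   amino acid).
#' @param background_rates Residue-category probabilities outside exon
#'   models, named `constrained`, `flexible`, `nonconserved` (remainder
#'   is ordered).
#' @param exon_model List: `n_ts_events`, `n_general_events`,
#'   `n_distal_per_protein`, `exon_length_range` (residues),
#'   `max_events_per_protein`.
#' @param planted_rates Data frame (`role`, `label`, `constrained`,
#'   `flexible`, `nonconserved`) of target class rates inside exons.
#' @param feature_model List: `phospho_density` and `motif_density`
#'   (named per-role per-residue probabilities, plus `rest`),
#'   `motif_length_range`, `profile_planting` (plant constrained disorder
#'   exactly at phosphosites with flexible flanks), `profile_flank`,
#'   `n_profile_sites_per_protein`.
#' @param expression_model List: `n_tissues`, `transcript_length`,
#'   `total_mapped_reads`, `expressed_crpkm_meanlog`,
#'   `expressed_crpkm_sdlog`, `min_expressed_crpkm`,
#'   `max_unexpressed_crpkm`, `duplicate_pair_fraction`,
#'   `ts_disorder_coupling` (0 = tissue breadth independent of planted
#'   disorder).
#' @param mutation_model List: `n_sites`, `driver_site_fraction`,
#'   `neighborhood_rel_rate` (driver:passenger odds multiplier inside
#'   C1/A/C2), `wgs_study_fraction`, `n_studies`, `wgs_path_fraction`,
#'   `driver_samples_range`, `driver_studies_range`,
#'   `wgs_driver_samples_range`.
#' @param annotation_model List: `n_terms`, `term_size_range`,
#'   `n_enriched_terms`, `bona_fide_rate`, `bona_fide_ts_log_odds`.
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_groups = 40L,
                       n_species = 22L,
                       protein_length_range = c(450L, 700L),
                       gap_rate = 0.05,
                       indel_mean_len = 5,
                       disorder_segment_model = list(
                         constrained = list(disordered = TRUE,
                                            cons_of_disorder = 0.90,
                                            identity = 0.95),
                         flexible = list(disordered = TRUE,
                                         cons_of_disorder = 0.90,
                                         identity = 0.40),
                         nonconserved = list(disordered = TRUE,
                                             cons_of_disorder = 0.10,
                                             identity = 0.40),
                         ordered = list(disordered = FALSE,
                                        cons_of_disorder = 0.90,
                                        identity = 0.60)),
                       background_rates = c(constrained = 0.03,
                                            flexible = 0.12,
                                            nonconserved = 0.05),
                       exon_model = list(n_ts_events = 10L,
                                         n_general_events = 40L,
                                         n_distal_per_protein = 2L,
                                         exon_length_range = c(20L, 60L),
                                         max_events_per_protein = 3L),
                       planted_rates = default_planted_rates(),
                       feature_model = list(
                         phospho_density = c(C1 = 0.08, A = 0.03, C2 = 0.08,
                                             distal_C = 0.03, rest = 0.01),
                         motif_density = c(C1 = 0.02, A = 0.01, C2 = 0.02,
                                           distal_C = 0.01, rest = 0.005),
                         motif_length_range = c(3L, 8L),
                         profile_planting = FALSE,
                         profile_flank = 5L,
                         n_profile_sites_per_protein = 3L),
                       expression_model = list(
                         n_tissues = 16L,
                         transcript_length = 600L,
                         total_mapped_reads = 1e7,
                         expressed_crpkm_meanlog = log(60),
                         expressed_crpkm_sdlog = 0.5,
                         min_expressed_crpkm = 20,
                         max_unexpressed_crpkm = 5,
                         duplicate_pair_fraction = 0,
                         ts_disorder_coupling = 0.5),
                       mutation_model = list(
                         n_sites = 2000L,
                         driver_site_fraction = 0.25,
                         neighborhood_rel_rate = 5,
                         wgs_study_fraction = 0.3,
                         n_studies = 30L,
                         wgs_path_fraction = 0.4,
                         driver_samples_range = c(5L, 9L),
                         driver_studies_range = c(3L, 4L),
                         wgs_driver_samples_range = c(3L, 5L)),
                       annotation_model = list(
                         n_terms = 25L,
                         term_size_range = c(8L, 30L),
                         n_enriched_terms = 3L,
                         bona_fide_rate = 0.3,
                         bona_fide_ts_log_odds = 1.0)) {
  cfg <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              n_species = as.integer(n_species),
              protein_length_range = as.integer(protein_length_range),
              gap_rate = gap_rate, indel_mean_len = indel_mean_len,
              disorder_segment_model = disorder_segment_model,
              background_rates = background_rates,
              exon_model = exon_model, planted_rates = planted_rates,
              feature_model = feature_model,
              expression_model = expression_model,
              mutation_model = mutation_model,
              annotation_model = annotation_model)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default planted class rates per exon role and label
#'
#' Flexible disorder is planted high in tissue-specific alternative (A)
#' exons and constrained disorder high in their flanking constitutive
#' exons, mirroring the enrichment pattern the pipeline is built to
#' detect; general events and distal exons sit at background-like rates.
#'
#' @return Data frame with columns `role`, `label`, `constrained`,
#'   `flexible`, `nonconserved`.
#' @export
default_planted_rates <- function() {
  data.frame(
    role = c("C1", "A", "C2", "C1", "A", "C2", "distal_C"),
    label = c(rep("tissue_specific", 3L), rep("general", 3L),
              "not_applicable"),
    constrained = c(0.30, 0.05, 0.30, 0.05, 0.05, 0.05, 0.05),
    flexible = c(0.15, 0.50, 0.15, 0.20, 0.20, 0.20, 0.15),
    nonconserved = rep(0.05, 7L),
    stringsAsFactors = FALSE)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  fail <- function(...) stop("invalid-config: ", ...)
  if (cfg$n_species < 2L) fail("n_species must be >= 2")
  if (cfg$n_groups < 1L) fail("n_groups must be positive")
  if (any(cfg$protein_length_range < 1L) ||
      cfg$protein_length_range[1L] > cfg$protein_length_range[2L])
    fail("bad protein_length_range")
  probs <- c(cfg$gap_rate, cfg$background_rates,
             unlist(lapply(cfg$disorder_segment_model,
                           function(m) c(m$cons_of_disorder, m$identity))),
             cfg$planted_rates$constrained, cfg$planted_rates$flexible,
             cfg$planted_rates$nonconserved,
             cfg$feature_model$phospho_density,
             cfg$feature_model$motif_density)
  if (any(probs < 0 | probs > 1)) fail("all probabilities must lie in [0,1]")
  if (sum(cfg$background_rates) > 1)
    fail("background category rates exceed 1")
  planted_tot <- cfg$planted_rates$constrained + cfg$planted_rates$flexible +
    cfg$planted_rates$nonconserved
  if (any(planted_tot > 1)) fail("planted class rates exceed 1 for a role")
  counts <- c(cfg$exon_model$n_ts_events, cfg$exon_model$n_general_events,
              cfg$exon_model$n_distal_per_protein,
              cfg$expression_model$n_tissues, cfg$mutation_model$n_sites,
              cfg$mutation_model$n_studies)
  if (any(counts < 0)) fail("counts must be non-negative")
  if (cfg$expression_model$n_tissues < 2L) fail("need at least 2 tissues")
  invisible(cfg)
}

#' Sample safely from a vector (no 1:n surprise for length-1 pools)
#' @keywords internal
sample_from <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Derive a stage seed from the master seed
#'
#' Linear-congruential mix kept below 2^31 so it is a valid R seed.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}
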