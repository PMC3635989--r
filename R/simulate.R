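#' Plan proteins, exon models and per-residue planted categories
#'
#' Deterministic given the config (uses a seed derived from
#' `cfg$seed`). Events that do not fit on their host protein are skipped
#' with a warning, never emitted as partial neighborhoods.
#'
#' @param cfg A [sim_config()].
#' @return List with `proteins` (`protein_id`, `length`), `exons` (exon
#'   model data frame), `categories` (named list: protein id ->
#'   per-residue planted category vector), and `phospho_planted` (data
#'   frame of profile-planted site positions, empty unless
#'   `feature_model$profile_planting`).
#' @export
sim_plan <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_groups
  ids <- sprintf("P%04d", seq_len(n))
  lens <- sample_from(cfg$protein_length_range[1L]:cfg$protein_length_range[2L],
                      n, replace = TRUE)
  em <- cfg$exon_model
  elr <- em$exon_length_range
  max_span <- 3L * elr[2L] + 10L
  distal_reserve <- em$n_distal_per_protein * (elr[2L] + 5L)
  capacity <- pmin(em$max_events_per_protein,
                   pmax(0L, (lens - distal_reserve) %/% max_span))
  # one slot entry per potential event, shuffled so labels spread evenly
  slots <- rep(seq_len(n), capacity)
  slots <- sample(slots)
  n_events <- em$n_ts_events + em$n_general_events
  if (length(slots) < n_events) {
    warning(n_events - length(slots),
            " event(s) skipped: host proteins too short")
    n_events <- length(slots)
  }
  labels <- sample(rep(c("tissue_specific", "general"),
                       c(min(em$n_ts_events, n_events),
                         max(0L, n_events - em$n_ts_events))))
  hosts <- slots[seq_len(n_events)]

  exon_rows <- list()
  cursor <- stats::setNames(rep(1L, n), ids)  # next free residue per protein
  eid <- 0L
  for (i in seq_len(n_events)) {
    p <- hosts[i]
    lens3 <- sample_from(elr[1L]:elr[2L], 3L, replace = TRUE)
    margin <- sample(2L:8L, 1L)
    start <- cursor[p] + margin
    if (start + sum(lens3) - 1L > lens[p] - distal_reserve) next
    eid <- eid + 1L
    ev <- sprintf("EV%04d", eid)
    s <- start
    for (r in 1:3) {
      role <- c("C1", "A", "C2")[r]
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        exon_id = paste0(ev, "_", role), event_id = ev,
        protein_id = ids[p], role = role, label = labels[i],
        start_res = s, end_res = s + lens3[r] - 1L,
        nt_length = 3L * lens3[r], stringsAsFactors = FALSE)
      s <- s + lens3[r]
    }
    cursor[p] <- s
  }
  # distal constitutive exons in the reserved tail
  for (p in seq_len(n)) {
    s <- max(cursor[p] + 5L, lens[p] - distal_reserve + 1L)
    for (j in seq_len(em$n_distal_per_protein)) {
      l <- sample_from(elr[1L]:elr[2L])
      if (s + l - 1L > lens[p]) break
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        exon_id = sprintf("%s_D%d", ids[p], j),
        event_id = NA_character_, protein_id = ids[p],
        role = "distal_C", label = "not_applicable",
        start_res = s, end_res = s + l - 1L, nt_length = 3L * l,
        stringsAsFactors = FALSE)
      s <- s + l + sample(2L:5L, 1L)
    }
  }
  exons <- if (length(exon_rows)) do.call(rbind, exon_rows)
    else data.frame(exon_id = character(), event_id = character(),
                    protein_id = character(), role = character(),
                    label = character(), start_res = integer(),
                    end_res = integer(), nt_length = integer(),
                    stringsAsFactors = FALSE)
  rownames(exons) <- NULL

  # per-residue planted categories: background, overridden inside exons
  br <- cfg$background_rates
  bg_probs <- c(br["constrained"], br["flexible"], br["nonconserved"],
                ordered = 1 - sum(br))
  cat_levels <- DISORDER_CATEGORIES
  categories <- lapply(seq_len(n), function(p)
    sample(cat_levels, lens[p], replace = TRUE, prob = bg_probs))
  names(categories) <- ids
  pr <- cfg$planted_rates
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    row <- pr[pr$role == e$role & pr$label == e$label, ]
    if (nrow(row) == 0L) next
    probs <- c(row$constrained, row$flexible, row$nonconserved,
               1 - row$constrained - row$flexible - row$nonconserved)
    span <- e$start_res:e$end_res
    categories[[e$protein_id]][span] <-
      sample(cat_levels, length(span), replace = TRUE, prob = probs)
  }

  phospho_planted <- data.frame(protein_id = character(),
                                start_res = integer(),
                                stringsAsFactors = FALSE)
  fm <- cfg$feature_model
  if (isTRUE(fm$profile_planting)) {
    w <- fm$profile_flank
    for (p in seq_len(n)) {
      k <- fm$n_profile_sites_per_protein
      span <- 2L * w + 4L
      if (lens[p] < k * span + 2L * w) k <- max(1L, (lens[p] - 2L * w) %/% span)
      pos <- (w + 2L) + (seq_len(k) - 1L) * span +
        sample(0L:3L, k, replace = TRUE)
      pos <- pos[pos + w <= lens[p]]
      cats <- categories[[ids[p]]]
      for (x in pos) {
        cats[x] <- "constrained_disorder"
        fl <- setdiff((x - w):(x + w), x)
        cats[fl] <- "flexible_disorder"
      }
      categories[[ids[p]]] <- cats
      if (length(pos))
        phospho_planted <- rbind(phospho_planted,
          data.frame(protein_id = ids[p], start_res = as.integer(pos),
                     stringsAsFactors = FALSE))
    }
  }

  list(proteins = data.frame(protein_id = ids, length = lens,
                             stringsAsFactors = FALSE),
       exons = exons, categories = categories,
       phospho_planted = phospho_planted)
}

#' Realize one ortholog alignment group from the plan
#'
#' Columns are generated independently given the planted per-residue
#' category: each non-reference row matches the reference amino acid with
#' the category's identity probability and shares the reference's
#' disorder state with its conservation-of-disorder probability. Gaps are
#' introduced per non-reference species as indel segments; the reference
#' row is always ungapped-complete.
#'
#' @param cfg A [sim_config()].
#' @param group_index Group index in `1..n_groups`.
#' @param plan Optional precomputed [sim_plan()] (recomputed otherwise).
#' @return List with `group` (an [aligned_group()]) and `truth` (data
#'   frame `protein_id`, `residue_pos`, `category`).
#' @export
generate_alignment_group <- function(cfg, group_index, plan = NULL) {
  if (group_index > cfg$n_groups) stop("group_index exceeds n_groups")
  if (is.null(plan)) plan <- sim_plan(cfg)
  set.seed(derive_seed(cfg$seed, 1000L + group_index))
  pid <- plan$proteins$protein_id[group_index]
  cats <- plan$categories[[pid]]
  l <- length(cats)
  k <- cfg$n_species
  m <- cfg$disorder_segment_model
  short <- c(constrained_disorder = "constrained",
             flexible_disorder = "flexible",
             nonconserved_disorder = "nonconserved",
             ordered = "ordered")[cats]
  a <- vapply(m[short], `[[`, numeric(1), "identity")
  d <- vapply(m[short], `[[`, numeric(1), "cons_of_disorder")
  ref_dis <- vapply(m[short], `[[`, logical(1), "disordered")

  ref_code <- sample.int(20L, l, replace = TRUE)
  match_mat <- matrix(stats::runif(k * l) <
                        matrix(a, k, l, byrow = TRUE), k, l)
  match_mat[1L, ] <- TRUE
  code_mat <- matrix(rep(ref_code, each = k), k, l)
  nm <- which(!match_mat)
  if (length(nm)) {
    off <- sample.int(19L, length(nm), replace = TRUE)
    code_mat[nm] <- (code_mat[nm] + off - 1L) %% 20L + 1L
  }
  same_mat <- matrix(stats::runif(k * l) <
                       matrix(d, k, l, byrow = TRUE), k, l)
  same_mat[1L, ] <- TRUE
  ref_state <- matrix(rep(ref_dis, each = k), k, l)
  dis_mat <- ifelse(same_mat, ref_state, !ref_state)

  aln <- matrix(AA_ALPHABET[code_mat], k, l)
  if (cfg$gap_rate > 0 && k > 1L) {
    for (s in 2:k) {
      n_seg <- stats::rpois(1L, cfg$gap_rate * l / cfg$indel_mean_len)
      if (n_seg == 0L) next
      starts <- sample.int(l, n_seg, replace = TRUE)
      seg_l <- 1L + stats::rpois(n_seg, cfg$indel_mean_len - 1)
      for (g in seq_len(n_seg)) {
        span <- starts[g]:min(l, starts[g] + seg_l[g] - 1L)
        aln[s, span] <- GAP
      }
    }
  }
  state_chr <- ifelse(dis_mat, "D", "O")
  tracks <- lapply(seq_len(k), function(s)
    state_chr[s, aln[s, ] != GAP])
  species_ids <- c(paste0("HUMAN|", pid),
                   sprintf("SP%02d|%s", 2:k, pid))
  grp <- aligned_group(aln, tracks, group_id = pid,
                       species_ids = species_ids, reference_index = 1L)
  truth <- data.frame(protein_id = pid, residue_pos = seq_len(l),
                      category = cats, stringsAsFactors = FALSE)
  list(group = grp, truth = truth)
}

#' Exon models with planted class rates
#'
#' @param cfg A [sim_config()].
#' @param plan Optional precomputed [sim_plan()].
#' @return The exon model data frame (see [exon_summaries()] for the
#'   column contract).
#' @export
generate_exon_models <- function(cfg, plan = NULL) {
  if (is.null(plan)) plan <- sim_plan(cfg)
  plan$exons
}

#' Phosphosite and linear-motif tables
#'
#' Feature positions are drawn per residue with role-specific densities
#' (or, under profile planting, phosphosites sit exactly at the planted
#' constrained-disorder positions). Motif intervals never cross protein
#' ends.
#'
#' @param cfg A [sim_config()].
#' @param plan Optional precomputed [sim_plan()].
#' @return Data frame: `protein_id`, `kind`, `start_res`, `end_res`,
#'   `source`.
#' @export
generate_features <- function(cfg, plan = NULL) {
  if (is.null(plan)) plan <- sim_plan(cfg)
  set.seed(derive_seed(cfg$seed, 2L))
  fm <- cfg$feature_model
  exons <- plan$exons
  role_of_residue <- function(pid, l) {
    role <- rep("rest", l)
    e <- exons[exons$protein_id == pid, , drop = FALSE]
    for (i in seq_len(nrow(e)))
      role[e$start_res[i]:e$end_res[i]] <- e$role[i]
    role
  }
  rows <- list()
  for (i in seq_len(nrow(plan$proteins))) {
    pid <- plan$proteins$protein_id[i]
    l <- plan$proteins$length[i]
    role <- role_of_residue(pid, l)
    if (isTRUE(fm$profile_planting)) {
      pp <- plan$phospho_planted
      pos <- pp$start_res[pp$protein_id == pid]
    } else {
      pos <- which(stats::runif(l) < fm$phospho_density[role])
    }
    if (length(pos))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, kind = "phosphosite",
        start_res = as.integer(pos), end_res = as.integer(pos),
        source = "synthetic", stringsAsFactors = FALSE)
    mstart <- which(stats::runif(l) < fm$motif_density[role])
    if (length(mstart)) {
      mlen <- sample_from(fm$motif_length_range[1L]:fm$motif_length_range[2L],
                          length(mstart), replace = TRUE)
      mend <- pmin(l, mstart + mlen - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, kind = "motif",
        start_res = as.integer(mstart), end_res = as.integer(mend),
        source = "synthetic", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(protein_id = character(), kind = character(),
                      start_res = integer(), end_res = integer(),
                      source = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Somatic mutation records with planted recurrence
#'
#' Sites are split into driver-like (recurrence at or above the
#' classification thresholds by construction) and passenger-like (1-2
#' samples). Driver sites are placed inside the C1/A/C2 neighborhood with
#' odds `neighborhood_rel_rate` times the length-proportional odds used
#' for passengers.
#'
#' @param cfg A [sim_config()].
#' @param plan Optional precomputed [sim_plan()].
#' @return List with `records` (mutation record table), `truth` (per-site
#'   planted call and region class) and `rest_exome_nt` (nt outside all
#'   exon models).
#' @export
generate_mutations <- function(cfg, plan = NULL) {
  if (is.null(plan)) plan <- sim_plan(cfg)
  set.seed(derive_seed(cfg$seed, 3L))
  mm <- cfg$mutation_model
  exons <- plan$exons
  # position pools (protein, residue) per region class
  pools <- list(neighborhood = NULL, other = NULL)
  pool_rows <- lapply(seq_len(nrow(plan$proteins)), function(i) {
    pid <- plan$proteins$protein_id[i]
    l <- plan$proteins$length[i]
    region <- rep("rest", l)
    e <- exons[exons$protein_id == pid, , drop = FALSE]
    for (j in seq_len(nrow(e)))
      region[e$start_res[j]:e$end_res[j]] <- e$role[j]
    data.frame(protein_id = pid, pos = seq_len(l), region = region,
               stringsAsFactors = FALSE)
  })
  all_pos <- do.call(rbind, pool_rows)
  in_nb <- all_pos$region %in% c("C1", "A", "C2")
  nb_pool <- all_pos[in_nb, ]
  other_pool <- all_pos[!in_nb, ]
  rest_exome_nt <- 3L * sum(all_pos$region == "rest")

  n_drv <- round(mm$n_sites * mm$driver_site_fraction)
  n_pas <- mm$n_sites - n_drv
  q_pas <- nrow(nb_pool) / nrow(all_pos)
  odds <- q_pas / (1 - q_pas) * mm$neighborhood_rel_rate
  q_drv <- odds / (1 + odds)

  if (mm$n_sites == 0L) {
    empty_rec <- data.frame(gene_id = character(), protein_pos = integer(),
                            aa_ref = character(), aa_alt = character(),
                            sample_id = character(), study_id = character(),
                            screen_type = character(),
                            stringsAsFactors = FALSE)
    empty_truth <- data.frame(gene_id = character(), protein_pos = integer(),
                              region = character(),
                              planted_call = character(),
                              stringsAsFactors = FALSE)
    return(list(records = empty_rec, truth = empty_truth,
                rest_exome_nt = rest_exome_nt))
  }
  # positions drawn without replacement jointly per pool, so no site
  # collides with another (collisions would thin passengers where drivers
  # are dense and bias the neighborhood ratio upward)
  n_drv_nb <- stats::rbinom(1L, n_drv, q_drv)
  n_pas_nb <- stats::rbinom(1L, n_pas, q_pas)
  take <- function(pool, n) {
    if (n == 0L) return(pool[0L, ])
    idx <- if (nrow(pool) >= n) sample.int(nrow(pool), n)
           else sample.int(nrow(pool), n, replace = TRUE)
    pool[idx, ]
  }
  nb_take <- take(nb_pool, n_drv_nb + n_pas_nb)
  ot_take <- take(other_pool, (n_drv - n_drv_nb) + (n_pas - n_pas_nb))
  site_df <- rbind(nb_take, ot_take)
  site_df$call <- c(rep("driver", n_drv_nb),
                    rep("passenger", n_pas_nb),
                    rep("driver", n_drv - n_drv_nb),
                    rep("passenger", n_pas - n_pas_nb))
  site_df <- site_df[!duplicated(paste(site_df$protein_id, site_df$pos)), ]
  rownames(site_df) <- NULL

  n_st <- mm$n_studies
  study_ids <- sprintf("ST%02d", seq_len(n_st))
  study_type <- rep("targeted", n_st)
  study_type[seq_len(round(mm$wgs_study_fraction * n_st))] <- "whole_genome"
  wgs_studies <- study_ids[study_type == "whole_genome"]
  tgt_studies <- study_ids[study_type == "targeted"]
  n_site <- nrow(site_df)
  aa_idx <- vapply(seq_len(n_site), function(i) sample.int(20L, 2L),
                   integer(2))
  studies_per_site <- vector("list", n_site)
  for (i in seq_len(n_site)) {
    if (site_df$call[i] == "driver") {
      if (length(wgs_studies) >= 1L &&
          stats::runif(1) < mm$wgs_path_fraction) {
        k <- sample_from(mm$wgs_driver_samples_range[1L]:
                           mm$wgs_driver_samples_range[2L])
        st <- sample(wgs_studies, min(2L, length(wgs_studies)),
                     replace = FALSE)
        studies <- sample(st, k, replace = TRUE)
      } else {
        k <- sample_from(mm$driver_samples_range[1L]:
                           mm$driver_samples_range[2L])
        ns <- sample_from(mm$driver_studies_range[1L]:
                            mm$driver_studies_range[2L])
        st <- sample(study_ids, ns)
        studies <- c(st, sample(st, k - ns, replace = TRUE))
      }
    } else {
      k <- sample(1:2, 1L, prob = c(0.8, 0.2))
      st <- if (length(tgt_studies)) sample(tgt_studies, 1L)
            else sample(study_ids, 1L)
      studies <- rep(st, k)
    }
    studies_per_site[[i]] <- studies
  }
  k_per_site <- lengths(studies_per_site)
  rep_idx <- rep(seq_len(n_site), k_per_site)
  study_vec <- unlist(studies_per_site, use.names = FALSE)
  records <- data.frame(
    gene_id = site_df$protein_id[rep_idx],
    protein_pos = site_df$pos[rep_idx],
    aa_ref = AA_ALPHABET[aa_idx[1L, rep_idx]],
    aa_alt = AA_ALPHABET[aa_idx[2L, rep_idx]],
    sample_id = sprintf("S%06d", seq_along(rep_idx)),
    study_id = study_vec,
    screen_type = ifelse(study_vec %in% wgs_studies,
                         "whole_genome", "targeted"),
    stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = site_df$protein_id,
                      protein_pos = site_df$pos,
                      region = ifelse(site_df$region %in% c("C1", "A", "C2"),
                                      site_df$region, site_df$region),
                      planted_call = site_df$call,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth, rest_exome_nt = rest_exome_nt)
}

#' Expression counts, transcripts and planted tissue breadth
#'
#' One transcript per gene. Counts are Poisson around a target cRPKM
#' drawn above the expressed cutoff in the gene's expressing tissues and
#' well below it elsewhere. Optionally a fraction of genes is arranged in
#' pairs sharing a duplicated nucleotide block, exercising the
#' mappability correction.
#'
#' @param cfg A [sim_config()].
#' @param plan Optional precomputed [sim_plan()].
#' @return List with `transcripts` (named character vector),
#'   `tx2gene` (named character vector), `counts` (`gene_id`, `tissue`,
#'   `raw_count`), `totals` (`tissue`, `total_mapped_reads`), and `truth`
#'   (`gene_id`, `t_true`).
#' @export
generate_expression <- function(cfg, plan = NULL) {
  if (is.null(plan)) plan <- sim_plan(cfg)
  set.seed(derive_seed(cfg$seed, 4L))
  em <- cfg$expression_model
  ids <- plan$proteins$protein_id
  n <- length(ids)
  tl <- em$transcript_length
  transcripts <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), tl, replace = TRUE), collapse = ""),
    character(1))
  names(transcripts) <- paste0(ids, "_t1")
  tx2gene <- stats::setNames(ids, names(transcripts))
  n_dup_pairs <- floor(em$duplicate_pair_fraction * n / 2)
  if (n_dup_pairs > 0L) {
    for (p in seq_len(n_dup_pairs)) {
      i <- 2L * p - 1L; j <- 2L * p
      block <- substr(transcripts[i], 1L, 60L)
      substr(transcripts[j], 1L, 60L) <- block
    }
  }
  # planted tissue breadth, optionally coupled to planted flexible disorder
  flex <- vapply(plan$categories, function(x)
    mean(x == "flexible_disorder"), numeric(1))[ids]
  r <- rank(flex, ties.method = "average") / n
  coup <- em$ts_disorder_coupling
  u <- coup * r + (1 - coup) * stats::runif(n)
  t_true <- pmin(em$n_tissues,
                 pmax(1L, 1L + floor((1 - u) * em$n_tissues)))
  tissues <- sprintf("tissue%02d", seq_len(em$n_tissues))
  rows <- vector("list", n)
  eff_kb <- max(0L, tl - 49L) / 1e3
  scale <- em$total_mapped_reads / 1e6
  for (i in seq_len(n)) {
    expr_in <- sample(tissues, t_true[i])
    target <- ifelse(
      tissues %in% expr_in,
      pmax(em$min_expressed_crpkm,
           stats::rlnorm(em$n_tissues, em$expressed_crpkm_meanlog,
                         em$expressed_crpkm_sdlog)),
      stats::runif(em$n_tissues, 0, em$max_unexpressed_crpkm))
    rows[[i]] <- data.frame(
      gene_id = ids[i], tissue = tissues,
      raw_count = stats::rpois(em$n_tissues, target * eff_kb * scale),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(transcripts = transcripts, tx2gene = tx2gene, counts = counts,
       totals = data.frame(tissue = tissues,
                           total_mapped_reads = em$total_mapped_reads,
                           stringsAsFactors = FALSE),
       truth = data.frame(gene_id = ids, t_true = as.integer(t_true),
                          stringsAsFactors = FALSE))
}

#' Synthetic GO-style annotations and bona-fide protein flags
#'
#' Random term memberships, with a configurable number of terms drawn
#' preferentially from the proteins with the highest planted flexible
#' disorder; bona-fide flags enriched among hosts of tissue-specific
#' events.
#'
#' @param cfg A [sim_config()].
#' @param plan Optional precomputed [sim_plan()].
#' @return List with `annotations` (`term_id`, `protein_id`),
#'   `bona_fide` (`protein_id`, `bona_fide`), and `enriched_terms`
#'   (character vector of planted term ids).
#' @export
generate_annotations <- function(cfg, plan = NULL) {
  if (is.null(plan)) plan <- sim_plan(cfg)
  set.seed(derive_seed(cfg$seed, 5L))
  am <- cfg$annotation_model
  ids <- plan$proteins$protein_id
  n <- length(ids)
  flex <- vapply(plan$categories, function(x)
    mean(x == "flexible_disorder"), numeric(1))[ids]
  top <- ids[order(-flex)]
  rows <- list()
  enriched <- character(0)
  sz_lo <- min(am$term_size_range[1L], n)
  sz_hi <- min(am$term_size_range[2L], n)
  for (t in seq_len(am$n_terms)) {
    sz <- sample_from(sz_lo:sz_hi)
    tid <- sprintf("GO:%07d", t)
    if (t <= am$n_enriched_terms) {
      members <- sample(utils::head(top, max(sz, ceiling(n / 3))), sz)
      enriched <- c(enriched, tid)
    } else {
      members <- sample(ids, sz)
    }
    rows[[t]] <- data.frame(term_id = tid, protein_id = members,
                            stringsAsFactors = FALSE)
  }
  hosts_ts <- unique(plan$exons$protein_id[
    plan$exons$label == "tissue_specific"])
  base <- am$bona_fide_rate
  p_bf <- ifelse(ids %in% hosts_ts,
                 stats::plogis(stats::qlogis(base) + am$bona_fide_ts_log_odds),
                 base)
  list(annotations = do.call(rbind, rows),
       bona_fide = data.frame(protein_id = ids,
                              bona_fide = stats::runif(n) < p_bf,
                              stringsAsFactors = FALSE),
       enriched_terms = enriched)
}

#' Simulate a complete synthetic dataset
#'
#' Runs every generator stage under seeds derived from `cfg$seed` and
#' returns the full input bundle plus ground truth. Identical
#' (seed, config) pairs reproduce identical outputs.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `disord_sim`: list with `config`, `plan`,
#'   `groups` (named list of [aligned_group()]), `exons`, `features`,
#'   `mutations` (`records`), `rest_exome_nt`, `expression`
#'   (transcripts/counts/totals), `annotations`, `bona_fide`, and
#'   `truth` (residues, exons, mutation sites, genes, enriched terms).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  plan <- sim_plan(cfg)
  realized <- lapply(seq_len(cfg$n_groups), function(i)
    generate_alignment_group(cfg, i, plan))
  groups <- lapply(realized, `[[`, "group")
  names(groups) <- plan$proteins$protein_id
  truth_res <- do.call(rbind, lapply(realized, `[[`, "truth"))
  features <- generate_features(cfg, plan)
  mut <- generate_mutations(cfg, plan)
  expr <- generate_expression(cfg, plan)
  ann <- generate_annotations(cfg, plan)
  structure(list(
    config = cfg, plan = plan, groups = groups, exons = plan$exons,
    features = features, mutations = mut$records,
    rest_exome_nt = mut$rest_exome_nt,
    expression = expr[c("transcripts", "tx2gene", "counts", "totals")],
    annotations = ann$annotations, bona_fide = ann$bona_fide,
    truth = list(residues = truth_res, exons = plan$exons,
                 mutation_sites = mut$truth, genes = expr$truth,
                 enriched_terms = ann$enriched_terms)),
    class = "disord_sim")
}

#' @export
print.disord_sim <- function(x, ...) {
  cat("disord_sim: ", length(x$groups), " ortholog groups, ",
      nrow(x$exons), " exon models, ", nrow(x$features), " features, ",
      nrow(x$mutations), " mutation records\n", sep = "")
  invisible(x)
}
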