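# Independent brute-force oracles and small fixture builders.
# Everything here recomputes quantities with plain loops, deliberately
# sharing no code with the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Build an aligned_group from aligned strings and track strings.
make_group <- function(rows, tracks, group_id = "g1", ref = 1L,
                       species_ids = NULL) {
  aligned_group(rows, lapply(tracks, function(s) strsplit(s, "")[[1]]),
                group_id = group_id, species_ids = species_ids,
                reference_index = ref)
}

# Random alignment with random gaps and disorder tracks; the reference
# row may be gapped (classification then skips those columns).
random_group <- function(n_species, n_cols, gap_p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    aln <- matrix(sample(AA20, n_species * n_cols, replace = TRUE),
                  n_species, n_cols)
    gaps <- matrix(runif(n_species * n_cols) < gap_p, n_species, n_cols)
    aln[gaps] <- "-"
    if (all(rowSums(aln != "-") > 0)) break  # keep every track non-empty
  }
  tracks <- lapply(seq_len(n_species), function(k)
    sample(c("D", "O"), sum(aln[k, ] != "-"), replace = TRUE))
  aligned_group(aln, tracks, group_id = "rand",
                reference_index = 1L)
}

# Naive per-column recount: identity, disorder fraction and category for
# every reference residue, with explicit loops.
oracle_classify <- function(group, d_th = 0.30, a_th = 0.80) {
  aln <- group$aln
  k <- nrow(aln)
  ri <- group$reference_index
  # per-row map: alignment column -> ungapped index (tabulated once)
  idx <- matrix(0L, k, ncol(aln))
  for (r in seq_len(k)) {
    cnt <- 0L
    for (j in seq_len(ncol(aln))) {
      if (aln[r, j] != "-") cnt <- cnt + 1L
      idx[r, j] <- cnt
    }
  }
  state_at <- function(row, col) {
    if (aln[row, col] == "-") return(NA_character_)
    group$tracks[[row]][idx[row, col]]
  }
  out <- NULL
  respos <- 0L
  for (j in seq_len(ncol(aln))) {
    if (aln[ri, j] == "-") next
    respos <- respos + 1L
    counts <- integer(0)
    for (r in seq_len(k)) {
      ch <- aln[r, j]
      if (ch != "-") counts[ch] <- (if (is.na(counts[ch][1])) 0L else counts[ch]) + 1L
    }
    idf <- if (length(counts)) max(counts) / k else 0
    ref_state <- state_at(ri, j)
    n_same <- 0L; n_res <- 0L
    for (r in seq_len(k)) {
      st <- state_at(r, j)
      if (!is.na(st)) {
        n_res <- n_res + 1L
        if (st == ref_state) n_same <- n_same + 1L
      }
    }
    dfr <- n_same / n_res
    cat <- if (ref_state == "O") "ordered"
      else if (dfr < d_th) "nonconserved_disorder"
      else if (idf >= a_th) "constrained_disorder"
      else "flexible_disorder"
    out <- rbind(out, data.frame(residue_pos = respos, column_index = j,
                                 category = cat, identity_fraction = idf,
                                 disorder_fraction = dfr,
                                 stringsAsFactors = FALSE))
  }
  out
}

# O(L^2) substring-search oracle for effective length.
oracle_effective_length <- function(transcripts, window = 50L) {
  sapply(names(transcripts), function(id) {
    s <- transcripts[[id]]
    l <- nchar(s)
    if (l < window) return(0L)
    eff <- 0L
    for (start in 1:(l - window + 1L)) {
      w <- substr(s, start, start + window - 1L)
      occ <- 0L
      for (t in transcripts) {
        p <- 1L
        while (p + window - 1L <= nchar(t)) {
          hit <- regexpr(w, substr(t, p, nchar(t)), fixed = TRUE)
          if (hit == -1L) break
          occ <- occ + 1L
          p <- p + hit  # continue after the match start
        }
      }
      if (occ == 1L) eff <- eff + 1L
    }
    eff
  })
}

# Closed-form 2x2 chi-squared: n(ad - bc)^2 / (row and column products).
oracle_chi2_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Hand step-up BH adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

# Driver/passenger rule applied directly to per-site aggregate counts.
oracle_driver_call <- function(n_samples, n_studies, n_wgs,
                               min_samples = 5, min_studies = 3,
                               min_wgs = 3) {
  if ((n_samples >= min_samples && n_studies >= min_studies) ||
      n_wgs >= min_wgs) "driver" else "passenger"
}
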