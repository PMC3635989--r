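#' @importFrom stats setNames
NULL

#' Amino-acid alphabet used throughout (20 canonical residues)
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue categories, in dominance tie-break order
#' @keywords internal
DISORDER_CATEGORIES <- c("constrained_disorder", "flexible_disorder",
                         "nonconserved_disorder", "ordered")

GAP <- "-"

#' Construct an aligned ortholog group
#'
#' Bundles a multiple sequence alignment with per-species binary disorder
#' tracks and a designated reference row (the human protein).
#'
#' @param aln Character matrix (rows = sequences, columns = alignment
#'   positions) of single characters over the amino-acid alphabet plus
#'   `"-"`, or a character vector of equal-length aligned strings.
#' @param tracks List of character vectors, one per row, each of length
#'   equal to the row's ungapped length, with symbols `"D"` (disordered)
#'   and `"O"` (ordered).
#' @param group_id Group identifier.
#' @param species_ids Row identifiers; the reference is conventionally
#'   prefixed `"HUMAN|"`.
#' @param reference_index Row index of the reference protein (default 1).
#' @return An object of class `aligned_group`.
#' @export
aligned_group <- function(aln, tracks, group_id = "group",
                          species_ids = NULL, reference_index = 1L) {
  if (is.character(aln) && is.null(dim(aln))) {
    nc <- unique(nchar(aln))
    if (length(nc) != 1L) stop("aligned rows must have equal length")
    aln <- t(vapply(strsplit(aln, ""), identity, character(nc)))
  }
  if (!is.matrix(aln)) stop("aln must be a character matrix or strings")
  k <- nrow(aln)
  if (k < 2L) stop("invalid-config: an alignment needs at least 2 sequences")
  if (is.null(species_ids)) species_ids <- rownames(aln)
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(k))
  if (length(tracks) != k) stop("one disorder track per sequence required")
  ungapped <- rowSums(aln != GAP)
  track_len <- vapply(tracks, length, 1L)
  if (any(track_len != ungapped)) {
    bad <- which(track_len != ungapped)[1L]
    stop("disorder track length mismatch for sequence '", species_ids[bad],
         "': track ", track_len[bad], ", ungapped length ", ungapped[bad])
  }
  if (any(!unlist(tracks) %in% c("D", "O")))
    stop("disorder tracks must use symbols 'D' and 'O'")
  structure(list(group_id = group_id, species_ids = species_ids,
                 aln = aln, tracks = tracks,
                 reference_index = as.integer(reference_index)),
            class = "aligned_group")
}

#' @export
print.aligned_group <- function(x, ...) {
  cat("aligned_group '", x$group_id, "': ", nrow(x$aln), " sequences x ",
      ncol(x$aln), " columns; reference ",
      x$species_ids[x$reference_index], "\n", sep = "")
  invisible(x)
}

#' Per-row disorder state matrix in alignment coordinates
#'
#' @param group An `aligned_group`.
#' @return Character matrix (same shape as the alignment) with `"D"`,
#'   `"O"`, or `NA` at gaps.
#' @keywords internal
states_matrix <- function(group) {
  aln <- group$aln
  st <- matrix(NA_character_, nrow(aln), ncol(aln))
  for (k in seq_len(nrow(aln))) {
    nongap <- aln[k, ] != GAP
    if (length(group$tracks[[k]]) != sum(nongap))
      stop("disorder track length mismatch in group '", group$group_id,
           "', sequence '", group$species_ids[k], "': track ",
           length(group$tracks[[k]]), ", ungapped length ", sum(nongap))
    st[k, nongap] <- group$tracks[[k]]
  }
  st
}

#' Column identity fraction a(i,n)/K
#'
#' The count of the most frequent amino-acid type in the column divided by
#' the total number of sequences K. Gaps count in the denominator but are
#' never a type.
#'
#' @param column Character vector of aligned symbols (one per sequence).
#' @return Fraction in `[0, 1]`; an all-gap column returns 0 (unusable).
#' @examples
#' identity_fraction(c("A", "A", "-", "G"))  # 0.5
#' @export
identity_fraction <- function(column) {
  if (length(column) == 0L) stop("column must be non-empty")
  cnt <- tabulate(match(column, AA_ALPHABET), nbins = 20L)
  max(cnt) / length(column)
}

#' Column disorder-conservation fraction
#'
#' Fraction of sequences (gaps excluded from numerator and denominator)
#' whose residue at this column carries the same disorder classification
#' as the reference residue. The reference itself is included.
#'
#' @param column Character vector of aligned symbols.
#' @param states Character vector of disorder states (`"D"`/`"O"`, `NA` at
#'   gaps), parallel to `column`.
#' @param reference_index Index of the reference row.
#' @return Fraction in `[0, 1]`.
#' @export
disorder_fraction <- function(column, states, reference_index = 1L) {
  if (column[reference_index] == GAP)
    stop("reference residue is a gap: disorder classification is reference-anchored")
  ref_state <- states[reference_index]
  ok <- !is.na(states)
  sum(states[ok] == ref_state) / sum(ok)
}

#' Bin fractional conservation scores
#'
#' Maps the identity and disorder fractions onto the integer bins used for
#' reporting: `D_bin = floor(10 d)` and `A_bin = min(10, floor(10 a) + 1)`,
#' so that `D >= 3` is equivalent to a disorder fraction of at least 0.30
#' and `A >= 9` to an identity fraction of at least 0.80.
#'
#' @param identity_fraction,disorder_fraction Fractions in `[0, 1]`.
#' @return List with integer `A_bin` and `D_bin`.
#' @export
bin_scores <- function(identity_fraction, disorder_fraction) {
  if (any(identity_fraction < 0 | identity_fraction > 1) ||
      any(disorder_fraction < 0 | disorder_fraction > 1))
    stop("fractions must lie in [0, 1]")
  list(A_bin = as.integer(pmin(10, floor(10 * identity_fraction) + 1)),
       D_bin = as.integer(floor(10 * disorder_fraction)))
}

#' Classify a reference residue into a disorder category
#'
#' An ordered reference residue is `ordered`. A disordered reference
#' residue is `nonconserved_disorder` when the column's disorder fraction
#' is below `disorder_threshold`; otherwise it is `constrained_disorder`
#' when the identity fraction reaches `identity_threshold` and
#' `flexible_disorder` when it does not.
#'
#' @param reference_disordered Logical: is the reference residue predicted
#'   disordered?
#' @param identity_fraction,disorder_fraction Column fractions.
#' @param disorder_threshold Disorder-conservation threshold (default 0.30).
#' @param identity_threshold Sequence-identity threshold (default 0.80).
#' @return Category string (vectorised over the fraction arguments).
#' @export
classify_residue <- function(reference_disordered, identity_fraction,
                             disorder_fraction,
                             disorder_threshold = 0.30,
                             identity_threshold = 0.80) {
  n <- max(length(reference_disordered), length(identity_fraction),
           length(disorder_fraction))
  rd <- rep_len(as.logical(reference_disordered), n)
  af <- rep_len(identity_fraction, n)
  df <- rep_len(disorder_fraction, n)
  out <- rep("ordered", n)
  out[rd & df < disorder_threshold] <- "nonconserved_disorder"
  out[rd & df >= disorder_threshold & af >= identity_threshold] <- "constrained_disorder"
  out[rd & df >= disorder_threshold & af < identity_threshold] <- "flexible_disorder"
  out
}

#' Per-column conservation scores for a group
#'
#' @param group An `aligned_group`.
#' @return Data frame with one row per alignment column: `column_index`,
#'   `identity_fraction`, `A_bin`, `disorder_fraction` (NA where the
#'   reference row is gapped), `D_bin`, `n_nongap`, `usable`.
#' @export
column_scores <- function(group) {
  aln <- group$aln
  k <- nrow(aln); l <- ncol(aln)
  codes <- matrix(match(aln, AA_ALPHABET), k, l)
  mx <- integer(l)
  for (i in seq_len(20L))  # modal count per column, one pass per residue type
    mx <- pmax(mx, colSums(codes == i, na.rm = TRUE))
  idf <- mx / k
  st <- states_matrix(group)
  ref_st <- st[group$reference_index, ]
  cmp <- st == matrix(ref_st, k, l, byrow = TRUE)
  dfr <- colSums(cmp, na.rm = TRUE) / colSums(!is.na(st))
  dfr[is.na(ref_st)] <- NA_real_
  n_nongap <- colSums(aln != GAP)
  d_bin <- ifelse(is.na(dfr), NA_integer_, as.integer(floor(10 * dfr)))
  data.frame(column_index = seq_len(l),
             identity_fraction = idf,
             A_bin = as.integer(pmin(10, floor(10 * idf) + 1)),
             disorder_fraction = dfr,
             D_bin = d_bin,
             n_nongap = n_nongap,
             usable = n_nongap > 0L)
}

#' Classify every reference residue of an ortholog group
#'
#' @param group An `aligned_group`.
#' @param protein_id Identifier recorded for the reference protein; by
#'   default taken from the reference row id (with any `"HUMAN|"` prefix
#'   stripped).
#' @inheritParams classify_residue
#' @return Data frame with one row per reference residue: `protein_id`,
#'   `residue_pos` (1-based in the ungapped reference), `column_index`,
#'   `category`, `identity_fraction`, `disorder_fraction`, `A_bin`,
#'   `D_bin`.
#' @export
classify_group <- function(group, protein_id = NULL,
                           disorder_threshold = 0.30,
                           identity_threshold = 0.80) {
  ri <- group$reference_index
  if (is.null(protein_id))
    protein_id <- sub("^HUMAN\\|", "", group$species_ids[ri])
  cs <- column_scores(group)
  ref_nongap <- group$aln[ri, ] != GAP
  cols <- which(ref_nongap)
  ref_track <- group$tracks[[ri]]
  data.frame(protein_id = protein_id,
             residue_pos = seq_along(cols),
             column_index = cols,
             category = classify_residue(ref_track == "D",
                                         cs$identity_fraction[cols],
                                         cs$disorder_fraction[cols],
                                         disorder_threshold,
                                         identity_threshold),
             identity_fraction = cs$identity_fraction[cols],
             disorder_fraction = cs$disorder_fraction[cols],
             A_bin = cs$A_bin[cols],
             D_bin = cs$D_bin[cols],
             stringsAsFactors = FALSE)
}

#' Per-protein disorder composition
#'
#' Counts and proportions of the four residue categories per protein, with
#' the dominant category (ties broken constrained > flexible >
#' nonconserved > ordered).
#'
#' @param residues Per-residue classification data frame (from
#'   [classify_group()], possibly row-bound over groups).
#' @return Data frame with one row per protein: length, `n_<cat>`,
#'   `p_<cat>`, `dominant_category`.
#' @export
protein_composition <- function(residues) {
  cats <- DISORDER_CATEGORIES
  tab <- table(factor(residues$protein_id, levels = unique(residues$protein_id)),
               factor(residues$category, levels = cats))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  len <- rowSums(counts)
  props <- counts / len
  dom <- cats[apply(props, 1L, which.max)]  # which.max takes first on ties
  out <- data.frame(protein_id = rownames(counts), length = len,
                    stringsAsFactors = FALSE, row.names = NULL)
  short <- c("constrained", "flexible", "nonconserved", "ordered")
  for (i in seq_along(cats)) out[[paste0("n_", short[i])]] <- counts[, cats[i]]
  for (i in seq_along(cats)) out[[paste0("p_", short[i])]] <- props[, cats[i]]
  out$dominant_category <- dom
  out
}

#' Filter ortholog candidates into retained groups
#'
#' Resolves one-to-many ortholog relationships per (protein, species) by
#' the lowest BLAST e-value (ties by lexicographically smallest ortholog
#' id), then retains proteins that carry a CCDS flag and have strictly
#' more than `min_orthologs` eukaryote orthologs.
#'
#' @param candidates Data frame with columns `protein_id`, `ortholog_id`,
#'   `species`, `e_value`, `eukaryote` (logical).
#' @param ccds_flags Named logical vector (or data frame with columns
#'   `protein_id`, `ccds`) marking CCDS-mapped proteins.
#' @param min_orthologs Retention requires more than this many eukaryote
#'   orthologs (default 15).
#' @return List with `proteins` (retained ids) and `orthologs` (resolved
#'   one-per-species table for the retained proteins).
#' @export
filter_orthologs <- function(candidates, ccds_flags, min_orthologs = 15L) {
  if (is.data.frame(ccds_flags))
    ccds_flags <- setNames(as.logical(ccds_flags$ccds), ccds_flags$protein_id)
  key <- paste(candidates$protein_id, candidates$species, sep = "\r")
  resolved <- do.call(rbind, lapply(split(candidates, key), function(d) {
    if (nrow(d) > 1L) {
      if (anyNA(d$e_value))
        stop("missing e-value on a many-mapping for protein '",
             d$protein_id[1L], "', species '", d$species[1L], "'")
      d <- d[order(d$e_value, d$ortholog_id), , drop = FALSE]
    }
    d[1L, , drop = FALSE]
  }))
  rownames(resolved) <- NULL
  n_euk <- tapply(resolved$eukaryote, resolved$protein_id, sum)
  prots <- names(n_euk)
  keep <- prots[n_euk > min_orthologs &
                !is.na(ccds_flags[prots]) & ccds_flags[prots]]
  list(proteins = sort(keep),
       orthologs = resolved[resolved$protein_id %in% keep, , drop = FALSE])
}

#' Cross-species agreement of disorder assignments
#'
#' Over aligned position pairs where both positions are residues and at
#' least one carries a disordered category, the fraction where both do.
#'
#' @param cat_a,cat_b Character vectors of per-position categories for the
#'   two aligned orthologs (`NA` at gaps), equal length.
#' @return Fraction in `[0, 1]` (`NaN` when no position qualifies).
#' @export
cross_species_agreement <- function(cat_a, cat_b) {
  if (length(cat_a) != length(cat_b))
    stop("aligned category vectors must have equal length")
  dis <- setdiff(DISORDER_CATEGORIES, "ordered")
  a <- cat_a %in% dis & !is.na(cat_a)
  b <- cat_b %in% dis & !is.na(cat_b)
  both_res <- !is.na(cat_a) & !is.na(cat_b)
  any_dis <- both_res & (a | b)
  if (!any(any_dis)) return(NaN)
  sum(a & b & both_res) / sum(any_dis)
}
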