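#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test with midranks for ties. The null distribution of the
#' Mann-Whitney U statistic is enumerated exactly (all
#' \eqn{\binom{n_x+n_y}{n_x}} assignments of the pooled ranks) when the
#' pooled sample size is at most `exact_max_n`; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y Numeric vectors of per-unit values for the two groups.
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exact_max_n Largest pooled size for which the exact null is
#'   enumerated (default 16).
#' @return A list with `statistic` (Mann-Whitney U for `x`), `p`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")$p  # 1/6
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact_max_n = 16L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  if (n <= exact_max_n) {
    idx <- utils::combn(n, nx)
    base <- nx * (nx + 1) / 2
    u_null <- colSums(matrix(r[idx], nrow = nx)) - base
    m <- ncol(idx)
    eps <- 1e-9
    p_le <- sum(u_null <= u + eps) / m
    p_ge <- sum(u_null >= u - eps) / m
    p <- switch(alternative,
      less = p_le,
      greater = p_ge,
      two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(statistic = u, p = p, method = "exact"))
  }

  mu <- nx * ny / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p = 1, method = "normal"))
  # continuity-corrected normal approximation (standard for the rank-sum
  # statistic; keeps the approximation close to the exact enumeration at
  # the crossover size)
  cc <- switch(alternative,
    two.sided = sign(u - mu) * 0.5, greater = 0.5, less = -0.5)
  z <- (u - mu - cc) / sqrt(sigma2)
  p <- switch(alternative,
    less = stats::pnorm(z),
    greater = stats::pnorm(z, lower.tail = FALSE),
    two.sided = 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p = min(1, p), method = "normal")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction; df = 1.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return List with `statistic` and `p`.
#' @export
chi_squared_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of raw p-values.
#' @return Adjusted p-values (same order as input), capped at 1.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Direction label for a two-group contrast
#'
#' @param u Mann-Whitney U statistic for the first group.
#' @param nx,ny Group sizes.
#' @param p Raw p-value.
#' @param alpha Significance level.
#' @return `"up"`, `"down"`, or `"none"`.
#' @keywords internal
contrast_direction <- function(u, nx, ny, p, alpha = 0.05) {
  if (p >= alpha) return("none")
  if (u > nx * ny / 2) "up" else "down"
}

#' GO-style term enrichment of a disorder class
#'
#' For each term, the class proportions of the member proteins are compared
#' to those of all non-member proteins with a two-sided Wilcoxon rank-sum
#' test; p-values are BH-adjusted across terms.
#'
#' @param composition Per-protein composition data frame from
#'   [protein_composition()] (needs `protein_id` plus the `p_<class>`
#'   column for `class`).
#' @param annotations Data frame with columns `term_id`, `protein_id`.
#' @param class One of `"constrained"`, `"flexible"`, `"nonconserved"`,
#'   `"ordered"`.
#' @param min_members Terms with fewer member proteins (after intersecting
#'   with `composition`) are dropped.
#' @return Data frame: `term_id`, `n_members`, `statistic`, `p_raw`,
#'   `p_adjusted`, `direction`.
#' @export
go_term_enrichment <- function(composition, annotations, class = "flexible",
                               min_members = 2L) {
  col <- paste0("p_", class)
  if (!col %in% names(composition)) stop("unknown class: ", class)
  vals <- stats::setNames(composition[[col]], composition$protein_id)
  annotations <- annotations[annotations$protein_id %in% names(vals), , drop = FALSE]
  terms <- split(annotations$protein_id, annotations$term_id)
  terms <- lapply(terms, unique)
  terms <- terms[vapply(terms, length, 1L) >= min_members]
  if (length(terms) == 0L)
    return(data.frame(term_id = character(), n_members = integer(),
                      statistic = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  res <- lapply(names(terms), function(tid) {
    members <- terms[[tid]]
    inside <- vals[members]
    outside <- vals[setdiff(names(vals), members)]
    if (length(outside) == 0L)
      return(data.frame(term_id = tid, n_members = length(members),
                        statistic = NA_real_, p_raw = 1, direction = "none",
                        stringsAsFactors = FALSE))
    w <- wilcoxon_rank_sum(inside, outside)
    data.frame(term_id = tid, n_members = length(members),
               statistic = w$statistic, p_raw = w$p,
               direction = contrast_direction(w$statistic, length(inside),
                                              length(outside), w$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_fdr(out$p_raw)
  out[, c("term_id", "n_members", "statistic", "p_raw", "p_adjusted",
          "direction")]
}

#' Overlap coefficient between two sets
#'
#' \eqn{|A \cap B| / \min(|A|, |B|)}.
#'
#' @param set_a,set_b Vectors of member identifiers.
#' @return Value in `[0, 1]`; 0 if either set is empty.
#' @export
overlap_coefficient <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Build an enrichment map from term memberships
#'
#' Nodes are terms (size attribute \eqn{-\log_{10}} adjusted p); edges carry
#' the overlap coefficient and are kept when it reaches `cutoff`.
#'
#' @param term_members Named list: term id -> character vector of members.
#' @param p_adjusted Named numeric vector of adjusted p-values per term.
#' @param cutoff Overlap-coefficient threshold for keeping an edge.
#' @return List with data frames `nodes` (`term_id`, `n_members`, `size`)
#'   and `edges` (`term_a`, `term_b`, `overlap_coefficient`, `kept`).
#' @export
build_enrichment_map <- function(term_members, p_adjusted, cutoff = 0.4) {
  ids <- names(term_members)
  if (is.null(ids)) stop("term_members must be a named list")
  nodes <- data.frame(
    term_id = ids,
    n_members = vapply(term_members, function(m) length(unique(m)), 1L),
    size = -log10(pmax(p_adjusted[ids], .Machine$double.xmin)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (length(ids) < 2L) {
    edges <- data.frame(term_a = character(), term_b = character(),
                        overlap_coefficient = numeric(), kept = logical(),
                        stringsAsFactors = FALSE)
    return(list(nodes = nodes, edges = edges))
  }
  pairs <- utils::combn(ids, 2L)
  oc <- apply(pairs, 2L, function(p)
    overlap_coefficient(term_members[[p[1L]]], term_members[[p[2L]]]))
  edges <- data.frame(term_a = pairs[1L, ], term_b = pairs[2L, ],
                      overlap_coefficient = oc, kept = oc >= cutoff,
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
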