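# Nonparametric group comparisons ----------------------------------------------
#
# ANOSIM is implemented from scratch (rank-based R statistic plus label
# permutation); Kruskal-Wallis and Mann-Whitney use their textbook rank
# formulas with tie corrections. Base R's exact Wilcoxon null distribution
# (pwilcox) supplies the exact Mann-Whitney p when there are no ties.

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise dissimilarities (average ranks on ties) and compares the
#' mean rank of between-group pairs with the mean rank of within-group pairs:
#' `R = (rb - rw) / (n (n - 1) / 4)`, in `[-1, 1]`; large positive R means
#' groups are more separated than internally variable. Significance is by
#' permutation of group labels over samples: the one-sided
#' `p = (1 + #{R_perm >= R_obs}) / (1 + n_permutations)`.
#'
#' @param distances Symmetric dissimilarity matrix with sample-id dimnames
#'   (e.g. from [bray_curtis_matrix()]).
#' @param groups Group label per sample, aligned by name with the matrix (a
#'   named vector) or by position.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation draw.
#' @return List of class `anosim_result`: `r_statistic`, `p_value`,
#'   `n_permutations`, `group_labels`, `n_samples`.
#' @export
anosim_test <- function(distances, groups, n_permutations = 999, seed = 1) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop("`distances` must be a square matrix")
  if (max(abs(distances - t(distances))) > 1e-12)
    stop("`distances` must be symmetric")
  n <- nrow(distances)
  if (!is.null(names(groups)) && !is.null(rownames(distances))) {
    missing_g <- setdiff(rownames(distances), names(groups))
    if (length(missing_g))
      stop("groups missing for samples: ", paste(missing_g, collapse = ", "))
    groups <- groups[rownames(distances)]
  }
  if (length(groups) != n) stop("one group label per sample required")
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("ANOSIM needs at least two groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  pair_i <- which(upper.tri(distances), arr.ind = TRUE)
  r <- rank(distances[upper.tri(distances)]) # average ranks on ties
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    between <- g[pair_i[, 1]] != g[pair_i[, 2]]
    (mean(r[between]) - mean(r[!between])) / denom
  }
  r_obs <- r_stat(groups)
  perm_ge <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations),
               function(k) r_stat(sample(groups)) >= r_obs, logical(1)))
  })
  structure(list(r_statistic = r_obs,
                 p_value = (1 + perm_ge) / (1 + n_permutations),
                 n_permutations = n_permutations,
                 group_labels = names(sizes),
                 n_samples = n),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4f (%d permutations; groups: %s)\n",
              x$r_statistic, x$p_value, x$n_permutations,
              paste(x$group_labels, collapse = ", ")))
  invisible(x)
}

#' All pairwise two-group ANOSIMs
#'
#' Runs one two-group ANOSIM per unordered pair of group labels, subsetting
#' the precomputed dissimilarity matrix (ranks are recomputed within each
#' subset).
#'
#' @inheritParams anosim_test
#' @return Data frame: `comparison`, `r_statistic`, `p_value`,
#'   `n_permutations`.
#' @export
pairwise_anosim <- function(distances, groups, n_permutations = 999, seed = 1) {
  if (!is.null(names(groups)) && !is.null(rownames(distances)))
    groups <- groups[rownames(distances)]
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  combos <- utils::combn(labs, 2, simplify = FALSE)
  rows <- lapply(seq_along(combos), function(k) {
    pair <- combos[[k]]
    sel <- groups %in% pair
    res <- anosim_test(distances[sel, sel, drop = FALSE], groups[sel],
                       n_permutations = n_permutations,
                       seed = substream_seed(seed, k))
    data.frame(comparison = paste(pair, collapse = " vs "),
               r_statistic = res$r_statistic, p_value = res$p_value,
               n_permutations = n_permutations, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom. When every value is identical the statistic is 0 and
#' p is 1.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (at least two groups).
#' @return List of class `rank_test_result`: `statistic` (H), `p_value`,
#'   `df`, `group_sizes`, `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) { # all values identical
    h <- 0; p <- 1
  } else {
    h <- h / correction
    p <- stats::pchisq(h, df = length(sizes) - 1, lower.tail = FALSE)
  }
  structure(list(statistic = h, p_value = p, df = length(sizes) - 1,
                 group_sizes = as.integer(sizes), method = "Kruskal-Wallis"),
            class = "rank_test_result")
}

#' Mann-Whitney U test
#'
#' U with average-rank tie handling; reports the smaller of the two mirrored
#' statistics. The two-sided p uses exact enumeration of the null (via the
#' exact Wilcoxon distribution) when `n_a * n_b <= 400` and there are no
#' ties, otherwise a normal approximation with tie and continuity correction.
#'
#' @param values_a,values_b Nonempty numeric vectors.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact p; default
#'   `NULL` picks automatically as above.
#' @return List of class `rank_test_result`: `statistic` (min U), `p_value`,
#'   `group_sizes`, `method`.
#' @export
mann_whitney <- function(values_a, values_b, exact = NULL) {
  if (!length(values_a) || !length(values_b)) stop("both samples must be nonempty")
  na <- length(values_a); nb <- length(values_b)
  r <- rank(c(values_a, values_b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u <- min(u_a, na * nb - u_a)
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  if (is.null(exact)) exact <- (na * nb <= 400) && !has_ties
  if (exact && has_ties) {
    warning("exact Mann-Whitney p unavailable with ties; using normal approximation")
    exact <- FALSE
  }
  if (exact) {
    # two-sided: double the smaller tail of the exact U distribution
    p <- min(1, 2 * stats::pwilcox(u, na, nb))
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((na + nb + 1) - sum(ties^3 - ties) / ((na + nb) * (na + nb - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_a - mu) - 0.5) / sqrt(sigma2) # continuity correction
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  structure(list(statistic = u, p_value = p,
                 group_sizes = c(na, nb),
                 method = if (exact) "Mann-Whitney (exact)"
                          else "Mann-Whitney (normal approximation)"),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}
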