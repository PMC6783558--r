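# Rarefaction, alpha diversity and Bray-Curtis distances ----------------------
#
# All indices are implemented from their standard definitions (natural-log
# Shannon, bias-corrected Chao1, Pielou evenness) so that the whole pipeline
# has a single, auditable code path; vegan serves as an independent
# cross-check in the test suite, not as the implementation.

#' Rarefy a count table to a common depth
#'
#' Each sample column is subsampled without replacement to exactly `depth`
#' reads, equalising sequencing effort before diversity comparisons. A column
#' whose total equals `depth` is returned unchanged (the exhaustive
#' subsample). Deterministic for a fixed `seed`.
#'
#' @param table A [count_table].
#' @param depth Target reads per sample; must not exceed the shallowest
#'   sample unless `drop_shallow = TRUE`.
#' @param seed Integer seed for the subsampling draw.
#' @param drop_shallow Drop (with a warning) samples with fewer than `depth`
#'   reads instead of erroring.
#' @return A rarefied [count_table]; every column sums to exactly `depth`.
#' @export
rarefy_table <- function(table, depth, seed = 1, drop_shallow = FALSE) {
  stopifnot(depth >= 1, depth == round(depth))
  cs <- sample_sums(table)
  shallow <- names(cs)[cs < depth]
  if (length(shallow)) {
    if (!drop_shallow)
      stop("depth ", depth, " exceeds reads in sample(s): ",
           paste(shallow, collapse = ", "),
           " (use drop_shallow = TRUE to remove them)")
    warning("dropping ", length(shallow), " sample(s) below depth ", depth, ": ",
            paste(shallow, collapse = ", "))
    keep <- setdiff(colnames(table$counts), shallow)
    table <- count_table(table$counts[, keep, drop = FALSE],
                         taxonomy = table$taxonomy)
  }
  m <- table$counts
  out <- m
  for (j in seq_len(ncol(m))) {
    if (sum(m[, j]) == depth) next
    out[, j] <- with_seed(substream_seed(seed, j), {
      pool <- rep.int(seq_len(nrow(m)), m[, j])
      drawn <- sample(pool, depth, replace = FALSE)
      tabulate(drawn, nbins = nrow(m))
    })
  }
  count_table(out, taxonomy = table$taxonomy)
}

#' Shannon diversity of one sample
#'
#' `H = -sum p_i log(p_i)` over taxa with positive counts; natural log by
#' default (the usual ecology convention).
#'
#' @param counts Non-negative count (or proportion) vector with at least one
#'   positive entry.
#' @param base Logarithm base.
#' @return H in nats (or units of `base`).
#' @examples
#' shannon(c(25, 25, 25, 25)) # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_sample_vector(counts)
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimate of one sample
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where F1 and F2
#' are the numbers of taxa observed exactly once and twice; defined even when
#' there are no doubletons. The classic form
#' `S_obs + F1^2 / (2 F2)` is available with `bias_corrected = FALSE` (it
#' requires `F2 > 0` and otherwise falls back to the corrected form with a
#' warning).
#'
#' @inheritParams shannon
#' @param bias_corrected Use the bias-corrected estimator (default).
#' @return Estimated richness, always `>= S_obs`.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_sample_vector(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (!bias_corrected) {
    if (f2 == 0) {
      warning("classic Chao1 undefined with no doubletons; using bias-corrected form")
    } else {
      return(s_obs + f1^2 / (2 * f2))
    }
  }
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Pielou evenness of one sample
#'
#' `J = H / log(S_obs)`, in `[0, 1]`; `NA` when only one taxon is observed
#' (evenness is then undefined).
#'
#' @inheritParams shannon
#' @return Evenness in `[0, 1]`, or `NA` for a single-taxon sample.
#' @export
pielou_evenness <- function(counts) {
  counts <- check_sample_vector(counts)
  s_obs <- sum(counts > 0)
  if (s_obs < 2) return(NA_real_)
  shannon(counts) / log(s_obs)
}

check_sample_vector <- function(counts) {
  if (!is.numeric(counts) || !length(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  counts
}

#' Alpha diversity table for every sample
#'
#' @param table A [count_table] (usually rarefied first).
#' @return Data frame: `sample_id`, `observed_taxa`, `shannon`, `chao1`,
#'   `evenness` (one row per sample).
#' @export
alpha_diversity <- function(table) {
  m <- table$counts
  data.frame(
    sample_id = colnames(m),
    observed_taxa = apply(m, 2, function(x) sum(x > 0)),
    shannon = apply(m, 2, shannon),
    chao1 = apply(m, 2, chao1),
    evenness = apply(m, 2, pielou_evenness),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' `d(A, B) = 1 - 2 sum_i min(A_i, B_i) / (sum_i A_i + sum_i B_i)`:
#' 0 for identical columns, 1 for disjoint supports.
#'
#' @param table A [count_table] (or `composition_table`) with at least two
#'   samples.
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(table) {
  m <- if (inherits(table, "composition_table")) table$proportions else table$counts
  if (ncol(m) < 2) stop("need at least two samples")
  cs <- colSums(m)
  if (any(cs == 0)) stop("zero-sum sample column(s)")
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(m[, i], m[, j])) / (cs[i] + cs[j])
    }
  }
  d
}

#' Rarefaction curve
#'
#' Observed richness after rarefying to each depth of a grid, averaged over
#' `n_draws` random subsamples; used to judge whether sampling depth has
#' plateaued.
#'
#' @param table A [count_table].
#' @param depths Integer vector of depths; defaults to 10 steps up to the
#'   shallowest sample.
#' @param n_draws Subsampling replicates per depth.
#' @param seed Integer seed.
#' @return Long data frame: `sample_id`, `depth`, `observed_taxa`.
#' @export
rarefaction_curve <- function(table, depths = NULL, n_draws = 1, seed = 1) {
  min_depth <- min(sample_sums(table))
  if (is.null(depths))
    depths <- unique(round(seq(1, min_depth, length.out = 10)))
  depths <- depths[depths <= min_depth]
  rows <- list()
  for (k in seq_along(depths)) {
    acc <- 0
    for (r in seq_len(n_draws)) {
      rt <- rarefy_table(table, depths[k], seed = substream_seed(seed, k * 1000 + r))
      acc <- acc + apply(rt$counts, 2, function(x) sum(x > 0))
    }
    rows[[k]] <- data.frame(sample_id = colnames(table$counts),
                            depth = depths[k],
                            observed_taxa = acc / n_draws,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
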