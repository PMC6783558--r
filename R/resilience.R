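# Resistance (RS) and resilience (RL) indices ---------------------------------
#
# A disturbance study with three groups per area: reference (never disturbed),
# flooding (currently disturbed), recovery (previously disturbed, re-exposed).
# With C0 the reference-group mean, P0 the disturbed-group mean and Px the
# recovery-group mean (and the end-of-study reference value Cx taken equal to
# C0, i.e. the reference is assumed stable):
#
#   RS = 1 - 2|C0 - P0| / (C0 + |C0 - P0|)
#   RL = 2|C0 - P0| / (|C0 - P0| + |Cx - Px|) - 1
#
# Both lie in [-1, 1]. RS = +1 means the disturbance changed nothing; RL = +1
# means the recovery group returned exactly to the reference value.

#' Resistance index
#'
#' `RS = 1 - 2|C0 - P0| / (C0 + |C0 - P0|)`, in `[-1, 1]`; `+1` iff the
#' disturbed mean equals the reference mean (maximal resistance), approaching
#' `-1` as the disturbed mean grows without bound. The index is scale
#' invariant, so it applies equally to gene-copy abundances, diversity indices
#' and relative abundances. The degenerate case `c0 = p0 = 0` (variable absent
#' everywhere) is defined as `1`: nothing changed.
#'
#' @param c0 Reference-group mean (must be `>= 0`).
#' @param p0 Disturbed-group mean. Both arguments are vectorised.
#' @return Numeric vector of RS values in `[-1, 1]`.
#' @examples
#' resistance_index(3.2e8, 1.2e9) # -0.467: abundance tripled under flooding
#' resistance_index(7, 7)         # 1: no change
#' @seealso [resilience_index()], [rs_rl_profile()]
#' @export
resistance_index <- function(c0, p0) {
  stopifnot(is.numeric(c0), is.numeric(p0))
  if (any(!is.finite(c0)) || any(!is.finite(p0)))
    stop("c0 and p0 must be finite")
  if (any(c0 < 0)) stop("c0 must be non-negative")
  n <- max(length(c0), length(p0))
  c0 <- rep_len(c0, n); p0 <- rep_len(p0, n)
  d <- abs(c0 - p0)
  rs <- ifelse(c0 == 0 & d == 0, 1, 1 - 2 * d / (c0 + d))
  rs
}

#' Resilience index
#'
#' `RL = 2|C0 - P0| / (|C0 - P0| + |C0 - Px|) - 1`, in `[-1, 1]` (the
#' undisturbed reference value Cx is taken equal to C0). `+1` iff the recovery
#' mean equals the reference mean (complete recovery); `0` when the recovery
#' group is as far from the reference as the disturbed group was; negative
#' when it drifted further. When `c0 = p0` there is no disturbance
#' displacement to recover from and the index is undefined: `NA` is returned.
#'
#' @param c0 Reference-group mean.
#' @param p0 Disturbed-group mean.
#' @param px Recovery-group mean. All arguments are vectorised.
#' @return Numeric vector of RL values in `[-1, 1]`, `NA` where undefined.
#' @examples
#' resilience_index(3.2e8, 1.2e9, 2.1e8) # 0.78: abundance largely recovered
#' resilience_index(10, 30, 10)          # 1: complete recovery
#' @export
resilience_index <- function(c0, p0, px) {
  stopifnot(is.numeric(c0), is.numeric(p0), is.numeric(px))
  if (any(!is.finite(c0)) || any(!is.finite(p0)) || any(!is.finite(px)))
    stop("c0, p0 and px must be finite")
  n <- max(length(c0), length(p0), length(px))
  c0 <- rep_len(c0, n); p0 <- rep_len(p0, n); px <- rep_len(px, n)
  d0 <- abs(c0 - p0)
  dx <- abs(c0 - px)
  ifelse(d0 == 0, NA_real_, 2 * d0 / (d0 + dx) - 1)
}

#' Mean of a per-sample variable within one (area, group) cell
#'
#' @param values Named numeric vector (names are sample ids) or unnamed vector
#'   aligned with `metadata$sample_id`.
#' @param metadata Metadata data frame (see [read_sample_metadata()]).
#' @param area Area label.
#' @param group One of `"reference"`, `"flooding"`, `"recovery"`.
#' @return Arithmetic mean over the matching samples.
#' @export
group_mean <- function(values, metadata, area, group) {
  group <- match.arg(tolower(group), GROUP_LEVELS)
  values <- align_values(values, metadata)
  sel <- metadata$area == area & metadata$group == group
  if (!any(sel))
    stop(sprintf("no samples in area '%s', group '%s'", area, group))
  mean(values[sel])
}

# Align a value vector to metadata rows, by name when names are present.
align_values <- function(values, metadata) {
  if (!is.null(names(values))) {
    missing_v <- setdiff(metadata$sample_id, names(values))
    if (length(missing_v))
      stop("values missing for samples: ", paste(missing_v, collapse = ", "))
    values <- values[metadata$sample_id]
  } else if (length(values) != nrow(metadata)) {
    stop("unnamed `values` must have one entry per metadata row")
  }
  unname(values)
}

#' Resistance/resilience profile of one variable in one area
#'
#' Computes group means over the three groups of `area`, then RS from the
#' reference and flooding means and RL adding the recovery mean.
#'
#' @inheritParams group_mean
#' @param variable_name Label for the variable (e.g. `"abundance"`).
#' @param units Units string, echoed in the result.
#' @return A one-row data frame: `area`, `variable`, `units`, `c0`, `p0`,
#'   `px`, `rs`, `rl` (full precision; round for presentation).
#' @examples
#' md <- data.frame(sample_id = paste0("s", 1:6),
#'                  area = "AA",
#'                  group = rep(c("reference", "flooding", "recovery"), each = 2))
#' x <- c(3.2e8, 3.2e8, 1.2e9, 1.2e9, 2.1e8, 2.1e8)
#' rs_rl_profile(x, md, "AA", "abundance")
#' @export
rs_rl_profile <- function(values, metadata, area, variable_name = "value",
                          units = "") {
  groups_here <- unique(metadata$group[metadata$area == area])
  missing_g <- setdiff(GROUP_LEVELS, groups_here)
  if (length(missing_g))
    stop(sprintf("area '%s' lacks group(s): %s", area,
                 paste(missing_g, collapse = ", ")))
  c0 <- group_mean(values, metadata, area, "reference")
  p0 <- group_mean(values, metadata, area, "flooding")
  px <- group_mean(values, metadata, area, "recovery")
  data.frame(area = area, variable = variable_name, units = units,
             c0 = c0, p0 = p0, px = px,
             rs = resistance_index(c0, p0),
             rl = resilience_index(c0, p0, px),
             stringsAsFactors = FALSE)
}

#' Per-taxon RS/RL from relative abundances
#'
#' Applies [rs_rl_profile()] to each taxon's per-sample relative abundance
#' within one area. Taxa absent from every sample of the area get `rs = 1`
#' (nothing changed) and undefined `rl`.
#'
#' @param composition A `composition_table` from [relative_abundance()].
#' @param metadata Metadata data frame.
#' @param area Area label.
#' @param taxa Character vector of taxon ids to profile.
#' @return Data frame with one row per taxon (columns as [rs_rl_profile()]).
#' @export
taxon_rs_rl <- function(composition, metadata, area, taxa) {
  unknown <- setdiff(taxa, rownames(composition$proportions))
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  rows <- lapply(taxa, function(tx) {
    v <- composition$proportions[tx, ]
    rs_rl_profile(v, metadata, area, variable_name = tx,
                  units = "proportion")
  })
  do.call(rbind, rows)
}

#' Most abundant taxa within an area
#'
#' Ranks taxa by their total relative abundance over the samples of `area`
#' (or over all samples when `area` is `NULL`).
#'
#' @inheritParams taxon_rs_rl
#' @param k Number of taxa to return.
#' @return Character vector of taxon ids, most abundant first.
#' @export
top_taxa <- function(composition, metadata = NULL, area = NULL, k = 4) {
  p <- composition$proportions
  if (!is.null(area)) {
    if (is.null(metadata)) stop("`metadata` is required when `area` is given")
    keep <- metadata$sample_id[metadata$area == area]
    keep <- intersect(colnames(p), keep)
    if (!length(keep)) stop(sprintf("no samples in area '%s'", area))
    p <- p[, keep, drop = FALSE]
  }
  totals <- rowSums(p)
  names(sort(totals, decreasing = TRUE))[seq_len(min(k, nrow(p)))]
}
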