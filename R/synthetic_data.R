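# Synthetic two-area, three-group datasets -------------------------------------
#
# Emulates a riparian flooding-gradient soil survey: two study areas with
# contrasting pollution levels, each sampled in three groups (reference soils
# never flooded, currently flooded soils, recovery soils re-exposed after
# flooding). Per sample the generator draws genus proportions from a
# logistic-normal-like model (log-normal latent abundances, renormalised) and
# counts from a multinomial at fixed sequencing depth, mirroring rarefied
# amplicon tables; per-sample total 16S copy numbers come from a log-normal
# around configured group means. Ground-truth resistance/resilience indices
# and planted genus-genus correlations are known analytically, so parameter
# recovery of every downstream stage can be tested.

# Built-in archaeal genus lineages used for default taxonomies (ammonia
# oxidisers, methanogens, and assorted other archaea typical of riparian soil).
ARCHAEAL_LINEAGES <- c(
  Nitrososphaera       = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae;Nitrososphaera",
  Nitrosopumilus       = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilaceae;Nitrosopumilus",
  Nitrosotalea         = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosotaleales;Nitrosotaleaceae;Nitrosotalea",
  Nitrosotenuis        = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilaceae;Nitrosotenuis",
  Nitrosoarchaeum      = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrosopumilales;Nitrosopumilaceae;Nitrosoarchaeum",
  Nitrosocosmicus      = "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae;Nitrosocosmicus",
  Methanosaeta         = "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosaetaceae;Methanosaeta",
  Methanosarcina       = "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcinaceae;Methanosarcina",
  Methanobacterium     = "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobacterium",
  Methanoregula        = "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanoregulaceae;Methanoregula",
  Methanocella         = "Archaea;Euryarchaeota;Methanocellia;Methanocellales;Methanocellaceae;Methanocella",
  Methanolinea         = "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanoregulaceae;Methanolinea",
  Methanospirillum     = "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanospirillaceae;Methanospirillum",
  Methanomassiliicoccus = "Archaea;Euryarchaeota;Thermoplasmata;Methanomassiliicoccales;Methanomassiliicoccaceae;Methanomassiliicoccus",
  Methanobrevibacter   = "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter",
  Methanoculleus       = "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanomicrobiaceae;Methanoculleus",
  Methanosphaerula     = "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanoregulaceae;Methanosphaerula",
  Methanomethylovorans = "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcinaceae;Methanomethylovorans",
  Thermoplasma         = "Archaea;Euryarchaeota;Thermoplasmata;Thermoplasmatales;Thermoplasmataceae;Thermoplasma",
  Ferroplasma          = "Archaea;Euryarchaeota;Thermoplasmata;Thermoplasmatales;Ferroplasmaceae;Ferroplasma",
  Halobacterium        = "Archaea;Euryarchaeota;Halobacteria;Halobacteriales;Halobacteriaceae;Halobacterium",
  Thermogymnomonas     = "Archaea;Euryarchaeota;Thermoplasmata;Thermoplasmatales;Thermoplasmatales_Incertae_Sedis;Thermogymnomonas",
  Sulfolobus           = "Archaea;Crenarchaeota;Thermoprotei;Sulfolobales;Sulfolobaceae;Sulfolobus",
  Vulcanisaeta         = "Archaea;Crenarchaeota;Thermoprotei;Thermoproteales;Thermoproteaceae;Vulcanisaeta"
)

AOA_GENERA <- names(ARCHAEAL_LINEAGES)[1:6]
METHANOGEN_GENERA <- names(ARCHAEAL_LINEAGES)[7:18]

#' Configuration for the synthetic dataset generator
#'
#' Defaults reproduce the study design the generator emulates: two areas
#' (`NA` = low pollution, `AA` = high pollution), per-area group sizes of 4
#' reference / 13 flooding / 7 recovery soils, 24 archaeal genera, multinomial
#' counts at a rarefied depth of 20,826 reads, and per-(area, group) mean
#' total abundances equal to the qPCR group means of the emulated survey.
#' Flooding enriches methanogens and depletes ammonia oxidisers; the recovery
#' group returns close to the reference in the low-pollution area and only
#' part-way in the high-pollution area.
#'
#' @param areas Character vector of area labels.
#' @param n_reference,n_flooding,n_recovery Per-area group sizes (>= 1).
#' @param n_genera Number of genera (<= 24 uses built-in archaeal lineages;
#'   beyond that, synthetic placeholder genera are appended).
#' @param sequencing_depth Reads per sample (>= 100); every generated sample
#'   column sums to exactly this value.
#' @param baseline_log_mean Baseline log expected latent abundance per genus:
#'   scalar, or vector of length `n_genera`. The default is a geometric
#'   rank-abundance decline dominated by the first (ammonia-oxidising) genus.
#' @param baseline_log_sd Log-scale noise s.d. per genus (scalar or vector).
#' @param group_effects List of `list(area=, group=, genera=, fold=)` entries:
#'   multiplicative fold-change (> 0) on the expected latent abundance of
#'   `genera` for samples of that (area, group). Omitted cells default to 1.
#' @param abundance_means Named list `area -> c(reference=, flooding=,
#'   recovery=)` of expected total 16S copies per g dry-weight soil.
#' @param abundance_cv Coefficient of variation of per-sample total abundance
#'   (log-normal); `0` gives noiseless group means.
#' @param planted_edges Data frame (or NULL) with columns `genus_a`,
#'   `genus_b`, `sign` (+1/-1) of genus pairs given a shared latent factor so
#'   their abundances correlate with the planted sign.
#' @param planted_loading Loading of the shared factor on the log scale;
#'   relative to `baseline_log_sd` it sets the planted correlation strength
#'   (log-scale correlation `loading^2 / (loading^2 + sd^2)`).
#' @param seed Master integer seed; all draws derive from it.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(areas = c("NA", "AA"),
                             n_reference = 4, n_flooding = 13, n_recovery = 7,
                             n_genera = 24,
                             sequencing_depth = 20826,
                             baseline_log_mean = NULL,
                             baseline_log_sd = 0.5,
                             group_effects = NULL,
                             abundance_means = list(
                               "NA" = c(reference = 8.6e8, flooding = 1.9e9, recovery = 4.6e8),
                               "AA" = c(reference = 3.2e8, flooding = 1.2e9, recovery = 2.1e8)),
                             abundance_cv = 0.5,
                             planted_edges = NULL,
                             planted_loading = 1.2,
                             seed = 1) {
  stopifnot(length(areas) >= 1, !anyDuplicated(areas),
            n_reference >= 1, n_flooding >= 1, n_recovery >= 1,
            n_genera >= 2, sequencing_depth >= 100,
            abundance_cv >= 0, planted_loading >= 0)
  genera <- if (n_genera <= length(ARCHAEAL_LINEAGES)) {
    names(ARCHAEAL_LINEAGES)[seq_len(n_genera)]
  } else {
    extra <- paste0("Genus_", seq_len(n_genera - length(ARCHAEAL_LINEAGES)))
    c(names(ARCHAEAL_LINEAGES), extra)
  }
  if (is.null(baseline_log_mean))
    baseline_log_mean <- -0.35 * (seq_len(n_genera) - 1)
  baseline_log_mean <- rep_len(baseline_log_mean, n_genera)
  baseline_log_sd <- rep_len(baseline_log_sd, n_genera)
  if (any(baseline_log_sd < 0)) stop("baseline_log_sd must be non-negative")
  if (is.null(group_effects)) group_effects <- default_group_effects(areas, genera)
  for (ge in group_effects) {
    stopifnot(all(c("area", "group", "genera", "fold") %in% names(ge)))
    if (!ge$area %in% areas) stop("group_effects area not in areas: ", ge$area)
    if (!ge$group %in% GROUP_LEVELS) stop("unknown group in group_effects: ", ge$group)
    unknown <- setdiff(ge$genera, genera)
    if (length(unknown)) stop("group_effects reference unknown genera: ",
                              paste(unknown, collapse = ", "))
    if (any(ge$fold <= 0)) stop("group_effects fold-changes must be > 0")
  }
  missing_a <- setdiff(areas, names(abundance_means))
  if (length(missing_a)) stop("abundance_means missing for area(s): ",
                              paste(missing_a, collapse = ", "))
  for (a in areas)
    if (!all(GROUP_LEVELS %in% names(abundance_means[[a]])))
      stop("abundance_means[['", a, "']] must name reference, flooding, recovery")
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges, stringsAsFactors = FALSE)
    stopifnot(all(c("genus_a", "genus_b", "sign") %in% names(planted_edges)))
    if (any(planted_edges$genus_a == planted_edges$genus_b))
      stop("planted_edges may not contain self-pairs")
    unknown <- setdiff(c(planted_edges$genus_a, planted_edges$genus_b), genera)
    if (length(unknown)) stop("planted_edges reference unknown genera: ",
                              paste(unknown, collapse = ", "))
    if (!all(planted_edges$sign %in% c(-1, 1)))
      stop("planted_edges$sign must be +1 or -1")
  }
  structure(list(areas = areas, n_reference = n_reference,
                 n_flooding = n_flooding, n_recovery = n_recovery,
                 genera = genera, n_genera = n_genera,
                 sequencing_depth = as.integer(sequencing_depth),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 group_effects = group_effects,
                 abundance_means = abundance_means,
                 abundance_cv = abundance_cv,
                 planted_edges = planted_edges,
                 planted_loading = planted_loading,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Default disturbance response: flooding enriches methanogens ~3x and depletes
# ammonia oxidisers to 0.4x in both areas; the recovery group is nearly back
# to reference in the first (low-pollution) area and only part-way in the
# others.
default_group_effects <- function(areas, genera) {
  meth <- intersect(METHANOGEN_GENERA, genera)
  aoa <- intersect(AOA_GENERA, genera)
  out <- list()
  for (i in seq_along(areas)) {
    a <- areas[i]
    out <- c(out, list(
      list(area = a, group = "flooding", genera = meth, fold = 3.0),
      list(area = a, group = "flooding", genera = aoa, fold = 0.4)))
    if (i == 1) {
      out <- c(out, list(
        list(area = a, group = "recovery", genera = meth, fold = 1.15),
        list(area = a, group = "recovery", genera = aoa, fold = 0.95)))
    } else {
      out <- c(out, list(
        list(area = a, group = "recovery", genera = meth, fold = 1.8),
        list(area = a, group = "recovery", genera = aoa, fold = 0.65)))
    }
  }
  out
}

# Multiplicative fold per genus for one (area, group) cell.
effect_folds <- function(config, area, group) {
  folds <- stats::setNames(rep(1, config$n_genera), config$genera)
  for (ge in config$group_effects)
    if (ge$area == area && ge$group == group)
      folds[ge$genera] <- folds[ge$genera] * ge$fold
  folds
}

# Expected genus proportions for one (area, group) cell: renormalised
# baseline x fold.
expected_proportions <- function(config, area, group) {
  w <- exp(config$baseline_log_mean) * effect_folds(config, area, group)
  w / sum(w)
}

#' Analytic ground-truth RS/RL implied by a synthetic configuration
#'
#' Pure arithmetic on the configured expectations, no sampling: the total
#' abundance indices come from `abundance_means`, the per-genus indices from
#' the renormalised baseline-times-fold expected proportions.
#'
#' @param config A [synthetic_config()].
#' @return List of class `ground_truth`: `abundance` (data frame area, c0,
#'   p0, px, rs, rl), `genera` (data frame area, genus, expected group
#'   proportions, rs, rl), `planted_sign` (data frame or NULL).
#' @export
ground_truth_rs_rl <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ab <- do.call(rbind, lapply(config$areas, function(a) {
    m <- config$abundance_means[[a]]
    data.frame(area = a, variable = "abundance",
               c0 = unname(m["reference"]), p0 = unname(m["flooding"]),
               px = unname(m["recovery"]),
               rs = resistance_index(m[["reference"]], m[["flooding"]]),
               rl = resilience_index(m[["reference"]], m[["flooding"]],
                                     m[["recovery"]]),
               stringsAsFactors = FALSE)
  }))
  gen <- do.call(rbind, lapply(config$areas, function(a) {
    pr <- expected_proportions(config, a, "reference")
    pf <- expected_proportions(config, a, "flooding")
    px <- expected_proportions(config, a, "recovery")
    data.frame(area = a, genus = config$genera,
               c0 = unname(pr), p0 = unname(pf), px = unname(px),
               rs = resistance_index(pr, pf),
               rl = resilience_index(pr, pf, px),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(abundance = ab, genera = gen,
                 planted_sign = config$planted_edges),
            class = "ground_truth")
}

#' Generate a synthetic two-area, three-group dataset
#'
#' Draws, per sample: latent genus abundances
#' `log x_g = log(baseline_g * fold_g) + loading * shared factors + sd_g * noise`,
#' proportions by renormalisation, counts by a multinomial at
#' `sequencing_depth`, and a total 16S abundance from a log-normal with the
#' configured (area, group) mean and CV. Planted genus pairs share a latent
#' factor with +/- loading, inducing correlations of the planted sign.
#' Identical seeds give bit-identical datasets; each sample uses its own
#' deterministic substream of the master seed.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `table` (a [count_table] with built-in archaeal
#'   taxonomy), `metadata` (data frame with sample_id, area, group,
#'   elevation_m, flooding_duration_days), `abundance` (named numeric vector
#'   of 16S copies per g d.w.s.), `truth` (the [ground_truth_rs_rl()] of
#'   `config`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  md <- synthetic_metadata(config)
  n_samples <- nrow(md)
  counts <- matrix(0L, config$n_genera, n_samples,
                   dimnames = list(config$genera, md$sample_id))
  abundance <- stats::setNames(numeric(n_samples), md$sample_id)
  cv <- config$abundance_cv
  sdlog <- sqrt(log(1 + cv^2))
  edges <- config$planted_edges
  for (i in seq_len(n_samples)) {
    a <- md$area[i]; g <- md$group[i]
    mu <- config$baseline_log_mean + log(effect_folds(config, a, g))
    draw <- with_seed(substream_seed(config$seed, i), {
      z <- stats::rnorm(config$n_genera, 0, config$baseline_log_sd)
      if (!is.null(edges) && nrow(edges)) {
        f <- stats::rnorm(nrow(edges))
        for (e in seq_len(nrow(edges))) {
          ia <- match(edges$genus_a[e], config$genera)
          ib <- match(edges$genus_b[e], config$genera)
          z[ia] <- z[ia] + config$planted_loading * f[e]
          z[ib] <- z[ib] + edges$sign[e] * config$planted_loading * f[e]
        }
      }
      p <- exp(mu + z)
      p <- p / sum(p)
      cnt <- stats::rmultinom(1, config$sequencing_depth, p)[, 1]
      m_ab <- config$abundance_means[[a]][[g]]
      ab <- if (cv > 0)
        stats::rlnorm(1, meanlog = log(m_ab) - sdlog^2 / 2, sdlog = sdlog)
      else m_ab
      list(cnt = cnt, ab = ab)
    })
    counts[, i] <- as.integer(draw$cnt)
    abundance[i] <- draw$ab
  }
  taxonomy <- stats::setNames(
    ifelse(config$genera %in% names(ARCHAEAL_LINEAGES),
           ARCHAEAL_LINEAGES[config$genera],
           paste0("Archaea;Unknown_phylum;Unknown_class;Unknown_order;",
                  "Unknown_family;", config$genera)),
    config$genera)
  list(table = count_table(counts, taxonomy = taxonomy),
       metadata = md,
       abundance = abundance,
       truth = ground_truth_rs_rl(config))
}

# Sample sheet for the configured design. Reference soils sit at the
# never-flooded elevation (175.5 m); flooding soils below the water level;
# recovery soils previously flooded, now exposed.
synthetic_metadata <- function(config) {
  rows <- list()
  for (a in config$areas) {
    n <- c(reference = config$n_reference, flooding = config$n_flooding,
           recovery = config$n_recovery)
    for (g in names(n)) {
      k <- seq_len(n[[g]])
      elev <- switch(g,
        reference = rep(175.5, n[[g]]),
        flooding = seq(150, 170, length.out = n[[g]]),
        recovery = seq(170.5, 175, length.out = n[[g]]))
      afd <- switch(g,
        reference = rep(0, n[[g]]),
        flooding = round(seq(180, 60, length.out = n[[g]])),
        recovery = round(seq(55, 10, length.out = n[[g]])))
      rows[[paste(a, g)]] <- data.frame(
        sample_id = sprintf("%s_%s_%02d", a, substr(g, 1, 3), k),
        area = a, group = g, elevation_m = elev,
        flooding_duration_days = afd, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a generated dataset to a directory
#'
#' Emits the same TSV formats the readers accept (`counts.tsv`,
#' `metadata.tsv`, `abundance.tsv`) plus the ground truth as
#' `ground_truth.json`.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(dataset$table, file.path(dir, "counts.tsv"))
  write_sample_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(data.frame(sample_id = names(dataset$abundance),
                       abundance = unname(dataset$abundance),
                       stringsAsFactors = FALSE),
            file.path(dir, "abundance.tsv"))
  jsonlite::write_json(
    list(abundance = dataset$truth$abundance, genera = dataset$truth$genera,
         planted_sign = dataset$truth$planted_sign),
    file.path(dir, "ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
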