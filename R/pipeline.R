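# End-to-end study pipeline ----------------------------------------------------
#
# One config drives the whole per-area workflow: load or simulate -> rarefy ->
# aggregate to genus -> alpha diversity -> RS/RL (abundance, diversity
# indices, top-k taxa) -> pairwise ANOSIM -> co-occurrence network + topology.
# All outputs are plain TSV/GraphML/JSON and are pure functions of
# (inputs, config, seeds): running the same config twice gives byte-identical
# files.

#' Subset a count table to a set of samples
#'
#' @param table A [count_table].
#' @param ids Sample ids to keep (order preserved as given).
#' @return A [count_table] with those columns.
#' @export
subset_samples <- function(table, ids) {
  missing_ids <- setdiff(ids, colnames(table$counts))
  if (length(missing_ids))
    stop("samples not in table: ", paste(missing_ids, collapse = ", "))
  count_table(table$counts[, ids, drop = FALSE], taxonomy = table$taxonomy)
}

#' Validate a pipeline configuration
#'
#' A config is a named list with exactly one of:
#' * `input`: list with paths `counts`, `metadata` and optionally `abundance`
#'   (TSV with columns sample_id, abundance), or
#' * `simulate`: a [synthetic_config()] or a list of arguments for it;
#'
#' plus optional settings `rarefaction_depth` (`"min-sample"`, the default,
#' or an integer), `rank` (default `"genus"`; `NULL` to skip aggregation),
#' `rho_min` (0.6), `p_max` (0.01), `min_prevalence` (1/3),
#' `n_permutations` (999), `top_k` (4) and `seed` (1).
#'
#' @param config Named list (or path to a JSON file holding one).
#' @return The completed config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop("config must contain exactly one of 'input' or 'simulate'")
  defaults <- list(rarefaction_depth = "min-sample", rank = "genus",
                   rho_min = 0.6, p_max = 0.01, min_prevalence = 1 / 3,
                   n_permutations = 999, top_k = 4, seed = 1)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (!identical(config$rarefaction_depth, "min-sample") &&
      !(is.numeric(config$rarefaction_depth) && config$rarefaction_depth >= 1))
    stop("rarefaction_depth must be 'min-sample' or a positive integer")
  if (has_sim && !inherits(config$simulate, "synthetic_config"))
    config$simulate <- do.call(synthetic_config, as.list(config$simulate))
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full disturbance-response pipeline
#'
#' Executes every analysis stage per study area and writes, under `out_dir`:
#' `alpha_diversity_<area>.tsv`, `rs_rl_<area>.tsv` (abundance, Shannon,
#' Chao1, evenness and the top-k most abundant taxa), `anosim_<area>.tsv`
#' (all pairwise two-group comparisons), `network_<area>.graphml`,
#' `network_edges_<area>.tsv`, `topology_<area>.tsv`, and `manifest.json`
#' (thresholds, seeds, file checksums). Undefined resilience values and taxa
#' dropped as constant are reported as warnings and recorded as `NA`.
#'
#' @param config See [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results per area plus the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_files <- character(0)
  if (!is.null(config$simulate)) {
    data <- stage("simulate", generate_dataset(config$simulate))
    table <- data$table; metadata <- data$metadata; abundance <- data$abundance
  } else {
    inp <- config$input
    stopifnot(!is.null(inp$counts), !is.null(inp$metadata))
    table <- stage("read counts", read_count_table(inp$counts))
    metadata <- stage("read metadata", read_sample_metadata(inp$metadata))
    abundance <- NULL
    if (!is.null(inp$abundance)) {
      ab <- utils::read.delim(inp$abundance, colClasses = c("character", "numeric"),
                              na.strings = character(0))
      abundance <- stats::setNames(ab$abundance, ab$sample_id)
    }
    input_files <- unlist(inp)
  }
  stage("metadata check", check_samples_covered(table, metadata))
  metadata <- metadata[match(colnames(table$counts), metadata$sample_id), ]

  depth <- if (identical(config$rarefaction_depth, "min-sample"))
    min(sample_sums(table)) else as.integer(config$rarefaction_depth)
  table <- stage("rarefaction", rarefy_table(table, depth, seed = config$seed))
  if (!is.null(config$rank) && !is.null(table$taxonomy))
    table <- stage("taxonomic aggregation", aggregate_to_rank(table, config$rank))

  results <- list()
  for (a in unique(metadata$area)) {
    md_a <- metadata[metadata$area == a, ]
    tab_a <- subset_samples(table, md_a$sample_id)
    alpha <- stage("alpha diversity", {
      out <- alpha_diversity(tab_a)
      merge(out, md_a[, c("sample_id", "area", "group")], by = "sample_id",
            sort = FALSE)
    })
    write_tsv(alpha, file.path(out_dir, sprintf("alpha_diversity_%s.tsv", a)))

    rsrl <- stage("resilience", {
      comp_a <- relative_abundance(tab_a)
      vars <- list(
        shannon = stats::setNames(alpha$shannon, alpha$sample_id),
        chao1 = stats::setNames(alpha$chao1, alpha$sample_id),
        evenness = stats::setNames(alpha$evenness, alpha$sample_id))
      rows <- list()
      if (!is.null(abundance))
        rows$abundance <- rs_rl_profile(abundance[md_a$sample_id], md_a, a,
                                        "abundance", units = "copies per g d.w.s.")
      for (v in names(vars))
        rows[[v]] <- rs_rl_profile(vars[[v]], md_a, a, v)
      top <- top_taxa(comp_a, md_a, a, k = config$top_k)
      rows$taxa <- taxon_rs_rl(comp_a, md_a, a, top)
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      if (any(is.na(out$rl)))
        warning("undefined resilience (no disturbance displacement) for: ",
                paste(out$variable[is.na(out$rl)], collapse = ", "))
      out
    })
    write_tsv(rsrl, file.path(out_dir, sprintf("rs_rl_%s.tsv", a)))

    anosim_tab <- stage("anosim", {
      d <- bray_curtis_matrix(tab_a)
      out <- pairwise_anosim(d, stats::setNames(md_a$group, md_a$sample_id),
                             n_permutations = config$n_permutations,
                             seed = config$seed)
      cbind(area = a, out)
    })
    write_tsv(anosim_tab, file.path(out_dir, sprintf("anosim_%s.tsv", a)))

    net_out <- stage("network", {
      filt <- filter_network_taxa(tab_a, min_prevalence = config$min_prevalence)
      corr <- spearman_matrix(relative_abundance(filt))
      phyl <- if (!is.null(filt$taxonomy)) taxonomy_at_rank(filt, "phylum") else NULL
      net <- build_network(corr, rho_min = config$rho_min, p_max = config$p_max,
                           phylum = phyl)
      topo <- cbind(area = a, topology_summary(net, modularity_seed = config$seed))
      export_network(net, file.path(out_dir, sprintf("network_%s.graphml", a)),
                     "graphml")
      export_network(net, file.path(out_dir, sprintf("network_edges_%s.tsv", a)),
                     "edge_tsv")
      write_tsv(topo, file.path(out_dir, sprintf("topology_%s.tsv", a)))
      list(network = net, topology = topo)
    })

    results[[a]] <- list(alpha_diversity = alpha, rs_rl = rsrl,
                         anosim = anosim_tab, network = net_out$network,
                         topology = net_out$topology)
  }

  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ripresil")),
    seed = config$seed,
    rarefaction_depth = depth,
    rank = config$rank,
    thresholds = list(rho_min = config$rho_min, p_max = config$p_max,
                      min_prevalence = config$min_prevalence),
    n_permutations = config$n_permutations,
    top_k = config$top_k,
    input_checksums = as.list(tools::md5sum(input_files)),
    output_checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$output_checksums) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
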