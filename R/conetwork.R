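# Co-occurrence networks from thresholded Spearman correlations ---------------
#
# Nodes are genera, edges are strong (|rho| > rho_min) and significant
# (p < p_max) pairwise Spearman rank correlations of relative abundances
# across samples. Topology summaries follow the usual network-ecology
# vocabulary: average degree avgK = 2E/N, average path length and diameter on
# the largest connected component, mean local clustering, and Louvain
# modularity on the unweighted, sign-ignored graph.

#' Pairwise Spearman correlation matrices
#'
#' Ranks each taxon's abundances across samples (average ranks on ties) and
#' computes Pearson correlation on the ranks; two-sided p values use the t
#' approximation on n - 2 degrees of freedom. Taxa constant across samples
#' have undefined correlations: their pairs are `NA` with a warning.
#'
#' @param composition A `composition_table` (or [count_table]) with at least
#'   5 samples and 2 taxa.
#' @return List of class `correlation_matrices`: `taxon_ids`, `rho`
#'   (symmetric, unit diagonal), `p` (symmetric, zero diagonal by
#'   convention), `n_samples`.
#' @export
spearman_matrix <- function(composition) {
  m <- if (inherits(composition, "composition_table")) composition$proportions
       else composition$counts
  if (ncol(m) < 5) stop("need at least 5 samples for correlation analysis")
  if (nrow(m) < 2) stop("need at least 2 taxa")
  n <- ncol(m)
  ranks <- t(apply(m, 1, rank)) # average ranks on ties
  constant <- apply(ranks, 1, function(x) max(x) == min(x))
  if (any(constant))
    warning("taxa constant across samples (correlations undefined): ",
            paste(rownames(m)[constant], collapse = ", "))
  centered <- ranks - rowMeans(ranks)
  ss <- sqrt(rowSums(centered^2))
  ss[constant] <- NA_real_
  rho <- tcrossprod(centered / ss)
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- ifelse(constant, NA_real_, 1)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- list(rownames(m), rownames(m))
  structure(list(taxon_ids = rownames(m), rho = rho, p = p, n_samples = n),
            class = "correlation_matrices")
}

#' Filter taxa before network construction
#'
#' Keeps taxa detected in at least `min_prevalence` of samples and with mean
#' relative abundance at least `min_mean_abundance`. The default prevalence
#' of 1/3 reflects that correlations estimated from taxa absent in most
#' samples are dominated by tied zeros.
#'
#' @param table A [count_table].
#' @param min_prevalence Minimum fraction of samples with a positive count.
#' @param min_mean_abundance Minimum mean relative abundance.
#' @return Filtered [count_table].
#' @export
filter_network_taxa <- function(table, min_prevalence = 1 / 3,
                                min_mean_abundance = 0) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1,
            min_mean_abundance >= 0, min_mean_abundance <= 1)
  m <- table$counts
  prevalence <- rowMeans(m > 0)
  mean_ab <- rowMeans(sweep(m, 2, colSums(m), "/"))
  keep <- prevalence >= min_prevalence & mean_ab >= min_mean_abundance
  if (!any(keep))
    stop("no taxa pass the filter; relax min_prevalence/min_mean_abundance")
  count_table(m[keep, , drop = FALSE],
              taxonomy = if (is.null(table$taxonomy)) NULL
                         else table$taxonomy[rownames(m)[keep]])
}

#' Construct a co-occurrence network object
#'
#' Low-level constructor used by [build_network()] and available for building
#' networks from externally computed edge lists.
#'
#' @param nodes Data frame with columns `taxon_id` and optionally `phylum`.
#' @param edges Data frame with columns `taxon_a`, `taxon_b`, `rho`, `p`
#'   (may have zero rows).
#' @param rho_min,p_max Thresholds recorded (and enforced) on the edges.
#' @return Object of class `cooccurrence_network`: `nodes` (with recomputed
#'   `degree`), `edges` (with `sign` column), `rho_min`, `p_max`.
#' @export
cooccurrence_network <- function(nodes, edges, rho_min = 0.6, p_max = 0.01) {
  stopifnot(is.data.frame(nodes), "taxon_id" %in% names(nodes))
  if (!"phylum" %in% names(nodes)) nodes$phylum <- NA_character_
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate node taxon ids")
  if (nrow(edges)) {
    stopifnot(all(c("taxon_a", "taxon_b", "rho", "p") %in% names(edges)))
    if (any(edges$taxon_a == edges$taxon_b)) stop("self-loop edges not allowed")
    unknown <- setdiff(c(edges$taxon_a, edges$taxon_b), nodes$taxon_id)
    if (length(unknown)) stop("edges reference unknown nodes: ",
                              paste(unknown, collapse = ", "))
    if (any(abs(edges$rho) <= rho_min) || any(edges$p >= p_max))
      stop("edges violate thresholds |rho| > ", rho_min, ", p < ", p_max)
    key <- paste(pmin(edges$taxon_a, edges$taxon_b),
                 pmax(edges$taxon_a, edges$taxon_b))
    if (anyDuplicated(key)) stop("duplicate edges")
    edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  } else {
    edges <- data.frame(taxon_a = character(0), taxon_b = character(0),
                        rho = numeric(0), p = numeric(0), sign = character(0),
                        stringsAsFactors = FALSE)
  }
  deg <- table(factor(c(edges$taxon_a, edges$taxon_b), levels = nodes$taxon_id))
  nodes$degree <- as.integer(deg[nodes$taxon_id])
  structure(list(nodes = nodes, edges = edges, rho_min = rho_min, p_max = p_max),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "cooccurrence_network: %d nodes, %d edges (%d positive, %d negative); |rho| > %g, p < %g\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive"),
    sum(x$edges$sign == "negative"), x$rho_min, x$p_max))
  invisible(x)
}

#' Build a network from correlation matrices
#'
#' An edge joins taxa i and j iff `|rho_ij| > rho_min` **and** `p_ij < p_max`
#' (strict inequalities). Isolated taxa stay in the node set (their degree is
#' 0); drop them with `drop_isolated = TRUE` to count only connected genera.
#'
#' @param corr A `correlation_matrices` object from [spearman_matrix()].
#' @param rho_min Correlation-magnitude threshold (default 0.6).
#' @param p_max Significance threshold (default 0.01).
#' @param drop_isolated Drop nodes with no incident edge.
#' @param phylum Optional named character vector taxon id -> phylum for node
#'   annotation (see [taxonomy_at_rank()]).
#' @return A [cooccurrence_network()].
#' @export
build_network <- function(corr, rho_min = 0.6, p_max = 0.01,
                          drop_isolated = FALSE, phylum = NULL) {
  stopifnot(inherits(corr, "correlation_matrices"),
            rho_min >= 0, rho_min <= 1, p_max > 0, p_max <= 1)
  rho <- corr$rho; p <- corr$p
  sel <- which(upper.tri(rho) & !is.na(rho) & abs(rho) > rho_min & p < p_max,
               arr.ind = TRUE)
  edges <- data.frame(taxon_a = corr$taxon_ids[sel[, 1]],
                      taxon_b = corr$taxon_ids[sel[, 2]],
                      rho = rho[sel], p = p[sel], stringsAsFactors = FALSE)
  nodes <- data.frame(taxon_id = corr$taxon_ids, stringsAsFactors = FALSE)
  if (!is.null(phylum)) nodes$phylum <- unname(phylum[nodes$taxon_id])
  net <- cooccurrence_network(nodes, edges, rho_min = rho_min, p_max = p_max)
  if (drop_isolated) {
    keep <- net$nodes$degree > 0
    net <- cooccurrence_network(net$nodes[keep, c("taxon_id", "phylum")],
                                net$edges[, c("taxon_a", "taxon_b", "rho", "p")],
                                rho_min = rho_min, p_max = p_max)
  }
  net
}

#' Convert a co-occurrence network to an igraph graph
#'
#' @param net A `cooccurrence_network`.
#' @return Undirected [igraph::graph] with vertex attributes `phylum`,
#'   `degree` and edge attributes `rho`, `p`, `sign`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b", "rho", "p", "sign")],
    directed = FALSE,
    vertices = net$nodes[, c("taxon_id", "phylum", "degree")])
  g
}

#' Topology summary of a co-occurrence network
#'
#' Reports node/edge counts (split by correlation sign), average degree
#' `avgK = 2E/N`, average path length and diameter on the largest connected
#' component (unweighted), mean local clustering coefficient (nodes of degree
#' < 2 contribute 0), and best modularity Q from Louvain community detection
#' on the unweighted, sign-ignored graph under a fixed seed.
#'
#' @param net A `cooccurrence_network` with at least one node.
#' @param modularity_seed Seed for the Louvain run.
#' @return One-row data frame: `n_nodes`, `n_edges`, `n_positive_edges`,
#'   `n_negative_edges`, `average_degree`, `average_path_length`, `diameter`,
#'   `clustering_coefficient`, `modularity`, `largest_component_size`.
#' @export
topology_summary <- function(net, modularity_seed = 1) {
  stopifnot(inherits(net, "cooccurrence_network"))
  n_nodes <- nrow(net$nodes)
  if (n_nodes == 0) stop("network has no nodes")
  n_edges <- nrow(net$edges)
  g <- as_igraph(net)
  if (n_edges > 0) {
    comp <- igraph::components(g)
    giant_ids <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(g, giant_ids)
    apl <- igraph::mean_distance(sub, weights = NA)
    diam <- igraph::diameter(sub, weights = NA)
    local_cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    cc <- mean(local_cc)
    q <- with_seed(modularity_seed, {
      cl <- igraph::cluster_louvain(g, weights = NA)
      igraph::modularity(cl)
    })
    giant_size <- max(comp$csize)
  } else {
    apl <- NA_real_; diam <- NA_real_; cc <- 0; q <- NA_real_; giant_size <- 1L
  }
  data.frame(n_nodes = n_nodes, n_edges = n_edges,
             n_positive_edges = sum(net$edges$sign == "positive"),
             n_negative_edges = sum(net$edges$sign == "negative"),
             average_degree = 2 * n_edges / n_nodes,
             average_path_length = apl, diameter = diam,
             clustering_coefficient = cc, modularity = q,
             largest_component_size = giant_size,
             stringsAsFactors = FALSE)
}

#' Export a co-occurrence network
#'
#' Writes GraphML (via igraph), GEXF 1.2, or a plain edge-list TSV
#' (`taxon_a`, `taxon_b`, `rho`, `p`, `sign`). GraphML and GEXF preserve node
#' attributes (phylum, degree) and edge attributes (rho, sign) and load in
#' standard graph viewers.
#'
#' @param net A `cooccurrence_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"gexf"`, or `"edge_tsv"`.
#' @export
export_network <- function(net, path, format = c("graphml", "gexf", "edge_tsv")) {
  format <- match.arg(format)
  switch(format,
    graphml = {
      g <- as_igraph(net)
      igraph::V(g)$phylum <- ifelse(is.na(igraph::V(g)$phylum), "",
                                    igraph::V(g)$phylum)
      igraph::write_graph(g, path, format = "graphml")
    },
    gexf = write_gexf(net, path),
    edge_tsv = write_tsv(net$edges, path)
  )
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# Minimal static GEXF 1.2 writer (undirected, node/edge attvalues).
write_gexf <- function(net, path) {
  nodes <- net$nodes
  edges <- net$edges
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph mode="static" defaultedgetype="undirected">')
  w('    <attributes class="node">')
  w('      <attribute id="phylum" title="phylum" type="string"/>')
  w('      <attribute id="degree" title="degree" type="integer"/>')
  w('    </attributes>')
  w('    <attributes class="edge">')
  w('      <attribute id="rho" title="rho" type="double"/>')
  w('      <attribute id="sign" title="sign" type="string"/>')
  w('    </attributes>')
  w('    <nodes>')
  for (i in seq_len(nrow(nodes))) {
    w('      <node id="%s" label="%s">', xml_escape(nodes$taxon_id[i]),
      xml_escape(nodes$taxon_id[i]))
    w('        <attvalues>')
    w('          <attvalue for="phylum" value="%s"/>',
      xml_escape(ifelse(is.na(nodes$phylum[i]), "", nodes$phylum[i])))
    w('          <attvalue for="degree" value="%d"/>', nodes$degree[i])
    w('        </attvalues>')
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  for (i in seq_len(nrow(edges))) {
    w('      <edge id="%d" source="%s" target="%s" weight="%.6f">', i,
      xml_escape(edges$taxon_a[i]), xml_escape(edges$taxon_b[i]),
      abs(edges$rho[i]))
    w('        <attvalues>')
    w('          <attvalue for="rho" value="%.10g"/>', edges$rho[i])
    w('          <attvalue for="sign" value="%s"/>', edges$sign[i])
    w('        </attvalues>')
    w('      </edge>')
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}
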