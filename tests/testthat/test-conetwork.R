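test_that("Spearman matrix matches a brute-force rank-then-Pearson oracle", {
  set.seed(2)
  m <- matrix(runif(9 * 8), nrow = 9)
  m[3, 1:4] <- m[3, 5] # introduce ties in one taxon
  ct <- make_counts(matrix(as.integer(m * 1000) + 1L, nrow = 9))
  comp <- relative_abundance(ct)
  corr <- spearman_matrix(comp)
  p <- comp$proportions
  for (i in 1:8) {
    for (j in (i + 1):9) {
      oracle <- cor(rank(p[i, ]), rank(p[j, ])) # rank then Pearson
      expect_equal(corr$rho[i, j], oracle, tolerance = 1e-12)
    }
  }
  # agrees with R's own Spearman as well
  expect_equal(unname(corr$rho), unname(cor(t(p), method = "spearman")),
               tolerance = 1e-12)
  expect_equal(corr$rho, t(corr$rho))
  expect_equal(unname(diag(corr$rho)), rep(1, 9))
  expect_equal(unname(diag(corr$p)), rep(0, 9))
  expect_true(all(corr$p >= 0 & corr$p <= 1))
})

test_that("Spearman hits exact +/-1 for monotone pairs and flags constant taxa", {
  x <- c(3, 9, 1, 7, 5, 2)
  m <- rbind(a = x, b = 2 * x, c = max(x) + 1 - x, d = rep(4, 6))
  ct <- make_counts(m, taxa = rownames(m))
  expect_warning(corr <- spearman_matrix(count_table(ct$counts)), "constant.*d")
  expect_equal(corr$rho["a", "b"], 1)
  expect_equal(corr$rho["a", "c"], -1)
  expect_equal(corr$p["a", "b"], 0)
  expect_true(all(is.na(corr$rho["d", c("a", "b", "c")])))
  expect_error(spearman_matrix(make_counts(matrix(1:8, nrow = 2))), "5 samples")
})

test_that("taxon filtering applies prevalence and abundance thresholds at the boundary", {
  set.seed(6)
  n_genera <- 30
  m <- matrix(0L, n_genera, 10,
              dimnames = list(paste0("t", seq_len(n_genera)), paste0("s", 1:10)))
  prevalences <- sample(1:10, n_genera, replace = TRUE)
  for (i in seq_len(n_genera)) m[i, sample(10, prevalences[i])] <- rpois(prevalences[i], 20) + 1L
  ct <- make_counts(m)
  # identity at zero thresholds
  expect_identical(filter_network_taxa(ct, 0, 0)$counts, ct$counts)
  # boundary: present in 3 of 10 samples is kept at 0.3, dropped just above
  kept_03 <- taxon_ids(filter_network_taxa(ct, 0.3, 0))
  kept_031 <- taxon_ids(filter_network_taxa(ct, 0.31, 0))
  expect_setequal(kept_03, rownames(m)[prevalences >= 3])
  expect_setequal(kept_031, rownames(m)[prevalences >= 4])
  # hand enumeration oracle for the joint rule
  mean_ab <- rowMeans(sweep(m, 2, colSums(m), "/"))
  joint <- taxon_ids(filter_network_taxa(ct, 0.5, 0.02))
  expect_setequal(joint, rownames(m)[prevalences >= 5 & mean_ab >= 0.02])
  expect_error(filter_network_taxa(ct, 1, 1), "no taxa pass")
})

test_that("network construction enforces strict thresholds and keeps isolated nodes", {
  rho <- diag(4)
  dimnames(rho) <- list(paste0("g", 1:4), paste0("g", 1:4))
  p <- matrix(1, 4, 4, dimnames = dimnames(rho)); diag(p) <- 0
  rho["g1", "g2"] <- rho["g2", "g1"] <- 0.7;  p["g1", "g2"] <- p["g2", "g1"] <- 0.005
  rho["g1", "g3"] <- rho["g3", "g1"] <- -0.8; p["g1", "g3"] <- p["g3", "g1"] <- 0.001
  rho["g2", "g3"] <- rho["g3", "g2"] <- 0.6;  p["g2", "g3"] <- p["g3", "g2"] <- 0.001
  rho["g2", "g4"] <- rho["g4", "g2"] <- 0.9;  p["g2", "g4"] <- p["g4", "g2"] <- 0.01
  corr <- structure(list(taxon_ids = paste0("g", 1:4), rho = rho, p = p,
                         n_samples = 10), class = "correlation_matrices")
  net <- build_network(corr, rho_min = 0.6, p_max = 0.01)
  # rho = 0.6 and p = 0.01 fail the strict inequalities
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$taxon_a, net$edges$taxon_b),
                  c("g1 g2", "g1 g3"))
  expect_equal(sort(net$edges$sign), c("negative", "positive"))
  expect_equal(net$nodes$degree[net$nodes$taxon_id == "g4"], 0L)
  # rho_min = 1 excludes everything (strict)
  expect_equal(nrow(build_network(corr, rho_min = 1, p_max = 0.5)$edges), 0)
  dropped <- build_network(corr, drop_isolated = TRUE)
  expect_setequal(dropped$nodes$taxon_id, c("g1", "g2", "g3"))
})

test_that("edge sets are invariant to sample and taxon ordering", {
  set.seed(44)
  m <- matrix(rpois(20 * 24, 30) + 1L, nrow = 20)
  ct <- make_counts(m)
  net1 <- build_network(spearman_matrix(relative_abundance(ct)),
                        rho_min = 0.3, p_max = 0.2)
  perm_t <- sample(20); perm_s <- sample(24)
  ct2 <- count_table(ct$counts[perm_t, perm_s])
  net2 <- build_network(spearman_matrix(relative_abundance(ct2)),
                        rho_min = 0.3, p_max = 0.2)
  key <- function(net) sort(paste(pmin(net$edges$taxon_a, net$edges$taxon_b),
                                  pmax(net$edges$taxon_a, net$edges$taxon_b)))
  expect_equal(key(net2), key(net1))
})

test_that("topology summary reproduces closed forms on canonical graphs", {
  # complete graph on 4 nodes
  pairs <- t(combn(paste0("g", 1:4), 2))
  net <- cooccurrence_network(
    data.frame(taxon_id = paste0("g", 1:4)),
    data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2], rho = 0.9, p = 1e-4))
  topo <- topology_summary(net)
  expect_equal(topo$average_degree, 3)
  expect_equal(topo$average_path_length, 1)
  expect_equal(topo$diameter, 1)
  expect_equal(topo$clustering_coefficient, 1)
  expect_equal(topo$n_positive_edges, 6)
  # avgK identity 2E/N on an arbitrary constructed network
  expect_equal(topo$average_degree, 2 * topo$n_edges / topo$n_nodes)
})

test_that("Louvain modularity on two disjoint 5-cliques is exactly 1/2", {
  nodes <- paste0("g", 1:10)
  e1 <- t(combn(nodes[1:5], 2)); e2 <- t(combn(nodes[6:10], 2))
  edges <- rbind(e1, e2)
  net <- cooccurrence_network(
    data.frame(taxon_id = nodes),
    data.frame(taxon_a = edges[, 1], taxon_b = edges[, 2], rho = 0.8, p = 1e-5))
  # closed form for the two-clique partition: 2 * (10/20 - (20/40)^2) = 0.5,
  # and no bipartition does better (verified by exhaustive search below)
  topo <- topology_summary(net, modularity_seed = 3)
  expect_equal(topo$modularity, 0.5, tolerance = 1e-12)
  g <- as_igraph(net)
  best_bipart <- max(sapply(0:(2^10 - 1), function(mask) {
    mem <- as.integer(intToBits(mask))[1:10] + 1L
    igraph::modularity(g, mem)
  }))
  expect_equal(best_bipart, 0.5, tolerance = 1e-12)
  # determinism across repeated runs with one seed
  expect_identical(topology_summary(net, modularity_seed = 7)$modularity,
                   topology_summary(net, modularity_seed = 7)$modularity)
  # Q is stable across seeds on this fixture and within theoretical bounds
  qs <- sapply(1:5, function(s) topology_summary(net, modularity_seed = s)$modularity)
  expect_lt(diff(range(qs)), 0.05)
  expect_true(all(qs >= -0.5 & qs <= 1))
})

test_that("path length and diameter are computed on the largest component", {
  # a path of 3 nodes plus an isolated pair-component of 2
  net <- cooccurrence_network(
    data.frame(taxon_id = paste0("g", 1:5)),
    data.frame(taxon_a = c("g1", "g2", "g4"), taxon_b = c("g2", "g3", "g5"),
               rho = c(0.9, 0.9, -0.9), p = 1e-4))
  topo <- topology_summary(net)
  expect_equal(topo$largest_component_size, 3)
  expect_equal(topo$average_path_length, (1 + 1 + 2) / 3)
  expect_equal(topo$diameter, 2)
  expect_equal(topo$n_negative_edges, 1)
})

test_that("network export round-trips through GraphML and writes valid GEXF and TSV", {
  nodes <- data.frame(taxon_id = paste0("g", 1:5),
                      phylum = c("Thaumarchaeota", "Euryarchaeota",
                                 "Euryarchaeota", "Crenarchaeota", NA))
  edges <- data.frame(taxon_a = c("g1", "g2", "g3"),
                      taxon_b = c("g2", "g3", "g4"),
                      rho = c(0.75, -0.81, 0.92), p = c(1e-3, 1e-4, 1e-6))
  net <- cooccurrence_network(nodes, edges)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g2)$name, nodes$taxon_id)
  reread <- igraph::as_data_frame(g2, "edges")
  expect_setequal(paste(reread$from, reread$to), paste(edges$taxon_a, edges$taxon_b))
  expect_equal(sort(reread$rho), sort(edges$rho), tolerance = 1e-12)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_tsv")
  back <- read.delim(tsv)
  expect_equal(nrow(back), 3)
  expect_equal(back$sign, c("positive", "negative", "positive"))

  skip_if_not_installed("xml2")
  gexf <- withr::local_tempfile(fileext = ".gexf")
  export_network(net, gexf, "gexf")
  doc <- xml2::read_xml(gexf)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")), 5)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 3)

  # an edgeless network still exports a valid file with nodes only
  empty <- cooccurrence_network(nodes, edges[0, ])
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, gml2, "graphml")
  expect_equal(igraph::vcount(igraph::read_graph(gml2, format = "graphml")), 5)
})
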