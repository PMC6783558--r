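small_cfg <- function(...) {
  args <- utils::modifyList(list(sequencing_depth = 1000, seed = 5), list(...))
  do.call(synthetic_config, args)
}

test_that("configuration validation rejects inconsistent designs up front", {
  expect_error(synthetic_config(sequencing_depth = 50), "sequencing_depth")
  expect_error(synthetic_config(n_reference = 0), "n_reference")
  expect_error(small_cfg(group_effects = list(
    list(area = "NA", group = "flooding", genera = "Nosuchgenus", fold = 2))),
    "unknown genera")
  expect_error(small_cfg(group_effects = list(
    list(area = "NA", group = "flooding", genera = "Methanosaeta", fold = 0))),
    "fold")
  expect_error(small_cfg(planted_edges = data.frame(
    genus_a = "Methanosaeta", genus_b = "Methanosaeta", sign = 1)),
    "self-pairs")
  expect_error(small_cfg(abundance_means = list(
    "NA" = c(reference = 1, flooding = 2, recovery = 1))), "AA")
})

test_that("analytic ground truth applies the index formulas to configured means", {
  # flooding mean = reference mean: maximal resistance, undefined resilience
  cfg_flat <- small_cfg(abundance_means = list(
    "NA" = c(reference = 1e9, flooding = 1e9, recovery = 1e9),
    "AA" = c(reference = 1e8, flooding = 5e8, recovery = 1e8)))
  gt <- ground_truth_rs_rl(cfg_flat)
  na_row <- gt$abundance[gt$abundance$area == "NA", ]
  expect_equal(na_row$rs, 1)
  expect_true(is.na(na_row$rl))
  # recovery mean = reference mean (and flooding different): RL = 1
  aa_row <- gt$abundance[gt$abundance$area == "AA", ]
  expect_equal(aa_row$rl, 1)
  # hand-arithmetic triplet (10, 30, 15): RS = -1/3, RL = 0.6
  cfg_hand <- small_cfg(abundance_means = list(
    "NA" = c(reference = 10, flooding = 30, recovery = 15),
    "AA" = c(reference = 10, flooding = 30, recovery = 10)))
  gt2 <- ground_truth_rs_rl(cfg_hand)
  expect_equal(gt2$abundance$rs, c(-1 / 3, -1 / 3))
  expect_equal(gt2$abundance$rl[1], 0.6)
  # per-genus truths stay in bounds and an all-ones effect gives RS = 1
  cfg_null <- small_cfg(group_effects = list())
  gt3 <- ground_truth_rs_rl(cfg_null)
  expect_true(all(gt3$genera$rs == 1))
  expect_true(all(is.na(gt3$genera$rl)))
  gt_def <- ground_truth_rs_rl(small_cfg())
  expect_true(all(gt_def$genera$rs >= -1 & gt_def$genera$rs <= 1))
  ok_rl <- gt_def$genera$rl[!is.na(gt_def$genera$rl)]
  expect_true(all(ok_rl >= -1 & ok_rl <= 1))
})

test_that("generated datasets honour the design, the depth, and the seed contract", {
  cfg <- small_cfg()
  d <- generate_dataset(cfg)
  expect_equal(ncol(d$table$counts), 2 * (4 + 13 + 7))
  expect_true(all(sample_sums(d$table) == 1000))
  expect_equal(as.vector(table(d$metadata$group)[c("reference", "flooding", "recovery")]),
               c(8, 26, 14))
  expect_equal(d$metadata$elevation_m[d$metadata$group == "reference"],
               rep(175.5, 8))
  expect_true(all(d$metadata$flooding_duration_days[d$metadata$group == "flooding"] > 0))
  expect_true(all(d$abundance > 0))
  # bit-identical under the same seed, different under another
  d2 <- generate_dataset(cfg)
  expect_identical(d$table$counts, d2$table$counts)
  expect_identical(d$abundance, d2$abundance)
  d3 <- generate_dataset(small_cfg(seed = 6))
  expect_false(identical(d$table$counts, d3$table$counts))
})

test_that("empirical group means converge to the configured expectations", {
  # large groups, mild noise: per-genus mean proportions within 3 standard
  # errors of the analytic expectation for the dominant genera
  cfg <- synthetic_config(areas = "NA", n_reference = 200, n_flooding = 200,
                          n_recovery = 200, sequencing_depth = 2000,
                          baseline_log_sd = 0.2, abundance_cv = 0.3,
                          abundance_means = list(
                            "NA" = c(reference = 8.6e8, flooding = 1.9e9,
                                     recovery = 4.6e8)),
                          seed = 9)
  d <- generate_dataset(cfg)
  comp <- relative_abundance(d$table)$proportions
  for (grp in c("reference", "flooding")) {
    ids <- d$metadata$sample_id[d$metadata$group == grp]
    expected <- ripresil:::expected_proportions(cfg, "NA", grp)
    for (g in names(sort(expected, decreasing = TRUE))[1:5]) {
      obs <- comp[g, ids]
      se <- sd(obs) / sqrt(length(obs))
      expect_lt(abs(mean(obs) - expected[[g]]), 3 * se + 0.004)
    }
  }
  # abundance means converge too
  fl <- d$metadata$sample_id[d$metadata$group == "flooding"]
  se_ab <- sd(d$abundance[fl]) / sqrt(length(fl))
  expect_lt(abs(mean(d$abundance[fl]) - 1.9e9), 3 * se_ab)
})

test_that("planted correlations carry the configured sign in nearly every draw", {
  edges <- data.frame(genus_a = c("Methanosaeta", "Nitrososphaera"),
                      genus_b = c("Methanoregula", "Methanobacterium"),
                      sign = c(1, -1))
  hits <- 0; total <- 0
  for (s in 1:20) {
    cfg <- synthetic_config(areas = "NA", sequencing_depth = 1000,
                            group_effects = list(), planted_edges = edges,
                            planted_loading = 0.8, seed = s,
                            abundance_means = list(
                              "NA" = c(reference = 1e9, flooding = 1e9,
                                       recovery = 1e9)))
    d <- generate_dataset(cfg)
    p <- relative_abundance(d$table)$proportions
    for (e in 1:2) {
      rho <- cor(rank(p[edges$genus_a[e], ]), rank(p[edges$genus_b[e], ]))
      total <- total + 1
      if (sign(rho) == edges$sign[e]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("datasets round-trip through the TSV/JSON writers", {
  cfg <- small_cfg()
  d <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  back <- read_count_table(file.path(dir, "counts.tsv"))
  expect_identical(back$counts, d$table$counts)
  expect_identical(back$taxonomy, d$table$taxonomy)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, d$metadata$sample_id)
  expect_equal(md$group, d$metadata$group)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$abundance$rs, d$truth$abundance$rs, tolerance = 1e-12)
})
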