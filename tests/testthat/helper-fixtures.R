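# Fixture builders shared across test files. Everything is generated in code;
# no data files.

make_counts <- function(m, taxa = NULL, samples = NULL, taxonomy = NULL) {
  taxa <- taxa %||% paste0("t", seq_len(nrow(m)))
  samples <- samples %||% paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  count_table(m, taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three-group metadata for one area with given group sizes.
make_metadata <- function(area = "A1", n_ref = 4, n_flood = 13, n_rec = 7) {
  groups <- rep(c("reference", "flooding", "recovery"), c(n_ref, n_flood, n_rec))
  data.frame(sample_id = sprintf("%s_%02d", area, seq_along(groups)),
             area = area, group = groups, stringsAsFactors = FALSE)
}

# Write a small taxa-x-samples TSV and return its path.
write_counts_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent ANOSIM R statistic, written directly from the definition:
# rank all pairwise distances, compare mean between- and within-group ranks.
anosim_r_oracle <- function(d, groups) {
  n <- nrow(d)
  ut <- upper.tri(d)
  r <- rank(d[ut])
  idx <- which(ut, arr.ind = TRUE)
  between <- groups[idx[, 1]] != groups[idx[, 2]]
  (mean(r[between]) - mean(r[!between])) / (n * (n - 1) / 4)
}
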