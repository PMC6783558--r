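# Count tables, metadata and composition tables ------------------------------

GROUP_LEVELS <- c("reference", "flooding", "recovery")

#' Construct a taxon-by-sample count table
#'
#' The canonical container for amplicon count data in this package: an integer
#' matrix with taxa as rows and samples as columns, plus an optional taxonomy
#' lineage per taxon (semicolon-delimited, domain to genus, with or without
#' `d__`/`g__`-style rank prefixes).
#'
#' @param counts Numeric matrix of non-negative integers, taxa x samples, with
#'   row and column names set to taxon and sample identifiers.
#' @param taxonomy Optional named character vector mapping taxon ids to
#'   lineage strings. Names must cover all row names of `counts`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (named character vector or `NULL`).
#' @examples
#' m <- matrix(c(5L, 3L, 2L, 0L, 2L, 8L), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' ct <- count_table(m)
#' sample_sums(ct)
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"
  empty <- colSums(counts) == 0
  if (any(empty))
    stop("empty sample column(s): ", paste(colnames(counts)[empty], collapse = ", "))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("`taxonomy` must be a named character vector")
    missing_tax <- setdiff(rownames(counts), names(taxonomy))
    if (length(missing_tax))
      stop("taxonomy missing for taxa: ", paste(missing_tax, collapse = ", "))
    taxonomy <- taxonomy[rownames(counts)]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  invisible(x)
}

#' @rdname count_table
#' @param x A `count_table`.
#' @export
sample_sums <- function(x) colSums(x$counts)

#' @rdname count_table
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read a count table from a tab-delimited file
#'
#' The file has one header row of identifiers and an identifier first column.
#' An optional final column named `taxonomy` (case-insensitive) carries
#' lineage strings. Cells must be non-negative integers; any other cell is
#' reported with its row and column.
#'
#' @param path Path to a TSV file.
#' @param orientation `"taxa_by_samples"` (rows are taxa; the default) or
#'   `"samples_by_taxa"` (rows are samples). The returned table is always in
#'   canonical taxa x samples orientation.
#' @return A [count_table].
#' @export
read_count_table <- function(path, orientation = c("taxa_by_samples", "samples_by_taxa")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = character(0))
  if (ncol(raw) < 2) stop("count table needs an id column and at least one data column")
  row_ids <- trimws(raw[[1]])
  raw <- raw[, -1, drop = FALSE]
  taxonomy <- NULL
  tax_col <- which(tolower(names(raw)) == "taxonomy")
  if (length(tax_col)) {
    if (orientation == "samples_by_taxa")
      stop("a taxonomy column is only valid in taxa_by_samples orientation")
    taxonomy <- stats::setNames(trimws(raw[[tax_col]]), row_ids)
    raw <- raw[, -tax_col, drop = FALSE]
  }
  col_ids <- trimws(names(raw))
  m <- as.matrix(raw)
  bad <- matrix(!grepl("^[0-9]+$", m), nrow = nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count '%s' at row '%s', column '%s'",
                 m[idx[1], idx[2]], row_ids[idx[1]], col_ids[idx[2]]))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(row_ids, col_ids)
  if (orientation == "samples_by_taxa") m <- t(m)
  count_table(m, taxonomy = taxonomy)
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: taxa x samples, header row of sample ids,
#' first column `taxon_id`, optional trailing `taxonomy` column.
#'
#' @param table A [count_table].
#' @param path Output path.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from a BIOM (JSON dialect) file
#'
#' Thin adapter over the `biomformat` package for BIOM 1.0 JSON tables.
#'
#' @param path Path to a BIOM file.
#' @return A [count_table].
#' @export
read_count_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  tax <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  taxonomy <- NULL
  if (!is.null(tax) && length(tax)) {
    lineage <- vapply(seq_len(nrow(m)), function(i) {
      entry <- if (is.data.frame(tax)) unlist(tax[i, ]) else unlist(tax[[i]])
      paste(entry[!is.na(entry) & nzchar(entry)], collapse = ";")
    }, character(1))
    taxonomy <- stats::setNames(lineage, rownames(m))
  }
  count_table(m, taxonomy = taxonomy)
}

#' Read sample metadata
#'
#' Expects a tab-delimited file with columns `sample_id`, `area`, `group`
#' and optionally `elevation_m` and `flooding_duration_days`. Group labels are
#' matched case-insensitively against `reference`, `flooding`, `recovery`.
#'
#' @param path Path to a TSV file.
#' @return A data frame with normalised (lower-case) group labels.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = character(0))
  validate_metadata(md)
}

#' @keywords internal
validate_metadata <- function(md) {
  md <- as.data.frame(md, stringsAsFactors = FALSE)
  required <- c("sample_id", "area", "group")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols))
    stop("metadata missing required column(s): ", paste(missing_cols, collapse = ", "))
  md$sample_id <- trimws(md$sample_id)
  md$area <- trimws(md$area)
  md$group <- tolower(trimws(md$group))
  bad <- !md$group %in% GROUP_LEVELS
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(md$group[bad]), collapse = ", "),
         "; allowed: ", paste(GROUP_LEVELS, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  for (col in c("elevation_m", "flooding_duration_days"))
    if (col %in% names(md)) md[[col]] <- as.numeric(md[[col]])
  if ("flooding_duration_days" %in% names(md) &&
      any(md$flooding_duration_days < 0, na.rm = TRUE))
    stop("flooding_duration_days must be non-negative")
  md
}

#' Write sample metadata as TSV
#' @param metadata A metadata data frame (see [read_sample_metadata()]).
#' @param path Output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a count table and metadata cover the same samples
#' @keywords internal
check_samples_covered <- function(table, metadata) {
  missing_md <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(missing_md))
    stop("samples without metadata: ", paste(missing_md, collapse = ", "))
  invisible(TRUE)
}

# Taxonomy ---------------------------------------------------------------------

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Split a lineage string into named ranks
#'
#' Strips `k__`/`d__`-style prefixes. Returns a character vector of length 6
#' (domain..genus) with `NA` where the lineage is unresolved.
#' @keywords internal
parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  parts <- sub("^[a-zA-Z]__", "", parts)
  parts[parts == ""] <- NA_character_
  out <- stats::setNames(rep(NA_character_, length(TAXONOMY_RANKS)), TAXONOMY_RANKS)
  n <- min(length(parts), length(out))
  out[seq_len(n)] <- parts[seq_len(n)]
  out
}

#' Extract one taxonomy rank for every taxon of a table
#'
#' @param table A [count_table] with taxonomy.
#' @param rank One of domain, phylum, class, order, family, genus.
#' @return Named character vector taxon id -> name at `rank` (`NA` if
#'   unresolved).
#' @export
taxonomy_at_rank <- function(table, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  if (is.null(table$taxonomy)) stop("count table has no taxonomy")
  vapply(table$taxonomy, function(l) parse_lineage(l)[[rank]], character(1))
}

#' Aggregate a count table to a taxonomy rank
#'
#' Rows sharing the same name at `rank` are summed. Taxa unresolved at that
#' rank are pooled into one `unclassified_<parent>` row per parent lineage
#' (the most specific resolved name above `rank`), so per-sample column sums
#' are conserved exactly.
#'
#' @param table A [count_table] whose every taxon has a taxonomy lineage.
#' @param rank Target rank, e.g. `"genus"` or `"phylum"`.
#' @return A [count_table] whose taxa are names at `rank` (plus pooled
#'   unclassified rows); taxonomy lineages truncated at `rank`.
#' @export
aggregate_to_rank <- function(table, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  if (is.null(table$taxonomy)) stop("aggregate_to_rank requires taxonomy lineages")
  rank_i <- match(rank, TAXONOMY_RANKS)
  lineages <- lapply(table$taxonomy, parse_lineage)
  label <- character(length(lineages))
  new_lineage <- character(length(lineages))
  for (i in seq_along(lineages)) {
    lin <- lineages[[i]]
    if (!is.na(lin[[rank_i]])) {
      label[i] <- lin[[rank_i]]
      new_lineage[i] <- paste(lin[seq_len(rank_i)], collapse = ";")
    } else {
      resolved <- lin[seq_len(rank_i - 1)]
      resolved <- resolved[!is.na(resolved)]
      parent <- if (length(resolved)) resolved[length(resolved)] else "root"
      label[i] <- paste0("unclassified_", parent)
      new_lineage[i] <- paste(c(resolved, label[i]), collapse = ";")
    }
  }
  groups <- factor(label, levels = unique(label))
  agg <- rowsum(table$counts, group = groups, reorder = FALSE)
  taxonomy <- stats::setNames(new_lineage[!duplicated(label)], levels(groups))
  count_table(agg, taxonomy = taxonomy)
}

#' Convert counts to per-sample relative abundances
#'
#' Each cell is divided by its sample column sum, so every column of the
#' result sums to 1.
#'
#' @param table A [count_table].
#' @return An object of class `composition_table`: list with `proportions`
#'   (numeric matrix in \[0, 1\]) and the source `taxonomy`.
#' @export
relative_abundance <- function(table) {
  cs <- colSums(table$counts)
  if (any(cs == 0)) stop("zero-sum sample column(s): ",
                         paste(colnames(table$counts)[cs == 0], collapse = ", "))
  p <- sweep(table$counts, 2, cs, "/")
  structure(list(proportions = p, taxonomy = table$taxonomy),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition_table: %d taxa x %d samples\n",
              nrow(x$proportions), ncol(x$proportions)))
  invisible(x)
}
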