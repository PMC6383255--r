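#' Compute FPKM from a raw read count
#'
#' Fragments (reads) per kilobase of coding sequence per million mapped reads:
#' `count * 1e9 / (library_size * gene_length)`. Gene length is the CDS length
#' in nucleotides; library size is the number of mapped reads in the sample.
#'
#' @param count Non-negative read count (vectorised).
#' @param gene_length Positive CDS length in nucleotides.
#' @param library_size Positive number of mapped reads in the sample.
#' @return Numeric FPKM, zero wherever `count` is zero.
#' @examples
#' compute_fpkm(250, 500, 2e7)  # 25
#' @export
compute_fpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0))
    stop("gene_length must be positive", call. = FALSE)
  if (any(library_size <= 0))
    stop("library_size must be positive", call. = FALSE)
  if (any(count < 0))
    stop("count must be non-negative", call. = FALSE)
  count * 1e9 / (library_size * gene_length)
}

#' Filter an ortholog map to one-to-one entries
#'
#' Retains reference genes with exactly one ortholog match in every compared
#' species. Entries with two or more matches in any species are excluded as
#' multi-match; entries lacking a match in at least one species are excluded
#' as missing. Multi-match takes precedence when both conditions hold, so the
#' three counts partition the input.
#'
#' @param map Data frame with column `ref_gene` plus one character column per
#'   compared species; multiple candidate ids within a cell are comma-separated
#'   and an empty string (or NA) means no match.
#' @return List with `retained` (the one-to-one subset, same columns),
#'   `excluded_multi` and `excluded_missing` (counts).
#' @export
filter_one_to_one <- function(map) {
  if (!is.data.frame(map) || !"ref_gene" %in% names(map))
    stop("map must be a data frame with a ref_gene column", call. = FALSE)
  if (nrow(map) == 0L)
    stop("map is empty", call. = FALSE)
  if (anyDuplicated(map$ref_gene))
    stop("duplicate ref_gene rows in ortholog map", call. = FALSE)
  sp_cols <- setdiff(names(map), "ref_gene")
  if (!length(sp_cols))
    stop("map has no species columns", call. = FALSE)
  n_match <- sapply(sp_cols, function(cl) {
    v <- map[[cl]]
    v[is.na(v)] <- ""
    ifelse(v == "", 0L, lengths(strsplit(v, ",", fixed = TRUE)))
  })
  if (nrow(map) == 1L) n_match <- matrix(n_match, nrow = 1L)
  multi   <- apply(n_match, 1L, function(r) any(r >= 2L))
  missing <- !multi & apply(n_match, 1L, function(r) any(r == 0L))
  keep    <- !multi & !missing
  list(
    retained         = map[keep, , drop = FALSE],
    excluded_multi   = sum(multi),
    excluded_missing = sum(missing)
  )
}

# -- tabular readers/writers -------------------------------------------------
#
# All interchange is TSV with fixed headers; gzip is handled transparently by
# the connection layer. Reals are serialized at 6 significant digits.

.expr_cols <- c("gene_id", "species", "tissue", "sample", "count", "length")

.open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.read_tsv <- function(path, required) {
  con <- .open_read(path)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 6L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gonad expression table
#'
#' Expected columns: `gene_id`, `species`, `tissue`, `sample`, `count`,
#' `length`. Counts must be non-negative integers and lengths positive;
#' violations are reported with the offending data line number. A header-only
#' file yields an empty (zero-row) table.
#'
#' @param path TSV path (optionally gzipped).
#' @param phylo Optional [phylo_context()] used to validate species labels.
#' @return Data frame with the expression schema.
#' @export
read_expression <- function(path, phylo = NULL) {
  df <- .read_tsv(path, .expr_cols)
  if (nrow(df)) {
    bad <- which(is.na(df$count) | df$count < 0)
    if (length(bad))
      stop(sprintf("%s: negative or missing count at line %d", path,
                   bad[1L] + 1L), call. = FALSE)
    bad <- which(is.na(df$length) | df$length <= 0)
    if (length(bad))
      stop(sprintf("%s: non-positive gene length at line %d", path,
                   bad[1L] + 1L), call. = FALSE)
    if (!is.null(phylo)) .check_species(df$species, phylo)
    key <- paste(df$gene_id, df$species, df$tissue, df$sample)
    if (anyDuplicated(key))
      stop(sprintf("%s: duplicate (gene, species, tissue, sample) at line %d",
                   path, anyDuplicated(key) + 1L), call. = FALSE)
  }
  df
}

#' Write a gonad expression table
#' @param df Expression data frame (see [read_expression()]).
#' @param path Output TSV path (optionally gzipped).
#' @return The path, invisibly.
#' @export
write_expression <- function(df, path) {
  miss <- setdiff(.expr_cols, names(df))
  if (length(miss))
    stop("expression table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .write_tsv(df[, union(.expr_cols, names(df))], path)
}

#' Read an ortholog map table
#'
#' TSV with a `ref_gene` column plus one column per compared species holding
#' comma-separated candidate ids (empty cell = no match).
#' @param path TSV path.
#' @return Data frame suitable for [filter_one_to_one()].
#' @export
read_ortholog_map <- function(path) {
  df <- .read_tsv(path, "ref_gene")
  if (anyDuplicated(df$ref_gene))
    stop(sprintf("%s: duplicate ref_gene at line %d", path,
                 anyDuplicated(df$ref_gene) + 1L), call. = FALSE)
  df
}

#' Read a tissue expression matrix for breadth analysis
#'
#' Genes in rows, named tissues/stages in columns, FPKM values. The first
#' column must be `gene_id`.
#' @param path TSV path.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_breadth_matrix <- function(path) {
  df <- .read_tsv(path, "gene_id")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(df) && any(is.na(m)))
    stop(sprintf("%s: non-numeric expression value", path), call. = FALSE)
  rownames(m) <- df$gene_id
  m
}

#' Write a tissue expression matrix
#' @param m Numeric matrix, gene ids as row names.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_breadth_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a per-branch dN/dS table
#'
#' Expected columns: `gene_id`, `branch`, `dN`, `dS`. Negative rates are a
#' format error.
#' @param path TSV path.
#' @return Data frame of branch rates.
#' @export
read_branch_rates <- function(path) {
  df <- .read_tsv(path, c("gene_id", "branch", "dN", "dS"))
  if (nrow(df)) {
    bad <- which(is.na(df$dN) | is.na(df$dS) | df$dN < 0 | df$dS < 0)
    if (length(bad))
      stop(sprintf("%s: negative or missing dN/dS at line %d", path,
                   bad[1L] + 1L), call. = FALSE)
  }
  df
}

#' Write a per-branch dN/dS table
#' @param df Branch-rate data frame (see [read_branch_rates()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_branch_rates <- function(df, path) {
  .write_tsv(df[, union(c("gene_id", "branch", "dN", "dS"), names(df))], path)
}

#' Add FPKM to an expression table
#'
#' Computes per-row FPKM from counts, gene lengths and per-sample library
#' sizes. Library sizes default to the per-(species, tissue, sample) total of
#' mapped reads in the table itself.
#'
#' @param df Expression data frame.
#' @param library_sizes Optional named numeric vector of mapped reads keyed by
#'   `species:tissue:sample`; when `NULL`, column sums of `count` are used.
#' @return `df` with an `fpkm` column appended.
#' @export
add_fpkm <- function(df, library_sizes = NULL) {
  key <- paste(df$species, df$tissue, df$sample, sep = ":")
  if (is.null(library_sizes)) {
    library_sizes <- tapply(df$count, key, sum)
    if (any(library_sizes <= 0))
      stop("a sample has zero total counts; supply library_sizes",
           call. = FALSE)
  }
  ls <- library_sizes[key]
  if (any(is.na(ls)))
    stop("library_sizes missing for sample(s): ",
         paste(unique(key[is.na(ls)]), collapse = ", "), call. = FALSE)
  df$fpkm <- compute_fpkm(df$count, df$length, as.numeric(ls))
  df
}
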