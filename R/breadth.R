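#' Expression breadth of one gene across 17 tissues
#'
#' Breadth is the percentage of the 17 reference tissues/stages in which the
#' gene shows presence of expression (FPKM strictly above the presence
#' threshold, default 0). It proxies pleiotropy: broadly expressed genes are
#' presumed multifunctional.
#'
#' @param tissue_fpkm Numeric vector of length 17.
#' @param presence_threshold FPKM above which a tissue counts as expressed;
#'   default 0 (any expression), a stricter sensitivity setting is 1.
#' @return List with `n_tissues_expressed` (0..17) and `breadth_pct`
#'   (`n / 17 * 100`).
#' @examples
#' compute_breadth(c(rep(5, 7), rep(0, 10)))  # 7/17 expressed
#' @export
compute_breadth <- function(tissue_fpkm, presence_threshold = 0) {
  if (length(tissue_fpkm) != 17L)
    stop("breadth requires exactly 17 tissue values", call. = FALSE)
  if (presence_threshold < 0)
    stop("presence_threshold must be >= 0", call. = FALSE)
  n <- sum(tissue_fpkm > presence_threshold)
  list(n_tissues_expressed = n, breadth_pct = n / 17 * 100)
}

#' Breadth for every gene in a tissue matrix
#'
#' @param mat Genes x 17 tissues FPKM matrix (gene ids as row names).
#' @param presence_threshold See [compute_breadth()].
#' @return Data frame: `gene_id`, `n_tissues_expressed`, `breadth_pct`.
#' @export
breadth_profiles <- function(mat, presence_threshold = 0) {
  if (ncol(mat) != 17L)
    stop("breadth matrix must have exactly 17 tissue columns", call. = FALSE)
  n <- rowSums(mat > presence_threshold)
  data.frame(gene_id = rownames(mat), n_tissues_expressed = as.integer(n),
             breadth_pct = n / 17 * 100, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Contrast expression breadth across gene groups
#'
#' Mean and standard error of breadth per group, with Mann-Whitney pairwise
#' tests and, for three or more groups, Kruskal-Wallis with Dunn's post hoc.
#' Typical groupings are the six transition categories of the reference
#' branch, or the clade-wide categories (ovary-biased, unbiased,
#' testis-biased, testis-specific).
#'
#' @param breadths Data frame from [breadth_profiles()].
#' @param grouping Named character vector or factor mapping `gene_id` to a
#'   group label; genes not covered are ignored.
#' @param min_n Groups below this size are summarised but not tested.
#' @return List with `summary` (group, n, mean, se), `tests` (as in
#'   [foldbias_by_tier()]).
#' @export
breadth_by_group <- function(breadths, grouping, min_n = 2L) {
  grp <- grouping[breadths$gene_id]
  keep <- !is.na(grp)
  b <- breadths$breadth_pct[keep]
  grp <- as.character(grp[keep])
  if (!length(b)) stop("no genes covered by the grouping", call. = FALSE)
  xs <- split(b, grp)
  summ <- data.frame(
    group = names(xs),
    n = vapply(xs, length, 0L),
    mean = vapply(xs, mean, 0),
    se = vapply(xs, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  testable <- xs[vapply(xs, length, 0L) >= min_n]
  tests <- list(skipped = length(testable) < 2L)
  if (!tests$skipped) {
    if (length(testable) >= 3L) {
      kw <- kruskal_dunn(testable)
      tests$kruskal_p <- kw$kruskal_p
      tests$dunn <- kw$dunn
    }
    prs <- utils::combn(names(testable), 2L, simplify = FALSE)
    tests$mwu <- do.call(rbind, lapply(prs, function(p)
      data.frame(group_a = p[[1L]], group_b = p[[2L]],
                 p_value = mwu(testable[[p[[1L]]]],
                               testable[[p[[2L]]]])$p_value,
                 stringsAsFactors = FALSE)))
  }
  list(summary = summ[order(summ$group), , drop = FALSE], tests = tests)
}

#' Clade-wide breadth grouping including testis-specificity
#'
#' Builds the grouping used for the pleiotropy contrast of conserved genes:
#' clade-wide ovary-biased, unbiased and testis-biased (testis-biased genes
#' that are clade-wide testis-specific form their own group).
#'
#' @param profiles Classified profiles from [classify_profiles()].
#' @param calls Calls data frame (for per-species `sex_specific` flags).
#' @param phylo A [phylo_context()].
#' @return Named character vector mapping gene_id to group label
#'   (`cw_ovary`, `cw_unbiased`, `cw_testis`, `cw_testis_specific`).
#' @export
cladewide_breadth_groups <- function(profiles, calls,
                                     phylo = phylo_context()) {
  cw <- profiles[profiles$class == "clade_wide", , drop = FALSE]
  status <- .short_status(cw[[phylo$species[[1L]]]])
  spec_tab <- tapply(calls$sex_specific, calls$gene_id, all)
  universal_spec <- names(spec_tab)[spec_tab]
  grp <- ifelse(status == "ov", "cw_ovary",
                ifelse(status == "unb", "cw_unbiased", "cw_testis"))
  grp[status == "ts" & cw$gene_id %in% universal_spec] <-
    "cw_testis_specific"
  stats::setNames(grp, cw$gene_id)
}
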