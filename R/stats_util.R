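#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the exact
#' permutation distribution for n <= 10 without ties and the t approximation
#' otherwise. A constant vector has no defined rank correlation and returns
#' `NA` for both values.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r` and `p_value`.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(r = NA_real_, p_value = NA_real_))
  r <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) || anyDuplicated(y)
  if (n <= 10L && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = min(1, p))
}

#' Mann-Whitney U test (two-sided)
#'
#' Wilcoxon rank-sum test; exact where the sample permits (no ties, small n),
#' normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors, each of length >= 2. Infinite values are
#'   allowed (rank-based).
#' @return List with `statistic` (U for the first sample) and `p_value`.
#' @export
mwu <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                            correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Kruskal-Wallis test with Dunn's post hoc contrasts
#'
#' Ranked one-way ANOVA across k groups (chi-squared reference, k-1 df)
#' followed by Dunn's pairwise z tests on mean ranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Dunn p-values are
#' two-sided and unadjusted by default; Bonferroni adjustment over the pair
#' count is available.
#'
#' @param groups Named list of numeric vectors (>= 2 groups). Infinite values
#'   are allowed.
#' @param adjust `"none"` (default) or `"bonferroni"` for the Dunn p-values.
#' @return List with `kruskal_statistic`, `kruskal_df`, `kruskal_p` and
#'   `dunn`, a data frame of pairwise `group_a`, `group_b`, `z`, `p_value`.
#' @export
kruskal_dunn <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)

  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 0L))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  nn <- tapply(rk, g, length)
  tie_sizes <- table(x)
  tiecor <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  dunn <- do.call(rbind, lapply(pairs, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tiecor) *
                 (1 / nn[[p[[1L]]]] + 1 / nn[[p[[2L]]]]))
    z <- (rbar[[p[[1L]]]] - rbar[[p[[2L]]]]) / se
    data.frame(group_a = p[[1L]], group_b = p[[2L]], z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  if (adjust == "bonferroni")
    dunn$p_value <- stats::p.adjust(dunn$p_value, "bonferroni")
  list(kruskal_statistic = unname(kw$statistic),
       kruskal_df = unname(kw$parameter),
       kruskal_p = kw$p.value, dunn = dunn)
}

#' Pearson chi-squared test on an r x c table
#'
#' @param tab Non-negative integer matrix.
#' @param correct Continuity correction for 2x2 tables, default `FALSE`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_rxc <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("table entries must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row/column marginal", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per value.
#' @param p P-value vector.
#' @param m Number of tests, >= 1.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}

#' Hierarchically cluster expression samples
#'
#' Dissimilarity between sample columns is `1 - Spearman R`; agglomeration is
#' average linkage (UPGMA). Deterministic given the input: ties in merge
#' heights are broken by `hclust`'s ordering of the lexicographically sorted
#' sample labels.
#'
#' @param mat Numeric matrix, genes in rows and samples in columns (>= 3
#'   genes, >= 2 samples). Column names label the leaves.
#' @return An object of class `hclust`.
#' @export
cluster_samples <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L || nrow(mat) < 3L)
    stop("need >= 2 samples and >= 3 genes", call. = FALSE)
  const <- apply(mat, 2L, function(cl) length(unique(cl)) == 1L)
  if (any(const))
    stop("constant expression column(s): ",
         paste(colnames(mat)[const], collapse = ", "), call. = FALSE)
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(mat, method = "spearman"))
  stats::hclust(d, method = "average")
}

#' Serialize a sample dendrogram as Newick
#'
#' Branch lengths are merge-height differences (the tree is ultrametric under
#' average linkage on a fixed dissimilarity).
#' @param hc An `hclust` object from [cluster_samples()].
#' @return A Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Does a dendrogram bipartition samples into two given sets?
#'
#' Cuts the tree into two clusters and checks that the clusters coincide with
#' the supplied label partition (e.g. all testis samples vs all ovary
#' samples).
#' @param hc An `hclust` object.
#' @param set_a Character vector of leaf labels forming one side.
#' @return Logical.
#' @export
bipartitions_by <- function(hc, set_a) {
  cl <- stats::cutree(hc, k = 2L)
  a <- names(cl)[cl == 1L]
  setequal(a, set_a) || setequal(a, setdiff(names(cl), set_a))
}
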