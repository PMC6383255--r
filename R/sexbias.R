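#' Median normalization of two count samples
#'
#' Rescales two samples so that each sample's median of positive counts equals
#' a common reference, taken as the geometric mean of the two per-sample
#' medians. Only genes with a positive count within a sample enter that
#' sample's median; within-sample rank order is unchanged by the scaling.
#'
#' @param counts_a,counts_b Non-negative count vectors over the same genes.
#' @return List with `scale_a`, `scale_b` (multiplicative factors), `median_a`,
#'   `median_b` (the per-sample medians of positive counts, usable as relative
#'   library-depth proxies) and `reference` (the common target median).
#' @examples
#' median_normalize(c(5, 10, 15), c(20, 40, 60))  # factors 2 and 0.5
#' @export
median_normalize <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("samples must cover the same genes", call. = FALSE)
  ma <- stats::median(counts_a[counts_a > 0])
  mb <- stats::median(counts_b[counts_b > 0])
  if (!is.finite(ma) || !is.finite(mb))
    stop("cannot median-normalize an all-zero sample", call. = FALSE)
  ref <- sqrt(ma * mb)
  list(scale_a = ref / ma, scale_b = ref / mb,
       median_a = ma, median_b = mb, reference = ref)
}

#' Exact binomial differential expression test for one gene
#'
#' Two-sided exact binomial test of the testis read count against the total
#' gonadal count for the gene, with null proportion
#' `p0 = scale_t / (scale_t + scale_o)` where the scales are relative
#' library-depth proxies for the two samples (e.g. the per-sample medians of
#' positive counts from [median_normalize()]). Equal depths give `p0 = 0.5`.
#' The two-sided p-value is the doubled smaller tail, clamped at 1. A gene
#' with zero total count carries no evidence and returns p = 1.
#'
#' @param count_t,count_o Raw read counts in testis and ovary.
#' @param scale_t,scale_o Relative library depths of the two samples.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' binomial_de_test(10, 0)  # 2 * 0.5^10
#' @export
binomial_de_test <- function(count_t, count_o, scale_t = 1, scale_o = 1) {
  if (count_t < 0 || count_o < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (scale_t <= 0 || scale_o <= 0)
    stop("scales must be positive", call. = FALSE)
  n <- count_t + count_o
  if (n == 0) return(1)
  p0 <- scale_t / (scale_t + scale_o)
  lower <- stats::pbinom(count_t, n, p0)
  upper <- stats::pbinom(count_t - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# vectorised doubled-tail binomial p over genes (same construction as above)
.binom_p_vec <- function(count_t, count_o, p0) {
  n <- count_t + count_o
  lower <- stats::pbinom(count_t, n, p0)
  upper <- stats::pbinom(count_t - 1, n, p0, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- 1
  p
}

#' Call sex-bias status for one gene in one species
#'
#' A gene is testis-biased when testis FPKM is at least twice ovary FPKM, the
#' differential expression p-value is below `p_cutoff`, and the larger of the
#' two FPKM values exceeds `fpkm_floor`; symmetric for ovary bias; all other
#' genes are unbiased (including genes with no gonadal expression at all).
#' Fold-bias is the ratio of the higher to the lower gonad FPKM (`Inf` when
#' the lower is zero and the higher positive; 1 when both are zero). A biased
#' gene with exactly zero FPKM in the opposite gonad is flagged sex-specific.
#'
#' @param fpkm_t,fpkm_o Gonadal FPKM values (non-negative).
#' @param p_value Differential expression p-value.
#' @param fold_cutoff Minimal fold difference, default 2 (a fold of exactly 2
#'   counts as biased).
#' @param p_cutoff Significance threshold, default 0.05 (strict).
#' @param fpkm_floor Minimal FPKM in at least one gonad, default 1 (strict).
#' @return List with `status` (one of `"testis_biased"`, `"ovary_biased"`,
#'   `"unbiased"`), `fold_bias`, `sex_specific`, `p_value`, `fpkm_t`, `fpkm_o`.
#' @examples
#' call_sex_bias(10, 2, 0.001)$status  # testis_biased, fold 5
#' @export
call_sex_bias <- function(fpkm_t, fpkm_o, p_value,
                          fold_cutoff = 2, p_cutoff = 0.05, fpkm_floor = 1) {
  if (fpkm_t < 0 || fpkm_o < 0)
    stop("FPKM values must be non-negative", call. = FALSE)
  hi <- max(fpkm_t, fpkm_o)
  lo <- min(fpkm_t, fpkm_o)
  fold <- if (hi == 0) 1 else if (lo == 0) Inf else hi / lo
  status <- "unbiased"
  if (hi > fpkm_floor && p_value < p_cutoff) {
    if (fpkm_t >= fold_cutoff * fpkm_o && fpkm_t > fpkm_o) {
      status <- "testis_biased"
    } else if (fpkm_o >= fold_cutoff * fpkm_t && fpkm_o > fpkm_t) {
      status <- "ovary_biased"
    }
  }
  specific <- status != "unbiased" &&
    ((status == "testis_biased" && fpkm_o == 0) ||
     (status == "ovary_biased" && fpkm_t == 0))
  list(status = status, fold_bias = fold, sex_specific = specific,
       p_value = p_value, fpkm_t = fpkm_t, fpkm_o = fpkm_o)
}

#' Is a call sex-specific?
#'
#' Sex-specificity requires a sex-biased status and exactly zero FPKM (zero
#' mapped reads) in the opposite gonad.
#' @param call A call list from [call_sex_bias()].
#' @return Logical.
#' @export
call_specificity <- function(call) {
  isTRUE(call$status != "unbiased") &&
    ((call$status == "testis_biased" && call$fpkm_o == 0) ||
     (call$status == "ovary_biased" && call$fpkm_t == 0))
}

#' Call sex-bias status for every gene of every species in a dataset
#'
#' For each species: sums counts over replicate samples per tissue (with a
#' warning, since the binomial test then ignores biological variance), median
#' normalizes the testis and ovary samples, tests each gene with the exact
#' binomial construction of [binomial_de_test()], computes FPKM from the
#' supplied or inferred library sizes, and applies the two-fold /
#' significance / FPKM-floor rule of [call_sex_bias()].
#'
#' @param expr Expression data frame (see [read_expression()]) restricted to
#'   tissues `"testis"` and `"ovary"`.
#' @param library_sizes Optional named vector as in [add_fpkm()], keyed by
#'   `species:tissue` after replicate pooling.
#' @param fold_cutoff,p_cutoff,fpkm_floor Calling thresholds (defaults 2,
#'   0.05, 1).
#' @param bonferroni Logical; when `TRUE`, status is called at
#'   `p_cutoff / m` where `m` is the number of genes tested in the species
#'   (sensitivity mode). Default `FALSE`: uncorrected p-values drive status.
#' @return Data frame with one row per gene x species: `gene_id`, `species`,
#'   `status`, `fold_bias`, `p_value`, `sex_specific`, `fpkm_t`, `fpkm_o`.
#' @export
classify_sex_bias <- function(expr, library_sizes = NULL,
                              fold_cutoff = 2, p_cutoff = 0.05,
                              fpkm_floor = 1, bonferroni = FALSE) {
  expr <- expr[expr$tissue %in% c("testis", "ovary"), , drop = FALSE]
  if (!nrow(expr)) stop("no testis/ovary rows in expression table",
                        call. = FALSE)
  out <- lapply(split(expr, expr$species), function(sp) {
    species <- sp$species[[1L]]
    if (length(unique(sp$sample[sp$tissue == "testis"])) > 1L ||
        length(unique(sp$sample[sp$tissue == "ovary"])) > 1L)
      warning(sprintf(
        "%s: replicate samples pooled by summing counts; the binomial test ignores biological variance",
        species), call. = FALSE)
    genes <- sort(unique(sp$gene_id))
    ct <- cs <- stats::setNames(numeric(length(genes)), genes)
    lent <- stats::setNames(rep(NA_real_, length(genes)), genes)
    tt <- sp[sp$tissue == "testis", ]
    oo <- sp[sp$tissue == "ovary", ]
    ct_t <- tapply(tt$count, tt$gene_id, sum)
    ct_o <- tapply(oo$count, oo$gene_id, sum)
    cnt_t <- cnt_o <- stats::setNames(numeric(length(genes)), genes)
    cnt_t[names(ct_t)] <- ct_t
    cnt_o[names(ct_o)] <- ct_o
    len <- tapply(sp$length, sp$gene_id, function(x) x[[1L]])
    lent[names(len)] <- len

    if (any(cnt_t > 0) && any(cnt_o > 0)) {
      norm <- median_normalize(cnt_t, cnt_o)
      p0 <- norm$median_a / (norm$median_a + norm$median_b)
    } else {
      p0 <- 0.5   # a gonad without reads carries no depth information
    }
    p <- .binom_p_vec(cnt_t, cnt_o, p0)

    if (is.null(library_sizes)) {
      ls_t <- sum(cnt_t); ls_o <- sum(cnt_o)
    } else {
      ls_t <- library_sizes[[paste0(species, ":testis")]]
      ls_o <- library_sizes[[paste0(species, ":ovary")]]
      if (is.null(ls_t) || is.null(ls_o))
        stop("library_sizes missing for ", species, call. = FALSE)
    }
    fpkm_t <- compute_fpkm(cnt_t, lent, ls_t)
    fpkm_o <- compute_fpkm(cnt_o, lent, ls_o)

    eff_p <- if (bonferroni) p_cutoff / length(genes) else p_cutoff
    hi <- pmax(fpkm_t, fpkm_o); lo <- pmin(fpkm_t, fpkm_o)
    fold <- ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
    ts <- hi > fpkm_floor & p < eff_p & fpkm_t >= fold_cutoff * fpkm_o &
      fpkm_t > fpkm_o
    ov <- hi > fpkm_floor & p < eff_p & fpkm_o >= fold_cutoff * fpkm_t &
      fpkm_o > fpkm_t
    status <- ifelse(ts, "testis_biased", ifelse(ov, "ovary_biased",
                                                 "unbiased"))
    specific <- (ts & fpkm_o == 0) | (ov & fpkm_t == 0)
    data.frame(gene_id = genes, species = species, status = status,
               fold_bias = fold, p_value = p, sex_specific = specific,
               fpkm_t = as.numeric(fpkm_t), fpkm_o = as.numeric(fpkm_o),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bonferroni sensitivity of sex-bias calls
#'
#' Fraction of sex-biased calls whose p-value stays below `p_cutoff / m`,
#' i.e. that would retain sex-biased status after Bonferroni correction for
#' `m` tests. Non-increasing in `m`; 1 when `m = 1`.
#'
#' @param calls Calls data frame from [classify_sex_bias()].
#' @param m Number of tests (default: number of calls per species, applied
#'   within species).
#' @param p_cutoff Uncorrected threshold, default 0.05.
#' @return Named numeric vector, one fraction per species.
#' @export
bonferroni_sensitivity <- function(calls, m = NULL, p_cutoff = 0.05) {
  if (!is.null(m) && m < 1) stop("m must be >= 1", call. = FALSE)
  sapply(split(calls, calls$species), function(sp) {
    biased <- sp[sp$status != "unbiased", , drop = FALSE]
    if (!nrow(biased)) return(NA_real_)
    mm <- if (is.null(m)) nrow(sp) else m
    mean(biased$p_value < p_cutoff / mm)
  })
}

#' Concordance of sex-specific calls with an independent reference
#'
#' For each query sex-specific gene, checks that an independent expression
#' table shows positive expression in the biased gonad and exactly zero in
#' the opposite gonad. Genes absent from the reference are unevaluable and
#' reported separately.
#'
#' @param calls Calls data frame; only rows with `sex_specific` are used.
#' @param reference Data frame with columns `gene_id`, `fpkm_t`, `fpkm_o`.
#' @return List with `concordance` (fraction of evaluable genes concordant),
#'   `n_evaluated`, `n_unevaluable`, and `discordant` (gene ids).
#' @export
concordance_check <- function(calls, reference) {
  q <- calls[calls$sex_specific, , drop = FALSE]
  idx <- match(q$gene_id, reference$gene_id)
  eval_ok <- !is.na(idx)
  ref <- reference[idx[eval_ok], , drop = FALSE]
  qq <- q[eval_ok, , drop = FALSE]
  conc <- ifelse(qq$status == "testis_biased",
                 ref$fpkm_t > 0 & ref$fpkm_o == 0,
                 ref$fpkm_o > 0 & ref$fpkm_t == 0)
  list(
    concordance   = if (nrow(qq)) mean(conc) else NA_real_,
    n_evaluated   = nrow(qq),
    n_unevaluable = sum(!eval_ok),
    discordant    = qq$gene_id[!conc]
  )
}
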