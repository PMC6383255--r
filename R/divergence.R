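#' Saturation filter for branch substitution rates
#'
#' Retains (gene, branch) pairs with `dN < 1.5`, `dS < 1.5` and
#' `dS > 0.001` (all strict). The bounds limit substitution saturation and
#' guard alignment quality; the dS floor removes branches where omega is
#' numerically unstable. Filtering is per branch: a gene may pass in one
#' branch and fail in another. Idempotent.
#'
#' @param rates Data frame with `gene_id`, `branch`, `dN`, `dS`.
#' @param dn_max,ds_max,ds_min Filter bounds (defaults 1.5, 1.5, 0.001).
#' @return List with `retained` (passing rows, with an `omega` column),
#'   `excluded` (per-branch exclusion counts) and `passes_filter` (logical
#'   vector over the input rows).
#' @export
apply_saturation_filter <- function(rates, dn_max = 1.5, ds_max = 1.5,
                                    ds_min = 0.001) {
  if (any(rates$dN < 0) || any(rates$dS < 0))
    stop("negative dN or dS", call. = FALSE)
  pass <- rates$dN < dn_max & rates$dS < ds_max & rates$dS > ds_min
  kept <- rates[pass, , drop = FALSE]
  kept$omega <- kept$dN / kept$dS
  excl <- table(factor(rates$branch[!pass], levels = unique(rates$branch)))
  list(retained = kept,
       excluded = as.data.frame(excl, responseName = "n_excluded",
                                stringsAsFactors = FALSE),
       passes_filter = pass)
}

#' Single-ratio omega proxy per gene
#'
#' `mean(dN) / mean(dS)` across a gene's passing terminal branches,
#' comparable to a single-ratio (one omega for the whole tree) model
#' estimate. Genes with no passing branch, or with mean dS of zero, are
#' omitted.
#'
#' @param rates Filtered rates (the `retained` element of
#'   [apply_saturation_filter()]).
#' @return Data frame: `gene_id`, `n_branches`, `omega_proxy`.
#' @export
m0_proxy <- function(rates) {
  sp <- split(rates, rates$gene_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    ds <- mean(d$dS)
    if (ds <= 0) return(NULL)
    data.frame(gene_id = d$gene_id[[1L]], n_branches = nrow(d),
               omega_proxy = mean(d$dN) / ds, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test p-value from two log-likelihoods
#'
#' `2 * (lnL_alt - lnL_null)` referred to the chi-squared distribution with
#' `df` degrees of freedom (upper tail). A negative statistic beyond 1e-6
#' (optimizer noise) is clamped to zero with a warning.
#'
#' @param lnl_null,lnl_alt Log-likelihoods of the nested and alternative
#'   models.
#' @param df Degrees of freedom, >= 1.
#' @return List with `lnl_null`, `lnl_alt`, `two_delta`, `df`, `p_value`.
#' @examples
#' lrt_pvalue(-1000, -1000 + 3.841459/2, df = 1)$p_value  # 0.05
#' @export
lrt_pvalue <- function(lnl_null, lnl_alt, df) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  two_delta <- 2 * (lnl_alt - lnl_null)
  if (two_delta < 0) {
    if (two_delta < -1e-6)
      warning("alternative log-likelihood below null; statistic clamped to 0",
              call. = FALSE)
    two_delta <- 0
  }
  list(lnl_null = lnl_null, lnl_alt = lnl_alt, two_delta = two_delta,
       df = df,
       p_value = stats::pchisq(two_delta, df = df, lower.tail = FALSE))
}

#' Omega distributions across expression categories
#'
#' For each species branch, summarises filtered omega distributions over a
#' gene grouping (e.g. clade-wide ts/ov/unb; unbiased-to-testis vs
#' unbiased-to-ovary transition genes; testis-specificity tiers) and runs
#' Kruskal-Wallis with Dunn's post hoc (3+ groups) and pairwise
#' Mann-Whitney tests.
#'
#' @param rates Filtered rates with an `omega` column.
#' @param grouping Named character vector mapping gene_id to category; genes
#'   not covered are ignored.
#' @param min_n Groups below this size are summarised, not tested.
#' @return List with `summary` (branch, group, n, median, mean) and `tests`
#'   (per branch).
#' @export
omega_by_category <- function(rates, grouping, min_n = 2L) {
  grp <- grouping[rates$gene_id]
  dat <- rates[!is.na(grp), , drop = FALSE]
  dat$group <- as.character(grp[!is.na(grp)])
  if (!nrow(dat)) stop("no genes covered by the grouping", call. = FALSE)
  summ <- do.call(rbind, lapply(split(dat, list(dat$branch, dat$group),
                                      drop = TRUE), function(d)
    data.frame(branch = d$branch[[1L]], group = d$group[[1L]], n = nrow(d),
               median_omega = stats::median(d$omega),
               mean_omega = mean(d$omega), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  tests <- lapply(split(dat, dat$branch), function(d) {
    xs <- split(d$omega, d$group)
    xs <- xs[vapply(xs, length, 0L) >= min_n]
    if (length(xs) < 2L) return(list(skipped = TRUE))
    res <- list(skipped = FALSE)
    if (length(xs) >= 3L) {
      kw <- kruskal_dunn(xs)
      res$kruskal_p <- kw$kruskal_p
      res$dunn <- kw$dunn
    }
    prs <- utils::combn(names(xs), 2L, simplify = FALSE)
    res$mwu <- do.call(rbind, lapply(prs, function(p)
      data.frame(group_a = p[[1L]], group_b = p[[2L]],
                 p_value = mwu(xs[[p[[1L]]]], xs[[p[[2L]]]])$p_value,
                 stringsAsFactors = FALSE)))
    res
  })
  list(summary = summ, tests = tests)
}

#' Testis-specificity tiers for the omega contrast
#'
#' Per species, splits testis-biased genes into three tiers: testis-biased
#' but not testis-specific (`ts_biased_NS`), testis-specific but not
#' universally so (`ts_specific_NU`), and universally (clade-wide)
#' testis-specific (`ts_specific_U`).
#'
#' @param calls Calls data frame.
#' @param species The species branch to tier.
#' @return Named character vector keyed by gene_id.
#' @export
testis_specificity_tiers <- function(calls, species) {
  sp <- calls[calls$species == species &
                calls$status == "testis_biased", , drop = FALSE]
  spec_tab <- tapply(calls$sex_specific, calls$gene_id, all)
  universal <- names(spec_tab)[spec_tab]
  tier <- ifelse(!sp$sex_specific, "ts_biased_NS",
                 ifelse(sp$gene_id %in% universal, "ts_specific_U",
                        "ts_specific_NU"))
  stats::setNames(tier, sp$gene_id)
}

#' Median omega by status and fold class, with cross-species concordance
#'
#' For each species branch: median filtered omega for testis- and
#' ovary-biased genes in each fold-bias class plus unbiased genes, and the
#' Spearman correlation of these median profiles between every pair of
#' species.
#'
#' @param rates Filtered rates with `omega`.
#' @param calls Calls data frame.
#' @return List with `medians` (species, status, fold_class, n,
#'   median_omega) and `species_concordance` (pairwise Spearman of the
#'   median profiles).
#' @export
omega_by_foldclass <- function(rates, calls) {
  calls$cat <- ifelse(calls$status == "unbiased", "unb",
                      paste(.short_status(calls$status),
                            as.character(assign_fold_class(
                              pmax(calls$fold_bias, 2))), sep = "_"))
  key_r <- paste(rates$gene_id, rates$branch)
  key_c <- paste(calls$gene_id, calls$species)
  cat <- calls$cat[match(key_r, key_c)]
  dat <- rates[!is.na(cat), , drop = FALSE]
  dat$cat <- cat[!is.na(cat)]
  med <- do.call(rbind, lapply(split(dat, list(dat$branch, dat$cat),
                                     drop = TRUE), function(d)
    data.frame(species = d$branch[[1L]], category = d$cat[[1L]],
               n = nrow(d), median_omega = stats::median(d$omega),
               stringsAsFactors = FALSE)))
  rownames(med) <- NULL
  wide <- stats::reshape(med[, c("species", "category", "median_omega")],
                         idvar = "category", timevar = "species",
                         direction = "wide")
  spp <- sub("^median_omega\\.", "", names(wide)[-1L])
  conc <- NULL
  if (length(spp) >= 2L) {
    prs <- utils::combn(spp, 2L, simplify = FALSE)
    conc <- do.call(rbind, lapply(prs, function(p) {
      a <- wide[[paste0("median_omega.", p[[1L]])]]
      b <- wide[[paste0("median_omega.", p[[2L]])]]
      ok <- stats::complete.cases(a, b)
      sr <- if (sum(ok) >= 3L) spearman_r(a[ok], b[ok])
            else list(r = NA_real_, p_value = NA_real_)
      data.frame(species_a = p[[1L]], species_b = p[[2L]], r = sr$r,
                 p_value = sr$p_value, n = sum(ok),
                 stringsAsFactors = FALSE)
    }))
  }
  list(medians = med, species_concordance = conc)
}

#' Parse a codeml free-ratio (M1) main result file
#'
#' Extracts per-terminal-branch dN and dS for one gene from the text output
#' of a free-ratio codon model fit. The file must contain a labelled tree
#' line (used to map terminal branch numbers to species names, in the order
#' the taxa appear) and the branch table whose header starts with `branch`
#' and includes `dN/dS`, `dN` and `dS` columns; terminal branches are rows
#' whose child node number is a leaf index.
#'
#' @param path Path to the result file.
#' @param gene_id Gene identifier attached to the returned rows.
#' @param phylo A [phylo_context()]; the tree must contain these labels.
#' @return Data frame with one row per terminal branch: `gene_id`, `branch`
#'   (species label), `dN`, `dS`, `omega`.
#' @export
parse_freeratio_output <- function(path, gene_id,
                                   phylo = phylo_context()) {
  lines <- readLines(path, warn = FALSE)
  tree_line <- grep("\\(", lines, value = TRUE)
  tree_line <- tree_line[vapply(tree_line, function(l)
    all(vapply(phylo$species, grepl, TRUE, x = l, fixed = TRUE)),
    logical(1L))]
  if (!length(tree_line))
    stop(sprintf("%s: no labelled tree line found (gene %s)", path, gene_id),
         call. = FALSE)
  taxa <- regmatches(tree_line[[1L]],
                     gregexpr("[A-Za-z_][A-Za-z0-9_.]*",
                              tree_line[[1L]]))[[1L]]
  taxa <- taxa[taxa %in% phylo$species]
  if (length(taxa) != 4L)
    stop(sprintf("%s: tree does not contain the four species (gene %s)",
                 path, gene_id), call. = FALSE)

  hdr <- grep("^\\s*branch\\s+", lines)
  hdr <- hdr[grepl("dN/dS", lines[hdr]) & grepl("\\bdS\\b", lines[hdr])]
  if (!length(hdr))
    stop(sprintf("%s: branch dN/dS table not found (gene %s)", path,
                 gene_id), call. = FALSE)
  cols <- strsplit(trimws(lines[hdr[[1L]]]), "\\s+")[[1L]]
  i <- hdr[[1L]] + 1L
  rows <- list()
  while (i <= length(lines) && grepl("^\\s*\\d+\\.\\.\\d+", lines[i])) {
    rows[[length(rows) + 1L]] <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    i <- i + 1L
  }
  if (!length(rows))
    stop(sprintf("%s: empty branch table (gene %s)", path, gene_id),
         call. = FALSE)
  child <- vapply(rows, function(r)
    as.integer(sub("^\\d+\\.\\.(\\d+)$", "\\1", r[[1L]])), 0L)
  dn <- vapply(rows, function(r) as.numeric(r[[match("dN", cols)]]), 0)
  ds <- vapply(rows, function(r) as.numeric(r[[match("dS", cols)]]), 0)
  term <- child <= length(taxa)
  got <- taxa[child[term]]
  if (!setequal(got, phylo$species))
    stop(sprintf("%s: missing terminal branch for %s (gene %s)", path,
                 paste(setdiff(phylo$species, got), collapse = ","),
                 gene_id), call. = FALSE)
  out <- data.frame(gene_id = gene_id, branch = got, dN = dn[term],
                    dS = ds[term], stringsAsFactors = FALSE)
  out$omega <- ifelse(out$dS > 0, out$dN / out$dS, NA_real_)
  out[match(phylo$species, out$branch), , drop = FALSE]
}
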