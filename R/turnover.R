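#' Four-species sex-biased expression turnover analysis
#'
#' The package's top-level analysis. From per-gene testis/ovary counts of the
#' four species it calls sex-bias status per gene and species, classifies
#' each gene's four-species status profile (clade-wide conservation,
#' lineage-specific transition, ingroup conservation, multiple transitions),
#' computes the standardized transition rate (S-LST) for every branch and
#' transition category with the standard within-branch contrasts, and
#' analyses fold-bias magnitude across conservation tiers. When a 17-tissue
#' breadth matrix and/or a per-branch dN/dS table are supplied, the
#' pleiotropy and protein-divergence contrasts are run as well.
#'
#' @param expr Expression data frame (see [read_expression()]).
#' @param breadth Optional genes x 17 tissue FPKM matrix for the reference
#'   species (see [read_breadth_matrix()]).
#' @param rates Optional per-branch dN/dS data frame (see
#'   [read_branch_rates()]).
#' @param library_sizes Optional named vector of mapped reads per
#'   `species:tissue` sample.
#' @param phylo A [phylo_context()].
#' @param fold_cutoff,p_cutoff,fpkm_floor Sex-bias calling thresholds
#'   (defaults 2, 0.05, 1).
#' @param presence_threshold Breadth presence threshold (default 0).
#' @return Object of class `sexbias_turnover` with components `calls`,
#'   `profiles`, `slst`, `contrasts`, `foldbias`, `foldclass_expression`,
#'   `breadth` (profiles plus group contrasts, or `NULL`), `divergence`
#'   (filtered rates, proxy, category contrasts, or `NULL`), `phylo`,
#'   `thresholds`.
#' @examples
#' sim <- simulate_gonad_data(generator_config(seed = 1, n_genes = 300))
#' fit <- sexbias_turnover(sim$expression, sim$breadth, sim$rates,
#'                         library_sizes = sim$library_sizes)
#' fit
#' @export
sexbias_turnover <- function(expr, breadth = NULL, rates = NULL,
                             library_sizes = NULL,
                             phylo = phylo_context(),
                             fold_cutoff = 2, p_cutoff = 0.05,
                             fpkm_floor = 1, presence_threshold = 0) {
  calls <- classify_sex_bias(expr, library_sizes = library_sizes,
                             fold_cutoff = fold_cutoff,
                             p_cutoff = p_cutoff, fpkm_floor = fpkm_floor)
  profiles <- classify_profiles(calls, phylo)
  slst <- build_slst_table(profiles, phylo)
  contrasts <- slst_contrasts(slst)
  tiered <- assign_tiers(calls, profiles, phylo)
  fb <- foldbias_by_tier(tiered)
  fce <- expression_by_foldclass(calls)

  breadth_res <- NULL
  if (!is.null(breadth)) {
    bp <- breadth_profiles(breadth, presence_threshold)
    cw_groups <- cladewide_breadth_groups(profiles, calls, phylo)
    ref_lst <- profiles$class == "lst" &
      profiles$branch == phylo$species[[1L]]
    lst_groups <- stats::setNames(profiles$category[ref_lst],
                                  profiles$gene_id[ref_lst])
    breadth_res <- list(
      profiles = bp,
      cladewide = breadth_by_group(bp, cw_groups),
      lst_categories = if (length(lst_groups))
        breadth_by_group(bp, lst_groups) else NULL
    )
  }

  div_res <- NULL
  if (!is.null(rates)) {
    filt <- apply_saturation_filter(rates)
    cw_groups <- cladewide_breadth_groups(profiles, calls, phylo)
    cw3 <- ifelse(cw_groups == "cw_testis_specific", "cw_testis", cw_groups)
    names(cw3) <- names(cw_groups)
    lst_gain <- profiles$class == "lst" &
      profiles$category %in% c("unb-ts", "unb-ov")
    gain_groups <- stats::setNames(profiles$category[lst_gain],
                                   profiles$gene_id[lst_gain])
    spec_tiers <- lapply(stats::setNames(nm = phylo$species),
                         function(sp) {
      tiers <- testis_specificity_tiers(calls, sp)
      sub <- filt$retained[filt$retained$branch == sp, , drop = FALSE]
      if (!nrow(sub) || !length(tiers)) return(NULL)
      omega_by_category(sub, tiers)
    })
    div_res <- list(
      filtered = filt$retained,
      excluded = filt$excluded,
      m0 = m0_proxy(filt$retained),
      cladewide = omega_by_category(filt$retained, cw3),
      lst_gain = if (length(gain_groups))
        omega_by_category(filt$retained, gain_groups) else NULL,
      specificity_tiers = spec_tiers,
      foldclass = omega_by_foldclass(filt$retained, calls)
    )
  }

  structure(
    list(calls = tiered, profiles = profiles, slst = slst,
         contrasts = contrasts, foldbias = fb,
         foldclass_expression = fce, breadth = breadth_res,
         divergence = div_res, phylo = phylo,
         thresholds = list(fold_cutoff = fold_cutoff, p_cutoff = p_cutoff,
                           fpkm_floor = fpkm_floor,
                           presence_threshold = presence_threshold)),
    class = "sexbias_turnover")
}

#' @export
print.sexbias_turnover <- function(x, ...) {
  n <- nrow(x$profiles)
  cls <- table(x$profiles$class)
  n_of <- function(k) if (k %in% names(cls)) cls[[k]] else 0L
  cat("Sex-biased gonadal expression turnover analysis\n")
  cat(sprintf("  genes with four-species profiles: %d\n", n))
  cat(sprintf("  clade-wide: %d  LST: %d  multi (2+2): %d  multi (3-state): %d\n",
              n_of("clade_wide"), n_of("lst"), n_of("multi_two_two"),
              n_of("multi_three_state")))
  cat("  S-LST table: 4 branches x 6 categories (see $slst)\n")
  if (!is.null(x$breadth)) cat("  breadth contrasts computed (see $breadth)\n")
  if (!is.null(x$divergence))
    cat("  dN/dS contrasts computed (see $divergence)\n")
  invisible(x)
}

#' @export
summary.sexbias_turnover <- function(object, ...) {
  x <- object
  per_species <- do.call(rbind, lapply(split(x$calls, x$calls$species),
                                       function(sp)
    data.frame(species = sp$species[[1L]],
               n_testis_biased = sum(sp$status == "testis_biased"),
               n_ovary_biased = sum(sp$status == "ovary_biased"),
               n_unbiased = sum(sp$status == "unbiased"),
               n_testis_specific = sum(sp$sex_specific &
                                         sp$status == "testis_biased"),
               n_ovary_specific = sum(sp$sex_specific &
                                        sp$status == "ovary_biased"),
               stringsAsFactors = FALSE)))
  rownames(per_species) <- NULL
  out <- list(per_species = per_species,
              class_counts = table(x$profiles$class),
              slst = x$slst[, c("branch", "category", "n_lst", "pool",
                                "s_lst")],
              contrasts = x$contrasts)
  class(out) <- "summary.sexbias_turnover"
  out
}

#' @export
print.summary.sexbias_turnover <- function(x, ...) {
  cat("Per-species sex-bias calls:\n")
  print(x$per_species, row.names = FALSE)
  cat("\nProfile classes:\n")
  print(x$class_counts)
  cat("\nS-LST (per 1,000 genes with the ancestral state):\n")
  s <- x$slst
  s$s_lst <- round(s$s_lst, 2)
  print(s, row.names = FALSE)
  cat("\nWithin-branch contrasts:\n")
  cc <- x$contrasts
  cc$ratio <- round(cc$ratio, 2)
  cc$statistic <- signif(cc$statistic, 4)
  cc$p_value <- signif(cc$p_value, 3)
  print(cc, row.names = FALSE)
  invisible(x)
}

#' Plot a turnover analysis
#'
#' `which = "foldbias"` draws per-tier fold-bias box plots for a species and
#' status (magnitude growing with conservation age); `which = "slst"` draws
#' the branch x category S-LST bar plot; `which = "breadth"` draws mean
#' expression breadth with standard-error bars per clade-wide group.
#'
#' @param x A `sexbias_turnover` object.
#' @param which One of `"foldbias"`, `"slst"`, `"breadth"`.
#' @param species Species shown for the fold-bias panel.
#' @param status `"ts"` or `"ov"` for the fold-bias panel.
#' @param ... Passed to the underlying base graphics call.
#' @return Invisibly, `x`.
#' @export
plot.sexbias_turnover <- function(x, which = c("foldbias", "slst",
                                               "breadth"),
                                  species = x$phylo$species[[1L]],
                                  status = "ts", ...) {
  which <- match.arg(which)
  if (which == "foldbias") {
    d <- x$calls[!is.na(x$calls$tier) & x$calls$species == species &
                   .short_status(x$calls$status) == status, ]
    f <- pmin(d$fold_bias, 10^4)    # cap infinities for display
    graphics::boxplot(f ~ droplevels(d$tier), log = "y",
                      xlab = "conservation tier", ylab = "fold sex-bias",
                      main = sprintf("%s, %s-biased", species, status), ...)
  } else if (which == "slst") {
    m <- stats::xtabs(s_lst ~ category + branch, data = x$slst)
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                      ylab = "S-LST (per 1,000)", ...)
  } else {
    if (is.null(x$breadth)) stop("no breadth data in this analysis",
                                 call. = FALSE)
    s <- x$breadth$cladewide$summary
    bp <- graphics::barplot(s$mean, names.arg = s$group,
                            ylab = "mean expression breadth (%)",
                            ylim = c(0, 105), ...)
    graphics::arrows(bp, s$mean - s$se, bp, s$mean + s$se, angle = 90,
                     code = 3, length = 0.04)
  }
  invisible(x)
}
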