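# Conservation tiers for sex-biased genes, ordered by the minimum time the
# status has been conserved: a branch-specific transition (lst), conservation
# across the three-species ingroup (tsi), conservation clade-wide.
.tier_levels <- c("lst", "tsi", "clade_wide")

#' Assign a fold-bias magnitude class
#'
#' Sex-biased genes are binned by fold-bias with half-open boundaries:
#' `[2, 5)` low, `[5, 10)` mid, `[10, Inf]` high. Sex-specific genes
#' (infinite fold) fall in the high class. Folds below the bias cutoff are an
#' error, since unbiased genes are not classed.
#'
#' @param fold Fold-bias value(s), each `>= 2` (may be `Inf`).
#' @param breaks Lower bounds of the mid and high classes, default `c(5, 10)`.
#' @return Factor with levels `low`, `mid`, `high`.
#' @examples
#' assign_fold_class(c(2, 5, 9.999, Inf))
#' @export
assign_fold_class <- function(fold, breaks = c(5, 10)) {
  if (any(fold < 2))
    stop("fold < 2: gene is unbiased and is not fold-classed", call. = FALSE)
  cut(fold, breaks = c(2, breaks, Inf), labels = c("low", "mid", "high"),
      right = FALSE, include.lowest = TRUE)
}

#' Conservation tier of each sex-biased call
#'
#' Joins per-species calls with profile classes and assigns, per biased
#' gene x species, the tier of its status: `clade_wide` when the gene has
#' that status in all four species; `tsi` when the three ingroup species
#' share the status but the outgroup differs (only ingroup calls get this
#' tier); `lst` when the species is the derived branch of a
#' lineage-specific transition from unbiased to that status. Other biased
#' calls (e.g. one state of a multiple-transition gene, or LSTs arising from
#' a reversal) are untiered (`NA`), matching an analysis of gains from the
#' unbiased state.
#'
#' @param calls Calls data frame from [classify_sex_bias()].
#' @param profiles Classified profiles from [classify_profiles()].
#' @param phylo A [phylo_context()].
#' @return `calls` with columns `tier` (factor lst < tsi < clade_wide) and
#'   `age` (My of conservation implied by the tier).
#' @export
assign_tiers <- function(calls, profiles, phylo = phylo_context()) {
  idx <- match(calls$gene_id, profiles$gene_id)
  cls <- profiles$class[idx]
  cat <- profiles$category[idx]
  br  <- profiles$branch[idx]
  tsi <- profiles$tsi_status[idx]
  st  <- .short_status(calls$status)

  tier <- rep(NA_character_, nrow(calls))
  biased <- st %in% c("ts", "ov")
  tier[biased & cls == "clade_wide"] <- "clade_wide"
  is_tsi <- biased & cls == "lst" & br == phylo$outgroup &
    !is.na(tsi) & st == tsi & calls$species != phylo$outgroup
  tier[is_tsi] <- "tsi"
  is_lst <- biased & cls == "lst" & calls$species == br &
    cat %in% c("unb-ts", "unb-ov")
  tier[is_lst] <- "lst"

  calls$tier <- factor(tier, levels = .tier_levels, ordered = TRUE)
  age_of <- c(lst = NA_real_, tsi = unname(phylo$ages[[phylo$ingroup[3L]]]),
              clade_wide = unname(phylo$ages[[phylo$outgroup]]))
  branch_age <- phylo$ages[calls$species]
  calls$age <- ifelse(tier == "lst", as.numeric(branch_age),
                      age_of[tier])
  calls
}

#' Fold-bias distributions across conservation tiers
#'
#' For each species and biased status, summarises the fold-bias distribution
#' per conservation tier and tests the directional-increase hypothesis:
#' pairwise Mann-Whitney for two-tier contrasts and Kruskal-Wallis with
#' Dunn's post hoc for the three-tier comparison. Infinite folds
#' (sex-specific genes) are retained as the largest ranks. Reports whether
#' the tier medians are strictly increasing lst < tsi < clade_wide.
#'
#' @param tiered_calls Output of [assign_tiers()].
#' @param min_n Minimal genes per compared group, default 2; smaller groups
#'   drop the contrast with a message.
#' @return List with `summary` (per species x status x tier: n, median,
#'   quartiles), `tests` (per species x status: Kruskal-Wallis p, Dunn pairs,
#'   MWU pairs) and `monotone` (per species x status logical).
#' @export
foldbias_by_tier <- function(tiered_calls, min_n = 2L) {
  dat <- tiered_calls[!is.na(tiered_calls$tier), , drop = FALSE]
  dat$status <- .short_status(dat$status)
  groups <- split(dat, list(dat$species, dat$status), drop = TRUE)

  summ <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    do.call(rbind, lapply(levels(d$tier), function(tr) {
      x <- d$fold_bias[d$tier == tr]
      if (!length(x)) return(NULL)
      q <- stats::quantile(x[is.finite(x)], c(.25, .5, .75), na.rm = TRUE)
      med <- stats::median(x)   # Inf-aware median over all values
      data.frame(species = d$species[[1L]], status = d$status[[1L]],
                 tier = tr, n = length(x), median = med,
                 q25 = q[[1L]], q75 = q[[3L]], stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL

  tests <- lapply(groups, function(d) {
    xs <- split(d$fold_bias, d$tier, drop = FALSE)
    xs <- xs[vapply(xs, length, 0L) >= min_n]
    if (length(xs) < 2L) return(list(skipped = TRUE))
    res <- list(skipped = FALSE)
    if (length(xs) >= 3L) {
      kw <- kruskal_dunn(xs)
      res$kruskal_p <- kw$kruskal_p
      res$dunn <- kw$dunn
    }
    prs <- utils::combn(names(xs), 2L, simplify = FALSE)
    res$mwu <- do.call(rbind, lapply(prs, function(p) {
      data.frame(group_a = p[[1L]], group_b = p[[2L]],
                 p_value = mwu(xs[[p[[1L]]]], xs[[p[[2L]]]])$p_value,
                 stringsAsFactors = FALSE)
    }))
    res
  })

  monotone <- vapply(names(groups), function(g) {
    m <- summ[summ$species == groups[[g]]$species[[1L]] &
                summ$status == groups[[g]]$status[[1L]], ]
    m <- m[match(.tier_levels, m$tier), ]
    if (any(is.na(m$n))) return(NA)
    all(diff(m$median) > 0)
  }, logical(1L))

  list(summary = summ, tests = tests, monotone = monotone)
}

#' Gonadal expression level by fold class
#'
#' Median testis and ovary FPKM per fold-bias class, per species and status,
#' showing whether fold differences track expression changes in one or both
#' gonads.
#'
#' @param calls Calls data frame with `fold_bias`, `fpkm_t`, `fpkm_o`.
#' @return Data frame: species, status, fold_class, n, median_fpkm_testis,
#'   median_fpkm_ovary.
#' @export
expression_by_foldclass <- function(calls) {
  dat <- calls[calls$status != "unbiased", , drop = FALSE]
  dat$fold_class <- assign_fold_class(dat$fold_bias)
  dat$status <- .short_status(dat$status)
  agg <- split(dat, list(dat$species, dat$status, dat$fold_class),
               drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(d) {
    data.frame(species = d$species[[1L]], status = d$status[[1L]],
               fold_class = as.character(d$fold_class[[1L]]), n = nrow(d),
               median_fpkm_testis = stats::median(d$fpkm_t),
               median_fpkm_ovary = stats::median(d$fpkm_o),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
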