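# Status codes used throughout: "ts" (testis-biased), "ov" (ovary-biased),
# "unb" (unbiased). Long-form statuses from the caller are mapped down.

.status_levels <- c("ts", "ov", "unb")

.short_status <- function(x) {
  map <- c(testis_biased = "ts", ovary_biased = "ov", unbiased = "unb",
           ts = "ts", ov = "ov", unb = "unb")
  out <- map[x]
  if (any(is.na(out)))
    stop("invalid status value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

# the six transition categories, ancestral -> derived
.lst_categories <- c("ov-ts", "unb-ts", "ts-ov", "unb-ov", "ts-unb", "ov-unb")

#' Classify a four-species sex-bias status profile
#'
#' Assigns one of four mutually exclusive classes to a gene's ordered
#' four-species status vector:
#' * `clade_wide` - all four statuses identical (conserved across the clade);
#' * `lst` - exactly three identical (the ancestral state under parsimony on
#'   the fixed topology) and one deviant terminal branch (the derived state);
#' * `multi_two_two` - two distinct statuses, twice each; the species
#'   bipartition is recorded since the ancestral state cannot be determined;
#' * `multi_three_state` - three distinct statuses present.
#'
#' Additionally, whenever the three ingroup species share one status the
#' profile is flagged as ingroup-conserved (TSI) with that shared status; an
#' LST on the outgroup branch is exactly the case where the TSI status
#' differs from the outgroup's.
#'
#' @param statuses Character vector of four statuses in species order; either
#'   short (`ts`, `ov`, `unb`) or long (`testis_biased`, ...) codes.
#' @param phylo A [phylo_context()].
#' @return List with `class`, and depending on class: `status` (clade_wide),
#'   `ancestral`, `derived`, `branch`, `category` (lst), `status_pair` and
#'   `arrangement` (multi_two_two). Always contains `tsi_status` (the shared
#'   ingroup status, or `NA`) and, for outgroup-branch LSTs,
#'   `outgroup_caveat = TRUE` (the deviation may be a reversal on the short
#'   internal branch rather than a change in the outgroup itself).
#' @examples
#' classify_profile(c("ov", "ts", "ts", "ts"))
#' @export
classify_profile <- function(statuses, phylo = phylo_context()) {
  s <- .short_status(statuses)
  if (length(s) != 4L)
    stop("a profile has exactly four statuses", call. = FALSE)
  tsi <- if (length(unique(s[1:3])) == 1L) s[[1L]] else NA_character_
  tab <- table(factor(s, levels = .status_levels))
  counts <- sort(as.integer(tab[tab > 0]), decreasing = TRUE)
  out <-
    if (length(counts) == 1L) {
      list(class = "clade_wide", status = s[[1L]])
    } else if (identical(counts, c(3L, 1L))) {
      derived <- names(tab)[tab == 1L]
      ancestral <- names(tab)[tab == 3L]
      branch <- phylo$species[[which(s == derived)]]
      list(class = "lst", ancestral = ancestral, derived = derived,
           branch = branch, category = paste0(ancestral, "-", derived),
           outgroup_caveat = branch == phylo$outgroup)
    } else if (identical(counts, c(2L, 2L))) {
      pair <- names(tab)[tab == 2L]
      grp1 <- phylo$species[s == pair[[1L]]]
      grp2 <- phylo$species[s == pair[[2L]]]
      list(class = "multi_two_two",
           status_pair = pair,
           arrangement = sprintf("{%s}=%s vs {%s}=%s",
                                 paste(grp1, collapse = ","), pair[[1L]],
                                 paste(grp2, collapse = ","), pair[[2L]]))
    } else {
      list(class = "multi_three_state")
    }
  out$tsi_status <- tsi
  out
}

#' Classify all gene profiles in a calls table
#'
#' Pivots per-gene, per-species calls into four-species profiles and
#' classifies each with [classify_profile()]. Genes lacking a call in any
#' species are dropped with a warning.
#'
#' @param calls Calls data frame from [classify_sex_bias()].
#' @param phylo A [phylo_context()].
#' @return Data frame with one row per gene: `gene_id`, the four per-species
#'   statuses (short codes, columns named by species), `class`, `ancestral`,
#'   `derived`, `branch`, `category`, `tsi_status`, `arrangement`.
#' @export
classify_profiles <- function(calls, phylo = phylo_context()) {
  .check_species(calls$species, phylo)
  st <- .short_status(calls$status)
  wide <- matrix(NA_character_, nrow = length(unique(calls$gene_id)),
                 ncol = 4L, dimnames = list(sort(unique(calls$gene_id)),
                                            phylo$species))
  wide[cbind(match(calls$gene_id, rownames(wide)),
             match(calls$species, phylo$species))] <- st
  complete <- rowSums(is.na(wide)) == 0L
  if (any(!complete))
    warning(sum(!complete), " gene(s) lack a call in some species; dropped",
            call. = FALSE)
  wide <- wide[complete, , drop = FALSE]

  res <- data.frame(gene_id = rownames(wide), wide,
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  cls <- apply(wide, 1L, classify_profile, phylo = phylo)
  pick <- function(field) vapply(cls, function(cl)
    if (is.null(cl[[field]])) NA_character_ else cl[[field]], character(1L))
  res$class      <- pick("class")
  res$ancestral  <- pick("ancestral")
  res$derived    <- pick("derived")
  res$branch     <- pick("branch")
  res$category   <- pick("category")
  res$tsi_status <- pick("tsi_status")
  res$arrangement <- pick("arrangement")
  res
}

#' Standardized lineage-specific transition rate (S-LST)
#'
#' `S-LST = N_lst / (N_cladewide_x + N_lst + N_alt) * 1000`, where `N_lst`
#' counts x->y transitions in the target branch, `N_cladewide_x` counts genes
#' with the ancestral status x conserved clade-wide, and `N_alt` counts x->z
#' transitions (the alternate derived state) in the same branch. The
#' denominator is the pool of genes that held the ancestral state when the
#' branch diverged, making rates comparable across categories; the factor
#' 1000 is for readability.
#'
#' @param n_lst,n_alt,n_cladewide_x Non-negative counts.
#' @return The S-LST value in `[0, 1000]`, or `NA` when the denominator is 0.
#' @examples
#' compute_slst(9, 1, 90)  # 90
#' @export
compute_slst <- function(n_lst, n_alt, n_cladewide_x) {
  if (any(c(n_lst, n_alt, n_cladewide_x) < 0))
    stop("counts must be non-negative", call. = FALSE)
  denom <- n_cladewide_x + n_lst + n_alt
  if (denom == 0) return(NA_real_)
  n_lst / denom * 1000
}

#' Build the branch x category S-LST table
#'
#' Tabulates every LST gene into its (branch, category) cell, pools
#' clade-wide genes by ancestral status, and computes the S-LST for each of
#' the 4 branches x 6 categories. Outgroup-branch rows carry a caveat flag:
#' an apparent outgroup LST may comprise a reversal on the short internal
#' branch leading to the ingroup.
#'
#' @param profiles Classified profiles from [classify_profiles()].
#' @param phylo A [phylo_context()].
#' @return Data frame with one row per branch x category: `branch`,
#'   `category`, `ancestral`, `derived`, `n_lst`, `n_alt`, `n_cladewide`,
#'   `pool` (the denominator), `s_lst`, `outgroup_caveat`.
#' @export
build_slst_table <- function(profiles, phylo = phylo_context()) {
  # clade-wide pools by status: the shared status is the reference species'
  cw_status <- profiles[[phylo$species[[1L]]]][profiles$class == "clade_wide"]
  n_cw <- table(factor(.short_status(cw_status), levels = .status_levels))

  lst <- profiles[profiles$class == "lst", , drop = FALSE]
  grid <- expand.grid(branch = phylo$species, category = .lst_categories,
                      stringsAsFactors = FALSE)
  parts <- strsplit(grid$category, "-", fixed = TRUE)
  grid$ancestral <- vapply(parts, `[[`, "", 1L)
  grid$derived   <- vapply(parts, `[[`, "", 2L)
  grid$n_lst <- mapply(function(b, cat)
    sum(lst$branch == b & lst$category == cat), grid$branch, grid$category)
  alt_cat <- function(anc, der) {
    z <- setdiff(.status_levels, c(anc, der))
    paste0(anc, "-", z)
  }
  grid$n_alt <- mapply(function(b, anc, der)
    sum(lst$branch == b & lst$category == alt_cat(anc, der)),
    grid$branch, grid$ancestral, grid$derived)
  grid$n_cladewide <- as.integer(n_cw[grid$ancestral])
  grid$pool <- grid$n_cladewide + grid$n_lst + grid$n_alt
  grid$s_lst <- mapply(compute_slst, grid$n_lst, grid$n_alt,
                       grid$n_cladewide)
  grid$outgroup_caveat <- grid$branch == phylo$outgroup
  grid[order(match(grid$branch, phylo$species),
             match(grid$category, .lst_categories)), , drop = FALSE]
}

#' Ratio of two S-LST values
#'
#' Reported ratios are computed from unrounded S-LSTs and rounded to two
#' decimals for display.
#' @param slst_a,slst_b S-LST values.
#' @param digits Rounding for the reported ratio; `NULL` for unrounded.
#' @return The ratio, or `NA` when the divisor is zero or missing.
#' @examples
#' slst_ratio(21.47, 1.92)  # 11.18
#' @export
slst_ratio <- function(slst_a, slst_b, digits = 2L) {
  if (is.na(slst_a) || is.na(slst_b) || slst_b == 0) return(NA_real_)
  r <- slst_a / slst_b
  if (is.null(digits)) r else round(r, digits)
}

#' Chi-squared contrast between two transition types
#'
#' 2x2 Pearson chi-squared test (1 df) on
#' `[[N_a, pool_a - N_a], [N_b, pool_b - N_b]]`, comparing the frequency of
#' two transition types relative to their ancestral pools. No continuity
#' correction by default (counts in this design are large); enable with
#' `correct = TRUE`.
#'
#' @param n_a,pool_a,n_b,pool_b Transition counts and ancestral-pool sizes.
#' @param correct Apply Yates continuity correction? Default `FALSE`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
transition_contrast <- function(n_a, pool_a, n_b, pool_b, correct = FALSE) {
  if (pool_a <= 0 || pool_b <= 0)
    stop("ancestral pools must be positive", call. = FALSE)
  tab <- rbind(c(n_a, pool_a - n_a), c(n_b, pool_b - n_b))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell count below 1; chi-squared approximation is poor",
            call. = FALSE)
  if (all(tab[1, ] == tab[2, ]))
    return(list(statistic = 0, df = 1L, p_value = 1))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value))
}

#' All within-branch category contrasts for an S-LST table
#'
#' Runs [transition_contrast()] for the standard comparisons of the turnover
#' analysis in each branch: gain-of-testis (unb-ts vs ov-ts), gain-of-ovary
#' (unb-ov vs ts-ov), loss (ov-unb vs ts-unb) and reversal (ts-ov vs ov-ts),
#' with the corresponding S-LST ratios.
#'
#' @param slst S-LST table from [build_slst_table()].
#' @return Data frame: `branch`, `contrast`, `category_a`, `category_b`,
#'   `ratio`, `statistic`, `p_value`.
#' @export
slst_contrasts <- function(slst) {
  pairs <- list(
    c("gain_testis",  "unb-ts", "ov-ts"),
    c("gain_ovary",   "unb-ov", "ts-ov"),
    c("loss",         "ov-unb", "ts-unb"),
    c("reversals",    "ts-ov",  "ov-ts")
  )
  rows <- lapply(unique(slst$branch), function(b) {
    sub <- slst[slst$branch == b, , drop = FALSE]
    do.call(rbind, lapply(pairs, function(p) {
      a <- sub[sub$category == p[[2L]], ]
      z <- sub[sub$category == p[[3L]], ]
      ct <- transition_contrast(a$n_lst, a$pool, z$n_lst, z$pool)
      data.frame(branch = b, contrast = p[[1L]],
                 category_a = p[[2L]], category_b = p[[3L]],
                 ratio = slst_ratio(a$s_lst, z$s_lst),
                 statistic = ct$statistic, p_value = ct$p_value,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
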