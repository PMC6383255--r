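# Synthetic four-species gonad datasets with planted ground truth.
#
# The sampling scheme is built so that the standardized transition rate is an
# unbiased estimator of the planted per-pool transition probability: each
# gene draws an ancestral clade-wide status x, then transitions independently
# in each terminal branch with the configured category probabilities. For a
# branch b and category x->y the genes entering the S-LST denominator are
# exactly those with no transition elsewhere, and within that pool the x->y
# fraction has expectation r_xy(b); hence E[S-LST] = r_xy(b) * 1000. The
# ancestral-state frequencies are derived by inverting the no-transition
# product so the expected clade-wide proportions equal the configured
# targets; leftover probability mass yields explicit multiple-transition
# profiles.

# Default per-branch, per-category transition probabilities (per ancestral
# pool, i.e. S-LST / 1000 scale).
.default_rates <- function() {
  m <- rbind(
    Dmel = c(1.92,  90.26, 21.47,  95.01, 106.53,  56.97),
    Dsim = c(2.23, 111.64, 15.17,  69.25,  60.69,  85.81),
    Dyak = c(3.43, 163.72,  4.99,  77.43,  54.93, 152.79),
    Dana = c(13.85, 111.11, 19.06, 148.87, 122.67, 108.08)
  ) / 1000
  colnames(m) <- .lst_categories
  m
}

#' Configuration for the synthetic gonad-expression generator
#'
#' Defaults describe the study conditions the generator emulates: four
#' species at 5/13/44 My divergence, clade-wide status proportions
#' 0.192/0.183/0.128 (testis/ovary/unbiased), per-branch transition
#' probabilities on the S-LST/1000 scale, fold-bias medians increasing with
#' conservation age, negative-binomial count noise around planted FPKM at a
#' deep single library per gonad, category-dependent expression breadth, and
#' category-dependent dN/dS.
#'
#' @param seed Integer seed; fully determines the output. Mandatory.
#' @param n_genes Number of genes (default 10740).
#' @param cladewide_props Named target proportions of clade-wide ts/ov/unb.
#' @param rates 4 x 6 matrix of per-branch transition probabilities (rows =
#'   species, columns = the six categories `ov-ts`, `unb-ts`, `ts-ov`,
#'   `unb-ov`, `ts-unb`, `ov-unb`).
#' @param fold_medians List with `ts` and `ov`, each a named vector of median
#'   fold-bias per tier `lst`/`tsi`/`clade_wide`.
#' @param fold_sigma Log-scale spread of fold draws.
#' @param library_size Mapped reads per gonad library.
#' @param dispersion Negative-binomial dispersion of counts (var =
#'   mu + dispersion * mu^2).
#' @param base_fpkm_meanlog,base_fpkm_sdlog Log-normal gene expression level.
#' @param species_sdlog Named per-species log-scale expression deviation
#'   (grows with divergence age, so interspecies correlations decay).
#' @param multi_probs Subtype probabilities for explicit multiple-transition
#'   genes (`two_two_unb_ov`, `two_two_ts_unb`, `two_two_ts_ov`,
#'   `three_state`).
#' @param universal_ts_specific_frac Fraction of clade-wide testis-biased
#'   genes that are testis-specific in all species.
#' @param species_ts_specific_frac Per-species probability that a
#'   (non-universal) testis-biased call is testis-specific.
#' @param ov_specific_frac Per-species probability that an ovary-biased call
#'   is ovary-specific.
#' @param breadth_lst_means Named mean breadth (percent) per transition
#'   category for reference-branch LST genes.
#' @param breadth_cw_means Named mean breadth per clade-wide group.
#' @param breadth_default_mean Mean breadth for other genes.
#' @param omega_means Named base dN/dS per category.
#' @param omega_sdlog Gene-level log-scale omega spread.
#' @param ds_per_my Median dS per My of branch age.
#' @param ds_sdlog,dn_sdlog Branch-level log-scale noise on dS and dN.
#' @param phylo A [phylo_context()].
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(seed,
                             n_genes = 10740L,
                             cladewide_props = c(ts = 0.192, ov = 0.183,
                                                 unb = 0.128),
                             rates = .default_rates(),
                             fold_medians = list(
                               ts = c(lst = 3, tsi = 6, clade_wide = 12),
                               ov = c(lst = 2.5, tsi = 5, clade_wide = 10)),
                             fold_sigma = 0.5,
                             library_size = 45e6,
                             dispersion = 0.1,
                             base_fpkm_meanlog = log(20),
                             base_fpkm_sdlog = 1,
                             species_sdlog = c(Dmel = 0.15, Dsim = 0.20,
                                               Dyak = 0.30, Dana = 0.45),
                             multi_probs = c(two_two_unb_ov = 0.368,
                                             two_two_ts_unb = 0.359,
                                             two_two_ts_ov = 0.014,
                                             three_state = 0.259),
                             universal_ts_specific_frac = 0.083,
                             species_ts_specific_frac = 0.15,
                             ov_specific_frac = 0.003,
                             breadth_lst_means = c("ov-unb" = 98.72,
                                                   "unb-ov" = 89.22,
                                                   "ts-unb" = 81.82,
                                                   "ts-ov" = 79.25,
                                                   "ov-ts" = 75.00,
                                                   "unb-ts" = 61.26),
                             breadth_cw_means = c(cw_ovary = 96.02,
                                                  cw_unbiased = 70.72,
                                                  cw_testis = 65.71,
                                                  cw_testis_specific = 43.1),
                             breadth_default_mean = 80,
                             omega_means = c(cw_testis = 0.25,
                                             cw_ovary = 0.10,
                                             cw_unbiased = 0.15,
                                             lst_unb_ts = 0.22,
                                             lst_unb_ov = 0.14,
                                             ts_specific_NU = 0.32,
                                             ts_specific_U = 0.45,
                                             default = 0.15),
                             omega_sdlog = 0.4,
                             ds_per_my = 0.008,
                             ds_sdlog = 0.5,
                             dn_sdlog = 0.3,
                             phylo = phylo_context()) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory", call. = FALSE)
  if (any(cladewide_props < 0) || sum(cladewide_props) > 1)
    stop("clade-wide proportions must be in [0,1] and sum to at most 1",
         call. = FALSE)
  if (!identical(sort(rownames(rates)), sort(phylo$species)) ||
      !identical(colnames(rates), .lst_categories))
    stop("rates must be a species x category matrix over the six categories",
         call. = FALSE)
  rates <- rates[phylo$species, , drop = FALSE]
  # total transition probability out of each ancestral state per branch
  out_of <- function(x) rowSums(rates[, grep(paste0("^", x, "-"),
                                             colnames(rates)), drop = FALSE])
  p_keep <- sapply(c("ts", "ov", "unb"),
                   function(x) prod(1 - out_of(x)))
  if (any(out_of("ts") + out_of("ov") + out_of("unb") > 1))
    stop("transition probabilities out of a state exceed 1 in some branch",
         call. = FALSE)
  q <- cladewide_props[c("ts", "ov", "unb")] / p_keep
  if (sum(q) > 1)
    stop("infeasible config: clade-wide proportions unreachable under the ",
         "given transition rates", call. = FALSE)
  if (abs(sum(multi_probs) - 1) > 1e-8)
    stop("multi_probs must sum to 1", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         cladewide_props = cladewide_props, rates = rates,
         ancestral_probs = c(q, multi = 1 - sum(q)),
         fold_medians = fold_medians, fold_sigma = fold_sigma,
         library_size = library_size, dispersion = dispersion,
         base_fpkm_meanlog = base_fpkm_meanlog,
         base_fpkm_sdlog = base_fpkm_sdlog,
         species_sdlog = species_sdlog[phylo$species],
         multi_probs = multi_probs,
         universal_ts_specific_frac = universal_ts_specific_frac,
         species_ts_specific_frac = species_ts_specific_frac,
         ov_specific_frac = ov_specific_frac,
         breadth_lst_means = breadth_lst_means,
         breadth_cw_means = breadth_cw_means,
         breadth_default_mean = breadth_default_mean,
         omega_means = omega_means, omega_sdlog = omega_sdlog,
         ds_per_my = ds_per_my, ds_sdlog = ds_sdlog, dn_sdlog = dn_sdlog,
         phylo = phylo),
    class = "generator_config")
}

# draw the n x 4 status matrix plus generating-origin labels
.draw_statuses <- function(cfg) {
  n <- cfg$n_genes
  phylo <- cfg$phylo
  origin <- sample(names(cfg$ancestral_probs), n, replace = TRUE,
                   prob = cfg$ancestral_probs)
  status <- matrix(NA_character_, n, 4L,
                   dimnames = list(NULL, phylo$species))
  for (x in c("ts", "ov", "unb")) {
    idx <- which(origin == x)
    if (!length(idx)) next
    m <- matrix(x, length(idx), 4L)
    others <- setdiff(.status_levels, x)
    for (b in seq_len(4L)) {
      r1 <- cfg$rates[b, paste0(x, "-", others[[1L]])]
      r2 <- cfg$rates[b, paste0(x, "-", others[[2L]])]
      u <- stats::runif(length(idx))
      m[u < r1, b] <- others[[1L]]
      m[u >= r1 & u < r1 + r2, b] <- others[[2L]]
    }
    status[idx, ] <- m
  }
  midx <- which(origin == "multi")
  if (length(midx)) {
    sub <- sample(names(cfg$multi_probs), length(midx), replace = TRUE,
                  prob = cfg$multi_probs)
    pair_of <- list(two_two_unb_ov = c("unb", "ov"),
                    two_two_ts_unb = c("ts", "unb"),
                    two_two_ts_ov = c("ts", "ov"))
    splits <- utils::combn(4L, 2L)          # which two species take state A
    three_state_profiles <- {
      all81 <- as.matrix(expand.grid(.status_levels, .status_levels,
                                     .status_levels, .status_levels,
                                     stringsAsFactors = FALSE))
      all81[apply(all81, 1L, function(s) length(unique(s)) == 3L), ,
            drop = FALSE]
    }
    for (k in seq_along(midx)) {
      i <- midx[[k]]
      if (sub[[k]] == "three_state") {
        status[i, ] <- three_state_profiles[
          sample.int(nrow(three_state_profiles), 1L), ]
      } else {
        pr <- pair_of[[sub[[k]]]]
        who <- splits[, sample.int(ncol(splits), 1L)]
        s <- rep(pr[[2L]], 4L)
        s[who] <- pr[[1L]]
        status[i, ] <- s
      }
    }
  }
  list(status = status, origin = origin)
}

# per-gene x species planted fold tier (only biased cells get one)
.planted_tiers <- function(status, phylo) {
  n <- nrow(status)
  tier <- matrix(NA_character_, n, 4L, dimnames = dimnames(status))
  uniq <- apply(status, 1L, function(s) length(unique(s)))
  cw <- uniq == 1L
  tier[cw, ] <- "clade_wide"
  for (i in which(uniq == 2L)) {
    s <- status[i, ]
    tab <- table(s)
    if (!any(tab == 3L)) next
    anc <- names(tab)[tab == 3L]; der <- names(tab)[tab == 1L]
    b <- which(s == der)
    if (b == 4L) {                         # outgroup deviates: ingroup is TSI
      if (anc %in% c("ts", "ov")) tier[i, 1:3] <- "tsi"
      if (der %in% c("ts", "ov") && anc == "unb") tier[i, 4L] <- "lst"
    } else {
      if (der %in% c("ts", "ov") && anc == "unb") tier[i, b] <- "lst"
    }
  }
  tier[status == "unb"] <- NA_character_
  tier
}

#' Generate a synthetic four-species gonad dataset
#'
#' Draws per-gene four-species status profiles, gonadal FPKM and
#' negative-binomial read counts consistent with the calling rule in
#' expectation, a 17-tissue breadth matrix for the reference species, and
#' per-branch dN/dS, together with the full planted ground truth.
#'
#' @param config A [generator_config()].
#' @param components Character subset of
#'   `c("expression", "breadth", "rates")`; omit components you do not need
#'   (the truth table is always produced, and the random streams of the
#'   remaining components are unaffected by what is skipped).
#' @return List with `expression` (schema of [read_expression()]),
#'   `library_sizes` (named vector for [classify_sex_bias()]), `breadth`
#'   (genes x 17 matrix), `rates` (per-branch dN/dS), and `truth` (per-gene
#'   data frame: origin, per-species planted status/fold/specificity,
#'   breadth group and expected breadth, gene-level omega).
#' @export
simulate_gonad_data <- function(config,
                                components = c("expression", "breadth",
                                               "rates")) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  if (length(components))
    components <- match.arg(components, several.ok = TRUE)
  phylo <- cfg$phylo
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  dr <- .draw_statuses(cfg)
  status <- dr$status
  tier <- .planted_tiers(status, phylo)

  # planted fold per biased gene x species
  fold <- matrix(NA_real_, n, 4L, dimnames = dimnames(status))
  for (b in seq_len(4L)) {
    for (st in c("ts", "ov")) {
      sel <- status[, b] == st
      if (!any(sel)) next
      tr <- tier[sel, b]
      med <- cfg$fold_medians[[st]][ifelse(is.na(tr), "tsi", tr)]
      f <- exp(stats::rnorm(sum(sel), log(med), cfg$fold_sigma))
      fold[sel, b] <- pmax(f, 2.2)
    }
  }

  # specificity flags
  specific <- matrix(FALSE, n, 4L, dimnames = dimnames(status))
  cw_ts <- apply(status == "ts", 1L, all)
  universal_spec <- cw_ts &
    stats::runif(n) < cfg$universal_ts_specific_frac
  specific[universal_spec, ] <- TRUE
  ts_cells <- status == "ts" & !specific
  specific[ts_cells] <- stats::runif(sum(ts_cells)) <
    cfg$species_ts_specific_frac
  ov_cells <- status == "ov"
  specific[ov_cells] <- stats::runif(sum(ov_cells)) < cfg$ov_specific_frac
  fold[specific] <- Inf

  # planted FPKM per gene x species x gonad
  base <- exp(stats::rnorm(n, cfg$base_fpkm_meanlog, cfg$base_fpkm_sdlog))
  gene_len <- pmax(300, round(exp(stats::rnorm(n, log(1500), 0.35))))
  fpkm_t <- fpkm_o <- matrix(0, n, 4L, dimnames = dimnames(status))
  for (b in seq_len(4L)) {
    lev <- base * exp(stats::rnorm(n, 0, cfg$species_sdlog[[b]]))
    st <- status[, b]
    f <- fold[, b]
    unb <- st == "unb"
    rho <- exp(stats::rnorm(n, 0, 0.15))
    rho <- pmin(pmax(rho, 1 / 1.8), 1.8)
    fpkm_t[unb, b] <- lev[unb] * sqrt(rho[unb])
    fpkm_o[unb, b] <- lev[unb] / sqrt(rho[unb])
    for (st2 in c("ts", "ov")) {
      sel <- st == st2
      fin <- sel & is.finite(f)
      hi <- lev * sqrt(ifelse(is.finite(f), f, 1))
      lo <- lev / sqrt(ifelse(is.finite(f), f, 1))
      sp <- sel & !is.finite(f)           # sex-specific: opposite gonad 0
      if (st2 == "ts") {
        fpkm_t[fin, b] <- hi[fin]; fpkm_o[fin, b] <- lo[fin]
        fpkm_t[sp, b] <- lev[sp] * 2; fpkm_o[sp, b] <- 0
      } else {
        fpkm_o[fin, b] <- hi[fin]; fpkm_t[fin, b] <- lo[fin]
        fpkm_o[sp, b] <- lev[sp] * 2; fpkm_t[sp, b] <- 0
      }
    }
  }

  # breadth grouping truth
  cls <- apply(status, 1L, function(s) {
    tab <- table(s)
    if (length(tab) == 1L) "clade_wide"
    else if (any(tab == 3L)) "lst"
    else if (length(tab) == 2L) "multi_two_two" else "multi_three_state"
  })
  lst_cat <- rep(NA_character_, n)
  lst_branch <- rep(NA_character_, n)
  is_lst <- cls == "lst"
  if (any(is_lst)) {
    for (i in which(is_lst)) {
      tab <- table(status[i, ])
      anc <- names(tab)[tab == 3L]; der <- names(tab)[tab == 1L]
      lst_cat[[i]] <- paste0(anc, "-", der)
      lst_branch[[i]] <- phylo$species[[which(status[i, ] == der)]]
    }
  }
  bgroup <- rep("other", n)
  cw_status <- status[, 1L]
  bgroup[cls == "clade_wide" & cw_status == "ov"] <- "cw_ovary"
  bgroup[cls == "clade_wide" & cw_status == "unb"] <- "cw_unbiased"
  bgroup[cls == "clade_wide" & cw_status == "ts"] <- "cw_testis"
  bgroup[universal_spec] <- "cw_testis_specific"
  ref_lst <- is_lst & lst_branch == phylo$species[[1L]]
  bgroup[ref_lst] <- lst_cat[ref_lst]

  bmean <- rep(cfg$breadth_default_mean, n)
  cwm <- cfg$breadth_cw_means
  lm_ <- cfg$breadth_lst_means
  hit <- bgroup %in% names(cwm)
  bmean[hit] <- cwm[bgroup[hit]]
  hit <- bgroup %in% names(lm_)
  bmean[hit] <- lm_[bgroup[hit]]
  n_expr <- stats::rbinom(n, 17L, bmean / 100)

  # gene-level omega by category
  om <- cfg$omega_means
  obase <- rep(om[["default"]], n)
  obase[cls == "clade_wide" & cw_status == "ts"] <- om[["cw_testis"]]
  obase[cls == "clade_wide" & cw_status == "ov"] <- om[["cw_ovary"]]
  obase[cls == "clade_wide" & cw_status == "unb"] <- om[["cw_unbiased"]]
  obase[is_lst & lst_cat == "unb-ts"] <- om[["lst_unb_ts"]]
  obase[is_lst & lst_cat == "unb-ov"] <- om[["lst_unb_ov"]]
  any_spec_ts <- rowSums(specific & status == "ts") > 0
  obase[any_spec_ts & !universal_spec] <- om[["ts_specific_NU"]]
  obase[universal_spec] <- om[["ts_specific_U"]]
  # fold magnitude pushes omega up for biased genes
  medfold <- apply(fold, 1L, function(f) {
    f <- f[is.finite(f)]
    if (length(f)) stats::median(f) else NA_real_
  })
  fold_mult <- ifelse(is.na(medfold), 1,
                      pmax(0.6, 1 + 0.25 * log2(pmin(medfold, 64) / 4)))
  omega_gene <- obase * fold_mult *
    exp(stats::rnorm(n, 0, cfg$omega_sdlog))

  # component outputs draw from their own derived seeds so that skipping one
  # component leaves the others (and the truth above) bit-identical
  comp_seed <- function(off) (cfg$seed %% 2147483000L) + off
  out <- list()
  if ("expression" %in% components) {
    set.seed(comp_seed(1L))
    rows <- vector("list", 8L)
    k <- 1L
    size <- 1 / cfg$dispersion
    for (b in seq_len(4L)) {
      for (tis in c("testis", "ovary")) {
        mu <- (if (tis == "testis") fpkm_t else fpkm_o)[, b] *
          gene_len * cfg$library_size / 1e9
        cnt <- integer(n)
        pos <- mu > 0
        cnt[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
        rows[[k]] <- data.frame(
          gene_id = gene_id, species = phylo$species[[b]], tissue = tis,
          sample = paste0(phylo$species[[b]], "_", tis, "_1"),
          count = cnt, length = gene_len, stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
    out$expression <- do.call(rbind, rows)
    ls <- rep(cfg$library_size, 8L)
    names(ls) <- as.vector(outer(c("testis", "ovary"), phylo$species,
                                 function(t, s) paste0(s, ":", t)))
    out$library_sizes <- ls
  }
  if ("breadth" %in% components) {
    set.seed(comp_seed(2L))
    bm <- matrix(0, n, 17L,
                 dimnames = list(gene_id, sprintf("T%02d", 1:17)))
    lev <- exp(stats::rnorm(n * 17L, log(15), 1))
    dim(lev) <- c(n, 17L)
    for (i in seq_len(n)) {
      if (n_expr[[i]] > 0L) {
        on <- sample.int(17L, n_expr[[i]])
        bm[i, on] <- lev[i, on]
      }
    }
    out$breadth <- bm
  }
  if ("rates" %in% components) {
    set.seed(comp_seed(3L))
    rr <- vector("list", 4L)
    for (b in seq_len(4L)) {
      ds <- exp(stats::rnorm(n, log(cfg$ds_per_my * phylo$ages[[b]]),
                             cfg$ds_sdlog))
      dn <- omega_gene * ds * exp(stats::rnorm(n, 0, cfg$dn_sdlog))
      rr[[b]] <- data.frame(gene_id = gene_id,
                            branch = phylo$species[[b]],
                            dN = dn, dS = ds, stringsAsFactors = FALSE)
    }
    out$rates <- do.call(rbind, rr)
  }

  truth <- data.frame(gene_id = gene_id, origin = dr$origin, class = cls,
                      category = lst_cat, branch = lst_branch,
                      breadth_group = bgroup, breadth_mean = bmean,
                      n_tissues = n_expr, omega = omega_gene,
                      stringsAsFactors = FALSE)
  for (b in seq_len(4L)) {
    sp <- phylo$species[[b]]
    truth[[paste0("status_", sp)]] <- status[, b]
    truth[[paste0("fold_", sp)]] <- fold[, b]
    truth[[paste0("tier_", sp)]] <- tier[, b]
    truth[[paste0("specific_", sp)]] <- specific[, b]
  }
  out$truth <- truth
  out$config <- cfg
  out
}

#' Degrade a synthetic expression dataset
#'
#' Downsamples read depth by binomial thinning to probe caller robustness
#' near the two-fold and FPKM-floor thresholds. `depth_factor = 1` is the
#' identity; `depth_factor = 0` removes all reads (every call becomes
#' unbiased for lack of power/expression).
#'
#' @param expr Expression data frame.
#' @param depth_factor Retention probability per read, in `[0, 1]`.
#' @param seed Seed for the thinning draws.
#' @return The perturbed expression data frame.
#' @export
degrade <- function(expr, depth_factor = 1, seed = 1L) {
  if (depth_factor < 0 || depth_factor > 1)
    stop("depth_factor must be in [0, 1]", call. = FALSE)
  if (depth_factor == 1) return(expr)
  set.seed(seed)
  expr$count <- stats::rbinom(nrow(expr), expr$count, depth_factor)
  expr
}
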