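# Stage-wise pipeline: each stage reads its upstream TSV artifacts from the
# output directory and writes its own, so a run can be resumed or inspected
# per stage. All randomness flows through the single config seed.

.log <- function(...) message("[sbturnover] ", sprintf(...))

#' Resolve a pipeline run configuration
#'
#' Fills defaults for a pipeline run: calling thresholds (fold cutoff 2,
#' p cutoff 0.05, FPKM floor 1), breadth presence threshold 0, dN/dS
#' saturation bounds (1.5/1.5/0.001), species order, seed and output
#' directory. Accepts a YAML file path or a named list; unknown keys are an
#' error so typos do not pass silently.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A complete config list; the resolved config is logged.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "sbturnover_out", seed = NULL, n_genes = 10740L,
    fold_cutoff = 2, p_cutoff = 0.05, fpkm_floor = 1,
    presence_threshold = 0, dn_max = 1.5, ds_max = 1.5, ds_min = 0.001,
    species = c("Dmel", "Dsim", "Dyak", "Dana"),
    expression = NULL, breadth = NULL, rates = NULL, library_sizes = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  .log("resolved config: %s",
       paste(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v)
                       paste(format(v), collapse = ","), "")),
             collapse = " "))
  cfg
}

.artifact <- function(cfg, name) file.path(cfg$out_dir, name)

.need <- function(cfg, name, stage) {
  p <- .artifact(cfg, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact %s: run the '%s' stage first", p, stage),
         call. = FALSE)
  p
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic dataset + ground truth), `classify`
#' (per-gene, per-species sex-bias calls), `transitions` (profile classes,
#' S-LST table, contrasts), `foldbias` (tier summaries and tests),
#' `breadth` (pleiotropy contrasts), `divergence` (dN/dS contrasts),
#' `report` (consolidated tables with partition identities). Each stage
#' writes TSV artifacts into `out_dir` and errors with the name of the
#' missing prior stage if its inputs are absent.
#'
#' @param stage One of the stages above.
#' @param config YAML path or named list; see [resolve_config()].
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_pipeline <- function(stage = c("simulate", "classify", "transitions",
                                   "foldbias", "breadth", "divergence",
                                   "report"),
                         config = list()) {
  stage <- match.arg(stage)
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  phylo <- phylo_context(cfg$species)
  written <- character(0)
  w <- function(df, name) {
    p <- .artifact(cfg, name)
    .write_tsv(df, p)
    written <<- c(written, p)
    .log("wrote %s (%d rows)", p, nrow(df))
  }

  read_calls <- function() {
    df <- .read_tsv(.need(cfg, "calls.tsv", "classify"),
                    c("gene_id", "species", "status", "fold_bias",
                      "p_value", "sex_specific", "fpkm_t", "fpkm_o"))
    df$sex_specific <- as.logical(df$sex_specific)
    df
  }
  read_profiles <- function()
    .read_tsv(.need(cfg, "profiles.tsv", "transitions"),
              c("gene_id", "class", "category", "branch", "tsi_status"))

  if (stage == "simulate") {
    if (is.null(cfg$seed)) stop("simulate requires a seed", call. = FALSE)
    sim <- simulate_gonad_data(generator_config(seed = cfg$seed,
                                                n_genes = cfg$n_genes,
                                                phylo = phylo))
    w(sim$expression, "expression.tsv")
    w(data.frame(sample = names(sim$library_sizes),
                 reads = as.numeric(sim$library_sizes)),
      "library_sizes.tsv")
    w(data.frame(gene_id = rownames(sim$breadth), sim$breadth,
                 check.names = FALSE), "breadth.tsv")
    w(sim$rates, "rates.tsv")
    w(sim$truth, "truth.tsv")
  } else if (stage == "classify") {
    expr_path <- if (!is.null(cfg$expression)) cfg$expression else
      .need(cfg, "expression.tsv", "simulate")
    expr <- read_expression(expr_path, phylo)
    ls <- NULL
    ls_path <- if (!is.null(cfg$library_sizes)) cfg$library_sizes else
      .artifact(cfg, "library_sizes.tsv")
    if (file.exists(ls_path)) {
      lsd <- .read_tsv(ls_path, c("sample", "reads"))
      ls <- stats::setNames(lsd$reads, lsd$sample)
    }
    calls <- classify_sex_bias(expr, library_sizes = ls,
                               fold_cutoff = cfg$fold_cutoff,
                               p_cutoff = cfg$p_cutoff,
                               fpkm_floor = cfg$fpkm_floor)
    w(calls, "calls.tsv")
  } else if (stage == "transitions") {
    calls <- read_calls()
    profiles <- classify_profiles(calls, phylo)
    w(profiles, "profiles.tsv")
    slst <- build_slst_table(profiles, phylo)
    w(slst, "slst.tsv")
    w(slst_contrasts(slst), "slst_contrasts.tsv")
  } else if (stage == "foldbias") {
    calls <- read_calls()
    profiles <- read_profiles()
    tiered <- assign_tiers(calls, profiles, phylo)
    fb <- foldbias_by_tier(tiered)
    w(fb$summary, "foldbias_summary.tsv")
    w(expression_by_foldclass(calls), "foldclass_expression.tsv")
  } else if (stage == "breadth") {
    calls <- read_calls()
    profiles <- read_profiles()
    bm_path <- if (!is.null(cfg$breadth)) cfg$breadth else
      .need(cfg, "breadth.tsv", "simulate")
    bp <- breadth_profiles(read_breadth_matrix(bm_path),
                           cfg$presence_threshold)
    w(bp, "breadth_profiles.tsv")
    cw <- breadth_by_group(bp, cladewide_breadth_groups(profiles, calls,
                                                        phylo))
    w(cw$summary, "breadth_cladewide.tsv")
    ref_lst <- profiles$class == "lst" &
      profiles$branch == phylo$species[[1L]]
    if (any(ref_lst)) {
      lg <- breadth_by_group(bp, stats::setNames(
        profiles$category[ref_lst], profiles$gene_id[ref_lst]))
      w(lg$summary, "breadth_lst.tsv")
    }
  } else if (stage == "divergence") {
    calls <- read_calls()
    profiles <- read_profiles()
    rt_path <- if (!is.null(cfg$rates)) cfg$rates else
      .need(cfg, "rates.tsv", "simulate")
    filt <- apply_saturation_filter(read_branch_rates(rt_path),
                                    cfg$dn_max, cfg$ds_max, cfg$ds_min)
    w(filt$retained, "rates_filtered.tsv")
    w(m0_proxy(filt$retained), "m0_proxy.tsv")
    cw <- cladewide_breadth_groups(profiles, calls, phylo)
    cw3 <- stats::setNames(ifelse(cw == "cw_testis_specific", "cw_testis",
                                  cw), names(cw))
    w(omega_by_category(filt$retained, cw3)$summary,
      "omega_cladewide.tsv")
  } else if (stage == "report") {
    calls <- read_calls()
    profiles <- read_profiles()
    slst <- .read_tsv(.need(cfg, "slst.tsv", "transitions"),
                      c("branch", "category", "n_lst", "pool", "s_lst"))
    cls <- table(factor(profiles$class,
                        levels = c("clade_wide", "lst", "multi_two_two",
                                   "multi_three_state")))
    n <- nrow(profiles)
    variable <- n - cls[["clade_wide"]]
    rep_df <- data.frame(
      quantity = c("genes", "clade_wide", "variable", "lst", "multi",
                   "partition_ok", "lst_plus_multi_ok"),
      value = c(n, cls[["clade_wide"]], variable, cls[["lst"]],
                cls[["multi_two_two"]] + cls[["multi_three_state"]],
                as.integer(sum(cls) == n),
                as.integer(cls[["lst"]] + cls[["multi_two_two"]] +
                             cls[["multi_three_state"]] == variable)),
      stringsAsFactors = FALSE)
    w(rep_df, "report.tsv")
    if (!all(rep_df$value[rep_df$quantity %in%
                            c("partition_ok", "lst_plus_multi_ok")] == 1))
      stop("report partition identities violated", call. = FALSE)
  }
  invisible(written)
}
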