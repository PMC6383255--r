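test_that("saturation filter applies strict bounds per branch", {
  rt <- data.frame(
    gene_id = paste0("g", 1:6), branch = "Dmel",
    dN = c(0.1, 0.1, 0.1, 1.5, 1.6, 0.2),
    dS = c(0.3, 1.6, 0.0005, 0.3, 0.3, 1.5),
    stringsAsFactors = FALSE)
  res <- apply_saturation_filter(rt)
  expect_equal(res$retained$gene_id, "g1")          # only the clean row
  expect_false(res$passes_filter[[4L]])             # dN = 1.5 is excluded
  expect_false(res$passes_filter[[6L]])             # dS = 1.5 is excluded
  expect_false(res$passes_filter[[3L]])             # dS below the floor
  expect_equal(res$retained$omega, 0.1 / 0.3)
  # idempotence
  again <- apply_saturation_filter(res$retained[, 1:4])
  expect_equal(again$retained$gene_id, res$retained$gene_id)
  expect_error(apply_saturation_filter(
    data.frame(gene_id = "g", branch = "Dmel", dN = -1, dS = 0.1)),
    "negative")
})

test_that("a gene may pass the filter in one branch and fail in another", {
  rt <- data.frame(gene_id = "g1", branch = c("Dmel", "Dana"),
                   dN = c(0.1, 0.1), dS = c(0.3, 1.7),
                   stringsAsFactors = FALSE)
  res <- apply_saturation_filter(rt)
  expect_equal(res$retained$branch, "Dmel")
  expect_equal(res$excluded$n_excluded[res$excluded$Var1 == "Dana"], 1L)
})

test_that("the single-ratio proxy is mean dN over mean dS", {
  rt <- data.frame(gene_id = "g1", branch = species4,
                   dN = rep(0.1, 4), dS = rep(0.5, 4),
                   stringsAsFactors = FALSE)
  expect_equal(m0_proxy(rt)$omega_proxy, 0.2)
  rt2 <- data.frame(gene_id = "g2", branch = species4[1:2],
                    dN = c(0.1, 0.3), dS = c(0.5, 0.5),
                    stringsAsFactors = FALSE)
  expect_equal(m0_proxy(rt2)$omega_proxy, 0.4)
  # equals the per-branch omega when all branches are identical
  expect_equal(m0_proxy(rt)$omega_proxy, 0.1 / 0.5)
})

test_that("the proxy tracks the planted gene-level omega", {
  sim <- simulate_gonad_data(generator_config(seed = 13, n_genes = 1500),
                             components = "rates")
  filt <- apply_saturation_filter(sim$rates)
  prox <- m0_proxy(filt$retained)
  truth <- sim$truth$omega[match(prox$gene_id, sim$truth$gene_id)]
  expect_gte(spearman_r(prox$omega_proxy, truth)$r, 0.8)
})

test_that("LRT p-values match the chi-squared survival function", {
  expect_equal(lrt_pvalue(-100, -100, 1)$p_value, 1)
  expect_equal(lrt_pvalue(-100, -100 + 3.841459 / 2, 1)$p_value, 0.05,
               tolerance = 1e-6)
  expect_equal(lrt_pvalue(-100, -100 + 5.991465 / 2, 2)$p_value, 0.05,
               tolerance = 1e-6)
  # grid identity to 1e-9
  for (df in c(1, 2, 5)) {
    for (td in c(0, 0.1, 1, 3.84, 10, 50)) {
      expect_equal(lrt_pvalue(0, td / 2, df)$p_value,
                   pchisq(td, df, lower.tail = FALSE), tolerance = 1e-9)
    }
  }
  # tiny optimizer noise is clamped silently, real inversions warn
  expect_silent(p0 <- lrt_pvalue(-100, -100 - 1e-9, 1))
  expect_equal(p0$two_delta, 0)
  expect_warning(lrt_pvalue(-100, -101, 1), "clamped")
  expect_error(lrt_pvalue(-1, -1, 0), "df")
})

test_that("planted omega ordering across categories is recovered", {
  sim <- simulate_gonad_data(generator_config(seed = 19, n_genes = 4000),
                             components = "rates")
  truth <- sim$truth
  filt <- apply_saturation_filter(sim$rates)
  grp <- with(truth, ifelse(class == "clade_wide" & status_Dmel == "ts" &
                              breadth_group != "cw_testis_specific",
                            "cw_testis",
                     ifelse(class == "clade_wide" & status_Dmel == "ov",
                            "cw_ovary",
                     ifelse(class == "clade_wide" & status_Dmel == "unb",
                            "cw_unbiased", NA))))
  res <- omega_by_category(filt$retained, setNames(grp, truth$gene_id))
  for (b in species4) {
    s <- res$summary[res$summary$branch == b, ]
    med <- s$median_omega[match(c("cw_testis", "cw_unbiased", "cw_ovary"),
                                s$group)]
    expect_true(all(diff(med) < 0))  # ts > unb > ov
    dunn <- res$tests[[b]]$dunn
    expect_lt(dunn$p_value[dunn$group_a == "cw_ovary" &
                             dunn$group_b == "cw_testis" |
                           dunn$group_a == "cw_testis" &
                             dunn$group_b == "cw_ovary"], 0.05)
  }
})

test_that("testis-specificity tiers order NS < NU < U in omega", {
  sim <- simulate_gonad_data(generator_config(seed = 23, n_genes = 6000),
                             components = "rates")
  truth <- sim$truth
  filt <- apply_saturation_filter(sim$rates)
  # tiers in the reference branch from planted flags
  ts_dmel <- truth$status_Dmel == "ts"
  uni <- truth$breadth_group == "cw_testis_specific"
  any_spec <- truth$specific_Dmel
  tier <- ifelse(!ts_dmel, NA,
                 ifelse(uni, "U", ifelse(any_spec, "NU", "NS")))
  res <- omega_by_category(filt$retained[filt$retained$branch == "Dmel", ],
                           setNames(tier, truth$gene_id))
  med <- res$summary$median_omega[match(c("NS", "NU", "U"),
                                        res$summary$group)]
  expect_true(all(diff(med) > 0))
})

test_that("identical planted omega gives few significant contrasts", {
  set.seed(51)
  hits <- replicate(25, {
    om <- exp(rnorm(240, log(0.2), 0.4))
    rt <- data.frame(gene_id = paste0("g", 1:240), branch = "Dmel",
                     dN = om * 0.3, dS = 0.3, omega = om,
                     stringsAsFactors = FALSE)
    grp <- setNames(rep(c("a", "b", "c"), each = 80), rt$gene_id)
    omega_by_category(rt, grp)$tests$Dmel$kruskal_p < 0.05
  })
  expect_lte(mean(hits), 0.10)
})

test_that("fold-class omega medians are concordant across species", {
  sim <- simulate_gonad_data(generator_config(seed = 29, n_genes = 5000))
  filt <- apply_saturation_filter(sim$rates)
  truth <- sim$truth
  calls <- do.call(rbind, lapply(species4, function(sp) {
    st <- truth[[paste0("status_", sp)]]
    long <- c(ts = "testis_biased", ov = "ovary_biased", unb = "unbiased")
    data.frame(gene_id = truth$gene_id, species = sp, status = long[st],
               fold_bias = ifelse(st == "unb", 1,
                                  truth[[paste0("fold_", sp)]]),
               p_value = 1e-6,
               sex_specific = truth[[paste0("specific_", sp)]],
               fpkm_t = 10, fpkm_o = 1, stringsAsFactors = FALSE)
  }))
  res <- omega_by_foldclass(filt$retained, calls)
  expect_true(all(res$species_concordance$r > 0.5))
  # testis-biased medians rise with fold class in the reference branch
  m <- res$medians[res$medians$species == "Dmel", ]
  ts_med <- m$median_omega[match(c("ts_low", "ts_mid", "ts_high"),
                                 m$category)]
  expect_true(all(diff(ts_med) > 0))
})

test_that("codeml free-ratio output parses to per-species branch rates", {
  dn <- c(0.01, 0.02, 0.05, 0.12); ds <- c(0.04, 0.05, 0.11, 0.35)
  p <- tempfile(fileext = ".txt")
  writeLines(codeml_fixture_text(dn, ds), p)
  br <- parse_freeratio_output(p, "gX")
  expect_equal(br$branch, species4)
  expect_equal(br$dN, dn)
  expect_equal(br$dS, ds)
  expect_equal(br$omega, dn / ds, tolerance = 1e-4)
  # file missing a terminal branch errors with the species name
  txt <- codeml_fixture_text()
  writeLines(txt[-grep("6..3", txt, fixed = TRUE)], p)
  expect_error(parse_freeratio_output(p, "gX"), "Dyak")
  # round-trip through the TSV layer
  writeLines(codeml_fixture_text(dn, ds), p)
  br <- parse_freeratio_output(p, "gX")
  p2 <- tempfile(fileext = ".tsv")
  write_branch_rates(br, p2)
  expect_equal(read_branch_rates(p2)$dS, br$dS, tolerance = 1e-5)
  unlink(c(p, p2))
})

test_that("the shipped synthetic free-ratio fixture parses", {
  fx <- system.file("extdata", "synthetic_codeml_freeratio.txt",
                    package = "sbturnover")
  br <- parse_freeratio_output(fx, "FBgn0000001")
  expect_equal(nrow(br), 4L)
  expect_setequal(br$branch, species4)
  expect_true(all(br$dS > 0))
})
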