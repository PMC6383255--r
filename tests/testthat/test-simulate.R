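test_that("the generator is fully determined by its seed", {
  a <- simulate_gonad_data(generator_config(seed = 3, n_genes = 300))
  b <- simulate_gonad_data(generator_config(seed = 3, n_genes = 300))
  expect_identical(a$expression, b$expression)
  expect_identical(a$breadth, b$breadth)
  expect_identical(a$rates, b$rates)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_gonad_data(generator_config(seed = 4, n_genes = 300))
  expect_false(identical(a$expression, c2$expression))
})

test_that("zero transition rates give an all-clade-wide or multi dataset", {
  cfg <- generator_config(seed = 6, n_genes = 500,
                          rates = .default_rates() * 0,
                          cladewide_props = c(ts = 0.3, ov = 0.3,
                                              unb = 0.4))
  sim <- simulate_gonad_data(cfg, components = character(0))
  expect_true(all(sim$truth$class == "clade_wide"))
  status <- as.matrix(sim$truth[, paste0("status_", species4)])
  colnames(status) <- species4
  tab <- build_slst_table(classify_profiles(make_calls(status)))
  expect_true(all(tab$s_lst == 0))
})

test_that("infeasible configurations are rejected before sampling", {
  expect_error(generator_config(seed = 1,
                                cladewide_props = c(ts = 0.5, ov = 0.4,
                                                    unb = 0.3)),
               "at most 1")
  big <- .default_rates(); big[, ] <- 0.4
  expect_error(generator_config(seed = 1, rates = big), "exceed 1")
  expect_error(generator_config(seed = 1,
                                cladewide_props = c(ts = 0.6, ov = 0.3,
                                                    unb = 0.09)),
               "unreachable")
  expect_error(generator_config(), "seed")
})

test_that("clade-wide proportions are recovered within 3 SE at n = 10,000", {
  n <- 10000L
  sim <- simulate_gonad_data(generator_config(seed = 8, n_genes = n),
                             components = character(0))
  status <- as.matrix(sim$truth[, paste0("status_", species4)])
  colnames(status) <- species4
  profiles <- classify_profiles(make_calls(status))
  cw <- profiles[profiles$class == "clade_wide", ]
  planted <- c(ts = 0.192, ov = 0.183, unb = 0.128)
  for (st in names(planted)) {
    phat <- sum(cw$Dmel == st) / n
    se <- sqrt(planted[[st]] * (1 - planted[[st]]) / n)
    expect_lt(abs(phat - planted[[st]]), 3 * se)
  }
})

test_that("planted per-branch transition probabilities are unbiased S-LSTs", {
  n <- 10000L
  sim <- simulate_gonad_data(generator_config(seed = 9, n_genes = n),
                             components = character(0))
  status <- as.matrix(sim$truth[, paste0("status_", species4)])
  colnames(status) <- species4
  tab <- build_slst_table(classify_profiles(make_calls(status)))
  rates <- .default_rates()
  for (r in seq_len(nrow(tab))) {
    planted <- rates[tab$branch[[r]], tab$category[[r]]]
    pool <- tab$pool[[r]]
    se <- sqrt(planted * (1 - planted) / pool)
    expect_lt(abs(tab$s_lst[[r]] / 1000 - planted), 3 * se + 1e-9)
  }
})

test_that("status calls from counts match ground truth where fold >= 4", {
  sim <- simulate_gonad_data(generator_config(seed = 10, n_genes = 2500))
  calls <- classify_sex_bias(sim$expression,
                             library_sizes = sim$library_sizes)
  truth <- sim$truth
  short <- c(testis_biased = "ts", ovary_biased = "ov", unbiased = "unb")
  acc <- vapply(species4, function(sp) {
    tr_status <- truth[[paste0("status_", sp)]]
    tr_fold <- truth[[paste0("fold_", sp)]]
    sel <- !is.na(tr_fold) & tr_fold >= 4
    got <- short[calls$status[calls$species == sp][
      match(truth$gene_id[sel], calls$gene_id[calls$species == sp])]]
    mean(got == tr_status[sel])
  }, numeric(1L))
  expect_true(all(acc >= 0.95))
})

test_that("sex-specific planting yields zero counts and recovered flags", {
  sim <- simulate_gonad_data(generator_config(seed = 12, n_genes = 1500))
  truth <- sim$truth
  expr <- sim$expression
  spec_dmel <- truth$gene_id[truth$specific_Dmel &
                               truth$status_Dmel == "ts"]
  ov_counts <- expr$count[expr$species == "Dmel" & expr$tissue == "ovary" &
                            expr$gene_id %in% spec_dmel]
  expect_true(all(ov_counts == 0))
  calls <- classify_sex_bias(expr, library_sizes = sim$library_sizes)
  got <- calls[calls$species == "Dmel" & calls$gene_id %in% spec_dmel, ]
  expect_true(all(got$sex_specific))
  expect_true(all(is.infinite(got$fold_bias)))
})

test_that("degradation is the identity at full depth and kills power at zero", {
  sim <- simulate_gonad_data(generator_config(seed = 14, n_genes = 400))
  expect_identical(degrade(sim$expression, 1), sim$expression)
  dead <- degrade(sim$expression, 0, seed = 2)
  expect_true(all(dead$count == 0))
  calls <- classify_sex_bias(dead, library_sizes = sim$library_sizes)
  expect_true(all(calls$status == "unbiased"))
})

test_that("status-recovery accuracy declines monotonically with depth", {
  sim <- simulate_gonad_data(generator_config(seed = 15, n_genes = 800))
  truth <- sim$truth
  short <- c(testis_biased = "ts", ovary_biased = "ov", unbiased = "unb")
  acc_at <- function(depth) {
    ex <- degrade(sim$expression, depth, seed = 99)
    calls <- classify_sex_bias(ex, library_sizes = sim$library_sizes)
    calls <- calls[calls$species == "Dmel", ]
    mean(short[calls$status[match(truth$gene_id, calls$gene_id)]] ==
           truth$status_Dmel)
  }
  accs <- c(acc_at(1), acc_at(1e-4), acc_at(1e-6))
  expect_true(all(diff(accs) < 0.02))   # monotone decline up to noise
  expect_lt(accs[[3]], accs[[1]])
})

test_that("planted breadth categories shape the emitted matrix", {
  sim <- simulate_gonad_data(generator_config(seed = 16, n_genes = 2000))
  bp <- breadth_profiles(sim$breadth)
  truth <- sim$truth
  m <- tapply(bp$breadth_pct[match(truth$gene_id, bp$gene_id)],
              truth$breadth_group, mean)
  expect_gt(m[["cw_ovary"]], m[["cw_unbiased"]])
  expect_gt(m[["cw_unbiased"]], m[["cw_testis_specific"]])
  # matrix breadth equals the planted tissue count exactly
  expect_equal(bp$n_tissues_expressed[match(truth$gene_id, bp$gene_id)],
               truth$n_tissues)
})
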