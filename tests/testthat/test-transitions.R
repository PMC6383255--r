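test_that("profile classification matches the exhaustive enumeration oracle", {
  profs <- all_profiles()
  got <- apply(profs, 1L, function(s) classify_profile(s)$class)
  want <- apply(profs, 1L, oracle_classify)
  expect_equal(got, want)
  # multinomial partition counts over all 81 profiles: 3 / 24 / 18 / 36
  expect_equal(unname(table(got)[c("clade_wide", "lst", "multi_two_two",
                                   "multi_three_state")]),
               c(3L, 24L, 18L, 36L), ignore_attr = TRUE)
})

test_that("LST fields identify ancestral state, derived state and branch", {
  cl <- classify_profile(c("ov", "ts", "ts", "ts"))
  expect_equal(cl$class, "lst")
  expect_equal(cl$ancestral, "ts")
  expect_equal(cl$derived, "ov")
  expect_equal(cl$branch, "Dmel")
  expect_equal(cl$category, "ts-ov")
  expect_false(cl$outgroup_caveat)
  # clade-wide
  expect_equal(classify_profile(rep("ts", 4))$class, "clade_wide")
  expect_equal(classify_profile(rep("ts", 4))$status, "ts")
  # long-form statuses are accepted
  expect_equal(classify_profile(c("unbiased", "testis_biased",
                                  "unbiased", "unbiased"))$branch, "Dsim")
})

test_that("outgroup-branch LSTs coincide exactly with ingroup conservation", {
  profs <- all_profiles()
  for (i in seq_len(nrow(profs))) {
    cl <- classify_profile(profs[i, ])
    tsi_set <- !is.na(cl$tsi_status)
    dana_lst <- cl$class == "lst" && cl$branch == "Dana"
    # an LST on the outgroup branch <=> ingroup shares a status that
    # differs from the outgroup's
    expect_equal(dana_lst,
                 tsi_set && cl$tsi_status != profs[i, 4L])
    if (dana_lst) expect_true(cl$outgroup_caveat)
  }
})

test_that("two-two arrangements record the species bipartition", {
  cl <- classify_profile(c("ts", "ts", "unb", "unb"))
  expect_equal(cl$class, "multi_two_two")
  expect_setequal(cl$status_pair, c("ts", "unb"))
  expect_match(cl$arrangement, "Dmel,Dsim")
  expect_match(cl$arrangement, "Dyak,Dana")
})

test_that("S-LST formula, bounds and undefined denominator", {
  expect_equal(compute_slst(9, 1, 90), 90)
  expect_equal(compute_slst(0, 5, 100), 0)
  expect_equal(compute_slst(0, 0, 10), 0)
  expect_true(is.na(compute_slst(0, 0, 0)))  # missing, not 0
  expect_error(compute_slst(-1, 0, 10), "non-negative")
  # bounds and pairing: s(x->y) + s(x->z) <= 1000
  set.seed(3)
  for (i in 1:20) {
    n1 <- rpois(1, 5); n2 <- rpois(1, 5); cw <- rpois(1, 50)
    if (n1 + n2 + cw == 0) next
    s1 <- compute_slst(n1, n2, cw)
    s2 <- compute_slst(n2, n1, cw)
    expect_gte(s1, 0); expect_lte(s1, 1000)
    expect_lte(s1 + s2, 1000 + 1e-9)
  }
})

test_that("S-LST table agrees with an independent brute-force recount", {
  set.seed(21)
  sim <- simulate_gonad_data(generator_config(seed = 77, n_genes = 3000),
                             components = character(0))
  truth <- sim$truth
  status <- as.matrix(truth[, paste0("status_", species4)])
  colnames(status) <- species4
  calls <- make_calls(status)
  profiles <- classify_profiles(calls)
  tab <- build_slst_table(profiles)

  # brute-force recount straight from the raw status matrix
  for (r in seq_len(nrow(tab))) {
    b <- match(tab$branch[[r]], species4)
    anc <- tab$ancestral[[r]]; der <- tab$derived[[r]]
    alt <- setdiff(c("ts", "ov", "unb"), c(anc, der))
    is_lst_cell <- apply(status, 1L, function(s)
      s[[b]] == der && all(s[-b] == anc))
    is_alt_cell <- apply(status, 1L, function(s)
      s[[b]] == alt && all(s[-b] == anc))
    n_cw <- sum(apply(status, 1L, function(s) all(s == anc)))
    expect_equal(tab$n_lst[[r]], sum(is_lst_cell))
    expect_equal(tab$n_alt[[r]], sum(is_alt_cell))
    expect_equal(tab$n_cladewide[[r]], n_cw)
    denom <- n_cw + sum(is_lst_cell) + sum(is_alt_cell)
    expect_equal(tab$s_lst[[r]],
                 if (denom == 0) NA_real_ else
                   sum(is_lst_cell) / denom * 1000)
  }
  # every LST gene lands in exactly one cell
  expect_equal(sum(tab$n_lst), sum(profiles$class == "lst"))
  # partition identity over classes
  expect_equal(sum(table(profiles$class)), nrow(profiles))
})

test_that("an all-clade-wide dataset yields zero S-LSTs everywhere", {
  status <- matrix(rep(c(rep("ts", 4), rep("ov", 3), rep("unb", 3)),
                       each = 4), ncol = 4, byrow = TRUE)
  calls <- make_calls(status)
  tab <- build_slst_table(classify_profiles(calls))
  expect_true(all(tab$n_lst == 0))
  expect_true(all(tab$s_lst == 0))
})

test_that("a single LST against a clade-wide pool gives the direct formula", {
  status <- matrix("unb", 100, 4)
  status[1L, 1L] <- "ts"  # one unb->ts LST on the reference branch
  calls <- make_calls(status)
  tab <- build_slst_table(classify_profiles(calls))
  cell <- tab[tab$branch == "Dmel" & tab$category == "unb-ts", ]
  expect_equal(cell$s_lst, 1 / (99 + 1 + 0) * 1000)
})

test_that("S-LST ratios reproduce the printed two-decimal convention", {
  expect_equal(slst_ratio(21.47, 1.92), 11.18)
  expect_equal(slst_ratio(148.87, 19.06), 7.81)
  expect_equal(slst_ratio(5, 5), 1)
  expect_true(is.na(slst_ratio(5, 0)))
})

test_that("transition contrasts match the closed-form chi-squared", {
  # identical rows: statistic 0, p 1
  same <- transition_contrast(10, 100, 10, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand oracle on [[10, 90], [50, 50]]
  tab <- rbind(c(10, 90), c(50, 50))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  got <- transition_contrast(10, 100, 50, 100)
  expect_equal(got$statistic, stat, tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_warning(transition_contrast(0, 3, 1, 3), "below 1")
})

test_that("contrast p-values are uniform under the null and small under effect", {
  set.seed(5)
  ps <- replicate(300, {
    n1 <- rbinom(1, 200, 0.1); n2 <- rbinom(1, 200, 0.1)
    transition_contrast(n1, 200, n2, 200)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  strong <- transition_contrast(80, 200, 10, 200)
  expect_lt(strong$p_value, 1e-10)
})

test_that("slst_contrasts covers the four standard comparisons per branch", {
  set.seed(9)
  sim <- simulate_gonad_data(generator_config(seed = 5, n_genes = 2000),
                             components = character(0))
  status <- as.matrix(sim$truth[, paste0("status_", species4)])
  colnames(status) <- species4
  tab <- build_slst_table(classify_profiles(make_calls(status)))
  cc <- slst_contrasts(tab)
  expect_equal(nrow(cc), 16L)
  expect_setequal(unique(cc$contrast),
                  c("gain_testis", "gain_ovary", "loss", "reversals"))
  expect_true(all(cc$p_value >= 0 & cc$p_value <= 1, na.rm = TRUE))
})
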