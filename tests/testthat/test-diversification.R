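test_that("ms_rate reproduces closed-form limits and known values", {
  expect_equal(ms_rate(4, 1, 0, "crown"), log(2), tolerance = 1e-12)
  expect_equal(ms_rate(1, 5, 0, "stem"), 0)
  expect_equal(ms_rate(23, 26, 0, "crown"), 0.0939, tolerance = 1e-3)
  # epsilon = 0 limits across a grid, to machine precision
  for (N in c(2, 5, 23, 100, 500)) for (t in c(1, 10, 26)) {
    expect_equal(ms_rate(N, t, 0, "crown"), log(N / 2) / t,
                 tolerance = 1e-12)
    expect_equal(ms_rate(N, t, 0, "stem"), log(N) / t, tolerance = 1e-12)
  }
  expect_error(ms_rate(4, 1, 1), "eps")
  expect_error(ms_rate(1, 1, 0, "crown"), "N >= 2")
  expect_error(ms_rate(4, 0, 0), "positive")
})

test_that("ms_rate is continuous and decreasing in the extinction fraction", {
  eps <- seq(0, 0.99, by = 0.01)
  for (N in c(5, 23, 83)) {
    r <- ms_rate(N, 10, eps, "crown")
    expect_true(all(diff(r) < 1e-12))
    # continuity at 0
    expect_lt(abs(ms_rate(N, 10, 1e-9) - ms_rate(N, 10, 0)), 1e-6)
  }
})

test_that("ms_rate_table mirrors the clade inputs", {
  cl <- data.frame(clade = c("C1", "A2b"), crown_age = c(26, 10),
                   total_richness = c(23, 83))
  tab <- ms_rate_table(cl)
  expect_equal(tab$r_0, c(log(23 / 2) / 26, log(83 / 2) / 10),
               tolerance = 1e-12)
  expect_equal(names(tab), c("clade", "N", "t", "mode",
                             "r_0", "r_0.5", "r_0.99"))
})

test_that("gamma statistic matches hand values and the ape oracle", {
  expect_equal(gamma_statistic(new_branching_times(c(2, 1)))$gamma,
               -0.3464102, tolerance = 1e-6)
  # numerator vanishes when the cumulative lineage-time equals T/2
  g0 <- new_branching_times(rev(cumsum(rev(c(1.5, 1))))[1:2])
  expect_equal(gamma_statistic(g0)$gamma, 0, tolerance = 1e-12)
  b4 <- new_branching_times(c(3, 2, 1))
  expect_equal(gamma_statistic(b4)$gamma, -0.5443311, tolerance = 1e-6)
  expect_error(gamma_statistic(new_branching_times(2)), "3 tips")

  set.seed(5)
  for (i in 1:15) {
    tr <- simulate_bd_tree(sample(5:60, 1), birth = 1,
                           death = runif(1, 0, 0.5))
    expect_equal(gamma_statistic(branching_times(tr))$gamma,
                 ape::gammaStat(tr), tolerance = 1e-8)
  }
})

test_that("mccr_test is reproducible, floors p, and tracks the analytic test", {
  m1 <- mccr_test(-1, 40, 20, reps = 200, seed = 9)
  m2 <- mccr_test(-1, 40, 20, reps = 200, seed = 9)
  expect_identical(m1$null, m2$null)

  low <- mccr_test(-10, 30, 10, reps = 200, seed = 1)
  expect_equal(low$p_corrected, 1 / 201)
  expect_true(low$significant)

  full <- mccr_test(-2, 50, 50, reps = 3000, seed = 2)
  expect_lt(abs(full$p_corrected - pnorm(-2)), 0.02)
  expect_lt(abs(full$critical - (-1.645)), 0.15)

  # incomplete sampling drags the null (and so the critical value) down
  pruned <- mccr_test(-2, 60, 15, reps = 400, seed = 3)
  expect_lt(pruned$critical, full$critical)
  expect_error(mccr_test(-1, 10, 20), "exceed")
})

test_that("pure-birth fit has the closed-form MLE", {
  b4 <- new_branching_times(c(3, 2, 1))
  f <- fit_model(b4, "PB")
  expect_equal(unname(f$params["lambda"]), 2 / 9, tolerance = 1e-12)
  expect_equal(f$AIC, -2 * f$lnL + 2)
})

test_that("likelihood nesting holds across the model family", {
  set.seed(6)
  for (i in 1:30) {
    tr <- simulate_bd_tree(sample(8:50, 1), birth = 1,
                           death = runif(1, 0, 0.6))
    bt <- branching_times(tr)
    l <- vapply(c("PB", "BD", "DDL", "DDX", "YULE2", "YULE3"),
                function(m) fit_model(bt, m)$lnL, numeric(1))
    expect_gte(l["BD"], l["PB"] - 1e-6)
    expect_gte(l["DDL"], l["PB"] - 1e-6)
    expect_gte(l["DDX"], l["PB"] - 1e-6)
    expect_gte(l["YULE2"], l["PB"] - 1e-6)
    expect_gte(l["YULE3"], l["YULE2"] - 1e-6)
  }
})

test_that("birth-death fit agrees with the independent ape implementation", {
  set.seed(7)
  for (i in 1:3) {
    tr <- simulate_bd_tree(60, birth = 1, death = 0.5)
    f <- fit_model(branching_times(tr), "BD")
    ab <- ape::birthdeath(tr)
    expect_equal(f$lnL, -ab$dev / 2, tolerance = 1e-4)
    expect_equal(unname(f$params["eps"]), unname(ab$para["d/b"]),
                 tolerance = 1e-2)
  }
})

test_that("density-dependent fits collapse to pure birth at their null point", {
  set.seed(8)
  bt <- sim_yule_bt(40)
  pb <- fit_model(bt, "PB")
  ddx <- fit_model(bt, "DDX")
  # x = 0 is an explicit candidate, so DDX can never fall below PB
  expect_gte(ddx$lnL, pb$lnL)
  ddl <- fit_model(bt, "DDL")
  expect_gte(ddl$lnL, pb$lnL - 1e-6)
  expect_gt(unname(ddl$params["K"]), bt$n_tips)
})

test_that("a strong rate drop is located by the two-rate Yule fit", {
  set.seed(10)
  bt <- sim_shift_bt(80, 40, l1 = 1, l2 = 0.1)
  f <- fit_model(bt, "YULE2")
  expect_gt(unname(f$params["lambda1"] / f$params["lambda2"]), 3)
  expect_true(f$params["shift1"] %in% bt$ages)
  ms <- model_select(bt)
  expect_gte(ms$delta_AIC_RC, 4)
  expect_equal(ms$table$model[ms$table$class == "RC"], c("PB", "BD"))
  expect_equal(ms$delta_AIC_RC,
               min(ms$table$AIC[ms$table$class == "RC"]) -
                 min(ms$table$AIC[ms$table$class == "RV"]))
})

test_that("diversification_table assembles rates, gamma and MCCR per clade", {
  set.seed(11)
  tr <- simulate_bd_tree(12)
  tr$edge.length <- tr$edge.length * (10 / tree_depth(tr))
  cl <- data.frame(clade = "R1", crown_age = 10, total_richness = 20)
  cl$tips <- list(tr$tip.label)
  tab <- diversification_table(tr, cl, mccr_reps = 200, seed = 1)
  expect_equal(tab$n_sampled, 12)
  expect_equal(tab$r_0, log(10) / 10, tolerance = 1e-12)
  expect_true(tab$p_mccr > 0 && tab$p_mccr <= 1)
})
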