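test_that("spatial similarity decays linearly with great-circle distance", {
  # three species along one meridian at 0, 50, 100 km-equivalent spacing
  step <- 50 / (6371 * pi / 180)
  cents <- data.frame(species = c("a", "b", "c"), lon = 0,
                      lat = c(0, step, 2 * step))
  S <- spatial_similarity(cents)
  expect_equal(unname(S), rbind(c(1, .5, 0), c(.5, 1, .5), c(0, .5, 1)),
               tolerance = 1e-6, ignore_attr = TRUE)

  # coincident pair keeps similarity 1; most distant pair is 0
  cents2 <- data.frame(species = c("a", "b", "c"),
                       lon = c(10, 10, 20), lat = c(-30, -30, -30))
  S2 <- spatial_similarity(cents2)
  expect_equal(S2["a", "b"], 1)
  expect_equal(S2["a", "c"], 0)

  expect_error(spatial_similarity(
    data.frame(species = c("a", "b"), lon = c(1, 1), lat = c(2, 2))),
    "degenerate")

  S3 <- spatial_similarity(cents, kernel = "exponential")
  expect_equal(diag(S3), c(a = 1, b = 1, c = 1))
  expect_true(all(S3[upper.tri(S3)] > 0))
})

test_that("with S = identity the fit collapses to the Pagel-lambda model", {
  set.seed(15)
  tr <- simulate_bd_tree(40)
  Id <- diag(1, 40)
  dimnames(Id) <- list(tr$tip.label, tr$tip.label)
  for (lam_true in c(0.3, 0.9)) {
    y <- simulate_trait(tr, 1, lambda = lam_true)
    f0 <- fit_space_phylo(tr, NULL, y)   # single-signal reference
    # internal oracle: plain grid search at 1e-3 resolution
    C <- phylo_correlation(tr, 1)
    off <- row(C) != col(C)
    grid_lnL <- vapply(seq(0, 1, by = 1e-3), function(l) {
      V <- C; V[off] <- V[off] * l
      radshift:::gls_profile(y[tr$tip.label], V)$lnL
    }, numeric(1))
    lam_grid <- seq(0, 1, by = 1e-3)[which.max(grid_lnL)]
    expect_lt(abs(f0$lambda - lam_grid), 1.1e-3)
    # external oracle
    ps <- phytools::phylosig(tr, y, method = "lambda")
    expect_lt(abs(f0$lambda - min(ps$lambda, 1)), 1e-3)
    expect_lt(abs(f0$lnL - ps$logL), 1e-3)
  }
})

test_that("the decomposition identity holds to machine precision", {
  set.seed(16)
  tr <- simulate_bd_tree(24)
  cents <- data.frame(species = tr$tip.label,
                      lon = runif(24, 16, 30), lat = runif(24, -35, -28))
  S <- spatial_similarity(cents)
  for (w in c(0, 0.5, 1)) {
    y <- simulate_trait(tr, 1, S = S, w_s = w)
    f <- fit_space_phylo(tr, S, y)
    expect_equal(f$lambda_prime + f$gamma_indep + f$phi, 1,
                 tolerance = 1e-12)
    expect_equal(f$lambda_prime, (1 - f$phi) * f$lambda, tolerance = 1e-12)
    expect_equal(f$gamma_indep, (1 - f$phi) * (1 - f$lambda),
                 tolerance = 1e-12)
  }
})

test_that("the optimum dominates the corners of the (lambda, phi) square", {
  set.seed(17)
  tr <- simulate_bd_tree(24)
  cents <- data.frame(species = tr$tip.label,
                      lon = runif(24, 16, 30), lat = runif(24, -35, -28))
  S <- spatial_similarity(cents)
  y <- simulate_trait(tr, 1, S = S, w_s = 0.4)
  f <- fit_space_phylo(tr, S, y)
  C <- phylo_correlation(tr, 1)
  off <- row(C) != col(C)
  corner <- function(l, p) {
    Vl <- C; Vl[off] <- Vl[off] * l
    radshift:::gls_profile(y[tr$tip.label], (1 - p) * Vl + p * S)$lnL
  }
  for (cc in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
    expect_gte(f$lnL, corner(cc[1], cc[2]) - 1e-6)
})

test_that("fit is invariant to trait shift and equivariant under scaling", {
  set.seed(18)
  tr <- simulate_bd_tree(20)
  cents <- data.frame(species = tr$tip.label,
                      lon = runif(20, 16, 30), lat = runif(20, -35, -28))
  S <- spatial_similarity(cents)
  y <- simulate_trait(tr, 1, S = S, w_s = 0.3)
  f1 <- fit_space_phylo(tr, S, y)
  f2 <- fit_space_phylo(tr, S, y + 100)
  f3 <- fit_space_phylo(tr, S, y * 7)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-5)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-5)
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-6)
  expect_equal(f1$lambda, f3$lambda, tolerance = 1e-5)
  expect_equal(f3$sigma2, 49 * f1$sigma2, tolerance = 1e-4)
})

test_that("phi recovers the generating regime (smoke-scale)", {
  set.seed(19)
  tr <- simulate_bd_tree(48)
  cents <- data.frame(species = tr$tip.label,
                      lon = runif(48, 16, 30), lat = runif(48, -35, -28))
  S <- spatial_similarity(cents)
  phi_p <- replicate(20, fit_space_phylo(tr, S,
    simulate_trait(tr, 1, lambda = 1, w_s = 0))$phi)
  phi_s <- replicate(20, fit_space_phylo(tr, S,
    simulate_trait(tr, 1, S = S, w_s = 1))$phi)
  expect_lte(median(phi_p), 0.1)
  expect_gte(median(phi_s), 0.9)
})

test_that("signal_decomposition returns one row per clade and variable", {
  sc <- radiating_clade_scenario(n_species = 8, n_points = 30, seed = 3)
  tab <- signal_decomposition(sc$tree, sc$occ, sc$clades)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$phi >= 0 & tab$phi <= 1))
  expect_equal(tab$lambda_prime + tab$gamma_indep + tab$phi, c(1, 1),
               tolerance = 1e-12)
})
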