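test_that("read_newick parses, derives ages, and enforces ultrametricity", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(tree_depth(tr), 1)

  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  ages <- sort(node_ages(tr3)[4:5], decreasing = TRUE)
  expect_equal(unname(ages), c(2, 1))

  expect_error(read_newick("(A:1,B:2);"), "not ultrametric")
  expect_warning(read_newick("(A:1,B:2);", strict = FALSE), "not ultrametric")
  expect_error(read_newick("(A:1,B:-1);"), "negative")
  expect_error(read_newick("(A:1,A:1);"), "duplicated")
})

test_that("polytomies are resolved into zero-length bifurcations", {
  expect_warning(tr <- read_newick("((A:1,B:1,C:1):1,D:2);"), "polytomies")
  expect_true(ape::is.binary(tr))
  expect_equal(tree_depth(tr), 2)
  expect_equal(ape::Ntip(tr), 4)
})

test_that("branching_times matches hand-computed internode structure", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  bt <- branching_times(tr)
  expect_equal(bt$ages, c(2, 1))
  expect_equal(unname(bt$g), c(1, 1))
  expect_equal(bt$T, 5)

  # clade subset uses the MRCA subtree
  bt_ab <- branching_times(tr, c("A", "B"))
  expect_equal(bt_ab$ages, 1)

  # balanced 4-tip tree, internals at ages 3, 1, 1
  b4 <- new_branching_times(c(3, 1, 1))
  expect_equal(unname(b4$g), c(2, 0, 1))
  expect_equal(b4$T, 8)

  expect_error(branching_times(tr, c("A", "Z")), "unknown tips")
  expect_error(branching_times(tr, "A"), "at least 2")
})

test_that("branching times are invariant to tip-label order and sum to crown age", {
  t1 <- read_newick("((A:1,B:1):2,(C:2,D:2):1);")
  t2 <- read_newick("((D:2,C:2):1,(B:1,A:1):2);")
  expect_equal(branching_times(t1)$ages, branching_times(t2)$ages)
  set.seed(1)
  for (i in 1:20) {
    bt <- branching_times(simulate_bd_tree(sample(5:40, 1)))
    expect_equal(sum(bt$g), bt$ages[1])
    expect_equal(length(bt$ages), bt$n_tips - 1L)
  }
})

test_that("phylo_correlation scales off-diagonals by lambda and stays PSD", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(phylo_correlation(tr, 0), diag(3),
               ignore_attr = TRUE)
  C <- phylo_correlation(tr, 1)
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1))
  expect_error(phylo_correlation(tr, 1.2), "lambda")

  set.seed(2)
  for (i in 1:10) {
    tr <- simulate_bd_tree(sample(4:30, 1))
    lam <- runif(1)
    ev <- eigen(phylo_correlation(tr, lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("clean_outliers removes distant records via the median + k*MAD rule", {
  set.seed(3)
  occ <- occ_df("sp1", c(rnorm(10, 20, 0.05), 30), c(rnorm(10, -30, 0.05), -30))
  out <- clean_outliers(occ, k = 5)
  expect_equal(nrow(out), 10)
  rem <- attr(out, "removed")
  expect_equal(nrow(rem), 1)
  expect_equal(rem$lon, 30)
  expect_gt(rem$dist_km, 900)

  # identical points: zero distances, all retained
  same <- occ_df("sp2", rep(20, 5), rep(-30, 5))
  expect_equal(nrow(clean_outliers(same)), 5)

  # two far-apart points: below the minimum record count, rule disabled
  two <- occ_df("sp3", c(10, 40), c(-30, -30))
  expect_equal(nrow(clean_outliers(two)), 2)
})

test_that("great-circle distance is sane", {
  expect_equal(gc_dist(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
})

test_that("tabular readers roundtrip occurrences, clades and grids", {
  d <- withr::local_tempdir()
  occ <- occ_df(c("a", "a", "b"), c(18, 19, 25), c(-33, -32, -30),
                SPP = c(100, 120, 400))
  f <- file.path(d, "occ.csv")
  write.csv(occ, f, row.names = FALSE)
  expect_equal(read_occurrences(f), occ)

  cl <- data.frame(clade = "X", tips = "a;b", crown_age = 10,
                   total_richness = 12)
  fc <- file.path(d, "clades.csv")
  write.csv(cl, fc, row.names = FALSE)
  got <- read_clades(fc)
  expect_equal(got$tips[[1]], c("a", "b"))
  expect_equal(got$crown_age, 10)

  grid <- simulate_landscape(grid_n = 10, seed = 4)
  fg <- file.path(d, "grid.csv")
  write.csv(as.data.frame(grid), fg, row.names = FALSE)
  g2 <- read_climate_grid(fg)
  expect_equal(g2$SPP, grid$SPP)
  expect_equal(attr(g2, "resolution"), attr(grid, "resolution"),
               tolerance = 1e-8)
})

test_that("ESRI ASCII grids load as cell-centered long tables", {
  d <- withr::local_tempdir()
  f <- file.path(d, "x.asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 2 3", "4 -9999 6"), f)
  g <- read_climate_grid(f, var = "elev")
  expect_equal(nrow(g), 5)          # one NODATA cell dropped
  # top-left of the raster is the north-west cell
  expect_equal(g$elev[g$lon == 0.5 & g$lat == 1.5], 1)
  expect_equal(g$elev[g$lon == 2.5 & g$lat == 0.5], 6)
})
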