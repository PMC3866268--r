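## Synthetic-data generators: birth-death trees, traits with phylogenetic and
## spatial signal, gradient landscapes, and suitability-sampled occurrences.
## These define the testbed conditions for every analysis stage.

# Yule (pure-birth) simulation conditioned on n tips, kept as flat arrays for
# speed. Waiting time with k lineages ~ Exp(k * lambda) for k = 2..n; the
# final interval (k = n, no further split) is included so that internode
# durations satisfy k * g_k ~ iid Exp(lambda), the construction under which
# the gamma statistic is calibrated. Children always get larger ids than
# their parent, which the pruning pass relies on.
yule_sim_events <- function(n, lambda = 1) {
  stopifnot(n >= 3)
  nn <- 2L * n - 1L
  parent <- integer(nn)
  age <- numeric(nn)
  g <- stats::rexp(n - 1L, rate = lambda * (2:n))
  A <- rev(cumsum(rev(g)))        # A[j]: age of the split creating j+1 lineages
  age[1L] <- A[1L]
  parent[2:3] <- 1L
  alive <- c(2L, 3L)
  nid <- 3L
  for (j in 2:(n - 1L)) {
    i <- sample.int(j, 1L)
    nd <- alive[i]
    age[nd] <- A[j]
    parent[nid + 1L] <- nd
    parent[nid + 2L] <- nd
    alive[i] <- nid + 1L
    alive[j + 1L] <- nid + 2L
    nid <- nid + 2L
  }
  list(parent = parent, age = age, tips = alive, g = g, crown = A[1L])
}

# Internal-node ages of the subtree induced by a tip subset: a node is a
# branching point of the induced tree iff both its children hold kept tips.
induced_ages <- function(sim, keep) {
  parent <- sim$parent
  has <- logical(length(parent))
  has[keep] <- TRUE
  npos <- integer(length(parent))
  for (id in seq.int(length(parent), 2L)) {
    if (has[id]) {
      p <- parent[id]
      npos[p] <- npos[p] + 1L
      has[p] <- TRUE
    }
  }
  sort(sim$age[npos == 2L], decreasing = TRUE)
}

# parent/age arrays -> ape phylo on the lineages ancestral to `tips`
build_phylo <- function(parent, age, tips, labels = NULL) {
  nn <- length(parent)
  has <- logical(nn)
  has[tips] <- TRUE
  npos <- integer(nn)
  for (id in seq.int(nn, 2L)) {
    if (has[id]) {
      p <- parent[id]
      npos[p] <- npos[p] + 1L
      has[p] <- TRUE
    }
  }
  kept_int <- which(npos >= 2L)
  n <- length(tips)
  stopifnot(length(kept_int) == n - 1L)
  newid <- integer(nn)
  newid[tips] <- seq_len(n)
  root <- kept_int[which.max(age[kept_int])]
  newid[root] <- n + 1L
  newid[setdiff(kept_int, root)] <- n + 1L + seq_len(n - 2L)
  edge <- matrix(0L, n + n - 2L, 2L)
  elen <- numeric(n + n - 2L)
  e <- 0L
  for (id in c(tips, setdiff(kept_int, root))) {
    anc <- parent[id]
    while (npos[anc] < 2L) anc <- parent[anc]   # skip pass-through nodes
    e <- e + 1L
    edge[e, ] <- c(newid[anc], newid[id])
    elen[e] <- age[anc] - (if (id %in% tips) 0 else age[id])
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = labels, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a birth-death chronogram conditioned on tip count
#'
#' Forward simulation from a crown pair of lineages with per-lineage birth
#' rate `birth` and death rate `death`. The process stops the first time the
#' number of extant lineages reaches `n_tips`; the present is placed a full
#' exponential waiting interval after that event (so that under pure birth
#' the internode durations follow the calibrated Yule construction). Extinct
#' lineages are pruned, leaving an ultrametric reconstructed tree.
#' Replicates that go extinct before reaching `n_tips` are retried.
#'
#' @param n_tips number of extant tips (`>= 3`).
#' @param birth per-lineage speciation rate (`> death`).
#' @param death per-lineage extinction rate (`>= 0`).
#' @param seed optional integer seed.
#' @param max_tries retries before giving up (extinction-prone settings).
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_bd_tree <- function(n_tips, birth = 1, death = 0, seed = NULL,
                             max_tries = 1000) {
  stopifnot(n_tips >= 3, birth > death, death >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (death == 0) {
    sim <- yule_sim_events(n_tips, birth)
    return(build_phylo(sim$parent, sim$age, sim$tips))
  }
  for (try in seq_len(max_tries)) {
    cap <- 64L
    parent <- integer(cap)
    btime <- numeric(cap)
    parent[2:3] <- 1L
    alive <- c(2L, 3L)
    nid <- 3L
    t <- 0
    t_pres <- NA_real_
    repeat {
      k <- length(alive)
      if (k == 0L) break
      w <- stats::rexp(1L, k * (birth + death))
      if (k == n_tips) {
        t_pres <- t + w
        break
      }
      t <- t + w
      i <- sample.int(k, 1L)
      nd <- alive[i]
      if (stats::runif(1L) < birth / (birth + death)) {
        if (nid + 2L > cap) {
          cap <- cap * 2L
          length(parent) <- cap
          length(btime) <- cap
        }
        parent[nid + 1L] <- nd
        parent[nid + 2L] <- nd
        btime[nd] <- t                # split (forward) time of nd
        alive[i] <- nid + 1L
        alive[length(alive) + 1L] <- nd <- nid + 2L
        nid <- nid + 1L + 1L
      } else {
        alive <- alive[-i]
      }
    }
    if (!is.na(t_pres)) {
      parent <- parent[seq_len(nid)]
      age <- t_pres - btime[seq_len(nid)]
      return(build_phylo(parent, age, alive))
    }
  }
  stop("birth-death simulation failed to reach n_tips in max_tries attempts")
}

#' Randomly prune a tree to a fixed number of tips
#'
#' Uniform sample of tips retained; the result stays ultrametric. The crown
#' age shrinks only when the sampled tips all fall on one side of the root.
#'
#' @param tree a `phylo`.
#' @param keep number of tips to retain (`3 <= keep <= Ntip`).
#' @param seed optional integer seed.
#' @return pruned `phylo`.
#' @export
prune_random <- function(tree, keep, seed = NULL) {
  n <- ape::Ntip(tree)
  if (keep < 3 || keep > n) stop("keep must be in [3, Ntip]")
  if (!is.null(seed)) set.seed(seed)
  if (keep == n) return(tree)
  ape::keep.tip(tree, sample(tree$tip.label, keep))
}

#' Simulate a trait with phylogenetic and spatial covariance components
#'
#' One multivariate-normal draw with mean 0 and covariance
#' \eqn{\sigma^2 [(1-w_s) V_\lambda + w_s S]}, where \eqn{V_\lambda} is the
#' unit-diagonal phylogenetic correlation of the tree with off-diagonals
#' scaled by `lambda` (see [phylo_correlation()]) and `S` a unit-diagonal
#' spatial similarity matrix. `w_s = 0` gives a pure (lambda-scaled)
#' Brownian trait, `w_s = 1` a purely spatially structured trait.
#'
#' @param tree a `phylo` chronogram.
#' @param sigma2 trait variance scale (per unit correlation).
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param S spatial similarity matrix over tips (ignored when `w_s = 0`).
#' @param w_s spatial mixing weight in `[0, 1]`.
#' @param seed optional integer seed.
#' @return named numeric vector over tips.
#' @export
simulate_trait <- function(tree, sigma2 = 1, lambda = 1, S = NULL,
                           w_s = 0, seed = NULL) {
  stopifnot(w_s >= 0, w_s <= 1, sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  V <- (1 - w_s) * phylo_correlation(tree, lambda)
  if (w_s > 0) {
    if (is.null(S)) stop("w_s > 0 requires a spatial similarity matrix S")
    S <- S[tree$tip.label, tree$tip.label]
    V <- V + w_s * S
  }
  n <- nrow(V)
  if (sigma2 == 0) return(stats::setNames(numeric(n), tree$tip.label))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    warning("covariance combination not PSD; adding jitter")
    V <- V + diag(1e-8 * max(ev), n)
  }
  x <- MASS::mvrnorm(1, mu = rep(0, n), Sigma = sigma2 * V,
                     tol = 1e-6)
  stats::setNames(as.numeric(x), tree$tip.label)
}

#' Simulate a gridded climate landscape
#'
#' Rectangular lon/lat grid with one value per cell per variable. Each
#' variable is a linear spatial gradient (along longitude, latitude, or flat)
#' plus an optional smooth random field (a sum of low-frequency cosine
#' components), rescaled to the requested range.
#'
#' @param grid_n cells per side (`>= 10`).
#' @param variables a data frame with columns `name`, `min`, `max`,
#'   `direction` (one of `"+lon"`, `"-lon"`, `"+lat"`, `"-lat"`, `"flat"`)
#'   and `noise_sd` (smooth-noise standard deviation, in value units).
#' @param lon_range,lat_range grid extent in decimal degrees.
#' @param seed optional integer seed.
#' @return data frame `lon`, `lat`, one column per variable; `resolution`
#'   attribute in degrees.
#' @export
simulate_landscape <- function(grid_n = 40,
                               variables = data.frame(
                                 name = c("SPP", "CTRL"),
                                 min = c(50, 100), max = c(600, 200),
                                 direction = c("-lon", "flat"),
                                 noise_sd = c(0, 25)),
                               lon_range = c(16, 30),
                               lat_range = c(-35, -28), seed = NULL) {
  stopifnot(grid_n >= 10)
  if (!is.null(seed)) set.seed(seed)
  lon <- seq(lon_range[1], lon_range[2], length.out = grid_n)
  lat <- seq(lat_range[1], lat_range[2], length.out = grid_n)
  grid <- expand.grid(lon = lon, lat = lat)
  u <- (grid$lon - lon_range[1]) / diff(lon_range)
  v <- (grid$lat - lat_range[1]) / diff(lat_range)
  for (i in seq_len(nrow(variables))) {
    base <- switch(variables$direction[i],
                   "+lon" = u, "-lon" = 1 - u,
                   "+lat" = v, "-lat" = 1 - v,
                   "flat" = rep(0.5, nrow(grid)),
                   stop("unknown direction ", variables$direction[i]))
    val <- variables$min[i] + base * (variables$max[i] - variables$min[i])
    if (variables$noise_sd[i] > 0)
      val <- val + variables$noise_sd[i] * smooth_field(u, v)
    grid[[variables$name[i]]] <- val
  }
  attr(grid, "resolution") <- diff(lon)[1]
  grid
}

# smooth unit-variance random field: sum of random low-frequency cosines
smooth_field <- function(u, v, n_comp = 8) {
  z <- numeric(length(u))
  for (i in seq_len(n_comp)) {
    f <- stats::runif(2, 0.5, 3)
    phi <- stats::runif(1, 0, 2 * pi)
    z <- z + cos(2 * pi * (f[1] * u + f[2] * v) + phi)
  }
  z / stats::sd(z)
}

#' Sample species occurrences from Gaussian climate suitability
#'
#' Grid cells are sampled (with replacement) with probability proportional
#' to a Gaussian suitability surface around each species' climate optimum:
#' `exp(-0.5 * sum_v ((value_v - optimum_v) / breadth_v)^2)`. Records carry
#' the sampled cell's coordinates and climate values.
#'
#' @param grid landscape as from [simulate_landscape()].
#' @param optima data frame: column `species` plus one column per climate
#'   variable holding that species' optimum (omit a variable for no
#'   preference on it).
#' @param breadth niche breadth: single number or named vector per variable
#'   (same units as the variable).
#' @param n_points occurrences per species (scalar or per-species vector).
#' @param seed optional integer seed.
#' @return occurrence data frame `species`, `lon`, `lat`, climate columns.
#' @export
simulate_occurrences <- function(grid, optima, breadth, n_points = 50,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- setdiff(names(optima), "species")
  stopifnot(all(vars %in% names(grid)))
  if (is.null(names(breadth))) breadth <- stats::setNames(
    rep(breadth, length.out = length(vars)), vars)
  n_points <- rep(n_points, length.out = nrow(optima))
  gvars <- setdiff(names(grid), c("lon", "lat"))
  out <- vector("list", nrow(optima))
  for (i in seq_len(nrow(optima))) {
    d2 <- 0
    for (v in vars)
      d2 <- d2 + ((grid[[v]] - optima[[v]][i]) / breadth[[v]])^2
    suit <- exp(-0.5 * d2)
    if (sum(suit) < 1e-12)
      stop("suitability mass ~ 0 for species ", optima$species[i],
           " (optimum outside the landscape range?)")
    cells <- sample.int(nrow(grid), n_points[i], replace = TRUE,
                        prob = suit)
    out[[i]] <- cbind(data.frame(species = optima$species[i]),
                      grid[cells, c("lon", "lat", gvars), drop = FALSE])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundled "radiating clade" scenario
#'
#' A complete synthetic study system reproducing the structure the pipeline
#' targets: a pure-birth clade whose species partition a monotone summer
#' precipitation (SPP) gradient, versus a gradient-free control variable
#' (CTRL) on which all species share climate preferences. Species optima for
#' SPP are evenly spaced along the gradient (so species climate means are
#' spatially structured); CTRL optima are small random perturbations around
#' a common value (no spatial or phylogenetic structure).
#'
#' @param n_species number of species.
#' @param n_points occurrences per species.
#' @param grid_n landscape cells per side.
#' @param seed integer seed.
#' @return list: `tree`, `grid`, `occ` (occurrences with climate values),
#'   `clades` (single-clade table covering all species), `optima`,
#'   `config` (the generating parameters).
#' @export
radiating_clade_scenario <- function(n_species = 16, n_points = 60,
                                     grid_n = 40, seed = 1) {
  set.seed(seed)
  tree <- simulate_bd_tree(n_species, birth = 1, death = 0)
  depth <- tree_depth(tree)
  tree$edge.length <- tree$edge.length * (10 / depth)  # 10 MY crown age
  grid <- simulate_landscape(grid_n = grid_n)
  spp_opt <- seq(100, 550, length.out = n_species)
  ctrl_opt <- 150 + stats::rnorm(n_species, 0, 15)
  optima <- data.frame(species = tree$tip.label,
                       SPP = spp_opt, CTRL = ctrl_opt)
  occ <- simulate_occurrences(grid, optima,
                              breadth = c(SPP = 40, CTRL = 30),
                              n_points = n_points)
  clades <- data.frame(clade = "R1", crown_age = 10,
                       total_richness = n_species)
  clades$tips <- list(tree$tip.label)
  list(tree = tree, grid = grid, occ = occ, clades = clades,
       optima = optima,
       config = list(n_species = n_species, n_points = n_points,
                     grid_n = grid_n, seed = seed,
                     breadth = c(SPP = 40, CTRL = 30)))
}
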