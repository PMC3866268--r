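#' Species occurrence centroids
#'
#' @param occ occurrence data frame (`species`, `lon`, `lat`).
#' @return data frame `species`, `lon`, `lat` (mean coordinates).
#' @export
species_centroids <- function(occ) {
  sp <- sort(unique(occ$species))
  data.frame(species = sp,
             lon = vapply(sp, function(s) mean(occ$lon[occ$species == s]),
                          numeric(1)),
             lat = vapply(sp, function(s) mean(occ$lat[occ$species == s]),
                          numeric(1)))
}

#' Spatial similarity matrix from species centroids
#'
#' Linear decay of great-circle distance:
#' \eqn{s_{ij} = 1 - d_{ij} / d_{max}} with unit diagonal, so that the most
#' distant pair has similarity 0 and coincident species 1. With the linear
#' kernel, the matrix is a valid unit-diagonal similarity that can be mixed
#' convexly with a phylogenetic correlation. An exponential kernel
#' \eqn{s_{ij} = \exp(-d_{ij}/range)} is available as an alternative.
#'
#' @param centroids data frame `species`, `lon`, `lat` (see
#'   [species_centroids()]), or a named matrix of coordinates.
#' @param kernel `"linear"` (default) or `"exponential"`.
#' @param range decay range in km for the exponential kernel (default: the
#'   maximum pairwise distance / 3).
#' @return symmetric similarity matrix with species names, class
#'   `spatial_similarity` attributes recording provenance.
#' @export
spatial_similarity <- function(centroids, kernel = c("linear", "exponential"),
                               range = NULL) {
  kernel <- match.arg(kernel)
  if (nrow(centroids) < 2) stop("need at least 2 species")
  if (any(!is.finite(centroids$lon)) || any(!is.finite(centroids$lat)))
    stop("non-finite centroid coordinates")
  n <- nrow(centroids)
  D <- matrix(0, n, n, dimnames = list(centroids$species, centroids$species))
  for (i in seq_len(n - 1)) {
    d <- gc_dist(centroids$lon[i], centroids$lat[i],
                 centroids$lon[(i + 1):n], centroids$lat[(i + 1):n])
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  dmax <- max(D)
  if (dmax <= 0)
    stop("all species share one location; spatial similarity is degenerate")
  S <- if (kernel == "linear") 1 - D / dmax else {
    if (is.null(range)) range <- dmax / 3
    exp(-D / range)
  }
  diag(S) <- 1
  attr(S, "kernel") <- kernel
  attr(S, "d_max_km") <- dmax
  S
}

# profiled GLS log-likelihood of trait y ~ N(mu 1, sigma2 V)
gls_profile <- function(y, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), n)),
                   error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    warning("near-singular covariance; 1e-8 jitter applied")
  }
  ldet <- 2 * sum(log(diag(ch)))
  Li1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  Liy <- backsolve(ch, y, transpose = TRUE)
  mu <- sum(Li1 * Liy) / sum(Li1^2)
  q <- sum((Liy - mu * Li1)^2)
  sigma2 <- q / n
  if (sigma2 <= 0) return(NULL)
  list(mu = mu, sigma2 = sigma2,
       lnL = -0.5 * (n * log(2 * pi * sigma2) + ldet + n))
}

#' Joint spatial-phylogenetic signal decomposition of a trait
#'
#' Maximum-likelihood fit of the model in which a species trait is
#' multivariate normal with mean \eqn{\mu} and covariance
#' \eqn{\sigma^2 [(1-\phi) V_\lambda + \phi S]}: \eqn{V_\lambda} is the
#' phylogenetic correlation with off-diagonals scaled by Pagel's
#' \eqn{\lambda}, `S` a unit-diagonal spatial similarity, and \eqn{\phi}
#' weighs space against phylogeny (0 = only phylogeny matters, 1 = only
#' space). \eqn{\mu} and \eqn{\sigma^2} are profiled analytically by
#' generalized least squares; \eqn{(\lambda, \phi)} are optimized on
#' \eqn{[0,1]^2} by an 11 x 11 grid search followed by bounded local
#' refinement. Reported alongside are the space-corrected phylogenetic
#' signal \eqn{\lambda' = (1-\phi)\lambda} and the independent fraction
#' \eqn{\Gamma = (1-\phi)(1-\lambda)}, which satisfy
#' \eqn{\lambda' + \Gamma + \phi = 1}.
#'
#' @param tree a `phylo` chronogram.
#' @param S spatial similarity matrix over the tree's tips (see
#'   [spatial_similarity()]). `NULL` collapses the model to the standard
#'   Pagel-lambda fit (`phi` fixed at 0).
#' @param trait named per-tip numeric vector.
#' @param grid_n grid points per axis for the initial search.
#' @return object of class `space_phylo_fit`: `lambda`, `phi`, `sigma2`,
#'   `mu`, `lambda_prime`, `gamma_indep`, `lnL`, `boundary` (which of
#'   lambda/phi sit on a bound).
#' @export
fit_space_phylo <- function(tree, S, trait, grid_n = 11) {
  tree <- validate_chronogram(tree, strict = FALSE)
  if (is.null(names(trait))) stop("trait must be named by tip label")
  y <- trait[tree$tip.label]
  if (any(is.na(y))) stop("trait does not cover all tips")
  C <- phylo_correlation(tree, 1)
  use_space <- !is.null(S)
  if (use_space) {
    if (!all(tree$tip.label %in% rownames(S)))
      stop("S does not cover all tips")
    S <- S[tree$tip.label, tree$tip.label]
  }
  off <- row(C) != col(C)
  obj <- function(lambda, phi) {
    Vl <- C
    Vl[off] <- Vl[off] * lambda
    V <- if (use_space) (1 - phi) * Vl + phi * S else Vl
    p <- gls_profile(y, V)
    if (is.null(p)) -Inf else p$lnL
  }
  gr <- seq(0, 1, length.out = grid_n)
  phis <- if (use_space) gr else 0
  grid_lnL <- outer(gr, phis, Vectorize(function(l, p) obj(l, p)))
  i <- which(grid_lnL == max(grid_lnL), arr.ind = TRUE)[1, ]
  start <- c(gr[i[1]], phis[i[2]])
  if (use_space) {
    opt <- stats::optim(start, function(p) -obj(p[1], p[2]),
                        method = "L-BFGS-B", lower = c(0, 0),
                        upper = c(1, 1),
                        control = list(factr = 1e4))
    lambda <- opt$par[1]; phi <- opt$par[2]
    lnL <- -opt$value
  } else {
    opt <- stats::optimize(function(l) obj(l, 0), c(0, 1), maximum = TRUE,
                           tol = 1e-8)
    # optimize() can miss a boundary maximum; keep the best of all candidates
    cand <- c(opt$maximum, 0, 1, start[1])
    lnLs <- vapply(cand, function(l) obj(l, 0), numeric(1))
    lambda <- cand[which.max(lnLs)]
    phi <- 0
    lnL <- max(lnLs)
  }
  Vl <- C
  Vl[off] <- Vl[off] * lambda
  V <- if (use_space) (1 - phi) * Vl + phi * S else Vl
  p <- gls_profile(y, V)
  boundary <- c(lambda = lambda <= 1e-8 || lambda >= 1 - 1e-8,
                phi = use_space && (phi <= 1e-8 || phi >= 1 - 1e-8))
  structure(list(lambda = lambda, phi = phi, sigma2 = p$sigma2, mu = p$mu,
                 lambda_prime = (1 - phi) * lambda,
                 gamma_indep = (1 - phi) * (1 - lambda),
                 lnL = lnL, n = length(y), boundary = boundary,
                 spatial = use_space),
            class = "space_phylo_fit")
}

#' @export
print.space_phylo_fit <- function(x, ...) {
  cat(sprintf(paste0("space-vs-phylogeny fit (n = %d): lambda = %.3f, ",
                     "phi = %.3f\n  lambda' = %.3f, Gamma = %.3f, ",
                     "sigma2 = %.4g, lnL = %.3f\n"),
              x$n, x$lambda, x$phi, x$lambda_prime, x$gamma_indep,
              x$sigma2, x$lnL))
  if (any(x$boundary))
    cat("  note: ", paste(names(x$boundary)[x$boundary], collapse = ", "),
        " at a [0,1] bound\n", sep = "")
  invisible(x)
}

#' Signal decomposition for every clade and climate variable
#'
#' Runs [fit_space_phylo()] on species mean climate values per clade, with
#' the spatial similarity built from that clade's occurrence centroids.
#'
#' @inheritParams felsen_table
#' @param kernel passed to [spatial_similarity()].
#' @return long data frame: `clade`, `variable`, `lambda`, `phi`,
#'   `lambda_prime`, `gamma_indep`, `sigma2`, `lnL`, `n_species`.
#' @export
signal_decomposition <- function(tree, occ, clades, variables = NULL,
                                 kernel = "linear") {
  means <- species_climate_means(occ, variables)
  variables <- setdiff(names(means), "species")
  cents <- species_centroids(occ)
  rows <- list()
  for (i in seq_len(nrow(clades))) {
    tips <- intersect(clades$tips[[i]], means$species)
    if (length(tips) < 4) {
      warning("clade ", clades$clade[i],
              " has fewer than 4 usable species; skipped")
      next
    }
    sub <- ape::keep.tip(tree, tips)
    S <- spatial_similarity(cents[match(tips, cents$species), ],
                            kernel = kernel)
    m <- means[match(tips, means$species), ]
    for (v in variables) {
      f <- fit_space_phylo(sub, S, stats::setNames(m[[v]], m$species))
      rows[[length(rows) + 1L]] <-
        data.frame(clade = clades$clade[i], variable = v,
                   lambda = f$lambda, phi = f$phi,
                   lambda_prime = f$lambda_prime,
                   gamma_indep = f$gamma_indep, sigma2 = f$sigma2,
                   lnL = f$lnL, n_species = length(tips))
    }
  }
  do.call(rbind, rows)
}
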