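#' Read a time-calibrated (ultrametric) tree from Newick
#'
#' Parses a Newick string or file into an [ape::phylo] chronogram and
#' validates it: branch lengths must be present and non-negative, tip labels
#' unique, and root-to-tip path lengths equal within a relative tolerance
#' (chronograms produced by rate smoothing are only numerically ultrametric).
#' Polytomies are accepted and resolved into zero-length bifurcations (the
#' gamma statistic and independent contrasts require binary trees); a warning
#' reports how many were resolved.
#'
#' @param text Newick string (mutually exclusive with `file`).
#' @param file path to a Newick file.
#' @param strict if `TRUE` (default) a non-ultrametric tree is an error;
#'   if `FALSE` it is accepted with a warning.
#' @param tol relative ultrametricity tolerance, as a fraction of tree depth.
#' @return an object of class `phylo`, binary, with node ages retrievable via
#'   [node_ages()].
#' @export
read_newick <- function(text = NULL, file = NULL, strict = TRUE, tol = 1e-6) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- if (!is.null(text)) ape::read.tree(text = text) else
    ape::read.tree(file = file)
  if (is.null(tree)) stop("Newick parse failure")
  validate_chronogram(tree, strict = strict, tol = tol)
}

#' Validate and normalize a chronogram
#'
#' @param tree a `phylo` object.
#' @inheritParams read_newick
#' @return the validated (binary) tree.
#' @export
validate_chronogram <- function(tree, strict = TRUE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels")
  if (!ape::is.binary(tree)) {
    n_poly <- tree$Nnode
    tree <- ape::multi2di(tree, random = FALSE)
    warning(sprintf("resolved polytomies into %d zero-length bifurcations",
                    tree$Nnode - n_poly))
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(depths)
  if (depth <= 0) stop("tree has zero depth")
  if (diff(range(depths)) > tol * depth) {
    msg <- sprintf("tree is not ultrametric (tip depth spread %.3g of depth)",
                   diff(range(depths)) / depth)
    if (strict) stop(msg) else warning(msg)
  }
  tree
}

#' Node ages of a chronogram
#'
#' Ages (time before present, in the tree's branch-length units, typically MY)
#' for every node: tips first (age ~ 0), then internal nodes in `phylo`
#' numbering order. Tip depths are averaged out so that ages of a numerically
#' near-ultrametric tree are exact at the tips.
#'
#' @param tree a `phylo` chronogram.
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

#' Tree depth (crown age) in branch-length units
#' @param tree a `phylo` chronogram.
#' @export
tree_depth <- function(tree) max(ape::node.depth.edgelength(tree))

#' Branching times of a clade
#'
#' Extracts the most-recent-common-ancestor subtree of `clade` (all tips by
#' default) and returns its internal-node ages in descending order, together
#' with the internode durations \eqn{g_k} (the time during which exactly
#' \eqn{k} lineages existed, for \eqn{k = 2..n}; \eqn{g_n} runs to the
#' present) and the lineage-time total \eqn{T = \sum_k k g_k} that the gamma
#' statistic and the pure-birth likelihood are built on.
#'
#' @param tree a `phylo` chronogram.
#' @param clade character vector of tip labels, or `NULL` for the whole tree.
#' @return an object of class `branching_times`: list with `ages` (descending,
#'   first element the crown age), `n_tips`, `g` (named `g2..gn`), and `T`.
#' @export
branching_times <- function(tree, clade = NULL) {
  tree <- validate_chronogram(tree, strict = FALSE)
  if (!is.null(clade)) {
    unknown <- setdiff(clade, tree$tip.label)
    if (length(unknown))
      stop("unknown tips: ", paste(unknown, collapse = ", "))
    if (length(clade) < 2) stop("clade must contain at least 2 tips")
    if (length(clade) < ape::Ntip(tree)) {
      mrca <- ape::getMRCA(tree, clade)
      tree <- ape::extract.clade(tree, mrca)
    }
  }
  ages <- sort(node_ages(tree)[ape::Ntip(tree) + seq_len(tree$Nnode)],
               decreasing = TRUE)
  new_branching_times(ages)
}

#' Construct branching times directly from node ages
#'
#' @param ages positive node ages, any order; the maximum is the crown age.
#' @return a `branching_times` object (see [branching_times()]).
#' @export
new_branching_times <- function(ages) {
  ages <- sort(as.numeric(ages), decreasing = TRUE)
  if (any(ages < 0)) stop("negative node age")
  n <- length(ages) + 1L
  # g_k = duration with k lineages; g_n measured down to the present
  g <- c(-diff(ages), ages[n - 1L])
  names(g) <- paste0("g", 2:n)
  structure(list(ages = ages, n_tips = n, g = g,
                 T = sum((2:n) * g)),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("Branching times: %d tips, crown age %.4g, lineage-time T = %.4g\n",
              x$n_tips, x$ages[1], x$T))
  invisible(x)
}

#' Lineage-through-time plot of a set of branching times
#' @param x a `branching_times` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.branching_times <- function(x, ...) {
  n <- x$n_tips
  graphics::plot(c(-x$ages, 0), c(2:n, n), type = "s", log = "y",
                 xlab = "time before present", ylab = "lineages", ...)
  invisible(x)
}

#' Phylogenetic correlation matrix under Pagel's lambda
#'
#' Shared-path-length matrix of an ultrametric tree divided by tree depth
#' (unit diagonal), with off-diagonal entries multiplied by `lambda`.
#' `lambda = 0` gives the identity (no phylogenetic signal); `lambda = 1`
#' gives the Brownian-motion correlation structure.
#'
#' @param tree a `phylo` chronogram.
#' @param lambda signal multiplier in `[0, 1]`.
#' @return a symmetric correlation matrix with rows/columns named by tip.
#' @export
phylo_correlation <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  V <- ape::vcv.phylo(tree)
  C <- V / max(diag(V))
  off <- row(C) != col(C)
  C[off] <- C[off] * lambda
  diag(C) <- 1
  C
}

#' Great-circle distance (km) by the spherical law of cosines
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (WGS-84 assumed).
#' @return distance in km (mean Earth radius 6371 km). Vectorized.
#' @export
gc_dist <- function(lon1, lat1, lon2, lat2) {
  geosphere::distCosine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Remove outlier occurrences per species
#'
#' For each species with at least 3 records, computes great-circle distances
#' to the species' median center (component-wise median of longitude and
#' latitude) and removes records whose distance exceeds
#' `median(d) + k * mad(d)` (raw median absolute deviation, no consistency
#' constant). Species with fewer than 3 records pass through untouched.
#'
#' @param occ occurrence data frame with columns `species`, `lon`, `lat` and
#'   optionally climate variables.
#' @param k robustness multiplier (default 5).
#' @return the cleaned data frame, with a `removed` attribute holding the
#'   report of removed records (`species`, `lon`, `lat`, `dist_km`,
#'   `threshold_km`).
#' @export
clean_outliers <- function(occ, k = 5) {
  stopifnot(all(c("species", "lon", "lat") %in% names(occ)), k > 0)
  drop <- logical(nrow(occ))
  rep_list <- list()
  for (sp in unique(occ$species)) {
    idx <- which(occ$species == sp)
    if (length(idx) < 3) next
    d <- gc_dist(occ$lon[idx], occ$lat[idx],
                 stats::median(occ$lon[idx]), stats::median(occ$lat[idx]))
    thr <- stats::median(d) + k * stats::mad(d, constant = 1)
    out <- d > thr
    if (any(out)) {
      drop[idx[out]] <- TRUE
      rep_list[[sp]] <- data.frame(species = sp,
                                   lon = occ$lon[idx[out]],
                                   lat = occ$lat[idx[out]],
                                   dist_km = d[out], threshold_km = thr)
    }
  }
  res <- occ[!drop, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "removed") <- if (length(rep_list))
    do.call(rbind, c(rep_list, make.row.names = FALSE)) else
    data.frame(species = character(), lon = numeric(), lat = numeric(),
               dist_km = numeric(), threshold_km = numeric())
  res
}

#' Read an occurrence table
#'
#' Expected columns: `species`, `lon`, `lat`, then zero or more climate
#' variables (one column each). Climate values must be finite where present.
#'
#' @param file delimited text file (comma-separated by default).
#' @param sep field separator.
#' @return a data frame.
#' @export
read_occurrences <- function(file, sep = ",") {
  occ <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(occ)))
    stop("occurrence file must have columns species, lon, lat")
  vars <- setdiff(names(occ), need)
  for (v in vars)
    if (any(!is.finite(occ[[v]])))
      stop("non-finite values in climate column ", v)
  occ
}

#' Read a clade-definition table
#'
#' Columns: `clade`, `tips` (tip labels joined by `;`), `crown_age` (MY),
#' `total_richness` (total known species, for sampling-corrected analyses).
#'
#' @param file CSV path.
#' @return data frame with a list-column `tips`.
#' @export
read_clades <- function(file) {
  cl <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("clade", "tips", "crown_age", "total_richness")
  if (!all(need %in% names(cl)))
    stop("clade file must have columns ", paste(need, collapse = ", "))
  cl$tips <- strsplit(cl$tips, ";", fixed = TRUE)
  cl
}

#' Read a gridded climate layer set
#'
#' Accepts either a CSV with columns `lon`, `lat`, then one column per
#' variable, or a single-variable ESRI ASCII grid (`.asc`), which is
#' converted to the same long format with the variable named by `var`.
#'
#' @param file path.
#' @param var variable name used for ASCII grids.
#' @return data frame `lon`, `lat`, variables; attribute `resolution` in
#'   degrees.
#' @export
read_climate_grid <- function(file, var = "value") {
  first <- readLines(file, n = 1)
  if (grepl("^\\s*ncols", tolower(first))) {
    grid <- read_esri_ascii(file, var)
  } else {
    grid <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("lon", "lat") %in% names(grid)))
      stop("climate grid CSV must have lon and lat columns")
  }
  if (anyDuplicated(grid[c("lon", "lat")])) stop("duplicated grid cells")
  vars <- setdiff(names(grid), c("lon", "lat"))
  for (v in vars)
    if (any(!is.finite(grid[[v]]))) stop("non-finite values in ", v)
  lons <- sort(unique(grid$lon))
  attr(grid, "resolution") <- if (length(lons) > 1) min(diff(lons)) else NA_real_
  grid
}

# ESRI ASCII raster -> long data frame (cell centers); NODATA cells dropped.
read_esri_ascii <- function(file, var) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1
  while (grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  ncols <- hdr$ncols; nrows <- hdr$nrows; cs <- hdr$cellsize
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner + cs / 2 else hdr$xllcenter
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner + cs / 2 else hdr$yllcenter
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows) stop("ASCII grid size mismatch")
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  # rows of m run top (max lat) to bottom; expand.grid varies lon fastest
  grid <- expand.grid(lon = x0 + (0:(ncols - 1)) * cs,
                      lat = y0 + ((nrows - 1):0) * cs)
  out <- data.frame(lon = grid$lon, lat = grid$lat, v = as.vector(t(m)))
  names(out)[3] <- var
  out <- out[out[[var]] != nodata, ]
  rownames(out) <- NULL
  out
}
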