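#' Species mean climate values
#'
#' Arithmetic mean per species per climate variable, from cleaned
#' occurrences.
#'
#' @param occ occurrence data frame (`species`, `lon`, `lat`, variables).
#' @param variables variables to average; default all non-coordinate
#'   columns.
#' @return data frame: one row per species, one column per variable.
#' @export
species_climate_means <- function(occ, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(names(occ), c("species", "lon", "lat"))
  if (!length(variables)) stop("no climate variables in occurrence table")
  sp <- sort(unique(occ$species))
  out <- data.frame(species = sp)
  for (v in variables)
    out[[v]] <- vapply(sp, function(s) mean(occ[[v]][occ$species == s]),
                       numeric(1))
  out
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts by Felsenstein's pruning algorithm: at each
#' internal node the difference of the two descendant values divided by the
#' square root of the sum of their (adjusted) branch lengths, with ancestral
#' values formed as branch-length-weighted averages and the ancestral branch
#' extended by `v_l * v_r / (v_l + v_r)`. Computed via [ape::pic()];
#' polytomies are resolved into zero-length bifurcations first.
#'
#' @param tree a `phylo` chronogram.
#' @param trait named numeric vector over the tips (every tip valued).
#' @return numeric vector of `Ntip - 1` standardized contrasts.
#' @export
independent_contrasts <- function(tree, trait) {
  tree <- validate_chronogram(tree, strict = FALSE)
  if (is.null(names(trait))) {
    if (length(trait) != ape::Ntip(tree))
      stop("trait length does not match tip count")
    names(trait) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop("missing trait values for: ", paste(missing, collapse = ", "))
  if (any(!is.finite(trait))) stop("non-finite trait values")
  ape::pic(trait[tree$tip.label], tree)
}

#' Brownian-motion rate in felsens
#'
#' The felsen is the Brownian rate unit of a natural-log-transformed trait:
#' one unit of ln-trait variance accumulated per million years. Estimated as
#' the variance of the standardized independent contrasts of
#' `ln(raw_trait)`, with branch lengths in MY:
#' \eqn{\beta = \frac{1}{n-1}\sum_i c_i^2} (divisor = number of contrasts).
#' Because contrasts are differences of logs, the estimate is exactly
#' invariant to multiplying the raw trait by any positive constant.
#'
#' @param tree a `phylo` chronogram (branch lengths in MY).
#' @param raw_trait named positive per-tip values (e.g. species mean of a
#'   climate variable). Zeros are only allowed with a positive `offset`.
#' @param offset optional shift: the log transform becomes
#'   `log(x + offset)` (for variables with legitimate zeros, e.g. zero
#'   summer precipitation); a message reports when it is engaged.
#' @param divisor `"contrasts"` (n-1, default) or `"ml"` (n).
#' @return the rate `beta` (felsens), with attributes `n_contrasts` and
#'   `contrasts`.
#' @export
felsen_rate <- function(tree, raw_trait, offset = 0,
                        divisor = c("contrasts", "ml")) {
  divisor <- match.arg(divisor)
  if (any(raw_trait + offset <= 0))
    stop("raw trait must be positive on the log scale; ",
         "use `offset` for variables with zeros")
  if (offset > 0 && any(raw_trait <= 0))
    message("log offset engaged: trait transformed as log(x + ", offset, ")")
  cc <- independent_contrasts(tree, log(raw_trait + offset))
  n <- length(cc) + 1L
  beta <- sum(cc^2) / if (divisor == "contrasts") (n - 1) else n
  structure(beta, n_contrasts = length(cc), contrasts = cc)
}

#' Felsen rates per clade and climate variable
#'
#' @param tree chronogram containing all clade tips.
#' @param occ cleaned occurrences with climate columns.
#' @param clades clade table (with `tips` list-column) as from
#'   [read_clades()].
#' @param variables climate variables; default all present.
#' @param offset log offset passed to [felsen_rate()].
#' @return long data frame: `clade`, `variable`, `beta`, `n_species`.
#' @export
felsen_table <- function(tree, occ, clades, variables = NULL, offset = 0) {
  means <- species_climate_means(occ, variables)
  variables <- setdiff(names(means), "species")
  rows <- list()
  for (i in seq_len(nrow(clades))) {
    tips <- intersect(clades$tips[[i]], means$species)
    if (length(tips) < 3) {
      warning("clade ", clades$clade[i], " has fewer than 3 species with ",
              "climate data; skipped")
      next
    }
    sub <- ape::keep.tip(tree, tips)
    m <- means[match(sub$tip.label, means$species), ]
    for (v in variables) {
      b <- felsen_rate(sub, stats::setNames(m[[v]], m$species),
                       offset = offset)
      rows[[length(rows) + 1L]] <-
        data.frame(clade = clades$clade[i], variable = v,
                   beta = as.numeric(b), n_species = length(tips))
    }
  }
  do.call(rbind, rows)
}
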