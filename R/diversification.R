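#' Magallon-Sanderson net diversification rate
#'
#' Method-of-moments estimator of the net diversification rate
#' \eqn{r = \lambda - \mu} (speciation events per MY) from a clade's standing
#' richness `N` and age `t`, under an assumed extinction fraction
#' \eqn{\epsilon = \mu/\lambda}. The crown estimator is
#' \deqn{r = t^{-1} \{\ln[ N(1-\epsilon^2)/2 + 2\epsilon +
#'   \tfrac{1-\epsilon}{2}\sqrt{N(N\epsilon^2 - 8\epsilon + 2N\epsilon + N)}]
#'   - \ln 2\}}
#' which reduces to \eqn{\ln(N/2)/t} at \eqn{\epsilon = 0}; the stem
#' estimator is \eqn{r = \ln[N(1-\epsilon) + \epsilon]/t}, reducing to
#' \eqn{\ln(N)/t}. A nonpositive estimate is truncated to 0.
#'
#' @param N standing species richness (integer; crown mode needs `N >= 2`).
#' @param t clade age in MY (crown or stem age to match `mode`).
#' @param eps extinction fraction(s) in `[0, 1)`; vectorized.
#' @param mode `"crown"` (default: richness pairs with crown ages) or
#'   `"stem"`.
#' @return numeric vector of rates, one per `eps`.
#' @export
ms_rate <- function(N, t, eps = 0, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  if (any(eps < 0 | eps >= 1)) stop("eps must be in [0, 1)")
  if (t <= 0) stop("t must be positive")
  if (N != round(N) || N < 1) stop("N must be a positive integer")
  if (mode == "crown" && N < 2) stop("crown mode requires N >= 2")
  r <- if (mode == "stem") {
    log(N * (1 - eps) + eps) / t
  } else {
    inner <- N * (1 - eps^2) / 2 + 2 * eps +
      (1 - eps) / 2 * sqrt(N * (N * eps^2 - 8 * eps + 2 * N * eps + N))
    (log(inner) - log(2)) / t
  }
  pmax(r, 0)
}

#' Per-clade diversification-rate table
#'
#' @param clades clade table as from [read_clades()]: columns `clade`,
#'   `crown_age`, `total_richness`.
#' @param eps extinction fractions, default `c(0, 0.5, 0.99)`.
#' @param mode passed to [ms_rate()].
#' @return data frame with one rate column per extinction fraction
#'   (`r_0`, `r_0.5`, ...), plus the inputs used.
#' @export
ms_rate_table <- function(clades, eps = c(0, 0.5, 0.99),
                          mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  rates <- t(mapply(function(N, t) ms_rate(N, t, eps, mode),
                    clades$total_richness, clades$crown_age))
  rates <- matrix(rates, nrow = nrow(clades))
  colnames(rates) <- paste0("r_", eps)
  cbind(data.frame(clade = clades$clade, N = clades$total_richness,
                   t = clades$crown_age, mode = mode), rates)
}

# gamma from internode durations g_k (k = 2..n); closed form
gamma_from_g <- function(g) {
  n <- length(g) + 1L
  kg <- (2:n) * g
  T <- sum(kg)
  cum <- cumsum(kg)
  (mean(cum[seq_len(n - 2L)]) - T / 2) / (T * sqrt(1 / (12 * (n - 2L))))
}

#' Gamma statistic for diversification slowdown
#'
#' Standardized summary of internode spacing: negative values indicate
#' branching events concentrated early in the clade's history (a slowdown in
#' diversification); under constant-rate pure birth the statistic is
#' asymptotically standard normal. The one-tailed p-value is the lower
#' normal tail \eqn{P(Z \le \gamma)}.
#'
#' @param bt a [branching_times] object (needs `n_tips >= 3`).
#' @return object of class `gamma_test`: `gamma`, `n_tips`, `p_value`.
#' @export
gamma_statistic <- function(bt) {
  stopifnot(inherits(bt, "branching_times"))
  if (bt$n_tips < 3) stop("gamma requires at least 3 tips")
  g <- gamma_from_g(bt$g)
  structure(list(gamma = g, n_tips = bt$n_tips,
                 p_value = stats::pnorm(g)),
            class = "gamma_test")
}

#' @export
print.gamma_test <- function(x, ...) {
  cat(sprintf("gamma = %.4f (n = %d tips), one-tailed P = %.4g\n",
              x$gamma, x$n_tips, x$p_value))
  invisible(x)
}

#' Monte Carlo constant-rates (MCCR) test
#'
#' Corrects the gamma test for incomplete taxon sampling. For each replicate
#' a complete pure-birth phylogeny with `N_total` tips is simulated, pruned
#' uniformly at random to `n_sampled` tips, and its gamma computed; the
#' critical value is the 5th percentile of the null distribution and the
#' corrected p-value is `(1 + #{gamma_null <= observed}) / (1 + reps)`.
#'
#' @param obs_gamma observed gamma of the sampled clade.
#' @param N_total total (true) clade richness.
#' @param n_sampled number of tips actually sampled (`>= 3`).
#' @param reps number of null simulations (default 10000).
#' @param seed integer seed for reproducibility.
#' @param alpha tail probability defining the critical value.
#' @return object of class `mccr_test`: observed and critical gamma,
#'   corrected and analytic p-values, the null distribution, inputs.
#' @export
mccr_test <- function(obs_gamma, N_total, n_sampled, reps = 10000,
                      seed = NULL, alpha = 0.05) {
  if (inherits(obs_gamma, "gamma_test")) obs_gamma <- obs_gamma$gamma
  if (n_sampled < 3) stop("n_sampled must be >= 3")
  if (n_sampled > N_total) stop("n_sampled cannot exceed N_total")
  if (!is.null(seed)) set.seed(seed)
  full <- n_sampled == N_total
  null_gamma <- vapply(seq_len(reps), function(i) {
    if (full) {
      gamma_from_g(stats::rexp(N_total - 1L, rate = 2:N_total))
    } else {
      sim <- yule_sim_events(N_total)
      keep <- sample(sim$tips, n_sampled)
      gamma_from_g(ages_to_g(induced_ages(sim, keep)))
    }
  }, numeric(1))
  crit <- unname(stats::quantile(null_gamma, alpha))
  p <- (1 + sum(null_gamma <= obs_gamma)) / (1 + reps)
  structure(list(obs_gamma = obs_gamma, critical = crit,
                 obs_minus_critical = obs_gamma - crit,
                 p_corrected = p, p_analytic = stats::pnorm(obs_gamma),
                 significant = obs_gamma <= crit,
                 reps = reps, N_total = N_total, n_sampled = n_sampled,
                 seed = seed, null = null_gamma),
            class = "mccr_test")
}

#' @export
print.mccr_test <- function(x, ...) {
  cat(sprintf(paste0("MCCR test: observed gamma %.3f vs critical %.3f ",
                     "(N_total = %d, sampled = %d, %d reps)\n",
                     "corrected P = %.4g -> %s\n"),
              x$obs_gamma, x$critical, x$N_total, x$n_sampled, x$reps,
              x$p_corrected,
              if (x$significant) "significant slowdown" else
                "rate constancy not rejected"))
  invisible(x)
}

# ages (descending internal node ages) -> internode durations g_2..g_n
ages_to_g <- function(ages) {
  n <- length(ages) + 1L
  c(-diff(ages), ages[n - 1L])
}

## ---- diversification model likelihoods ----------------------------------
## All log-likelihoods are for the reconstructed birth process conditioned on
## the crown age and on both crown lineages surviving, and share the
## combinatorial constant lfactorial(n - 1), so they are mutually comparable
## (and nested) for AIC purposes.

loglik_pb <- function(lambda, T, n) {
  lfactorial(n - 1) + (n - 2) * log(lambda) - lambda * T
}

# Nee et al. birth-death likelihood on node ages x (descending, x[1] = crown)
loglik_bd <- function(r, a, x) {
  n <- length(x) + 1L
  # log(exp(r x) - a) computed as r x + log(1 - a exp(-r x)) for stability
  lfactorial(n - 1) + (n - 2) * log(r) + r * sum(x[-1]) + n * log(1 - a) -
    2 * sum(r * x + log(1 - a * exp(-r * x)))
}

#' Fit a diversification model to branching times
#'
#' Maximum-likelihood fit of one of six models of the reconstructed
#' diversification process, conditioned on crown age and survival:
#' \describe{
#'   \item{PB}{pure birth, constant \eqn{\lambda}; closed-form MLE
#'     \eqn{\hat\lambda = (n-2)/T}.}
#'   \item{BD}{constant birth-death \eqn{(\lambda, \mu)} (Nee et al.
#'     reconstructed-process likelihood).}
#'   \item{DDL}{linear density dependence,
#'     \eqn{\lambda(N) = \lambda_0 (1 - N/K)}, `K > n`.}
#'   \item{DDX}{exponential density dependence,
#'     \eqn{\lambda(N) = \lambda_0 N^{-x}}, \eqn{x \in [-1, 5]}.}
#'   \item{YULE2, YULE3}{piecewise-constant pure birth with 1 or 2 rate
#'     shifts; shift times are profiled over the grid of observed branching
#'     times, ties broken toward the older shift.}
#' }
#' Parameter counts for AIC: PB 1, BD 2, DDL 2, DDX 2, YULE2 3, YULE3 5
#' (shift times count as parameters); `AIC = -2 lnL + 2 k`.
#'
#' @param bt a [branching_times] object (`n_tips >= 4` for multi-parameter
#'   models).
#' @param model one of `"PB"`, `"BD"`, `"DDL"`, `"DDX"`, `"YULE2"`,
#'   `"YULE3"`.
#' @return object of class `div_model_fit`: `model`, `params` (named),
#'   `lnL`, `k`, `AIC`, `convergence` (0 = ok).
#' @export
fit_model <- function(bt, model = c("PB", "BD", "DDL", "DDX",
                                    "YULE2", "YULE3")) {
  model <- match.arg(model)
  stopifnot(inherits(bt, "branching_times"))
  n <- bt$n_tips
  if (n < 3) stop("need at least 3 tips")
  if (model != "PB" && n < 4)
    stop("multi-parameter models require n_tips >= 4")
  fit <- switch(model,
                PB = fit_pb(bt), BD = fit_bd(bt),
                DDL = fit_ddl(bt), DDX = fit_ddx(bt),
                YULE2 = fit_yule_shift(bt, 1L),
                YULE3 = fit_yule_shift(bt, 2L))
  k <- c(PB = 1, BD = 2, DDL = 2, DDX = 2, YULE2 = 3, YULE3 = 5)[[model]]
  structure(c(list(model = model), fit,
              list(k = k, AIC = -2 * fit$lnL + 2 * k, n_tips = n)),
            class = "div_model_fit")
}

#' @export
print.div_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, AIC = %.4f (k = %d)\n",
              x$model, x$lnL, x$AIC, x$k))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), x$params),
                  collapse = ", "), "\n")
  invisible(x)
}

fit_pb <- function(bt) {
  n <- bt$n_tips
  lam <- (n - 2) / bt$T
  list(params = c(lambda = lam), lnL = loglik_pb(lam, bt$T, n),
       convergence = 0L)
}

fit_bd <- function(bt) {
  x <- bt$ages
  n <- bt$n_tips
  pb <- fit_pb(bt)
  nll <- function(par) {
    val <- loglik_bd(exp(par[1]), par[2], x)
    if (!is.finite(val)) 1e10 else -val
  }
  starts <- cbind(log(pmax(pb$params[["lambda"]] *
                             (1 - c(0, 0.2, 0.5, 0.8, 0.95)), 1e-8)),
                  c(0, 0.2, 0.5, 0.8, 0.95))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = c(log(1e-10), 0), upper = c(log(1e6), 1 - 1e-8)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("BD optimizer failed to converge")
  r <- exp(best$par[1]); a <- best$par[2]
  lam <- r / (1 - a)
  lnL <- -best$value
  # pure-birth boundary (a = 0) is inside the parameter space; never report
  # a local optimum below the nested PB maximum
  if (pb$lnL > lnL) {
    lam <- pb$params[["lambda"]]; a <- 0; lnL <- pb$lnL
  }
  list(params = c(lambda = lam, mu = a * lam, eps = a),
       lnL = lnL, convergence = best$convergence)
}

# DDL: lambda(k) = lambda0 (1 - k/K); lambda0 profiled in closed form
fit_ddl <- function(bt) {
  n <- bt$n_tips
  g <- bt$g
  k <- 2:n
  prof <- function(K) {
    W <- sum(k * (1 - k / K) * g)
    if (W <= 0) return(list(lnL = -Inf))
    lam0 <- (n - 2) / W
    # sum(log(k * lambda(k))) carries the Sum log k constant itself
    lnL <- sum(log(k[-(n - 1)] * lam0 * (1 - k[-(n - 1)] / K))) -
      lam0 * W
    list(lnL = lnL, lambda0 = lam0)
  }
  # profile over K = n + exp(u); boundary u -> Inf recovers pure birth
  us <- seq(log(1e-3 * n), log(1e8 * n), length.out = 60)
  vals <- vapply(us, function(u) prof(n + exp(u))$lnL, numeric(1))
  i <- which.max(vals)
  lo <- us[max(1, i - 1)]; hi <- us[min(length(us), i + 1)]
  opt <- stats::optimize(function(u) prof(n + exp(u))$lnL, c(lo, hi),
                         maximum = TRUE, tol = 1e-8)
  cand_u <- c(opt$maximum, us[length(us)])
  cand_lnL <- vapply(cand_u, function(u) prof(n + exp(u))$lnL, numeric(1))
  j <- which.max(cand_lnL)
  K <- n + exp(cand_u[j])
  pf <- prof(K)
  list(params = c(lambda0 = pf$lambda0, K = K), lnL = pf$lnL,
       convergence = 0L)
}

# DDX: lambda(k) = lambda0 k^(-x); lambda0 profiled in closed form
fit_ddx <- function(bt) {
  n <- bt$n_tips
  g <- bt$g
  k <- 2:n
  prof <- function(x) {
    W <- sum(k^(1 - x) * g)
    lam0 <- (n - 2) / W
    lnL <- sum(log(k[-(n - 1)]) * (1 - x) + log(lam0)) - lam0 * W
    list(lnL = lnL, lambda0 = lam0)
  }
  xs <- seq(-1, 5, length.out = 61)
  vals <- vapply(xs, function(x) prof(x)$lnL, numeric(1))
  i <- which.max(vals)
  opt <- stats::optimize(function(x) prof(x)$lnL,
                         c(xs[max(1, i - 1)], xs[min(length(xs), i + 1)]),
                         maximum = TRUE, tol = 1e-9)
  cand <- c(opt$maximum, 0)   # x = 0 is exactly pure birth
  lnLs <- vapply(cand, function(x) prof(x)$lnL, numeric(1))
  j <- which.max(lnLs)
  pf <- prof(cand[j])
  list(params = c(lambda0 = pf$lambda0, x = cand[j]), lnL = pf$lnL,
       convergence = 0L)
}

# piecewise-constant pure birth with `n_shifts` rate shifts; shift times
# profiled on the grid of observed (interior) branching times
fit_yule_shift <- function(bt, n_shifts) {
  n <- bt$n_tips
  g <- bt$g
  ages <- bt$ages
  kg <- as.numeric((2:n) * g)
  cumkg <- cumsum(kg)          # lineage-time from crown down to ages[j], j>=2
  T <- bt$T
  nev <- n - 2L                # branching events excluding the crown
  term <- function(nn, BB) {
    out <- numeric(length(nn))
    pos <- nn > 0
    out[pos] <- nn[pos] * (log(nn[pos] / BB[pos]) - 1)
    out[pos & BB <= 0] <- -Inf
    out
  }
  lfac <- lfactorial(n - 1)
  if (n_shifts == 1L) {
    j <- 2:(n - 1)             # shift at interior event age ages[j]
    B1 <- cumkg[j - 1]; n1 <- j - 1
    B2 <- T - B1;       n2 <- nev - n1
    lnL <- lfac + term(n1, B1) + term(n2, B2)
    i <- which.max(lnL)        # ties resolve to the older shift
    sj <- j[i]
    lam <- c(n1[i] / B1[i], if (n2[i] > 0) n2[i] / B2[i] else 0)
    list(params = c(lambda1 = lam[1], lambda2 = lam[2],
                    shift1 = ages[sj]),
         lnL = lnL[i], convergence = 0L)
  } else {
    grid <- expand.grid(j = 2:(n - 2), l = 3:(n - 1))
    grid <- grid[grid$j < grid$l, ]
    j <- grid$j; l <- grid$l
    B1 <- cumkg[j - 1];            n1 <- j - 1
    B2 <- cumkg[l - 1] - B1;       n2 <- l - j
    B3 <- T - cumkg[l - 1];        n3 <- nev - n1 - n2
    lnL <- lfac + term(n1, B1) + term(n2, B2) + term(n3, B3)
    ord <- order(-lnL, j, l)   # ties toward older shifts
    i <- ord[1]
    lam <- c(n1[i] / B1[i], n2[i] / B2[i],
             if (n3[i] > 0) n3[i] / B3[i] else 0)
    list(params = c(lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
                    shift1 = ages[j[i]], shift2 = ages[l[i]]),
         lnL = lnL[i], convergence = 0L)
  }
}

#' Fit all six diversification models and select by AIC
#'
#' Fits PB, BD (rate-constant) and DDL, DDX, YULE2, YULE3 (rate-variable)
#' with [fit_model()] and reports
#' \eqn{\Delta AIC_{RC} = AIC_{RC} - AIC_{RV}} computed from the best
#' (lowest-AIC) model within each class; positive values favor rate
#' variation, with values near 4 conventionally required to reject rate
#' constancy with confidence.
#'
#' @param bt a [branching_times] object.
#' @return object of class `div_model_selection`: `table` (per-model data
#'   frame), `fits` (list of `div_model_fit`), `delta_AIC_RC`, `best_rc`,
#'   `best_rv`, `best_model`, `decision`.
#' @export
model_select <- function(bt) {
  models <- c("PB", "BD", "DDL", "DDX", "YULE2", "YULE3")
  fits <- lapply(models, function(m) fit_model(bt, m))
  names(fits) <- models
  tab <- data.frame(model = models,
                    class = c("RC", "RC", "RV", "RV", "RV", "RV"),
                    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                    k = vapply(fits, function(f) as.numeric(f$k), numeric(1)),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
                    row.names = NULL)
  rc <- tab[tab$class == "RC", ]
  rv <- tab[tab$class == "RV", ]
  best_rc <- rc$model[which.min(rc$AIC)]
  best_rv <- rv$model[which.min(rv$AIC)]
  delta <- min(rc$AIC) - min(rv$AIC)
  structure(list(table = tab, fits = fits, delta_AIC_RC = delta,
                 best_rc = best_rc, best_rv = best_rv,
                 best_model = tab$model[which.min(tab$AIC)],
                 decision = if (delta >= 4)
                   "rate-constant models rejected (delta AIC_RC >= 4)"
                 else "rate constancy not rejected with confidence"),
            class = "div_model_selection")
}

#' @export
print.div_model_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("delta AIC_RC (best RC %s - best RV %s) = %.3f\n%s\n",
              x$best_rc, x$best_rv, x$delta_AIC_RC, x$decision))
  invisible(x)
}

#' Per-clade diversification summary table
#'
#' Combines the Magallon-Sanderson rates, the gamma statistic and the MCCR
#' test into one table, one row per clade. Sampled clade sizes are taken
#' from the tree, total richness from the clade table.
#'
#' @param tree chronogram containing all clade tips.
#' @param clades clade table as from [read_clades()] (needs the `tips`
#'   list-column).
#' @param eps extinction fractions for [ms_rate()].
#' @param mccr_reps MCCR replicates per clade.
#' @param seed integer seed; each clade derives its own sub-seed.
#' @return data frame mirroring a classic diversification-rate table: rates
#'   per extinction fraction, observed gamma, analytic P, critical gamma,
#'   observed minus critical, MCCR-corrected P.
#' @export
diversification_table <- function(tree, clades, eps = c(0, 0.5, 0.99),
                                  mccr_reps = 10000, seed = 1) {
  rates <- ms_rate_table(clades, eps)
  rows <- lapply(seq_len(nrow(clades)), function(i) {
    bt <- branching_times(tree, clades$tips[[i]])
    gs <- gamma_statistic(bt)
    mc <- mccr_test(gs, N_total = clades$total_richness[i],
                    n_sampled = bt$n_tips, reps = mccr_reps,
                    seed = seed + i)
    data.frame(n_sampled = bt$n_tips, obs_gamma = gs$gamma,
               p_gamma = gs$p_value, critical_gamma = mc$critical,
               obs_minus_critical = mc$obs_minus_critical,
               p_mccr = mc$p_corrected)
  })
  cbind(rates, do.call(rbind, rows))
}
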