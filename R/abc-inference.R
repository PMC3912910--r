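#' Prior specification for the FGM parameters
#'
#' Independent priors: `log10(U)` uniform on `[-3.5, -0.5]` (spanning the
#' plausible range of genome-wide fitness-altering mutation rates in a
#' mutator *E. coli*), `sigma` exponential (a very flat prior over the
#' plausible range, default mean 0.1), and `n` uniform on the integers
#' `{1, ..., 30}`.
#'
#' @param log10U_min,log10U_max Support of the uniform prior on `log10(U)`.
#' @param sigma_mean Mean of the exponential prior on `sigma`.
#' @param n_min,n_max Support of the discrete uniform prior on `n`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(log10U_min = -3.5, log10U_max = -0.5,
                       sigma_mean = 0.1, n_min = 1L, n_max = 30L) {
  stopifnot(log10U_min < log10U_max, sigma_mean > 0, n_min >= 1,
            n_min <= n_max)
  structure(list(log10U_min = log10U_min, log10U_max = log10U_max,
                 sigma_mean = sigma_mean,
                 n_min = as.integer(n_min), n_max = as.integer(n_max)),
            class = "prior_spec")
}

#' Draw parameter vectors from the joint prior
#'
#' @param spec A [prior_spec()] object.
#' @param n_draws Number of independent draws.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `U`, `n`, `sigma`, one row per draw.
#' @export
sample_prior <- function(spec = prior_spec(), n_draws = 1L, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    U = 10^stats::runif(n_draws, spec$log10U_min, spec$log10U_max),
    n = sample.int(spec$n_max - spec$n_min + 1L, n_draws,
                   replace = TRUE) + spec$n_min - 1L,
    sigma = stats::rexp(n_draws, rate = 1 / spec$sigma_mean))
}

#' Simulate one composite dataset and reduce it to the summary vector
#'
#' Runs the MA simulation (fast engine by default) and the recovery
#' simulation, then applies [summarize_experiments()]. This is the
#' simulator that seeds the rejection sampler.
#'
#' @param params An [fgm_params()] object.
#' @param ma_design An [ma_design()].
#' @param rec_design A [recovery_design()]; the default uses the fast
#'   recovery engine with one replicate per starting fitness, the
#'   desk-scale configuration used for rejection sampling.
#' @param seed Optional integer seed.
#' @return An `fgm_summary` vector of length 39.
#' @export
simulate_dataset <- function(params,
                             ma_design = fgmabc::ma_design(engine = "fast"),
                             rec_design = recovery_design(engine = "fast",
                                                          replicates = 1L),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ma <- run_ma_experiment(params, ma_design)
  rec <- run_recovery_experiment(params, rec_design)
  summarize_experiments(ma, rec)
}

#' Simulate a reference table of prior draws and their summaries
#'
#' Draws `M` parameter vectors from the prior and simulates one composite
#' dataset for each, producing the reference table that [abc_reject()]
#' consumes. Sequential and fully reproducible from `seed`.
#'
#' @param M Number of simulations.
#' @param spec A [prior_spec()].
#' @param ma_design,rec_design Simulation designs, as in
#'   [simulate_dataset()].
#' @param seed Optional integer seed.
#' @return A list with `theta` (data.frame `U`, `n`, `sigma`) and `stats`
#'   (an `M` x 39 matrix).
#' @export
simulate_pool <- function(M, spec = prior_spec(),
                          ma_design = fgmabc::ma_design(engine = "fast"),
                          rec_design = recovery_design(engine = "fast",
                                                       replicates = 1L),
                          seed = NULL) {
  stopifnot(M >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- sample_prior(spec, M)
  stats <- matrix(NA_real_, nrow = M, ncol = 39L,
                  dimnames = list(NULL, summary_statistic_names()))
  for (i in seq_len(M)) {
    p <- fgm_params(theta$U[i], theta$n[i], theta$sigma[i])
    stats[i, ] <- simulate_dataset(p, ma_design, rec_design)
  }
  list(theta = theta, stats = stats)
}

#' Rejection sampling against an observed summary vector
#'
#' Euclidean distance on statistics standardized by their median absolute
#' deviation across the simulated reference table (statistics with zero
#' MAD carry no information at this scale and are excluded with a
#' warning); the `round(M * tol)` parameter vectors with the smallest
#' distances form the approximate posterior sample.
#'
#' @param observed The observed summary vector (length 39, canonical
#'   order).
#' @param theta Data.frame of the parameter vectors that seeded the
#'   simulations (columns `U`, `n`, `sigma`).
#' @param stats Matrix of simulated summary vectors, one row per
#'   simulation.
#' @param tol Acceptance fraction (e.g. 0.001).
#' @param standardize Use MAD standardization (default `TRUE`); `FALSE`
#'   gives the unstandardized Euclidean distance.
#' @return An object of class `abc_run`: list with `accepted` (data.frame
#'   `U`, `n`, `sigma`, `distance`, sorted by distance), `M`, `tol`,
#'   `scale` (the per-statistic scale used) and `excluded` (names of
#'   zero-scale statistics).
#' @export
abc_reject <- function(observed, theta, stats, tol, standardize = TRUE) {
  stopifnot(is.matrix(stats), nrow(stats) == nrow(theta),
            length(observed) == ncol(stats), tol > 0, tol <= 1)
  M <- nrow(stats)
  n_keep <- max(1L, round(M * tol))
  if (M < n_keep) stop("need at least 1/tol simulations")
  scale <- if (standardize) {
    apply(stats, 2L, stats::mad)
  } else {
    rep(1, ncol(stats))
  }
  excluded <- colnames(stats)[scale == 0]
  if (length(excluded) > 0)
    warning(sprintf("%d zero-variance statistics excluded from the distance: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  use <- scale > 0
  z <- sweep(stats[, use, drop = FALSE], 2L, scale[use], "/")
  zo <- as.numeric(observed)[use] / scale[use]
  d <- sqrt(rowSums(sweep(z, 2L, zo, "-")^2))
  ord <- order(d)[seq_len(n_keep)]
  accepted <- data.frame(U = theta$U[ord], n = theta$n[ord],
                         sigma = theta$sigma[ord], distance = d[ord])
  structure(list(accepted = accepted, M = M, tol = tol, scale = scale,
                 excluded = excluded),
            class = "abc_run")
}

#' @export
print.abc_run <- function(x, ...) {
  cat(sprintf("ABC rejection run: %d accepted of %d simulations (tol = %g)\n",
              nrow(x$accepted), x$M, x$tol))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior medians and 95% central intervals
#'
#' @param run An `abc_run`.
#' @return A data.frame with one row per parameter (`U`, `n`, `sigma`):
#'   `median`, `lower` and `upper` (2.5 and 97.5 percentiles). Summaries
#'   for `n` are rounded back to the integer grid on which its prior
#'   lives; `U` is summarized on the natural scale.
#' @export
posterior_summary <- function(run) {
  stopifnot(inherits(run, "abc_run"))
  if (nrow(run$accepted) == 0L) stop("empty accepted set")
  one <- function(v, integer_grid = FALSE) {
    q <- stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
    if (integer_grid) q <- round(q)
    q
  }
  qs <- rbind(U = one(run$accepted$U),
              n = one(run$accepted$n, integer_grid = TRUE),
              sigma = one(run$accepted$sigma))
  data.frame(parameter = rownames(qs), median = qs[, 1L],
             lower = qs[, 2L], upper = qs[, 3L], row.names = NULL)
}

#' Prediction error of an estimator across validation datasets
#'
#' Mean squared bias plus variance of the estimates about the truths,
#' per parameter: with `d = estimate - truth`,
#' `pe = mean(d)^2 + mean((d - mean(d))^2)`. Estimates equal to the truths
#' give 0; a pure constant offset `c` gives exactly `c^2`.
#'
#' @param estimates,truths Data.frames (or matrices) with matching columns
#'   and at least 2 paired rows.
#' @return A named numeric vector, one entry per column.
#' @export
prediction_error <- function(estimates, truths) {
  estimates <- as.data.frame(estimates)
  truths <- as.data.frame(truths)
  if (nrow(estimates) != nrow(truths))
    stop("estimates and truths must have the same number of rows")
  if (nrow(estimates) < 2L) stop("need at least 2 paired validation sets")
  stopifnot(identical(names(estimates), names(truths)))
  vapply(names(estimates), function(p) {
    d <- estimates[[p]] - truths[[p]]
    mean(d)^2 + mean((d - mean(d))^2)
  }, numeric(1L))
}
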