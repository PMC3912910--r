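#' Competition-assay counts
#'
#' Container for 1:1 competition assays: initial and final colony counts of
#' the test strain (`a`) and the reference strain (`b`). Vectorized over
#' replicates.
#'
#' @param N_ia,N_ib Test and reference counts before the competition.
#' @param N_fa,N_fb Test and reference counts after the competition.
#' @return A data.frame of class `competition_counts`.
#' @export
competition_counts <- function(N_ia, N_ib, N_fa, N_fb) {
  counts <- data.frame(N_ia = N_ia, N_ib = N_ib, N_fa = N_fa, N_fb = N_fb)
  if (any(!is.finite(as.matrix(counts))) || any(as.matrix(counts) <= 0))
    stop("all counts must be positive and finite")
  class(counts) <- c("competition_counts", "data.frame")
  counts
}

#' Generations elapsed for the reference strain
#'
#' Assuming no death, the reference underwent `G = log2(N_fb / N_ib)`
#' doublings during the competition.
#'
#' @param counts A [competition_counts()] data.frame.
#' @return Numeric vector of generations, one per replicate. A warning is
#'   raised when the reference did not grow (`G <= 0`), which makes the
#'   per-generation normalization degenerate.
#' @export
generations_elapsed <- function(counts) {
  stopifnot(inherits(counts, "competition_counts"))
  G <- log2(counts$N_fb / counts$N_ib)
  if (any(G <= 0))
    warning("reference strain did not grow in some replicates (G <= 0): normalization degenerate")
  G
}

#' Relative fitness from a competition assay
#'
#' The per-generation selection coefficient of the test strain is the
#' difference in Malthusian growth between test and reference, normalized
#' by the reference's doublings:
#' `s = (ln(N_fa / N_ia) - ln(N_fb / N_ib)) / G`, and relative fitness
#' `W_a = 1 + s`. Multiplying all four counts by a common dilution factor
#' leaves `s` unchanged.
#'
#' @param counts A [competition_counts()] data.frame.
#' @return A data.frame with columns `G`, `s`, `W` (one row per replicate).
#' @export
relative_fitness <- function(counts) {
  stopifnot(inherits(counts, "competition_counts"))
  G <- suppressWarnings(generations_elapsed(counts))
  if (any(G <= 0)) stop("degenerate assay: reference did not grow (G <= 0)")
  s <- (log(counts$N_fa / counts$N_ia) - log(counts$N_fb / counts$N_ib)) / G
  data.frame(G = G, s = s, W = 1 + s)
}

#' Standardize fitness values to a measured ancestor
#'
#' Divides each fitness by the ancestor's measured fitness so the ancestor
#' is exactly 1; fitness ratios are preserved.
#'
#' @param W Numeric vector of fitness values.
#' @param W_ancestor The ancestor's measured fitness (positive).
#' @return The standardized fitness vector.
#' @export
standardize_to_ancestor <- function(W, W_ancestor) {
  if (!is.numeric(W_ancestor) || length(W_ancestor) != 1L ||
      !is.finite(W_ancestor) || W_ancestor <= 0)
    stop("W_ancestor must be a single positive number")
  W / W_ancestor
}

#' Linear versus quadratic decline of log mean fitness
#'
#' Compares Gaussian OLS fits of degree 1 and 2 for log mean fitness
#' against time by AIC (`AIC = N * ln(RSS / N) + 2 k`, `k` counting the
#' regression coefficients plus the error variance, so the additive
#' constants cancel in the comparison). A quadratic term picking up
#' curvature would indicate directional epistasis in the trajectory mean;
#' differences below 2 AIC units are reported as indistinguishable.
#'
#' @param times Numeric time axis (at least 4 points).
#' @param log_mean_fitness Log of mean fitness at each time.
#' @return A list with `AIC_linear`, `AIC_quadratic`, `delta_AIC`
#'   (`AIC_quadratic - AIC_linear`) and `preferred` (`"linear"`,
#'   `"quadratic"` or `"indistinguishable"`).
#' @export
trajectory_model_compare <- function(times, log_mean_fitness) {
  stopifnot(length(times) == length(log_mean_fitness))
  if (length(times) < 4L) stop("need at least 4 time points")
  N <- length(times)
  aic_ols <- function(fit, k) {
    rss <- max(sum(stats::residuals(fit)^2), 1e-300)
    N * log(rss / N) + 2 * k
  }
  fit1 <- stats::lm(log_mean_fitness ~ times)
  fit2 <- stats::lm(log_mean_fitness ~ times + I(times^2))
  a1 <- aic_ols(fit1, 3L)  # intercept, slope, variance
  a2 <- aic_ols(fit2, 4L)
  delta <- a2 - a1
  tss <- sum((log_mean_fitness - mean(log_mean_fitness))^2)
  preferred <- if (sum(stats::residuals(fit1)^2) <= 1e-12 * max(tss, 1e-300))
    "linear"  # the linear fit is already exact; curvature cannot help
  else if (abs(delta) < 2) "indistinguishable"
  else if (a1 < a2) "linear" else "quadratic"
  list(AIC_linear = a1, AIC_quadratic = a2, delta_AIC = delta,
       preferred = preferred,
       quadratic_coefficient = unname(stats::coef(fit2)[3L]))
}
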