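#' Gaussian fitness landscape
#'
#' Fitness of a phenotype `x` (an `n`-vector of trait deviations from the
#' optimum at the origin) is `w(x) = exp(-sum(x^2))`. The optimum has fitness
#' 1 and fitness decreases isotropically with Euclidean distance from it.
#' With this scaling, the mean log-fitness effect of a random mutation with
#' independent `N(0, sigma^2)` displacements on each trait is exactly
#' `-n * sigma^2` on every background.
#'
#' @param x Numeric vector of trait values (finite).
#' @return `fgm_fitness()` returns fitness in `(0, 1]`; `fgm_log_fitness()`
#'   returns its logarithm `-sum(x^2)` (preferred internally, immune to
#'   underflow far from the optimum).
#' @examples
#' fgm_fitness(rep(0, 9))        # optimum: 1
#' fgm_fitness(c(0.1, rep(0, 8)))  # exp(-0.01)
#' @export
fgm_fitness <- function(x) exp(fgm_log_fitness(x))

#' @rdname fgm_fitness
#' @export
fgm_log_fitness <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || !all(is.finite(x)))
    stop("phenotype must be a non-empty numeric vector with finite entries")
  -sum(x * x)
}

#' Draw random mutational displacements
#'
#' Mutations are fully pleiotropic: a single mutation displaces every trait
#' by an independent `N(0, sigma^2)` amount.
#'
#' @param params An [fgm_params()] object.
#' @param n_draws Number of mutations to draw.
#' @param seed Optional integer seed (set once at entry).
#' @return A `n_draws x n` numeric matrix; each row is one mutation.
#' @export
draw_mutation <- function(params, n_draws = 1L, seed = NULL) {
  stopifnot(inherits(params, "fgm_params"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n_draws * params$n, 0, params$sigma),
         nrow = n_draws, ncol = params$n)
}

#' Selection coefficient of a mutation on a given background
#'
#' The selection coefficient is the per-generation log-fitness change,
#' `s = log w(x + d) - log w(x)`. Under the Gaussian landscape this is
#' `s = -2 * sum(x * d) - sum(d^2)`: at the optimum every mutation is
#' deleterious, away from it mutations pointing back toward the optimum can
#' be beneficial (compensatory).
#'
#' @param background Numeric phenotype vector `x`.
#' @param displacement Numeric displacement vector `d`, same length.
#' @return The selection coefficient `s` (a single number).
#' @examples
#' selection_coefficient(c(0.5, 0), c(-0.1, 0))  # +0.09, beneficial
#' @export
selection_coefficient <- function(background, displacement) {
  if (length(background) != length(displacement))
    stop("background and displacement must have the same length")
  if (!all(is.finite(background)) || !all(is.finite(displacement)))
    stop("background and displacement must be finite")
  -2 * sum(background * displacement) - sum(displacement^2)
}

#' Mean fitness effect of a mutation at the optimum
#'
#' Closed form `E[s] = -n * sigma^2` for a random mutation hitting a
#' genotype at the phenotypic optimum; under the adopted landscape and
#' log-fitness selection coefficients the same mean holds on every
#' background.
#'
#' @param params An [fgm_params()] object.
#' @return `-n * sigma^2`.
#' @examples
#' expected_s_at_optimum(fgm_params(0.01, 9, 0.034))  # -0.010404
#' @export
expected_s_at_optimum <- function(params) {
  stopifnot(inherits(params, "fgm_params"))
  -params$n * params$sigma^2
}

#' Probability that a mutation escapes genetic drift
#'
#' Kimura's diffusion approximation for the fixation probability of a new
#' mutation with selection coefficient `s` in a population of effective size
#' `Ne`: `(1 - exp(-2 s)) / (1 - exp(-2 Ne s))`. Continuous at `s = 0`
#' (limit `1/Ne`), increasing in `s`, and tending to `1 - exp(-2 s)` for
#' beneficial mutations as `Ne` grows. Evaluated in log space so strongly
#' deleterious mutations at large `Ne` underflow cleanly to 0.
#'
#' @param s Selection coefficient(s), vectorized.
#' @param Ne Effective population size, `Ne >= 1`.
#' @return Survival (fixation) probabilities in `[0, 1]`.
#' @examples
#' survival_probability(0, 23)    # 1/23
#' survival_probability(0.1, 23)  # ~0.183
#' @export
survival_probability <- function(s, Ne) {
  stopifnot(is.numeric(s), is.numeric(Ne), length(Ne) == 1L, Ne >= 1)
  vapply(s, survival_probability_cpp, numeric(1L), Ne = Ne)
}

#' Sample the distribution of fitness effects before and after drift
#'
#' Draws `n_draws` random mutations on a background constructed at the
#' stated fitness, computes their selection coefficients, and flags each
#' with a Bernoulli draw of probability [survival_probability()] - the
#' drift filter. Summaries of the `survived` subset give the DFE of
#' mutations that escape drift.
#'
#' @param params An [fgm_params()] object.
#' @param background_fitness Fitness of the background genotype, in `(0, 1]`.
#' @param Ne Effective population size used in the drift filter.
#' @param n_draws Number of mutations to sample (`>= 1`).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `s`, `survived` (0/1) and
#'   `background_fitness`.
#' @export
dfe_after_drift <- function(params, background_fitness, Ne, n_draws, seed = NULL) {
  stopifnot(inherits(params, "fgm_params"))
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- make_founder_at_fitness(background_fitness, params)
  d <- matrix(stats::rnorm(n_draws * params$n, 0, params$sigma), nrow = n_draws)
  s <- -2 * drop(d %*% x) - rowSums(d * d)
  p <- survival_probability(s, Ne)
  data.frame(s = s,
             survived = as.integer(stats::runif(n_draws) < p),
             background_fitness = background_fitness)
}

#' Pairwise epistasis between two mutations
#'
#' Deviation of the double mutant's selection coefficient from the sum of
#' the single-mutant coefficients on the same background, all measured as
#' log-fitness changes. Under the Gaussian landscape
#' `epsilon = -2 * sum(d1 * d2)`, independent of the background, with mean 0
#' and a symmetric distribution over random mutation pairs.
#'
#' @param background Phenotype vector.
#' @param d1,d2 Displacement vectors of the two mutations.
#' @return The epistasis coefficient `epsilon`.
#' @export
pairwise_epistasis <- function(background, d1, d2) {
  if (length(d1) != length(background) || length(d2) != length(background))
    stop("background, d1 and d2 must have the same length")
  s12 <- selection_coefficient(background, d1 + d2)
  s1 <- selection_coefficient(background, d1)
  s2 <- selection_coefficient(background, d2)
  s12 - s1 - s2
}

#' Crude estimate of trait number from the first adaptive step
#'
#' Close to the optimum and ignoring clonal interference, the mean effect of
#' the first beneficial mutation fixed is `E[s_b | fix] = 4 s0 / (4 + n)`,
#' with `s0 ~ 1 - W0` the distance to the peak. Given the fitted slope of
#' fitness gain on `s0`, this inverts to `n = 4 / slope - 4`.
#'
#' @param slope Fitted slope of fitness increase on distance to peak, in
#'   `(0, 1]`.
#' @return The implied number of traits `n` (not rounded).
#' @examples
#' first_step_n_estimate(4 / 13)  # 9
#' @export
first_step_n_estimate <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope <= 0 || slope > 1)
    stop("slope must lie in (0, 1] for the first-step theory to apply")
  n_hat <- 4 / slope - 4
  if (n_hat == 0)
    warning("slope = 1 implies n = 0: boundary of the model's validity")
  n_hat
}

#' Construct a founder phenotype at a given fitness
#'
#' By isotropy of the landscape the axis is arbitrary: returns the
#' phenotype `(sqrt(-log(W0)), 0, ..., 0)`, so that
#' `fgm_fitness(result) == W0` to machine precision.
#'
#' @param W0 Target fitness in `(0, 1]`.
#' @param params An [fgm_params()] object (supplies the dimension).
#' @return A numeric phenotype vector of length `params$n`.
#' @export
make_founder_at_fitness <- function(W0, params) {
  stopifnot(inherits(params, "fgm_params"))
  if (!is.numeric(W0) || length(W0) != 1L || !is.finite(W0) || W0 <= 0 || W0 > 1)
    stop("W0 must lie in (0, 1]")
  x <- numeric(params$n)
  x[1L] <- sqrt(-log(W0))
  x
}

#' Write a DFE sample to CSV
#'
#' @param dfe A data.frame as returned by [dfe_after_drift()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dfe_csv <- function(dfe, path) {
  stopifnot(all(c("s", "survived", "background_fitness") %in% names(dfe)))
  utils::write.csv(dfe, path, row.names = FALSE)
  invisible(path)
}
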