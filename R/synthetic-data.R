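# md5 of the shipped observed-summary fixture; verified at load so silent
# corruption of the packaged file is caught.
.observed_summary_md5 <- "7fe7008ca0c8cb6881f7e6caaf9df403"

#' Load the observed 39-statistic summary vector
#'
#' Returns the observed composite summary of the two experiments: the
#' seven-bin fitness counts of the 50 MA lines at bottlenecks 10-50 and
#' the fitness-recovery regression coefficients at generations 120 and
#' 240 (slope120 = -0.7986, intercept120 = 0.7585, slope240 = -0.8873,
#' intercept240 = 0.8647). Shipped as a plain CSV fixture whose checksum
#' is verified at load.
#'
#' @return An `fgm_summary` vector of length 39.
#' @export
load_observed_summary <- function() {
  path <- system.file("extdata", "observed_summary.csv", package = "fgmabc",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .observed_summary_md5))
    stop("observed-summary fixture failed its integrity check (md5 mismatch)")
  read_summary_csv(path)
}

#' Generate a pseudo-observed composite dataset at known parameters
#'
#' Simulates a full MA + recovery dataset at a known parameter triple and
#' reduces it to the summary vector; used to validate the ABC estimator
#' (parameter recovery, prediction error) without any external data. The
#' default designs reproduce the experimental geometry: 50 MA lines with
#' 5 checkpoints, three recovery starting fitnesses.
#'
#' @param theta An [fgm_params()] object (the true parameters).
#' @param ma_design An [ma_design()].
#' @param rec_design A [recovery_design()].
#' @param seed Integer seed; regeneration from the same `(theta, seed)` is
#'   bit-identical.
#' @return An object of class `pseudo_observed`: list with `theta_true`,
#'   `ma`, `rec`, `summary`, `seed`.
#' @export
make_pseudo_observed <- function(theta,
                                 ma_design = fgmabc::ma_design(engine = "fast"),
                                 rec_design = recovery_design(engine = "fast",
                                                              replicates = 1L),
                                 seed = 1L) {
  stopifnot(inherits(theta, "fgm_params"))
  set.seed(seed)
  ma <- run_ma_experiment(theta, ma_design)
  rec <- run_recovery_experiment(theta, rec_design)
  structure(list(theta_true = theta, ma = ma, rec = rec,
                 summary = summarize_experiments(ma, rec),
                 seed = as.integer(seed)),
            class = "pseudo_observed")
}

#' @export
print.pseudo_observed <- function(x, ...) {
  cat(sprintf("Pseudo-observed dataset at U = %g, n = %d, sigma = %g (seed %d)\n",
              x$theta_true$U, x$theta_true$n, x$theta_true$sigma, x$seed))
  print(x$summary)
  invisible(x)
}
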