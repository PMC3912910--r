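#' Canonical fitness bin edges and summary-vector layout
#'
#' The composite summary vector has 39 entries in a fixed canonical order:
#' for each MA checkpoint (bottlenecks 10, 20, 30, 40, 50) the counts of
#' lines in seven fitness bins with edges 0.77, 0.81, 0.85, 0.89, 0.93,
#' 0.97 (interior bins right-open `[lo, hi)`, first bin `(-Inf, 0.77)`,
#' last bin `[0.97, Inf)`), followed by the recovery regression
#' coefficients slope/intercept at generations 120 and 240.
#'
#' @return `fitness_bin_edges()` returns the 8 bin edges (including the
#'   infinite outer edges); `summary_statistic_names()` the 39 canonical
#'   names.
#' @export
fitness_bin_edges <- function() {
  c(-Inf, 0.77, 0.81, 0.85, 0.89, 0.93, 0.97, Inf)
}

#' @rdname fitness_bin_edges
#' @export
summary_statistic_names <- function() {
  bins <- c("lt0.77", "0.77_0.81", "0.81_0.85", "0.85_0.89", "0.89_0.93",
            "0.93_0.97", "ge0.97")
  c(as.vector(t(outer(paste0("bot", c(10, 20, 30, 40, 50)), bins, paste,
                      sep = "_"))),
    "slope_120", "intercept_120", "slope_240", "intercept_240")
}

#' Bin fitness values into the seven canonical classes
#'
#' Half-open binning `[lo, hi)` with open-ended first and last bins, so a
#' value exactly on an interior edge (e.g. 0.97) falls in the upper bin.
#'
#' @param values Numeric vector of fitness values (finite).
#' @return Integer vector of 7 counts summing to `length(values)`.
#' @examples
#' bin_fitness(c(0.95, 0.98, 0.80))  # 0 1 0 0 0 1 1
#' @export
bin_fitness <- function(values) {
  if (length(values) == 0L) {
    warning("empty input: returning zero counts")
    return(integer(7L))
  }
  if (!all(is.finite(values))) stop("fitness values must be finite")
  counts <- table(cut(values, breaks = fitness_bin_edges(), right = FALSE))
  as.integer(counts)
}

#' Reduce an MA + recovery experiment pair to the 39-statistic summary
#'
#' Concatenates, in canonical order, the seven-bin fitness counts of the MA
#' lines at bottlenecks 10-50 and the OLS slope and intercept of fitness
#' change on initial fitness at recovery generations 120 and 240.
#'
#' @param ma An `ma_dataset` recorded at (at least) cycles 10, 20, 30, 40,
#'   50.
#' @param rec A `recovery_dataset` with checkpoints 120 and 240.
#' @return A named numeric vector of length 39, class `fgm_summary`.
#' @export
summarize_experiments <- function(ma, rec) {
  stopifnot(inherits(ma, "ma_dataset"))
  cps <- c(10L, 20L, 30L, 40L, 50L)
  if (!all(cps %in% ma$cycles))
    stop("MA dataset must be recorded at cycles 10, 20, 30, 40, 50")
  counts <- unlist(lapply(cps, function(cp) {
    bin_fitness(ma$fitness[, ma$cycles == cp])
  }))
  sl <- recovery_slopes(rec)
  if (!all(c(120L, 240L) %in% sl$generation))
    stop("recovery dataset must include checkpoints 120 and 240")
  reg <- c(sl$slope[sl$generation == 120L], sl$intercept[sl$generation == 120L],
           sl$slope[sl$generation == 240L], sl$intercept[sl$generation == 240L])
  out <- c(counts, reg)
  names(out) <- summary_statistic_names()
  class(out) <- "fgm_summary"
  out
}

#' @export
print.fgm_summary <- function(x, ...) {
  cat("Composite summary vector (39 statistics)\n")
  m <- matrix(unclass(x)[1:35], nrow = 5, byrow = TRUE,
              dimnames = list(paste0("bot", c(10, 20, 30, 40, 50)),
                              c("<0.77", "[0.77,0.81)", "[0.81,0.85)",
                                "[0.85,0.89)", "[0.89,0.93)", "[0.93,0.97)",
                                ">=0.97")))
  print(m)
  cat(sprintf("  slope120 = %.4f, intercept120 = %.4f, slope240 = %.4f, intercept240 = %.4f\n",
              x[["slope_120"]], x[["intercept_120"]], x[["slope_240"]],
              x[["intercept_240"]]))
  invisible(x)
}

#' Serialize a summary vector as a single-row CSV
#'
#' @param summary A length-39 `fgm_summary` (or compatible named vector).
#' @param path File path.
#' @return `write_summary_csv()` returns `path` invisibly;
#'   `read_summary_csv()` returns the `fgm_summary` vector.
#' @export
write_summary_csv <- function(summary, path) {
  stopifnot(length(summary) == 39L,
            identical(names(summary), summary_statistic_names()))
  df <- as.data.frame(as.list(unclass(summary)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- as.numeric(df[1L, ])
  names(out) <- colnames(df)
  if (!identical(names(out), summary_statistic_names()))
    stop("file does not contain the canonical 39-statistic layout")
  class(out) <- "fgm_summary"
  out
}

#' Regression and rank-correlation of fitness change on initial fitness
#'
#' The analysis applied to the pooled per-interval pairs of an MA
#' experiment: OLS slope with its 95% confidence interval plus the
#' Spearman rank correlation with a two-sided p-value (exact for fewer
#' than 20 pairs, large-sample approximation otherwise).
#'
#' @param pairs A data.frame with columns `initial` and `change` (as
#'   produced by [change_vs_initial()]), at least 3 rows.
#' @return A list with `slope`, `ci` (length-2), `spearman_rho`, `p_value`,
#'   and the underlying `lm` fit.
#' @export
change_regression <- function(pairs) {
  stopifnot(all(c("initial", "change") %in% names(pairs)))
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  if (stats::sd(pairs$initial) == 0)
    stop("degenerate design: initial fitness is constant")
  fit <- stats::lm(change ~ initial, data = pairs)
  ci <- unname(stats::confint(fit, "initial", level = 0.95))
  ct <- suppressWarnings(
    stats::cor.test(pairs$initial, pairs$change, method = "spearman",
                    exact = nrow(pairs) < 20L))
  list(slope = unname(stats::coef(fit)[2L]),
       ci = as.numeric(ci),
       spearman_rho = unname(ct$estimate),
       p_value = ct$p.value,
       fit = fit)
}
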