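#' Design of a fitness-recovery experiment
#'
#' Large constant effective population size for `total_generations`
#' generations, founders constructed at each of the `starting_fitnesses`,
#' population mean fitness recorded at the `checkpoints`.
#'
#' @param Ne Effective population size (default `3e5`).
#' @param total_generations Length of the experiment (default 240).
#' @param checkpoints Generations at which mean fitness is recorded
#'   (default `c(120, 240)`).
#' @param starting_fitnesses Initial fitnesses of the founders, each in
#'   `(0, 1]` (default `c(0.77, 0.88, 0.99)`, spanning the range of founder
#'   fitness in the experiment).
#' @param replicates Independent populations per starting fitness
#'   (default 10).
#' @param engine `"exact"` (genotype-class Wright-Fisher; default) or
#'   `"fast"` (deterministic frequencies with stochastic establishment;
#'   used at ABC scale, validated against the exact engine).
#' @return An object of class `recovery_design`.
#' @export
recovery_design <- function(Ne = 3e5, total_generations = 240L,
                            checkpoints = c(120L, 240L),
                            starting_fitnesses = c(0.77, 0.88, 0.99),
                            replicates = 10L,
                            engine = c("exact", "fast")) {
  engine <- match.arg(engine)
  checkpoints <- sort(as.integer(checkpoints))
  stopifnot(Ne >= 1, total_generations >= 1, replicates >= 1,
            all(checkpoints >= 1), all(checkpoints <= total_generations),
            all(starting_fitnesses > 0), all(starting_fitnesses <= 1))
  structure(list(Ne = as.numeric(Ne),
                 total_generations = as.integer(total_generations),
                 checkpoints = checkpoints,
                 starting_fitnesses = as.numeric(starting_fitnesses),
                 replicates = as.integer(replicates),
                 engine = engine),
            class = "recovery_design")
}

#' @export
print.recovery_design <- function(x, ...) {
  cat(sprintf("Recovery design: Ne = %g, %d generations, checkpoints %s, W0 in {%s} x %d replicates, engine = %s\n",
              x$Ne, x$total_generations,
              paste(x$checkpoints, collapse = ", "),
              paste(x$starting_fitnesses, collapse = ", "),
              x$replicates, x$engine))
  invisible(x)
}

#' Simulate one recovery population
#'
#' Wright-Fisher dynamics on genotype classes at constant size `Ne`: each
#' generation offspring are multinomially assigned with weights
#' count x fitness, new mutations (Poisson, rate `U` per individual) each
#' found a size-1 class, and extinct classes are pruned. Clonal
#' interference is emergent, never approximated analytically in the exact
#' engine.
#'
#' @param W0 Founder fitness in `(0, 1]`.
#' @param params An [fgm_params()] object.
#' @param design A [recovery_design()] object.
#' @param seed Optional integer seed.
#' @return A data.frame with one row per checkpoint: `W0`, `generation`,
#'   `mean_fitness`, `delta_fitness`.
#' @export
run_recovery <- function(W0, params, design = recovery_design(), seed = NULL) {
  stopifnot(inherits(params, "fgm_params"), inherits(design, "recovery_design"))
  if (!is.null(seed)) set.seed(seed)
  x0 <- make_founder_at_fitness(W0, params)
  meanw <- if (design$engine == "exact") {
    cpp_recovery_exact(x0, params$U, params$sigma, design$Ne,
                       design$total_generations, design$checkpoints)
  } else {
    cpp_recovery_fast(x0, params$U, params$sigma, design$Ne,
                      design$total_generations, design$checkpoints)
  }
  data.frame(W0 = W0, generation = design$checkpoints,
             mean_fitness = meanw, delta_fitness = meanw - W0)
}

#' Simulate a full recovery experiment
#'
#' Runs [run_recovery()] for every starting fitness and replicate of the
#' design.
#'
#' @param params An [fgm_params()] object.
#' @param design A [recovery_design()] object.
#' @param seed Optional integer seed.
#' @return An object of class `recovery_dataset`: a data.frame with columns
#'   `W0`, `replicate`, `generation`, `mean_fitness`, `delta_fitness`.
#' @export
run_recovery_experiment <- function(params, design = recovery_design(),
                                    seed = NULL) {
  stopifnot(inherits(params, "fgm_params"), inherits(design, "recovery_design"))
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(design$starting_fitnesses, function(w0) {
    do.call(rbind, lapply(seq_len(design$replicates), function(r) {
      entry <- run_recovery(w0, params, design)
      entry$replicate <- r
      entry
    }))
  }))
  out <- out[, c("W0", "replicate", "generation", "mean_fitness",
                 "delta_fitness")]
  class(out) <- c("recovery_dataset", "data.frame")
  attr(out, "design") <- design
  attr(out, "params") <- params
  out
}

#' Regression of fitness change on initial fitness per checkpoint
#'
#' Ordinary least squares of `delta_fitness` on `W0` at each recorded
#' checkpoint; the slopes and intercepts at generations 120 and 240 are the
#' four regression summary statistics of the composite summary vector.
#'
#' @param data A `recovery_dataset` (or any data.frame with columns `W0`,
#'   `generation`, `delta_fitness`).
#' @return A data.frame with columns `generation`, `slope`, `intercept`.
#' @export
recovery_slopes <- function(data) {
  stopifnot(all(c("W0", "generation", "delta_fitness") %in% names(data)))
  if (length(unique(data$W0)) < 2L)
    stop("degenerate design: need at least two distinct starting fitnesses")
  gens <- sort(unique(data$generation))
  out <- do.call(rbind, lapply(gens, function(g) {
    sub <- data[data$generation == g, ]
    fit <- stats::lm(delta_fitness ~ W0, data = sub)
    data.frame(generation = g,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]))
  }))
  rownames(out) <- NULL
  out
}

#' Write a recovery dataset as tidy CSV
#'
#' @param data A `recovery_dataset`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_recovery_csv <- function(data, path) {
  stopifnot(inherits(data, "data.frame"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recovery_csv
#' @export
read_recovery_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("recovery_dataset", "data.frame")
  out
}
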