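#' Design of a mutation-accumulation experiment
#'
#' Describes the serial single-cell-bottleneck demography: each cycle the
#' population is crashed to one cell and regrows by doubling for
#' `cycle_generations` generations, so the effective population size of a
#' cycle is taken as `Ne = cycle_generations` (the harmonic-mean convention
#' for periodic bottlenecks). Fitness of the bottlenecked founder is
#' recorded every `record_every` cycles.
#'
#' @param n_lines Number of independent MA lines (default 50).
#' @param cycle_generations Generations of doubling growth per bottleneck
#'   cycle (default 23).
#' @param n_cycles Number of bottleneck cycles (default 50).
#' @param record_every Record fitness every this many cycles (default 10;
#'   must divide `n_cycles`). Use 1 to record every bottleneck, e.g. for
#'   slope-distribution analyses at single-cycle resolution.
#' @param Ne Effective population size used by the drift filter of the fast
#'   engine (default equal to `cycle_generations`).
#' @param engine `"fast"` (drift-filtered focal lineage; default) or
#'   `"exact"` (genotype-class simulation of the full doubling growth;
#'   exponential in `cycle_generations`, use reduced designs).
#' @param selection_on If `FALSE`, every mutation arising on the focal
#'   lineage is retained (fast engine) or offspring are assigned without
#'   fitness weighting (exact engine): the pure mutation-accumulation null.
#' @return An object of class `ma_design`.
#' @export
ma_design <- function(n_lines = 50L, cycle_generations = 23L, n_cycles = 50L,
                      record_every = 10L, Ne = cycle_generations,
                      engine = c("fast", "exact"), selection_on = TRUE) {
  engine <- match.arg(engine)
  stopifnot(n_lines >= 1, cycle_generations >= 1, n_cycles >= 1,
            record_every >= 1, Ne > 0)
  if (n_cycles %% record_every != 0L)
    stop("record_every must divide n_cycles")
  structure(list(n_lines = as.integer(n_lines),
                 cycle_generations = as.integer(cycle_generations),
                 n_cycles = as.integer(n_cycles),
                 record_every = as.integer(record_every),
                 Ne = as.numeric(Ne),
                 engine = engine,
                 selection_on = isTRUE(selection_on)),
            class = "ma_design")
}

#' @export
print.ma_design <- function(x, ...) {
  cat(sprintf("MA design: %d lines, %d cycles of %d generations (Ne = %g), record every %d, engine = %s, selection %s\n",
              x$n_lines, x$n_cycles, x$cycle_generations, x$Ne,
              x$record_every, x$engine, if (x$selection_on) "on" else "off"))
  invisible(x)
}

#' Simulate a mutation-accumulation experiment
#'
#' Runs `n_lines` independent bottleneck lineages under Fisher's geometric
#' model and records the bottlenecked founder's genotypic fitness (ancestor
#' = 1) and carried mutation count at each recorded cycle. The fast engine
#' follows the focal lineage, with candidate mutations arising at rate `U`
#' per generation and retained through the drift filter
#' `min(1, Ne * survival_probability(s, Ne))`; the exact engine simulates
#' the full doubling growth with multinomial selection and samples one cell
#' at each crash.
#'
#' @param params An [fgm_params()] object.
#' @param design An [ma_design()] object.
#' @param seed Optional integer seed; identical seeds replay identical
#'   datasets.
#' @return An object of class `ma_dataset`: list with `fitness` and
#'   `n_mutations` matrices (`n_lines` rows; columns named by recorded
#'   cycle, including cycle 0 where all fitnesses are 1), `cycles`, and the
#'   design and parameters used.
#' @export
run_ma_experiment <- function(params, design = ma_design(), seed = NULL) {
  stopifnot(inherits(params, "fgm_params"), inherits(design, "ma_design"))
  if (!is.null(seed)) set.seed(seed)
  rec <- seq(design$record_every, design$n_cycles, by = design$record_every)
  res <- if (design$engine == "fast") {
    cpp_ma_fast(params$n, params$U, params$sigma, design$n_lines,
                design$n_cycles, design$cycle_generations, design$Ne,
                design$selection_on, as.integer(rec))
  } else {
    cpp_ma_exact(params$n, params$U, params$sigma, design$n_lines,
                 design$n_cycles, design$cycle_generations,
                 design$selection_on, as.integer(rec))
  }
  fitness <- cbind(1, res$fitness)
  n_mut <- cbind(0L, res$n_mutations)
  cycles <- c(0L, rec)
  colnames(fitness) <- colnames(n_mut) <- paste0("cycle", cycles)
  structure(list(fitness = fitness, n_mutations = n_mut, cycles = cycles,
                 design = design, params = params),
            class = "ma_dataset")
}

#' @export
print.ma_dataset <- function(x, ...) {
  last <- x$fitness[, ncol(x$fitness)]
  cat(sprintf("MA dataset: %d lines, recorded at cycles %s\n",
              nrow(x$fitness), paste(x$cycles, collapse = ", ")))
  cat(sprintf("  mean fitness at final checkpoint: %.4f (range %.4f-%.4f)\n",
              mean(last), min(last), max(last)))
  invisible(x)
}

#' Advance one bottleneck cycle from an explicit founder
#'
#' Grows a single founder through one crash-and-regrow cycle and returns
#' the next cycle's founder. With `U = 0` the founder is returned unchanged.
#'
#' @param founder Numeric phenotype vector of the current founder.
#' @param params An [fgm_params()] object.
#' @param design An [ma_design()] object (engine, cycle length, Ne,
#'   selection switch are honoured).
#' @param seed Optional integer seed.
#' @return A list with `x` (next founder's phenotype), `n_mutations`
#'   (mutations gained this cycle relative to `founder`) and `log_fitness`.
#' @export
ma_grow_cycle <- function(founder, params, design = ma_design(), seed = NULL) {
  stopifnot(inherits(params, "fgm_params"), inherits(design, "ma_design"))
  if (length(founder) != params$n)
    stop("founder must have length params$n")
  if (!is.null(seed)) set.seed(seed)
  if (design$engine == "fast") {
    cpp_ma_cycle_fast(founder, params$U, params$sigma,
                      design$cycle_generations, design$Ne,
                      design$selection_on)
  } else {
    cpp_ma_cycle_exact(founder, params$U, params$sigma,
                       design$cycle_generations, design$selection_on)
  }
}

#' Per-interval fitness change versus initial fitness
#'
#' For every line and every pair of consecutive recorded checkpoints
#' (excluding the cycle-0 baseline by default, matching the experimental
#' analysis where each line contributes one point per 10-bottleneck
#' interval), emits the pair (fitness at interval start, fitness change
#' over the interval).
#'
#' @param data An `ma_dataset`.
#' @param include_baseline Include the interval starting at cycle 0
#'   (default `FALSE`: the default design then yields 4 pairs per line).
#' @return A data.frame with columns `line`, `cycle_start`, `initial`,
#'   `change`.
#' @export
change_vs_initial <- function(data, include_baseline = FALSE) {
  stopifnot(inherits(data, "ma_dataset"))
  fit <- data$fitness
  cycles <- data$cycles
  if (!include_baseline) {
    keep <- cycles > 0L
    fit <- fit[, keep, drop = FALSE]
    cycles <- cycles[keep]
  }
  if (ncol(fit) < 2L)
    stop("need at least two recorded checkpoints")
  k <- ncol(fit) - 1L
  out <- data.frame(
    line = rep(seq_len(nrow(fit)), times = k),
    cycle_start = rep(cycles[seq_len(k)], each = nrow(fit)),
    initial = as.vector(fit[, seq_len(k)]),
    change = as.vector(fit[, -1L, drop = FALSE] - fit[, seq_len(k)]))
  out[order(out$line, out$cycle_start), , drop = FALSE]
}

#' Distribution of change-vs-initial slopes over replicate MA datasets
#'
#' Simulates `n_datasets` independent MA datasets and returns each
#' dataset's pooled OLS slope of per-interval fitness change on
#' interval-start fitness. With selection off the distribution is centered
#' at `-U * cycle_generations * record_every * n * sigma^2` (the purely
#' multiplicative decline); selection during growth makes it more negative.
#'
#' @param params An [fgm_params()] object.
#' @param design An [ma_design()] object.
#' @param n_datasets Number of replicate datasets.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_datasets` slopes.
#' @export
ma_slope_distribution <- function(params, design = ma_design(),
                                  n_datasets = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_datasets), function(i) {
    d <- run_ma_experiment(params, design)
    p <- change_vs_initial(d)
    unname(stats::coef(stats::lm(change ~ initial, data = p))[2L])
  }, numeric(1L))
}

#' Write / read an MA dataset as tidy CSV
#'
#' Columns `line`, `cycle`, `fitness`, `n_mutations`; one row per line and
#' recorded cycle.
#'
#' @param data An `ma_dataset`.
#' @param path File path.
#' @return `write_ma_csv()` returns `path` invisibly; `read_ma_csv()`
#'   returns a data.frame in the tidy layout.
#' @export
write_ma_csv <- function(data, path) {
  stopifnot(inherits(data, "ma_dataset"))
  tidy <- data.frame(
    line = rep(seq_len(nrow(data$fitness)), times = length(data$cycles)),
    cycle = rep(data$cycles, each = nrow(data$fitness)),
    fitness = as.vector(data$fitness),
    n_mutations = as.vector(data$n_mutations))
  tidy <- tidy[order(tidy$line, tidy$cycle), ]
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ma_csv
#' @export
read_ma_csv <- function(path) {
  utils::read.csv(path)
}
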