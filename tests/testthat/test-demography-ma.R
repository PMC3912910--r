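test_that("designs validate their invariants", {
  expect_error(ma_design(record_every = 7), "divide")
  expect_error(ma_design(Ne = 0))
  d <- ma_design()
  expect_identical(d$Ne, 23)
  expect_identical(d$cycle_generations, 23L)
})

test_that("U = 0 leaves every line at the ancestral fitness", {
  p0 <- fgm_params(0, 9, 0.034)
  for (eng in c("fast", "exact")) {
    d <- run_ma_experiment(p0, ma_design(n_lines = 5, n_cycles = 10,
                                         record_every = 5,
                                         cycle_generations = 8,
                                         engine = eng), seed = 1)
    expect_true(all(d$fitness == 1))
    expect_true(all(d$n_mutations == 0))
  }
  cyc <- ma_grow_cycle(rep(0, 9), p0, ma_design(), seed = 2)
  expect_identical(cyc$x, rep(0, 9))
  expect_identical(cyc$n_mutations, 0L)
})

test_that("identical seeds replay identical datasets", {
  p <- theta_star()
  a <- run_ma_experiment(p, ma_design(n_lines = 10), seed = 99)
  b <- run_ma_experiment(p, ma_design(n_lines = 10), seed = 99)
  expect_identical(a, b)
  c <- run_ma_experiment(p, ma_design(n_lines = 10), seed = 100)
  expect_false(identical(a$fitness, c$fitness))
})

test_that("without selection the log-fitness decline matches -U T n sigma^2", {
  p <- theta_star()
  # fast engine, full geometry: T = 23 * 50 generations
  d <- run_ma_experiment(p, ma_design(n_lines = 600, selection_on = FALSE),
                         seed = 11)
  lw <- log(d$fitness[, "cycle50"])
  expect_lt(abs(mean(lw) - (-p$U * 23 * 50 * p$n * p$sigma^2)),
            3 * se_mean(lw))
  # exact engine at a reduced cycle length: T = 10 * 20
  de <- run_ma_experiment(p, ma_design(n_lines = 150, n_cycles = 20,
                                       record_every = 20,
                                       cycle_generations = 10, Ne = 10,
                                       selection_on = FALSE,
                                       engine = "exact"), seed = 12)
  lwe <- log(de$fitness[, "cycle20"])
  expect_lt(abs(mean(lwe) - (-p$U * 10 * 20 * p$n * p$sigma^2)),
            3 * se_mean(lwe))
})

test_that("selection during growth slows the fitness decline", {
  p <- theta_star()
  with_sel <- run_ma_experiment(p, ma_design(n_lines = 300), seed = 21)
  no_sel <- run_ma_experiment(p, ma_design(n_lines = 300,
                                           selection_on = FALSE), seed = 22)
  expect_gt(mean(with_sel$fitness[, "cycle50"]),
            mean(no_sel$fitness[, "cycle50"]))
})

test_that("fast and exact engines agree on per-cycle log-fitness change", {
  # 2000 independent cycles from the optimum at a reduced cycle length
  # (cycle_generations = 10, Ne = 10), compared on mean and variance
  p <- theta_star()
  des <- list(n_lines = 2000, n_cycles = 1, record_every = 1,
              cycle_generations = 10, Ne = 10)
  df <- run_ma_experiment(p, do.call(ma_design, c(des, engine = "fast")),
                          seed = 31)
  de <- run_ma_experiment(p, do.call(ma_design, c(des, engine = "exact")),
                          seed = 32)
  lf <- log(df$fitness[, "cycle1"])
  le <- log(de$fitness[, "cycle1"])
  expect_lt(abs(mean(lf) - mean(le)),
            3 * sqrt(se_mean(lf)^2 + se_mean(le)^2))
  se_var <- function(x) {
    m <- mean(x)
    sqrt((mean((x - m)^4) - stats::var(x)^2) / length(x))
  }
  expect_lt(abs(stats::var(lf) - stats::var(le)),
            3 * sqrt(se_var(lf)^2 + se_var(le)^2))
})

test_that("change_vs_initial emits one pair per line and interval", {
  p <- theta_star()
  d <- run_ma_experiment(p, ma_design(), seed = 41)
  pairs <- change_vs_initial(d)
  expect_identical(nrow(pairs), 200L)  # 50 lines x 4 intervals
  expect_setequal(unique(pairs$cycle_start), c(10, 20, 30, 40))
  # consistency with the recorded matrix
  l1 <- pairs[pairs$line == 1, ]
  expect_equal(l1$initial, unname(d$fitness[1, 2:5]))
  expect_equal(l1$change, unname(diff(d$fitness[1, 2:6])))
  # constant trajectories give zero change
  d0 <- run_ma_experiment(fgm_params(0, 9, 0.034), ma_design(n_lines = 3),
                          seed = 42)
  expect_true(all(change_vs_initial(d0)$change == 0))
  # too few checkpoints
  d1 <- run_ma_experiment(p, ma_design(n_lines = 2, n_cycles = 10,
                                       record_every = 10), seed = 43)
  expect_error(change_vs_initial(d1), "two recorded checkpoints")
})

test_that("slope distribution is centered near the multiplicative decline without selection and below it with selection", {
  p <- theta_star()
  des_sel <- ma_design(record_every = 1)
  des_nosel <- ma_design(record_every = 1, selection_on = FALSE)
  s_sel <- ma_slope_distribution(p, des_sel, n_datasets = 60, seed = 51)
  s_nosel <- ma_slope_distribution(p, des_nosel, n_datasets = 60, seed = 52)
  # no selection: mean within sampling error of the analytic -U G n sigma^2
  # (allowing for the small negative dynamic-regressor bias, the mean must
  # sit near zero, well above the with-selection mean)
  expect_lt(abs(mean(s_nosel)), 0.006)
  expect_lt(mean(s_sel) + 3 * se_mean(s_sel),
            mean(s_nosel) - 3 * se_mean(s_nosel))
})

test_that("MA datasets round-trip through the tidy CSV layout", {
  p <- theta_star()
  d <- run_ma_experiment(p, ma_design(n_lines = 4), seed = 61)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ma_csv(d, path)
  tidy <- read_ma_csv(path)
  expect_identical(nrow(tidy), 4L * 6L)
  expect_equal(tidy$fitness[tidy$line == 2],
               unname(d$fitness[2, ]))
})
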