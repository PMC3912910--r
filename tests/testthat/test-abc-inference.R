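test_that("prior draws respect their supports and marginals", {
  spec <- prior_spec()
  th <- sample_prior(spec, 1e5, seed = 1)
  expect_true(all(log10(th$U) >= -3.5 & log10(th$U) <= -0.5))
  expect_true(all(th$n %in% 1:30))
  expect_true(all(th$sigma > 0))
  # discrete uniform on n: each value near frequency 1/30
  freq <- tabulate(th$n, 30) / 1e5
  se <- sqrt((1 / 30) * (29 / 30) / 1e5)
  expect_true(all(abs(freq - 1 / 30) < 3 * se))
  # exponential mean
  expect_lt(abs(mean(th$sigma) - 0.1), 3 * se_mean(th$sigma))
  # log10 U roughly uniform: mean near -2
  expect_lt(abs(mean(log10(th$U)) - (-2)), 3 * se_mean(log10(th$U)))
})

test_that("rejection keeps exactly the closest round(M tol) draws", {
  set.seed(2)
  M <- 500
  theta <- sample_prior(prior_spec(), M)
  stats <- matrix(rnorm(M * 39, sd = rep(c(5, 1), length.out = 39)),
                  nrow = M, ncol = 39,
                  dimnames = list(NULL, summary_statistic_names()))
  obs <- stats[17, ]
  run <- abc_reject(obs, theta, stats, tol = 1 / M)
  expect_identical(nrow(run$accepted), 1L)
  expect_equal(run$accepted$distance, 0)
  expect_equal(run$accepted$U, theta$U[17])

  run10 <- abc_reject(obs, theta, stats, tol = 0.02)
  expect_identical(nrow(run10$accepted), 10L)
  expect_true(!is.unsorted(run10$accepted$distance))
  # accepted distances are the smallest overall: re-run with larger tol
  run50 <- abc_reject(obs, theta, stats, tol = 0.1)
  expect_true(all(run10$accepted$distance <= max(run50$accepted$distance)))

  # MAD standardization makes the accepted set scale-equivariant
  run2 <- abc_reject(2 * obs, theta, 2 * stats, tol = 0.02)
  expect_equal(run2$accepted$U, run10$accepted$U)

  # order of simulations does not matter
  perm <- sample(M)
  run_perm <- abc_reject(obs, theta[perm, ], stats[perm, ], tol = 0.02)
  expect_equal(sort(run_perm$accepted$U), sort(run10$accepted$U))
})

test_that("zero-variance statistics are excluded with a warning", {
  set.seed(3)
  M <- 200
  theta <- sample_prior(prior_spec(), M)
  stats <- matrix(rnorm(M * 39), nrow = M,
                  dimnames = list(NULL, summary_statistic_names()))
  stats[, 4] <- 7  # constant column
  expect_warning(run <- abc_reject(stats[1, ], theta, stats, tol = 0.05),
                 "zero-variance")
  expect_identical(run$excluded, summary_statistic_names()[4])
})

test_that("posterior summaries report medians and central intervals on the right scales", {
  acc <- data.frame(U = rep(0.01, 10), n = rep(9L, 10),
                    sigma = rep(0.034, 10), distance = 1:10)
  run <- structure(list(accepted = acc, M = 1000, tol = 0.01,
                        scale = rep(1, 39), excluded = character(0)),
                   class = "abc_run")
  ps <- posterior_summary(run)
  expect_equal(ps$median, c(0.01, 9, 0.034))
  expect_equal(ps$lower, ps$upper - c(0, 0, 0))
  # n reported on the integer grid
  acc$n <- rep(c(8L, 9L), 5)
  run$accepted <- acc
  expect_true(posterior_summary(run)$median[2] %% 1 == 0)
})

test_that("prediction error adds squared bias and variance", {
  truths <- data.frame(U = c(0.01, 0.02, 0.03), n = c(5, 9, 12),
                       sigma = c(0.02, 0.03, 0.04))
  expect_equal(unname(prediction_error(truths, truths)), c(0, 0, 0))
  shifted <- truths + 0.5
  expect_equal(unname(prediction_error(shifted, truths)), rep(0.25, 3))
  expect_error(prediction_error(truths[1:2, ], truths), "rows")
})

test_that("composite simulation is deterministic and degenerates correctly", {
  a <- simulate_dataset(theta_star(), seed = 12)
  b <- simulate_dataset(theta_star(), seed = 12)
  expect_identical(a, b)
  z <- simulate_dataset(fgm_params(0, 9, 0.034), seed = 13)
  expect_true(all(matrix(unclass(z)[1:35], nrow = 5, byrow = TRUE)[, 7] == 50))
  expect_equal(unname(unclass(z)[36:39]), rep(0, 4))
})

test_that("simulation at the reference parameters concentrates the final counts in the observed bins", {
  sv <- simulate_dataset(theta_star(), seed = 14)
  bot50 <- unclass(sv)[29:35]
  # bulk of the 50 lines between 0.77 and 0.97 after 50 bottlenecks, as in
  # the observed data
  expect_gt(sum(bot50[2:6]), 25)
  expect_lt(sv[["slope_240"]], 0)
})
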