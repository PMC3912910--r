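test_that("fitness landscape has its maximum at the optimum and is isotropic", {
  expect_identical(fgm_fitness(rep(0, 9)), 1)
  expect_equal(fgm_fitness(c(0.1, rep(0, 8))), exp(-0.01))
  # equal norm => equal fitness, regardless of direction
  x1 <- c(0.3, 0.4, 0)
  x2 <- c(0, 0, 0.5)
  expect_equal(fgm_fitness(x1), fgm_fitness(x2))
  expect_error(fgm_fitness(c(0.1, NA)), "finite")
  # strictly decreasing in distance from the optimum
  r <- seq(0, 2, by = 0.25)
  w <- vapply(r, function(ri) fgm_fitness(c(ri, 0)), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("selection coefficients follow the closed form -2 x.d - |d|^2", {
  expect_identical(selection_coefficient(c(0.5, 0.2), c(0, 0)), 0)
  expect_equal(selection_coefficient(c(0.5, 0, 0), c(-0.1, 0, 0)), 0.09)
  expect_error(selection_coefficient(c(1, 2), c(1, 2, 3)), "length")
  # every mutation at the optimum is deleterious
  set.seed(101)
  p <- theta_star()
  d <- draw_mutation(p, n_draws = 1e4)
  s <- apply(d, 1, function(di) selection_coefficient(rep(0, p$n), di))
  expect_true(all(s < 0))
})

test_that("mean log-fitness effect of mutations is -n sigma^2 on every background", {
  p <- theta_star()
  expect_equal(expected_s_at_optimum(p), -9 * 0.034^2)
  expect_equal(round(expected_s_at_optimum(p), 2), -0.01)
  expect_identical(expected_s_at_optimum(fgm_params(0.01, 5, 0)), 0)
  expect_equal(expected_s_at_optimum(fgm_params(0.01, 5, 0.1)), -0.05)

  # Monte-Carlo oracle at backgrounds of fitness 1, 0.9, 0.77
  set.seed(202)
  d <- draw_mutation(p, n_draws = 1e5)
  expect_lt(abs(mean(d)), 3 * se_mean(as.vector(d)))  # per-trait mean 0
  for (W0 in c(1, 0.9, 0.77)) {
    x <- make_founder_at_fitness(W0, p)
    s <- -2 * drop(d %*% x) - rowSums(d^2)
    expect_lt(abs(mean(s) - expected_s_at_optimum(p)), 3 * se_mean(s))
  }
})

test_that("sigma = 0 mutations leave fitness unchanged", {
  p0 <- fgm_params(0.01, 9, 0)
  d <- draw_mutation(p0, n_draws = 10, seed = 1)
  expect_true(all(d == 0))
})

test_that("drift-survival probability matches Kimura's expression and its limits", {
  expect_equal(survival_probability(0, 23), 1 / 23)
  expect_equal(survival_probability(1e-13, 23), 1 / 23)
  expect_equal(survival_probability(0.1, 23),
               (1 - exp(-0.2)) / (1 - exp(-4.6)))
  expect_identical(survival_probability(-1, 1e5), 0)
  # monotone increasing in s
  s <- seq(-0.2, 0.2, by = 0.01)
  expect_true(all(diff(survival_probability(s, 23)) > 0))
  # large-Ne limit: 1 - exp(-2s) for beneficial mutations
  s <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(abs(survival_probability(s, 1e7) / (1 - exp(-2 * s)) - 1)
                  < 1e-4))
})

test_that("DFE sampling with the drift filter behaves as theory predicts", {
  p <- theta_star()
  expect_error(dfe_after_drift(p, 1, 23, 0), "n_draws")
  dfe <- dfe_after_drift(p, 1, 23, 2e4, seed = 303)
  expect_identical(nrow(dfe), 20000L)
  # at the optimum no raw draw is beneficial
  expect_identical(sum(dfe$s > 0), 0L)
  # raw mean matches the closed form
  expect_lt(abs(mean(dfe$s) - expected_s_at_optimum(p)), 3 * se_mean(dfe$s))
  # drift filter enriches for milder mutations
  expect_gt(mean(dfe$s[dfe$survived == 1]), mean(dfe$s))
  # on a degraded background some surviving mutations are compensatory
  dfe2 <- dfe_after_drift(p, 0.77, 23, 2e4, seed = 304)
  expect_gt(mean(dfe2$s > 0), 0)
  expect_gt(mean(dfe2$s[dfe2$survived == 1]), mean(dfe2$s))
})

test_that("pairwise epistasis has mean zero and a symmetric distribution", {
  expect_equal(pairwise_epistasis(c(0, 0), c(1, 0), c(0, 1)), 0)
  cc <- 0.3
  expect_equal(pairwise_epistasis(c(0, 0, 0), c(cc, 0, 0), c(cc, 0, 0)),
               -2 * cc^2)
  # background independence of the closed form -2 d1.d2
  set.seed(404)
  for (i in 1:20) {
    bg <- rnorm(5)
    d1 <- rnorm(5, 0, 0.05)
    d2 <- rnorm(5, 0, 0.05)
    expect_equal(pairwise_epistasis(bg, d1, d2), -2 * sum(d1 * d2))
  }
  # Monte Carlo over 1e5 random pairs: mean 0 within 3 SE, skewness ~ 0
  p <- theta_star()
  set.seed(405)
  d1 <- draw_mutation(p, 1e5)
  d2 <- draw_mutation(p, 1e5)
  eps <- -2 * rowSums(d1 * d2)
  expect_lt(abs(mean(eps)), 3 * se_mean(eps))
  g1 <- mean((eps - mean(eps))^3) / stats::sd(eps)^3
  expect_lt(abs(g1), 0.05)
})

test_that("first-step trait-number estimate inverts the fixed-effect slope", {
  expect_equal(first_step_n_estimate(4 / 13), 9)
  expect_equal(first_step_n_estimate(4 / 7), 3)
  expect_warning(n0 <- first_step_n_estimate(1), "boundary")
  expect_identical(n0, 0)
  expect_error(first_step_n_estimate(0), "slope")
  expect_error(first_step_n_estimate(1.2), "slope")
})

test_that("founders constructed at a target fitness round-trip exactly", {
  p <- theta_star()
  expect_identical(make_founder_at_fitness(1, p), rep(0, 9))
  x <- make_founder_at_fitness(0.77, p)
  expect_equal(x[1], sqrt(-log(0.77)))
  expect_equal(fgm_fitness(x), 0.77)
  expect_equal(fgm_fitness(make_founder_at_fitness(0.99, p)), 0.99,
               tolerance = 1e-12)
  expect_error(make_founder_at_fitness(0, p), "W0")
  expect_error(make_founder_at_fitness(1.01, p), "W0")
})

test_that("parameter objects validate and serialize", {
  expect_error(fgm_params(-1, 9, 0.03))
  expect_error(fgm_params(0.01, 2.5, 0.03))
  p <- theta_star()
  path <- withr::local_tempfile(fileext = ".json")
  write_fgm_params(p, path)
  expect_identical(read_fgm_params(path), p)
})
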