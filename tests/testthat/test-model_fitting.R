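test_that("design rows encode the tied basis (1+PNA, GA, GA^2, GA*PNA, PNA^2)", {
  expect_equal(unname(design_row(40, 0)), c(1, 40, 1600, 0, 0))
  expect_equal(unname(design_row(0, 0)), c(1, 0, 0, 0, 0))
  expect_equal(unname(design_row(30, 7)), c(8, 30, 900, 210, 49))
})

test_that("closed-form fit recovers the shipped coefficients from noise-free grids", {
  for (m in list(chb, hct)) {
    fit <- fit_closed_form(noise_free_grid(m))
    expect_lt(max(abs(unclass(fit$surface) - unclass(m$surface))), 1e-6)
    expect_true(fit$converged)
    expect_identical(fit$method, "closed_form")
    expect_lt(fit$sse, 1e-12)
  }
})

test_that("closed-form fit interpolates a plane tied to (1 + pna)", {
  pts <- data.frame(ga = c(22, 30, 40, 30, 40), pna = c(0, 0, 0, 7, 10))
  data <- grid_dataset(pts$ga, pts$pna, mean = 2 * (1 + pts$pna))
  fit <- fit_closed_form(data)
  expect_equal(unname(unclass(fit$surface)), c(2, 0, 0, 0, 0),
               tolerance = 1e-9)
})

test_that("rank-deficient designs raise an identifiability error naming the direction", {
  # all observations at day 0: the PNA-dependent regressors are degenerate
  data <- grid_dataset(22:42, 0, mean = evaluate_mean(chb, 22:42, 0))
  expect_error(fit_closed_form(data), "rank-deficient")
  expect_error(fit_closed_form(data), "p4|p5")
})

test_that("Levenberg-Marquardt converges to the closed-form solution", {
  grid <- noise_free_grid(chb, layout = default_grid_layout())
  fit_lm0 <- fit_lm(grid)  # zero init
  fit_cf <- fit_closed_form(grid)
  expect_lt(max(abs(unclass(fit_lm0$surface) - unclass(fit_cf$surface))), 1e-6)
  expect_identical(fit_lm0$method, "levenberg_marquardt")
  expect_true(fit_lm0$converged)

  # starting at the truth on exact data is a fixed point
  fit_true <- fit_lm(grid, init = chb$surface)
  expect_lte(fit_true$n_iterations, 2L)
  expect_lt(fit_true$sse, 1e-18)
})

test_that("LM fit on noisy data lands within 3 standard errors of the truth", {
  set.seed(101)
  layout <- full_integer_grid()
  sd <- 0.5
  grid <- generate_grid(chb, layout = layout,
                        noise = noise_spec(sd_mean = sd, seed = 2024))
  fit <- fit_lm(grid)
  # classical OLS standard errors from the design, as the independent yardstick
  X <- design_matrix(layout$ga, layout$pna)
  se <- sqrt(diag(solve(crossprod(X))) * sd^2)
  expect_true(all(abs(unclass(fit$surface) - unclass(chb$surface)) < 3 * se))
})

test_that("LM raises a convergence error carrying the iterate when capped", {
  grid <- generate_grid(chb, noise = noise_spec(0.5, seed = 5))
  err <- tryCatch(fit_lm(grid, max_iter = 1L), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "converge")
  expect_length(err$iterate, 5L)
})

test_that("coefficient RMSE shrinks roughly as 1/sqrt(n) under grid replication", {
  layout1 <- default_grid_layout()
  layout4 <- do.call(rbind, replicate(4, layout1, simplify = FALSE))
  rmse <- function(layout, seeds) {
    errs <- vapply(seeds, function(s) {
      g <- generate_grid(chb, layout = layout, noise = noise_spec(1, seed = s))
      fit <- fit_closed_form(g)
      sqrt(mean((unclass(fit$surface) - unclass(chb$surface))^2))
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  seeds <- 1:60
  ratio <- rmse(layout1, seeds) / rmse(layout4, seeds + 1000)
  expect_gt(ratio, 1.5)  # ideal ratio 2
  expect_lt(ratio, 2.7)
})

test_that("offset estimator returns the pooled mean half-spread", {
  grid <- noise_free_grid(chb)  # percentile columns at exactly mean -/+ 3.76
  expect_equal(estimate_offset(grid), 3.76, tolerance = 1e-12)
  expect_equal(estimate_offset(noise_free_grid(hct)), 10.69, tolerance = 1e-12)

  flat <- grid_dataset(c(30, 35), c(1, 2), mean = c(10, 12),
                       p5 = c(10, 12), p95 = c(10, 12))
  expect_identical(estimate_offset(flat), 0)

  # half-spreads alternating 3 (below) and 5 (above) average to 4
  alt <- grid_dataset(c(30, 35), c(1, 2), mean = c(10, 12),
                      p5 = c(10, 12) - 3, p95 = c(10, 12) + 5)
  expect_identical(estimate_offset(alt), 4)
})

test_that("offset estimator is symmetric in the roles of p5 and p95", {
  set.seed(33)
  lay <- random_layout(30)
  mu <- evaluate_mean(chb, lay$ga, lay$pna)
  lo <- runif(30, 2, 4)
  hi <- runif(30, 2, 4)
  a <- estimate_offset(grid_dataset(lay$ga, lay$pna, mu, mu - lo, mu + hi))
  b <- estimate_offset(grid_dataset(lay$ga, lay$pna, mu, mu - hi, mu + lo))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("offset estimation fills missing means from the fitted surface", {
  lay <- data.frame(ga = c(30, 35, 40), pna = c(2, 5, 9))
  mu <- evaluate_mean(chb, lay$ga, lay$pna)
  grid <- grid_dataset(lay$ga, lay$pna, mean = c(mu[1], NA, NA),
                       p5 = mu - 3.76, p95 = mu + 3.76)
  expect_equal(estimate_offset(grid, chb$surface), 3.76, tolerance = 1e-12)
  expect_error(estimate_offset(grid), "surface")
  no_pct <- grid_dataset(lay$ga, lay$pna, mean = mu)
  expect_error(estimate_offset(no_pct), "no percentile data")
})

test_that("two-stage refit returns surface plus offset and builds a model", {
  grid <- noise_free_grid(hct)
  fit <- fit_reference_model(grid)
  expect_equal(fit$offset, 10.69, tolerance = 1e-12)
  m <- as_reference_model(fit, "Hct")
  expect_equal(unclass(m$surface), unclass(hct$surface), tolerance = 1e-9)
  expect_equal(m$offset, 10.69, tolerance = 1e-12)
  expect_identical(m$unit, "%")
})
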