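test_that("evaluate_mean reproduces hand-computed values for both presets", {
  # chb: -0.3409 + 0.8300*40 - 0.0093*1600 = 17.9791
  expect_equal(evaluate_mean(chb, 40, 0), 17.9791, tolerance = 1e-12)
  expect_equal(evaluate_mean(chb, 30, 7), 14.1500, tolerance = 1e-12)
  # hct: -1.2956 + 2.5369*40 - 0.0300*1600 = 52.1804
  expect_equal(evaluate_mean(hct, 40, 0), 52.1804, tolerance = 1e-12)
  zero <- surface_parameters(0, 0, 0, 0, 0)
  expect_identical(evaluate_mean(zero, 31.4, 15.9), 0)
})

test_that("evaluate_mean agrees with the term-by-term oracle on random points", {
  set.seed(7)
  ga <- runif(1000, 15, 45)
  pna <- runif(1000, 0, 35)
  for (m in list(chb, hct)) {
    got <- evaluate_mean(m$surface, ga, pna)
    want <- oracle_mean(m$surface, ga, pna)
    expect_lt(max(abs(got - want) / abs(want)), 1e-12)
  }
  s <- random_surface()
  expect_equal(evaluate_mean(s, ga, pna), oracle_mean(s, ga, pna),
               tolerance = 1e-12)
})

test_that("non-finite ages are rejected", {
  expect_error(evaluate_mean(chb, NA_real_, 0), "finite")
  expect_error(evaluate_mean(chb, 30, Inf), "finite")
  expect_error(evaluate_band(chb, NaN, 1), "finite")
})

test_that("surface_parameters requires exactly 5 finite values", {
  expect_error(surface_parameters(1, 2, 3, 4, NA), "finite")
  expect_error(surface_parameters(1, 2, 3, 4, Inf), "finite")
  expect_s3_class(surface_parameters(1, 2, 3, 4, 5), "surface_parameters")
})

test_that("evaluate_band is a symmetric constant-width band around the mean", {
  b <- evaluate_band(chb, 40, 0)
  expect_equal(b$mean, 17.9791, tolerance = 1e-12)
  expect_equal(b$p5, 17.9791 - 3.76, tolerance = 1e-12)
  expect_equal(b$p95, 17.9791 + 3.76, tolerance = 1e-12)
  expect_false(b$extrapolated)

  set.seed(11)
  grid <- random_layout(200)
  for (m in list(chb, hct)) {
    b <- evaluate_band(m, grid$ga, grid$pna)
    expect_equal(b$mean - b$p5, b$p95 - b$mean, tolerance = 1e-12)
    expect_equal(b$p95 - b$p5, rep(2 * m$offset, nrow(grid)),
                 tolerance = 1e-12)
  }

  degenerate <- reference_model("cHb", chb$surface, offset = 0)
  b0 <- evaluate_band(degenerate, 35, 10)
  expect_identical(b0$p5, b0$mean)
  expect_identical(b0$p95, b0$mean)
})

test_that("out-of-domain queries are answered but flagged and warned", {
  expect_warning(b <- evaluate_band(chb, 45, 0), "extrapolated")
  expect_true(b$extrapolated)
  expect_equal(b$mean, evaluate_mean(chb, 45, 0))
  # title-vs-methods discrepancy: day 29 is treated as extrapolation
  expect_warning(b29 <- evaluate_band(chb, 40, 29), "extrapolated")
  expect_true(b29$extrapolated)
  expect_silent(evaluate_band(chb, 45, 0, quiet = TRUE))
  expect_false(evaluate_band(chb, 22, 0)$extrapolated)
})

test_that("classification is inclusive at both band edges", {
  obs <- rbind(
    observation(40, 0, "cHb", 13.0, "low"),
    observation(40, 0, "cHb", 17.9791, "mid"),
    observation(40, 0, "cHb", 14.2191, "edge5"),
    observation(40, 0, "cHb", 21.7391, "edge95"),
    observation(40, 0, "cHb", 22.0, "high"))
  cls <- classify(chb, obs)
  expect_equal(as.character(cls$flag),
               c("below", "within", "within", "within", "above"))
})

test_that("classify rejects analyte mismatch and missing columns", {
  obs <- observation(40, 0, "Hct", 50, "x")
  expect_error(classify(chb, obs), "mismatch")
  expect_error(classify(chb, data.frame(ga = 40, pna = 0)), "lack")
})

test_that("partial derivatives match hand arithmetic", {
  d <- partial_derivatives(chb, 22, 0)
  expect_equal(d$d_ga, 0.8300 - 0.0186 * 22, tolerance = 1e-12)  # 0.4208
  d2 <- partial_derivatives(chb, 42, 28)
  expect_equal(d2$d_pna, -0.3409 + 0.0003 * 42 + 0.0116 * 28,
               tolerance = 1e-12)                                 # -0.0035
  expect_lt(d2$d_pna, 0)
  z <- partial_derivatives(surface_parameters(0, 0, 0, 0, 0), 30, 10)
  expect_identical(c(z$d_ga, z$d_pna), c(0, 0))
})

test_that("presets rise with gestational age over the whole domain", {
  grid <- expand.grid(ga = seq(22, 42, by = 0.1), pna = seq(0, 28, by = 0.1))
  for (m in list(chb, hct)) {
    d <- partial_derivatives(m, grid$ga, grid$pna)
    expect_true(all(d$d_ga > 0))
  }
})

test_that("postnatal decline holds everywhere for cHb, and for Hct outside the late-PNA/high-GA corner", {
  grid <- expand.grid(ga = seq(22, 42, by = 0.1), pna = seq(0, 28, by = 0.1))
  d_chb <- partial_derivatives(chb, grid$ga, grid$pna)
  expect_true(all(d_chb$d_pna < 0))
  # Hct: d/dPNA = -1.2956 + 0.0069*GA + 0.0380*PNA changes sign when
  # PNA > (1.2956 - 0.0069*GA)/0.0380, i.e. beyond ~26.5 days at GA 42, so
  # the printed parameters are not monotone in the extreme corner of the
  # domain.
  d_hct <- partial_derivatives(hct, grid$ga, grid$pna)
  boundary <- (1.2956 - 0.0069 * grid$ga) / 0.0380
  expect_true(all((d_hct$d_pna < 0) == (grid$pna < boundary)))
  expect_gt(partial_derivatives(hct, 42, 28)$d_pna, 0)
  # the non-monotone region is a thin sliver of the domain (< 2%)
  expect_lt(mean(d_hct$d_pna >= 0), 0.02)
})

test_that("shipped presets round-trip through JSON serialization bit-exactly", {
  for (m in list(chb, hct)) {
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    expect_identical(load_model(path), m)
  }
})
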