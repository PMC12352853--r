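test_that("collinear data give an exact fit with zero-width intervals", {
  d <- loglinear_xy(2, 1)
  f <- sma_fit(d$x, d$y)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope_ci_low, f$slope_ci_high, tolerance = 1e-12)
  expect_equal(f$intercept_ci_low, f$intercept_ci_high, tolerance = 1e-12)
})

test_that("SMA symmetry and scale invariance", {
  set.seed(7)
  x <- 10^rnorm(100); y <- 10^(0.7 * log10(x) + rnorm(100, 0, 0.1))
  f <- sma_fit(x, y); g <- sma_fit(y, x)
  expect_equal(g$slope, 1 / f$slope)
  # rescaling x shifts only the intercept
  f2 <- sma_fit(1000 * x, y)
  expect_equal(f2$slope, f$slope)
  expect_equal(f2$r_squared, f$r_squared)
  expect_equal(f2$intercept, f$intercept - 3 * f$slope)
  # sign(slope) follows the sample correlation
  yneg <- 10^(-0.7 * log10(x) + rnorm(100, 0, 0.1))
  expect_lt(sma_fit(x, yneg)$slope, 0)
  # CI ordering invariant holds for negative slopes too
  fn <- sma_fit(x, yneg)
  expect_true(fn$slope_ci_low <= fn$slope && fn$slope <= fn$slope_ci_high)
})

test_that("input validation names offending rows", {
  expect_error(sma_fit(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(sma_fit(c(1, -2, 3), c(1, 2, 3)), "rows: 2")
  expect_error(sma_fit(rep(2, 5), 1:5), "zero variance")
  expect_error(sma_fit(1:5, 2:6, ci_level = 1.2), "ci_level")
})

test_that("slope CI attains nominal coverage under the SMA error model", {
  # bivariate error design SMA assumes: x = t + ex, y = b*t + ey with
  # sd(ey)/sd(ex) = b; 200 replicates at n = 200
  b <- 0.75
  cover <- 0
  set.seed(1234)
  for (i in 1:200) {
    t <- rnorm(200, 0, 0.4)
    x <- 10^(t + rnorm(200, 0, 0.05))
    y <- 10^(b * t + rnorm(200, 0, b * 0.05))
    f <- sma_fit(x, y)
    if (f$slope_ci_low <= b && b <= f$slope_ci_high) cover <- cover + 1
  }
  expect_gte(cover, 180)
})

test_that("exponent predictions follow the closed forms", {
  cfs <- predict_exponents(2)
  expect_identical(cfs$model_name, "CFS")
  expect_equal(unname(cfs$exponents),
               c(3 / 4, 2, 1 / 4, 1 / 2, 1 / 3, 2 / 3))
  wbe <- predict_exponents(2 / 3)
  expect_identical(wbe$model_name, "WBE")
  expect_equal(unname(wbe$exponents),
               c(5 / 8, 2 / 3, 3 / 8, 1 / 4, 3 / 5, 2 / 5))
  # alpha = 1 makes L and D interchangeable: D~V and L~V coincide at 1/3
  one <- predict_exponents(1)$exponents
  expect_equal(unname(one["D~V"]), 1 / 3)
  expect_equal(unname(one["L~V"]), 1 / 3)
  # printed CFS-WBE gaps per pair
  gaps <- abs(cfs$exponents - wbe$exponents)
  expect_equal(unname(gaps),
               c(1 / 8, 4 / 3, 1 / 8, 1 / 4, 4 / 15, 4 / 15))
  expect_error(predict_exponents(0), "positive")
})

test_that("model evaluation is absolute slope deviation", {
  mkfit <- function(slope, pair) {
    d <- loglinear_xy(slope)
    sma_fit(d$x, d$y, pair = pair)
  }
  expect_equal(evaluate_model(mkfit(0.756, "SA~V"), predict_exponents(2))$rmse,
               0.006, tolerance = 1e-9)
  expect_equal(evaluate_model(mkfit(2.060, "L~D"), predict_exponents(2 / 3))$rmse,
               1.393, tolerance = 1e-3)
  expect_equal(evaluate_model(mkfit(0.75, "SA~V"), predict_exponents(2))$rmse,
               0, tolerance = 1e-12)
  expect_error(evaluate_model(mkfit(1, "bogus"), predict_exponents(2)),
               "variable pair")
  # pooled RMSE matches a direct computation
  s <- c(1.899, 2.137, 2.054, 2.170)
  expect_equal(model_rmse(s, 2), sqrt(mean((s - 2)^2)))
})

test_that("sma_table produces one row per group and pair", {
  cfg <- simulation_config(mode = "allometric_coupling", n_trees = 2,
                           base_radius = 8, seed = 6)
  dat <- derive_dimensions(simulate_network(cfg))
  tab <- sma_table(dat)
  expect_equal(nrow(tab), 6 * 3)  # all + 2 trees
  expect_setequal(unique(tab$pair), variable_pairs()$pair)
  expect_true(all(tab$slope_ci_low <= tab$slope & tab$slope <= tab$slope_ci_high))
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
  nall <- tab$n[tab$group == "all"]
  expect_true(all(nall == nrow(dat)))
})
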