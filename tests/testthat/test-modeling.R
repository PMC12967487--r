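test_that("noise-free pairs on a line are recovered exactly", {
  l <- c(2, 5, 9, 14, 20, 27)
  pairs <- data.frame(l_mm = l, d_gy = -0.92 * l + 28.45)
  m <- fit_model(pairs, "heart", 10, "left_pmrmrt")
  expect_equal(m$slope, -0.92, tolerance = 1e-12)
  expect_equal(m$intercept, 28.45, tolerance = 1e-12)
  expect_equal(m$r_squared, 1)
  expect_equal(m$p_value, 0)
  expect_equal(m$l_range, range(l))
})

test_that("a flat dose response yields zero slope and zero r-squared", {
  m <- fit_model(data.frame(l_mm = c(1, 4, 9, 16), d_gy = rep(7, 4)),
                 "lung", 50, "left_bcrt")
  expect_equal(m$slope, 0)
  expect_equal(m$r_squared, 0)
})

test_that("simulated fits recover slope and the analytic r-squared", {
  set.seed(88)
  n <- 200; a <- -0.9; b <- 50; sigma <- 2
  l <- runif(n, 0, 30)
  d <- a * l + b + rnorm(n, sd = sigma)
  m <- fit_model(data.frame(l_mm = l, d_gy = d), "lung", 50, "left_pmrmrt")
  # cross-check against the independent stats:: routes
  lmfit <- stats::lm(d ~ l)
  expect_equal(m$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(m$intercept, unname(coef(lmfit)[1]), tolerance = 1e-12)
  expect_equal(m$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)
  ct <- stats::cor.test(l, d)
  expect_equal(m$p_value, ct$p.value, tolerance = 1e-12)
  # recovery at stated tolerances
  se <- summary(lmfit)$coefficients[2, 2]
  expect_lt(abs(m$slope - a), 3 * se)
  r2_expected <- (a^2 * 75) / (a^2 * 75 + sigma^2)  # Var(aL)/(Var(aL)+s^2), L~U(0,30)
  expect_lt(abs(m$r_squared - r2_expected), 0.05)
})

test_that("fitting is order-invariant and affine-equivariant in L", {
  set.seed(5)
  l <- runif(30, 5, 40); d <- -0.5 * l + 20 + rnorm(30, sd = 1)
  m1 <- fit_model(data.frame(l_mm = l, d_gy = d), "lung", 35, "right_bcrt")
  perm <- sample(30)
  m2 <- fit_model(data.frame(l_mm = l[perm], d_gy = d[perm]),
                  "lung", 35, "right_bcrt")
  expect_equal(m1$slope, m2$slope)
  expect_equal(m1$r_squared, m2$r_squared)
  cc <- 2.5; k <- -7
  m3 <- fit_model(data.frame(l_mm = cc * l + k, d_gy = d),
                  "lung", 35, "right_bcrt")
  expect_equal(m3$slope, m1$slope / cc, tolerance = 1e-12)
  expect_equal(m3$r_squared, m1$r_squared, tolerance = 1e-12)
})

test_that("degenerate fits are rejected", {
  expect_error(fit_model(data.frame(l_mm = c(1, 2), d_gy = c(1, 2)),
                         "lung", 50, "left_pmrmrt"), "n >= 3")
  expect_error(fit_model(data.frame(l_mm = rep(4, 5), d_gy = 1:5),
                         "lung", 50, "left_pmrmrt"), "unidentifiable")
})

test_that("predictions evaluate the line, clamp at zero, and flag extrapolation", {
  models <- bundled_models("left_pmrmrt")
  heart10 <- Filter(function(m) m$organ == "heart" && m$x == 10, models)[[1]]
  p <- predict_dx(heart10, 10)
  expect_equal(p$dose_gy, 19.25)
  expect_false(p$clamped)
  lung50_bcrt <- Filter(function(m) m$organ == "lung" && m$x == 50,
                        bundled_models("left_bcrt"))[[1]]
  expect_equal(predict_dx(lung50_bcrt, 0)$dose_gy, 4.99)
  # far beyond the zero crossing the line is clamped with a flag
  expect_warning(pc <- predict_dx(heart10, 100), "clamped")
  expect_equal(pc$dose_gy, 0)
  expect_true(pc$clamped)
  # fitted models carry an L range and flag extrapolation
  mf <- fit_model(data.frame(l_mm = c(5, 10, 15, 20), d_gy = c(40, 35, 30, 25)),
                  "heart", 5, "left_pmrmrt")
  expect_warning(pe <- predict_dx(mf, 30), "extrapolate")
  expect_true(pe$extrapolated)
  expect_false(suppressWarnings(predict_dx(mf, 12))$extrapolated)
})

test_that("the bundled reference models are complete and as published", {
  counts <- vapply(ovhplan:::ovhplan_cohorts,
                   function(ch) length(bundled_models(ch)), numeric(1))
  expect_equal(unname(counts), c(5, 3, 5, 3))  # 16 models in all
  m <- bundled_models("left_pmrmrt")
  heart10 <- Filter(function(x) x$organ == "heart" && x$x == 10, m)[[1]]
  expect_identical(heart10$slope, -0.92)
  expect_identical(heart10$intercept, 28.45)
  expect_identical(heart10$r_squared, 0.70)
  expect_identical(heart10$p_bound, "<0.001")
  rb <- Filter(function(x) x$organ == "lung" && x$x == 25,
               bundled_models("right_bcrt"))[[1]]
  expect_identical(rb$slope, -0.56)
  expect_identical(rb$intercept, 23.87)
  expect_identical(rb$r_squared, 0.68)
  # right-sided cohorts have no heart models
  expect_false(any(vapply(bundled_models("right_pmrmrt"),
                          function(x) x$organ == "heart", logical(1))))
  expect_error(bundled_models("both_sides"), "arg")
})

test_that("models round-trip bit-identically through the JSON format", {
  models <- c(bundled_models("left_pmrmrt"),
              list(fit_model(data.frame(l_mm = c(1, 5, 9, 13), d_gy = c(9, 7, 6, 3)),
                             "lung", 25, "left_pmrmrt")))
  f <- withr::local_tempfile(fileext = ".json")
  write_models_json(models, f)
  back <- read_models_json(f)
  expect_equal(length(back), length(models))
  for (i in seq_along(models)) {
    for (fld in c("slope", "intercept", "r_squared", "p_value", "n", "l_range"))
      expect_identical(back[[i]][[fld]], models[[i]][[fld]])
    expect_identical(back[[i]]$cohort, models[[i]]$cohort)
  }
})

test_that("cohort CSV io validates its schema and flags odd values", {
  tab <- data.frame(patient_id = c("a", "a", "b", "b"),
                    cohort = "left_pmrmrt", organ = "lung",
                    x = c(50, 25, 50, 25),
                    l_mm = c(10, 4, 12, 5), d_gy = c(5, 20, 4.5, 19))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(tab, f)
  expect_equal(read_cohort_csv(f), tab)
  tab$l_mm[1] <- -2
  write_cohort_csv(tab, f)
  expect_warning(read_cohort_csv(f), "negative L")
  expect_error(write_cohort_csv(tab[, 1:3], f), "columns")
})

test_that("cohort fitting refuses mixed strata", {
  tab <- data.frame(patient_id = letters[1:4],
                    cohort = c("left_pmrmrt", "left_pmrmrt", "left_bcrt", "left_bcrt"),
                    organ = "lung", x = 50, l_mm = 1:4, d_gy = 4:1)
  expect_error(fit_cohort_models(tab), "separately")
})
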