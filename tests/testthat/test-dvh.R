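uniform_plan <- function(level = 10, shape = c(8, 8, 8), spacing = c(2, 2, 2)) {
  g <- grid_geometry(shape, spacing = spacing)
  v <- array(FALSE, shape); v[3:6, 3:6, 3:6] <- TRUE
  list(dose = scalar_field(array(level, shape), g, "Gy"),
       mask = structure_mask(v, g, "PTV"), g = g)
}

test_that("a uniform field gives a step DVH with exact metric read-offs", {
  p <- uniform_plan(10)
  dvh <- compute_dvh(p$dose, p$mask)
  expect_equal(dvh$fractions[1], 1)
  expect_equal(dvh$fractions[length(dvh$fractions)], 0)
  expect_true(all(dvh$fractions[dvh$doses <= 10] == 1))
  expect_equal(d_x(dvh, 50), 10, tolerance = dvh$bin_width)
  expect_equal(v_d(dvh, 5), 100)
  expect_equal(v_d(dvh, 20), 0)
  expect_equal(mean_dose(p$dose, p$mask), 10)
})

test_that("a two-level field splits quantiles and mean as expected", {
  g <- grid_geometry(c(10, 10, 2), spacing = c(1, 1, 1))
  vals <- array(0, c(10, 10, 2)); vals[, , 2] <- 20
  dose <- scalar_field(vals, g, "Gy")
  mask <- structure_mask(array(TRUE, c(10, 10, 2)), g, "S")
  dvh <- compute_dvh(dose, mask)
  expect_equal(d_x(dvh, 25), 20, tolerance = dvh$bin_width)
  expect_equal(d_x(dvh, 75), 0, tolerance = dvh$bin_width)
  expect_equal(mean_dose(dose, mask), 10)
  expect_true(all(dvh$fractions[dvh$doses > 0 & dvh$doses <= 20] == 0.5))
})

test_that("D_x is non-increasing in x and inverse to V_d within a bin", {
  set.seed(12)
  g <- grid_geometry(c(12, 12, 6), spacing = c(2, 2, 3))
  dose <- scalar_field(array(rgamma(prod(g$shape), 4, 0.2), g$shape), g, "Gy")
  mask <- structure_mask(array(TRUE, g$shape), g, "S")
  dvh <- compute_dvh(dose, mask)
  xs <- c(2, 10, 35, 50, 75, 98)
  expect_true(all(diff(d_x(dvh, xs)) <= 1e-9))
  for (x in c(20, 35, 60, 80))
    expect_equal(v_d(dvh, d_x(dvh, x)), x, tolerance = 1.5)
  # integrating the cumulative DVH recovers the mean dose
  mid <- (dvh$fractions[-1] + dvh$fractions[-length(dvh$fractions)]) / 2
  expect_equal(sum(mid * diff(dvh$doses)), mean_dose(dose, mask),
               tolerance = dvh$bin_width)
})

test_that("trilinear dose resampling is exact for constant and linear fields", {
  g <- grid_geometry(c(10, 10, 10), spacing = c(2, 2, 2), origin = c(0, 0, 0))
  const <- scalar_field(array(50, g$shape), g, "Gy")
  # identity resample returns bitwise-equal values
  expect_identical(resample_dose(const, g)$values, const$values)
  inner <- grid_geometry(c(8, 8, 8), spacing = c(1.7, 1.7, 1.7),
                         origin = c(2, 2, 2))
  expect_equal(resample_dose(const, inner)$values,
               array(50, inner$shape), tolerance = 1e-12)
  # a linear ramp is reproduced exactly at half spacing
  ax <- ovhplan:::axis_centers(g)
  ramp_vals <- array(rep(2 * ax[[1]], times = 100), g$shape)
  ramp <- scalar_field(ramp_vals, g, "Gy")
  half <- grid_geometry(c(16, 16, 16), spacing = c(1, 1, 1), origin = c(1, 1, 1))
  out <- resample_dose(ramp, half)
  axh <- ovhplan:::axis_centers(half)
  expected <- array(rep(2 * axh[[1]], times = 256), half$shape)
  expect_equal(out$values, expected, tolerance = 1e-12)
  # points outside the source hull get 0
  outside <- grid_geometry(c(4, 4, 4), spacing = c(2, 2, 2), origin = c(100, 0, 0))
  expect_true(all(resample_dose(const, outside)$values == 0))
})

test_that("conformity index follows its closed forms and guards", {
  g <- grid_geometry(c(10, 10, 10), spacing = c(2, 2, 2))
  ptv_v <- array(FALSE, c(10, 10, 10)); ptv_v[3:7, 3:7, 3:6] <- TRUE
  ptv <- structure_mask(ptv_v, g, "PTV")
  # prescription isodose exactly on the PTV -> CI = 1
  vals <- array(0, c(10, 10, 10)); vals[ptv_v] <- 50
  expect_equal(conformity_index(scalar_field(vals, g, "Gy"), ptv, 50), 1)
  # TV_P = 80, V_PTV = 100, V_P = 100 -> CI = 0.64
  v100 <- array(FALSE, c(10, 10, 10)); v100[1:10, 1:10, 1] <- TRUE
  ptv100 <- structure_mask(v100, g, "PTV")
  dose_v <- array(0, c(10, 10, 10))
  dose_v[1:8, 1:10, 1] <- 50   # 80 inside covered
  dose_v[9:10, 1:10, 2] <- 50  # 20 outside covered
  expect_equal(conformity_index(scalar_field(dose_v, g, "Gy"), ptv100, 50), 0.64)
  # isodose covering the PTV plus an equal outside volume -> CI = 0.5
  dose_v2 <- array(0, c(10, 10, 10))
  dose_v2[1:10, 1:10, 1:2] <- 50
  expect_equal(conformity_index(scalar_field(dose_v2, g, "Gy"), ptv100, 50), 0.5)
  expect_error(conformity_index(scalar_field(array(10, c(10, 10, 10)), g, "Gy"),
                                ptv, 50), "isodose region is empty")
})

test_that("homogeneity index is 0 for uniform dose and scales with prescription", {
  p <- uniform_plan(50)
  dvh <- compute_dvh(p$dose, p$mask)
  expect_equal(homogeneity_index(dvh, 50), 0)
  # fixed D2/D98 halves HI when prescription doubles
  hi1 <- homogeneity_index(dvh, 25)
  expect_equal(homogeneity_index(dvh, 50), hi1 / 2)
  expect_error(homogeneity_index(dvh, 0), "positive")
})

test_that("plan evaluation satisfies the D2 >= D95 >= D98 ordering and JSON io", {
  set.seed(9)
  g <- grid_geometry(c(10, 10, 10), spacing = c(2, 2, 2))
  v <- array(FALSE, c(10, 10, 10)); v[3:8, 3:8, 3:8] <- TRUE
  ptv <- structure_mask(v, g, "PTV")
  vals <- array(1, c(10, 10, 10))
  vals[v] <- rnorm(sum(v), 52, 1)
  pq <- evaluate_plan(scalar_field(vals, g, "Gy"), ptv, 50)
  expect_gte(pq$d2, pq$d95); expect_gte(pq$d95, pq$d98)
  expect_equal(pq$hi, (pq$d2 - pq$d98) / 50, tolerance = 1e-9)
  expect_gt(pq$ci, 0); expect_lte(pq$ci, 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan_quality_json(pq, f)
  pq2 <- read_plan_quality_json(f)
  expect_equal(unclass(pq2), unclass(pq))
})

test_that("DVH computation rejects mismatched grids and empty masks", {
  g1 <- grid_geometry(c(6, 6, 6)); g2 <- grid_geometry(c(6, 6, 6), c(2, 2, 2))
  dose <- scalar_field(array(1, c(6, 6, 6)), g1, "Gy")
  v <- array(FALSE, c(6, 6, 6)); v[2, 2, 2] <- TRUE
  expect_error(compute_dvh(dose, structure_mask(v, g2, "S")), "geometry mismatch")
  expect_error(d_x(compute_dvh(dose, structure_mask(v, g1, "S")), 0),
               "percent volume")
  expect_error(v_d(compute_dvh(dose, structure_mask(v, g1, "S")), -1),
               "non-negative")
})
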