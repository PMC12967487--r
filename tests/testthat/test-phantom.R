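# voxel centers of a mask, via the independent oracle helpers
mask_centers <- function(mask) oracle_centers(mask$geometry)[as.vector(mask$voxels), , drop = FALSE]

# boundary voxels of a mask: true voxels with a false 6-neighbor or on the edge
boundary_centers <- function(mask) {
  v <- mask$voxels; sh <- dim(v)
  pad <- array(FALSE, sh + 2L)
  pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)] <- v
  nb <- pad[1:sh[1], 2:(sh[2] + 1), 2:(sh[3] + 1)] &
        pad[3:(sh[1] + 2), 2:(sh[2] + 1), 2:(sh[3] + 1)] &
        pad[2:(sh[1] + 1), 1:sh[2], 2:(sh[3] + 1)] &
        pad[2:(sh[1] + 1), 3:(sh[2] + 2), 2:(sh[3] + 1)] &
        pad[2:(sh[1] + 1), 2:(sh[2] + 1), 1:sh[3]] &
        pad[2:(sh[1] + 1), 2:(sh[2] + 1), 3:(sh[3] + 2)]
  oracle_centers(mask$geometry)[as.vector(v & !nb), , drop = FALSE]
}

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(phantom_spec(seed = 4))
  b <- generate_phantom(phantom_spec(seed = 4))
  expect_identical(a$ptv$voxels, b$ptv$voxels)
  expect_identical(a$heart$voxels, b$heart$voxels)
  expect_identical(a$lungs$voxels, b$lungs$voxels)
  c2 <- generate_phantom(phantom_spec(seed = 5))
  expect_false(identical(a$heart$voxels, c2$heart$voxels))
})

test_that("stated gaps to heart and lung are realized at voxel resolution", {
  spec <- phantom_spec(laterality = "left", ptv_heart_gap_mm = 10,
                       ptv_lung_gap_mm = 3, seed = 2)
  ph <- generate_phantom(spec)
  diag <- voxel_diagonal(spec$grid)
  gap_heart <- min(oracle_min_dist(mask_centers(ph$ptv), boundary_centers(ph$heart)))
  expect_gte(gap_heart, 10 - 1e-9)
  expect_lte(gap_heart, 10 + 2 * diag)
  gap_lung <- min(oracle_min_dist(mask_centers(ph$ptv), boundary_centers(ph$lung_ipsi)))
  expect_gte(gap_lung, 3 - 1e-9)
  expect_lte(gap_lung, 3 + diag)
})

test_that("for right-sided targets the heart sits at much larger OVH distances", {
  left <- generate_phantom(phantom_spec("left", seed = 3))
  right <- generate_phantom(phantom_spec("right", seed = 3))
  ovh_l <- compute_ovh(left$heart, left$ptv)
  ovh_r <- compute_ovh(right$heart, right$ptv)
  for (x in c(10, 50, 90))
    expect_gt(l_x(ovh_r, x), l_x(ovh_l, x) + 5)
  # the closest approach itself moves out
  sd_l <- signed_distance_field(left$ptv)$values
  sd_r <- signed_distance_field(right$ptv)$values
  expect_gt(min(sd_r[right$heart$voxels]), min(sd_l[left$heart$voxels]))
})

test_that("noise-free monotone falloff ties D_x to f(L_x) exactly", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  lin <- dose_model(prescription = 50, kind = "linear", rate = 0.9, noise_sd = 0)
  met <- phantom_metrics(ph, generate_dose(ph, lin))
  expect_equal(met$d_gy, 50 - 0.9 * met$l_mm, tolerance = 0.1)
  expo <- dose_model(prescription = 50, kind = "exponential",
                     half_distance = 15, noise_sd = 0)
  met_e <- phantom_metrics(ph, generate_dose(ph, expo))
  expect_equal(met_e$d_gy, 50 * 2^(-met_e$l_mm / 15), tolerance = 0.2)
})

test_that("a zero-rate falloff yields a uniform prescription field with HI = 0", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  dose <- generate_dose(ph, dose_model(prescription = 50, rate = 0, noise_sd = 0))
  expect_true(all(dose$values == 50))
  pq <- evaluate_plan(dose, ph$ptv, 50)
  expect_equal(pq$hi, 0)
  expect_equal(pq$d2, pq$d98)
})

test_that("dose generation is seeded and truncates noise at zero", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  m <- dose_model(rate = 0.9, noise_sd = 3, seed = 21)
  d1 <- generate_dose(ph, m)
  d2 <- generate_dose(ph, m)
  expect_identical(d1$values, d2$values)
  expect_true(all(d1$values >= 0))
  expect_true(all(d1$values[ph$ptv$voxels] == 50))  # noise applies outside only
  m2 <- m; m2$seed <- 22
  expect_false(identical(d1$values, generate_dose(ph, m2)$values))
})

test_that("structures that cannot fit the grid are rejected", {
  small <- grid_geometry(c(24, 24, 16), spacing = c(2.5, 2.5, 2.5))
  expect_error(generate_phantom(phantom_spec(grid = small)), "exceeds the grid")
})

test_that("cohort generation is reproducible and writes its files", {
  dir <- withr::local_tempdir()
  t1 <- generate_cohort(3, cohort = "left_bcrt", seed = 11,
                        model = dose_model(noise_sd = 0.5),
                        out_dir = file.path(dir, "run1"))
  t2 <- generate_cohort(3, cohort = "left_bcrt", seed = 11,
                        model = dose_model(noise_sd = 0.5),
                        out_dir = file.path(dir, "run2"))
  attr(t1, "params") <- NULL; attr(t2, "params") <- NULL
  expect_identical(t1, t2)
  expect_identical(readLines(file.path(dir, "run1", "cohort.csv")),
                   readLines(file.path(dir, "run2", "cohort.csv")))
  expect_true(file.exists(file.path(dir, "run1", "manifest.json")))
  # left-sided BCRT cohorts carry lung and heart metric pairs
  expect_setequal(unique(t1$organ), c("lung", "heart"))
  expect_equal(nrow(t1), 3 * 5)
})

test_that("a single-phantom cohort cannot support a regression fit", {
  t1 <- generate_cohort(1, cohort = "right_bcrt", seed = 13)
  expect_error(fit_cohort_models(t1), "n >= 3")
})
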