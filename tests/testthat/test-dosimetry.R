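test_that("EQD2 conversion reproduces the closed form and its fixed point", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  s30 <- fractionation_scheme(30)
  expect_equal(eqd2_convert(flat_dose(g, 60), s30)$dose[1, 1, 1], 60,
               tolerance = 1e-13)                       # 2 Gy/fraction fixed point
  expect_equal(eqd2_convert(flat_dose(g, 0), s30)$dose[1, 1, 1], 0)
  # 55 Gy in 20 fractions: 55 * (2.75 + 10) / 12 = 58.4375 exactly
  expect_identical(eqd2_convert(flat_dose(g, 55), fractionation_scheme(20))$dose[1, 1, 1],
                   55 * 12.75 / 12)
  expect_error(fractionation_scheme(0), "positive")
  expect_error(fractionation_scheme(30, alpha_beta = -1), "positive")
})

test_that("EQD2 inflates hypofractionated and deflates hyperfractionated dose", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(4, 4, 4))
  s30 <- fractionation_scheme(30)
  doses <- array(seq(0.5, 80, length.out = 64), c(4, 4, 4))
  eq <- eqd2_convert(dose_grid(doses, g), s30)$dose
  hyper <- doses / 30 < 2; hypo <- doses / 30 > 2
  expect_true(all(eq[hyper] < doses[hyper]))
  expect_true(all(eq[hypo] > doses[hypo]))
  expect_true(all(diff(as.vector(eq)) > 0))  # strictly increasing in D
})

test_that("dose sampling is exact on coincident grids and for constant fields", {
  cs <- tiny_case()
  expect_true(all(sample_dose(flat_dose(cs$occ$grid, 10), cs$occ) == 10))
  got <- sample_dose(cs$dose, cs$occ)
  expect_identical(got, as.numeric(cs$dose$dose[cs$occ$occupancy]))
  empty <- structure_mask(array(FALSE, cs$occ$grid$dims), cs$occ$grid)
  expect_error(sample_dose(cs$dose, empty), "empty")
})

test_that("trilinear sampling reproduces an affine dose field at offset voxel centres", {
  gd <- voxel_grid(c(0, 0, 0), c(2, 2, 2), c(12, 12, 12))
  ax <- grid_axes(gd)
  lin <- outer(outer(rep(0, 12), rep(0, 12), `+`), ax[[3]], `+`)  # D = z Gy
  dose <- dose_grid(array(lin, gd$dims), gd)
  # structure grid offset by half a dose voxel in every direction
  gs <- voxel_grid(c(1, 1, 1), c(2, 2, 2), c(10, 10, 10))
  m <- structure_mask(array(TRUE, gs$dims), gs, "box")
  got <- sample_dose(dose, m)
  want <- mucoshell:::occupied_centers(m)[, 3]
  expect_equal(got, want, tolerance = 1e-9)
  # centres far outside the dose bounding box are an error naming the count
  gout <- voxel_grid(c(100, 100, 100), c(2, 2, 2), c(2, 2, 2))
  mout <- structure_mask(array(TRUE, gout$dims), gout)
  expect_error(sample_dose(dose, mout), "8 structure voxel centres")
})

test_that("DVH reproduces direct counting on known samples", {
  cv <- compute_dvh(rep(50, 100), bin_width = 1)
  expect_true(all(cv$volume_pct[cv$dose_gy <= 50] == 100))
  expect_true(all(cv$volume_pct[cv$dose_gy > 50] == 0))
  cv2 <- compute_dvh(c(10, 20, 30, 40), bin_width = 5)
  expect_equal(cv2$volume_pct[cv2$dose_gy == 25], 50)
  expect_equal(cv2$volume_pct[cv2$dose_gy == 20], 75)  # at-least convention
  expect_error(compute_dvh(numeric(0)), "zero samples")
  expect_error(compute_dvh(c(1, 2), bin_width = 0), "positive")
})

test_that("DVH curves satisfy their invariants over randomised draws", {
  set.seed(42)
  for (rep in 1:25) {
    samples <- rgamma(500, shape = runif(1, 0.5, 4), scale = runif(1, 2, 20))
    bw <- sample(c(0.1, 0.5, 1), 1)
    cv <- compute_dvh(samples, bw)
    expect_equal(cv$volume_pct[1], 100)
    expect_true(all(diff(cv$volume_pct) <= 0))
    expect_true(all(cv$volume_pct >= 0 & cv$volume_pct <= 100))
    expect_equal(cv$volume_pct[nrow(cv)], 0)
    implied_mean <- bw * sum(cv$volume_pct[-nrow(cv)]) / 100
    expect_lt(abs(implied_mean - mean(samples)), bw)
  }
})

test_that("DVH of a union of equal-size disjoint structures averages the parts", {
  set.seed(1)
  a <- runif(300, 0, 50); b <- runif(300, 10, 70)
  cu <- compute_dvh(c(a, b), 0.5)
  al <- mucoshell:::align_dvh(list(compute_dvh(a, 0.5), compute_dvh(b, 0.5), cu))
  expect_equal(rowMeans(al$volume_pct[, 1:2]), al$volume_pct[, 3], tolerance = 1e-12)
})

test_that("dose summary reports mean, max and a deterministic max location", {
  g <- voxel_grid(c(0, 0, 0), c(1, 2, 3), c(3, 3, 3))
  arr <- array(10, c(3, 3, 3)); arr[2, 3, 1] <- 30; arr[1, 1, 2] <- 20
  m <- structure_mask(array(TRUE, c(3, 3, 3)), g, "all")
  s <- summarise_dose(dose_grid(arr, g), m, fractionation_scheme(10))
  # EQD2 with n = 10: d = D/10; max voxel is (2, 3, 1) -> world (1, 4, 0)
  expect_equal(c(s$max_x_mm, s$max_y_mm, s$max_z_mm), c(1, 4, 0))
  expect_lte(s$mean_eqd2_gy, s$max_eqd2_gy)
  expect_equal(s$n_voxels, 27)
  # tied maxima: smallest (i, j, k) lexicographically
  arr2 <- array(0, c(3, 3, 3)); arr2[3, 1, 1] <- 30; arr2[1, 2, 3] <- 30
  s2 <- summarise_dose(dose_grid(arr2, g), m, fractionation_scheme(10))
  expect_equal(c(s2$max_x_mm, s2$max_y_mm, s2$max_z_mm), c(0, 2, 6))  # (1,2,3) wins
})
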