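test_that("distance transform matches brute-force enumeration on anisotropic grids", {
  set.seed(11)
  for (rep in 1:5) {
    g <- voxel_grid(origin = runif(3, -5, 5),
                    spacing = c(0.7, 1.3, 2.1), dims = c(9, 8, 7))
    feat <- array(runif(prod(g$dims)) < 0.08, g$dims)
    if (!any(feat)) feat[1, 1, 1] <- TRUE
    expect_equal(mucoshell:::distance_to_feature(feat, g),
                 brute_distance_mm(feat, g), tolerance = 1e-9)
  }
})

test_that("flat-sheet expansion produces the exact digital slab and converges to 1200 mm^3", {
  # at 0.5 mm the +-1.5 mm band holds exactly 7 centre layers (inclusive
  # tie at the threshold); frozen from lattice counting, not the analytic
  # 20 x 20 x 3 slab, which voxel counting only reaches in the limit
  slab_vol <- function(h) {
    g <- centred_grid(h, c(20 + h, 20 + h, 10 + h))
    sheet <- array(FALSE, g$dims)
    sheet[, , (g$dims[3] + 1) %/% 2] <- TRUE
    msc <- expand_sheet_to_shell(structure_mask(sheet, g, "sheet"), thickness = 3)
    # expansion is purely axial here: assert the set is the exact band
    ax <- grid_axes(g)
    n_layers <- sum(abs(ax[[3]]) <= 1.5 + 1e-12)
    expect_identical(sum(msc$occupancy), as.integer(g$dims[1] * g$dims[2] * n_layers))
    structure_volume(msc) * 1000
  }
  expect_equal(slab_vol(0.5), 41 * 41 * 7 * 0.125)   # lattice oracle
  expect_lt(abs(slab_vol(0.1) / 1200 - 1), 0.05)     # fine-spacing convergence
})

test_that("single-voxel expansion gives the digital 1.5 mm ball, converging to the analytic ball", {
  # enumeration oracle: lattice points with |p| <= 1.5 at spacing h
  ball_count <- function(h) {
    pts <- expand.grid(x = seq(-2, 2, by = h), y = seq(-2, 2, by = h),
                       z = seq(-2, 2, by = h))
    sum(pts$x^2 + pts$y^2 + pts$z^2 <= 1.5^2 + 1e-12)
  }
  expect_identical(ball_count(1), 19L)  # digital ball, radius 1.5, unit grid
  for (h in c(1, 0.25)) {
    g <- centred_grid(h, rep(4 + h, 3))
    s <- array(FALSE, g$dims)
    s[(g$dims[1] + 1) %/% 2, (g$dims[2] + 1) %/% 2, (g$dims[3] + 1) %/% 2] <- TRUE
    b <- expand_sheet_to_shell(structure_mask(s, g, "pt"), thickness = 3)
    expect_identical(sum(b$occupancy), as.integer(ball_count(h)))
  }
  g <- centred_grid(0.25, rep(4.25, 3))
  s <- array(FALSE, g$dims); s[9, 9, 9] <- TRUE
  b <- expand_sheet_to_shell(structure_mask(s, g, "pt"), thickness = 3)
  expect_lt(abs(structure_volume(b) * 1000 / (4 / 3 * pi * 1.5^3) - 1), 0.05)
})

test_that("sheet expansion is a superset of the sheet and warns when under-resolved", {
  g <- centred_grid(1, c(10, 10, 10))
  sheet <- array(TRUE, g$dims)
  m <- structure_mask(sheet, g, "all")
  out <- expand_sheet_to_shell(m, 3)
  expect_true(all(out$occupancy[m$occupancy]))
  expect_error(expand_sheet_to_shell(structure_mask(array(FALSE, g$dims), g), 3),
               "empty")
  thin <- array(FALSE, g$dims); thin[5, 5, 5] <- TRUE
  expect_warning(expand_sheet_to_shell(structure_mask(thin, g), 0.8),
                 "discontinuous")
})

test_that("one-sided expansion clips the wall to the reference solid", {
  g <- centred_grid(0.5, c(10, 10, 10))
  occ <- sphere_mask(g, 4.5)
  sheet <- structure_mask(mucoshell:::boundary_layer(occ$occupancy), g, "sheet")
  inward <- expand_sheet_to_shell(sheet, 2, side = "within", within = occ)
  expect_true(all(occ$occupancy[inward$occupancy] | sheet$occupancy[inward$occupancy]))
  symm <- expand_sheet_to_shell(sheet, 2)
  expect_false(all(occ$occupancy[symm$occupancy]))  # symmetric wall pokes outward
  expect_error(expand_sheet_to_shell(sheet, 2, side = "within"), "within")
})

test_that("inward annulus of a sphere matches the analytic shell volume", {
  g <- centred_grid(1, c(64, 64, 64))
  sph <- sphere_mask(g, 30)
  surf <- derive_occ_surface(sph, 3)
  analytic <- 4 / 3 * pi * (30^3 - 27^3)
  expect_lt(abs(structure_volume(surf) * 1000 / analytic - 1), 0.05)
  expect_true(all(sph$occupancy[surf$occupancy]))  # subset of the solid
})

test_that("inward annulus degenerates correctly for thin solids and full erosion", {
  g <- centred_grid(0.5, c(20, 20, 10))
  slab <- array(FALSE, g$dims)
  slab[, , abs(grid_axes(g)[[3]]) <= 1] <- TRUE  # 2 mm slab
  m <- structure_mask(slab, g, "slab")
  expect_identical(derive_occ_surface(m, 3)$occupancy, m$occupancy)
  # thickness covering the radius plus the digital boundary's half-voxel
  # outward bias recovers the whole solid
  sph <- sphere_mask(g, 6)
  expect_identical(derive_occ_surface(sph, 6.5)$occupancy, sph$occupancy)
  expect_error(derive_occ_surface(structure_mask(array(FALSE, g$dims), g), 3),
               "empty")
})

test_that("a solid touching the grid edge still receives a surface there", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8))
  solid <- structure_mask(array(TRUE, c(8, 8, 8)), g, "block")
  surf <- derive_occ_surface(solid, 3)
  expect_true(surf$occupancy[1, 1, 1])     # corner is within 1 mm of exterior
  expect_false(surf$occupancy[5, 5, 5])    # centre is 4 mm deep
})

test_that("structure volumes follow count times voxel volume", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10))
  occ <- array(TRUE, c(10, 10, 10))
  expect_equal(structure_volume(structure_mask(occ, g)), 1.0)
  expect_equal(structure_volume(structure_mask(array(FALSE, g$dims), g)), 0)
  g2 <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(10, 10, 10))
  expect_equal(structure_volume(structure_mask(occ, g2)), 2.0)
})

test_that("overlap volume is symmetric, bounded, and exact for nested spheres", {
  g <- centred_grid(1, c(64, 64, 64))
  big <- sphere_mask(g, 30)
  small <- sphere_mask(g, 10)
  expect_equal(overlap_volume(big, small), overlap_volume(small, big))
  expect_equal(overlap_volume(big, small), structure_volume(small))  # nesting
  expect_lt(abs(overlap_volume(big, small) * 1000 / (4 / 3 * pi * 1000) - 1), 0.03)
  far <- sphere_mask(g, 5, center = c(25, 25, 25))
  expect_equal(overlap_volume(small, far), 0)
  other <- voxel_grid(c(0, 0, 0), c(2, 2, 2), c(10, 10, 10))
  expect_error(overlap_volume(big, structure_mask(array(TRUE, c(10, 10, 10)), other)),
               "resample")
})

test_that("mask resampling is identity on the same grid and conserves smooth volumes", {
  g <- centred_grid(1, c(60, 60, 60))
  sph <- sphere_mask(g, 20)
  expect_identical(resample_mask(sph, g)$occupancy, sph$occupancy)
  coarse <- centred_grid(2, c(60, 60, 60))
  down <- resample_mask(sph, coarse)
  expect_lt(abs(structure_volume(down) / structure_volume(sph) - 1), 0.1)
  outside <- voxel_grid(c(500, 500, 500), c(1, 1, 1), c(10, 10, 10))
  expect_equal(sum(resample_mask(sph, outside)$occupancy), 0L)
})

test_that("shell constructions are monotone in thickness and annulus never exceeds the solid", {
  set.seed(7)
  g <- centred_grid(1, c(30, 30, 30))
  for (rep in 1:3) {
    blob <- sphere_mask(g, runif(1, 8, 12), center = runif(3, -3, 3))
    sheet <- structure_mask(mucoshell:::boundary_layer(blob$occupancy), g, "sheet")
    s1 <- expand_sheet_to_shell(sheet, 2); s2 <- expand_sheet_to_shell(sheet, 4)
    expect_true(all(s2$occupancy[s1$occupancy]))
    a1 <- derive_occ_surface(blob, 2); a2 <- derive_occ_surface(blob, 4)
    expect_true(all(a2$occupancy[a1$occupancy]))
    expect_lte(structure_volume(a2), structure_volume(blob))
  }
})
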