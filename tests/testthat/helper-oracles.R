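# Shared fixture builders and independent oracles.  Everything is built
# in code at test time; no binary fixtures.

# centred grid with the given isotropic (or length-3) spacing and extent
centred_grid <- function(spacing, extent) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  dims <- as.integer(round(extent / spacing))
  voxel_grid(origin = -(dims - 1) * spacing / 2, spacing = spacing, dims = dims)
}

# digital sphere: voxel centres within `radius` mm of `center`
sphere_mask <- function(grid, radius, center = c(0, 0, 0), name = "sphere") {
  ax <- grid_axes(grid)
  d2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, `+`),
              (ax[[3]] - center[3])^2, `+`)
  structure_mask(d2 <= radius^2, grid, name = name)
}

# brute-force oracle: distance (mm) from every voxel centre to the
# nearest feature-voxel centre, by direct minimisation over all pairs.
# O(n * m); only for tiny grids.
brute_distance_mm <- function(feature, grid) {
  ax <- grid_axes(grid)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  feat <- pts[as.vector(feature), , drop = FALSE]
  out <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(feat) - p)^2))))
  array(out, dim = grid$dims)
}

# uniform-dose grid helper
flat_dose <- function(grid, gy) dose_grid(array(gy, dim = grid$dims), grid)

# a small fully synthetic patient case on a coarse grid: cavity sphere,
# equatorial sheet, PTV sphere, radially decaying dose
tiny_case <- function(dose_fun = NULL, spacing = 2) {
  g <- centred_grid(spacing, c(40, 40, 40))
  occ <- sphere_mask(g, 16, name = "OCC")
  sheet_occ <- occ$occupancy
  sheet_occ[, , ] <- FALSE
  mid <- (g$dims[3] + 1) %/% 2
  sheet_occ[, , mid] <- occ$occupancy[, , mid]
  sheet <- structure_mask(sheet_occ, g, "sheet")
  msc <- expand_sheet_to_shell(sheet, thickness = 4, name = "MSC")
  ptv <- sphere_mask(g, 8, center = c(0, 6, 0), name = "PTV")
  ax <- grid_axes(g)
  r <- sqrt(outer(outer((ax[[1]])^2, (ax[[2]] - 6)^2, `+`), (ax[[3]])^2, `+`))
  dose_arr <- if (is.null(dose_fun)) 60 * exp(-pmax(r - 8, 0)^2 / 200) else dose_fun(g)
  list(occ = occ, sheet = sheet, msc = msc, ptv = ptv,
       dose = dose_grid(array(dose_arr, g$dims), g),
       scheme = fractionation_scheme(30))
}
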