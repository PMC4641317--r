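#' Specify a synthetic oral-cavity phantom
#'
#' Parameters of a seeded, fully synthetic oral-cavity test case: an
#' ellipsoidal cavity (the solid oral-cavity contour, OCC), an interior
#' tongue ellipsoid resting on its floor, the mucosal lining sheet (the
#' cavity wall minus a posterior opening to the oropharynx, plus the
#' superior-facing tongue dorsum), a spherical planning target volume
#' placed medially/posteriorly so that it overlaps the cavity, and a dose
#' distribution at prescription level inside the PTV falling off as a
#' Gaussian of the distance to the PTV surface.  All primitives have
#' closed-form volumes, so every geometric operation has an analytic
#' oracle.
#'
#' The world frame is centred on the cavity: x left-right, y
#' anterior-posterior (+y posterior), z inferior-superior.
#'
#' @param spacing voxel spacing in mm (scalar isotropic or length-3);
#'   default 1; must be at most 2 so that a 3 mm shell is resolvable.
#' @param extent grid extent in mm along each axis; default
#'   `c(120, 120, 100)`.
#' @param cavity_semiaxes mm, default `c(35, 45, 30)`.
#' @param tongue_semiaxes mm, default `c(25, 35, 18)`.
#' @param tongue_offset mm offset of the tongue centre (default
#'   `c(0, 0, -12)`, inferior, resting on the floor of mouth).
#' @param posterior_cap_halfangle degrees, default 40: the cap of the
#'   cavity boundary around +y excluded from the mucosal sheet,
#'   representing the opening to the oropharynx.
#' @param ptv_center,ptv_radius PTV sphere, mm; defaults `c(0, 25, -5)`
#'   and 25.
#' @param prescription_dose Gy total, default 65.
#' @param n_fractions default 30.
#' @param falloff_sigma mm, default 10: dose falloff scale outside the PTV.
#' @param noise_sd Gy, default 0 (off): optional zero-mean Gaussian dose
#'   noise, clipped at 0.
#' @param seed integer RNG seed for the noise stream.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = 1, extent = c(120, 120, 100),
                         cavity_semiaxes = c(35, 45, 30),
                         tongue_semiaxes = c(25, 35, 18),
                         tongue_offset = c(0, 0, -12),
                         posterior_cap_halfangle = 40,
                         ptv_center = c(0, 25, -5), ptv_radius = 25,
                         prescription_dose = 65, n_fractions = 30,
                         falloff_sigma = 10, noise_sd = 0, seed = 0L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spec <- structure(list(
    spacing = as.numeric(spacing), extent = as.numeric(extent),
    cavity_semiaxes = as.numeric(cavity_semiaxes),
    tongue_semiaxes = as.numeric(tongue_semiaxes),
    tongue_offset = as.numeric(tongue_offset),
    posterior_cap_halfangle = as.numeric(posterior_cap_halfangle),
    ptv_center = as.numeric(ptv_center), ptv_radius = as.numeric(ptv_radius),
    prescription_dose = as.numeric(prescription_dose),
    n_fractions = as.integer(n_fractions),
    falloff_sigma = as.numeric(falloff_sigma),
    noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lens <- c(spec$spacing, spec$extent, spec$cavity_semiaxes,
            spec$tongue_semiaxes, spec$ptv_radius, spec$prescription_dose,
            spec$falloff_sigma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths, doses and scales must be positive")
  if (any(spec$spacing > 2))
    stop("spacing must be at most 2 mm so that a 3 mm shell is resolvable")
  if (spec$n_fractions < 1L) stop("n_fractions must be at least 1")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  if (!tongue_inside_cavity(spec))
    stop("tongue ellipsoid is not contained in the cavity ellipsoid")
  invisible(spec)
}

# Containment check of the (offset, axis-aligned) tongue ellipsoid in the
# cavity ellipsoid by dense sampling of the tongue boundary.  Tangency
# (e.g. the tongue resting on the cavity floor) is allowed: the tolerance
# on the cavity's unit quadratic form admits boundary excursions of a few
# hundredths of a millimetre, far below voxel size.
tongue_inside_cavity <- function(spec, tol = 1e-3) {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  ph <- seq(0, pi, length.out = 91)
  sp <- sin(ph); cp <- cos(ph)
  worst <- 0
  for (t in th) {
    x <- spec$tongue_offset[1] + spec$tongue_semiaxes[1] * sp * cos(t)
    y <- spec$tongue_offset[2] + spec$tongue_semiaxes[2] * sp * sin(t)
    z <- spec$tongue_offset[3] + spec$tongue_semiaxes[3] * cp
    f <- (x / spec$cavity_semiaxes[1])^2 + (y / spec$cavity_semiaxes[2])^2 +
      (z / spec$cavity_semiaxes[3])^2
    worst <- max(worst, max(f))
  }
  worst <= 1 + tol
}

# grid centred on the cavity centre (world 0)
phantom_grid <- function(spec) {
  dims <- pmax(1L, as.integer(round(spec$extent / spec$spacing)))
  voxel_grid(origin = -(dims - 1) * spec$spacing / 2,
             spacing = spec$spacing, dims = dims)
}

# per-voxel quadratic form value of an axis-aligned ellipsoid, as a 3-D
# array over the grid
ellipsoid_field <- function(grid, center, semiaxes) {
  ax <- grid_axes(grid)
  ux <- ((ax[[1]] - center[1]) / semiaxes[1])^2
  uy <- ((ax[[2]] - center[2]) / semiaxes[2])^2
  uz <- ((ax[[3]] - center[3]) / semiaxes[3])^2
  outer(outer(ux, uy, `+`), uz, `+`)
}

# interior boundary layer: solid voxels with a face-adjacent non-solid
# (or out-of-grid) neighbour
boundary_layer <- function(solid) {
  d <- dim(solid)
  shift <- function(arr, axis, by) {
    out <- array(FALSE, dim = d)
    n <- d[axis]
    if (by == 1) {
      idx_to <- 1:(n - 1); idx_from <- 2:n
    } else {
      idx_to <- 2:n; idx_from <- 1:(n - 1)
    }
    switch(axis,
           `1` = { out[idx_to, , ] <- arr[idx_from, , ] },
           `2` = { out[, idx_to, ] <- arr[, idx_from, ] },
           `3` = { out[, , idx_to] <- arr[, , idx_from] })
    out
  }
  exterior_neighbour <- array(FALSE, dim = d)
  for (axis in 1:3) for (by in c(1L, -1L))
    exterior_neighbour <- exterior_neighbour | !shift(solid, axis, by)
  solid & exterior_neighbour
}

#' Generate a synthetic oral-cavity phantom case
#'
#' Realises a [phantom_spec()] on its voxel grid: the solid cavity mask
#' (OCC analogue), the one-voxel mucosal lining sheet, the ground-truth
#' mucosal surface contour (3 mm symmetric expansion of the sheet), the
#' PTV sphere, and the dose grid.  Identical spec and seed give a
#' bit-identical case.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_case`: a list with elements
#'   `occ_solid`, `mucosal_sheet`, `msc_truth`, `ptv`
#'   ([structure_mask()]s), `dose` ([dose_grid()]), `scheme`
#'   ([fractionation_scheme()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  grid <- phantom_grid(spec)
  ax <- grid_axes(grid)

  cavity <- ellipsoid_field(grid, c(0, 0, 0), spec$cavity_semiaxes) <= 1
  tongue <- ellipsoid_field(grid, spec$tongue_offset, spec$tongue_semiaxes) <= 1

  # cavity wall sheet, minus the posterior opening (spherical cap about +y)
  wall <- boundary_layer(cavity)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  ycoord <- outer(outer(rep(0, grid$dims[1]), ax[[2]], `+`),
                  rep(0, grid$dims[3]), `+`)
  cos_cap <- cos(spec$posterior_cap_halfangle * pi / 180)
  in_cap <- ycoord >= cos_cap * sqrt(pmax(r2, .Machine$double.eps))
  sheet <- wall & !in_cap

  # superior-facing tongue dorsum (outward normal with positive z)
  zrel <- outer(outer(rep(0, grid$dims[1]), rep(0, grid$dims[2]), `+`),
                ax[[3]] - spec$tongue_offset[3], `+`)
  sheet <- sheet | (boundary_layer(tongue) & zrel > 0)

  sheet_mask <- structure_mask(sheet, grid, name = "mucosal sheet")
  occ <- structure_mask(cavity, grid, name = "OCC")
  msc <- expand_sheet_to_shell(sheet_mask, thickness = 3, name = "MSC")

  # PTV sphere and plateau-plus-Gaussian-falloff dose
  dist_ptv <- sqrt(outer(outer((ax[[1]] - spec$ptv_center[1])^2,
                               (ax[[2]] - spec$ptv_center[2])^2, `+`),
                         (ax[[3]] - spec$ptv_center[3])^2, `+`))
  ptv <- structure_mask(dist_ptv <= spec$ptv_radius, grid, name = "PTV")
  s <- pmax(dist_ptv - spec$ptv_radius, 0)
  dose_vals <- spec$prescription_dose * exp(-s^2 / (2 * spec$falloff_sigma^2))
  if (spec$noise_sd > 0) {
    dose_vals <- dose_vals + with_seed(spec$seed, {
      array(stats::rnorm(length(dose_vals), sd = spec$noise_sd),
            dim = dim(dose_vals))
    })
    dose_vals <- pmax(dose_vals, 0)
  }

  structure(list(occ_solid = occ, mucosal_sheet = sheet_mask, msc_truth = msc,
                 ptv = ptv, dose = dose_grid(dose_vals, grid),
                 scheme = fractionation_scheme(spec$n_fractions),
                 spec = spec),
            class = c("phantom_case", "list"))
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded phantom cohort
#'
#' Draws `n_patients` anatomically jittered variants of a base
#' [phantom_spec()]: cavity and tongue semi-axes scaled by independent
#' uniform factors within +/-10%, the PTV centre shifted uniformly within
#' +/-8 mm per axis, and the PTV radius within +/-5 mm.  Jitters that
#' violate the phantom invariants (e.g. the tongue poking out of the
#' cavity) are redrawn, up to `max_retries` per patient.  The same seed
#' always yields the identical cohort.
#'
#' @param base a [phantom_spec()]; defaults to `phantom_spec()`.
#' @param n_patients number of cases; default 11.
#' @param seed integer seed for the jitter stream.
#' @param max_retries redraw budget per patient before failing.
#' @return list of `phantom_case` objects.
#' @export
generate_cohort <- function(base = phantom_spec(), n_patients = 11, seed = 0L,
                            max_retries = 100L) {
  stopifnot(inherits(base, "phantom_spec"))
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("n_patients must be at least 1")
  specs <- with_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      for (try in seq_len(max_retries)) {
        sp <- base
        sp$cavity_semiaxes <- base$cavity_semiaxes * stats::runif(3, 0.9, 1.1)
        sp$tongue_semiaxes <- base$tongue_semiaxes * stats::runif(3, 0.9, 1.1)
        sp$ptv_center <- base$ptv_center + stats::runif(3, -8, 8)
        sp$ptv_radius <- base$ptv_radius + stats::runif(1, -5, 5)
        sp$seed <- as.integer(sample.int(.Machine$integer.max - 1L, 1))
        ok <- tryCatch({ validate_phantom_spec(sp); TRUE },
                       error = function(e) FALSE)
        if (ok) return(sp)
      }
      stop(sprintf("could not draw a valid jittered spec for patient %d within %d tries",
                   i, max_retries))
    })
  })
  lapply(specs, generate_phantom)
}
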