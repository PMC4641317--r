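#' Define a voxel grid
#'
#' A `voxel_grid` is the geometric frame shared by structure masks and dose
#' grids: a regular, axis-aligned 3-D lattice in world (patient)
#' coordinates.  All lengths are in millimetres.  The centre of voxel
#' `(i, j, k)` (0-based indices) is at `origin + c(i, j, k) * spacing`.
#' Axes follow the usual convention: x runs patient left-right, y
#' anterior-posterior, z inferior-superior.
#'
#' @param origin numeric length-3, world coordinates (mm) of the centre of
#'   voxel `(0, 0, 0)`.
#' @param spacing numeric length-3, voxel size (mm) along each axis; all
#'   components must be positive.
#' @param dims integer length-3, number of voxels along each axis; all at
#'   least 1.
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(origin = c(0, 0, 0), spacing = c(1, 1, 2), dims = c(10, 10, 5))
#' g
#' @export
voxel_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be positive")
  if (any(is.na(dims)) || any(dims < 1L))
    stop("all dims must be >= 1")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Test whether two voxel grids coincide
#'
#' @param a,b `voxel_grid` objects.
#' @param tol absolute tolerance (mm) on origin and spacing.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

#' World coordinates of voxel centres along each axis
#'
#' @param grid a `voxel_grid`.
#' @return list of three numeric vectors (x, y, z centre coordinates, mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a])
}

# volume of one voxel in mm^3
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Create a structure mask
#'
#' A `structure_mask` is a named binary occupancy on a [voxel_grid()]: the
#' container used for the oral-cavity contour (OCC), the mucosal surface
#' contour (MSC), the delineated mucosal sheet, the PTV and derived
#' structures.  A voxel belongs to the structure iff its centre does.
#'
#' @param occupancy logical (or coercible) 3-D array matching `grid$dims`.
#' @param grid a [voxel_grid()].
#' @param name text label for the structure.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, grid, name = "structure") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.null(dim(occupancy)) && !identical(as.integer(dim(occupancy)), grid$dims))
    stop("occupancy dimensions do not match the grid")
  if (length(occupancy) != prod(grid$dims))
    stop("occupancy dimensions do not match the grid")
  occ <- array(as.logical(occupancy), dim = grid$dims)
  if (anyNA(occ)) stop("mask occupancy must be strictly binary (no NA)")
  structure(list(name = as.character(name), grid = grid, occupancy = occ),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d of %d voxels set (%.3f cm^3)\n",
              x$name, sum(x$occupancy), prod(x$grid$dims),
              structure_volume(x)))
  print(x$grid)
  invisible(x)
}

#' Create a dose grid
#'
#' Per-voxel total physical dose in Gy on a [voxel_grid()].  Values must be
#' finite and non-negative.  Use [eqd2_convert()] to express the dose as
#' the equivalent dose in 2 Gy fractions.
#'
#' @param dose numeric 3-D array of doses (Gy) matching `grid$dims`.
#' @param grid a [voxel_grid()].
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(dose, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.null(dim(dose)) && !identical(as.integer(dim(dose)), grid$dims))
    stop("dose dimensions do not match the grid")
  if (length(dose) != prod(grid$dims))
    stop("dose dimensions do not match the grid")
  d <- array(as.numeric(dose), dim = grid$dims)
  bad <- sum(!is.finite(d) | d < 0)
  if (bad > 0)
    stop(sprintf("dose grid contains %d negative or non-finite values", bad))
  structure(list(grid = grid, dose = d), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> dose range [%.3f, %.3f] Gy\n",
              min(x$dose), max(x$dose)))
  print(x$grid)
  invisible(x)
}

#' Define a fractionation scheme
#'
#' The plan-level parameters needed for the EQD2 conversion under the
#' linear-quadratic model: the number of fractions the total dose was
#' delivered in, and the tissue alpha/beta ratio.  The reference dose per
#' fraction is fixed at 2 Gy.
#'
#' @param n_fractions positive integer, number of treatment fractions.
#' @param alpha_beta alpha/beta ratio in Gy; defaults to 10 Gy, typical for
#'   acute-responding tissues such as mucosa.
#' @return an object of class `fractionation_scheme`.
#' @examples
#' fractionation_scheme(n_fractions = 30)
#' @export
fractionation_scheme <- function(n_fractions, alpha_beta = 10) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("n_fractions must be a positive integer")
  if (!is.finite(alpha_beta) || alpha_beta <= 0)
    stop("alpha_beta must be positive")
  structure(list(n_fractions = n_fractions, alpha_beta = as.numeric(alpha_beta),
                 reference_dose_per_fraction = 2),
            class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("<fractionation_scheme> %d fractions, alpha/beta = %g Gy (reference 2 Gy/fraction)\n",
              x$n_fractions, x$alpha_beta))
  invisible(x)
}
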