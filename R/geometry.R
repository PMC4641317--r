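# Distance fields ----------------------------------------------------------

# Euclidean distance (mm) from every voxel centre to the nearest centre of
# a voxel in `feature`, honouring anisotropic spacing.  Exact (separable
# parabola-envelope transform); Inf where `feature` is empty.
distance_to_feature <- function(feature, grid) {
  sq <- edt3d_sq(as.logical(feature), as.integer(grid$dims),
                 as.numeric(grid$spacing))
  d <- sqrt(array(sq, dim = grid$dims))
  d[d > 1e14] <- Inf
  d
}

# Distance (mm) from voxels of `solid` to the nearest exterior voxel
# centre, where "exterior" includes the one-voxel layer just outside the
# grid's bounding box: a solid touching the grid edge still has a surface
# there.  Implemented by padding with exterior before the transform.
distance_to_exterior <- function(solid, grid) {
  dims <- grid$dims
  padded <- array(TRUE, dim = dims + 2L)
  padded[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- !solid
  sq <- edt3d_sq(as.logical(padded), as.integer(dims + 2L),
                 as.numeric(grid$spacing))
  d <- sqrt(array(sq, dim = dims + 2L))
  d[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)]
}

# Construction --------------------------------------------------------------

#' Expand a delineated mucosal sheet into a surface shell
#'
#' Turns a thin delineated sheet (the clinician's single-line mucosal
#' contour, rasterised to voxels) into a wall of tissue of the requested
#' total thickness: the mucosal surface contour (MSC).  By default the
#' expansion is symmetric — every voxel whose centre lies within
#' `thickness / 2` mm of any sheet-voxel centre is included, leaving the
#' delineated line at the wall's mid-surface.  With `side = "within"` the
#' wall instead extends the full `thickness` from the sheet but is clipped
#' to a reference solid, for workflows that expanded the line toward one
#' side only.
#'
#' Distances are Euclidean in millimetres and honour anisotropic voxel
#' spacing; a distance exactly equal to the threshold counts as inside.
#' The result is always a superset of the sheet.
#'
#' @param sheet a non-empty [structure_mask()] forming a thin (locally at
#'   most two-voxel) set.
#' @param thickness total wall thickness in mm; default 3, matching the
#'   mean anatomical mucosal thickness reported in cadaver studies
#'   (3.12 +/- 1.43 mm).
#' @param side `"both"` (symmetric, the default) or `"within"`.
#' @param within for `side = "within"`, the [structure_mask()] the wall is
#'   clipped to (e.g. the solid oral-cavity contour).
#' @param name label for the result.
#' @return a [structure_mask()] on the same grid.
#' @examples
#' g <- voxel_grid(c(0, 0, -5), c(1, 1, 1), c(21, 21, 11))
#' sheet <- array(FALSE, g$dims); sheet[, , 6] <- TRUE
#' msc <- expand_sheet_to_shell(structure_mask(sheet, g, "sheet"), thickness = 3)
#' structure_volume(msc)  # about 21 * 21 * 3 / 1000 cm^3
#' @export
expand_sheet_to_shell <- function(sheet, thickness = 3, side = c("both", "within"),
                                  within = NULL, name = "MSC") {
  stopifnot(inherits(sheet, "structure_mask"))
  side <- match.arg(side)
  if (!any(sheet$occupancy))
    stop("cannot expand an empty sheet")
  if (!is.finite(thickness) || thickness <= 0)
    stop("thickness must be positive")
  if (thickness < max(sheet$grid$spacing))
    warning("shell thickness is smaller than the largest voxel spacing; ",
            "the shell may be discontinuous")
  d <- distance_to_feature(sheet$occupancy, sheet$grid)
  # exact ties at the threshold count as inside; the 1e-9 mm slack keeps
  # that rule robust when the spacing is not binary-representable
  if (side == "both") {
    occ <- d <= thickness / 2 + 1e-9
  } else {
    if (is.null(within) || !inherits(within, "structure_mask"))
      stop("side = \"within\" requires a reference structure_mask in `within`")
    if (!same_grid(sheet$grid, within$grid))
      stop("`within` must be on the same grid as the sheet")
    occ <- (d <= thickness + 1e-9) & (within$occupancy | sheet$occupancy)
  }
  structure_mask(occ | sheet$occupancy, sheet$grid, name = name)
}

#' Derive the inward surface annulus of a solid structure
#'
#' Constructs the "OCC surface": the shell of the solid oral-cavity
#' contour extending `thickness` mm inward from its outer surface.  A
#' voxel of the solid belongs to the annulus iff its Euclidean distance
#' (mm) to the nearest exterior voxel centre is at most `thickness`; this
#' equals the solid minus its mm-accurate erosion by `thickness`.  The
#' region outside the grid's bounding box counts as exterior, so a solid
#' touching the grid edge still receives a surface shell there.  Where the
#' solid is everywhere thinner than `thickness` the result equals the
#' input.
#'
#' @param solid a non-empty [structure_mask()].
#' @param thickness annulus depth in mm; default 3.
#' @param name label for the result.
#' @return a [structure_mask()]; always a non-empty subset of `solid`.
#' @export
derive_occ_surface <- function(solid, thickness = 3, name = "OCC surface") {
  stopifnot(inherits(solid, "structure_mask"))
  if (!any(solid$occupancy))
    stop("cannot derive the surface of an empty solid")
  if (!is.finite(thickness) || thickness <= 0)
    stop("thickness must be positive")
  d <- distance_to_exterior(solid$occupancy, solid$grid)
  # inclusive tie at the threshold, robust to non-representable spacings
  structure_mask(solid$occupancy & (d <= thickness + 1e-9), solid$grid, name = name)
}

# Measurement ---------------------------------------------------------------

#' Volume of a structure
#'
#' Occupied-voxel count times voxel volume (voxel-centre membership, no
#' partial-volume weighting), in cm^3.
#'
#' @param mask a [structure_mask()] (may be empty).
#' @return volume in cm^3.
#' @export
structure_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * voxel_volume_mm3(mask$grid) / 1000
}

#' Overlap volume of two structures
#'
#' Volume (cm^3) of the voxelwise conjunction of two masks on the same
#' grid, e.g. a structure's overlap with the planning target volume.
#' Symmetric, and never larger than either argument's volume.
#'
#' @param a,b [structure_mask()] objects on the same grid; resample one
#'   with [resample_mask()] first if their grids differ.
#' @return overlap volume in cm^3.
#' @export
overlap_volume <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!same_grid(a$grid, b$grid))
    stop("masks are on different grids; resample one onto the other's grid ",
         "with resample_mask() before computing overlap")
  sum(a$occupancy & b$occupancy) * voxel_volume_mm3(a$grid) / 1000
}

#' Resample a mask onto another grid
#'
#' Nearest-neighbour assignment at the target grid's voxel centres in
#' world coordinates (occupancy is never interpolated).  Target voxels
#' whose centre falls outside the source grid are unoccupied.
#'
#' @param mask a [structure_mask()].
#' @param target a [voxel_grid()].
#' @return a [structure_mask()] on `target`.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "structure_mask"), inherits(target, "voxel_grid"))
  if (same_grid(mask$grid, target))
    return(structure_mask(mask$occupancy, target, name = mask$name))
  src <- mask$grid
  idx <- lapply(1:3, function(a) {
    centers <- target$origin[a] + (seq_len(target$dims[a]) - 1) * target$spacing[a]
    i <- as.integer(round((centers - src$origin[a]) / src$spacing[a])) + 1L
    i[i < 1L | i > src$dims[a]] <- NA_integer_
    i
  })
  occ <- array(FALSE, dim = target$dims)
  ok <- list(which(!is.na(idx[[1]])), which(!is.na(idx[[2]])), which(!is.na(idx[[3]])))
  if (all(lengths(ok) > 0)) {
    occ[ok[[1]], ok[[2]], ok[[3]]] <-
      mask$occupancy[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]]]
  }
  structure_mask(occ, target, name = mask$name)
}
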