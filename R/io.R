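#' Read a structure mask from NIfTI
#'
#' Reads a 3-D NIfTI volume and interprets it as a binary structure mask:
#' occupancy is true exactly where the stored voxel value is non-zero.
#' The voxel grid (origin, spacing) is taken from the NIfTI affine.  Only
#' axis-aligned grids with positive spacing are supported; oblique or
#' axis-permuting affines are rejected rather than resampled, so that all
#' downstream geometry stays exact.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param name structure label; defaults to the file name without extension.
#' @return a [structure_mask()].
#' @seealso [write_mask()]
#' @export
read_mask <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  img <- read_nifti_checked(path)
  structure_mask(as.array(img) != 0, grid_from_affine(RNifti::xform(img), dim(img)),
                 name = name)
}

#' Write a structure mask to NIfTI
#'
#' Occupancy is stored as unsigned 8-bit integers (0/1) with a diagonal
#' affine carrying the grid origin and spacing, so a write/read round-trip
#' is bit-exact.
#'
#' @param mask a [structure_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  write_nifti_volume(array(as.integer(mask$occupancy), dim = mask$grid$dims),
                     mask$grid, path, datatype = "uint8")
  invisible(path)
}

#' Read a dose grid from NIfTI
#'
#' Reads a 3-D NIfTI volume of per-voxel total physical dose in Gy.
#' Negative values are rejected with an error naming how many voxels
#' offend; the grid is taken from the affine as in [read_mask()].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [dose_grid()].
#' @seealso [write_dose()]
#' @export
read_dose <- function(path) {
  img <- read_nifti_checked(path)
  vals <- as.array(img)
  bad <- sum(!is.finite(vals) | vals < 0)
  if (bad > 0)
    stop(sprintf("dose volume '%s' contains %d negative or non-finite values",
                 path, bad))
  dose_grid(vals, grid_from_affine(RNifti::xform(img), dim(img)))
}

#' Write a dose grid to NIfTI
#'
#' Doses are stored as 32-bit floats, so a round-trip preserves values to
#' single precision (about 1e-7 relative).
#'
#' @param dose a [dose_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_dose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  write_nifti_volume(dose$dose, dose$grid, path, datatype = "float")
  invisible(path)
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read NIfTI '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s' is %d-D; only 3-D volumes are supported",
                 path, length(dim(img))))
  img
}

# Extract origin/spacing from a NIfTI affine; reject anything that is not
# a positive diagonal (axis-aligned, no flips or permutations).
grid_from_affine <- function(affine, dims, tol = 1e-6) {
  m <- affine[1:3, 1:3]
  offdiag <- m; diag(offdiag) <- 0
  if (max(abs(offdiag)) > tol || any(diag(m) <= 0))
    stop("only axis-aligned grids with positive spacing are supported; ",
         "oblique or flipped affines are rejected, not resampled")
  voxel_grid(origin = affine[1:3, 4], spacing = diag(m), dims = dims)
}

write_nifti_volume <- function(arr, grid, path, datatype) {
  img <- RNifti::asNifti(arr)
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  # sform only: the quaternion form cannot carry the scaling exactly
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
}

#' Write a per-structure metrics report
#'
#' Serialises the geometric and dosimetric comparison quantities — one row
#' per structure with its volume, PTV-overlap volume and mean/maximum EQD2
#' — to CSV.  Numbers are printed with at least four significant figures;
#' output is byte-deterministic for identical input.
#'
#' @param rows data frame with columns `structure`, `volume_cm3`,
#'   `ptv_overlap_cm3`, `mean_eqd2_gy`, `max_eqd2_gy` (zero rows allowed).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(rows, path) {
  required <- c("structure", "volume_cm3", "ptv_overlap_cm3",
                "mean_eqd2_gy", "max_eqd2_gy")
  missing <- setdiff(required, names(rows))
  if (length(missing) > 0)
    stop("metrics records lack required fields: ", paste(missing, collapse = ", "))
  rows <- as.data.frame(rows)[, required, drop = FALSE]
  out <- rows
  for (col in required[-1]) out[[col]] <- fmt_sig(rows[[col]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# format with >= 4 significant figures (fixed notation, trailing zeros kept)
fmt_sig <- function(x, digits = 4) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    formatC(v, digits = digits, format = "fg", flag = "#")
  }, character(1))
}
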