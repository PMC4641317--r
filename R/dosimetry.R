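#' Convert physical dose to EQD2
#'
#' Re-expresses a per-voxel total physical dose D as the equivalent dose
#' in 2 Gy fractions under the linear-quadratic model,
#' \deqn{EQD2 = D \frac{d + \alpha/\beta}{2 + \alpha/\beta},}
#' where the per-voxel dose per fraction is `d = D / n_fractions`.  The
#' whole plan shares one fraction count, so `d` varies across voxels with
#' D.  The conversion is the identity exactly where `d` is 2 Gy,
#' increases doses delivered at more than 2 Gy per fraction, and decreases
#' those delivered at less.
#'
#' @param dose a [dose_grid()] of total physical dose (Gy).
#' @param scheme a [fractionation_scheme()].
#' @return a [dose_grid()] of EQD2 on the identical grid.
#' @examples
#' g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
#' d <- dose_grid(array(55, c(2, 2, 2)), g)
#' eqd2_convert(d, fractionation_scheme(20))$dose[1]  # 58.4375
#' @export
eqd2_convert <- function(dose, scheme) {
  stopifnot(inherits(dose, "dose_grid"), inherits(scheme, "fractionation_scheme"))
  d_per_fx <- dose$dose / scheme$n_fractions
  ref <- scheme$reference_dose_per_fraction
  dose_grid(dose$dose * (d_per_fx + scheme$alpha_beta) / (ref + scheme$alpha_beta),
            dose$grid)
}

#' Sample dose values within a structure
#'
#' Returns one dose value (Gy) per occupied voxel of the structure.  When
#' the structure and dose grids coincide the stored voxel values are read
#' directly; otherwise the dose is interpolated trilinearly at the
#' structure's voxel centres in world coordinates (dose is smooth, so
#' interpolation is appropriate; occupancy never is).  Structure voxel
#' centres falling outside the dose grid's bounding box (voxel centres
#' plus a half-voxel margin) are an error reporting how many fall outside.
#'
#' @param dose a [dose_grid()].
#' @param structure a non-empty [structure_mask()].
#' @return numeric vector of doses, one per occupied voxel, in array
#'   (column-major) voxel order.
#' @export
sample_dose <- function(dose, structure) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structure, "structure_mask"))
  if (!any(structure$occupancy))
    stop("cannot sample dose in an empty structure")
  if (same_grid(dose$grid, structure$grid))
    return(as.numeric(dose$dose[structure$occupancy]))
  pts <- occupied_centers(structure)
  interp_trilinear(dose, pts)
}

# world coordinates (n x 3, mm) of a mask's occupied voxel centres, in
# column-major voxel order
occupied_centers <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)  # 1-based, column-major order
  g <- mask$grid
  sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
}

interp_trilinear <- function(dose, pts) {
  g <- dose$grid
  # continuous 0-based index coordinates
  u <- sweep(sweep(pts, 2, g$origin, `-`), 2, g$spacing, `/`)
  outside <- rowSums(u < -0.5 | u > matrix(g$dims - 0.5, nrow(u), 3, byrow = TRUE)) > 0
  if (any(outside))
    stop(sprintf("%d structure voxel centres lie outside the dose grid's bounding box",
                 sum(outside)))
  # clamp the half-voxel margin onto the centre hull (constant extrapolation)
  for (a in 1:3) u[, a] <- pmin(pmax(u[, a], 0), g$dims[a] - 1)
  i0 <- pmax(pmin(floor(u), matrix(g$dims - 2, nrow(u), 3, byrow = TRUE)), 0)
  i1 <- pmin(i0 + 1, matrix(g$dims - 1, nrow(u), 3, byrow = TRUE))
  f <- u - i0
  v <- numeric(nrow(u))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx == 1) f[, 1] else 1 - f[, 1]) *
         (if (cy == 1) f[, 2] else 1 - f[, 2]) *
         (if (cz == 1) f[, 3] else 1 - f[, 3])
    ii <- cbind(if (cx == 1) i1[, 1] else i0[, 1],
                if (cy == 1) i1[, 2] else i0[, 2],
                if (cz == 1) i1[, 3] else i0[, 3]) + 1L
    v <- v + w * dose$dose[ii]
  }
  v
}

#' Compute a cumulative dose-volume histogram
#'
#' Builds the cumulative, relative DVH of a set of dose samples: for each
#' point D on a fixed-step dose axis, the percentage of the structure's
#' volume receiving at least D.  The axis runs from 0 Gy in `bin_width`
#' steps up to the first multiple of `bin_width` strictly above the
#' maximum sample, so the curve always reaches 0%.
#'
#' @param samples non-empty numeric vector of per-voxel doses (Gy), e.g.
#'   from [sample_dose()].
#' @param bin_width dose-axis step in Gy; default 0.1, fine enough that
#'   binning error is negligible for mean-dose work.
#' @return a tibble of class `dvh_curve` with columns `dose_gy` and
#'   `volume_pct`; `volume_pct` is non-increasing, starts at 100 and ends
#'   at 0.
#' @export
compute_dvh <- function(samples, bin_width = 0.1) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("cannot compute a DVH from zero samples")
  if (anyNA(samples) || any(samples < 0)) stop("dose samples must be non-negative")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be positive")
  n_bins <- floor(max(samples) / bin_width) + 1L
  axis <- (0:n_bins) * bin_width
  s <- sort(samples)
  # count of samples >= a  =  n - #(samples < a)
  at_least <- length(s) - findInterval(axis, s, left.open = TRUE)
  tibble::new_tibble(
    list(dose_gy = axis, volume_pct = 100 * at_least / length(s)),
    class = "dvh_curve")
}

#' Summarise the dose to a structure
#'
#' Converts the dose to EQD2, samples it within the structure, and
#' reports the mean and maximum EQD2 together with the world coordinates
#' of the maximum-dose structure voxel.  Ties at the maximum are broken
#' deterministically by the smallest `(i, j, k)` voxel index in
#' lexicographic order.
#'
#' @param dose a [dose_grid()] of physical dose.
#' @param structure a non-empty [structure_mask()].
#' @param scheme a [fractionation_scheme()].
#' @return a one-row tibble: `structure`, `mean_eqd2_gy`, `max_eqd2_gy`,
#'   `max_x_mm`, `max_y_mm`, `max_z_mm`, `n_voxels`.
#' @export
summarise_dose <- function(dose, structure, scheme) {
  eq <- eqd2_convert(dose, scheme)
  samples <- sample_dose(eq, structure)
  idx <- which(structure$occupancy, arr.ind = TRUE)
  # which() is column-major, i.e. already lexicographic in (k, j, i) from
  # the slowest axis; for ties on the smallest (i, j, k) order explicitly
  best <- order(-samples, idx[, 1], idx[, 2], idx[, 3])[1]
  g <- structure$grid
  loc <- unname(g$origin + (idx[best, ] - 1) * g$spacing)
  tibble::tibble(
    structure = structure$name,
    mean_eqd2_gy = mean(samples),
    max_eqd2_gy = samples[best],
    max_x_mm = loc[1], max_y_mm = loc[2], max_z_mm = loc[3],
    n_voxels = length(samples))
}

#' @rdname autoplot.dvh_curve
#' @export
plot_dvh <- function(curve, ...) autoplot.dvh_curve(curve, ...)

#' Plot a DVH curve
#'
#' @param object,curve a `dvh_curve` from [compute_dvh()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy, y = .data$volume_pct)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "EQD2 (Gy)", y = "Volume (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
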