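#' Percent reduction in mean dose
#'
#' The headline per-patient comparison: the percentage by which the mean
#' mucosal dose falls when the mucosal surface contour (MSC) replaces the
#' solid oral-cavity contour (OCC) as the mucosa surrogate, relative to
#' the OCC baseline.  Negative when the MSC mean exceeds the OCC mean.
#'
#' @param mean_occ mean dose over the OCC (Gy); must be positive.
#' @param mean_msc mean dose over the MSC (Gy).
#' @return percent reduction, `100 * (mean_occ - mean_msc) / mean_occ`.
#' @examples
#' percent_reduction(50, 40)  # 20
#' @export
percent_reduction <- function(mean_occ, mean_msc) {
  if (!all(is.finite(mean_occ)) || any(mean_occ <= 0))
    stop("mean_occ must be positive to define a percent reduction")
  100 * (mean_occ - mean_msc) / mean_occ
}

#' Cohort median and range of reductions
#'
#' @param reductions non-empty numeric vector of per-patient percent
#'   reductions.
#' @return a one-row tibble with `median`, `min`, `max` (standard median,
#'   midpoint interpolation for even counts).
#' @export
cohort_reduction_stats <- function(reductions) {
  reductions <- as.numeric(reductions)
  if (length(reductions) == 0 || anyNA(reductions))
    stop("reductions must be a non-empty numeric vector without NA")
  tibble::tibble(median = stats::median(reductions),
                 min = min(reductions), max = max(reductions))
}

# Re-evaluate dvh_curve tibbles on a shared axis running from 0 to the
# global maximum.  All curves must share one bin width; cumulative curves
# are exact step functions of their samples, so extension with 0% beyond
# each curve's own axis is exact, not interpolation.
align_dvh <- function(curves) {
  stopifnot(length(curves) > 0)
  widths <- vapply(curves, function(cv) {
    stopifnot(inherits(cv, "dvh_curve"))
    cv$dose_gy[2] - cv$dose_gy[1]
  }, numeric(1))
  if (diff(range(widths)) > 1e-9)
    stop("all DVH curves must share the same bin width to be aligned")
  n <- max(vapply(curves, nrow, integer(1)))
  axis <- (seq_len(n) - 1) * widths[1]
  mat <- vapply(curves, function(cv) c(cv$volume_pct, rep(0, n - nrow(cv))),
                numeric(n))
  list(axis = axis, volume_pct = mat)
}

#' Pointwise median DVH with range envelope
#'
#' Aggregates per-patient DVH curves into the cohort display used for
#' mucosal dose reporting: at every point of a common dose axis
#' (0 Gy to the cohort-wide maximum), the pointwise median across
#' patients plus the min and max envelope.  Each output curve is itself a
#' valid cumulative DVH (non-increasing, within [0, 100]).
#'
#' @param curves non-empty list of `dvh_curve` tibbles sharing one bin
#'   width (see [compute_dvh()]).
#' @return a tibble of class `dvh_envelope` with columns `dose_gy`,
#'   `vol_median`, `vol_min`, `vol_max`.
#' @export
median_dvh <- function(curves) {
  if (length(curves) == 0) stop("median_dvh needs at least one curve")
  al <- align_dvh(curves)
  tibble::new_tibble(
    list(dose_gy = al$axis,
         vol_median = apply(al$volume_pct, 1, stats::median),
         vol_min = apply(al$volume_pct, 1, min),
         vol_max = apply(al$volume_pct, 1, max)),
    class = "dvh_envelope")
}

#' Compare OCC and MSC dosimetry for one patient
#'
#' Runs the full per-patient comparison: EQD2 mean doses over the solid
#' oral-cavity contour (OCC) and the mucosal surface contour (MSC), the
#' percent mean-dose reduction, structure volumes (OCC, OCC surface, MSC),
#' PTV overlap volumes, and whether the OCC maximum-EQD2 voxel lies
#' inside the PTV and inside the MSC.  The dose comparison pairs the MSC
#' against the full solid OCC; the OCC-surface annulus enters the
#' geometric comparison only.
#'
#' @param occ,msc non-empty [structure_mask()] objects on a common grid.
#' @param occ_surface the inward annulus from [derive_occ_surface()];
#'   derived from `occ` (3 mm) when `NULL`.
#' @param ptv the planning target volume mask.
#' @param dose a [dose_grid()] of physical dose.
#' @param scheme a [fractionation_scheme()].
#' @param patient identifier for the output row.
#' @return a one-row tibble (see field list above).
#' @export
build_patient_comparison <- function(occ, msc, occ_surface = NULL, ptv, dose,
                                     scheme, patient = "patient") {
  if (is.null(occ_surface)) occ_surface <- derive_occ_surface(occ, 3)
  s_occ <- summarise_dose(dose, occ, scheme)
  s_msc <- summarise_dose(dose, msc, scheme)
  max_pt <- c(s_occ$max_x_mm, s_occ$max_y_mm, s_occ$max_z_mm)
  tibble::tibble(
    patient = as.character(patient),
    mean_occ = s_occ$mean_eqd2_gy,
    mean_msc = s_msc$mean_eqd2_gy,
    reduction_pct = percent_reduction(s_occ$mean_eqd2_gy, s_msc$mean_eqd2_gy),
    occ_max_in_ptv = point_in_mask(max_pt, ptv),
    occ_max_in_msc = point_in_mask(max_pt, msc),
    vol_occ = structure_volume(occ),
    vol_occ_surface = structure_volume(occ_surface),
    vol_msc = structure_volume(msc),
    overlap_occ_ptv = overlap_volume(occ, ptv),
    overlap_msc_ptv = overlap_volume(msc, ptv))
}

# does a world point (mm) fall in an occupied voxel of the mask?
point_in_mask <- function(pt, mask) {
  g <- mask$grid
  i <- as.integer(round((pt - g$origin) / g$spacing)) + 1L
  if (any(i < 1L) || any(i > g$dims)) return(FALSE)
  mask$occupancy[i[1], i[2], i[3]]
}

#' Compare OCC and MSC dosimetry across a cohort
#'
#' Applies [build_patient_comparison()] to every case of a cohort and
#' aggregates: the median and range of the per-patient percent mean-dose
#' reductions, and the cohort median DVH with range envelopes for both
#' contouring approaches.
#'
#' @param cases list of cases; each case is a list (or
#'   `phantom_case`) with elements `occ` (or `occ_solid`), `msc` (or
#'   `msc_truth`), `ptv`, `dose`, `scheme`, and optionally `occ_surface`
#'   and `patient`.
#' @param bin_width DVH bin width in Gy (default 0.1).
#' @return an object of class `cohort_comparison`: a list with `patients`
#'   (one tibble row per case), `reduction` (median/min/max tibble), and
#'   `dvh` (long tibble of `dvh_envelope` rows for OCC and MSC).  Use
#'   [tidy.cohort_comparison()], [glance.cohort_comparison()] and
#'   [autoplot.cohort_comparison()] to extract and display.
#' @export
compare_cohort <- function(cases, bin_width = 0.1) {
  if (length(cases) == 0) stop("cohort is empty")
  rows <- vector("list", length(cases))
  occ_curves <- msc_curves <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    occ <- cs$occ %||% cs$occ_solid
    msc <- cs$msc %||% cs$msc_truth
    if (is.null(occ) || is.null(msc))
      stop(sprintf("case %d lacks an OCC or MSC mask", i))
    id <- cs$patient %||% sprintf("P%02d", i)
    rows[[i]] <- build_patient_comparison(
      occ = occ, msc = msc, occ_surface = cs$occ_surface, ptv = cs$ptv,
      dose = cs$dose, scheme = cs$scheme, patient = id)
    eq <- eqd2_convert(cs$dose, cs$scheme)
    occ_curves[[i]] <- compute_dvh(sample_dose(eq, occ), bin_width)
    msc_curves[[i]] <- compute_dvh(sample_dose(eq, msc), bin_width)
  }
  patients <- dplyr::bind_rows(rows)
  env <- dplyr::bind_rows(
    dplyr::mutate(median_dvh(occ_curves), structure = "OCC", .before = 1),
    dplyr::mutate(median_dvh(msc_curves), structure = "MSC", .before = 1))
  structure(list(patients = patients,
                 reduction = cohort_reduction_stats(patients$reduction_pct),
                 dvh = tibble::as_tibble(env)),
            class = "cohort_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d patients\n", nrow(x$patients)))
  cat(sprintf("  mean-dose reduction with MSC: median %.1f%% (range %.1f-%.1f%%)\n",
              x$reduction$median, x$reduction$min, x$reduction$max))
  cat(sprintf("  OCC max inside PTV: %d/%d; OCC max inside MSC: %d/%d\n",
              sum(x$patients$occ_max_in_ptv), nrow(x$patients),
              sum(x$patients$occ_max_in_msc), nrow(x$patients)))
  invisible(x)
}

#' Tidy a cohort comparison
#'
#' @param x a `cohort_comparison` from [compare_cohort()].
#' @param ... unused.
#' @return the per-patient tibble (one row per case).
#' @export
tidy.cohort_comparison <- function(x, ...) x$patients

#' One-row cohort summary
#'
#' @param x a `cohort_comparison` from [compare_cohort()].
#' @param ... unused.
#' @return a one-row tibble: patient count, median/min/max percent
#'   mean-dose reduction, and the counts of patients whose OCC
#'   maximum-dose voxel lies inside the PTV and inside the MSC.
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$patients),
    reduction_median = x$reduction$median,
    reduction_min = x$reduction$min,
    reduction_max = x$reduction$max,
    n_occ_max_in_ptv = sum(x$patients$occ_max_in_ptv),
    n_occ_max_in_msc = sum(x$patients$occ_max_in_msc))
}

#' Plot cohort median DVHs with range envelopes
#'
#' Median cumulative DVH per contouring approach (solid line MSC, dashed
#' line OCC) with the cohort range as a shaded band.
#'
#' @param object a `cohort_comparison` from [compare_cohort()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  ggplot2::ggplot(object$dvh,
                  ggplot2::aes(x = .data$dose_gy, group = .data$structure)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$vol_min, ymax = .data$vol_max,
                                      fill = .data$structure), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$vol_median, colour = .data$structure,
                                    linetype = .data$structure)) +
    ggplot2::scale_linetype_manual(values = c(OCC = "dashed", MSC = "solid")) +
    ggplot2::labs(x = "EQD2 (Gy)", y = "Volume (%)",
                  colour = NULL, fill = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
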