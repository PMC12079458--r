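# Time-resolved morphology features and archetype classification.

#' Occupancy-grid area curve of one aggregate
#'
#' At each cadence tick, the area is the number of `grid_nm` x `grid_nm`
#' cells containing at least one localization acquired up to that tick, times
#' the cell area.  Cumulative occupancy makes the curve non-decreasing by
#' construction.  The grid is preferred over a convex hull because dendritic
#' phase-1 shapes would make hulls gross overestimates.
#'
#' @param table a `loc_table`.
#' @param members optional integer row indices restricting the computation to
#'   one cluster (default: all rows).
#' @param grid_nm occupancy cell edge, nm (> 0).  The default (300 nm) keeps
#'   the per-cell fill time short relative to typical growth timescales at
#'   realistic binding densities; see the methods vignette.
#' @param cadence_s curve sampling cadence, s (>= the frame interval).
#' @return a `growth_curve` data.frame with `time_s` and `area_nm2`
#'   (empty for an empty cluster).
#' @export
compute_area_curve <- function(table, members = NULL, grid_nm = 300,
                               cadence_s = NULL) {
  fi <- frame_interval(table)
  if (is.null(cadence_s)) cadence_s <- fi
  if (grid_nm <= 0) stop("compute_area_curve: grid_nm must be > 0")
  if (cadence_s < fi)
    stop("compute_area_curve: cadence_s must be >= the frame interval")
  if (is.null(members)) members <- seq_len(nrow(table))
  if (!length(members))
    return(growth_curve(numeric(0), numeric(0)))
  x <- table$x[members]; y <- table$y[members]
  tt <- loc_times(table)[members]
  cx <- floor(x / grid_nm); cy <- floor(y / grid_nm)
  # exact double-precision composite key (coordinates span < 1e7 cells)
  key <- (cx + 2^25) * 2^26 + (cy + 2^25)
  first <- vapply(split(tt, key), min, numeric(1L))
  ticks <- seq(cadence_s * ceiling(min(tt) / cadence_s),
               cadence_s * ceiling(max(tt) / cadence_s), by = cadence_s)
  n_occ <- findInterval(ticks, sort(first))
  growth_curve(ticks, n_occ * grid_nm^2)
}

#' Growth curve container
#'
#' @param time_s sampling times, s (strictly increasing).
#' @param area_nm2 areas, nm^2 (non-negative, non-decreasing).
#' @return data.frame of class `growth_curve`.
#' @export
growth_curve <- function(time_s, area_nm2) {
  stopifnot(length(time_s) == length(area_nm2))
  if (length(time_s)) {
    if (is.unsorted(time_s, strictly = TRUE))
      stop("growth_curve: times must be strictly increasing")
    if (any(area_nm2 < 0) || is.unsorted(area_nm2))
      stop("growth_curve: areas must be non-negative and non-decreasing")
  }
  structure(data.frame(time_s = time_s, area_nm2 = area_nm2),
            class = c("growth_curve", "data.frame"))
}

# Axis ratio sqrt(lambda_max / lambda_min) of the localization covariance,
# cumulatively over time; vectorized via cumulative moments.
axis_ratio_curve <- function(x, y, tt, ticks) {
  o <- order(tt)
  x <- x[o]; y <- y[o]; tt <- tt[o]
  n <- findInterval(ticks, tt)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  ratio <- rep(NA_real_, length(ticks))
  ok <- n >= 2L
  if (any(ok)) {
    nn <- n[ok]
    mx <- cx[nn] / nn; my <- cy[nn] / nn
    sxx <- cxx[nn] / nn - mx^2
    syy <- cyy[nn] / nn - my^2
    sxy <- cxy[nn] / nn - mx * my
    tr <- sxx + syy
    dd <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
    l1 <- (tr + dd) / 2
    l2 <- pmax((tr - dd) / 2, .Machine$double.eps)
    ratio[ok] <- sqrt(l1 / l2)
  }
  ratio
}

#' Morphology fingerprint of one aggregate
#'
#' Per-tick occupancy area and covariance axis ratio, plus the final area in
#' square microns (1 um^2 = 1e6 nm^2).  The final area is measured on a
#' finer occupancy grid (`final_grid_nm`) than the curve: the boundary bias
#' of an occupancy count scales with cell size times perimeter, and the
#' final footprint of a compact aggregate is exactly the quantity the
#' small-aggregate area threshold is applied to, while the coarser curve
#' grid keeps growth-rate slopes faithful (see the methods vignette).
#'
#' @inheritParams compute_area_curve
#' @param final_grid_nm occupancy cell edge for the final-area estimate, nm.
#' @return list of class `morphology_fingerprint`: `curve` (a
#'   [growth_curve()]), `axis_ratio` (per tick, >= 1), `final_area_um2`.
#' @export
morphology_fingerprint <- function(table, members = NULL, grid_nm = 300,
                                   cadence_s = NULL, final_grid_nm = 100) {
  curve <- compute_area_curve(table, members, grid_nm, cadence_s)
  if (is.null(members)) members <- seq_len(nrow(table))
  ar <- if (nrow(curve))
    axis_ratio_curve(table$x[members], table$y[members],
                     loc_times(table)[members], curve$time_s)
  else numeric(0)
  final_um2 <- if (length(members)) {
    cx <- floor(table$x[members] / final_grid_nm)
    cy <- floor(table$y[members] / final_grid_nm)
    sum(!duplicated(cbind(cx, cy))) * final_grid_nm^2 / 1e6
  } else 0
  structure(list(curve = curve, axis_ratio = ar,
                 final_area_um2 = final_um2),
            class = "morphology_fingerprint")
}

# Tick indices of the growth phase: final-area fraction in (lo, hi].
growth_phase_idx <- function(curve, lo = 0.05, hi = 0.95) {
  a <- curve$area_nm2
  if (!length(a)) return(integer(0))
  fin <- a[length(a)]
  which(a > lo * fin & a <= hi * fin)
}

#' Classify an aggregate from its morphology fingerprint
#'
#' Small if the final footprint area is below `small_area_threshold_um2`
#' (the canonical 10 um^2 cut for small aggregates); otherwise anisotropic if
#' the median axis ratio over the first `early_fraction` of the growth phase
#' (5-95% of final area) reaches `axis_ratio_cut`, else isotropic.  The
#' axis-ratio cut and early fraction are package choices exposed in the
#' configuration; no numeric criterion is established in the field.
#'
#' @param fingerprint a [morphology_fingerprint()].
#' @param small_area_threshold_um2 area cut, um^2.
#' @param axis_ratio_cut elongation cut (dimensionless, >= 1).
#' @param early_fraction fraction of the growth phase considered "early".
#' @return list of class `aggregate_classification`: `label` (one of
#'   `"anisotropic"`, `"isotropic"`, `"small"`), `final_area_um2`,
#'   `early_axis_ratio`, `terminated` (set by the kinetics stage, NA here).
#' @export
classify_aggregate <- function(fingerprint, small_area_threshold_um2 = 10,
                               axis_ratio_cut = 1.8, early_fraction = 0.3) {
  stopifnot(inherits(fingerprint, "morphology_fingerprint"))
  if (!nrow(fingerprint$curve))
    stop("classify_aggregate: empty fingerprint")
  fa <- fingerprint$final_area_um2
  gp <- growth_phase_idx(fingerprint$curve)
  early <- gp[seq_len(max(1L, ceiling(length(gp) * early_fraction)))]
  ear <- stats::median(fingerprint$axis_ratio[early], na.rm = TRUE)
  label <- if (fa < small_area_threshold_um2) "small"
  else if (is.finite(ear) && ear >= axis_ratio_cut) "anisotropic"
  else "isotropic"
  structure(list(label = label, final_area_um2 = fa,
                 early_axis_ratio = ear, terminated = NA),
            class = "aggregate_classification")
}
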