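# Ensemble lag-phase estimation from turbidity kinetics.

#' Estimate the lag phase of one turbidity curve
#'
#' Baseline-tangent method: the smoothed slope (centred 3-point differences)
#' is maximized, and the tangent at that point is intersected with the
#' baseline (mean of the pre-growth points, those within `baseline_frac` of
#' the minimum on the absorbance range).  A threshold-crossing alternative
#' (first time above baseline + `threshold_frac` of the amplitude) is
#' available; the tangent method is the default because no canonical lag
#' operator is established for these assays.
#'
#' The estimate is invariant to absorbance offsets and is clamped to the
#' observed time range.
#'
#' @param time sampling times, min (>= 5 points).
#' @param absorbance absorbance values, AU.
#' @param method `"tangent"` or `"threshold"`.
#' @param baseline_frac pre-growth band as a fraction of the signal range.
#' @param threshold_frac crossing level for the threshold method.
#' @return lag in minutes.
#' @export
estimate_lag <- function(time, absorbance,
                         method = c("tangent", "threshold"),
                         baseline_frac = 0.05, threshold_frac = 0.05) {
  method <- match.arg(method)
  stopifnot(length(time) == length(absorbance))
  if (length(time) < 5L) stop("estimate_lag: need at least 5 points")
  o <- order(time)
  t <- time[o]; y <- absorbance[o]
  rng <- max(y) - min(y)
  if (rng <= 0) stop("estimate_lag: flat curve, no growth detected")
  base_pts <- y <= min(y) + baseline_frac * rng
  baseline <- mean(y[base_pts])
  n <- length(t)
  slope <- (y[-(1:2)] - y[seq_len(n - 2L)]) / (t[-(1:2)] - t[seq_len(n - 2L)])
  if (max(slope) <= 0) stop("estimate_lag: no rising phase detected")
  i <- which.max(slope) + 1L  # index of the centre point
  lag <- if (method == "tangent") {
    t[i] - (y[i] - baseline) / slope[i - 1L]
  } else {
    cross <- which(y >= baseline + threshold_frac * rng & t >= t[base_pts][1L])
    if (!length(cross)) stop("estimate_lag: threshold never crossed")
    t[cross[1L]]
  }
  min(max(lag, t[1L]), t[n])
}

#' Per-replicate lag estimates of a turbidity dataset
#'
#' @param data data.frame with `condition`, `replicate`, `time_min`,
#'   `absorbance` (long format).  Conditions with fewer than 3 replicates
#'   trigger a warning (summary statistics want >= 3 plate replicates).
#' @param ... passed to [estimate_lag()].
#' @return data.frame `condition`, `replicate`, `lag_min`.
#' @export
lag_by_condition <- function(data, ...) {
  stopifnot(all(c("condition", "replicate", "time_min", "absorbance") %in%
                  names(data)))
  out <- do.call(rbind, lapply(split(data, data[c("replicate", "condition")],
                                     drop = TRUE), function(d)
    data.frame(condition = d$condition[1L], replicate = d$replicate[1L],
               lag_min = estimate_lag(d$time_min, d$absorbance, ...))))
  rownames(out) <- NULL
  nrep <- table(unique(out[c("condition", "replicate")])$condition)
  if (any(nrep < 3L))
    warning("lag_by_condition: fewer than 3 replicates for condition(s): ",
            paste(names(nrep)[nrep < 3L], collapse = ", "))
  out[order(out$condition, out$replicate), , drop = FALSE]
}

#' Compare condition lag phases against a control
#'
#' Per condition: mean and SD of the replicate lags plus a two-sided Welch
#' t-test against the control condition's replicate lags.  The control row
#' carries t = 0, p = 1.  Results do not depend on the ordering of the
#' conditions in the input.
#'
#' @param lags data.frame `condition`, `lag_min` (one row per replicate),
#'   e.g. from [lag_by_condition()].
#' @param control name of the control condition (must be present).
#' @return data.frame `condition`, `n`, `mean_lag_min`, `sd_lag_min`, `t`,
#'   `p`, control first, then alphabetical.
#' @export
compare_conditions <- function(lags, control = "control") {
  stopifnot(all(c("condition", "lag_min") %in% names(lags)))
  if (!control %in% lags$condition)
    stop("compare_conditions: control condition '", control, "' not found")
  ctrl <- lags$lag_min[lags$condition == control]
  conds <- unique(as.character(lags$condition))
  conds <- c(control, sort(setdiff(conds, control)))
  out <- do.call(rbind, lapply(conds, function(cn) {
    v <- lags$lag_min[lags$condition == cn]
    w <- welch_t_test(v, ctrl)
    data.frame(condition = cn, n = length(v), mean_lag_min = mean(v),
               sd_lag_min = stats::sd(v), t = w$t, p = w$p)
  }))
  rownames(out) <- NULL
  out
}
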