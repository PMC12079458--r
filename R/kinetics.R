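# Per-aggregate growth-rate fitting and condition-level statistics.
#
# Growth curves of spherulites are piecewise-linear in area: anisotropic
# growth has a dendritic phase (rate R1) followed by a branching phase (rate
# R2) joined continuously at a changepoint; isotropic growth has a single
# rate Rx; small aggregates grow at a single rate R until growth terminates.
# All rates are ordinary least-squares slopes in nm^2/s.

new_rate_fit <- function(archetype, rates, se, changepoint_s = NA,
                         termination_s = NA, sigma = NA, degenerate = FALSE) {
  structure(list(archetype = archetype, rates = rates, se = se,
                 changepoint_s = changepoint_s, termination_s = termination_s,
                 sigma = sigma, degenerate = degenerate),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> ", x$archetype, ": ",
      paste(sprintf("%s = %.4g +/- %.3g nm^2/s", names(x$rates), x$rates,
                    x$se), collapse = ", "), sep = "")
  if (!is.na(x$changepoint_s)) cat(", changepoint", x$changepoint_s, "s")
  if (!is.na(x$termination_s)) cat(", termination", x$termination_s, "s")
  if (isTRUE(x$degenerate)) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

#' Single-phase growth rate
#'
#' OLS slope of area vs time over the growth phase (5-95% of final area by
#' default, avoiding nucleus and plateau artefacts); slopes are clipped at 0.
#'
#' @param curve a [growth_curve()].
#' @param window optional integer indices of the points to fit; default is
#'   the 5-95% growth phase (the whole curve if that leaves < 3 points).
#' @param archetype label stored in the fit.
#' @return a `rate_fit` with rate `rx`.
#' @export
fit_single_rate <- function(curve, window = NULL, archetype = "isotropic") {
  if (is.null(window)) {
    window <- growth_phase_idx(curve)
    if (length(window) < 3L) window <- seq_len(nrow(curve))
  }
  if (length(window) < 3L)
    stop("fit_single_rate: need at least 3 points in the fitting window")
  t <- curve$time_s[window]; a <- curve$area_nm2[window]
  fit <- stats::lm(a ~ t)
  sm <- suppressWarnings(summary(fit))$coefficients
  rate <- max(unname(stats::coef(fit)[2L]), 0)
  nm <- if (archetype == "small") "r" else "rx"
  new_rate_fit(archetype, stats::setNames(rate, nm),
               stats::setNames(sm["t", "Std. Error"], nm),
               sigma = suppressWarnings(summary(fit))$sigma)
}

#' Two-phase (continuous piecewise-linear) growth rates
#'
#' Fits `area ~ t` with one continuity-constrained changepoint; the
#' changepoint is chosen by exhaustive search over the interior observed time
#' points, minimizing total SSE (area curves are physically continuous, so no
#' free intercept for the second phase).  If the two-phase model improves SSE
#' over the single line by less than `min_improvement` (relative), the fit is
#' flagged degenerate and both rates equal the single-phase slope.
#'
#' @param curve a [growth_curve()].
#' @param window optional indices (default 5-95% growth phase, whole curve if
#'   that leaves < 6 points).
#' @param min_improvement relative SSE improvement below which the two-phase
#'   model is rejected.
#' @return a `rate_fit` with rates `r1`, `r2` and `changepoint_s`.
#' @export
fit_two_phase <- function(curve, window = NULL, min_improvement = 0.05) {
  if (is.null(window)) {
    window <- growth_phase_idx(curve)
    if (length(window) < 6L) window <- seq_len(nrow(curve))
  }
  if (length(window) < 6L)
    stop("fit_two_phase: need at least 6 points in the fitting window")
  t <- curve$time_s[window]; a <- curve$area_nm2[window]
  n <- length(t)
  lin <- stats::lm(a ~ t)
  sse1 <- sum(stats::residuals(lin)^2)
  best <- list(sse = Inf, j = NA)
  for (j in 3:(n - 3L)) {
    tc <- t[j]
    X <- cbind(1, t, pmax(t - tc, 0))
    f <- stats::lm.fit(X, a)
    sse <- sum(f$residuals^2)
    if (sse < best$sse - 1e-12) best <- list(sse = sse, j = j)
  }
  sl1 <- max(unname(stats::coef(lin)[2L]), 0)
  se1 <- suppressWarnings(summary(lin))$coefficients["t", "Std. Error"]
  degenerate <- sse1 <= .Machine$double.eps * max(1, sum(a^2)) ||
    (sse1 - best$sse) / sse1 < min_improvement
  if (degenerate) {
    return(new_rate_fit("anisotropic", c(r1 = sl1, r2 = sl1),
                        c(r1 = se1, r2 = se1), changepoint_s = NA,
                        sigma = suppressWarnings(summary(lin))$sigma,
                        degenerate = TRUE))
  }
  tc <- t[best$j]
  tp <- pmax(t - tc, 0)
  fit <- stats::lm(a ~ t + tp)
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))  # summary warns on perfect fits
  r1 <- max(unname(cf["t"]), 0)
  r2 <- max(unname(cf["t"] + cf["tp"]), 0)
  se_r1 <- sqrt(vc["t", "t"])
  se_r2 <- sqrt(vc["t", "t"] + vc["tp", "tp"] + 2 * vc["t", "tp"])
  new_rate_fit("anisotropic", c(r1 = r1, r2 = r2), c(r1 = se_r1, r2 = se_r2),
               changepoint_s = tc, sigma = suppressWarnings(summary(fit))$sigma)
}

#' Detect growth termination
#'
#' Computes rolling-window OLS slopes (windows `[t, t + plateau_window_s]`)
#' and reports the earliest time after which every window slope stays below
#' `slope_tol` times the maximum slope.  The kink location is then refined by
#' a continuity-constrained piecewise-linear fit over the curve points within
#' two windows of the detected onset (the rolling-window scan alone locates
#' the plateau only to within a window, biased early by the window that
#' straddles the kink); if the local fit degenerates, the scan result plus
#' the deterministic straddle correction `f* x window` is returned instead
#' (OLS slope of a window whose first fraction `p` is still growing is
#' `p^2 (3 - 2p)` of the growth rate, so `f*^2 (3 - 2 f*) = slope_tol`).
#'
#' Rolling slopes are smoothed with a 3-window running mean before the scan:
#' occupancy-grid curves advance in whole-cell steps, and a single new cell
#' inside an otherwise flat window would otherwise spike the slope above the
#' threshold.
#'
#' @param curve a [growth_curve()].
#' @param plateau_window_s rolling-window width, s (shorter than the curve).
#' @param slope_tol plateau threshold relative to the maximum slope.
#' @return termination time in s, or `NULL` if growth never terminates.
#'   An all-flat curve terminates at its start.
#' @export
detect_termination <- function(curve, plateau_window_s = 400,
                               slope_tol = 0.2) {
  t <- curve$time_s; a <- curve$area_nm2
  if (length(t) < 3L) return(NULL)
  if (plateau_window_s >= t[length(t)] - t[1L])
    stop("detect_termination: plateau_window_s must be shorter than the curve")
  if (max(a) == min(a)) return(t[1L])
  starts <- which(t + plateau_window_s <= t[length(t)])
  slopes <- vapply(starts, function(i) {
    j <- which(t >= t[i] & t <= t[i] + plateau_window_s)
    if (length(j) < 2L) return(NA_real_)
    tj <- t[j]; aj <- a[j]
    sum((tj - mean(tj)) * (aj - mean(aj))) / sum((tj - mean(tj))^2)
  }, numeric(1L))
  if (length(slopes) >= 3L) {
    sm <- stats::filter(slopes, rep(1 / 3, 3L), sides = 2L)
    slopes <- ifelse(is.na(sm), slopes, as.numeric(sm))
  }
  mx <- max(slopes, na.rm = TRUE)
  if (mx <= 0) return(t[1L])
  flat <- !is.na(slopes) & slopes < slope_tol * mx
  run <- rev(cumprod(rev(flat)))  # 1 where all subsequent windows are flat
  i <- which(run == 1L)[1L]
  if (is.na(i)) return(NULL)
  ts0 <- t[starts[i]]
  fstar <- stats::uniroot(function(p) p^2 * (3 - 2 * p) - slope_tol,
                          c(0, 1))$root
  fallback <- ts0 + fstar * plateau_window_s
  # kink refinement: near the plateau onset the curve is two-phase with a
  # near-zero second slope, so a continuous piecewise fit over a local window
  # (where the growth limb is effectively linear) locates the kink precisely
  centre <- ts0
  est <- NA_real_
  for (it in 1:3) {  # re-centre the local window on the current estimate
    j <- which(t >= centre - 1.2 * plateau_window_s &
                 t <= centre + 2 * plateau_window_s)
    if (length(j) < 6L) break
    ref <- tryCatch(fit_two_phase(curve, window = j, min_improvement = 0),
                    error = function(e) NULL)
    if (is.null(ref) || ref$degenerate || is.na(ref$changepoint_s)) break
    est <- ref$changepoint_s
    if (abs(est - centre) < plateau_window_s / 10) break
    centre <- est
  }
  if (!is.na(est) && abs(est - ts0) <= 3 * plateau_window_s) est else fallback
}

#' Fit growth kinetics according to an aggregate's archetype
#'
#' Dispatcher: anisotropic aggregates get a two-phase fit, isotropic a
#' single-phase fit, and small aggregates a termination scan followed by a
#' single-phase fit over the pre-termination growth phase.
#'
#' @param curve a [growth_curve()].
#' @param label archetype label (e.g. from [classify_aggregate()]).
#' @param termination_curve optional finer-resolution [growth_curve()] of the
#'   same aggregate used only to locate the termination kink of small
#'   aggregates (kink timing is most precise on a fine occupancy grid, while
#'   slope magnitudes are most faithful on a coarse one; see the methods
#'   vignette).  Defaults to `curve`.
#' @param ... passed to the specific fitter.
#' @return a `rate_fit`.
#' @export
fit_growth <- function(curve, label, termination_curve = NULL, ...) {
  switch(label,
    anisotropic = fit_two_phase(curve, ...),
    isotropic = fit_single_rate(curve, archetype = "isotropic", ...),
    small = {
      if (is.null(termination_curve)) termination_curve <- curve
      term <- tryCatch(detect_termination(termination_curve),
                       error = function(e) NULL)
      window <- growth_phase_idx(curve)
      if (!is.null(term)) window <- window[curve$time_s[window] <= term]
      if (length(window) < 3L) window <- NULL
      f <- fit_single_rate(curve, window = window, archetype = "small", ...)
      f$termination_s <- if (is.null(term)) NA else term
      f
    },
    stop("fit_growth: unknown archetype label: ", label))
}

#' Condition-level rate summary
#'
#' Per archetype and rate: number of aggregates, mean rate and standard
#' error (SD/sqrt(n); reported as SE, matching how single-aggregate rate
#' tables are presented).  Archetypes absent from `fits` appear with n = 0;
#' single-fit SEs are reported as 0 and flagged.
#'
#' @param fits list of `rate_fit` objects.
#' @param label condition label.
#' @return data.frame of class `condition_summary` with columns `condition`,
#'   `archetype`, `rate`, `n`, `mean`, `se`, `se_defined`; the raw rate
#'   vectors are attached as `attr(, "samples")` for downstream tests.
#' @export
summarize_condition <- function(fits, label = "condition") {
  spec <- list(anisotropic = c("r1", "r2"), isotropic = "rx", small = "r")
  rows <- list()
  samples <- list()
  for (arch in names(spec)) {
    sub <- Filter(function(f) f$archetype == arch, fits)
    for (rn in spec[[arch]]) {
      v <- vapply(sub, function(f) unname(f$rates[rn]), numeric(1L))
      n <- length(v)
      key <- paste(arch, rn, sep = "_")
      samples[[key]] <- v
      rows[[key]] <- data.frame(
        condition = label, archetype = arch, rate = rn, n = n,
        mean = if (n) mean(v) else NA_real_,
        se = if (n >= 2L) stats::sd(v) / sqrt(n) else 0,
        se_defined = n >= 2L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Two-sided Welch t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom, implemented from
#' the closed form (the standard library test serves as an independent oracle
#' in the package's tests).  Two samples with zero variance and equal means
#' give t = 0, p = 1.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test: each sample needs n >= 2")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  dm <- mean(a) - mean(b)
  if (va + vb == 0) {
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf, df = NA_real_,
                p = if (dm == 0) 1 else 0))
  }
  t <- dm / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
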