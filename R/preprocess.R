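# Quality filtering and drift correction.

#' Otsu threshold of log-intensities
#'
#' Classic maximum between-class-variance split computed on a 256-bin
#' histogram of log10 photon counts, mapped back to the photon scale.
#'
#' @param intensity positive photon counts.
#' @param bins histogram resolution.
#' @return threshold (photons); localizations below it are the dim class.
#' @export
otsu_threshold <- function(intensity, bins = 256L) {
  v <- log10(intensity[intensity > 0])
  if (length(v) < 2L || diff(range(v)) == 0) return(0)
  h <- hist(v, breaks = seq(min(v), max(v), length.out = bins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sb2[!is.finite(sb2)] <- -Inf
  10^mids[which.max(sb2)]
}

# Automatic threshold with a bimodality guard: the Otsu split is only applied
# if the log-intensity histogram has a genuine valley at the split (smoothed
# density there below 25% of the smaller neighbouring peak) and neither class
# is vanishingly small; otherwise 0 (keep everything).  Otsu happily splits a
# unimodal histogram down the middle, which would throw away half the signal.
auto_intensity_threshold <- function(intensity, min_class_frac = 0.001,
                                     valley_frac = 0.25, bins = 256L) {
  v <- log10(intensity[intensity > 0])
  if (length(v) < 10L || diff(range(v)) == 0) return(0)
  thr <- otsu_threshold(intensity, bins)
  if (thr <= 0) return(0)
  n_lo <- sum(intensity < thr)
  n_hi <- sum(intensity >= thr)
  if (min(n_lo, n_hi) / length(intensity) < min_class_frac) return(0)
  h <- hist(v, breaks = seq(min(v), max(v), length.out = bins + 1L),
            plot = FALSE)
  sm <- stats::filter(h$counts, rep(1 / 5, 5L), sides = 2L)
  sm[is.na(sm)] <- h$counts[is.na(sm)]
  k <- findInterval(log10(thr), h$breaks, all.inside = TRUE)
  pk_lo <- max(sm[seq_len(k)])
  pk_hi <- max(sm[k:length(sm)])
  if (sm[k] < valley_frac * min(pk_lo, pk_hi)) thr else 0
}

#' Remove dim localizations
#'
#' Rows with `intensity < threshold` are dropped.  With `threshold = NULL`
#' the threshold is chosen automatically: an Otsu split of the log-intensity
#' histogram, applied only when the histogram is convincingly bimodal (dim
#' false positives form a separate mode), otherwise nothing is removed.
#'
#' @param table a `loc_table`.
#' @param threshold photons (>= 0), or `NULL` for automatic.
#' @return the filtered `loc_table`; the number of removed rows is available
#'   as `attr(, "n_removed")` and the kept original row indices as
#'   `attr(, "kept_rows")`.
#' @export
filter_intensity <- function(table, threshold = NULL) {
  if (is.null(threshold)) threshold <- auto_intensity_threshold(table$intensity)
  if (threshold < 0) stop("filter_intensity: threshold must be >= 0")
  keep <- table$intensity >= threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "frame_interval_s") <- attr(table, "frame_interval_s")
  attr(out, "fov_size") <- attr(table, "fov_size")
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "kept_rows") <- which(keep)
  attr(out, "threshold") <- threshold
  out
}

#' Drift model
#'
#' Piecewise-linear displacement track (nm) anchored so the displacement at
#' t = 0 is exactly (0, 0); between the estimation bins the displacement is
#' interpolated linearly and extrapolated linearly at both ends.
#'
#' @param t bin-centre times, s.
#' @param dx,dy displacements vs the first bin, nm.
#' @return object of class `drift_model` (data.frame t/dx/dy).
#' @export
drift_model <- function(t, dx, dy) {
  stopifnot(length(t) == length(dx), length(t) == length(dy), length(t) >= 1L)
  o <- order(t)
  m <- data.frame(t = t[o], dx = dx[o], dy = dy[o])
  # extend linearly to t = 0 and anchor there
  if (nrow(m) >= 2L) {
    sl_x <- (m$dx[2L] - m$dx[1L]) / (m$t[2L] - m$t[1L])
    sl_y <- (m$dy[2L] - m$dy[1L]) / (m$t[2L] - m$t[1L])
  } else sl_x <- sl_y <- 0
  d0x <- m$dx[1L] - sl_x * m$t[1L]
  d0y <- m$dy[1L] - sl_y * m$t[1L]
  m$dx <- m$dx - d0x
  m$dy <- m$dy - d0y
  if (m$t[1L] > 0) m <- rbind(data.frame(t = 0, dx = 0, dy = 0), m)
  class(m) <- c("drift_model", "data.frame")
  m
}

# displacement at arbitrary times (linear interpolation, linear extrapolation
# at the far end from the last two bins).
drift_at <- function(model, t) {
  m <- as.data.frame(model)
  if (nrow(m) == 1L) return(cbind(dx = rep(m$dx, length(t)),
                                  dy = rep(m$dy, length(t))))
  dx <- stats::approx(m$t, m$dx, xout = t, rule = 2)$y
  dy <- stats::approx(m$t, m$dy, xout = t, rule = 2)$y
  late <- t > m$t[nrow(m)]
  if (any(late)) {
    k <- nrow(m)
    sx <- (m$dx[k] - m$dx[k - 1L]) / (m$t[k] - m$t[k - 1L])
    sy <- (m$dy[k] - m$dy[k - 1L]) / (m$t[k] - m$t[k - 1L])
    dx[late] <- m$dx[k] + sx * (t[late] - m$t[k])
    dy[late] <- m$dy[k] + sy * (t[late] - m$t[k])
  }
  cbind(dx = dx, dy = dy)
}

# FFT cross-correlation shift of img relative to ref (both matrices), with
# zero padding against circular wrap-around and parabolic subpixel refinement.
xcorr_shift <- function(ref, img) {
  d <- dim(ref)
  n1 <- 2L * d[1L]; n2 <- 2L * d[2L]
  pad <- function(m) { out <- matrix(0, n1, n2); out[seq_len(d[1L]), seq_len(d[2L])] <- m; out }
  cc <- Re(stats::fft(stats::fft(pad(img)) * Conj(stats::fft(pad(ref))),
                      inverse = TRUE))
  pk <- which.max(cc)
  pi1 <- (pk - 1L) %% n1 + 1L
  pi2 <- (pk - 1L) %/% n1 + 1L
  sub <- function(cvals) {
    den <- cvals[1L] - 2 * cvals[2L] + cvals[3L]
    if (den >= 0 || !all(is.finite(cvals))) 0 else 0.5 * (cvals[1L] - cvals[3L]) / den
  }
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  off1 <- sub(cc[cbind(wrap(pi1 + c(-1L, 0L, 1L), n1), pi2)])
  off2 <- sub(cc[cbind(pi1, wrap(pi2 + c(-1L, 0L, 1L), n2))])
  s1 <- pi1 - 1L + off1
  s2 <- pi2 - 1L + off2
  if (s1 > n1 / 2) s1 <- s1 - n1
  if (s2 > n2 / 2) s2 <- s2 - n2
  c(s1, s2)
}

#' Estimate stage drift by cross-correlation of time-binned reconstructions
#'
#' The acquisition is cut into time bins; each bin is rendered as a 2D
#' histogram and cross-correlated against the first bin.  The correlation
#' peak (refined to subpixel precision by parabolic interpolation) gives the
#' displacement of that bin relative to the reference, and displacements are
#' interpolated linearly in between.
#'
#' @param table a `loc_table`.
#' @param bin_duration_s time-bin width, s; the table must span at least two
#'   bins.
#' @param pixel_nm rendering pixel for the correlation images.
#' @param min_locs minimum localizations per bin; bins below it trigger an
#'   error advising larger bins.
#' @return a [drift_model()].
#' @export
estimate_drift <- function(table, bin_duration_s = NULL, pixel_nm = 200,
                           min_locs = 50L) {
  tt <- loc_times(table)
  span <- max(tt) - min(tt)
  if (is.null(bin_duration_s)) bin_duration_s <- span / 4
  nb <- max(2L, floor(span / bin_duration_s + 1e-9))
  edges <- min(tt) + seq(0, span, length.out = nb + 1L)
  bin <- findInterval(tt, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nb)
  if (nb < 2L || any(counts < min_locs))
    stop("estimate_drift: fewer than ", min_locs, " localizations in a time ",
         "bin; use a larger bin_duration_s")
  bounds <- {
    fov <- attr(table, "fov_size")
    if (!is.null(fov)) list(x = c(0, fov[1L]), y = c(0, fov[2L]))
    else list(x = range(table$x), y = range(table$y))
  }
  imgs <- lapply(seq_len(nb), function(b)
    render_reconstruction(table[bin == b, , drop = FALSE], pixel_nm,
                          bounds = bounds))
  ctr <- (edges[-(nb + 1L)] + edges[-1L]) / 2
  sh <- t(vapply(seq_len(nb), function(b) {
    if (b == 1L) c(0, 0) else xcorr_shift(imgs[[1L]], imgs[[b]])
  }, numeric(2L)))
  drift_model(ctr, sh[, 1L] * pixel_nm, sh[, 2L] * pixel_nm)
}

#' Apply (or revert) a drift correction
#'
#' Subtracts the model displacement at each localization's acquisition time;
#' row order is preserved.  `invert = TRUE` adds the displacement back, so
#' `apply_drift(apply_drift(T, M), M, invert = TRUE)` returns `T` up to float
#' tolerance.
#'
#' @param table a `loc_table`.
#' @param model a [drift_model()].
#' @param invert revert instead of correct.
#' @return the shifted `loc_table`.
#' @export
apply_drift <- function(table, model, invert = FALSE) {
  d <- drift_at(model, loc_times(table))
  s <- if (invert) 1 else -1
  table$x <- table$x + s * d[, "dx"]
  table$y <- table$y + s * d[, "dy"]
  table
}

#' One-call preprocessing
#'
#' Intensity filtering (automatic threshold unless given) followed by drift
#' estimation and correction.  Mirrors the published pipeline's order:
#' threshold first, then drift correction, then segmentation.
#'
#' @param table a `loc_table`.
#' @param min_intensity photons or `NULL` (automatic).
#' @param drift `TRUE`/`FALSE`; drift estimation failures (too few
#'   localizations per bin) degrade gracefully to no correction.
#' @param drift_bin_s,drift_pixel_nm passed to [estimate_drift()].
#' @return the preprocessed `loc_table` (keeps `kept_rows`/`n_removed`
#'   attributes of the filtering step).
#' @export
preprocess <- function(table, min_intensity = NULL, drift = TRUE,
                       drift_bin_s = NULL, drift_pixel_nm = 200) {
  out <- filter_intensity(table, min_intensity)
  if (drift && nrow(out)) {
    dm <- tryCatch(estimate_drift(out, drift_bin_s, drift_pixel_nm),
                   error = function(e) NULL)
    if (!is.null(dm)) {
      kept <- attr(out, "kept_rows"); nrem <- attr(out, "n_removed")
      thr <- attr(out, "threshold")
      out <- apply_drift(out, dm)
      attr(out, "kept_rows") <- kept
      attr(out, "n_removed") <- nrem
      attr(out, "threshold") <- thr
      attr(out, "drift_model") <- dm
    }
  }
  out
}
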