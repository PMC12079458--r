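# Synthetic REPLOM-style data generator.
#
# A growing aggregate is a footprint (convex polygon + exact dilation, see
# footprint.R) whose true area follows the archetype's piecewise-linear law.
# Each frame, new binding events are drawn as a Poisson count proportional to
# the current footprint area and placed uniformly on it, then jittered by the
# localization precision.  This matches the binding-accumulation picture of
# real-time localization microscopy with minimal assumptions.

#' Growth model for a single aggregate
#'
#' Describes the true areal growth law of one aggregate.  Three archetypes
#' are supported: `"anisotropic"` spherulites grow as an elongating ellipse
#' (dendritic phase, areal rate `r1`) until `t_switch`, after which the
#' footprint dilates radially (branching phase, rate `r2`); `"isotropic"`
#' spherulites dilate radially at a single rate `rx`; `"small"` aggregates
#' grow at `r_small` until `t_term`, after which growth is terminated and
#' only a small residual binding rate (`residual_frac` of the pre-termination
#' rate) remains.
#'
#' All rates are areal rates in nm^2/s, matching how single-aggregate growth
#' rates are reported for insulin spherulites.
#'
#' @param archetype one of `"anisotropic"`, `"isotropic"`, `"small"`.
#' @param r1,r2 phase-1 and phase-2 rates of an anisotropic spherulite, nm^2/s.
#' @param rx rate of an isotropic spherulite, nm^2/s.
#' @param r_small pre-termination rate of a small aggregate, nm^2/s.
#' @param t_switch phase-1 to phase-2 changepoint, s (anisotropic only).
#' @param t_term termination time, s (small only).
#' @param nucleus_radius radius of the initial nucleus, nm.
#' @param aspect_ratio_phase1 major/minor axis ratio of the phase-1 ellipse
#'   (>= 1; elongation anisotropy, also used as the aspect of the frozen core
#'   in phase 2).
#' @param residual_frac residual binding rate after termination, as a fraction
#'   of the pre-termination event rate.
#' @return an object of class `growth_model`.
#' @seealso [anisotropic_model()], [isotropic_model()], [small_model()] for
#'   constructors preloaded with the field-typical rates.
#' @export
growth_model <- function(archetype = c("anisotropic", "isotropic", "small"),
                         r1 = NA, r2 = NA, rx = NA, r_small = NA,
                         t_switch = NA, t_term = NA,
                         nucleus_radius = 300, aspect_ratio_phase1 = 4,
                         residual_frac = 0.02) {
  archetype <- match.arg(archetype)
  m <- list(archetype = archetype, r1 = r1, r2 = r2, rx = rx,
            r_small = r_small, t_switch = t_switch, t_term = t_term,
            nucleus_radius = nucleus_radius,
            aspect_ratio_phase1 = aspect_ratio_phase1,
            residual_frac = residual_frac)
  rates <- switch(archetype,
                  anisotropic = c(r1 = r1, r2 = r2),
                  isotropic = c(rx = rx),
                  small = c(r_small = r_small))
  if (anyNA(rates) || any(rates < 0))
    stop("growth_model: all rates for archetype '", archetype,
         "' must be given and >= 0")
  if (archetype == "anisotropic" && (is.na(t_switch) || t_switch <= 0))
    stop("growth_model: t_switch must be > 0 for anisotropic growth")
  if (archetype == "small" && (is.na(t_term) || t_term <= 0))
    stop("growth_model: t_term must be > 0 for small aggregates")
  if (nucleus_radius <= 0) stop("growth_model: nucleus_radius must be > 0")
  if (aspect_ratio_phase1 < 1) stop("growth_model: aspect_ratio_phase1 must be >= 1")
  structure(m, class = "growth_model")
}

#' @rdname growth_model
#' @param ... passed on to [growth_model()].
#' @export
anisotropic_model <- function(r1 = 1599, r2 = 8073, t_switch = 3600, ...)
  growth_model("anisotropic", r1 = r1, r2 = r2, t_switch = t_switch, ...)

#' @rdname growth_model
#' @export
isotropic_model <- function(rx = 29211, ...)
  growth_model("isotropic", rx = rx, ...)

#' @rdname growth_model
#' @export
small_model <- function(r_small = 1170, t_term = 7620, ...)
  growth_model("small", r_small = r_small, t_term = t_term, ...)

#' @export
print.growth_model <- function(x, ...) {
  rates <- switch(x$archetype,
                  anisotropic = sprintf("r1 = %g, r2 = %g nm^2/s, t_switch = %g s",
                                        x$r1, x$r2, x$t_switch),
                  isotropic = sprintf("rx = %g nm^2/s", x$rx),
                  small = sprintf("r = %g nm^2/s, t_term = %g s", x$r_small, x$t_term))
  cat("<growth_model> ", x$archetype, ": ", rates, "\n", sep = "")
  invisible(x)
}

#' Imaging / acquisition model
#'
#' Acquisition parameters of a simulated real-time localization experiment.
#' The defaults emulate the published acquisition scheme: a 30 s waiting time
#' per frame and a multi-hour observation window.  Localization precision and
#' binding density are not reported for the real acquisitions; the defaults
#' (20 nm precision, 2e-6 events per nm^2 per frame, i.e. a total fluence of
#' a few hundred localizations per square micron over 2 h) are package
#' defaults chosen to be typical of SMLM reconstructions, not reproductions.
#'
#' @param frame_interval waiting time between frames, s.
#' @param n_frames number of frames (> 0).
#' @param localization_sigma localization precision (isotropic Gaussian), nm.
#' @param binding_rate_per_area new-event density on the occupied footprint,
#'   events/(nm^2 * frame).
#' @param false_positive_rate spurious detections per frame over the whole
#'   field of view.
#' @param drift_velocity length-2 numeric, stage drift in nm/frame applied
#'   cumulatively to all localizations of a field of view.
#' @param fov_size length-2 numeric, field-of-view width and height, nm.
#' @param seed integer seed; identical seed + configuration gives
#'   byte-identical output tables.
#' @param signal_intensity,fp_intensity median photon counts of genuine and
#'   false-positive localizations (false positives are dimmer, here half the
#'   signal intensity, so an intensity threshold can separate them).
#' @param intensity_sdlog log-normal spread of the photon counts.
#' @param site_density,site_fraction,site_jitter static binding-site texture:
#'   each aggregate carries a fixed random set of high-affinity sites
#'   (`site_density` per nm^2); a fraction `site_fraction` of binding events
#'   lands on a site currently inside the footprint (jittered by
#'   `site_jitter` nm), the rest uniformly on the footprint.  Real aggregate
#'   reconstructions show persistent substructure; this texture is also what
#'   lets cross-correlation drift estimation lock on.  `site_fraction = 0`
#'   gives untextured uniform binding.
#' @param drift_mode `"linear"` (default) or `"sinusoidal"` (stress tests;
#'   one full period over the acquisition with amplitude
#'   `drift_velocity * n_frames / (2*pi)`).
#' @return an object of class `imaging_model`.
#' @export
imaging_model <- function(frame_interval = 30, n_frames = 240,
                          localization_sigma = 20,
                          binding_rate_per_area = 2e-6,
                          false_positive_rate = 2,
                          drift_velocity = c(0, 0),
                          fov_size = c(6e4, 6e4),
                          seed = 1L,
                          signal_intensity = 1200, fp_intensity = 600,
                          intensity_sdlog = 0.15,
                          site_density = 2.5e-5, site_fraction = 0.6,
                          site_jitter = 25,
                          drift_mode = c("linear", "sinusoidal")) {
  drift_mode <- match.arg(drift_mode)
  if (frame_interval <= 0) stop("imaging_model: frame_interval must be > 0")
  if (is.na(n_frames) || n_frames < 1)
    stop("imaging_model: n_frames must be a positive count")
  if (localization_sigma < 0 || binding_rate_per_area < 0 ||
      false_positive_rate < 0)
    stop("imaging_model: rates and sigma must be >= 0")
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 localization_sigma = localization_sigma,
                 binding_rate_per_area = binding_rate_per_area,
                 false_positive_rate = false_positive_rate,
                 drift_velocity = drift_velocity, fov_size = fov_size,
                 seed = seed, signal_intensity = signal_intensity,
                 fp_intensity = fp_intensity,
                 intensity_sdlog = intensity_sdlog,
                 site_density = site_density,
                 site_fraction = site_fraction, site_jitter = site_jitter,
                 drift_mode = drift_mode),
            class = "imaging_model")
}

# True footprint of `model` at time t (s): list(poly, d, area).
model_footprint <- function(model, t) {
  a0 <- pi * model$nucleus_radius^2
  switch(model$archetype,
    isotropic = {
      poly <- footprint_polygon(a0, 1)
      a <- a0 + model$rx * t
      list(poly = poly, d = dilation_for_area(poly, a), area = a)
    },
    small = {
      poly <- footprint_polygon(a0, 1)
      a <- a0 + model$r_small * min(t, model$t_term)
      list(poly = poly, d = dilation_for_area(poly, a), area = a)
    },
    anisotropic = {
      if (t <= model$t_switch) {
        a <- a0 + model$r1 * t
        list(poly = footprint_polygon(a, model$aspect_ratio_phase1), d = 0, area = a)
      } else {
        a1 <- a0 + model$r1 * model$t_switch
        poly <- footprint_polygon(a1, model$aspect_ratio_phase1)
        a <- a1 + model$r2 * (t - model$t_switch)
        list(poly = poly, d = dilation_for_area(poly, a), area = a)
      }
    })
}

# True area law (vectorized over t).
model_area <- function(model, t) {
  a0 <- pi * model$nucleus_radius^2
  switch(model$archetype,
    isotropic = a0 + model$rx * t,
    small = a0 + model$r_small * pmin(t, model$t_term),
    anisotropic = a0 + model$r1 * pmin(t, model$t_switch) +
      model$r2 * pmax(t - model$t_switch, 0))
}

rloc_intensity <- function(n, median, sdlog)
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)

# Core per-aggregate event generator (no drift, no false positives).
# Returns data.frame(frame, x, y, intensity) using the aggregate-local RNG
# stream of the caller.
simulate_aggregate_events <- function(model, imaging, origin) {
  nf <- imaging$n_frames
  dt <- imaging$frame_interval
  frames <- seq_len(nf)
  tt <- (frames - 1) * dt
  area <- model_area(model, tt)
  lam <- imaging$binding_rate_per_area * area
  if (model$archetype == "small") {
    post <- tt > model$t_term
    lam[post] <- lam[post] * model$residual_frac
  }
  counts <- stats::rpois(nf, lam)
  tot <- sum(counts)

  # static binding-site texture: a fixed random site set over the final
  # footprint's bounding box; sites activate once the growing footprint
  # reaches them (membership re-checked every 10 frames)
  use_sites <- imaging$site_fraction > 0 && imaging$site_density > 0
  if (use_sites) {
    fin <- model_footprint(model, tt[nf])
    pad <- fin$d + 3 * imaging$localization_sigma
    bb <- cbind(range(fin$poly[, 1L]) + c(-pad, pad),
                range(fin$poly[, 2L]) + c(-pad, pad))
    nsites <- stats::rpois(1L, imaging$site_density * diff(bb[, 1L]) * diff(bb[, 2L]))
    sites <- cbind(stats::runif(nsites, bb[1L, 1L], bb[2L, 1L]),
                   stats::runif(nsites, bb[1L, 2L], bb[2L, 2L]))
    active <- logical(nsites)
  }

  xy <- matrix(0, tot, 2L)
  pos <- 0L
  for (f in frames) {
    fp <- NULL
    if (use_sites && (f == 1L || f %% 10L == 0L) && !all(active)) {
      fp <- model_footprint(model, tt[f])
      idx <- which(!active)
      active[idx] <- dist_to_footprint(fp$poly, fp$d,
                                       sites[idx, , drop = FALSE]) <= 0
    }
    n <- counts[f]
    if (n == 0L) next
    if (is.null(fp)) fp <- model_footprint(model, tt[f])
    n_act <- if (use_sites) sum(active) else 0L
    n_site <- if (n_act > 0L)
      stats::rbinom(1L, n, imaging$site_fraction) else 0L
    p <- matrix(0, n, 2L)
    if (n_site > 0L) {
      si <- which(active)[sample.int(n_act, n_site, replace = TRUE)]
      p[seq_len(n_site), ] <- sites[si, , drop = FALSE] +
        matrix(stats::rnorm(2L * n_site, 0, imaging$site_jitter), n_site, 2L)
    }
    if (n - n_site > 0L)
      p[(n_site + 1L):n, ] <- sample_footprint(fp$poly, fp$d, n - n_site)
    xy[pos + seq_len(n), ] <- p
    pos <- pos + n
  }
  if (tot > 0L && imaging$localization_sigma > 0) {
    xy <- xy + matrix(stats::rnorm(2L * tot, 0, imaging$localization_sigma),
                      tot, 2L)
  }
  data.frame(frame = rep.int(frames, counts),
             x = xy[, 1L] + origin[1L],
             y = xy[, 2L] + origin[2L],
             intensity = rloc_intensity(tot, imaging$signal_intensity,
                                        imaging$intensity_sdlog))
}

drift_offsets <- function(imaging, frames) {
  v <- imaging$drift_velocity
  if (imaging$drift_mode == "linear") {
    cbind((frames - 1) * v[1L], (frames - 1) * v[2L])
  } else {
    amp <- imaging$n_frames / (2 * pi)
    s <- sin(2 * pi * (frames - 1) / imaging$n_frames) * amp
    cbind(s * v[1L], s * v[2L])
  }
}

#' Simulate one growing aggregate
#'
#' Draws per-frame binding events on the current true footprint of a single
#' aggregate.  No false positives and no drift are added at this level (those
#' are field-of-view effects, see [simulate_fov()]).
#'
#' @param model a [growth_model()].
#' @param imaging an [imaging_model()]; `imaging$seed` determines the output
#'   reproducibly.
#' @param origin length-2 numeric, nucleation site in nm.
#' @return a list with elements
#'   \describe{
#'     \item{localizations}{data.frame `frame`, `x`, `y`, `intensity` (nm,
#'       photons) of class `loc_table`,}
#'     \item{truth}{ground truth: `aggregate_id` per localization (all 1
#'       here), the model, and the true `area` table
#'       (frame, time_s, area_nm2).}
#'   }
#' @export
simulate_aggregate <- function(model, imaging, origin = c(0, 0)) {
  stopifnot(inherits(model, "growth_model"), inherits(imaging, "imaging_model"))
  with_seed(imaging$seed, {
    loc <- simulate_aggregate_events(model, imaging, origin)
    tt <- (seq_len(imaging$n_frames) - 1) * imaging$frame_interval
    truth <- list(
      aggregate_id = rep.int(1L, nrow(loc)),
      aggregates = list(`1` = list(id = 1L, archetype = model$archetype,
                                   model = model, origin = origin)),
      area = data.frame(frame = seq_len(imaging$n_frames), time_s = tt,
                        area_nm2 = model_area(model, tt)))
    list(localizations = as_loc_table(loc, imaging$frame_interval,
                                      imaging$fov_size),
         truth = truth)
  })
}

#' Simulate a field of view
#'
#' Union of several simulated aggregates plus uniform false positives, with
#' cumulative stage drift applied to every localization.  Ground-truth ids are
#' recorded before drift is applied; id 0 marks false positives (noise).
#'
#' @param mix list of `list(model = <growth_model>, origin = c(x, y))`;
#'   origins must lie inside the field of view.  Overlapping/close origins are
#'   allowed (intertwined structures).
#' @param imaging an [imaging_model()].
#' @return list with `localizations` (a `loc_table`, rows ordered by frame)
#'   and `truth` (per-row `aggregate_id` with 0 = noise, per-aggregate models
#'   and true area tables, and the applied per-frame drift).
#' @export
simulate_fov <- function(mix, imaging) {
  stopifnot(inherits(imaging, "imaging_model"))
  for (m in mix) {
    stopifnot(inherits(m$model, "growth_model"), length(m$origin) == 2L)
    if (any(m$origin < 0) || any(m$origin > imaging$fov_size))
      stop("simulate_fov: aggregate origin outside the field of view")
  }
  with_seed(imaging$seed, {
    parts <- vector("list", length(mix))
    for (i in seq_along(mix)) {
      parts[[i]] <- simulate_aggregate_events(mix[[i]]$model, imaging,
                                              mix[[i]]$origin)
      parts[[i]]$aggregate_id <- i
    }
    nfp <- stats::rpois(imaging$n_frames, imaging$false_positive_rate)
    tfp <- sum(nfp)
    fp <- data.frame(
      frame = rep.int(seq_len(imaging$n_frames), nfp),
      x = stats::runif(tfp, 0, imaging$fov_size[1L]),
      y = stats::runif(tfp, 0, imaging$fov_size[2L]),
      intensity = rloc_intensity(tfp, imaging$fp_intensity,
                                 imaging$intensity_sdlog),
      aggregate_id = rep.int(0L, tfp))
    all <- rbind(do.call(rbind, parts), fp)
    ord <- order(all$frame)
    all <- all[ord, , drop = FALSE]
    rownames(all) <- NULL
    off <- drift_offsets(imaging, all$frame)
    all$x <- all$x + off[, 1L]
    all$y <- all$y + off[, 2L]
    tt <- (seq_len(imaging$n_frames) - 1) * imaging$frame_interval
    aggs <- lapply(seq_along(mix), function(i) {
      list(id = i, archetype = mix[[i]]$model$archetype,
           model = mix[[i]]$model, origin = mix[[i]]$origin,
           area = data.frame(frame = seq_len(imaging$n_frames), time_s = tt,
                             area_nm2 = model_area(mix[[i]]$model, tt)))
    })
    names(aggs) <- as.character(seq_along(mix))
    truth <- list(aggregate_id = all$aggregate_id,
                  aggregates = aggs,
                  drift = data.frame(frame = seq_len(imaging$n_frames),
                                     dx = drift_offsets(imaging, seq_len(imaging$n_frames))[, 1L],
                                     dy = drift_offsets(imaging, seq_len(imaging$n_frames))[, 2L]))
    loc <- all[, c("frame", "x", "y", "intensity")]
    list(localizations = as_loc_table(loc, imaging$frame_interval,
                                      imaging$fov_size),
         truth = truth)
  })
}

#' Standard benchmark field of view
#'
#' The layout used throughout the package's validation: one anisotropic
#' spherulite, one isotropic spherulite, one small aggregate, and one
#' intertwined pair of slow isotropic aggregates nucleating 3 um apart, sized
#' so their footprints merge in the final third of a 2 h acquisition.
#'
#' @param fov_size length-2 numeric, nm.
#' @return a `mix` list for [simulate_fov()].
#' @export
standard_fov_mix <- function(fov_size = c(6e4, 6e4)) {
  sc <- fov_size / 6e4
  at <- function(x_um, y_um) c(x_um * 1e3 * sc[1L], y_um * 1e3 * sc[2L])
  list(
    list(model = isotropic_model(),   origin = at(15, 15)),
    list(model = anisotropic_model(), origin = at(45, 15)),
    list(model = small_model(),       origin = at(12, 45)),
    list(model = isotropic_model(rx = 1700), origin = at(40, 42)),
    list(model = isotropic_model(rx = 1700), origin = at(43, 42)))
}

#' Simulate turbidity kinetics
#'
#' Sigmoidal (logistic) bulk-aggregation curves whose baseline-tangent lag
#' equals `lag_min` in the noiseless limit: for a logistic rising with rate
#' `growth_rate` k, the tangent at the inflection point intersects the
#' baseline at `t_mid - 2/k`, so the inflection is placed at
#' `lag_min + 2/growth_rate`.
#'
#' @param lag_min generating lag phase, min.
#' @param growth_rate logistic rate constant, 1/min.
#' @param plateau plateau absorbance above baseline, AU (must be >= 0).
#' @param noise_sd iid Gaussian absorbance noise per point, AU.
#' @param t_grid sampling times, min (increasing; typically a 10-min cadence).
#' @param n_replicates number of replicates (>= 1).
#' @param seed integer seed.
#' @param lag_sd per-replicate Gaussian jitter of the generating lag, min
#'   (replicate-to-replicate biological scatter; 0 disables it, and with
#'   `noise_sd = 0` all replicates are then identical).
#' @param baseline baseline absorbance, AU.
#' @return data.frame `replicate`, `time_min`, `absorbance`.
#' @export
simulate_turbidity <- function(lag_min, growth_rate = 0.05, plateau = 1,
                               noise_sd = 0.01, t_grid = seq(0, 600, by = 10),
                               n_replicates = 3, seed = 1L, lag_sd = 0,
                               baseline = 0.02) {
  if (plateau < 0) stop("simulate_turbidity: plateau must be >= 0")
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("simulate_turbidity: t_grid must be strictly increasing")
  if (n_replicates < 1) stop("simulate_turbidity: n_replicates must be >= 1")
  with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(r) {
      lag_r <- lag_min + if (lag_sd > 0) stats::rnorm(1, 0, lag_sd) else 0
      tmid <- lag_r + 2 / growth_rate
      y <- baseline + plateau * stats::plogis(growth_rate * (t_grid - tmid))
      if (noise_sd > 0) y <- y + stats::rnorm(length(t_grid), 0, noise_sd)
      data.frame(replicate = r, time_min = t_grid, absorbance = y)
    })
    do.call(rbind, out)
  })
}

#' Standard four-condition turbidity panel
#'
#' Generates the canonical modulation structure: control and low-concentration
#' ligand conditions share a ~103 min lag, the medium concentration lags at
#' ~120 min and the high concentration at ~160 min, each with three replicates
#' and a 6 min replicate-to-replicate lag scatter on a 10-min cadence.
#'
#' @param seed integer seed.
#' @param lags named numeric vector of generating lags, min.
#' @param lag_sd,noise_sd passed to [simulate_turbidity()].
#' @return data.frame `condition`, `replicate`, `time_min`, `absorbance`.
#' @export
standard_turbidity_panel <- function(seed = 1L,
                                     lags = c(control = 103, low = 103,
                                              medium = 120, high = 160),
                                     lag_sd = 6, noise_sd = 0.01) {
  out <- lapply(seq_along(lags), function(i) {
    d <- simulate_turbidity(lags[[i]], noise_sd = noise_sd, lag_sd = lag_sd,
                            seed = seed + 7919L * i)
    cbind(condition = names(lags)[i], d)
  })
  do.call(rbind, out)
}

# Evaluate `expr` under a reproducible local RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
    set.seed(seed)
  }
  expr
}
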