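# End-to-end convenience wrappers.

#' Analyze a field of view
#'
#' Default pipeline: preprocessing (automatic intensity threshold + drift
#' correction), incremental segmentation with dissection of intertwined
#' clusters, then per-aggregate morphology fingerprinting, classification and
#' archetype-specific rate fitting.
#'
#' @param table a raw `loc_table`.
#' @param min_events clusters with fewer member localizations are dropped
#'   from the per-aggregate analysis (they still appear in the segmentation).
#' @param grid_nm,cadence_s morphology parameters, see
#'   [morphology_fingerprint()].
#' @param ... segmentation parameters, see [segment_fov()].
#' @return list of class `fov_analysis`: `table` (preprocessed),
#'   `segmentation`, and `aggregates` — a list with, per analyzed cluster,
#'   `members`, `fingerprint`, `classification`, `fit`.
#' @export
analyze_fov <- function(table, min_events = 50, grid_nm = 300,
                        cadence_s = NULL, ...) {
  pre <- preprocess(table)
  seg <- segment_fov(pre, ...)
  aggs <- list()
  for (cl in seg$clusters) {
    if (length(cl$members) < min_events) next
    fp <- morphology_fingerprint(pre, cl$members, grid_nm, cadence_s)
    cls <- classify_aggregate(fp)
    tc <- if (cls$label == "small")
      compute_area_curve(pre, cl$members, grid_nm = 100, cadence_s) else NULL
    fit <- tryCatch(fit_growth(fp$curve, cls$label, termination_curve = tc),
                    error = function(e) NULL)
    if (!is.null(fit) && !is.na(fit$termination_s))
      cls$terminated <- TRUE
    aggs[[as.character(cl$id)]] <-
      list(id = cl$id, members = cl$members, fingerprint = fp,
           classification = cls, fit = fit)
  }
  structure(list(table = pre, segmentation = seg, aggregates = aggs),
            class = "fov_analysis")
}

#' Segmentation accuracy benchmark on simulated fields of view
#'
#' Simulates `length(seeds)` fields of view with the standard benchmark
#' layout (three archetypes plus an intertwined pair, see
#' [standard_fov_mix()]), runs preprocessing and segmentation with the
#' default configuration, and scores per-localization assignment accuracy
#' against the ground-truth sidecar after optimal label matching.  Rows
#' removed by the intensity filter count as predicted noise.
#'
#' @param seeds integer vector of simulation seeds, one per field of view.
#' @param imaging base [imaging_model()]; its seed is replaced per field.
#'   The default adds a typical slow stage drift (1, -0.6) nm/frame, i.e.
#'   about a quarter micron over a 2 h acquisition, which the preprocessing
#'   stage must correct.
#' @param mix aggregate mix; default [standard_fov_mix()].
#' @return data.frame `seed`, `accuracy` with the mean accuracy as
#'   `attr(, "mean_accuracy")`.
#' @export
benchmark_segmentation <- function(seeds = 1:20,
                                   imaging = imaging_model(
                                     drift_velocity = c(1, -0.6)),
                                   mix = NULL) {
  if (is.null(mix)) mix <- standard_fov_mix(imaging$fov_size)
  acc <- vapply(seeds, function(s) {
    im <- imaging
    im$seed <- s
    sim <- simulate_fov(mix, im)
    pre <- preprocess(sim$localizations)
    seg <- segment_fov(pre)
    pred <- integer(nrow(sim$localizations))   # filtered rows -> noise
    pred[attr(pre, "kept_rows")] <- seg$labels
    segmentation_accuracy(pred, sim$truth$aggregate_id)
  }, numeric(1L))
  out <- data.frame(seed = seeds, accuracy = acc)
  attr(out, "mean_accuracy") <- mean(acc)
  out
}
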