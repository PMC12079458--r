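# Condition-level aggregate-type abundance statistics.

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percentage of small aggregates
#'
#' `round(100 * n_small / (n_small + n_spherulites))` with half-away-from-zero
#' rounding to an integer percent (the rounding that reproduces the published
#' count tables from their own counts).  Vectorized.
#'
#' @param n_spherulites,n_small non-negative counts.
#' @return integer percent(s).
#' @export
percent_small <- function(n_spherulites, n_small) {
  if (any(n_spherulites < 0) || any(n_small < 0))
    stop("percent_small: counts must be >= 0")
  tot <- n_spherulites + n_small
  if (any(tot == 0))
    stop("percent_small: undefined when both counts are zero")
  as.integer(round_half_up(100 * n_small / tot))
}

#' Aggregate per-image counts into a condition-level count table
#'
#' Sums spherulite and small-aggregate counts over the images of each
#' condition (typically four spinning-disk images from four replicates) and
#' carries the per-image standard error of the counts.
#'
#' @param per_image data.frame with `condition`, `spherulites`,
#'   `small_aggregates` (one row per image; an `image` column is optional).
#' @return data.frame of class `count_table`: `condition`, `n_images`,
#'   `n_spherulites`, `n_small`, `se_spherulites`, `se_small`,
#'   `percent_small`.
#' @export
tabulate_counts <- function(per_image) {
  if (!nrow(per_image))
    return(structure(data.frame(condition = character(0),
                                n_images = integer(0),
                                n_spherulites = numeric(0),
                                n_small = numeric(0),
                                se_spherulites = numeric(0),
                                se_small = numeric(0),
                                percent_small = integer(0)),
                     class = c("count_table", "data.frame")))
  stopifnot(all(c("condition", "spherulites", "small_aggregates") %in%
                  names(per_image)))
  se <- function(v) if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else 0
  out <- do.call(rbind, lapply(split(per_image, per_image$condition),
                               function(d)
    data.frame(condition = d$condition[1L], n_images = nrow(d),
               n_spherulites = sum(d$spherulites),
               n_small = sum(d$small_aggregates),
               se_spherulites = se(d$spherulites),
               se_small = se(d$small_aggregates))))
  out$percent_small <- percent_small(out$n_spherulites, out$n_small)
  rownames(out) <- NULL
  class(out) <- c("count_table", "data.frame")
  out
}

#' Published spinning-disk aggregate counts
#'
#' The condition-level counts of spherulites and small aggregates (summed
#' over four spinning-disk images per condition) shipped with the package as
#' a plain-text table; inputs for the abundance statistics.
#'
#' @return data.frame `condition`, `spherulites`, `small_aggregates`.
#' @export
spinning_disk_counts <- function() {
  utils::read.csv(system.file("extdata", "spinning_disk_counts.csv",
                              package = "replomics"),
                  stringsAsFactors = FALSE)
}
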