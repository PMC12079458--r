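# Incremental spatiotemporal segmentation.
#
# Concept: process the acquisition in time windows; in each window, run a
# density clustering pass over the not-yet-assigned localizations acquired so
# far, with every previously assigned localization acting as a fixed seed.
# Structural density accumulated over time lets sparse binding events on an
# existing aggregate reach core status; temporal pathways (which aggregate a
# dense group touches, and along which seeds it is reached) decide membership.
# Assignments are never revoked.  This is a reimplementation of the concept
# behind incremental SMLM aggregate segmentation, not of any particular
# published code.

#' Incremental spatiotemporal clustering of localizations
#'
#' @param table a `loc_table` (preprocessed; see [preprocess()]).
#' @param window_s window length, s; must be at least one frame interval.
#'   Default: 10 frame intervals.
#' @param eps_nm density-clustering neighbourhood radius, nm.
#' @param min_pts DBSCAN core-point threshold (neighbours within `eps_nm`,
#'   counting the point itself; >= 2).
#' @param link_radius_nm a newborn dense group lying within this distance of
#'   an existing aggregate's points is linked to that aggregate rather than
#'   founding a new one (nearest aggregate wins; ties to the lower id).
#' @param sweep_passes after the last window, unassigned points within
#'   `eps_nm` of an assigned point are attached to the nearest one, repeated
#'   this many passes (0 disables; used by the plain-DBSCAN oracle mode).
#' @param establish_windows an aggregate this many windows old is considered
#'   established: dense groups bridging two established aggregates are
#'   dissected point-by-point along nearest-seed pathways, whereas younger
#'   aggregates (satellite fragments of an advancing growth front) merge into
#'   whatever they become density-connected with.
#' @param sep_ratio two bridged established aggregates are kept separate only
#'   if they look externally tangent — centroid separation at least
#'   `sep_ratio` times the sum of their equivalent radii; otherwise they are
#'   shards of a single structure and merge.
#' @return object of class `replom_segmentation`: list with `labels`
#'   (integer per row, 0 = noise), `clusters` (list of per-aggregate records:
#'   id, member row indices, first/last event time, per-window centroid
#'   track) and the configuration.
#' @export
cluster_incremental <- function(table, window_s = NULL, eps_nm = 150,
                                min_pts = 5, link_radius_nm = 500,
                                sweep_passes = 2, establish_windows = 6,
                                sep_ratio = 0.7) {
  fi <- frame_interval(table)
  if (is.null(window_s)) window_s <- 10 * fi
  if (window_s < fi)
    stop("cluster_incremental: window_s must be >= the frame interval")
  if (eps_nm <= 0) stop("cluster_incremental: eps_nm must be > 0")
  if (min_pts < 2) stop("cluster_incremental: min_pts must be >= 2")
  n <- nrow(table)
  cfg <- list(window_s = window_s, eps_nm = eps_nm, min_pts = min_pts,
              link_radius_nm = link_radius_nm, sweep_passes = sweep_passes)
  if (n == 0L)
    return(structure(list(labels = integer(0), clusters = list(),
                          noise = integer(0), config = cfg),
                     class = "replom_segmentation"))
  tt <- loc_times(table)
  labels <- integer(n)
  next_id <- 1L
  birth <- integer(0)               # birth window index per aggregate id
  wends <- seq(min(tt) + window_s, max(tt) + window_s, by = window_s)
  for (wi in seq_along(wends)) {
    we <- wends[wi]
    act <- which(tt <= we)          # unassigned pool + seeds, cumulative
    lab_act <- labels[act]
    established <- if (next_id > 1L)
      (wi - birth) >= establish_windows else logical(0)
    nid <- next_id - 1L
    cen_x <- cen_y <- cen_r <- numeric(nid)
    if (nid > 0L) {
      pos <- lab_act > 0L
      if (any(pos)) {
        sx <- rowsum(table$x[act][pos], lab_act[pos])
        sy <- rowsum(table$y[act][pos], lab_act[pos])
        cnt <- rowsum(rep(1, sum(pos)), lab_act[pos])
        ids <- as.integer(rownames(sx))
        cen_x[ids] <- sx[, 1L] / cnt[, 1L]
        cen_y[ids] <- sy[, 1L] / cnt[, 1L]
        r2 <- rowsum((table$x[act][pos] - cen_x[lab_act[pos]])^2 +
                       (table$y[act][pos] - cen_y[lab_act[pos]])^2,
                     lab_act[pos])
        cen_r[ids] <- sqrt(2 * r2[, 1L] / cnt[, 1L])  # uniform-disc radius
      }
    }
    new_lab <- dbscan_seeded_cpp(table$x[act], table$y[act], lab_act,
                                 eps_nm, as.integer(min_pts), next_id,
                                 established, cen_x, cen_y, cen_r, sep_ratio)
    born <- sort(unique(new_lab[new_lab >= next_id]))
    if (length(born) && any(new_lab > 0 & new_lab < next_id) &&
        link_radius_nm > eps_nm) {
      # link newborn groups within link_radius of an existing footprint
      for (b in born) {
        mem <- which(new_lab == b)
        nl <- nearest_labeled_cpp(table$x[act], table$y[act],
                                  ifelse(new_lab > 0 & new_lab < next_id,
                                         new_lab, 0L),
                                  table$x[act][mem], table$y[act][mem],
                                  link_radius_nm)
        if (any(nl$label > 0)) {
          j <- which.min(ifelse(nl$label > 0, nl$dist, Inf))
          cand <- nl$label[nl$dist == nl$dist[j] & nl$label > 0]
          new_lab[mem] <- min(cand)
        }
      }
    }
    # renumber surviving new ids densely and record their birth window
    kept_new <- sort(unique(new_lab[new_lab >= next_id]))
    if (length(kept_new)) {
      remap <- seq.int(next_id, length.out = length(kept_new))
      new_lab[new_lab >= next_id] <-
        remap[match(new_lab[new_lab >= next_id], kept_new)]
      birth <- c(birth, rep.int(wi, length(kept_new)))
      next_id <- next_id + length(kept_new)
    }
    labels[act] <- new_lab
  }
  if (sweep_passes > 0 && any(labels > 0) && any(labels == 0)) {
    labels <- sweep_labels_cpp(table$x, table$y, labels, eps_nm,
                               as.integer(sweep_passes))
  }
  build_segmentation(table, labels, cfg)
}

build_segmentation <- function(table, labels, cfg) {
  tt <- loc_times(table)
  ids <- sort(unique(labels[labels > 0]))
  clusters <- lapply(ids, function(id) {
    mem <- which(labels == id)
    tw <- floor(tt[mem] / cfg$window_s)
    track <- do.call(rbind, lapply(split(mem, tw), function(ix)
      c(t = mean(tt[ix]), x = mean(table$x[ix]), y = mean(table$y[ix]))))
    list(id = id, members = mem,
         first_s = min(tt[mem]), last_s = max(tt[mem]),
         centroid_track = as.data.frame(track))
  })
  names(clusters) <- as.character(ids)
  structure(list(labels = labels, clusters = clusters,
                 noise = which(labels == 0), config = cfg),
            class = "replom_segmentation")
}

#' @export
print.replom_segmentation <- function(x, ...) {
  cat("<replom_segmentation> ", length(x$clusters), " aggregate(s), ",
      length(x$noise), " noise point(s) of ", length(x$labels),
      " localizations\n", sep = "")
  invisible(x)
}

#' Dissect an intertwined cluster
#'
#' Checks whether the early-time point cloud of one cluster contains two or
#' more density modes whose centroid tracks stay distinct over the cluster's
#' lifetime; if so, all member localizations are reassigned along
#' nearest-seed pathways (window by window, each point joins the group of its
#' nearest already-assigned member).  Single-origin clusters are returned
#' unchanged, as is everything when `k_windows = 0`.
#'
#' @param table the `loc_table` the cluster was built from.
#' @param members integer row indices of the cluster's localizations.
#' @param window_s,eps_nm,min_pts as in [cluster_incremental()].
#' @param k_windows number of initial windows that define the seed modes
#'   (0 disables splitting).
#' @param min_sep_nm early density modes closer than this merge into one
#'   origin before the track check.
#' @param sep_ratio scale-aware distinctness: at every window the group
#'   centroids must stay at least `sep_ratio` times the sum of the groups'
#'   equivalent radii apart (externally tangent or better), otherwise the
#'   groups are shards of one structure and the cluster is left unsplit.
#' @return a list of integer vectors (member indices), length 1 if unsplit.
#' @export
split_intertwined <- function(table, members, window_s = NULL, eps_nm = 150,
                              min_pts = 5, k_windows = 3, min_sep_nm = 1000,
                              sep_ratio = 0.7) {
  if (k_windows == 0 || length(members) < 2 * min_pts)
    return(list(members))
  fi <- frame_interval(table)
  if (is.null(window_s)) window_s <- 10 * fi
  tt <- loc_times(table)[members]
  t0 <- min(tt)
  early <- members[tt < t0 + k_windows * window_s]
  if (length(early) < 2 * min_pts) return(list(members))
  el <- dbscan_seeded_cpp(table$x[early], table$y[early],
                          integer(length(early)), eps_nm,
                          as.integer(min_pts), 1L, logical(0),
                          numeric(0), numeric(0), numeric(0), 0.7)
  modes <- sort(unique(el[el > 0]))
  sizes <- vapply(modes, function(m) sum(el == m), integer(1L))
  modes <- modes[sizes >= min_pts]
  if (length(modes) < 2L) return(list(members))
  # density modes closer than min_sep belong to one origin: merge them by
  # single linkage on their centroids, then require >= 2 distinct groups
  cen <- vapply(modes, function(m)
    c(mean(table$x[early][el == m]), mean(table$y[early][el == m])),
    numeric(2L))
  grp_of_mode <- stats::cutree(stats::hclust(stats::dist(t(cen)),
                                             method = "single"),
                               h = min_sep_nm)
  if (max(grp_of_mode) < 2L) return(list(members))
  el[el > 0] <- grp_of_mode[match(el[el > 0], modes)]
  modes <- sort(unique(el[el > 0]))

  # nearest-seed-pathway propagation through later windows
  grp <- integer(length(members))
  eidx <- match(early, members)
  grp[eidx[el > 0]] <- match(el[el > 0], modes)
  wb <- floor((tt - t0) / window_s)
  tracks_ok <- TRUE
  for (w in sort(unique(wb))) {
    todo <- which(grp == 0L & wb == w)
    if (length(todo)) {
      asg <- which(grp > 0L)
      nl <- nearest_labeled_cpp(table$x[members][asg], table$y[members][asg],
                                grp[asg], table$x[members][todo],
                                table$y[members][todo],
                                radius = max(min_sep_nm * 4, 1e4))
      grp[todo] <- nl$label
    }
    asg <- grp > 0L & wb <= w
    if (all(tabulate(grp[asg], length(modes)) > 0)) {
      cen_w <- vapply(seq_along(modes), function(m)
        c(mean(table$x[members][asg & grp == m]),
          mean(table$y[members][asg & grp == m])), numeric(2L))
      # equivalent (uniform-disc) radius of each group
      req <- vapply(seq_along(modes), function(m) {
        sel <- asg & grp == m
        sqrt(2 * mean((table$x[members][sel] - cen_w[1L, m])^2 +
                        (table$y[members][sel] - cen_w[2L, m])^2))
      }, numeric(1L))
      dmat <- as.matrix(stats::dist(t(cen_w)))
      for (a in seq_along(modes)[-1L])
        for (b in seq_len(a - 1L))
          if (dmat[a, b] < sep_ratio * (req[a] + req[b])) tracks_ok <- FALSE
    }
  }
  if (!tracks_ok || any(grp == 0L)) return(list(members))
  split(members, grp)
}

#' Count detected aggregates in a field of view
#'
#' @param seg a `replom_segmentation` (or list of clusters).
#' @param min_events minimum member localizations for a cluster to count.
#' @return integer count.
#' @export
count_per_fov <- function(seg, min_events = 1) {
  if (min_events < 1) stop("count_per_fov: min_events must be >= 1")
  cl <- if (inherits(seg, "replom_segmentation")) seg$clusters else seg
  sum(vapply(cl, function(c) length(c$members) >= min_events, logical(1L)))
}

#' Full segmentation pipeline for one field of view
#'
#' [cluster_incremental()] followed by a [split_intertwined()] pass over each
#' cluster (relabelling densely when a cluster is dissected).
#'
#' @inheritParams cluster_incremental
#' @param split_k `k_windows` of the dissection pass (0 disables).
#' @return a `replom_segmentation`.
#' @export
segment_fov <- function(table, window_s = NULL, eps_nm = 150, min_pts = 5,
                        link_radius_nm = 500, sweep_passes = 2, split_k = 3) {
  seg <- cluster_incremental(table, window_s, eps_nm, min_pts,
                             link_radius_nm, sweep_passes)
  if (split_k > 0 && length(seg$clusters)) {
    labels <- seg$labels
    next_id <- 1L
    out <- integer(length(labels))
    for (cl in seg$clusters) {
      parts <- split_intertwined(table, cl$members, window_s, eps_nm,
                                 min_pts, k_windows = split_k)
      for (p in parts) {
        out[p] <- next_id
        next_id <- next_id + 1L
      }
    }
    seg <- build_segmentation(table, out, seg$config)
  }
  seg
}

#' Per-localization segmentation accuracy against ground truth
#'
#' Predicted cluster ids are matched one-to-one to ground-truth aggregate ids
#' by greedy maximum overlap (noise, id 0, matches noise); accuracy is the
#' fraction of localizations whose mapped predicted id equals the true id.
#'
#' @param pred integer predicted labels (0 = noise).
#' @param truth integer ground-truth ids (0 = noise).
#' @return accuracy in `[0, 1]`.
#' @export
segmentation_accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (!length(pred)) return(NA_real_)
  pu <- sort(unique(pred[pred > 0]))
  tu <- sort(unique(truth[truth > 0]))
  mapped <- integer(length(pred))  # predicted ids mapped onto truth ids
  if (length(pu) && length(tu)) {
    ov <- table(factor(pred, levels = pu), factor(truth, levels = tu))
    map <- integer(length(pu))
    used <- logical(length(tu))
    repeat {
      if (all(ov < 0)) break
      k <- which.max(ov)
      if (ov[k] <= 0) break
      i <- (k - 1) %% length(pu) + 1
      j <- (k - 1) %/% length(pu) + 1
      map[i] <- tu[j]
      used[j] <- TRUE
      ov[i, ] <- -1
      ov[, j] <- -1
    }
    pos <- match(pred, pu)
    mapped[pred > 0] <- map[pos[pred > 0]]
  }
  mean(mapped == truth)
}
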