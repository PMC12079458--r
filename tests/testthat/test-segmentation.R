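# Incremental spatiotemporal clustering.

test_that("configuration errors and empty input", {
  tab <- static_table(1, 1)
  expect_error(cluster_incremental(tab, window_s = 1), "window_s")
  expect_error(cluster_incremental(tab, eps_nm = 0), "eps_nm")
  expect_error(cluster_incremental(tab, min_pts = 1), "min_pts")
  empty <- static_table(numeric(0), numeric(0))
  seg <- cluster_incremental(empty)
  expect_equal(length(seg$clusters), 0L)
  expect_equal(seg$labels, integer(0))
})

test_that("one aggregate, no noise: a single cluster holds the points", {
  sim <- simulate_aggregate(isotropic_model(), quick_imaging(2))
  seg <- cluster_incremental(sim$localizations)
  expect_equal(length(seg$clusters), 1L)
  expect_gt(segmentation_accuracy(seg$labels,
                                  rep(1L, nrow(sim$localizations))), 0.95)
  expect_partition(seg, nrow(sim$localizations))
})

test_that("two distant aggregates give two clusters, zero cross-assignment", {
  mix <- list(list(model = isotropic_model(rx = 4000), origin = c(8e3, 8e3)),
              list(model = isotropic_model(rx = 4000), origin = c(5.2e4, 5.2e4)))
  sim <- simulate_fov(mix, quick_imaging(5, false_positive_rate = 0))
  seg <- cluster_incremental(sim$localizations)
  expect_equal(length(seg$clusters), 2L)
  truth <- sim$truth$aggregate_id
  for (cl in seg$clusters)
    expect_equal(length(unique(truth[cl$members])), 1L)
})

test_that("single-window mode equals the brute-force DBSCAN oracle", {
  for (s in 1:5) {
    set.seed(100 + s)
    # three well-separated static blobs + background noise
    n <- 150
    blob <- function(cx, cy) cbind(rnorm(n, cx, 120), rnorm(n, cy, 120))
    pts <- rbind(blob(1000, 1000), blob(5000, 1200), blob(3000, 5200),
                 cbind(runif(30, 0, 6000), runif(30, 0, 6000)))
    tab <- static_table(pts[, 1], pts[, 2])
    seg <- cluster_incremental(tab, window_s = 1e6, eps_nm = 150,
                               min_pts = 5, sweep_passes = 0)
    ref <- brute_dbscan(pts[, 1], pts[, 2], eps = 150, min_pts = 5)
    expect_equal(segmentation_accuracy(seg$labels, ref), 1)
  }
})

test_that("assignments are incremental: early labels never revoked", {
  sim <- simulate_aggregate(isotropic_model(), quick_imaging(8))
  tab <- sim$localizations
  tt <- loc_times(tab)
  seg_half <- cluster_incremental(tab[tt <= 1800, , drop = FALSE])
  seg_full <- cluster_incremental(tab)
  half_assigned <- which(seg_half$labels > 0)
  # the full run assigns at least everything the half run did, to one cluster
  expect_true(all(seg_full$labels[half_assigned] > 0))
  expect_equal(length(unique(seg_full$labels[half_assigned])), 1L)
})

test_that("split_intertwined dissects a merged pair but not single origins", {
  mix <- list(list(model = isotropic_model(rx = 1700), origin = c(1.4e4, 1.5e4)),
              list(model = isotropic_model(rx = 1700), origin = c(1.7e4, 1.5e4)))
  sim <- simulate_fov(mix, quick_imaging(3, n_frames = 240,
                                         fov_size = c(3e4, 3e4),
                                         false_positive_rate = 0,
                                         binding_rate_per_area = 5e-6))
  tab <- sim$localizations
  members <- which(sim$truth$aggregate_id > 0)   # force one merged cluster
  parts <- split_intertwined(tab, members)
  expect_equal(length(parts), 2L)
  lab <- integer(nrow(tab))
  for (i in seq_along(parts)) lab[parts[[i]]] <- i
  expect_gt(segmentation_accuracy(lab, sim$truth$aggregate_id), 0.9)

  # single origin -> unchanged; k_windows = 0 disables
  one <- simulate_aggregate(isotropic_model(rx = 1700),
                            quick_imaging(4, n_frames = 240))
  m1 <- seq_len(nrow(one$localizations))
  expect_equal(length(split_intertwined(one$localizations, m1)), 1L)
  expect_equal(length(split_intertwined(tab, members, k_windows = 0)), 1L)
})

test_that("count_per_fov counts clusters above the event threshold", {
  expect_equal(count_per_fov(list()), 0L)
  fake <- list(list(members = 1:10), list(members = 1:3),
               list(members = 1:200))
  expect_equal(count_per_fov(fake, min_events = 1), 3L)
  expect_equal(count_per_fov(fake, min_events = 5), 2L)
  expect_error(count_per_fov(fake, min_events = 0), "min_events")
})

test_that("a standard field of view resolves its five aggregates", {
  sim <- simulate_fov(standard_fov_mix(), imaging_model(seed = 2))
  seg <- segment_fov(preprocess(sim$localizations))
  expect_equal(count_per_fov(seg, min_events = 50), 5L)
  expect_partition(seg, nrow(sim$localizations))
})
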