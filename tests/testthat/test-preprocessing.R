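# Intensity filtering and drift correction.

test_that("filter_intensity identity/empty boundaries and bookkeeping", {
  tab <- static_table(1:5 * 10, 1:5 * 10, intensity = c(100, 200, 300, 400, 500))
  expect_equal(nrow(filter_intensity(tab, 0)), 5L)
  expect_equal(nrow(filter_intensity(tab, 501)), 0L)
  f <- filter_intensity(tab, 250)
  expect_equal(attr(f, "n_removed"), 2L)
  expect_equal(attr(f, "kept_rows"), 3:5)
  expect_error(filter_intensity(tab, -1), ">= 0")
})

test_that("a threshold between the modes removes exactly the false positives", {
  mix <- list(list(model = isotropic_model(rx = 3000), origin = c(2e4, 2e4)))
  im <- quick_imaging(13, fov_size = c(4e4, 4e4), false_positive_rate = 20,
                      intensity_sdlog = 0.08)
  sim <- simulate_fov(mix, im)
  thr <- sqrt(600 * 1200)                 # geometric midpoint of the modes
  filt <- filter_intensity(sim$localizations, thr)
  removed <- setdiff(seq_len(nrow(sim$localizations)),
                     attr(filt, "kept_rows"))
  expect_true(all(sim$truth$aggregate_id[removed] == 0L))
  fp_rows <- which(sim$truth$aggregate_id == 0L)
  expect_gt(mean(fp_rows %in% removed), 0.99)
  # the automatic Otsu threshold lands between the modes here
  auto <- replomics:::auto_intensity_threshold(sim$localizations$intensity)
  expect_gt(auto, 700)
  expect_lt(auto, 1050)
})

test_that("auto threshold keeps everything when intensities are unimodal", {
  set.seed(1)
  v <- rlnorm(5000, log(1200), 0.15)
  expect_equal(replomics:::auto_intensity_threshold(v), 0)
})

test_that("drift: zero-drift estimates stay below one rendering pixel", {
  mix <- list(list(model = isotropic_model(rx = 8000), origin = c(2e4, 2e4)))
  sim <- simulate_fov(mix, quick_imaging(3, n_frames = 240,
                                         fov_size = c(4e4, 4e4)))
  dm <- estimate_drift(sim$localizations, bin_duration_s = 1800,
                       pixel_nm = 200)
  expect_lt(max(abs(as.data.frame(dm)[, c("dx", "dy")])), 200)
})

test_that("injected linear drift is recovered within 10% of its endpoint", {
  im <- imaging_model(seed = 9, n_frames = 600, drift_velocity = c(2, 0),
                      fov_size = c(4e4, 4e4))
  sim <- simulate_fov(list(list(model = isotropic_model(rx = 8000),
                                origin = c(2e4, 2e4))), im)
  dm <- estimate_drift(sim$localizations, bin_duration_s = 3000)
  end <- replomics:::drift_at(dm, (600 - 1) * 30)
  expect_lt(abs(end[, "dx"] - 2 * 599), 0.1 * 1200)
  expect_lt(abs(end[, "dy"]), 0.1 * 1200)
  # idempotence: after correction the re-estimated drift is ~ 0
  corr <- apply_drift(sim$localizations, dm)
  dm2 <- estimate_drift(corr, bin_duration_s = 3000)
  expect_lt(max(abs(as.data.frame(dm2)[, c("dx", "dy")])), 100)
})

test_that("apply_drift anchors at t = 0, inverts exactly, preserves order", {
  tab <- static_table(runif(50, 0, 1e4), runif(50, 0, 1e4),
                      frame = sample(1:100, 50, replace = TRUE))
  m <- drift_model(t = c(0, 1500, 3000), dx = c(0, 100, 250),
                   dy = c(0, -50, -80))
  expect_equal(unname(replomics:::drift_at(m, 0)[1, ]), c(0, 0))
  shifted <- apply_drift(tab, m)
  back <- apply_drift(shifted, m, invert = TRUE)
  expect_equal(back$x, tab$x, tolerance = 1e-12)
  expect_equal(back$y, tab$y, tolerance = 1e-12)
  expect_identical(back$frame, tab$frame)
  # identity model is the identity
  id <- drift_model(t = c(0, 1000), dx = c(0, 0), dy = c(0, 0))
  expect_equal(apply_drift(tab, id)$x, tab$x)
})

test_that("drift estimation refuses under-filled bins", {
  tab <- static_table(runif(30, 0, 1e4), runif(30, 0, 1e4),
                      frame = rep(1:30))
  expect_error(estimate_drift(tab, bin_duration_s = 300), "larger")
})

test_that("segmentation accuracy does not degrade with drift correction on", {
  # strong drift: 5 nm/frame ~ 1.2 um over the acquisition
  im <- imaging_model(seed = 4, drift_velocity = c(5, 0))
  sim <- simulate_fov(standard_fov_mix(), im)
  raw <- sim$localizations
  acc <- function(tab) {
    seg <- segment_fov(tab)
    segmentation_accuracy(seg$labels, sim$truth$aggregate_id)
  }
  a_corr <- acc(preprocess(raw, drift = TRUE))
  a_raw <- acc(preprocess(raw, drift = FALSE))
  expect_gte(a_corr + 0.005, a_raw)   # allow float-level ties
  expect_gt(a_corr, 0.9)
})
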