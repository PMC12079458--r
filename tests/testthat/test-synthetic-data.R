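# Generator: determinism, conservation, growth laws, turbidity shapes.

test_that("invalid configurations are rejected", {
  expect_error(growth_model("isotropic"), "rates")
  expect_error(growth_model("anisotropic", r1 = 1, r2 = 2), "t_switch")
  expect_error(growth_model("small", r_small = 5), "t_term")
  expect_error(isotropic_model(rx = -1), "rates")
  expect_error(imaging_model(n_frames = 0), "n_frames")
  expect_error(imaging_model(frame_interval = 0), "frame_interval")
  expect_error(simulate_turbidity(100, plateau = -1), "plateau")
  expect_error(simulate_fov(list(list(model = isotropic_model(),
                                      origin = c(-5, 0))),
                            imaging_model()), "origin")
})

test_that("identical seed and config give byte-identical tables", {
  mix <- list(list(model = isotropic_model(rx = 5000), origin = c(1e4, 1e4)),
              list(model = small_model(), origin = c(3e4, 3e4)))
  im <- quick_imaging(42, fov_size = c(4e4, 4e4),
                      drift_velocity = c(0.5, -0.5))
  a <- simulate_fov(mix, im)
  b <- simulate_fov(mix, im)
  expect_identical(a$localizations, b$localizations)
  expect_identical(a$truth$aggregate_id, b$truth$aggregate_id)
  # and a different seed gives different draws
  im$seed <- 43L
  expect_false(identical(simulate_fov(mix, im)$localizations,
                         a$localizations))
})

test_that("non-noise localizations are conserved across the union", {
  mix <- standard_fov_mix()
  sim <- simulate_fov(mix, quick_imaging(7))
  id <- sim$truth$aggregate_id
  expect_equal(sum(id > 0), nrow(sim$localizations) - sum(id == 0))
  expect_true(all(sort(unique(id)) %in% 0:length(mix)))
  # every non-noise localization maps to exactly one aggregate id
  expect_false(anyNA(id))
})

test_that("empty mix yields only false positives", {
  sim <- simulate_fov(list(), quick_imaging(3, false_positive_rate = 5))
  expect_true(all(sim$truth$aggregate_id == 0L))
  expect_gt(nrow(sim$localizations), 0)
})

test_that("zero growth keeps localizations near the nucleus", {
  m <- isotropic_model(rx = 0, nucleus_radius = 300)
  im <- quick_imaging(5, binding_rate_per_area = 2e-5, localization_sigma = 5,
                      site_fraction = 0)
  sim <- simulate_aggregate(m, im, origin = c(0, 0))
  r <- sqrt(sim$localizations$x^2 + sim$localizations$y^2)
  expect_gt(length(r), 50)
  expect_true(all(r <= 300 + 3 * 5))
})

test_that("true area laws follow the archetype (slope recovery within 2%)", {
  sim <- simulate_aggregate(isotropic_model(), quick_imaging(1))
  ar <- sim$truth$area
  sl <- stats::coef(lm(area_nm2 ~ time_s, ar))[2L]
  expect_lt(abs(sl / 29211 - 1), 0.02)
  # final area of the noiseless law
  expect_equal(ar$area_nm2[nrow(ar)],
               pi * 300^2 + 29211 * ar$time_s[nrow(ar)])

  sm <- simulate_aggregate(small_model(r_small = 1170, t_term = 7620),
                           quick_imaging(1, n_frames = 320))
  a2 <- sm$truth$area
  post <- a2$time_s > 7620
  expect_true(all(diff(a2$area_nm2[post]) == 0))

  an <- simulate_aggregate(anisotropic_model(), quick_imaging(1, n_frames = 360))
  a3 <- an$truth$area
  s1 <- stats::coef(lm(area_nm2 ~ time_s, a3[a3$time_s <= 3600, ]))[2L]
  s2 <- stats::coef(lm(area_nm2 ~ time_s, a3[a3$time_s > 3600, ]))[2L]
  expect_lt(abs(s1 / 1599 - 1), 1e-9)
  expect_lt(abs(s2 / 8073 - 1), 1e-9)
})

test_that("phase-1 anisotropy and isotropic symmetry show in the point cloud", {
  m <- anisotropic_model(aspect_ratio_phase1 = 4)
  im <- quick_imaging(11, n_frames = 100, localization_sigma = 5)
  sim <- simulate_aggregate(m, im)   # 100 frames, all inside phase 1
  ev <- eigen(stats::cov(cbind(sim$localizations$x, sim$localizations$y)),
              only.values = TRUE)$values
  expect_gt(sqrt(ev[1L] / ev[2L]), 4 - 0.8)
  iso <- simulate_aggregate(isotropic_model(), quick_imaging(11))
  ev2 <- eigen(stats::cov(cbind(iso$localizations$x, iso$localizations$y)),
               only.values = TRUE)$values
  expect_lt(sqrt(ev2[1L] / ev2[2L]), 1.2)
})

test_that("well-separated aggregates give spatially disjoint truth sets", {
  mix <- list(list(model = isotropic_model(rx = 2000), origin = c(5e3, 5e3)),
              list(model = isotropic_model(rx = 2000), origin = c(5.5e4, 5.5e4)))
  sim <- simulate_fov(mix, quick_imaging(9, false_positive_rate = 0))
  g1 <- sim$truth$aggregate_id == 1L
  g2 <- sim$truth$aggregate_id == 2L
  expect_gt(min(sim$localizations$x[g2]) - max(sim$localizations$x[g1]), 1e4)
})

test_that("turbidity: noiseless replicates identical, lag boundary, tangent law", {
  tb <- simulate_turbidity(103, noise_sd = 0, lag_sd = 0, n_replicates = 3,
                           seed = 1)
  w <- reshape(tb, idvar = "time_min", timevar = "replicate",
               direction = "wide")
  expect_equal(w[[2L]], w[[3L]])
  expect_equal(w[[2L]], w[[4L]])
  # lag ~ 0 with signal rising from the start
  t0 <- subset(simulate_turbidity(0, noise_sd = 0, lag_sd = 0, seed = 1),
               replicate == 1)
  expect_lt(abs(estimate_lag(t0$time_min, t0$absorbance)), 10)
  # generating lag 160 on a 10-min grid is recovered within one grid step
  t1 <- subset(simulate_turbidity(160, noise_sd = 0, lag_sd = 0, seed = 1),
               replicate == 1)
  expect_lt(abs(estimate_lag(t1$time_min, t1$absorbance) - 160), 10)
})
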