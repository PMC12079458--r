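# Growth-rate fitting, termination, condition statistics, Welch test.

noiseless_two_phase <- function(r1, r2, tc, t_end, by = 30, a0 = 1000) {
  t <- seq(0, t_end, by = by)
  growth_curve(t, a0 + r1 * pmin(t, tc) + r2 * pmax(t - tc, 0))
}

test_that("single-rate fit recovers exact lines and clips at zero", {
  t <- seq(0, 3600, by = 30)
  cv <- growth_curve(t, 1000 + 29211 * t)
  fit <- fit_single_rate(cv, window = seq_along(t))
  expect_equal(unname(fit$rates[["rx"]]), 29211, tolerance = 1e-9)
  expect_equal(unname(fit$se[["rx"]]), 0, tolerance = 1e-6)
  flat <- fit_single_rate(growth_curve(t, rep(5, length(t))),
                          window = seq_along(t))
  expect_equal(unname(flat$rates[["rx"]]), 0)
  expect_error(fit_single_rate(growth_curve(c(0, 30), c(0, 1))), "3 points")
})

test_that("two-phase fit recovers exact piecewise lines", {
  cv <- noiseless_two_phase(1599, 8073, 5000, 10000, by = 50)
  fit <- fit_two_phase(cv, window = seq_len(nrow(cv)))
  expect_false(fit$degenerate)
  expect_equal(unname(fit$rates[["r1"]]), 1599, tolerance = 1e-9)
  expect_equal(unname(fit$rates[["r2"]]), 8073, tolerance = 1e-9)
  expect_equal(fit$changepoint_s, 5000)
  # a pure line is flagged degenerate with both rates equal
  lin <- growth_curve(seq(0, 3000, 30), 100 + 50 * seq(0, 3000, 30))
  dfit <- fit_two_phase(lin, window = seq_len(101))
  expect_true(dfit$degenerate)
  expect_equal(unname(dfit$rates[["r1"]]), unname(dfit$rates[["r2"]]))
  expect_error(fit_two_phase(growth_curve(seq(0, 120, 30), 1:5)), "6 points")
})

test_that("two-phase fit equals the exhaustive-scan oracle on noisy curves", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- sample(50:200, 1)
    t <- seq(0, by = 30, length.out = n)
    tc <- t[sample(10:(n - 10), 1)]
    a <- cumsum(pmax(1000 + 800 * (t > tc) + rnorm(n, 0, 300), 0))
    a <- cummax(a)
    cv <- growth_curve(t, a)
    fit <- fit_two_phase(cv, window = seq_len(n), min_improvement = 0)
    # independent oracle: plain lm over every interior candidate
    sse <- vapply(3:(n - 3), function(j) {
      sum(stats::residuals(stats::lm(a ~ t + pmax(t - t[j], 0)))^2)
    }, numeric(1))
    best <- (3:(n - 3))[which.min(sse)]
    expect_equal(fit$changepoint_s, t[best])
  }
})

test_that("termination detection: exact kink, flat and linear boundaries", {
  t <- seq(0, 9600, by = 30)
  kinked <- growth_curve(t, 1000 + 1170 * pmin(t, 7620))
  est <- detect_termination(kinked)
  expect_lt(abs(est - 7620), 60)
  # strictly linear curve -> no termination
  expect_null(detect_termination(growth_curve(t, 10 + 3 * t)))
  # all-flat curve -> termination at start
  expect_equal(detect_termination(growth_curve(t, rep(7, length(t)))), 0)
  expect_error(detect_termination(kinked, plateau_window_s = 1e6), "shorter")
})

test_that("fit_growth dispatches per archetype and records termination", {
  t <- seq(0, 9600, by = 30)
  kinked <- growth_curve(t, 1000 + 1170 * pmin(t, 7620))
  fs <- fit_growth(kinked, "small")
  expect_equal(fs$archetype, "small")
  expect_lt(abs(fs$termination_s - 7620), 60)
  expect_lt(abs(fs$rates[["r"]] / 1170 - 1), 0.02)
  expect_error(fit_growth(kinked, "weird"), "archetype")
})

test_that("summarize_condition: closed-form SE, n conservation, Table-like shape", {
  mk <- function(arch, rates) replomics:::new_rate_fit(arch, rates,
                                                       rates * 0)
  fits <- c(lapply(1:39, function(i) mk("anisotropic",
                                        c(r1 = 1500 + i, r2 = 8000 + i))),
            lapply(1:16, function(i) mk("isotropic", c(rx = 29000 + i))),
            lapply(1:2, function(i) mk("small", c(r = 1700 + i))))
  sm <- summarize_condition(fits, "control")
  expect_equal(sm$n[sm$rate == "r1"], 39L)
  expect_equal(sm$n[sm$rate == "rx"], 16L)
  expect_equal(sm$n[sm$rate == "r"], 2L)
  # n conservation: anisotropic counted once per aggregate
  expect_equal(sum(sm$n[sm$rate != "r2"]), length(fits))
  # closed-form SE: {1,2,3} -> mean 2, SE 0.5774
  s3 <- summarize_condition(list(mk("isotropic", c(rx = 1)),
                                 mk("isotropic", c(rx = 2)),
                                 mk("isotropic", c(rx = 3))))
  expect_equal(s3$mean[s3$rate == "rx"], 2)
  expect_equal(s3$se[s3$rate == "rx"], 0.5773503, tolerance = 1e-6)
  # single fit: SE reported as 0 and flagged undefined
  s1 <- summarize_condition(list(mk("small", c(r = 5))))
  expect_equal(s1$se[s1$rate == "r"], 0)
  expect_false(s1$se_defined[s1$rate == "r"])
  # absent archetypes appear with n = 0
  expect_equal(s1$n[s1$rate == "rx"], 0L)
})

test_that("welch_t_test matches the standard-library oracle", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_t_test(a, b)
  o <- stats::t.test(a, b)
  expect_equal(w$t, unname(o$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(o$parameter), tolerance = 1e-12)
  expect_equal(w$p, o$p.value, tolerance = 1e-12)
  # frozen closed-form values for this example
  expect_equal(w$t, -1.095445, tolerance = 1e-6)
  expect_equal(w$p, 0.3153, tolerance = 1e-3)
  # antisymmetry
  w2 <- welch_t_test(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  # identical samples -> t = 0, p = 1 (also with zero variance)
  wi <- welch_t_test(a, a)
  expect_equal(wi$t, 0)
  expect_equal(wi$p, 1)
  wz <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(wz$p, 1)
  expect_error(welch_t_test(1, a), "n >= 2")
})

test_that("rate fits of simulated aggregates stay within tolerance (smoke)", {
  # deeper 20-seed study lives in test-acceptance.R
  sim <- simulate_aggregate(anisotropic_model(),
                            quick_imaging(3, n_frames = 360))
  fit <- fit_two_phase(compute_area_curve(sim$localizations))
  expect_lt(abs(fit$changepoint_s / 3600 - 1), 0.1)
  expect_lt(abs(fit$rates[["r2"]] / 8073 - 1), 0.15)
})
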