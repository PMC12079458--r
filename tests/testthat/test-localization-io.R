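# Localization table I/O and rendering.

test_that("write/read round-trips synthetic tables (property over configs)", {
  for (s in 1:4) {
    im <- quick_imaging(s, n_frames = 30, fov_size = c(2e4, 2e4),
                        false_positive_rate = 3)
    sim <- simulate_fov(list(list(model = isotropic_model(rx = 3000),
                                  origin = c(1e4, 1e4))), im)
    f <- withr::local_tempfile(fileext = ".csv")
    write_localizations(sim$localizations, f)
    back <- read_localizations(f, frame_interval_s = 30)
    expect_equal(back$frame, sim$localizations$frame)
    expect_equal(back$x, sim$localizations$x, tolerance = 1e-9)
    expect_equal(back$y, sim$localizations$y, tolerance = 1e-9)
    expect_equal(back$intensity, sim$localizations$intensity,
                 tolerance = 1e-9)
  }
})

test_that("ground-truth sidecar round-trips", {
  ids <- c(0L, 1L, 1L, 2L, 0L, 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(ids, f)
  expect_identical(read_ground_truth(f), ids)
})

test_that("dialects: thunderstorm header and generic column map parse alike", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frame = c(1L, 2L), x = c(10.5, 20.25), y = c(5, 7),
                   intensity = c(900, 1100))
  writeLines(c("\"frame\",\"x [nm]\",\"y [nm]\",\"intensity [photon]\"",
               "1,10.5,5,900", "2,20.25,7,1100"), f1)
  writeLines(c("frame_id,x_nm,y_nm,photons",
               "1,10.5,5,900", "2,20.25,7,1100"), f2)
  a <- read_localizations(f1)
  b <- read_localizations(f2, dialect = "generic",
                          column_map = list(frame = "frame_id", x = "x_nm",
                                            y = "y_nm",
                                            intensity = "photons"))
  expect_equal(as.data.frame(a)[1:4], as.data.frame(b)[1:4])
  expect_equal(df$x, a$x)
})

test_that("schema and parse errors are informative; empty file is fine", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("\"frame\",\"x [nm]\",\"y [nm]\"", f)
  expect_error(read_localizations(f), "intensity")
  writeLines(c("\"frame\",\"x [nm]\",\"y [nm]\",\"intensity [photon]\"",
               "1,10,5,bad"), f)
  expect_error(read_localizations(f), "line")
  writeLines("\"frame\",\"x [nm]\",\"y [nm]\",\"intensity [photon]\"", f)
  empty <- read_localizations(f)
  expect_equal(nrow(empty), 0L)
  expect_error(read_localizations(file.path(tempdir(), "nope.csv")), "file")
})

test_that("unknown columns are preserved as opaque extras", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("\"frame\",\"x [nm]\",\"y [nm]\",\"intensity [photon]\",\"sigma\"",
               "1,10,5,900,21.5"), f)
  tab <- read_localizations(f)
  expect_equal(tab$sigma, 21.5)
})

test_that("rendering bins correctly and conserves counts", {
  tab <- static_table(c(50, 150, 250), c(50, 50, 50))
  img <- render_reconstruction(tab, 100, bounds = list(x = c(0, 300),
                                                       y = c(0, 100)))
  expect_equal(dim(img), c(3L, 1L))
  expect_equal(as.numeric(img), c(1, 1, 1))
  # single localization -> exactly one nonzero pixel
  one <- static_table(123, 456)
  img1 <- render_reconstruction(one, 50, bounds = list(x = c(0, 500),
                                                       y = c(0, 500)))
  expect_equal(sum(img1 > 0), 1L)
  expect_equal(sum(img1), 1)
  # t_max = 0 keeps only frame 1 (time 0); later frames drop out
  two <- static_table(c(10, 20), c(10, 20), frame = c(1L, 5L))
  expect_equal(sum(render_reconstruction(two, 10, t_max = 0)), 1)
  # conservation within t_max
  sim <- simulate_aggregate(isotropic_model(), quick_imaging(2, n_frames = 40),
                            origin = c(3e4, 3e4))
  img2 <- render_reconstruction(sim$localizations, 200, t_max = 20 * 30)
  expect_equal(sum(img2), sum(loc_times(sim$localizations) <= 600))
  # empty table -> zero image, no error
  expect_equal(sum(render_reconstruction(static_table(numeric(0), numeric(0)),
                                         100)), 0)
})

test_that("frame timing follows the 1-based convention", {
  tab <- static_table(c(0, 0), c(0, 0), frame = c(1L, 11L),
                      frame_interval = 30)
  expect_equal(loc_times(tab), c(0, 300))
})
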