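test_that("frame statistics use the sample SD with sensible degenerate cases", {
  s <- frame_stats(c(10, 10, 10))
  expect_equal(s$mean_fluor, 10)
  expect_equal(s$sd_fluor, 0)

  s2 <- frame_stats(c(0, 20))
  expect_equal(s2$mean_fluor, 10)
  expect_equal(s2$sd_fluor, sqrt(200))

  s3 <- frame_stats(42)
  expect_equal(s3$n_cells, 1)
  expect_equal(s3$sd_fluor, 0)

  expect_error(frame_stats(numeric(0)), "at least one")
})

test_that("series statistics skip empty frames with a warning", {
  meas <- data.frame(
    frame_index = c(0, 0, 1, 2),
    time_h = c(0, 0, 1, 2),
    mean_normalized = c(5, 7, NA, 9),
    valid = c(TRUE, TRUE, TRUE, TRUE)
  )
  expect_warning(out <- series_stats(meas), "no valid cells")
  expect_equal(out$frame_index, c(0, 2))
  expect_equal(out$n_cells, c(2, 1))
})

test_that("the noise baseline is exact on noiseless lines and matches closed-form OLS", {
  m <- c(10, 20, 40, 80)
  fit <- fit_noise_baseline(data.frame(mean_fluor = m, sd_fluor = 0.1 * m + 2))
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(coef(fit)), c(2, 0.1))
  expect_equal(predict(fit, 100), 12)

  # normal-equations oracle on random point sets
  set.seed(51)
  for (i in 1:10) {
    x <- runif(30, 5, 200)
    y <- 0.05 * x + 3 + rnorm(30)
    got <- fit_noise_baseline(data.frame(mean_fluor = x, sd_fluor = y))
    xb <- mean(x); yb <- mean(y)
    slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    intercept <- yb - slope * xb
    expect_equal(got$slope, slope, tolerance = 1e-10)
    expect_equal(got$intercept, intercept, tolerance = 1e-10)
  }

  expect_error(fit_noise_baseline(data.frame(mean_fluor = c(1, 2), sd_fluor = c(1, 2))),
               "at least 3")
  expect_error(
    fit_noise_baseline(data.frame(mean_fluor = c(5, 5, 5), sd_fluor = 1:3)),
    "degenerate design"
  )
})

test_that("parameter recovery from a simulated four-level induction design", {
  pts <- simulate_control_series(seed = 52)
  expect_gte(nrow(pts), 500)
  fit <- fit_noise_baseline(pts)
  expect_lt(abs(fit$slope - 0.1) / 0.1, 0.1)
  expect_lt(abs(fit$intercept - 2) / 2, 0.1)
  expect_gt(fit$r_squared, 0.9)
})

test_that("heterogeneity correction subtracts the predicted baseline exactly", {
  model <- structure(list(slope = 0.1, intercept = 2, r_squared = 1,
                          n_points = 10, se_slope = 0, se_intercept = 0),
                     class = "noise_model")
  stats <- data.frame(frame_index = 0:1, time_h = 0:1, n_cells = 50,
                      mean_fluor = c(100, 100), sd_fluor = c(12, 20))
  out <- correct_heterogeneity(stats, model)
  expect_equal(out$predicted_sd, c(12, 12))
  expect_equal(out$corrected, c(0, 8))

  # monotone in raw SD at fixed mean; negatives preserved
  stats2 <- data.frame(mean_fluor = 50, sd_fluor = seq(0, 20, by = 2))
  out2 <- correct_heterogeneity(stats2, model)
  expect_identical(order(out2$corrected), order(out2$sd_fluor))
  expect_lt(min(out2$corrected), 0)
})

test_that("noise models survive a JSON round trip", {
  pts <- simulate_control_series(frames_per_level = 10, seed = 53)
  fit <- fit_noise_baseline(pts)
  path <- withr::local_tempfile(fileext = ".json")
  write_noise_model(fit, path)
  back <- read_noise_model(path)
  expect_equal(back$slope, fit$slope)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$r_squared, fit$r_squared)
  expect_equal(back$n_points, fit$n_points)
  expect_equal(predict(back, c(10, 50)), predict(fit, c(10, 50)))
})

test_that("time-point summaries pool frames exactly as concatenated cell values", {
  set.seed(54)
  v1 <- rnorm(30, 50, 8)
  v2 <- rnorm(45, 60, 12)
  stats <- rbind(
    frame_stats(v1, frame_index = 0, time_h = 1.0),
    frame_stats(v2, frame_index = 1, time_h = 1.4)
  )
  out <- summarize_timepoints(stats, times = 1.2, window_h = 0.5)
  pooled <- c(v1, v2)
  expect_equal(out$combined_mean, mean(pooled))
  expect_equal(out$combined_sd, sd(pooled))
  expect_equal(out$n_cells, 75)

  # nearest-frame matching picks the earlier frame on the smaller distance
  stats2 <- rbind(
    frame_stats(v1, frame_index = 0, time_h = 4.9),
    frame_stats(v2, frame_index = 1, time_h = 5.2)
  )
  near <- summarize_timepoints(stats2, times = 5.0)
  expect_equal(near$combined_mean, mean(v1))
  expect_equal(near$n_frames, 1)

  expect_equal(nrow(summarize_timepoints(stats2, times = c(4.95, 5.1))), 2)
  expect_error(summarize_timepoints(stats2, times = 7), "outside the series span")
})

test_that("the descriptive mode count separates unimodal from well-split bimodal data", {
  set.seed(55)
  uni <- rnorm(400, 100, 8)
  bi <- c(rnorm(200, 15, 5), rnorm(200, 150, 15))
  expect_equal(count_modes(uni), 1L)
  expect_gte(count_modes(bi), 2L)
})
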