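test_that("population simulation seeds, grows and divides deterministically", {
  p <- scenario_params("homogeneous", n_initial = 10, seed = 71)
  pop0 <- simulate_population(p, 0)
  expect_equal(nrow(pop0), 10)
  expect_true(all(pop0$length_px >= p$init_length_px))
  expect_true(all(pop0$length_px <= p$division_length_px))

  # after one doubling time every starter has divided about once
  pop1 <- simulate_population(p, p$doubling_time_h)
  expect_gte(nrow(pop1), 19)
  expect_lte(nrow(pop1), 23)

  # exact replay with the same seed
  again <- simulate_population(p, p$doubling_time_h)
  expect_identical(pop1, again)

  # daughters inherit the lineage and lengths stay in range
  expect_true(all(is.na(pop0$lineage_parent)))
  expect_true(any(!is.na(pop1$lineage_parent)))
  expect_true(all(pop1$length_px < p$division_length_px + 1e-9))
})

test_that("the bistable high-mode fraction follows the configured mixture", {
  p <- scenario_params("bistable", n_initial = 1000, fraction_high = 0.3,
                       field = c(4096, 4096), seed = 72)
  pop <- simulate_population(p, 0)
  frac <- mean(pop$mode == "high")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.3) / 1000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("rendering produces the documented optics and exact ground truth", {
  opt <- render_params(field = c(64, 64), phase_noise_sd = 0, fluor_noise_sd = 0)
  empty <- render_frame(new_cells <- data.frame(), opt)
  expect_true(all(empty$phase == 180))
  expect_true(all(empty$fluor == 8))
  expect_true(all(empty$labels == 0))

  p <- scenario_params("homogeneous", field = c(64, 64), seed = 73)
  set.seed(73)
  cells <- place_cells(p, 1)
  cells$true_intensity <- 120.4
  fr <- render_frame(cells, opt)
  interior <- fr$labels == 1
  expect_true(sum(interior) > 0)
  expect_true(all(fr$fluor[interior] == 120))
  expect_true(all(fr$phase[interior] == 60))

  # with noise, the region mean over the truth mask recovers the intensity
  optn <- render_params(field = c(64, 64))
  frn <- render_frame(cells, optn, seed = 74)
  m <- mean(frn$fluor[frn$labels == 1])
  se <- optn$fluor_noise_sd / sqrt(sum(frn$labels == 1))
  expect_lt(abs(m - 120), 1 + 3 * se)  # rounding plus read-noise tolerance

  expect_error(render_params(field = c(8, 8)), "field too small")
})

test_that("generated series are fencepost-complete, reproducible, and truthful", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p <- scenario_params("homogeneous", n_initial = 4, field = c(96, 96),
                       division_length_px = 16, init_length_px = 9,
                       width_px = 4, seed = 75)
  gen <- generate_timeseries(p, duration_h = 2, interval_h = 0.5, outdir = dir1)
  expect_equal(gen$n_frames, 5)
  expect_length(list.files(dir1, pattern = "_ph\\.tif$"), 5)

  truth <- read_measurements(gen$truth)
  expect_true(all(truth$mode == "single"))

  generate_timeseries(p, duration_h = 2, interval_h = 0.5, outdir = dir2)
  for (f in list.files(dir1, pattern = "\\.(tif|csv)$")) {
    expect_identical(readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f))),
                     readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f))),
                     label = f)
  }

  ts <- load_timeseries(dir1, interval_h = 0.5)
  expect_length(ts, 5)
  expect_equal(ts$frames[[5]]$time_h, 2)
})

test_that("segmentation plus quantification recovers true intensities end to end", {
  set.seed(76)
  p <- scenario_params("bistable", field = c(256, 256), seed = 76)
  cells <- place_cells(p, 15)
  opt <- render_params(field = c(256, 256))
  fr <- render_frame(cells, opt, seed = 77)
  seg <- segment_frame(fr$phase)
  q <- quantify_frame(fr$fluor, seg$mask, seg$particles)
  # match each measured particle to the nearest truth cell by centroid
  errs <- vapply(seq_len(nrow(q)), function(i) {
    part <- seg$particles[[q$particle_id[i]]]
    d2 <- (cells$center_row - part$centroid["row"])^2 +
          (cells$center_col - part$centroid["col"])^2
    truth <- cells$true_intensity[which.min(d2)]
    abs(q$mean_raw[i] - min(round(truth), 255))
  }, numeric(1))
  expect_equal(nrow(q), 15)
  expect_lt(mean(errs), opt$fluor_noise_sd)
})

test_that("colony layout keeps cells resolvable and modes heritable", {
  dir <- withr::local_tempdir()
  p <- scenario_params("bistable", n_initial = 5, field = c(256, 256), seed = 78)
  gen <- generate_timeseries(p, duration_h = 2, interval_h = 1, outdir = dir,
                             layout = "colony")
  truth <- read_measurements(gen$truth)
  # population grows roughly exponentially
  n_by_frame <- table(truth$frame_index)
  expect_gt(n_by_frame[[3]], n_by_frame[[1]] * 2.5)
  expect_true(all(truth$mode %in% c("low", "high")))
})
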