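test_that("background subtraction removes flat fields and preserves small features", {
  expect_true(all(subtract_background(matrix(100, 20, 20), 5) == 0))
  expect_true(all(subtract_background(matrix(100, 20, 20), 5, light_background = TRUE) == 0))

  # single bright spot, radius much larger than the spot: spot preserved
  img <- matrix(20, 32, 32)
  img[16, 16] <- 220
  out <- subtract_background(img, 8)
  expect_equal(out[16, 16], 200)
  expect_true(all(out[-(16 + 15 * 32)] <= 1))

  expect_error(subtract_background(img, 0), "radius")
})

test_that("background subtraction equals the brute-force grayscale opening residual", {
  set.seed(21)
  img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  for (r in c(2, 5)) {
    want <- pmin(pmax(round(img - brute_opening(img, r)), 0), 255)
    expect_identical(subtract_background(img, r), want)
  }
  # range contract on random images
  for (i in 1:5) {
    img <- matrix(sample(0:255, 24 * 24, TRUE), 24, 24)
    out <- subtract_background(img, 4)
    expect_true(min(out) >= 0 && max(out) <= 255)
  }
})

test_that("convolution is exact against a nested-loop oracle and honors contracts", {
  ident <- matrix(0, 3, 3)
  ident[2, 2] <- 1
  set.seed(22)
  img <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  expect_identical(convolve_kernel(img, make_kernel(ident)), img * 1)

  ones <- make_kernel(matrix(1, 3, 3), normalize = TRUE)
  expect_true(all(convolve_kernel(matrix(77, 10, 10), ones) == 77))

  # sharpening kernel on a step edge: overshoot, verified against brute force
  step <- matrix(50, 16, 16)
  step[, 9:16] <- 200
  sharp <- matrix(-1, 3, 3)
  sharp[2, 2] <- 9
  got <- convolve_kernel(step, make_kernel(sharp, normalize = FALSE))
  expect_identical(got, brute_convolve(step, sharp))
  expect_true(max(got) == 255 && min(got) == 0)  # overshoot both ways, clamped

  set.seed(23)
  img2 <- matrix(sample(0:255, 16 * 16, TRUE), 16, 16)
  k5 <- matrix(sample(-2:2, 25, TRUE), 5, 5)
  expect_identical(convolve_kernel(img2, make_kernel(k5, normalize = TRUE)),
                   brute_convolve(img2, k5, normalize = TRUE))

  expect_error(make_kernel(matrix(1, 4, 4)), "odd")
})

test_that("intermeans threshold matches the fixed-point oracle and shifts with intensity", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  expect_identical(auto_threshold(img), 105L)

  expect_identical(auto_threshold(matrix(50, 5, 5)), 50L)
  seg <- segment_frame(matrix(50, 40, 40))
  expect_length(seg$particles, 0)

  set.seed(24)
  for (i in 1:10) {
    img <- matrix(sample(0:240, 20 * 20, TRUE), 20, 20)
    t1 <- auto_threshold(img)
    expect_true(t1 %in% isodata_fixed_points(as.numeric(img)))
    expect_identical(auto_threshold(img + 10), t1 + 10L)
  }
})

test_that("binarization is strict and always produces a 0/255 mask", {
  img <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_true(all(binarize(img, 0, "above")[img > 0] == 255))
  expect_true(all(binarize(img, 255, "above") == 0))
  set.seed(25)
  img2 <- matrix(sample(0:255, 100, TRUE), 10, 10)
  m <- binarize(img2, 128, "below")
  expect_true(all(m %in% c(0, 255)))
  expect_equal(sum(m == 255), sum(img2 < 128))
})

test_that("despeckle removes isolated pixels, keeps block interiors, and is idempotent", {
  m <- matrix(0, 9, 9)
  m[5, 5] <- 255
  expect_true(all(despeckle(m) == 0))

  solid <- matrix(0, 9, 9)
  solid[3:7, 3:7] <- 255
  out <- despeckle(solid)
  expect_true(all(out[4:6, 4:6] == 255))

  # speckle-only masks are emptied by one pass and stay stable
  set.seed(26)
  for (i in 1:10) {
    speckles <- matrix(0, 20, 20)
    speckles[sample(400, 6)] <- 255
    once <- despeckle(speckles)
    expect_true(all(once == 0))
    expect_identical(despeckle(once), once)
  }
  # a despeckled pipeline rod mask is a fixed point of despeckle
  set.seed(32)
  p <- scenario_params("homogeneous", field = c(128, 128), seed = 32)
  fr <- render_frame(place_cells(p, 6), render_params(field = c(128, 128)), seed = 33)
  seg <- segment_frame(fr$phase)
  expect_identical(despeckle(seg$mask), seg$mask)
})

test_that("particle analysis labels components with area filtering and connectivity", {
  m <- matrix(0, 12, 20)
  m[2:6, 2:3] <- 255    # 10 px blob
  m[8:12, 15:16] <- 255 # 10 px blob
  ps <- label_particles(m, min_area = 5)
  expect_length(ps, 2)
  expect_equal(vapply(ps, `[[`, numeric(1), "area_px"), c(10, 10))
  expect_equal(vapply(ps, `[[`, numeric(1), "label"), c(1, 2))

  small <- matrix(0, 8, 8)
  small[4, 3:5] <- 255
  expect_length(label_particles(small, min_area = 5), 0)

  # diagonal touch: one particle under 8-connectivity, two under 4
  diagm <- matrix(0, 10, 10)
  diagm[2:4, 2:4] <- 255
  diagm[5:8, 5:7] <- 255
  expect_length(label_particles(diagm, min_area = 1, connectivity = 8), 1)
  expect_length(label_particles(diagm, min_area = 1, connectivity = 4), 2)

  expect_error(label_particles(m, min_area = 10, max_area = 5), "min_area")
})

test_that("two cells rendered in contact are counted as one particle", {
  set.seed(27)
  p <- scenario_params("homogeneous", field = c(64, 64), seed = 27)
  pair <- touching_pair(p)
  fr <- render_frame(pair, render_params(field = c(64, 64)), seed = 28)
  seg <- segment_frame(fr$phase)
  expect_length(seg$particles, 1)
  expect_equal(seg$particles[[1]]$area_px,
               sum(fr$labels != 0), tolerance = 0.25)
})

test_that("the default pipeline recovers well-separated rods deterministically", {
  set.seed(29)
  p <- scenario_params("homogeneous", field = c(256, 256), seed = 29)
  cells <- place_cells(p, 20)
  fr <- render_frame(cells, render_params(field = c(256, 256)), seed = 30)
  seg <- segment_frame(fr$phase)
  truth <- labels_to_particles(fr$labels)
  res <- match_particles(truth, seg$particles)
  expect_gte(res$matched, 19)
  expect_lt(res$spurious, 0.05 * length(truth) + 1)

  seg2 <- segment_frame(fr$phase)
  expect_identical(seg$mask, seg2$mask)
  expect_identical(particles_table(seg$particles), particles_table(seg2$particles))

  blank <- segment_frame(matrix(180, 64, 64))
  expect_length(blank$particles, 0)
})

test_that("every stage maps 8-bit images into the 8-bit range", {
  set.seed(31)
  img <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  stages <- list(
    subtract_background(img, 10),
    convolve_kernel(img, sharpen_kernel()),
    binarize(img, 100, "above"),
    despeckle(binarize(img, 100, "above"))
  )
  for (s in stages) expect_true(min(s) >= 0 && max(s) <= 255)
  expect_true(auto_threshold(img) >= 0 && auto_threshold(img) <= 255)
})
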