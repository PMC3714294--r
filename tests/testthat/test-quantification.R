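make_particle <- function(pixels, label = 1L) {
  list(label = label, pixels = pixels, area_px = length(pixels),
       centroid = c(row = 0, col = 0))
}

test_that("the inverted-mask scheme recovers original intensities arithmetically", {
  fluor <- matrix(0, 4, 4)
  fluor[1, 1:4] <- c(10, 20, 30, 40)
  mask <- matrix(0, 4, 4)
  mask[1, 1:4] <- 255
  p <- make_particle(which(mask == 255))
  out <- measure_cells_inverted(fluor, mask, list(p))
  # inverted values 245,235,225,215 -> mean 230 -> 255 - 230 = 25
  expect_equal(out$mean_raw, 25)
  expect_equal(out$area_px, 4)
  expect_true(out$valid)
})

test_that("background pixels clamp to zero and drop out of cell measurement", {
  fluor <- matrix(80, 3, 3)   # bright background everywhere
  mask <- matrix(0, 3, 3)
  mask[2, 2] <- 255
  fluor[2, 2] <- 100
  out <- measure_cells_inverted(fluor, mask, list(make_particle(5L)))
  expect_equal(out$mean_raw, 100)  # only the cell pixel contributes

  # fully saturated cell: inverted values are all 0 -> flagged invalid
  fluor[2, 2] <- 255
  out2 <- measure_cells_inverted(fluor, mask, list(make_particle(5L)))
  expect_false(out2$valid)
  expect_true(is.na(out2$mean_raw))
})

test_that("direct region means handle extremes and empty inputs", {
  fluor <- matrix(c(0, 255, 10, 10), 2, 2)
  out <- measure_cells_direct(fluor, list(make_particle(c(1L, 2L))))
  expect_equal(out$mean_raw, 127.5)
  expect_equal(nrow(measure_cells_direct(fluor, list())), 0)
})

test_that("inverted and direct schemes agree on particles without saturated pixels", {
  worst <- 0
  for (s in 1:30) {
    sc <- random_scene(n_cells = 4, seed = 100 + s)
    mask <- matrix(0, nrow(sc$frame$labels), ncol(sc$frame$labels))
    mask[sc$frame$labels != 0] <- 255
    inv <- measure_cells_inverted(sc$frame$fluor, mask, sc$particles)
    dir <- measure_cells_direct(sc$frame$fluor, sc$particles)
    for (i in seq_len(nrow(inv))) {
      px <- sc$particles[[i]]$pixels
      if (all(sc$frame$fluor[px] < 255)) {
        worst <- max(worst, abs(inv$mean_raw[i] - dir$mean_raw[i]))
      }
    }
  }
  expect_lt(worst, 1 / 255)
})

test_that("mask-addition background equals the complement mean, excluding saturated pixels", {
  fluor <- matrix(10, 8, 8)
  mask <- matrix(0, 8, 8)
  bg <- measure_background(fluor, mask)
  expect_equal(bg$mean_bg, 10)
  expect_equal(bg$n_pixels, 64)

  mask[, 1:4] <- 255
  fluor[, 5:8] <- 40
  bg2 <- measure_background(fluor, mask)
  expect_equal(bg2$mean_bg, 40)
  expect_equal(bg2$n_pixels, 32)

  # complement-mean oracle on random frames, including saturated background px
  set.seed(41)
  for (i in 1:20) {
    fl <- matrix(sample(0:255, 144, TRUE), 12, 12)
    mk <- matrix(sample(c(0, 255), 144, TRUE, prob = c(0.7, 0.3)), 12, 12)
    sel <- mk == 0 & fl < 255
    if (!any(sel)) next
    got <- measure_background(fl, mk)
    expect_identical(got$mean_bg, mean(fl[sel]))
    expect_identical(got$n_pixels, sum(sel))
  }

  expect_error(measure_background(matrix(5, 3, 3), matrix(255, 3, 3)),
               "no background")
})

test_that("normalization subtracts (or ratios) the background and preserves order", {
  cells <- data.frame(particle_id = 1:3, area_px = 10,
                      mean_raw = c(25, 10, 30), valid = TRUE)
  bg <- list(mean_bg = 10, n_pixels = 100)
  out <- normalize_cells(cells, bg)
  expect_equal(out$mean_normalized, c(15, 0, 20))
  expect_equal(attr(out, "normalization"), "subtract")

  rat <- normalize_cells(cells, bg, mode = "ratio")
  expect_equal(rat$mean_normalized[3], 2.0)

  # order preservation on random measurements
  set.seed(42)
  rcells <- data.frame(particle_id = 1:20, area_px = 5,
                       mean_raw = runif(20, 0, 255), valid = TRUE)
  rout <- normalize_cells(rcells, list(mean_bg = 37.5, n_pixels = 10))
  expect_identical(order(rout$mean_raw), order(rout$mean_normalized))
})

test_that("measurements are invariant to particle order", {
  sc <- random_scene(n_cells = 5, seed = 77)
  mask <- matrix(0, nrow(sc$frame$labels), ncol(sc$frame$labels))
  mask[sc$frame$labels != 0] <- 255
  fwd <- measure_cells_inverted(sc$frame$fluor, mask, sc$particles)
  rev_ <- measure_cells_inverted(sc$frame$fluor, mask, rev(sc$particles))
  fwd <- fwd[order(fwd$particle_id), ]
  rev_ <- rev_[order(rev_$particle_id), ]
  rownames(fwd) <- rownames(rev_) <- NULL
  expect_equal(fwd, rev_)
})
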