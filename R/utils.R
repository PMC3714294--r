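# Shared low-level helpers: 8-bit clamping, matrix shifts with fill, and
# separable running-extreme filters used by the grayscale morphology.

#' Clamp values to the 8-bit range
#'
#' @param x numeric vector or matrix.
#' @return `x` with every value forced into \[0, 255\].
#' @keywords internal
#' @noRd
clamp8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' @noRd
is_image8 <- function(x) {
  is.matrix(x) && is.numeric(x) && !anyNA(x) &&
    min(x) >= 0 && max(x) <= 255
}

#' @noRd
assert_image8 <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop(sprintf("%s must have intensities in [0, 255]", what), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
assert_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 255))) {
    stop("mask must be a matrix with values in {0, 255}", call. = FALSE)
  }
  invisible(mask)
}

# out[r, c] = m[r, c + s], out-of-range filled with `fill`.
#' @noRd
shift_cols <- function(m, s, fill) {
  nc <- ncol(m)
  nr <- nrow(m)
  if (s == 0) return(m)
  if (abs(s) >= nc) return(matrix(fill, nr, nc))
  if (s > 0) {
    cbind(m[, (1 + s):nc, drop = FALSE], matrix(fill, nr, s))
  } else {
    cbind(matrix(fill, nr, -s), m[, 1:(nc + s), drop = FALSE])
  }
}

# out[r, c] = m[r + s, c], out-of-range filled with `fill`.
#' @noRd
shift_rows <- function(m, s, fill) {
  nc <- ncol(m)
  nr <- nrow(m)
  if (s == 0) return(m)
  if (abs(s) >= nr) return(matrix(fill, nr, nc))
  if (s > 0) {
    rbind(m[(1 + s):nr, , drop = FALSE], matrix(fill, s, nc))
  } else {
    rbind(matrix(fill, -s, nc), m[1:(nr + s), , drop = FALSE])
  }
}

# Running extreme over a centred horizontal window of half-width h, computed
# with the sparse-table doubling trick (O(log h) vectorized passes). Using an
# infinite fill is equivalent to replicate-padding for min/max filters because
# the nearest in-range pixel always lies inside the window.
#' @noRd
run_extreme_cols <- function(m, h, op, fill) {
  if (h == 0) return(m)
  nr <- nrow(m)
  nc <- ncol(m)
  len <- 2L * h + 1L
  # pad so both sparse-table anchors stay in range at the borders
  f <- cbind(matrix(fill, nr, h), m, matrix(fill, nr, h))
  p <- 1L
  while (2L * p <= len) {
    f <- op(f, shift_cols(f, p, fill))
    p <- 2L * p
  }
  right <- shift_cols(f, len - p, fill)
  jj <- seq_len(nc)
  op(f[, jj, drop = FALSE], right[, jj, drop = FALSE])
}

# Grayscale erosion/dilation by a flat disc of radius r, decomposed into
# per-row horizontal running extremes over the disc's chords.
#' @noRd
gray_extreme_disc <- function(m, r, op, fill) {
  acc <- NULL
  for (dy in -r:r) {
    h <- as.integer(floor(sqrt(r^2 - dy^2)))
    row_part <- run_extreme_cols(shift_rows(m, dy, fill), h, op, fill)
    acc <- if (is.null(acc)) row_part else op(acc, row_part)
  }
  acc
}

#' @noRd
gray_erode_disc <- function(m, r) gray_extreme_disc(m, r, pmin, Inf)

#' @noRd
gray_dilate_disc <- function(m, r) gray_extreme_disc(m, r, pmax, -Inf)

# Morphological opening: erosion followed by dilation. Bounded above by the
# input, so it is a valid background estimate for bright-object images.
#' @noRd
gray_opening_disc <- function(m, r) gray_dilate_disc(gray_erode_disc(m, r), r)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
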