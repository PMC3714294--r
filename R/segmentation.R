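# Phase-contrast segmentation: rolling-ball background subtraction, kernel
# convolution, automatic thresholding, despeckling and particle analysis.
# The operator semantics mirror the ImageJ commands the pipeline is built on:
# clamped (never wrapped) 8-bit arithmetic, replicated edges, 8-connected
# particle analysis.

#' Construct a convolution kernel
#'
#' @param values square numeric matrix of signed weights, odd side length
#'   >= 3.
#' @param normalize if `TRUE` and the kernel sum is nonzero, the response is
#'   divided by the sum (ImageJ's "Normalize Kernel" behaviour).
#' @return an object of class `tlm_kernel`.
#' @export
make_kernel <- function(values, normalize = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) < 3L || nrow(values) %% 2L == 0L) {
    stop("kernel must be square with odd side length >= 3", call. = FALSE)
  }
  if (anyNA(values)) stop("kernel must not contain NA", call. = FALSE)
  structure(list(values = values, normalize = isTRUE(normalize)),
            class = "tlm_kernel")
}

#' Default cell-sharpening kernel
#'
#' A 5x5 center-weighted sharpening kernel (center 24, all other weights -1;
#' weight sum zero, so unnormalized). Suitable for thin rods a few pixels
#' wide; should be adjusted for other cell geometries or exposure settings.
#'
#' @return a `tlm_kernel`.
#' @export
sharpen_kernel <- function() {
  v <- matrix(-1, 5, 5)
  v[3, 3] <- 24
  make_kernel(v, normalize = FALSE)
}

#' Rolling-ball style background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image by a flat disc of the given radius and subtracts it, clamping the
#' result to \[0, 255\]. A flat image maps to all zeros. With
#' `light_background = TRUE` the image is inverted first (dark objects on a
#' bright field, as in phase contrast), so the output has background-levelled
#' cells *bright* on a dark field.
#'
#' A positive `smooth_radius` applies a grayscale closing by a small disc
#' before estimating the background. This bridges narrow dark pits — such as
#' the inverted halo rims around phase-contrast cells — that a flat disc would
#' otherwise mistake for background level (a physical rolling ball cannot
#' descend into pits narrower than its curvature, so the smoothing restores
#' that behaviour). Zero disables it, giving the pure-opening estimate.
#'
#' @param image 8-bit image matrix.
#' @param radius disc radius in pixels (>= 1).
#' @param light_background set for dark objects on a bright background.
#' @param smooth_radius pre-closing disc radius in pixels (0 = off).
#' @return 8-bit image matrix with the background removed.
#' @export
subtract_background <- function(image, radius, light_background = FALSE,
                                smooth_radius = 0) {
  assert_image8(image)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1) {
    stop("radius must be a single value >= 1", call. = FALSE)
  }
  r <- as.integer(round(radius))
  work <- if (light_background) 255 - image else image
  est_on <- work
  if (smooth_radius > 0) {
    rs <- as.integer(round(smooth_radius))
    est_on <- gray_erode_disc(gray_dilate_disc(work, rs), rs)
  }
  bg <- gray_opening_disc(est_on, r)
  clamp8(round(work - bg))
}

#' Convolve an image with a kernel
#'
#' 2-D correlation with edge replication at the borders; the result is rounded
#' and clamped to \[0, 255\]. An identity kernel returns the input unchanged.
#'
#' @param image 8-bit image matrix.
#' @param kernel a `tlm_kernel` (see [make_kernel()]) or a plain odd-sized
#'   square matrix (taken as `normalize = TRUE`).
#' @return 8-bit image matrix.
#' @export
convolve_kernel <- function(image, kernel) {
  assert_image8(image)
  if (!inherits(kernel, "tlm_kernel")) kernel <- make_kernel(kernel)
  k <- kernel$values
  h <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  padded <- image[
    c(rep(1L, h), seq_len(nr), rep(nr, h)),
    c(rep(1L, h), seq_len(nc), rep(nc, h)),
    drop = FALSE
  ]
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      w <- k[a, b]
      if (w != 0) {
        out <- out + w * padded[a:(a + nr - 1L), b:(b + nc - 1L), drop = FALSE]
      }
    }
  }
  s <- sum(k)
  if (kernel$normalize && s != 0) out <- out / s
  clamp8(round(out))
}

#' IsoData intermeans automatic threshold
#'
#' Iterates T <- round((mean below + mean above) / 2) until the threshold is
#' stable: the returned T equals the rounded average of the mean intensity of
#' pixels at or below T and the mean of pixels above it. Deterministic. For a
#' constant image the constant itself is returned (every pixel falls at or
#' below it, so an "above" binarization downstream yields an empty mask).
#'
#' @param image 8-bit image matrix.
#' @return integer threshold in \[0, 255\].
#' @export
auto_threshold <- function(image) {
  assert_image8(image)
  vals <- as.numeric(image)
  lo <- min(vals)
  hi <- max(vals)
  if (lo == hi) return(as.integer(lo))
  clampt <- function(t) min(max(t, lo), hi - 1)
  t <- clampt(floor((lo + hi) / 2))
  seen <- integer(0)
  repeat {
    m0 <- mean(vals[vals <= t])
    m1 <- mean(vals[vals > t])
    tn <- clampt(round((m0 + m1) / 2))
    if (tn == t || tn %in% seen) {
      t <- tn
      break
    }
    seen <- c(seen, t)
    t <- tn
  }
  as.integer(t)
}

#' Otsu threshold (between-class variance maximization)
#'
#' @param image 8-bit image matrix.
#' @return integer threshold in \[0, 255\]; foreground is "above".
#' @export
otsu_threshold <- function(image) {
  assert_image8(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * levels)
  total <- sum0[256]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - sum0) / w1, 0)
  between <- w0 * w1 * (mu0 - mu1)^2
  as.integer(levels[which.max(between)])
}

#' Binarize an image at a threshold
#'
#' @param image 8-bit image matrix.
#' @param threshold integer in \[0, 255\].
#' @param polarity `"above"` sets pixels strictly above the threshold to 255
#'   (objects counted as cells); `"below"` sets pixels strictly below.
#' @return a binary mask matrix over \{0, 255\}.
#' @export
binarize <- function(image, threshold, polarity = c("above", "below")) {
  assert_image8(image)
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]", call. = FALSE)
  keep <- if (polarity == "above") image > threshold else image < threshold
  matrix(ifelse(keep, 255, 0), nrow(image), ncol(image))
}

#' Despeckle a binary mask (3x3 median filter)
#'
#' Removes isolated foreground pixels and fills isolated holes; solid blocks
#' are preserved in their interior. For a binary mask the 3x3 median equals a
#' majority vote over the 9-pixel neighbourhood (edges replicated).
#'
#' @param mask binary mask over \{0, 255\}.
#' @return despeckled binary mask.
#' @export
despeckle <- function(mask) {
  assert_mask(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  f <- (mask == 255) * 1
  padded <- f[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc), drop = FALSE]
  cnt <- matrix(0, nr, nc)
  for (a in 0:2) {
    for (b in 0:2) {
      cnt <- cnt + padded[(1L + a):(nr + a), (1L + b):(nc + b), drop = FALSE]
    }
  }
  matrix(ifelse(cnt >= 5, 255, 0), nr, nc)
}

#' Particle analysis: label connected components with an area filter
#'
#' Connected components of the mask foreground (default 8-connectivity) with
#' areas inside `[min_area, max_area]` become particles, labelled consecutively
#' from 1 in row-major scan order of their first pixel. Touching cells form a
#' single component and are deliberately counted as one particle (no
#' watershed splitting).
#'
#' @param mask binary mask over \{0, 255\}.
#' @param min_area,max_area inclusive area bounds in pixels.
#' @param connectivity 4 or 8.
#' @param exclude_edges drop particles touching the image border.
#' @return list of particles; each has `label`, `pixels` (linear indices into
#'   the mask), `area_px` and `centroid` (row, col).
#' @export
label_particles <- function(mask, min_area = 20, max_area = Inf,
                            connectivity = 8, exclude_edges = FALSE) {
  assert_mask(mask)
  if (min_area > max_area) stop("min_area must not exceed max_area", call. = FALSE)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- mask == 255
  idx <- which(fg)
  if (length(idx) == 0L) return(list())
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0)
  to <- integer(0)
  for (off in offsets) {
    nb <- shift_rows(shift_cols(fg, off[2], FALSE), off[1], FALSE)
    both <- which(fg & nb)
    if (length(both)) {
      from <- c(from, both)
      to <- c(to, both + off[1] + off[2] * nr)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(pos[from], pos[to]))
  }
  membership <- igraph::components(g)$membership

  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  scan_key <- (rows - 1L) * nc + cols  # row-major position
  first_key <- tapply(scan_key, membership, min)
  rank <- rank(first_key)  # scan-order rank of each component id
  comp_of <- rank[as.character(membership)]

  areas <- tabulate(membership)
  keep_comp <- which(areas >= min_area & areas <= max_area)
  if (exclude_edges) {
    on_edge <- rows == 1L | rows == nr | cols == 1L | cols == nc
    edge_comps <- unique(membership[on_edge])
    keep_comp <- setdiff(keep_comp, edge_comps)
  }
  if (length(keep_comp) == 0L) return(list())

  keep_rank <- sort(rank[as.character(keep_comp)])
  out <- vector("list", length(keep_rank))
  for (i in seq_along(keep_rank)) {
    sel <- comp_of == keep_rank[i]
    out[[i]] <- list(
      label = i,
      pixels = idx[sel],
      area_px = sum(sel),
      centroid = c(row = mean(rows[sel]), col = mean(cols[sel]))
    )
  }
  out
}

#' Summarize a particle list as a data.frame
#'
#' @param particles output of [label_particles()].
#' @return data.frame with `label`, `area_px`, `centroid_row`, `centroid_col`.
#' @export
particles_table <- function(particles) {
  if (length(particles) == 0L) {
    return(data.frame(
      label = integer(0), area_px = integer(0),
      centroid_row = numeric(0), centroid_col = numeric(0)
    ))
  }
  data.frame(
    label = vapply(particles, `[[`, numeric(1), "label"),
    area_px = vapply(particles, `[[`, numeric(1), "area_px"),
    centroid_row = vapply(particles, function(p) p$centroid[["row"]], numeric(1)),
    centroid_col = vapply(particles, function(p) p$centroid[["col"]], numeric(1))
  )
}

#' Segmentation parameter set
#'
#' @param rolling_ball_radius background-subtraction disc radius in pixels.
#' @param smooth_radius pre-closing radius for the background estimate (see
#'   [subtract_background()]); bridges the narrow halo rims of phase-contrast
#'   cells.
#' @param kernel convolution kernel (`tlm_kernel` or matrix).
#' @param threshold_method `"isodata"` (ImageJ's default intermeans),
#'   `"otsu"`, or `"fixed"` (requires `fixed_threshold`).
#' @param fixed_threshold threshold used when `threshold_method = "fixed"`.
#' @param polarity side of the threshold counted as cells after convolution.
#' @param light_background treat the phase image as dark cells on a bright
#'   field (inverted during background subtraction).
#' @param despeckle apply the 3x3 median despeckle to the mask.
#' @param min_area,max_area particle area filter in pixels.
#' @param connectivity particle connectivity, 4 or 8.
#' @param exclude_edges drop border-touching particles.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(rolling_ball_radius = 50, smooth_radius = 3,
                       kernel = sharpen_kernel(),
                       threshold_method = c("isodata", "otsu", "fixed"),
                       fixed_threshold = NULL,
                       polarity = c("above", "below"),
                       light_background = TRUE, despeckle = TRUE,
                       min_area = 20, max_area = Inf, connectivity = 8,
                       exclude_edges = FALSE) {
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  if (!inherits(kernel, "tlm_kernel")) kernel <- make_kernel(kernel)
  if (rolling_ball_radius < 1) stop("rolling_ball_radius must be >= 1", call. = FALSE)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 255)) {
    stop("fixed threshold_method requires fixed_threshold in [0, 255]", call. = FALSE)
  }
  if (min_area < 1 || min_area > max_area) {
    stop("require 1 <= min_area <= max_area", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (smooth_radius < 0) stop("smooth_radius must be >= 0", call. = FALSE)
  structure(list(
    rolling_ball_radius = rolling_ball_radius, smooth_radius = smooth_radius,
    kernel = kernel,
    threshold_method = threshold_method, fixed_threshold = fixed_threshold,
    polarity = polarity, light_background = isTRUE(light_background),
    despeckle = isTRUE(despeckle), min_area = min_area, max_area = max_area,
    connectivity = connectivity, exclude_edges = isTRUE(exclude_edges)
  ), class = "seg_params")
}

#' Segment one phase-contrast frame
#'
#' Applies the full operator sequence: background subtraction, kernel
#' convolution, automatic threshold, binarization, despeckle, particle
#' analysis. Deterministic for fixed inputs and parameters.
#'
#' @param phase 8-bit phase-contrast image matrix.
#' @param params a [seg_params()] object.
#' @return a list of class `tlm_segmentation` with `mask`, `particles` and
#'   `threshold`.
#' @export
segment_frame <- function(phase, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  work <- subtract_background(phase, params$rolling_ball_radius,
                              light_background = params$light_background,
                              smooth_radius = params$smooth_radius)
  work <- convolve_kernel(work, params$kernel)
  th <- switch(params$threshold_method,
    isodata = auto_threshold(work),
    otsu = otsu_threshold(work),
    fixed = as.integer(params$fixed_threshold)
  )
  mask <- binarize(work, th, params$polarity)
  if (params$despeckle) mask <- despeckle(mask)
  particles <- label_particles(mask,
    min_area = params$min_area, max_area = params$max_area,
    connectivity = params$connectivity, exclude_edges = params$exclude_edges
  )
  structure(list(mask = mask, particles = particles, threshold = th),
            class = "tlm_segmentation")
}

#' @export
print.tlm_segmentation <- function(x, ...) {
  cat(sprintf(
    "Segmented frame: %d particles, threshold %d, %d foreground px\n",
    length(x$particles), x$threshold, sum(x$mask == 255)
  ))
  invisible(x)
}
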