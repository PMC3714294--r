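# Time-resolved intensity heatmaps (population histogram per frame, one
# column per time point, colour = cell count) and bar-chart summaries,
# rendered with base graphics.

#' Read a colour scheme CSV
#'
#' Two columns — a strictly increasing count upper bound and a colour — with
#' an optional header. Counts above the top bound render with the last colour.
#'
#' @param path CSV path.
#' @return a `color_scheme` data.frame with `upper_bound` and `color`.
#' @export
read_color_scheme <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1, stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]][1])))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  names(df) <- c("upper_bound", "color")[seq_len(min(2, ncol(df)))]
  color_scheme(df$upper_bound, df$color)
}

#' Construct and validate a colour scheme
#'
#' @param upper_bound strictly increasing numeric count bounds (>= 2 entries).
#' @param color colours, one per bound.
#' @return a `color_scheme` data.frame.
#' @export
color_scheme <- function(upper_bound, color) {
  upper_bound <- as.numeric(upper_bound)
  color <- as.character(color)
  if (length(upper_bound) < 2L) stop("colour scheme needs at least 2 entries", call. = FALSE)
  if (length(upper_bound) != length(color)) stop("bounds and colours must match in length", call. = FALSE)
  if (any(diff(upper_bound) <= 0)) stop("colour-scheme bounds must be strictly increasing", call. = FALSE)
  structure(data.frame(upper_bound = upper_bound, color = color,
                       stringsAsFactors = FALSE),
            class = c("color_scheme", "data.frame"))
}

#' Default heatmap colour scheme
#'
#' White for empty bins, then a blue-to-red ramp over doubling count bounds.
#'
#' @param max_bound top count bound.
#' @return a `color_scheme`.
#' @export
default_color_scheme <- function(max_bound = 64) {
  bounds <- c(0, 2^(0:ceiling(log2(max_bound))))
  ramp <- grDevices::colorRampPalette(c("#4575B4", "#FEE090", "#D73027"))
  color_scheme(bounds, c("#FFFFFF", ramp(length(bounds) - 1L)))
}

#' Map counts to colour-scheme indices
#'
#' Each count maps to the first bound at or above it; counts exceeding the top
#' bound saturate to the last colour.
#'
#' @param counts numeric vector or matrix of counts.
#' @param scheme a `color_scheme`.
#' @return integer indices into `scheme$color`, same shape as `counts`.
#' @export
color_index <- function(counts, scheme) {
  stopifnot(inherits(scheme, "color_scheme"))
  idx <- findInterval(counts, scheme$upper_bound, left.open = TRUE) + 1L
  idx[idx > nrow(scheme)] <- nrow(scheme)
  if (is.matrix(counts)) idx <- matrix(idx, nrow(counts), ncol(counts))
  idx
}

#' Build a time-resolved intensity histogram grid
#'
#' For every frame, the per-cell normalized intensities are histogrammed into
#' fixed global bins; the grid has one column per frame and colour later
#' encodes the number of cells per (time, intensity) bin. Values outside the
#' range are counted in the edge bins so that column sums equal per-frame cell
#' counts.
#'
#' @param measurements data.frame with `frame_index`, `time_h` and
#'   `mean_normalized` columns.
#' @param n_bins number of intensity bins (>= 2).
#' @param range intensity range `c(lo, hi)` in AU; defaults to the observed
#'   range.
#' @return an object of class `tlm_heatmap`: `counts` (n_bins x n_frames),
#'   `breaks`, `mids`, `times`, `frame_index`.
#' @export
build_heatmap <- function(measurements, n_bins = 64, range = NULL) {
  needed <- c("frame_index", "time_h", "mean_normalized")
  if (!all(needed %in% names(measurements))) {
    stop("measurements need frame_index, time_h, mean_normalized columns", call. = FALSE)
  }
  if (!is.null(measurements$valid)) measurements <- measurements[measurements$valid, ]
  measurements <- measurements[!is.na(measurements$mean_normalized), ]
  if (nrow(measurements) == 0L) stop("no measurements to bin", call. = FALSE)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  if (is.null(range)) range <- base::range(measurements$mean_normalized)
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)

  frames <- sort(unique(measurements$frame_index))
  counts <- matrix(0L, n_bins, length(frames))
  times <- numeric(length(frames))
  for (j in seq_along(frames)) {
    d <- measurements[measurements$frame_index == frames[j], ]
    times[j] <- d$time_h[1]
    v <- pmin(pmax(d$mean_normalized, range[1]), range[2])
    bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts[, j] <- tabulate(bin, nbins = n_bins)
  }
  structure(list(counts = counts, breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 times = times, frame_index = frames),
            class = "tlm_heatmap")
}

#' @noRd
open_device <- function(dest, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(dest))
  switch(ext,
    pdf = grDevices::pdf(dest, width = width, height = height),
    png = grDevices::png(dest, width = width * 100, height = height * 100),
    stop(sprintf("unsupported plot format '.%s' (use .pdf or .png)", ext), call. = FALSE)
  )
}

#' Render a heatmap grid to a plot file
#'
#' Time on the x axis (hours), normalized intensity on the y axis (AU), colour
#' by cell count according to the scheme. Deterministic content for fixed
#' inputs (up to device metadata such as PDF creation dates).
#'
#' @param grid a `tlm_heatmap` from [build_heatmap()].
#' @param scheme a `color_scheme`.
#' @param dest output path (`.pdf` or `.png`).
#' @param main plot title.
#' @return `dest`, invisibly.
#' @export
render_heatmap <- function(grid, scheme = default_color_scheme(),
                           dest = "heatmap.pdf", main = "Expression heterogeneity") {
  stopifnot(inherits(grid, "tlm_heatmap"))
  idx <- color_index(grid$counts, scheme)
  open_device(dest)
  on.exit(grDevices::dev.off(), add = TRUE)
  x <- if (length(grid$times) > 1L) grid$times else c(grid$times, grid$times + 1)
  z <- t(idx)
  if (length(grid$times) == 1L) z <- rbind(z, z)
  graphics::image(
    x = x, y = grid$mids, z = z,
    col = scheme$color, breaks = seq(0.5, nrow(scheme) + 0.5),
    xlab = "Time (h)", ylab = "Fluorescence (AU)", main = main,
    useRaster = FALSE
  )
  graphics::box()
  invisible(dest)
}

#' Render a bar-chart summary of heterogeneity measurements
#'
#' Grouped bars (one colour per time point) with standard-deviation error
#' bars, for comparing heterogeneity across conditions and times.
#'
#' @param summary data.frame from [summarize_timepoints()] (columns
#'   `condition`, `time_h`, `combined_mean`, `combined_sd`).
#' @param dest output path (`.pdf` or `.png`).
#' @param ylab y-axis label.
#' @return `dest`, invisibly.
#' @export
render_barchart <- function(summary, dest = "barchart.pdf",
                            ylab = "Fluorescence (AU)") {
  if (!is.data.frame(summary) || nrow(summary) == 0L) {
    stop("summary must be a non-empty data.frame", call. = FALSE)
  }
  if (is.null(summary$condition)) summary$condition <- "series"
  times <- sort(unique(summary$time_h))
  conds <- unique(summary$condition)
  height <- matrix(0, length(times), length(conds),
                   dimnames = list(paste0(times, " h"), conds))
  err <- height
  for (i in seq_len(nrow(summary))) {
    r <- match(summary$time_h[i], times)
    c_ <- match(summary$condition[i], conds)
    height[r, c_] <- summary$combined_mean[i]
    err[r, c_] <- summary$combined_sd[i]
  }
  open_device(dest)
  on.exit(grDevices::dev.off(), add = TRUE)
  cols <- grDevices::hcl.colors(length(times), "Dark 3")
  ylim <- c(min(0, min(height - err)), max(height + err) * 1.1)
  mids <- graphics::barplot(height, beside = TRUE, col = cols, ylim = ylim,
                            ylab = ylab, legend.text = rownames(height),
                            args.legend = list(x = "topright", bty = "n"))
  nonzero <- err > 0
  if (any(nonzero)) {
    graphics::arrows(mids[nonzero], (height - err)[nonzero],
                     mids[nonzero], (height + err)[nonzero],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(dest)
}
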