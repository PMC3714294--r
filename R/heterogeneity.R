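# Population statistics per frame, the homogeneous-control noise baseline
# (SD regressed on mean), and baseline-corrected expression heterogeneity.

#' Per-frame population statistics
#'
#' Mean and sample standard deviation (n - 1 denominator; 0 for a single
#' cell) of the normalized per-cell intensities of one frame.
#'
#' @param values numeric vector of per-cell normalized intensities (AU).
#' @param frame_index,time_h frame identity carried into the result.
#' @return one-row data.frame: `frame_index`, `time_h`, `n_cells`,
#'   `mean_fluor`, `sd_fluor`.
#' @export
frame_stats <- function(values, frame_index = NA_integer_, time_h = NA_real_) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("frame_stats requires at least one cell", call. = FALSE)
  data.frame(
    frame_index = frame_index, time_h = time_h, n_cells = length(values),
    mean_fluor = mean(values),
    sd_fluor = if (length(values) > 1L) stats::sd(values) else 0
  )
}

#' Per-frame statistics for a whole measurement table
#'
#' @param measurements data.frame with `frame_index`, `time_h` and
#'   `mean_normalized` columns (invalid rows are dropped). Frames with no
#'   valid cells are skipped with a warning, not reported as zero rows.
#' @return data.frame of [frame_stats()] rows, ordered by time.
#' @export
series_stats <- function(measurements) {
  if (!all(c("frame_index", "time_h", "mean_normalized") %in% names(measurements))) {
    stop("measurements need frame_index, time_h, mean_normalized columns", call. = FALSE)
  }
  split_by <- split(measurements, measurements$frame_index)
  split_by <- lapply(split_by, function(d) {
    if (!is.null(d$valid)) d <- d[d$valid, , drop = FALSE]
    d[!is.na(d$mean_normalized), , drop = FALSE]
  })
  empty <- vapply(split_by, function(d) nrow(d) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("skipping %d frame(s) with no valid cells", sum(empty)))
    split_by <- split_by[!empty]
  }
  if (length(split_by) == 0L) stop("no frames with valid cells", call. = FALSE)
  out <- do.call(rbind, lapply(split_by, function(d) {
    frame_stats(d$mean_normalized, frame_index = d$frame_index[1], time_h = d$time_h[1])
  }))
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the noise baseline: SD of cellular fluorescence regressed on the mean
#'
#' For a homogeneously expressing control, the per-image standard deviation in
#' cellular fluorescence represents measurement noise and correlates linearly
#' with the per-image mean intensity. This fits that line by ordinary least
#' squares (unweighted, free intercept) so it can serve as the
#' background-noise baseline for other series.
#'
#' @param points data.frame with `mean_fluor` and `sd_fluor` columns (e.g.
#'   rows of [series_stats()] pooled over control cultures), or a numeric
#'   vector of means when `sd_fluor` is given separately.
#' @param sd_fluor optional numeric vector of SDs matching `points`.
#' @return an object of class `noise_model` with `slope`, `intercept`,
#'   `r_squared`, `n_points` and coefficient standard errors.
#' @export
fit_noise_baseline <- function(points, sd_fluor = NULL) {
  if (is.data.frame(points)) {
    if (!all(c("mean_fluor", "sd_fluor") %in% names(points))) {
      stop("points must have mean_fluor and sd_fluor columns", call. = FALSE)
    }
    m <- points$mean_fluor
    s <- points$sd_fluor
  } else {
    m <- as.numeric(points)
    s <- as.numeric(sd_fluor)
  }
  ok <- !is.na(m) & !is.na(s)
  m <- m[ok]
  s <- s[ok]
  if (length(m) < 3L) stop("need at least 3 (mean, SD) points", call. = FALSE)
  if (diff(range(m)) == 0) stop("degenerate design: all mean intensities identical", call. = FALSE)
  fit <- stats::lm(s ~ m)
  # a noiseless calibration line is valid input; summary.lm warns on it
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    n_points = length(m),
    se_slope = sm$coefficients[2, 2],
    se_intercept = sm$coefficients[1, 2]
  ), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Noise baseline: SD = slope * mean + intercept\n")
  cat(sprintf("  slope     %.6g (SE %.3g)\n", x$slope, x$se_slope))
  cat(sprintf("  intercept %.6g AU (SE %.3g)\n", x$intercept, x$se_intercept))
  cat(sprintf("  r^2 = %.4f over %d image measurements\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.noise_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.noise_model <- function(object, ...) {
  out <- data.frame(
    term = c("intercept", "slope"),
    estimate = c(object$intercept, object$slope),
    std_error = c(object$se_intercept, object$se_slope)
  )
  attr(out, "r_squared") <- object$r_squared
  attr(out, "n_points") <- object$n_points
  out
}

#' Predict the baseline SD at given mean intensities
#'
#' @param object a `noise_model`.
#' @param mean_fluor numeric vector of mean intensities (AU).
#' @param ... unused.
#' @return predicted SDs: `slope * mean_fluor + intercept`.
#' @export
predict.noise_model <- function(object, mean_fluor, ...) {
  object$slope * mean_fluor + object$intercept
}

#' Serialize a noise model to JSON
#'
#' The model is a separate artifact so a control experiment's baseline can
#' correct any number of test series.
#'
#' @param model a `noise_model`.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_noise_model <- function(model, path) {
  stopifnot(inherits(model, "noise_model"))
  jsonlite::write_json(
    list(slope = model$slope, intercept = model$intercept,
         r_squared = model$r_squared, n_points = model$n_points,
         se_slope = model$se_slope, se_intercept = model$se_intercept),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a noise model written by [write_noise_model()]
#'
#' @param path JSON path.
#' @return a `noise_model`.
#' @export
read_noise_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n_points = x$n_points, se_slope = x$se_slope %||% NA_real_,
    se_intercept = x$se_intercept %||% NA_real_
  ), class = "noise_model")
}

#' Baseline-correct observed heterogeneity
#'
#' Subtracts the noise SD predicted by the control model at each frame's mean
#' intensity from the observed SD. Negative corrected values are preserved and
#' reported (clamping would hide model misfit).
#'
#' @param stats data.frame of per-frame statistics ([series_stats()]).
#' @param model a fitted `noise_model`.
#' @return `stats` with `predicted_sd` and `corrected` columns added
#'   (`corrected = sd_fluor - predicted_sd` exactly).
#' @export
correct_heterogeneity <- function(stats, model) {
  stopifnot(inherits(model, "noise_model"))
  if (!all(c("mean_fluor", "sd_fluor") %in% names(stats))) {
    stop("stats must have mean_fluor and sd_fluor columns", call. = FALSE)
  }
  stats$predicted_sd <- predict(model, stats$mean_fluor)
  stats$corrected <- stats$sd_fluor - stats$predicted_sd
  stats$raw_sd <- stats$sd_fluor
  stats
}

# Exact pooled mean/SD of concatenated per-cell values, reconstructed from
# per-group (n, mean, sd).
#' @noRd
pool_stats <- function(n, m, s) {
  total <- sum(n)
  pooled_mean <- sum(n * m) / total
  if (total < 2L) return(c(mean = pooled_mean, sd = 0, n = total))
  ss <- sum((n - 1) * s^2 + n * (m - pooled_mean)^2)
  c(mean = pooled_mean, sd = sqrt(ss / (total - 1)), n = total)
}

#' Summarize selected time points for bar-chart comparison
#'
#' For each requested time the nearest frame (earlier frame on ties) is
#' selected; with a pooling window, all frames within `window_h` of the
#' requested time are combined. Combined means and standard deviations are
#' computed from the combined per-cell fluorescence values (exact pooling from
#' the per-frame statistics).
#'
#' @param stats per-frame statistics data.frame ([series_stats()]), optionally
#'   with a `condition` column.
#' @param times requested times in hours; each must lie within the series
#'   span.
#' @param window_h optional pooling half-window in hours.
#' @return data.frame with one row per (condition, time): `condition`,
#'   `time_h`, `n_frames`, `n_cells`, `combined_mean`, `combined_sd`.
#' @export
summarize_timepoints <- function(stats, times, window_h = NULL) {
  if (is.null(stats$condition)) stats$condition <- "series"
  out <- list()
  for (cond in unique(stats$condition)) {
    sc <- stats[stats$condition == cond, , drop = FALSE]
    sc <- sc[order(sc$time_h), , drop = FALSE]
    span <- range(sc$time_h)
    for (t in times) {
      if (t < span[1] || t > span[2]) {
        stop(sprintf("requested time %.3g h is outside the series span [%.3g, %.3g]",
                     t, span[1], span[2]), call. = FALSE)
      }
      if (is.null(window_h)) {
        d <- abs(sc$time_h - t)
        sel <- which(d == min(d))[1]  # earlier frame wins ties (stats time-ordered)
      } else {
        sel <- which(abs(sc$time_h - t) <= window_h)
      }
      p <- pool_stats(sc$n_cells[sel], sc$mean_fluor[sel], sc$sd_fluor[sel])
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, time_h = t, n_frames = length(sel),
        n_cells = unname(p["n"]), combined_mean = unname(p["mean"]),
        combined_sd = unname(p["sd"])
      )
    }
  }
  do.call(rbind, out)
}

#' Descriptive intensity mode count (extension)
#'
#' A descriptive aid, not a formal bimodality test: counts local maxima of a
#' fixed-bandwidth kernel density estimate of the per-cell intensities.
#' Bar-chart summaries cannot discriminate highly heterogeneous from bistable
#' expression; this gives a rough per-frame indication of how many modes the
#' intensity distribution shows.
#'
#' @param values per-cell normalized intensities.
#' @param adjust bandwidth multiplier passed to [stats::density()].
#' @param min_height local maxima below this fraction of the tallest density
#'   peak are ignored.
#' @param valley_depth two peaks count as separate modes only if the valley
#'   between them drops below this fraction of the lower peak; shallower dips
#'   are sampling ripple and get merged.
#' @return integer mode count.
#' @export
count_modes <- function(values, adjust = 1, min_height = 0.1,
                        valley_depth = 0.5) {
  values <- values[!is.na(values)]
  if (length(values) < 2L || diff(range(values)) == 0) return(1L)
  d <- stats::density(values, adjust = adjust, n = 256)
  y <- d$y
  n <- length(y)
  up <- diff(y) > 0
  peaks <- which(c(FALSE, up[-(n - 1)] & !up[-1], FALSE))
  peaks <- peaks[y[peaks] >= min_height * max(y)]
  if (length(peaks) <= 1L) return(max(length(peaks), 1L))
  # merge adjacent peaks whose intervening valley is too shallow
  repeat {
    if (length(peaks) <= 1L) break
    scores <- vapply(seq_len(length(peaks) - 1L), function(i) {
      valley <- min(y[peaks[i]:peaks[i + 1L]])
      valley / min(y[peaks[i]], y[peaks[i + 1L]])
    }, numeric(1))
    worst <- which.max(scores)
    if (scores[worst] <= valley_depth) break
    drop <- if (y[peaks[worst]] < y[peaks[worst + 1L]]) worst else worst + 1L
    peaks <- peaks[-drop]
  }
  length(peaks)
}
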