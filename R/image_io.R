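# Reading and writing 8-bit TIFF time series and the pipeline's CSV tables.

#' Read a single-plane 8-bit grayscale TIFF
#'
#' Pixel values are loaded bit-exactly as integers in \[0, 255\]. Inputs with
#' any other bit depth are rejected rather than silently rescaled.
#'
#' @param path path to a TIFF file.
#' @return an integer-valued numeric matrix (rows = image rows).
#' @export
read_image8 <- function(path) {
  if (!file.exists(path)) stop(sprintf("image not found: %s", path), call. = FALSE)
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bps <- attr(img, "bits.per.sample")
  if (!is.null(bps) && any(bps != 8)) {
    stop(sprintf("expected 8-bit image, got %d-bit: %s", bps[1], path), call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) {
      stop(sprintf("expected single-channel grayscale image: %s", path), call. = FALSE)
    }
    img <- img[, , 1L]
  }
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (min(m) < 0 || max(m) > 255) {
    stop(sprintf("expected 8-bit image, values out of [0,255]: %s", path), call. = FALSE)
  }
  m
}

#' Write an 8-bit grayscale TIFF
#'
#' @param img integer-valued numeric matrix with values in \[0, 255\].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image8 <- function(img, path) {
  assert_image8(img)
  if (any(img != round(img))) stop("image values must be integral", call. = FALSE)
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Construct a single time point (registered phase + fluorescence pair)
#'
#' @param phase phase-contrast image matrix, 8-bit values.
#' @param fluor fluorescence image matrix, same dimensions.
#' @param time_h acquisition time in hours.
#' @param index ordinal position in the series (0-based).
#' @return an object of class `tlm_frame`.
#' @export
frame <- function(phase, fluor, time_h, index = 0L) {
  assert_image8(phase, "phase")
  assert_image8(fluor, "fluor")
  if (!identical(dim(phase), dim(fluor))) {
    stop(sprintf(
      "phase/fluor shape mismatch at time %.3g h: %dx%d vs %dx%d",
      time_h, nrow(phase), ncol(phase), nrow(fluor), ncol(fluor)
    ), call. = FALSE)
  }
  structure(
    list(phase = phase, fluor = fluor, time_h = as.numeric(time_h),
         index = as.integer(index)),
    class = "tlm_frame"
  )
}

#' Construct a time series of frames
#'
#' @param frames list of [frame()] objects.
#' @param channel_names fluorescence channel labels (at least one). The data
#'   model carries multiple channels, but each pipeline invocation processes
#'   one channel.
#' @return an object of class `tlm_timeseries`.
#' @export
timeseries <- function(frames, channel_names = "gfp") {
  if (length(frames) == 0L) stop("time series must contain at least one frame", call. = FALSE)
  if (length(channel_names) < 1L) stop("at least one channel name required", call. = FALSE)
  times <- vapply(frames, function(f) f$time_h, numeric(1))
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  dims <- vapply(frames, function(f) dim(f$phase), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  for (i in seq_along(frames)) frames[[i]]$index <- i - 1L
  structure(list(frames = frames, channel_names = channel_names),
            class = "tlm_timeseries")
}

#' @export
print.tlm_timeseries <- function(x, ...) {
  d <- dim(x$frames[[1]]$phase)
  times <- vapply(x$frames, function(f) f$time_h, numeric(1))
  cat(sprintf(
    "Time-lapse series: %d frames, %dx%d px, t = %.3g..%.3g h, channels: %s\n",
    length(x$frames), d[1], d[2], min(times), max(times),
    paste(x$channel_names, collapse = ", ")
  ))
  invisible(x)
}

#' @export
length.tlm_timeseries <- function(x) length(x$frames)

#' Load a registered phase/fluorescence TIFF time series
#'
#' `path` may be a directory of TIFF pairs or a manifest CSV. A directory is
#' scanned for files whose names end in the phase/fluorescence suffixes
#' (before the `.tif`/`.tiff` extension); shared stems pair the channels and
#' stems are ordered by name. If the directory contains a `manifest.csv` it is
#' used instead. A manifest CSV has columns `phase`, `fluor` (paths, relative
#' to the manifest's directory) and optionally `time_h`.
#'
#' @param path directory or manifest CSV path.
#' @param phase_suffix,fluor_suffix filename suffixes identifying the two
#'   channels when scanning a directory.
#' @param interval_h frame interval in hours, used when no times are given;
#'   frame i (0-based) is assigned `i * interval_h`.
#' @param channel_names passed to [timeseries()].
#' @return a `tlm_timeseries`.
#' @export
load_timeseries <- function(path, phase_suffix = "_ph", fluor_suffix = "_gfp",
                            interval_h = 1, channel_names = "gfp") {
  if (dir.exists(path)) {
    manifest <- file.path(path, "manifest.csv")
    if (file.exists(manifest)) {
      return(load_timeseries(manifest,
        interval_h = interval_h,
        channel_names = channel_names
      ))
    }
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE)
    strip <- function(fs, suffix) {
      hit <- grepl(paste0(suffix, "\\.tiff?$"), fs, ignore.case = TRUE)
      stems <- sub(paste0(suffix, "\\.tiff?$"), "", fs[hit], ignore.case = TRUE)
      stats::setNames(fs[hit], stems)
    }
    ph <- strip(files, phase_suffix)
    fl <- strip(files, fluor_suffix)
    stems <- sort(union(names(ph), names(fl)))
    if (length(stems) == 0L) stop(sprintf("no TIFF pairs found in %s", path), call. = FALSE)
    missing_ph <- setdiff(stems, names(ph))
    missing_fl <- setdiff(stems, names(fl))
    if (length(missing_ph) || length(missing_fl)) {
      stop(sprintf(
        "missing channel for time point(s): %s",
        paste(c(
          if (length(missing_ph)) paste0(missing_ph, " (phase)"),
          if (length(missing_fl)) paste0(missing_fl, " (fluorescence)")
        ), collapse = ", ")
      ), call. = FALSE)
    }
    df <- data.frame(
      phase = file.path(path, unname(ph[stems])),
      fluor = file.path(path, unname(fl[stems])),
      time_h = (seq_along(stems) - 1) * interval_h,
      stringsAsFactors = FALSE
    )
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("phase", "fluor") %in% names(df))) {
      stop("manifest must have 'phase' and 'fluor' columns", call. = FALSE)
    }
    base <- dirname(path)
    rel <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    df$phase <- rel(df$phase)
    df$fluor <- rel(df$fluor)
    if (is.null(df$time_h)) df$time_h <- (seq_len(nrow(df)) - 1) * interval_h
    df <- df[order(df$time_h), , drop = FALSE]
  } else {
    stop(sprintf("no such file or directory: %s", path), call. = FALSE)
  }
  frames <- lapply(seq_len(nrow(df)), function(i) {
    frame(read_image8(df$phase[i]), read_image8(df$fluor[i]),
          time_h = df$time_h[i], index = i - 1L)
  })
  timeseries(frames, channel_names = channel_names)
}

# Doubles are serialized with 17 significant digits so the CSV round-trips
# losslessly; integer columns are written as-is.
#' @noRd
format_csv_col <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- NA
    trimws(out)
  } else {
    x
  }
}

#' Write a measurement table to CSV
#'
#' Writes a header row plus one row per particle. Numeric values round-trip
#' losslessly through [read_measurements()]. An empty table yields a
#' header-only file.
#'
#' @param table a data.frame of measurements.
#' @param dest destination path.
#' @return `dest`, invisibly.
#' @export
write_measurements <- function(table, dest) {
  if (!is.data.frame(table)) stop("table must be a data.frame", call. = FALSE)
  out <- table
  for (j in seq_along(out)) out[[j]] <- format_csv_col(out[[j]])
  utils::write.table(out, dest,
    sep = ",", row.names = FALSE,
    col.names = TRUE, quote = FALSE, na = "NA"
  )
  invisible(dest)
}

#' Read a measurement table written by [write_measurements()]
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
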