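# Ground-truthed synthetic time-lapse generator: rod-shaped cells (capsules)
# rendered dark on a bright phase-contrast background with a halo rim, plus a
# matching fluorescence image, under three expression scenarios —
# homogeneous, noisy heterogeneous, and bistable. Replaces the microscope for
# testing every other module.

#' Scenario parameters for the synthetic generator
#'
#' Expression scenarios: `homogeneous` draws per-cell intensities from one
#' normal distribution whose SD follows the measurement-noise calibration line
#' `noise_slope * mean + noise_intercept` (the homogeneous-control study
#' condition); `noisy` draws from a broad lognormal; `bistable` draws from a
#' two-component normal mixture (low/high modes). Growth is per-cell: length
#' doubles over `doubling_time_h` and cells divide at `division_length_px`,
#' splitting at the midpoint with `division_jitter` relative jitter; daughters
#' inherit the mother's expression mode.
#'
#' @param scenario `"homogeneous"`, `"noisy"` or `"bistable"`.
#' @param n_initial number of seed cells at t = 0.
#' @param mean_level mean expression level (AU) for homogeneous/noisy.
#' @param sd_level homogeneous SD (AU); `NULL` uses the calibration line.
#' @param noise_slope,noise_intercept calibration line for the homogeneous
#'   control SD (AU per AU, and AU).
#' @param sdlog lognormal shape for the noisy scenario.
#' @param low_mean,low_sd,high_mean,high_sd bistable mixture components (AU).
#' @param fraction_high bistable high-mode fraction, in (0, 1).
#' @param doubling_time_h cell doubling time, hours.
#' @param division_length_px length at which a cell divides.
#' @param init_length_px initial/newborn reference length.
#' @param width_px rod width.
#' @param division_jitter relative jitter of the division midpoint.
#' @param induction_time_h intensities ramp linearly from 0 to full over this
#'   time; 0 means fully induced from the start.
#' @param field image field size `c(rows, cols)`.
#' @param seed RNG seed for reproducibility.
#' @return an object of class `scenario_params`.
#' @export
scenario_params <- function(scenario = c("homogeneous", "noisy", "bistable"),
                            n_initial = 10, mean_level = 100, sd_level = NULL,
                            noise_slope = 0.1, noise_intercept = 2,
                            sdlog = 0.5,
                            low_mean = 15, low_sd = 5,
                            high_mean = 150, high_sd = 15,
                            fraction_high = 0.3,
                            doubling_time_h = 1, division_length_px = 30,
                            init_length_px = 15, width_px = 5,
                            division_jitter = 0.05, induction_time_h = 0,
                            field = c(512, 512), seed = 1) {
  scenario <- match.arg(scenario)
  if (scenario == "bistable" && (fraction_high <= 0 || fraction_high >= 1)) {
    stop("fraction_high must be in (0, 1)", call. = FALSE)
  }
  if (width_px < 3) stop("width_px must be >= 3", call. = FALSE)
  if (init_length_px < width_px) stop("init_length_px must be >= width_px", call. = FALSE)
  if (division_length_px <= init_length_px) {
    stop("division_length_px must exceed init_length_px", call. = FALSE)
  }
  if (doubling_time_h <= 0) stop("doubling_time_h must be positive", call. = FALSE)
  if (division_jitter < 0 || division_jitter >= 0.5) {
    stop("division_jitter must be in [0, 0.5)", call. = FALSE)
  }
  structure(as.list(environment()), class = "scenario_params")
}

# Draw per-cell expression intensities (AU, truncated at 0) and mode labels.
#' @noRd
draw_intensities <- function(params, n, modes = NULL) {
  if (n == 0L) return(list(intensity = numeric(0), mode = character(0)))
  if (params$scenario == "homogeneous") {
    s <- params$sd_level %||%
      (params$noise_slope * params$mean_level + params$noise_intercept)
    list(intensity = pmax(stats::rnorm(n, params$mean_level, s), 0),
         mode = rep("single", n))
  } else if (params$scenario == "noisy") {
    mu <- log(params$mean_level) - params$sdlog^2 / 2
    list(intensity = stats::rlnorm(n, mu, params$sdlog),
         mode = rep("single", n))
  } else {
    if (is.null(modes)) {
      modes <- ifelse(stats::runif(n) < params$fraction_high, "high", "low")
    }
    hi <- modes == "high"
    intensity <- numeric(n)
    intensity[hi] <- stats::rnorm(sum(hi), params$high_mean, params$high_sd)
    intensity[!hi] <- stats::rnorm(sum(!hi), params$low_mean, params$low_sd)
    list(intensity = pmax(intensity, 0), mode = modes)
  }
}

# Shortest distance between two segments (p1-p2 and p3-p4), each a length-2
# numeric vector. Used for capsule separation during placement.
#' @noRd
seg_seg_dist <- function(p1, p2, p3, p4) {
  point_seg <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    sqrt(sum((a + t * ab - p)^2))
  }
  segs_intersect <- function(a, b, c, d) {
    cross <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
    d1 <- cross(c, d, a); d2 <- cross(c, d, b)
    d3 <- cross(a, b, c); d4 <- cross(a, b, d)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  if (segs_intersect(p1, p2, p3, p4)) return(0)
  min(point_seg(p1, p3, p4), point_seg(p2, p3, p4),
      point_seg(p3, p1, p2), point_seg(p4, p1, p2))
}

#' @noRd
cell_endpoints <- function(cell) {
  half <- max((cell$length_px - cell$width_px) / 2, 0)
  u <- c(cos(cell$orientation), sin(cell$orientation))
  list(a = c(cell$center_row, cell$center_col) + half * u,
       b = c(cell$center_row, cell$center_col) - half * u)
}

#' @noRd
new_cells_df <- function(n = 0L) {
  data.frame(
    id = integer(n), center_row = numeric(n), center_col = numeric(n),
    orientation = numeric(n), length_px = numeric(n), width_px = numeric(n),
    true_intensity = numeric(n), mode = character(n),
    lineage_parent = integer(n), stringsAsFactors = FALSE
  )
}

#' Place non-touching rod cells at random in the field
#'
#' Rejection sampling: candidate capsules (random centre and orientation,
#' lengths uniform between the newborn and division lengths) are accepted when
#' their axis segments keep at least `min_gap` pixels of clearance beyond the
#' cell widths from every accepted cell.
#'
#' @param params a [scenario_params()] object (field, geometry, scenario).
#' @param n number of cells to place.
#' @param min_gap minimal clearance between cell outlines, pixels.
#' @param max_tries placement attempts per cell before giving up.
#' @return data.frame of synthetic cells (`id`, `center_row`, `center_col`,
#'   `orientation`, `length_px`, `width_px`, `true_intensity`, `mode`,
#'   `lineage_parent`).
#' @export
place_cells <- function(params, n, min_gap = 3, max_tries = 500) {
  stopifnot(inherits(params, "scenario_params"))
  field <- params$field
  margin <- params$division_length_px / 2 + params$width_px
  if (field[1] <= 2 * margin || field[2] <= 2 * margin) {
    stop("field too small for cell placement", call. = FALSE)
  }
  cells <- new_cells_df()
  ends <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- data.frame(
        id = i,
        center_row = stats::runif(1, margin, field[1] - margin),
        center_col = stats::runif(1, margin, field[2] - margin),
        orientation = stats::runif(1, 0, pi),
        length_px = stats::runif(1, params$init_length_px, params$division_length_px),
        width_px = params$width_px, true_intensity = 0,
        mode = "single", lineage_parent = NA_integer_,
        stringsAsFactors = FALSE
      )
      e <- cell_endpoints(cand)
      ok <- TRUE
      for (j in seq_along(ends)) {
        d <- seg_seg_dist(e$a, e$b, ends[[j]]$a, ends[[j]]$b)
        if (d < cells$width_px[j] / 2 + cand$width_px / 2 + min_gap) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        cells <- rbind(cells, cand)
        ends[[length(ends) + 1L]] <- e
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place %d non-touching cells (placed %d)", n, i - 1L),
           call. = FALSE)
    }
  }
  draw <- draw_intensities(params, n)
  cells$true_intensity <- draw$intensity
  cells$mode <- draw$mode
  cells
}

# Event-driven lineage simulation up to t_max. Cells divide when their
# exponentially growing length reaches the division length; daughters get the
# jittered halves, a 2 px separation gap, slight orientation jitter, the
# mother's mode, and a freshly drawn intensity. Events are processed in
# chronological order (ties by id) so the RNG stream is deterministic.
#' @noRd
simulate_lineage <- function(params, t_max) {
  division_time <- function(birth_h, birth_len) {
    birth_h + params$doubling_time_h * log2(params$division_length_px / birth_len)
  }
  roots <- place_cells(params, params$n_initial, min_gap = 10)
  cells <- roots
  cells$birth_h <- 0
  cells$birth_length <- cells$length_px
  cells$division_h <- division_time(0, cells$birth_length)
  next_id <- nrow(cells) + 1L
  gap <- 2
  repeat {
    pending <- which(cells$division_h <= t_max & !duplicated(cells$id) &
                       !(cells$id %in% cells$lineage_parent))
    if (length(pending) == 0L) break
    i <- pending[order(cells$division_h[pending], cells$id[pending])][1]
    td <- cells$division_h[i]
    f <- stats::runif(1, 0.5 - params$division_jitter, 0.5 + params$division_jitter)
    len <- params$division_length_px
    u <- c(cos(cells$orientation[i]), sin(cells$orientation[i]))
    ctr <- c(cells$center_row[i], cells$center_col[i])
    offsets <- c(len * (f - 1) / 2 - gap / 2, len * f / 2 + gap / 2)
    lens <- c(f * len, (1 - f) * len)
    daughters <- new_cells_df(2L)
    for (k in 1:2) {
      pos <- ctr + offsets[k] * u
      daughters$id[k] <- next_id
      daughters$center_row[k] <- pos[1]
      daughters$center_col[k] <- pos[2]
      daughters$orientation[k] <- cells$orientation[i] + stats::rnorm(1, 0, 0.05)
      daughters$length_px[k] <- lens[k]
      daughters$width_px[k] <- params$width_px
      daughters$lineage_parent[k] <- cells$id[i]
      next_id <- next_id + 1L
    }
    modes <- if (params$scenario == "bistable") rep(cells$mode[i], 2) else NULL
    draw <- draw_intensities(params, 2L, modes = modes)
    daughters$true_intensity <- draw$intensity
    daughters$mode <- draw$mode
    daughters$birth_h <- td
    daughters$birth_length <- daughters$length_px
    daughters$division_h <- division_time(td, daughters$birth_length)
    cells <- rbind(cells, daughters)
  }
  cells
}

#' Simulate the cell population at a given time
#'
#' Runs the lineage simulation (exponential length growth, division at the
#' division length with jitter, mode inheritance) from `params$seed` and
#' returns the cells alive at time `t` with their current lengths.
#' Deterministic for a fixed seed.
#'
#' @param params a [scenario_params()].
#' @param t time in hours (>= 0).
#' @return data.frame of living synthetic cells.
#' @export
simulate_population <- function(params, t) {
  stopifnot(inherits(params, "scenario_params"))
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  set.seed(params$seed)
  lineage <- simulate_lineage(params, t)
  population_at(lineage, t, params)
}

#' @noRd
population_at <- function(lineage, t, params) {
  alive <- lineage$birth_h <= t & lineage$division_h > t
  out <- lineage[alive, , drop = FALSE]
  out$length_px <- out$birth_length * 2^((t - out$birth_h) / params$doubling_time_h)
  rownames(out) <- NULL
  out[, names(new_cells_df())]
}

#' Optical rendering parameters
#'
#' @param field image size `c(rows, cols)`.
#' @param phase_bg,phase_cell,rim_level phase-contrast grey levels of the
#'   background, cell interior and halo rim.
#' @param rim_width_px halo rim width.
#' @param phase_noise_sd,fluor_noise_sd additive Gaussian noise SD per channel
#'   (grey levels).
#' @param fluor_bg fluorescence background level.
#' @param grey_per_au intensity-to-8-bit scale (grey levels per AU).
#' @return an object of class `render_params`.
#' @export
render_params <- function(field = c(512, 512), phase_bg = 180, phase_cell = 60,
                          rim_level = 220, rim_width_px = 2,
                          phase_noise_sd = 2, fluor_bg = 8,
                          fluor_noise_sd = 2, grey_per_au = 1) {
  if (any(field < 32)) stop("field too small (minimum 32 px per side)", call. = FALSE)
  structure(as.list(environment()), class = "render_params")
}

#' Render one synthetic frame (phase + fluorescence + ground truth)
#'
#' Phase: bright background with dark capsule-shaped rods and a brighter halo
#' rim (the phase-contrast cue). Fluorescence: dim background with each cell's
#' interior set uniformly to its scaled true intensity. Additive Gaussian read
#' noise is applied per channel and everything is rounded and clamped to
#' \[0, 255\]. The exact per-pixel ground-truth label mask is returned
#' alongside. Off-field cells are clipped.
#'
#' @param cells synthetic cell data.frame ([place_cells()],
#'   [simulate_population()]).
#' @param optics a [render_params()].
#' @param seed optional seed for the rendering noise.
#' @return list with `phase`, `fluor` (8-bit matrices) and `labels` (integer
#'   matrix of cell ids, 0 = background).
#' @export
render_frame <- function(cells, optics = render_params(), seed = NULL) {
  stopifnot(inherits(optics, "render_params"))
  if (!is.null(seed)) set.seed(seed)
  nr <- optics$field[1]
  nc <- optics$field[2]
  phase <- matrix(optics$phase_bg, nr, nc)
  fluor <- matrix(optics$fluor_bg, nr, nc)
  labels <- matrix(0L, nr, nc)
  rims <- vector("list", nrow(cells))
  interiors <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    e <- cell_endpoints(cell)
    rad <- cell$width_px / 2
    reach <- rad + optics$rim_width_px + 1
    r0 <- max(1L, floor(min(e$a[1], e$b[1]) - reach))
    r1 <- min(nr, ceiling(max(e$a[1], e$b[1]) + reach))
    c0 <- max(1L, floor(min(e$a[2], e$b[2]) - reach))
    c1 <- min(nc, ceiling(max(e$a[2], e$b[2]) + reach))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1
    cc <- c0:c1
    pr <- rep(rr, times = length(cc))
    pc <- rep(cc, each = length(rr))
    ab <- e$b - e$a
    len2 <- sum(ab^2)
    tpar <- if (len2 == 0) rep(0, length(pr)) else {
      pmin(pmax(((pr - e$a[1]) * ab[1] + (pc - e$a[2]) * ab[2]) / len2, 0), 1)
    }
    d <- sqrt((e$a[1] + tpar * ab[1] - pr)^2 + (e$a[2] + tpar * ab[2] - pc)^2)
    lin <- pr + (pc - 1L) * nr
    rims[[i]] <- lin[d <= rad + optics$rim_width_px & d > rad]
    interiors[[i]] <- lin[d <= rad]
  }
  # Rims first, interiors second: the halo is an optical artifact around the
  # object boundary and never cuts through an attached neighbour's body.
  for (i in seq_len(nrow(cells))) phase[rims[[i]]] <- optics$rim_level
  for (i in seq_len(nrow(cells))) {
    interior <- interiors[[i]]
    phase[interior] <- optics$phase_cell
    labels[interior] <- cells$id[i]
    fluor[interior] <- clamp8(round(cells$true_intensity[i] * optics$grey_per_au))
  }
  if (optics$phase_noise_sd > 0) {
    phase <- phase + stats::rnorm(nr * nc, 0, optics$phase_noise_sd)
  }
  if (optics$fluor_noise_sd > 0) {
    fluor <- fluor + stats::rnorm(nr * nc, 0, optics$fluor_noise_sd)
  }
  list(phase = clamp8(round(phase)), fluor = clamp8(round(fluor)),
       labels = labels)
}

#' Ground-truth particles from a label mask
#'
#' Converts a synthetic label mask into the particle format used by the
#' measurement functions, so true per-cell statistics can be computed without
#' segmentation.
#'
#' @param labels integer label matrix (0 = background).
#' @param min_area minimal particle area.
#' @return particle list as from [label_particles()]; particle labels are the
#'   cell ids.
#' @export
labels_to_particles <- function(labels, min_area = 1) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  nr <- nrow(labels)
  out <- list()
  for (id in ids) {
    pix <- which(labels == id)
    if (length(pix) < min_area) next
    rows <- ((pix - 1L) %% nr) + 1L
    cols <- ((pix - 1L) %/% nr) + 1L
    out[[length(out) + 1L]] <- list(
      label = id, pixels = pix, area_px = length(pix),
      centroid = c(row = mean(rows), col = mean(cols))
    )
  }
  out
}

#' Two rods rendered in contact (merge-behaviour fixture)
#'
#' Generates a pair of collinear cells attached end to end at the division
#' site (outlines overlapping by one pixel, as in a non-separated division
#' pair), which the segmentation deliberately counts as one particle.
#'
#' @param params a [scenario_params()].
#' @return synthetic cell data.frame of two touching cells.
#' @export
touching_pair <- function(params = scenario_params()) {
  ctr <- params$field / 2
  len <- params$init_length_px
  cells <- new_cells_df(2L)
  cells$id <- 1:2
  cells$center_row <- ctr[1]
  cells$center_col <- c(ctr[2] - (len - 1) / 2, ctr[2] + (len - 1) / 2)
  cells$orientation <- pi / 2  # along the column axis
  cells$length_px <- len
  cells$width_px <- params$width_px
  draw <- draw_intensities(params, 2L)
  cells$true_intensity <- draw$intensity
  cells$mode <- draw$mode
  cells$lineage_parent <- NA_integer_
  cells
}

#' @noRd
induction_ramp <- function(t, induction_time_h) {
  if (induction_time_h <= 0) 1 else min(1, t / induction_time_h)
}

#' Generate a full synthetic time series on disk
#'
#' Writes, per frame, an 8-bit phase TIFF (`t%03d_ph.tif`), an 8-bit
#' fluorescence TIFF (`t%03d_gfp.tif`) and a 16-bit ground-truth label TIFF
#' (`t%03d_labels.tif`), plus `truth.csv` (per frame and cell: id, mode, true
#' intensity and geometry) and a `manifest.csv` readable by
#' [load_timeseries()]. Fully reproducible from `params$seed`.
#'
#' The default `"scattered"` layout places an exponentially growing number of
#' non-touching cells independently per frame with intensities drawn fresh
#' from the scenario distribution — the pipeline performs no tracking, so
#' per-frame population statistics are unaffected. The `"colony"` layout runs
#' the lineage simulation once and renders the living population of each
#' frame, preserving cell identity and mode inheritance over time.
#'
#' @param params a [scenario_params()].
#' @param duration_h total duration in hours.
#' @param interval_h frame interval in hours.
#' @param outdir output directory (created if needed).
#' @param optics a [render_params()].
#' @param layout `"scattered"` or `"colony"`.
#' @return (invisibly) list with `manifest`, `truth` paths and `n_frames`.
#' @export
generate_timeseries <- function(params, duration_h, interval_h, outdir,
                                optics = render_params(field = params$field),
                                layout = c("scattered", "colony")) {
  stopifnot(inherits(params, "scenario_params"))
  layout <- match.arg(layout)
  if (duration_h < interval_h) stop("duration_h must be >= interval_h", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(params$seed)
  times <- seq(0, duration_h, by = interval_h)
  lineage <- if (layout == "colony") simulate_lineage(params, duration_h)
  truth <- list()
  manifest <- list()
  for (k in seq_along(times)) {
    t <- times[k]
    cells <- if (layout == "colony") {
      population_at(lineage, t, params)
    } else {
      n_t <- max(1L, round(params$n_initial * 2^(t / params$doubling_time_h)))
      place_cells(params, n_t)
    }
    ramp <- induction_ramp(t, params$induction_time_h)
    cells$true_intensity <- cells$true_intensity * ramp
    fr <- render_frame(cells, optics)
    stem <- sprintf("t%03d", k - 1L)
    write_image8(fr$phase, file.path(outdir, paste0(stem, "_ph.tif")))
    write_image8(fr$fluor, file.path(outdir, paste0(stem, "_gfp.tif")))
    tiff::writeTIFF(fr$labels / 65535, file.path(outdir, paste0(stem, "_labels.tif")),
                    bits.per.sample = 16L, compression = "none")
    if (nrow(cells) > 0L) {
      truth[[k]] <- data.frame(
        frame_index = k - 1L, time_h = t, cell_id = cells$id,
        mode = cells$mode, true_intensity = cells$true_intensity,
        center_row = cells$center_row, center_col = cells$center_col,
        length_px = cells$length_px, orientation = cells$orientation,
        stringsAsFactors = FALSE
      )
    }
    manifest[[k]] <- data.frame(
      phase = paste0(stem, "_ph.tif"), fluor = paste0(stem, "_gfp.tif"),
      time_h = t, stringsAsFactors = FALSE
    )
  }
  truth_path <- file.path(outdir, "truth.csv")
  manifest_path <- file.path(outdir, "manifest.csv")
  write_measurements(do.call(rbind, truth), truth_path)
  write_measurements(do.call(rbind, manifest), manifest_path)
  invisible(list(manifest = manifest_path, truth = truth_path,
                 n_frames = length(times)))
}

#' Simulate a homogeneous-control calibration series (statistics level)
#'
#' Emulates the four-induction-level control experiment behind the noise
#' baseline: for each induction level, repeated images of a homogeneously
#' expressing population are simulated (per-cell intensities normal with SD
#' on the calibration line `noise_slope * mean + noise_intercept`), and each
#' image contributes one (mean, SD) point.
#'
#' @param mean_levels per-culture mean intensities (AU).
#' @param frames_per_level images per culture.
#' @param cells_per_frame cells measured per image.
#' @param noise_slope,noise_intercept the calibration line.
#' @param seed optional RNG seed.
#' @return data.frame with `level`, `frame`, `mean_fluor`, `sd_fluor`,
#'   `n_cells`.
#' @export
simulate_control_series <- function(mean_levels = c(20, 50, 100, 180),
                                    frames_per_level = 134,
                                    cells_per_frame = 100,
                                    noise_slope = 0.1, noise_intercept = 2,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (m in mean_levels) {
    s <- noise_slope * m + noise_intercept
    for (f in seq_len(frames_per_level)) {
      v <- stats::rnorm(cells_per_frame, m, s)
      out[[length(out) + 1L]] <- data.frame(
        level = m, frame = f, mean_fluor = mean(v), sd_fluor = stats::sd(v),
        n_cells = cells_per_frame
      )
    }
  }
  do.call(rbind, out)
}
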