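# Shared independent oracles and small fixture builders. The oracles are
# deliberately naive (nested loops, exhaustive scans) and never share code
# with the implementation paths they check.

# Brute-force grayscale erosion/dilation/opening by a flat disc.
brute_disc_extreme <- function(m, r, fun) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (dy in -r:r) {
        h <- floor(sqrt(r^2 - dy^2))
        y <- i + dy
        if (y >= 1 && y <= nr) {
          xs <- max(1, j - h):min(nc, j + h)
          vals <- c(vals, m[y, xs])
        }
      }
      out[i, j] <- fun(vals)
    }
  }
  out
}

brute_opening <- function(m, r) {
  brute_disc_extreme(brute_disc_extreme(m, r, min), r, max)
}

# Direct nested-loop 2-D correlation with replicated edges.
brute_convolve <- function(m, k, normalize = FALSE) {
  h <- (nrow(k) - 1) %/% 2
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in -h:h) {
        for (b in -h:h) {
          y <- min(max(i + a, 1), nr)
          x <- min(max(j + b, 1), nc)
          acc <- acc + k[a + h + 1, b + h + 1] * m[y, x]
        }
      }
      out[i, j] <- acc
    }
  }
  s <- sum(k)
  if (normalize && s != 0) out <- out / s
  pmin(pmax(round(out), 0), 255)
}

# Exhaustive intermeans fixed-point scan: all T in [min, max) where
# round((mean below + mean above)/2) == T.
isodata_fixed_points <- function(vals) {
  out <- integer(0)
  for (t in min(vals):(max(vals) - 1)) {
    m0 <- mean(vals[vals <= t])
    m1 <- mean(vals[vals > t])
    if (round((m0 + m1) / 2) == t) out <- c(out, t)
  }
  out
}

# Jaccard index between two pixel-index sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Match ground-truth particles against segmented particles: a truth cell is
# recovered when exactly one segmented particle overlaps it with Jaccard > 0.5.
match_particles <- function(truth, found, threshold = 0.5) {
  matched <- 0L
  used <- rep(FALSE, length(found))
  for (tp in truth) {
    js <- vapply(found, function(sp) jaccard(tp$pixels, sp$pixels), numeric(1))
    hits <- which(js > threshold)
    if (length(hits) == 1L) {
      matched <- matched + 1L
      used[hits] <- TRUE
    }
  }
  list(matched = matched, spurious = sum(!used))
}

# A small random scene rendered to frame images plus ground truth.
random_scene <- function(n_cells = 4, field = c(64, 64), scenario = "bistable",
                         optics = render_params(field = field), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- scenario_params(scenario,
    field = field, division_length_px = 16,
    init_length_px = 9, width_px = 4, seed = if (is.null(seed)) 1 else seed
  )
  cells <- place_cells(p, n_cells, min_gap = 2)
  fr <- render_frame(cells, optics)
  list(cells = cells, frame = fr,
       particles = labels_to_particles(fr$labels))
}
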