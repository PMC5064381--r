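#' Synthetic high-speed video specification
#'
#' Describes a ground-truthed synthetic recording emulating microfluidic cell
#' release past a brightfield viewing window: each object transits the window
#' along the column (flow) axis at constant velocity, tuned so that it is
#' visible in exactly \code{appearances_per_cell} frames — the multiplicity
#' the real system is set up to produce so that no cell is missed. Debris is
#' rendered as jagged star polygons with low solidity by construction;
#' sub-gate small cells fall below the 12 um diameter gate. Sensor noise is
#' i.i.d. truncated Gaussian (clipped at 3.5 sigma, so single hot pixels do
#' not masquerade as particles).
#'
#' @param n_cells number of in-gate cells.
#' @param diameter_dist uniform (min, max) cell diameter in um; the default
#'   15-30 um emulates A549 lung-carcinoma cells, comfortably inside the
#'   12-55 um gate.
#' @param axial_ratio_dist uniform (min, max) axial ratio (default 1-1.4,
#'   inside the 1-1.8 gate).
#' @param cell_contrast peak |signal - background| in counts (default 60).
#' @param appearances_per_cell frames each object is visible (default 6).
#' @param n_debris jagged low-solidity objects.
#' @param n_small_cells sub-gate (< 12 um) cells.
#' @param background_level background intensity in counts (default 1000).
#' @param noise_sigma Gaussian noise SD in counts (default 5).
#' @param frame_shape (rows, cols), default \code{c(256, 376)}.
#' @param fps frames per second (default 6006).
#' @param pixel_pitch um per pixel (default 2.8).
#' @param seed RNG seed; identical seeds give bit-identical stacks.
#' @param contrast_sign -1 for darker-than-background objects (brightfield
#'   absorption, the default) or +1 for bright objects.
#' @param min_separation minimum centre-to-centre separation in um between
#'   co-visible objects; default twice the largest object diameter.
#' @param debris_diameter_dist uniform (min, max) debris outer diameter um.
#' @param small_diameter_dist uniform (min, max) small-cell diameter um.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_cells = 10L, diameter_dist = c(15, 30),
                           axial_ratio_dist = c(1, 1.4), cell_contrast = 60,
                           appearances_per_cell = 6L, n_debris = 0L,
                           n_small_cells = 0L, background_level = 1000,
                           noise_sigma = 5, frame_shape = c(256L, 376L),
                           fps = 6006, pixel_pitch = 2.8, seed = 1L,
                           contrast_sign = -1,
                           min_separation = NULL,
                           debris_diameter_dist = c(35, 50),
                           small_diameter_dist = c(7, 10)) {
  stopifnot(n_cells >= 0, n_debris >= 0, n_small_cells >= 0,
            appearances_per_cell >= 1, noise_sigma >= 0,
            diameter_dist[1] <= diameter_dist[2],
            axial_ratio_dist[1] <= axial_ratio_dist[2],
            contrast_sign %in% c(-1, 1))
  if (is.null(min_separation))
    min_separation <- 2 * max(diameter_dist[2],
                              if (n_debris > 0) debris_diameter_dist[2] else 0)
  structure(list(n_cells = as.integer(n_cells),
                 diameter_dist = diameter_dist,
                 axial_ratio_dist = axial_ratio_dist,
                 cell_contrast = cell_contrast,
                 appearances_per_cell = as.integer(appearances_per_cell),
                 n_debris = as.integer(n_debris),
                 n_small_cells = as.integer(n_small_cells),
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 frame_shape = as.integer(frame_shape), fps = fps,
                 pixel_pitch = pixel_pitch, seed = as.integer(seed),
                 contrast_sign = contrast_sign,
                 min_separation = min_separation,
                 debris_diameter_dist = debris_diameter_dist,
                 small_diameter_dist = small_diameter_dist),
            class = "synthetic_spec")
}

# even-odd point-in-polygon test, vectorised over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# render one object's contribution patch (values in [0,1]); coords 0-based
render_patch <- function(obj, row_c, col_c, nr, nc) {
  half <- ceiling(obj$radius_px) + 4L
  r0 <- max(0L, floor(row_c) - half); r1 <- min(nr - 1L, floor(row_c) + half)
  c0 <- max(0L, floor(col_c) - half); c1 <- min(nc - 1L, floor(col_c) + half)
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - row_c, length(rr), length(cc))
  dx <- matrix(rep(cc - col_c, each = length(rr)), length(rr), length(cc))
  th <- obj$theta
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  if (obj$category == "debris") {
    k <- obj$n_spikes
    ang <- (seq_len(2 * k) - 1) * pi / k
    rad <- rep(c(obj$radius_px, obj$radius_px * obj$inner_ratio), k)
    f <- matrix(as.numeric(point_in_polygon(
      as.vector(u), as.vector(v), rad * cos(ang), rad * sin(ang))),
      length(rr), length(cc))
    return(list(rows = rr + 1L, cols = cc + 1L, f = f))  # sharp: debris is jagged
  } else {
    rho <- sqrt((u / obj$a_px)^2 + (v / obj$b_px)^2)
    f <- (1 - rho) * min(obj$a_px, obj$b_px) + 0.5
    f[f < 0] <- 0; f[f > 1] <- 1
    
  }
  f <- matrix(as.numeric(EBImage::gblur(f, sigma = 0.6)), length(rr))
  list(rows = rr + 1L, cols = cc + 1L, f = f)
}

#' Generate a ground-truthed synthetic stack
#'
#' Objects are scheduled in waves: each wave places at most one object per
#' row lane (lanes separated by at least the minimum separation), and
#' consecutive waves are separated in time so they are never co-visible.
#' Frame 0 is always empty, so it can serve as the background model.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return List with \code{stack} (a \code{\link{frame_stack}}),
#'   \code{truth} (one row per object: id, category, entry/exit frame, true
#'   diameter and axial ratio) and \code{positions} (per-frame true centroids
#'   in 0-based pixels).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  pitch <- spec$pixel_pitch
  A <- spec$appearances_per_cell
  n_obj <- spec$n_cells + spec$n_debris + spec$n_small_cells

  categories <- c(rep("cell", spec$n_cells),
                  rep("debris", spec$n_debris),
                  rep("small_cell", spec$n_small_cells))
  if (n_obj > 1L) categories <- sample(categories)

  objs <- lapply(seq_len(n_obj), function(i) {
    cat_i <- categories[i]
    if (cat_i == "debris") {
      d <- stats::runif(1, spec$debris_diameter_dist[1],
                        spec$debris_diameter_dist[2])
      list(category = cat_i, diameter = d, axial_ratio = NA_real_,
           radius_px = d / 2 / pitch, theta = stats::runif(1, 0, 2 * pi),
           n_spikes = sample(4:5, 1),
           inner_ratio = stats::runif(1, 0.25, 0.35))
    } else {
      dd <- if (cat_i == "cell") spec$diameter_dist else spec$small_diameter_dist
      d <- stats::runif(1, dd[1], dd[2])
      ar <- stats::runif(1, spec$axial_ratio_dist[1], spec$axial_ratio_dist[2])
      a <- d / 2 * sqrt(ar) / pitch  # semi-major, px
      b <- d / 2 / sqrt(ar) / pitch  # semi-minor, px
      list(category = cat_i, diameter = d, axial_ratio = ar,
           radius_px = a, a_px = a, b_px = b,
           theta = stats::runif(1, 0, 2 * pi))
    }
  })

  if (n_obj > 0L) {
    max_rad <- max(vapply(objs, `[[`, numeric(1), "radius_px"))
    margin <- ceiling(max_rad) + 4
    lane_pitch <- max(spec$min_separation / pitch, 2 * max_rad + 4)
    if (margin * 2 >= nr - 1 || (max_rad + 3) * 2 >= nc - 1)
      stop("objects cannot fit the frame at the requested diameter")
    lane_rows <- seq(margin, nr - 1 - margin, by = lane_pitch)
    n_lanes <- length(lane_rows)
    wave <- (seq_len(n_obj) - 1L) %/% n_lanes
    lane <- (seq_len(n_obj) - 1L) %% n_lanes + 1L
    entry <- 1L + wave * (A + 1L)
    n_frames <- max(entry) + A + 1L
  } else {
    n_frames <- max(A + 2L, 8L)
  }

  positions <- vector("list", n_obj)
  for (i in seq_len(n_obj)) {
    o <- objs[[i]]
    x_margin <- o$radius_px + 3
    span <- nc - 1 - 2 * x_margin
    jr <- stats::runif(1, -1.5, 1.5); jx <- stats::runif(1, -1, 1)
    tt <- seq_len(A) - 1L
    positions[[i]] <- data.frame(
      cell_id = sprintf("obj%04d", i),
      frame = entry[i] + tt,
      row = lane_rows[lane[i]] + jr,
      col = x_margin + (tt + 0.5) * span / A + jx)
  }
  positions <- if (n_obj) do.call(rbind, positions) else
    data.frame(cell_id = character(0), frame = integer(0),
               row = numeric(0), col = numeric(0))

  maxval <- 65535
  clip <- 3.5 * spec$noise_sigma
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames) - 1L) {
    img <- matrix(spec$background_level, nr, nc)
    if (spec$noise_sigma > 0) {
      noise <- stats::rnorm(nr * nc, 0, spec$noise_sigma)
      img <- img + matrix(pmin(clip, pmax(-clip, noise)), nr, nc)
    }
    vis <- which(positions$frame == t)
    for (v in vis) {
      i <- match(positions$cell_id[v], sprintf("obj%04d", seq_len(n_obj)))
      p <- render_patch(objs[[i]], positions$row[v], positions$col[v], nr, nc)
      img[p$rows, p$cols] <- img[p$rows, p$cols] +
        spec$contrast_sign * spec$cell_contrast * p$f
    }
    img[img < 0] <- 0; img[img > maxval] <- maxval
    frames[[t + 1L]] <- round(img)
  }

  truth <- if (n_obj) data.frame(
    cell_id = sprintf("obj%04d", seq_len(n_obj)),
    category = categories,
    entry_frame = entry, exit_frame = entry + A - 1L,
    true_diameter = vapply(objs, `[[`, numeric(1), "diameter"),
    true_axial_ratio = vapply(objs, `[[`, numeric(1), "axial_ratio"),
    stringsAsFactors = FALSE
  ) else data.frame(cell_id = character(0), category = character(0),
                    entry_frame = integer(0), exit_frame = integer(0),
                    true_diameter = numeric(0), true_axial_ratio = numeric(0),
                    stringsAsFactors = FALSE)

  list(stack = frame_stack(frames, fps = spec$fps, pixel_pitch = pitch,
                           bit_depth = 16L, sample_id = "synthetic",
                           blood_volume = NA_real_),
       truth = truth, positions = positions)
}

#' Generate a spike-in validation series
#'
#' One stack per requested true cell count, emulating the spike-in series in
#' which 10 to 600 cultured cells were added to 5 mL of carrier fluid and
#' enumerated. Per-stack seeds are derived deterministically from the base
#' seed and the series index.
#'
#' @param true_counts vector of positive cell counts.
#' @param base_spec a \code{\link{synthetic_spec}} supplying all other
#'   parameters.
#' @return List of \code{\link{generate}} results, one per count.
#' @export
spike_series <- function(true_counts, base_spec = synthetic_spec()) {
  stopifnot(all(true_counts > 0))
  lapply(seq_along(true_counts), function(i) {
    sp <- base_spec
    sp$n_cells <- as.integer(true_counts[i])
    sp$seed <- as.integer((base_spec$seed + 7919 * i) %% 2147483647)
    generate(sp)
  })
}
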