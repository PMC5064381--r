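#' Detection parameters
#'
#' Parameters of the image-processing chain: background subtraction,
#' interpolated upscaling, binarization, morphological closing and
#' connected-component analysis.
#'
#' The binarization threshold is \code{binarize_k} times the estimated noise
#' standard deviation of the difference image; the noise scale is estimated
#' robustly (median absolute deviation) so that frames containing cells do not
#' inflate it. \code{min_area} is a guard against noise specks, expressed in
#' upscaled pixels; its default is the upscaled-pixel area of a 6 um disk and
#' is resolved at segmentation time from the pixel pitch.
#'
#' @param background_mode one of \code{"first_frame"}, \code{"median"},
#'   \code{"explicit"}. The default uses the first recorded frame, captured
#'   while flow is stopped and before cell release, as the empty reference.
#' @param scale_factor integer upscaling factor applied before binarization
#'   (default 3, bilinear interpolation).
#' @param binarize_k noise multiplier for the binarization threshold
#'   (default 4).
#' @param closing_radius radius in upscaled pixels of the disc structuring
#'   element used for morphological closing (default 5).
#' @param min_area minimum component area in upscaled px^2; \code{NULL} means
#'   the area of a 6 um disk at the stack's pixel pitch.
#' @param background explicit background raster, required when
#'   \code{background_mode = "explicit"}.
#' @param median_subsample number of evenly spaced frames used for the
#'   per-pixel median background (default 25).
#' @return A list of class \code{detection_params}.
#' @export
detection_params <- function(background_mode = c("first_frame", "median",
                                                 "explicit"),
                             scale_factor = 3L, binarize_k = 4,
                             closing_radius = 5L, min_area = NULL,
                             background = NULL, median_subsample = 25L) {
  background_mode <- match.arg(background_mode)
  stopifnot(scale_factor >= 1, binarize_k > 0, closing_radius >= 0)
  structure(list(background_mode = background_mode,
                 scale_factor = as.integer(scale_factor),
                 binarize_k = binarize_k,
                 closing_radius = as.integer(closing_radius),
                 min_area = min_area,
                 background = background,
                 median_subsample = as.integer(median_subsample)),
            class = "detection_params")
}

default_min_area <- function(pixel_pitch, scale_factor) {
  # area of a 6 um disk, in upscaled pixels
  pi * (3 / (pixel_pitch / scale_factor))^2
}

#' Background model of a stack
#'
#' Returns the empty-frame reference subtracted from every subsequent frame.
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param params a \code{\link{detection_params}}.
#' @return Numeric matrix the size of one frame.
#' @export
background_model <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "frame_stack"), length(stack) > 0)
  switch(params$background_mode,
    first_frame = stack$frames[[1]] * 1.0,
    median = {
      n <- length(stack)
      idx <- unique(round(seq(1, n, length.out = min(params$median_subsample, n))))
      arr <- vapply(stack$frames[idx], as.numeric,
                    numeric(prod(dim(stack$frames[[1]]))))
      matrix(apply(arr, 1, stats::median), nrow = nrow(stack$frames[[1]]))
    },
    explicit = {
      if (is.null(params$background))
        stop("explicit background mode requires a supplied background frame")
      params$background * 1.0
    })
}

#' Absolute difference image
#'
#' \code{|frame - background|} in a widened numeric domain: darker-than-
#' background objects (the usual brightfield appearance) and brighter objects
#' both yield positive traces, with no integer wraparound.
#'
#' @param frame raster (integer matrix).
#' @param background raster of the same shape.
#' @return Non-negative numeric matrix.
#' @export
difference_image <- function(frame, background) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background shapes differ")
  abs(as.numeric(frame) - as.numeric(background)) |>
    matrix(nrow = nrow(frame))
}

#' Robust noise-scale estimate of a stack
#'
#' Median absolute deviation of background-model residuals, pooled over a few
#' evenly spaced frames and rescaled to the standard deviation of a Gaussian
#' (residuals are absolute values of zero-centred noise, so the median of the
#' half-normal is 0.6745 sigma).
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param background background raster.
#' @param n_frames how many frames to pool (default 5).
#' @return Estimated noise standard deviation in counts.
#' @export
estimate_noise_sigma <- function(stack, background, n_frames = 5L) {
  n <- length(stack)
  idx <- unique(round(seq(min(2L, n), n, length.out = min(n_frames, n))))
  resid <- unlist(lapply(stack$frames[idx], function(f)
    as.numeric(difference_image(f, background))))
  stats::median(resid) / 0.6745
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so label
# with it and then merge labels that touch diagonally (union-find over the
# small label graph).
label_components <- function(mask) {
  mode(mask) <- "numeric"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  remap <- integer(nlab)
  remap[sort(unique(root))] <- seq_along(unique(root))
  out <- lab
  out[lab > 0L] <- remap[root[lab[lab > 0L]]]
  out
}

# morphological closing with a disc structuring element; radius 0 is identity
morph_close <- function(mask, radius) {
  if (radius <= 0) return(mask * 1L)
  mode(mask) <- "numeric"
  out <- EBImage::closing(mask, EBImage::makeBrush(2L * radius + 1L, "disc"))
  matrix(as.integer(out > 0.5), nrow = nrow(mask))
}

#' Segment a difference image
#'
#' Upscales the difference image by \code{scale_factor} with bilinear
#' interpolation, binarizes at \code{binarize_k * noise_sigma}, fills particle
#' traces by morphological closing with a disc, labels 8-connected components
#' and discards those below \code{min_area}.
#'
#' @param diff non-negative difference raster (original resolution).
#' @param params a \code{\link{detection_params}}.
#' @param noise_sigma estimated noise standard deviation in counts.
#' @param pixel_pitch um per pixel at original resolution (used only to
#'   resolve the default \code{min_area}).
#' @return Integer label matrix at upscaled resolution; 0 is background and
#'   components are numbered 1..n.
#' @export
segment <- function(diff, params = detection_params(), noise_sigma,
                    pixel_pitch = 2.8) {
  stopifnot(all(diff >= 0))
  s <- params$scale_factor
  up <- if (s == 1L) diff else {
    m <- EBImage::resize(diff, w = nrow(diff) * s, h = ncol(diff) * s,
                         filter = "bilinear")
    matrix(as.numeric(m), nrow = nrow(diff) * s)
  }
  bin <- up > params$binarize_k * noise_sigma
  closed <- morph_close(bin, params$closing_radius)
  lab <- label_components(closed)
  min_area <- if (is.null(params$min_area))
    default_min_area(pixel_pitch, s) else params$min_area
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# count of grid points inside (or on) the convex hull of component pixels
convex_hull_pixel_count <- function(pix) {
  n <- nrow(pix)
  if (n <= 2L) return(n)
  h <- grDevices::chull(pix[, 2], pix[, 1])  # (x=col, y=row) order
  hx <- pix[h, 2]; hy <- pix[h, 1]
  m <- length(h)
  if (m <= 2L) return(n)  # collinear component: hull degenerates to a segment
  jj <- c(seq_len(m)[-1], 1L)
  signed_area <- sum(hx * hy[jj] - hx[jj] * hy) / 2
  s <- if (signed_area >= 0) 1 else -1  # orient the half-plane tests
  rs <- seq(min(pix[, 1]), max(pix[, 1]))
  cs <- seq(min(pix[, 2]), max(pix[, 2]))
  grid_r <- rep(rs, times = length(cs))
  grid_c <- rep(cs, each = length(rs))
  inside <- rep(TRUE, length(grid_r))
  for (i in seq_len(m)) {
    j <- jj[i]
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    cr <- ex * (grid_r - hy[i]) - ey * (grid_c - hx[i])
    inside <- inside & (s * cr >= -1e-9)
    if (!any(inside)) break
  }
  sum(inside)
}

#' Measure one labeled component
#'
#' Computes the four gated morphometric features in physical units.
#' Area is \code{pixel_count * (pixel_pitch / scale_factor)^2}; diameter is
#' that of the equal-area circle; solidity is pixel count over convex-hull
#' pixel count; axial ratio is major over minor axis of the moment-equivalent
#' ellipse (a 1/12-pixel variance term keeps single-pixel and single-row
#' components finite, with the convention that a 1-px component has solidity 1
#' and axial ratio 1). The interior intensity range (max minus min of raw
#' pixels) is taken on the original-resolution frame inside the down-mapped
#' component footprint, avoiding interpolation artifacts.
#'
#' @param labels label matrix from \code{\link{segment}} (upscaled).
#' @param id component label to measure.
#' @param frame raw original-resolution frame.
#' @param pixel_pitch um per pixel at original resolution.
#' @param scale_factor upscaling factor used in segmentation.
#' @param sample_id,frame_index carried through into the record.
#' @return One-row data frame (a detected-object record) with centroid in
#'   0-based original-resolution coordinates and a half-open bounding box.
#' @export
measure <- function(labels, id, frame, pixel_pitch, scale_factor,
                    sample_id = "", frame_index = NA_integer_) {
  pix <- which(labels == id, arr.ind = TRUE)
  if (nrow(pix) == 0L) stop("label ", id, " not present in mask")
  n <- nrow(pix)
  s <- scale_factor
  area_um2 <- n * (pixel_pitch / s)^2
  diameter <- 2 * sqrt(area_um2 / pi)
  centroid_row <- (mean(pix[, 1]) - 0.5) / s - 0.5
  centroid_col <- (mean(pix[, 2]) - 0.5) / s - 0.5

  if (n <= 2L) {
    solidity <- 1; axial_ratio <- 1
  } else {
    solidity <- min(1, n / convex_hull_pixel_count(pix))
    cv <- stats::cov(pix) * (n - 1) / n + diag(1 / 12, 2)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    axial_ratio <- sqrt(max(ev) / max(min(ev), 1e-12))
  }

  # down-map footprint to original resolution for raw-intensity statistics
  orig <- unique(cbind(ceiling(pix[, 1] / s), ceiling(pix[, 2] / s)))
  vals <- frame[orig]
  intensity_range <- max(vals) - min(vals)

  edge <- any(pix[, 1] == 1L | pix[, 2] == 1L |
              pix[, 1] == nrow(labels) | pix[, 2] == ncol(labels))

  data.frame(
    sample_id = sample_id, frame_index = frame_index,
    centroid_row = centroid_row, centroid_col = centroid_col,
    area_um2 = area_um2, diameter = diameter,
    solidity = solidity, axial_ratio = axial_ratio,
    intensity_range = as.numeric(intensity_range),
    bbox_rmin = min(orig[, 1]) - 1L, bbox_rmax = max(orig[, 1]),
    bbox_cmin = min(orig[, 2]) - 1L, bbox_cmax = max(orig[, 2]),
    edge_touching = edge,
    stringsAsFactors = FALSE
  )
}

#' Detect objects in every frame of a stack
#'
#' Runs background subtraction, segmentation and measurement over the stack
#' and concatenates the per-frame records, ordered by (frame, label). When the
#' background model is the first frame, detection starts at the second frame.
#' The noise scale is estimated once per stack.
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param params a \code{\link{detection_params}}.
#' @return Data frame of detected objects (possibly 0 rows), with the
#'   estimated noise sigma attached as attribute \code{"noise_sigma"}.
#' @export
detect_stack <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "frame_stack"), length(stack) > 0)
  bg <- background_model(stack, params)
  sigma <- estimate_noise_sigma(stack, bg)
  first <- if (params$background_mode == "first_frame") 2L else 1L
  out <- vector("list", length(stack))
  for (i in seq(first, length(stack))) {
    diff <- difference_image(stack$frames[[i]], bg)
    lab <- segment(diff, params, sigma, stack$pixel_pitch)
    nlab <- max(lab)
    if (nlab > 0L)
      out[[i]] <- do.call(rbind, lapply(seq_len(nlab), function(id)
        measure(lab, id, stack$frames[[i]], stack$pixel_pitch,
                params$scale_factor, sample_id = stack$sample_id,
                frame_index = i - 1L)))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- measure_empty_frame()
  attr(res, "noise_sigma") <- sigma
  res
}

measure_empty_frame <- function() {
  data.frame(sample_id = character(0), frame_index = integer(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             area_um2 = numeric(0), diameter = numeric(0),
             solidity = numeric(0), axial_ratio = numeric(0),
             intensity_range = numeric(0),
             bbox_rmin = integer(0), bbox_rmax = integer(0),
             bbox_cmin = integer(0), bbox_cmax = integer(0),
             edge_touching = logical(0), stringsAsFactors = FALSE)
}
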