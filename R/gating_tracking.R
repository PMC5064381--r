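#' Morphometric gate parameters
#'
#' Accept/reject intervals on the four object features, trained in the source
#' workflow on A549 lung-cancer cells imaged in flow. Diameter bounds are
#' exclusive ("greater than 12 um and less than 55 um"); the other three
#' gates are closed intervals.
#'
#' @param diameter open interval in um, default \code{c(12, 55)}.
#' @param solidity closed interval, default \code{c(0.7, 1)}.
#' @param axial_ratio closed interval, default \code{c(1, 1.8)}.
#' @param intensity_range closed interval in counts, default
#'   \code{c(0, 20000)}.
#' @return A list of class \code{gate_params}.
#' @export
gate_params <- function(diameter = c(12, 55), solidity = c(0.7, 1),
                        axial_ratio = c(1, 1.8),
                        intensity_range = c(0, 20000)) {
  for (iv in list(diameter, solidity, axial_ratio, intensity_range))
    if (length(iv) != 2L || iv[1] > iv[2]) stop("gate intervals must be ordered pairs")
  structure(list(diameter = diameter, solidity = solidity,
                 axial_ratio = axial_ratio, intensity_range = intensity_range),
            class = "gate_params")
}

#' Apply morphometric gates
#'
#' Keeps objects whose diameter lies strictly inside the open diameter
#' interval and whose solidity, axial ratio and intensity range lie inside
#' their closed intervals. Gates are applied in the order diameter, solidity,
#' axial ratio, intensity; the order affects only the per-gate rejection
#' tallies (attached as attribute \code{"rejections"}), never the surviving
#' set.
#'
#' @param objects data frame of detected objects.
#' @param gates a \code{\link{gate_params}}.
#' @return The surviving subset, with a named rejection-tally attribute.
#' @export
apply_gates <- function(objects, gates = gate_params()) {
  tally <- c(diameter = 0L, solidity = 0L, axial_ratio = 0L,
             intensity_range = 0L)
  if (nrow(objects)) {
    keep <- rep(TRUE, nrow(objects))
    pass_d <- objects$diameter > gates$diameter[1] &
              objects$diameter < gates$diameter[2]
    tally["diameter"] <- sum(keep & !pass_d); keep <- keep & pass_d
    pass_s <- objects$solidity >= gates$solidity[1] &
              objects$solidity <= gates$solidity[2]
    tally["solidity"] <- sum(keep & !pass_s); keep <- keep & pass_s
    pass_a <- objects$axial_ratio >= gates$axial_ratio[1] &
              objects$axial_ratio <= gates$axial_ratio[2]
    tally["axial_ratio"] <- sum(keep & !pass_a); keep <- keep & pass_a
    pass_i <- objects$intensity_range >= gates$intensity_range[1] &
              objects$intensity_range <= gates$intensity_range[2]
    tally["intensity_range"] <- sum(keep & !pass_i); keep <- keep & pass_i
    objects <- objects[keep, , drop = FALSE]
  }
  rownames(objects) <- NULL
  attr(objects, "rejections") <- tally
  objects
}

#' Link per-frame detections into tracks
#'
#' A cell released through the viewing window appears in about six successive
#' frames; counting raw detections would therefore overcount roughly sixfold.
#' This greedy nearest-neighbour linker collapses those appearances: for each
#' new frame, every open track claims the nearest unclaimed detection within
#' \code{max_displacement} of its predicted position (last position plus last
#' velocity; zero velocity for single-member tracks). Claims are resolved in
#' ascending (distance, track id) order, so the result is deterministic and
#' independent of detection input order within a frame. Unclaimed detections
#' open new tracks; tracks idle for more than \code{max_frame_gap} frames
#' close.
#'
#' @param objects gated detections from one sample (data frame).
#' @param max_displacement maximum allowed distance in original-resolution
#'   pixels between predicted and observed position. The default, frame width
#'   376 px divided by 6 appearances times 1.5, reflects a cell traversing
#'   the window in about six frames.
#' @param max_frame_gap maximum frame gap bridged within one track
#'   (default 1: consecutive frames only).
#' @return Data frame of tracks (one row per physical cell) with appearance
#'   count, frame span, per-feature medians and a \code{members} list-column
#'   of row indices into \code{objects}.
#' @export
link_tracks <- function(objects, max_displacement = 376 / 6 * 1.5,
                        max_frame_gap = 1L) {
  feats <- c("diameter", "solidity", "axial_ratio", "intensity_range")
  if (!nrow(objects)) {
    out <- data.frame(track_id = integer(0), n_appearances = integer(0),
                      first_frame = integer(0), last_frame = integer(0))
    for (f in feats) out[[f]] <- numeric(0)
    out$members <- I(list())
    return(out)
  }
  ord <- order(objects$frame_index)
  frames <- sort(unique(objects$frame_index))
  tracks <- list()   # each: members (row idx), last, prev (r,c), last_frame
  next_id <- 1L
  for (f in frames) {
    det_idx <- ord[objects$frame_index[ord] == f]
    pos <- cbind(objects$centroid_row[det_idx], objects$centroid_col[det_idx])
    open <- which(vapply(tracks, function(t)
      (f - t$last_frame) >= 1L && (f - t$last_frame) <= max_frame_gap + 0,
      logical(1)))
    claimed_det <- rep(FALSE, length(det_idx))
    claimed_trk <- rep(FALSE, length(open))
    if (length(open) && length(det_idx)) {
      cand <- do.call(rbind, lapply(seq_along(open), function(k) {
        t <- tracks[[open[k]]]
        pred <- t$last + (t$last - t$prev)
        d <- sqrt((pos[, 1] - pred[1])^2 + (pos[, 2] - pred[2])^2)
        cbind(k = k, j = seq_along(det_idx), d = d)
      }))
      cand <- cand[cand[, "d"] <= max_displacement, , drop = FALSE]
      cand <- cand[order(cand[, "d"], cand[, "k"]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        k <- cand[r, "k"]; j <- cand[r, "j"]
        if (claimed_trk[k] || claimed_det[j]) next
        claimed_trk[k] <- TRUE; claimed_det[j] <- TRUE
        ti <- open[k]
        tracks[[ti]]$prev <- tracks[[ti]]$last
        tracks[[ti]]$last <- pos[j, ]
        tracks[[ti]]$last_frame <- f
        tracks[[ti]]$members <- c(tracks[[ti]]$members, det_idx[j])
      }
    }
    # unclaimed detections open new tracks, in stable detection order
    for (j in which(!claimed_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, members = det_idx[j],
        last = pos[j, ], prev = pos[j, ], last_frame = f)
      next_id <- next_id + 1L
    }
  }
  rows <- lapply(tracks, function(t) {
    m <- t$members
    rec <- data.frame(track_id = t$id, n_appearances = length(m),
                      first_frame = min(objects$frame_index[m]),
                      last_frame = max(objects$frame_index[m]))
    for (f in feats) rec[[f]] <- stats::median(objects[[f]][m])
    rec
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id), , drop = FALSE]
  out$members <- I(lapply(tracks, `[[`, "members")[order(vapply(tracks, `[[`,
                  integer(1), "id"))])
  rownames(out) <- NULL
  out
}

#' Per-sample unique-cell count and rate
#'
#' @param tracks data frame from \code{\link{link_tracks}}.
#' @param blood_volume millilitres of whole blood the sample represents.
#' @param min_appearances minimum appearance count for a track to be counted
#'   (default 1: no persistence filter).
#' @param sample_id carried through.
#' @return List with \code{sample_id}, \code{n_unique_cells},
#'   \code{blood_volume} and \code{rate} in cells per mL.
#' @export
count_sample <- function(tracks, blood_volume, min_appearances = 1L,
                         sample_id = "") {
  if (!is.numeric(blood_volume) || is.na(blood_volume) || blood_volume <= 0)
    stop("'blood_volume' must be a positive number of mL")
  n <- sum(tracks$n_appearances >= min_appearances)
  list(sample_id = sample_id, n_unique_cells = as.integer(n),
       blood_volume = blood_volume, rate = n / blood_volume)
}

#' Appearance-division fallback estimator
#'
#' Cross-check for the tracking deduplication: divides the raw gated
#' detection count by the nominal number of appearances per cell and rounds.
#'
#' @param objects gated detections.
#' @param appearances_per_cell nominal appearance multiplicity (default 6).
#' @return Estimated unique-cell count (integer).
#' @export
count_by_division <- function(objects, appearances_per_cell = 6) {
  as.integer(round(nrow(objects) / appearances_per_cell))
}
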