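#' Classify one immunostained cell
#'
#' Encodes the written CK/CD45/DAPI enumeration criteria as a deterministic
#' rule cascade over the marker flags:
#' \enumerate{
#'   \item irregular/jagged debris morphology: \code{DEBRIS};
#'   \item CD45+ (regardless of CK): \code{WBC} (doubly stained CK+/CD45+
#'     cells correspond to activated granulocytes);
#'   \item CK+/CD45-: \code{CTC};
#'   \item DAPI-only: \code{CTC} when the nucleus is large
#'     (> \code{nucleus_cutoff}, default 9 um) with a large
#'     nuclear-to-cytoplasmic area ratio (>= \code{nc_cutoff}) and not
#'     lobular/segmented; otherwise \code{WBC};
#'   \item DAPI- without a debris flag: \code{DEBRIS} (anucleate object).
#' }
#' A DAPI-only cell with neither nucleus diameter nor N:C ratio available is
#' unclassifiable; when only one of the two is available, the missing
#' criterion is not held against the cell.
#'
#' @param dapi_pos,ck_pos,cd45_pos marker flags.
#' @param nucleus_diameter nucleus diameter in um (optional).
#' @param nc_ratio nuclear/cell area ratio in [0, 1] (optional).
#' @param lobular_nucleus flag for lobular or segmented granulocytic nuclei.
#' @param debris_morphology flag for irregular/jagged brightfield outline.
#' @param nucleus_cutoff large-nucleus cutoff in um (default 9).
#' @param nc_cutoff large-N:C cutoff (default 0.5).
#' @return One of \code{"CTC"}, \code{"WBC"}, \code{"DEBRIS"}.
#' @export
classify_marker_cell <- function(dapi_pos, ck_pos, cd45_pos,
                                 nucleus_diameter = NA_real_,
                                 nc_ratio = NA_real_,
                                 lobular_nucleus = FALSE,
                                 debris_morphology = FALSE,
                                 nucleus_cutoff = 9, nc_cutoff = 0.5) {
  stopifnot(is.logical(dapi_pos), is.logical(ck_pos), is.logical(cd45_pos))
  if (!is.na(nc_ratio) && (nc_ratio < 0 || nc_ratio > 1))
    stop("'nc_ratio' must lie in [0, 1]")
  if (!is.na(nucleus_diameter) && nucleus_diameter <= 0)
    stop("'nucleus_diameter' must be positive")
  if (isTRUE(debris_morphology)) return("DEBRIS")
  if (cd45_pos) return("WBC")
  if (ck_pos) return("CTC")
  if (!dapi_pos) return("DEBRIS")
  # DAPI-only cell: size / N:C / nuclear-shape criteria
  if (is.na(nucleus_diameter) && is.na(nc_ratio))
    stop("DAPI-only cell without nucleus_diameter or nc_ratio is unclassifiable")
  if (isTRUE(lobular_nucleus)) return("WBC")
  big_nucleus <- is.na(nucleus_diameter) || nucleus_diameter > nucleus_cutoff
  big_nc <- is.na(nc_ratio) || nc_ratio >= nc_cutoff
  if (big_nucleus && big_nc) "CTC" else "WBC"
}

#' Classify marker-cell records in a table
#'
#' Vectorised wrapper over \code{\link{classify_marker_cell}}; appends a
#' \code{class} column.
#'
#' @param cells data frame with logical columns \code{dapi_pos},
#'   \code{ck_pos}, \code{cd45_pos} and optional \code{nucleus_diameter},
#'   \code{nc_ratio}, \code{lobular_nucleus}, \code{debris_morphology}.
#' @inheritParams classify_marker_cell
#' @return The input with a \code{class} column appended.
#' @export
classify_marker_table <- function(cells, nucleus_cutoff = 9, nc_cutoff = 0.5) {
  get <- function(col, default) if (col %in% names(cells)) cells[[col]]
                                else rep(default, nrow(cells))
  cells$class <- vapply(seq_len(nrow(cells)), function(i)
    classify_marker_cell(
      as.logical(cells$dapi_pos[i]), as.logical(cells$ck_pos[i]),
      as.logical(cells$cd45_pos[i]),
      nucleus_diameter = get("nucleus_diameter", NA_real_)[i],
      nc_ratio = get("nc_ratio", NA_real_)[i],
      lobular_nucleus = isTRUE(as.logical(get("lobular_nucleus", FALSE)[i])),
      debris_morphology = isTRUE(as.logical(get("debris_morphology", FALSE)[i])),
      nucleus_cutoff = nucleus_cutoff, nc_cutoff = nc_cutoff),
    character(1))
  cells
}

# greedy pairing of red and green spots by ascending pairwise distance;
# ties broken by (red index, green index)
pair_spots <- function(red, green) {
  nr <- nrow(red); ng <- nrow(green)
  if (nr == 0L || ng == 0L)
    return(list(pairs = matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("r", "g", "d"))),
                unpaired_red = seq_len(nr), unpaired_green = seq_len(ng)))
  d <- outer(seq_len(nr), seq_len(ng), function(i, j)
    sqrt((red[i, 1] - green[j, 1])^2 + (red[i, 2] - green[j, 2])^2))
  cand <- cbind(r = rep(seq_len(nr), ng),
                g = rep(seq_len(ng), each = nr),
                d = as.vector(d))
  cand <- cand[order(cand[, "d"], cand[, "r"], cand[, "g"]), , drop = FALSE]
  used_r <- logical(nr); used_g <- logical(ng)
  pairs <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("r", "g", "d")))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "r"]; j <- cand[k, "g"]
    if (used_r[i] || used_g[j]) next
    used_r[i] <- TRUE; used_g[j] <- TRUE
    pairs <- rbind(pairs, cand[k, , drop = FALSE])
  }
  list(pairs = pairs, unpaired_red = which(!used_r),
       unpaired_green = which(!used_g))
}

#' Classify one nucleus from break-apart FISH spots
#'
#' In an ALK break-apart assay, red and green probes flank the locus: fused
#' (overlapping, yellow) red-green signals mark an intact locus; split
#' signals mark a rearrangement. Red and green spots are paired greedily by
#' ascending pairwise distance. Pairs closer than \code{fusion_distance}
#' count as fused copies; pairs beyond it, and unpaired spots of either
#' colour, each count as one rearrangement-consistent split copy.
#'
#' Calls: any split copy makes the nucleus \code{POSITIVE}
#' (\code{POSITIVE_POLYSOMY} when total copies >= 3); otherwise two fused
#' copies are \code{NEGATIVE} and three or more are
#' \code{NEGATIVE_POLYSOMY}. Nuclei flagged uninterpretable upstream, or
#' with at most one resolvable copy, are \code{UNINTERPRETABLE}.
#'
#' @param red_spots,green_spots 2-column matrices of (x, y) spot positions in
#'   image pixels (possibly 0 rows).
#' @param fusion_distance fusion cutoff in pixels (conventionally about one
#'   signal width).
#' @param interpretable upstream interpretability flag.
#' @return List with \code{call}, \code{n_fused}, \code{n_split}.
#' @export
classify_fish_cell <- function(red_spots, green_spots, fusion_distance,
                               interpretable = TRUE) {
  if (fusion_distance < 0) stop("'fusion_distance' must be non-negative")
  red <- matrix(as.numeric(red_spots), ncol = 2)
  green <- matrix(as.numeric(green_spots), ncol = 2)
  if (any(!is.finite(red)) || any(!is.finite(green)))
    stop("spot coordinates must be finite")
  p <- pair_spots(red, green)
  n_fused <- sum(p$pairs[, "d"] <= fusion_distance)
  n_split <- sum(p$pairs[, "d"] > fusion_distance) +
    length(p$unpaired_red) + length(p$unpaired_green)
  copies <- n_fused + n_split
  call <- if (!isTRUE(interpretable) || copies <= 1L) "UNINTERPRETABLE"
    else if (n_split >= 1L) {
      if (copies >= 3L) "POSITIVE_POLYSOMY" else "POSITIVE"
    } else if (copies >= 3L) "NEGATIVE_POLYSOMY" else "NEGATIVE"
  list(call = call, n_fused = as.integer(n_fused),
       n_split = as.integer(n_split))
}

#' Sample-level ALK call from per-nucleus FISH calls
#'
#' A sample is ALK-positive when the fraction of rearranged
#' (\code{POSITIVE} or \code{POSITIVE_POLYSOMY}) nuclei among interpretable
#' nuclei reaches \code{fraction_threshold} percent (inclusive); 15% is the
#' conventional tissue-FISH cutoff. Uninterpretable nuclei are excluded from
#' the denominator.
#'
#' @param calls character vector of per-nucleus calls.
#' @param fraction_threshold percent cutoff (default 15).
#' @return List with \code{fraction} (percent) and \code{positive} flag.
#' @export
call_sample_fish <- function(calls, fraction_threshold = 15) {
  interp <- calls != "UNINTERPRETABLE"
  if (!sum(interp)) stop("no interpretable nuclei")
  fraction <- 100 * sum(calls %in% c("POSITIVE", "POSITIVE_POLYSOMY")) /
    sum(interp)
  list(fraction = fraction, positive = fraction >= fraction_threshold)
}

#' Classify a FISH spot table
#'
#' @param spots data frame with columns \code{cell_id}, \code{channel}
#'   (\code{"red"}/\code{"green"}), \code{x}, \code{y}.
#' @param fusion_distance fusion cutoff in pixels.
#' @param fraction_threshold sample-level percent cutoff (default 15).
#' @return List with per-cell call data frame and the sample-level call.
#' @export
classify_fish_table <- function(spots, fusion_distance,
                                fraction_threshold = 15) {
  stopifnot(all(c("cell_id", "channel", "x", "y") %in% names(spots)))
  if (!nrow(spots)) stop("empty FISH spot table")
  ids <- unique(spots$cell_id)
  rows <- lapply(ids, function(id) {
    s <- spots[spots$cell_id == id, , drop = FALSE]
    r <- as.matrix(s[s$channel == "red", c("x", "y")])
    g <- as.matrix(s[s$channel == "green", c("x", "y")])
    cl <- classify_fish_cell(r, g, fusion_distance)
    data.frame(cell_id = id, call = cl$call, n_fused = cl$n_fused,
               n_split = cl$n_split, stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  list(cells = cells,
       sample = call_sample_fish(cells$call, fraction_threshold))
}
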