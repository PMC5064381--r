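#' Construct a frame stack
#'
#' A frame stack bundles an ordered sequence of grayscale frames with the
#' acquisition metadata needed to convert pixel measurements into physical
#' units: frame rate, pixel pitch at the sample plane, bit depth, and the
#' whole-blood volume the recording represents.
#'
#' Pixel coordinates throughout the package are 0-based \code{(row, col)};
#' region-of-interest rectangles are half-open
#' \code{c(rmin, rmax, cmin, cmax)}.
#'
#' @param frames list of integer matrices, all the same dimension.
#' @param fps frames per second (default 6006, the high-speed camera rate).
#' @param pixel_pitch micrometres per pixel at the sample plane (default 2.8).
#' @param bit_depth 8 or 16; inferred from pixel values when \code{NULL}.
#' @param roi optional half-open rectangle \code{c(rmin, rmax, cmin, cmax)},
#'   0-based, that must lie inside the frame bounds.
#' @param sample_id free-text sample identifier.
#' @param blood_volume millilitres of whole blood the recording represents.
#' @return An object of class \code{frame_stack}.
#' @export
frame_stack <- function(frames, fps = 6006, pixel_pitch = 2.8,
                        bit_depth = NULL, roi = NULL, sample_id = "",
                        blood_volume = NA_real_) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of matrices")
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f)) stop("every frame must be a matrix")
    if (!identical(dim(f), dims)) stop("frames have mixed shapes")
  }
  if (fps <= 0) stop("'fps' must be positive")
  if (pixel_pitch <= 0) stop("'pixel_pitch' must be positive")
  if (is.null(bit_depth)) {
    mx <- max(vapply(frames, max, numeric(1)))
    bit_depth <- if (mx > 255) 16L else 8L
  }
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  if (!is.null(roi)) {
    if (length(roi) != 4L || roi[1] < 0 || roi[3] < 0 ||
        roi[2] > dims[1] || roi[4] > dims[2] ||
        roi[1] >= roi[2] || roi[3] >= roi[4])
      stop("'roi' must be a half-open rectangle inside the frame bounds")
  }
  structure(list(
    frames = lapply(frames, function(f) {
      storage.mode(f) <- "integer"; f
    }),
    fps = as.numeric(fps),
    pixel_pitch = as.numeric(pixel_pitch),
    bit_depth = as.integer(bit_depth),
    duration = length(frames) / fps,
    roi = roi,
    sample_id = as.character(sample_id),
    blood_volume = as.numeric(blood_volume)
  ), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "frame_stack: %d frames of %d x %d px, %d-bit, %.0f fps, %.3g um/px\n",
    length(x$frames), d[1], d[2], x$bit_depth, x$fps, x$pixel_pitch))
  if (!is.na(x$blood_volume))
    cat(sprintf("  blood volume: %g mL\n", x$blood_volume))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

sidecar_path_for <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta")
}

#' Read an acquisition sidecar file
#'
#' Sidecars are flat \code{key = value} text files carrying the acquisition
#' metadata (fps, pixel_pitch, blood_volume, ...) that proprietary camera
#' containers would otherwise hold. Unknown keys are preserved.
#'
#' @param path sidecar file path.
#' @return Named list of values; numeric-looking values are converted.
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("unparseable sidecar line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_sidecar
#' @param meta named list of metadata values.
#' @export
write_sidecar <- function(meta, path) {
  keys <- names(meta)
  vals <- vapply(meta, function(v) format(v, digits = 15), character(1))
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}

# numeric sort of frame files by the last integer embedded in the filename,
# so frame_10 sorts after frame_2
order_frame_files <- function(files) {
  base <- basename(files)
  nums <- suppressWarnings(as.numeric(vapply(base, function(b) {
    m <- regmatches(b, gregexpr("[0-9]+", b))[[1]]
    if (length(m)) m[length(m)] else NA_character_
  }, character(1))))
  if (anyNA(nums)) order(base) else order(nums)
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    bits <- if (max(img) > 255 || attr(img, "bits.per.sample") %in% 16) 16L else 8L
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    # readPNG returns [0,1]; 16-bit PNGs have 1/65535 quantization
    bits <- if (any(abs(raw * 255 - round(raw * 255)) > 1e-6)) 16L else 8L
    img <- round(raw * (2^bits - 1))
  } else stop("unsupported frame format: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  storage.mode(img) <- "integer"
  list(frame = img, bit_depth = bits)
}

#' Read a high-speed video stack
#'
#' Accepts either a multi-page grayscale TIFF or a directory of numbered
#' single-frame PNG/TIFF images. Frames in a directory are ordered by the
#' integer embedded in their filenames, not lexicographically. Acquisition
#' metadata is taken from the sidecar file (default: same basename with a
#' \code{.meta} extension); when absent, defaults are used with a warning
#' (fps 6006, pixel pitch 2.8 um/px).
#'
#' @param path multi-page TIFF file or directory of numbered frames.
#' @param sidecar optional explicit sidecar path.
#' @return A \code{\link{frame_stack}}.
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("input not found: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("no frame images in directory: ", path)
    files <- files[order_frame_files(files)]
    read <- lapply(files, read_frame_file)
    frames <- lapply(read, `[[`, "frame")
    bit_depth <- max(vapply(read, `[[`, integer(1), "bit_depth"))
    dims <- lapply(frames, dim)
    if (length(unique(dims)) != 1L) stop("frames have mixed shapes")
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      storage.mode(p) <- "integer"; p
    })
    bit_depth <- if (max(vapply(frames, max, numeric(1))) > 255) 16L else 8L
  }

  if (is.null(sidecar)) {
    guess <- sidecar_path_for(path)
    sidecar <- if (file.exists(guess)) guess else NA_character_
  }
  if (!is.na(sidecar)) {
    meta <- read_sidecar(sidecar)
  } else {
    warning("no sidecar found; using default acquisition metadata ",
            "(fps 6006, pixel_pitch 2.8 um/px)")
    meta <- list()
  }
  frame_stack(
    frames,
    fps = if (!is.null(meta$fps)) meta$fps else 6006,
    pixel_pitch = if (!is.null(meta$pixel_pitch)) meta$pixel_pitch else 2.8,
    bit_depth = if (!is.null(meta$bit_depth)) as.integer(meta$bit_depth)
                else bit_depth,
    sample_id = if (!is.null(meta$sample_id)) meta$sample_id else "",
    blood_volume = if (!is.null(meta$blood_volume)) meta$blood_volume
                   else NA_real_
  )
}

#' Write a frame stack as a multi-page TIFF plus sidecar
#'
#' Integer pixel values survive the round trip bit-exactly;
#' \code{\link{read_stack}} inverts this function.
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param path output TIFF path; the sidecar is written alongside with the
#'   same basename and a \code{.meta} extension.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  maxval <- 2^stack$bit_depth - 1
  pages <- lapply(stack$frames, function(f) f / maxval)
  ok <- try(tiff::writeTIFF(pages, path,
                            bits.per.sample = stack$bit_depth), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  meta <- list(fps = stack$fps, pixel_pitch = stack$pixel_pitch,
               bit_depth = stack$bit_depth, sample_id = stack$sample_id,
               blood_volume = stack$blood_volume)
  meta <- meta[!vapply(meta, function(v) is.na(v) || identical(v, ""),
                       logical(1))]
  write_sidecar(meta, sidecar_path_for(path))
  invisible(path)
}

#' Write a record table as CSV
#'
#' One record per line with a header row and stable column order; floats keep
#' full double precision so a round-trip read returns equal values.
#'
#' @param records data frame of homogeneous records (detected objects, tracks,
#'   marker cells or FISH spot rows).
#' @param path output CSV path.
#' @export
write_table <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    if (!length(records)) stop("cannot infer columns from an empty list; ",
                               "pass a data frame")
    cols <- lapply(records, names)
    if (length(unique(cols)) != 1L) stop("heterogeneous records")
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  if (!is.data.frame(records)) stop("'records' must be a data frame")
  records <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  utils::write.csv(format(records, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
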