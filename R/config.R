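#' Default pipeline configuration
#'
#' Nested list with one section per pipeline stage. The defaults reproduce
#' the published operating point: 256 x 376 px frames at 6006 fps, x3
#' interpolated upscaling, gates of 12-55 um diameter / 0.7-1 solidity /
#' 1-1.8 axial ratio / 0-20000 counts intensity range, 6 appearances per
#' cell, healthy-cohort thresholds 3.15 / 7.7 / 1.46 cells/mL and the 15%
#' ALK-rearranged sample cutoff.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    io = list(fps = 6006, pixel_pitch = 2.8),
    detection = list(background_mode = "first_frame", scale_factor = 3L,
                     binarize_k = 4, closing_radius = 5L),
    gates = list(diameter = c(12, 55), solidity = c(0.7, 1),
                 axial_ratio = c(1, 1.8), intensity_range = c(0, 20000)),
    tracking = list(max_displacement = 376 / 6 * 1.5, max_frame_gap = 1L,
                    min_appearances = 1L),
    cohort = list(presets = list(automated = 3.15, wellplate = 7.7,
                                 immunofluorescence = 1.46)),
    fish = list(fusion_distance = 6, fraction_threshold = 15),
    marker = list(nucleus_cutoff = 9, nc_cutoff = 0.5),
    synthetic = list(n_cells = 10L, appearances_per_cell = 6L,
                     diameter_dist = c(15, 30), cell_contrast = 60,
                     background_level = 1000, noise_sigma = 5,
                     frame_shape = c(256L, 376L)),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a YAML configuration file over the defaults
#'
#' Keys absent from the file keep their default values.
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

config_detection_params <- function(cfg) {
  detection_params(background_mode = cfg$detection$background_mode,
                   scale_factor = cfg$detection$scale_factor,
                   binarize_k = cfg$detection$binarize_k,
                   closing_radius = cfg$detection$closing_radius)
}

config_gate_params <- function(cfg) {
  do.call(gate_params, cfg$gates)
}
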