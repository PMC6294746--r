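#' Default run configuration
#'
#' All pipeline constants in one nested list: the detection parameters
#' (10-16 Hz wavelet band, 100 ms envelope smoothing, 4x/2x MAD
#' thresholds, 300-3000 ms durations), the channel-level power-ratio
#' settings (11-15 Hz spindle band, 8-10 and 16-18 Hz neighbours,
#' activity threshold 1.5), the 9-region grid, the 50% topographic typing
#' cutoff, the permutation count (2500) and TFCE exponents, and the
#' simulation defaults.
#'
#' @return nested named list of class `spd_config`.
#' @export
default_config <- function() {
  structure(list(
    detection = unclass(detection_params()),
    ratio = unclass(ratio_params()),
    regions = list(n_regions = 9L, radius_frac = 0.25),
    typing = list(cutoff = 0.5),
    cycles = list(min_duration_min = 30, epoch_s = 30),
    stats = list(n_perm = 2500L, tfce_e = 0.5, tfce_h = 2,
                 adjacency_factor = 1.3),
    sim = unclass(sim_config())
  ), class = "spd_config")
}

#' Read a run configuration from YAML
#'
#' Keys absent from the file keep their defaults; keys not present in the
#' default configuration are rejected, so typos fail loudly.
#'
#' @param path YAML file.
#' @return `spd_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  for (section in names(user)) {
    if (!section %in% names(base))
      stop("unknown config section: ", section)
    for (key in names(user[[section]])) {
      if (!key %in% names(base[[section]]))
        stop("unknown config key: ", section, ".", key)
      val <- user[[section]][[key]]
      if (!is.null(val)) base[[section]][[key]] <- val
    }
  }
  base
}

#' Write a run configuration to YAML
#'
#' @param cfg `spd_config` list.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(s)
    lapply(s, function(v) if (is.null(v)) NULL else v)), path)
  invisible(path)
}

#' Detection and ratio parameter objects from a configuration
#'
#' @param cfg `spd_config` list.
#' @return list with `params` ([detection_params()]) and `rp`
#'   ([ratio_params()]).
#' @export
config_params <- function(cfg) {
  d <- cfg$detection; r <- cfg$ratio
  list(params = detection_params(d$band_lo, d$band_hi, d$smooth_ms,
                                 d$k_high, d$k_low, d$min_ms, d$max_ms,
                                 d$threshold_mode),
       rp = ratio_params(unlist(r$spindle_band), unlist(r$lower_neighbor),
                         unlist(r$upper_neighbor), r$active_threshold))
}
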