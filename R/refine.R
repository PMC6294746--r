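#' Channel-level power-ratio parameters
#'
#' The spindle band used for per-channel power, peak frequency and the
#' power ratio, with its flanking neighbour bands. The ratio (spindle band
#' over the mean of the neighbours) guards against broadband power bursts
#' such as short arousals: a channel expresses a spindle only if the
#' spindle band stands out from its surroundings.
#'
#' @param spindle_band length-2 Hz; band for power/ratio/peak frequency.
#' @param lower_neighbor,upper_neighbor length-2 Hz flanking bands.
#' @param active_threshold ratio above which a channel counts as active.
#' @return list of class `spd_ratio_params`.
#' @export
ratio_params <- function(spindle_band = c(11, 15),
                         lower_neighbor = c(8, 10),
                         upper_neighbor = c(16, 18),
                         active_threshold = 1.5) {
  stopifnot(lower_neighbor[2] <= spindle_band[1],
            spindle_band[2] <= upper_neighbor[1],
            diff(spindle_band) > 0, diff(lower_neighbor) > 0,
            diff(upper_neighbor) > 0, active_threshold >= 0)
  structure(list(spindle_band = spindle_band, lower_neighbor = lower_neighbor,
                 upper_neighbor = upper_neighbor,
                 active_threshold = active_threshold),
            class = "spd_ratio_params")
}

#' Per-channel spectra over one spindle event
#'
#' Welch PSD of every channel over the event interval; returns the mean
#' spindle-band power, the power ratio against the flanking bands, and the
#' peak frequency inside the spindle band.
#'
#' @param data channels x samples matrix (or a [recording()]).
#' @param fs sampling rate, Hz (ignored when `data` is a recording).
#' @param start_sample,end_sample 0-based half-open event interval.
#' @param rp [ratio_params()].
#' @return data.frame with one row per channel: `band_power`, `ratio`,
#'   `peak_freq`.
#' @export
event_channel_spectra <- function(data, fs = NULL, start_sample, end_sample,
                                  rp = ratio_params()) {
  if (inherits(data, "spd_recording")) { fs <- data$fs; data <- data$data }
  seg <- data[, (start_sample + 1L):end_sample, drop = FALSE]
  w <- welch_psd(seg, fs)
  bp <- band_power(w, rp$spindle_band)
  neigh <- (band_power(w, rp$lower_neighbor) +
              band_power(w, rp$upper_neighbor)) / 2
  data.frame(band_power = bp,
             ratio = ifelse(neigh > 0, bp / neigh, Inf),
             peak_freq = peak_frequency(w, rp$spindle_band),
             row.names = rownames(data))
}

#' Channel activity from power ratios
#'
#' A channel expresses the spindle when its power ratio is strictly above
#' the threshold (the spindle band is more than 50% stronger than its
#' neighbours at the default 1.5).
#'
#' @param ratio per-channel power ratios.
#' @param threshold activity cutoff.
#' @return logical vector.
#' @export
channel_activity <- function(ratio, threshold = 1.5) ratio > threshold

#' Classify a spindle as frontal, posterior or co-occurring
#'
#' Posterior if the posterior-region band power is at least 50% larger than
#' the frontal one (at the default cutoff), frontal in the mirrored case,
#' co-occurring otherwise.
#'
#' @param frontal_power,posterior_power region band powers (microvolts^2).
#' @param cutoff required relative dominance (0.5 = 50% larger).
#' @return one of `"frontal"`, `"posterior"`, `"co_occurring"`.
#' @export
classify_spindle_type <- function(frontal_power, posterior_power, cutoff = 0.5) {
  stopifnot(frontal_power >= 0, posterior_power >= 0)
  if (frontal_power == 0 && posterior_power == 0) return("co_occurring")
  if (posterior_power >= (1 + cutoff) * frontal_power) return("posterior")
  if (frontal_power >= (1 + cutoff) * posterior_power) return("frontal")
  "co_occurring"
}

#' Largest canonical peak-to-peak amplitude of an event
#'
#' Maximum over the member regions of the peak-to-peak excursion of the
#' band-filtered canonical trace within the event interval.
#'
#' @param filtered 9 x samples matrix of band-filtered canonical traces.
#' @param start_sample,end_sample 0-based half-open interval.
#' @param member_regions integer region ids contributing to the event.
#' @return amplitude in microvolts.
#' @export
canonical_amplitude <- function(filtered, start_sample, end_sample,
                                member_regions = seq_len(nrow(filtered))) {
  seg <- filtered[member_regions, (start_sample + 1L):end_sample, drop = FALSE]
  max(apply(seg, 1L, function(x) max(x) - min(x)))
}

#' Midline peak frequencies of an event
#'
#' Peak frequency of the frontal-mid, central-mid and posterior-mid
#' canonical traces over the event, each estimated independently — spindle
#' frequency is well known to decrease from posterior to frontal sites.
#'
#' @param cs canonical series from [compute_canonical_series()].
#' @param start_sample,end_sample 0-based half-open interval.
#' @param rp [ratio_params()]; peaks are searched inside its spindle band.
#' @return named numeric vector `c(frontal = , central = , posterior = )`, Hz.
#' @export
midline_peak_frequencies <- function(cs, start_sample, end_sample,
                                     rp = ratio_params()) {
  stopifnot(inherits(cs, "spd_canonical"))
  mid <- cs$regions$midline_ids
  seg <- cs$data[mid, (start_sample + 1L):end_sample, drop = FALSE]
  w <- welch_psd(seg, cs$fs)
  pf <- peak_frequency(w, rp$spindle_band)
  names(pf) <- c("frontal", "central", "posterior")
  pf
}

#' Assemble a finished spindle event record
#'
#' Combines the merged detection interval with the channel-level
#' refinement: activity, globality (percent of channels expressing the
#' spindle), topographic type, amplitude, midline peak frequencies, and the
#' summary power/ratio taken as the maximum over active channels. Events
#' with no active channel are retained but flagged, with the summary taken
#' over all channels as a fallback.
#'
#' @param merged one row of [merge_region_events()] output.
#' @param spectra per-channel data.frame from [event_channel_spectra()].
#' @param active logical per channel from [channel_activity()].
#' @param type spindle type from [classify_spindle_type()].
#' @param amplitude_uV canonical amplitude from [canonical_amplitude()].
#' @param peak_freqs midline frequencies from [midline_peak_frequencies()].
#' @param fs sampling rate, Hz.
#' @return one-row data.frame (the `SpindleTable` row format).
#' @export
finalize_event <- function(merged, spectra, active, type, amplitude_uV,
                           peak_freqs, fs) {
  n_ch <- nrow(spectra)
  n_active <- sum(active)
  pool <- if (n_active > 0L) which(active) else seq_len(n_ch)
  data.frame(start_sample = merged$start_sample,
             end_sample = merged$end_sample,
             duration_ms = (merged$end_sample - merged$start_sample) / fs * 1000,
             amplitude_uV = amplitude_uV,
             globality_pct = 100 * n_active / n_ch,
             n_active = n_active,
             flagged = n_active == 0L,
             type = type,
             summary_power = max(spectra$band_power[pool]),
             summary_ratio = max(spectra$ratio[pool]),
             freq_frontal = peak_freqs[["frontal"]],
             freq_central = peak_freqs[["central"]],
             freq_posterior = peak_freqs[["posterior"]],
             n_regions = merged$n_regions)
}
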