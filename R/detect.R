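#' Detection parameters
#'
#' Bundles the stage-2 detection constants: the wavelet pass band, the
#' envelope smoothing window, the high/low MAD-multiple thresholds, and the
#' event duration bounds.
#'
#' @param band_lo,band_hi wavelet pass band, Hz (-3 dB edges).
#' @param smooth_ms power-envelope sliding-window length, ms.
#' @param k_high,k_low high/low thresholds as multiples of the median
#'   absolute deviation of the envelope.
#' @param min_ms,max_ms admissible event duration, ms.
#' @param threshold_mode scale on which the MAD thresholds are taken.
#'   `"mad_amplitude"` (default) computes `k * MAD` on the band-filtered
#'   signal amplitude and squares it into power-envelope units — the scale
#'   on which amplitude-threshold spindle detectors operate.
#'   `"mad_only"` thresholds the power envelope directly at `k * MAD`;
#'   `"median_plus_mad"` at `median + k * MAD` of the envelope. The
#'   envelope modes are far more permissive: for a squared signal the MAD
#'   sits close to the median, so even the high threshold admits frequent
#'   background excursions.
#' @return list of class `spd_detection_params`.
#' @export
detection_params <- function(band_lo = 10, band_hi = 16, smooth_ms = 100,
                             k_high = 4, k_low = 2, min_ms = 300,
                             max_ms = 3000,
                             threshold_mode = c("mad_amplitude", "mad_only",
                                                "median_plus_mad")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(band_lo < band_hi, k_low < k_high, min_ms < max_ms,
            smooth_ms > 0)
  structure(list(band_lo = band_lo, band_hi = band_hi, smooth_ms = smooth_ms,
                 k_high = k_high, k_low = k_low, min_ms = min_ms,
                 max_ms = max_ms, threshold_mode = threshold_mode),
            class = "spd_detection_params")
}

.bspline3 <- function(u) {
  # cubic B-spline on support [-2, 2]
  au <- abs(u)
  ifelse(au < 1, 2 / 3 - au^2 + au^3 / 2,
         ifelse(au < 2, (2 - au)^3 / 6, 0))
}

.bspline_kernel <- function(fs, band_lo, band_hi) {
  fc <- (band_lo + band_hi) / 2
  hb <- (band_hi - band_lo) / 2
  # the kernel's magnitude response is sinc(f T / 4)^4 (cubic B-spline =
  # fourfold box convolution over support T); pick T so the -3 dB point of
  # the window sits at the half-bandwidth
  x0 <- stats::uniroot(function(x) (sin(pi * x) / (pi * x))^4 - 1 / sqrt(2),
                       c(1e-6, 0.5))$root
  T_s <- 4 * x0 / hb
  half <- floor(T_s / 2 * fs)
  t <- seq.int(-half, half) / fs
  w <- .bspline3(4 * t / T_s)
  h <- w * cos(2 * pi * fc * t)
  gain <- abs(sum(h * exp(-2i * pi * fc * t)))
  h / gain
}

.conv_same <- function(x, h) {
  # centered FFT convolution, |h| odd and symmetric -> zero phase
  n <- length(x); m <- length(h)
  full <- stats::convolve(x, rev(h), type = "open")
  full[((m - 1L) %/% 2L + 1L):((m - 1L) %/% 2L + n)]
}

#' Zero-phase b-spline wavelet band-pass filter
#'
#' Convolves the signal with a cubic-B-spline-windowed carrier at the band
#' center. The window support is chosen so the -3 dB points of the
#' magnitude response fall on `band_lo` and `band_hi`; the symmetric kernel
#' makes the filter zero-phase, preserving event timing.
#'
#' @param x numeric vector (one canonical trace).
#' @param fs sampling rate, Hz.
#' @param band_lo,band_hi pass band edges, Hz.
#' @return filtered signal, same length as `x`.
#' @export
bspline_wavelet_filter <- function(x, fs, band_lo = 10, band_hi = 16) {
  if (fs <= 2 * band_hi) stop("pass band reaches the Nyquist frequency")
  h <- .bspline_kernel(fs, band_lo, band_hi)
  .conv_same(as.numeric(x), h)
}

#' Power envelope of a filtered signal
#'
#' Squares the signal and smooths it with a centered moving average of
#' `smooth_ms` milliseconds. The average is truncated (not zero-padded) at
#' the series edges, so the envelope never dips spuriously at onset.
#'
#' @param xf band-filtered signal (microvolts).
#' @param fs sampling rate, Hz.
#' @param smooth_ms window length, ms.
#' @return non-negative envelope (microvolts squared), same length.
#' @export
power_envelope <- function(xf, fs, smooth_ms = 100) {
  stopifnot(smooth_ms > 0)
  n <- length(xf)
  w <- max(1L, round(smooth_ms * fs / 1000))
  half_l <- (w - 1L) %/% 2L
  half_r <- w %/% 2L
  cs <- cumsum(c(0, xf^2))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' MAD-based detection thresholds
#'
#' Derives the high and low power-envelope thresholds from the median
#' absolute deviation (plain MAD, no normal-consistency constant) over the
#' valid samples. In `"mad_amplitude"` mode the MAD is taken on the
#' band-filtered signal amplitude and `(k * MAD)^2` is returned in
#' envelope (power) units; `"mad_only"` returns `k * MAD` of the envelope
#' itself; `"median_plus_mad"` returns `median + k * MAD` of the envelope.
#'
#' @param env power envelope.
#' @param valid_mask logical; which samples enter the statistics (e.g. the
#'   artifact-free samples of one NREM cycle).
#' @param k_high,k_low MAD multiples.
#' @param mode threshold scale; see [detection_params()].
#' @param filtered the band-filtered signal (microvolts), required for
#'   `"mad_amplitude"`.
#' @return named numeric vector `c(high = , low = )`, envelope units.
#' @export
mad_thresholds <- function(env, valid_mask = NULL, k_high = 4, k_low = 2,
                           mode = c("mad_amplitude", "mad_only",
                                    "median_plus_mad"),
                           filtered = NULL) {
  mode <- match.arg(mode)
  stopifnot(k_low < k_high)
  if (mode == "mad_amplitude") {
    if (is.null(filtered))
      stop("mad_amplitude thresholds need the band-filtered signal")
    if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(filtered))
    v <- filtered[valid_mask]
    if (!length(v)) stop("no valid samples for threshold estimation")
    mad_v <- stats::median(abs(v - stats::median(v)))
    if (mad_v <= 0) stop("degenerate signal: MAD is zero")
    return(c(high = (k_high * mad_v)^2, low = (k_low * mad_v)^2))
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(env))
  v <- env[valid_mask]
  if (!length(v)) stop("no valid samples for threshold estimation")
  med <- stats::median(v)
  mad_v <- stats::median(abs(v - med))
  if (mad_v <= 0) stop("degenerate envelope: MAD is zero")
  if (mode == "mad_only") c(high = k_high * mad_v, low = k_low * mad_v)
  else c(high = med + k_high * mad_v, low = med + k_low * mad_v)
}

#' Extract threshold-crossing events from an envelope
#'
#' Every maximal run of samples with `env >= high` seeds a candidate event;
#' its boundaries are widened to the surrounding run of `env >= low`
#' samples (the low-threshold crossing times). Candidates sharing one
#' low-threshold span collapse into a single event. Events with a duration
#' outside `[min_ms, max_ms]`, or touching an invalid (artifact) sample,
#' are discarded.
#'
#' @param env power envelope.
#' @param fs sampling rate, Hz.
#' @param high,low thresholds from [mad_thresholds()]; `high > low > 0`.
#' @param min_ms,max_ms admissible duration, ms.
#' @param valid_mask logical; events overlapping a `FALSE` sample by one or
#'   more samples are dropped.
#' @param offset sample offset added to the reported indices (for
#'   cycle-relative envelopes).
#' @return data.frame with 0-based half-open `start_sample`, `end_sample`,
#'   plus `peak_envelope`, `peak_sample`, `duration_ms`.
#' @export
detect_region_events <- function(env, fs, high, low, min_ms = 300,
                                 max_ms = 3000, valid_mask = NULL,
                                 offset = 0L) {
  stopifnot(high > low, low > 0)
  n <- length(env)
  empty <- data.frame(start_sample = numeric(), end_sample = numeric(),
                      peak_envelope = numeric(), peak_sample = numeric(),
                      duration_ms = numeric())
  above_low <- env >= low
  if (!any(above_low)) return(empty)
  r <- rle(above_low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_run <- r$values
  starts <- starts[keep_run]; ends <- ends[keep_run]
  rows <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- env[i0:i1]
    if (!any(seg >= high)) return(NULL)
    dur <- (i1 - i0 + 1L) / fs * 1000
    if (dur < min_ms || dur > max_ms) return(NULL)
    if (!is.null(valid_mask) && any(!valid_mask[i0:i1])) return(NULL)
    pk <- which.max(seg)
    data.frame(start_sample = i0 - 1L + offset, end_sample = i1 + offset,
               peak_envelope = seg[pk], peak_sample = i0 - 1L + pk - 1L + offset,
               duration_ms = dur)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Merge temporally overlapping events across canonical regions
#'
#' Events from distinct regions whose intervals overlap are one underlying
#' spindle: the merged event runs from the earliest member start to the
#' latest member end (transitively), its peak envelope is the maximum over
#' members, and the contributing region ids are retained.
#'
#' @param events_by_region named list of per-region event data.frames from
#'   [detect_region_events()]; names are region ids.
#' @return data.frame with `start_sample`, `end_sample`, `peak_envelope`,
#'   `peak_sample`, `n_regions` and a list-column `regions`.
#' @export
merge_region_events <- function(events_by_region) {
  ids <- names(events_by_region)
  if (is.null(ids)) ids <- as.character(seq_along(events_by_region))
  all_ev <- do.call(rbind, lapply(seq_along(events_by_region), function(k) {
    ev <- events_by_region[[k]]
    if (is.null(ev) || !nrow(ev)) return(NULL)
    ev$region <- ids[k]
    ev
  }))
  out_empty <- data.frame(start_sample = numeric(), end_sample = numeric(),
                          peak_envelope = numeric(), peak_sample = numeric(),
                          n_regions = integer())
  if (is.null(all_ev) || !nrow(all_ev)) { out_empty$regions <- list(); return(out_empty) }
  all_ev <- all_ev[order(all_ev$start_sample, all_ev$end_sample), , drop = FALSE]
  grp <- integer(nrow(all_ev))
  g <- 1L; grp[1L] <- g; cur_end <- all_ev$end_sample[1L]
  for (i in seq_len(nrow(all_ev))[-1L]) {
    if (all_ev$start_sample[i] < cur_end) {    # half-open: touching != overlap
      grp[i] <- g
      cur_end <- max(cur_end, all_ev$end_sample[i])
    } else {
      g <- g + 1L; grp[i] <- g; cur_end <- all_ev$end_sample[i]
    }
  }
  merged <- lapply(split(seq_len(nrow(all_ev)), grp), function(ii) {
    e <- all_ev[ii, , drop = FALSE]
    pk <- which.max(e$peak_envelope)
    data.frame(start_sample = min(e$start_sample),
               end_sample = max(e$end_sample),
               peak_envelope = e$peak_envelope[pk],
               peak_sample = e$peak_sample[pk],
               n_regions = length(unique(e$region)))
  })
  out <- do.call(rbind, merged)
  out$regions <- lapply(split(seq_len(nrow(all_ev)), grp),
                        function(ii) unique(all_ev$region[ii]))
  rownames(out) <- NULL
  out
}
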