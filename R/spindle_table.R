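#' Run the full spindle detection pipeline on one recording
#'
#' Stages: spherical-spline interpolation of bad channels, average
#' referencing (in that order, so artifactual channels cannot bias the
#' reference), canonical region series, b-spline wavelet filtering, power
#' envelopes, MAD thresholds per NREM cycle (or one global threshold),
#' event extraction with the duration rule per region, cross-region
#' merging, and channel-level refinement of every merged event.
#'
#' @param r a [recording()].
#' @param h a [hypnogram()].
#' @param bad_channels labels of channels to interpolate before detection.
#' @param params [detection_params()].
#' @param rp [ratio_params()].
#' @param min_cycle_min minimum NREM-cycle duration, minutes.
#' @param thresholds `"per-cycle"` (separate MAD thresholds per NREM cycle)
#'   or `"global"` (one threshold over all cycles).
#' @param type_cutoff relative dominance for frontal/posterior typing.
#' @param radius_frac region assignment radius (see [build_grid_regions()]).
#' @return object of class `spd_spindles`: list with `events` (one row per
#'   unique spindle), `channel` (per-event x channel `active`, `power`,
#'   `ratio` matrices), `minutes` (artifact-free N2/N3 minutes per cycle),
#'   `cycles`, `regions`, `labels`, `report`.
#' @export
detect_spindles <- function(r, h, bad_channels = character(),
                            params = detection_params(),
                            rp = ratio_params(), min_cycle_min = 30,
                            thresholds = c("per-cycle", "global"),
                            type_cutoff = 0.5, radius_frac = 0.25) {
  thresholds <- match.arg(thresholds)
  stopifnot(inherits(r, "spd_recording"), inherits(h, "spd_hypnogram"))
  r <- interpolate_bad_channels(r, bad_channels)   # before average reference
  r <- average_reference(r)
  rs <- build_grid_regions(r$positions, radius_frac = radius_frac,
                           labels = r$labels)
  cs <- compute_canonical_series(r, rs)
  filt <- t(apply(cs$data, 1L, bspline_wavelet_filter, fs = r$fs,
                  band_lo = params$band_lo, band_hi = params$band_hi))
  env <- t(apply(filt, 1L, power_envelope, fs = r$fs,
                 smooth_ms = params$smooth_ms))
  cycles <- find_nrem_cycles(h, r$fs, min_duration_min = min_cycle_min)
  n <- ncol(r$data)
  in_cycle <- rep(FALSE, n)
  for (k in seq_len(nrow(cycles))) {
    i0 <- cycles$start_sample[k] + 1L
    i1 <- min(cycles$end_sample[k], n)
    if (i1 >= i0) in_cycle[i0:i1] <- TRUE
  }
  valid <- in_cycle & !r$artifact_mask
  thr_list <- list()
  merged_all <- list()
  global_thr <- NULL
  if (thresholds == "global" && nrow(cycles)) {
    global_thr <- lapply(1:9, function(reg)
      mad_thresholds(env[reg, ], valid, params$k_high, params$k_low,
                     params$threshold_mode, filtered = filt[reg, ]))
  }
  for (k in seq_len(nrow(cycles))) {
    i0 <- cycles$start_sample[k] + 1L
    i1 <- min(cycles$end_sample[k], n)
    vmask <- !r$artifact_mask[i0:i1]
    per_region <- list()
    thr_cycle <- matrix(NA_real_, 9L, 2L,
                        dimnames = list(rs$region_names, c("high", "low")))
    for (reg in 1:9) {
      thr <- if (is.null(global_thr))
        mad_thresholds(env[reg, i0:i1], vmask, params$k_high, params$k_low,
                       params$threshold_mode, filtered = filt[reg, i0:i1])
      else global_thr[[reg]]
      thr_cycle[reg, ] <- thr
      per_region[[as.character(reg)]] <-
        detect_region_events(env[reg, i0:i1], r$fs, thr["high"], thr["low"],
                             params$min_ms, params$max_ms,
                             valid_mask = vmask, offset = i0 - 1L)
    }
    thr_list[[k]] <- thr_cycle
    mg <- merge_region_events(per_region)
    if (nrow(mg)) mg$cycle_index <- cycles$index[k]
    merged_all[[k]] <- mg
  }
  merged_all <- merged_all[vapply(merged_all, nrow, 0L) > 0L]
  merged <- if (length(merged_all)) do.call(rbind, merged_all) else NULL
  labels <- r$labels
  n_ch <- length(labels)
  # artifact-free N2/N3 minutes per cycle
  ep <- pmin(length(h$stages),
             floor((seq_len(n) - 1L) / (h$epoch_s * r$fs)) + 1L)
  stage_per_sample <- h$stages[ep]
  mins <- vapply(seq_len(nrow(cycles)), function(k) {
    i0 <- cycles$start_sample[k] + 1L
    i1 <- min(cycles$end_sample[k], n)
    idx <- i0:i1
    sum(stage_per_sample[idx] %in% c("N2", "N3") & !r$artifact_mask[idx]) / r$fs / 60
  }, 0)
  minutes <- data.frame(cycle_index = cycles$index, minutes = mins)
  if (is.null(merged) || !nrow(merged)) {
    events <- data.frame()
    chan <- list(active = matrix(FALSE, 0L, n_ch),
                 power = matrix(0, 0L, n_ch), ratio = matrix(0, 0L, n_ch))
  } else {
    rows <- vector("list", nrow(merged))
    act <- matrix(FALSE, nrow(merged), n_ch, dimnames = list(NULL, labels))
    pow <- matrix(NA_real_, nrow(merged), n_ch, dimnames = list(NULL, labels))
    rat <- matrix(NA_real_, nrow(merged), n_ch, dimnames = list(NULL, labels))
    # canonical band power over the event decides the topographic type
    for (i in seq_len(nrow(merged))) {
      s0 <- merged$start_sample[i]; s1 <- merged$end_sample[i]
      sp <- event_channel_spectra(r$data, r$fs, s0, s1, rp)
      a <- channel_activity(sp$ratio, rp$active_threshold)
      wc <- welch_psd(cs$data[, (s0 + 1L):s1, drop = FALSE], r$fs)
      reg_bp <- band_power(wc, rp$spindle_band)
      type <- classify_spindle_type(max(reg_bp[rs$frontal_ids]),
                                    max(reg_bp[rs$posterior_ids]),
                                    cutoff = type_cutoff)
      amp <- canonical_amplitude(filt, s0, s1,
                                 as.integer(unlist(merged$regions[i])))
      pf <- midline_peak_frequencies(cs, s0, s1, rp)
      row <- finalize_event(merged[i, ], sp, a, type, amp, pf, r$fs)
      row$cycle_index <- merged$cycle_index[i]
      rows[[i]] <- row
      act[i, ] <- a; pow[i, ] <- sp$band_power; rat[i, ] <- sp$ratio
    }
    events <- do.call(rbind, rows)
    events$id <- seq_len(nrow(events))
    rownames(events) <- NULL
    chan <- list(active = act, power = pow, ratio = rat)
  }
  structure(list(events = events, channel = chan, minutes = minutes,
                 cycles = cycles, regions = rs, labels = labels,
                 report = list(params = unclass(params),
                               ratio_params = unclass(rp),
                               thresholds = thr_list,
                               threshold_mode = thresholds,
                               n_events = nrow(events),
                               n_channels = n_ch,
                               interpolated = bad_channels)),
            class = "spd_spindles")
}

#' @exportS3Method base::print
print.spd_spindles <- function(x, ...) {
  cat(sprintf("<spd_spindles> %d spindles in %d cycle(s), %.1f artifact-free N2/N3 min\n",
              nrow(x$events), nrow(x$cycles), sum(x$minutes$minutes)))
  if (nrow(x$events))
    cat(sprintf("  incidence %.1f/min; types: %s\n",
                incidence(x),
                paste(names(table(x$events$type)), table(x$events$type),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Spindle incidence per minute of artifact-free N2/N3
#'
#' @param x an `spd_spindles` result (or a data.frame of events when
#'   `minutes` is given explicitly).
#' @param scope `"total"` counts each unique (merged) spindle once;
#'   `"per_channel"` counts, per channel, the events active at it.
#' @param minutes override for the artifact-free N2/N3 minutes.
#' @return scalar (total) or named per-channel vector, spindles/minute.
#' @export
incidence <- function(x, scope = c("total", "per_channel"), minutes = NULL) {
  scope <- match.arg(scope)
  if (inherits(x, "spd_spindles")) {
    if (is.null(minutes)) minutes <- sum(x$minutes$minutes)
    n_ev <- nrow(x$events)
    act <- x$channel$active
  } else {
    if (is.null(minutes)) stop("minutes must be supplied for a plain table")
    n_ev <- nrow(x); act <- NULL
  }
  if (is.null(minutes) || !is.finite(minutes) || minutes <= 0)
    stop("artifact-free minutes must be positive")
  if (scope == "total") return(n_ev / minutes)
  if (is.null(act)) stop("per-channel incidence needs the channel activity matrix")
  colSums(act) / minutes
}

#' Per-participant means and paired test of a spindle parameter
#'
#' Averages the parameter per participant within each level of a two-level
#' condition and runs a dependent t-test across participants — the
#' traditional participant-mean analysis the individual-spindle mixed
#' model is compared against.
#'
#' @param tbl data.frame of individual spindles with a `participant` column.
#' @param parameter column to summarise.
#' @param by two-level condition column.
#' @return list with `means` (participant x level data.frame), `t`, `df`,
#'   `p`, `delta` (mean level2 - level1).
#' @export
participant_summary <- function(tbl, parameter, by) {
  stopifnot(all(c("participant", parameter, by) %in% names(tbl)))
  lev <- unique(as.character(tbl[[by]]))
  if (length(lev) != 2L) stop("'", by, "' must have exactly 2 levels, got ",
                              length(lev))
  lev <- sort(lev)
  ag <- stats::aggregate(tbl[[parameter]],
                         by = list(participant = tbl$participant,
                                   cond = as.character(tbl[[by]])),
                         FUN = mean)
  wide <- stats::reshape(ag, idvar = "participant", timevar = "cond",
                         direction = "wide")
  names(wide) <- sub("^x\\.", "", names(wide))
  complete <- stats::complete.cases(wide[, lev])
  if (any(!complete))
    warning(sum(!complete), " participant(s) missing a condition cell; excluded")
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2L) stop("paired test needs at least 2 complete participants")
  d <- wide[[lev[2L]]] - wide[[lev[1L]]]
  n <- length(d)
  if (stats::sd(d) == 0) {
    # degenerate: all differences identical
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- 2 * stats::pt(abs(t_stat), n - 1L, lower.tail = FALSE)
  }
  list(means = wide, t = t_stat, df = n - 1L, p = p, delta = mean(d))
}

#' Compare power spectra with and without the detected spindles
#'
#' The detector's internal sanity check: excising the detected events from
#' the artifact-free N2/N3 data should deflate the spindle bump in the
#' 10-16 Hz range while leaving the control bands essentially untouched.
#'
#' @param r a [recording()] (average-referenced).
#' @param spindles an `spd_spindles` result, or a data.frame with
#'   `start_sample`/`end_sample` columns.
#' @param channels channels to average over (default: all).
#' @param band spindle band, Hz.
#' @param control_bands list of control bands, Hz.
#' @param window_s Welch window for the long-data PSDs, seconds.
#' @return list with `freq`, `psd_with`, `psd_without` (channel-mean PSDs),
#'   `band_drop` (fractional power drop in the spindle band) and
#'   `control_drop` (per control band).
#' @export
spectra_with_without <- function(r, spindles, channels = NULL,
                                 band = c(10, 16),
                                 control_bands = list(c(4, 8), c(20, 30)),
                                 window_s = 2) {
  stopifnot(inherits(r, "spd_recording"))
  ev <- if (inherits(spindles, "spd_spindles")) spindles$events else spindles
  keep_ch <- if (is.null(channels)) seq_len(nrow(r$data))
             else match(channels, r$labels)
  n <- ncol(r$data)
  base_keep <- !r$artifact_mask
  excise <- base_keep
  for (i in seq_len(nrow(ev))) {
    a <- ev$start_sample[i] + 1L; b <- min(ev$end_sample[i], n)
    if (b >= a) excise[a:b] <- FALSE
  }
  if (!any(excise)) stop("event intervals cover every artifact-free sample")
  dat <- r$data[keep_ch, , drop = FALSE]
  w_with <- welch_psd(dat[, base_keep, drop = FALSE], r$fs, window_s = window_s)
  w_wo <- welch_psd(dat[, excise, drop = FALSE], r$fs, window_s = window_s)
  mean_psd <- function(w) colMeans(w$psd)
  pw <- mean_psd(w_with); pwo <- mean_psd(w_wo)
  drop_in <- function(b) {
    idx <- which(w_with$freq >= b[1] & w_with$freq <= b[2])
    (mean(pw[idx]) - mean(pwo[idx])) / mean(pw[idx])
  }
  list(freq = w_with$freq, psd_with = pw, psd_without = pwo,
       band_drop = drop_in(band),
       control_drop = vapply(control_bands, drop_in, 0))
}

#' Write spindle detection results to CSV/JSON files
#'
#' @param x an `spd_spindles` result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written: the tidy event table, the wide
#'   per-channel activity/power/ratio tables, and a JSON run report.
#' @export
write_spindle_table <- function(x, dir, prefix = "spindles") {
  stopifnot(inherits(x, "spd_spindles"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_ev <- file.path(dir, paste0(prefix, ".csv"))
  utils::write.csv(x$events, p_ev, row.names = FALSE)
  paths <- p_ev
  for (what in c("active", "power", "ratio")) {
    p <- file.path(dir, paste0(prefix, "_channel_", what, ".csv"))
    m <- as.data.frame(x$channel[[what]])
    if (nrow(x$events)) m <- cbind(id = x$events$id, m)
    utils::write.csv(m, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p_rep <- file.path(dir, paste0(prefix, "_report.json"))
  rep <- x$report
  rep$thresholds <- lapply(rep$thresholds, function(m)
    as.data.frame(cbind(region = rownames(m), as.data.frame(m))))
  jsonlite::write_json(rep, p_rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, p_rep))
}
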