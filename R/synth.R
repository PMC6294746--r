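#' Synthetic high-density montage on the upper hemisphere
#'
#' Deterministic golden-angle spiral of sensors over the scalp cap,
#' standing in for a geodesic net when real sensor coordinates are not
#' needed.
#'
#' @param n_channels number of sensors.
#' @return list with `labels` and `positions` (n x 3 unit-sphere xyz;
#'   x = right, y = anterior, z = up).
#' @export
synthetic_montage <- function(n_channels = 64) {
  i <- seq_len(n_channels)
  z <- 0.995 - (i - 0.5) / n_channels * (0.995 - 0.05)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  rho <- sqrt(1 - z^2)
  pos <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  rownames(pos) <- paste0("E", i)
  list(labels = paste0("E", i), positions = pos)
}

#' Simulation configuration for synthetic spindle recordings
#'
#' Defaults emulate the study conditions of overnight hd-EEG: ~500 Hz
#' sampling on 64+ channels, a 1/f background, spindles at ~18 events/min
#' lasting 0.3-3 s with waxing-waning envelopes, slower frontal
#' (~11.5 Hz) and faster posterior (~13.5 Hz) spindles, and a local
#' Gaussian topographic spread.
#'
#' @param n_channels sensor count.
#' @param fs sampling rate, Hz.
#' @param duration_min recording length, minutes.
#' @param spindle_rate events per minute (Poisson rate).
#' @param duration_range_s min/max event duration, seconds (uniform).
#' @param freq_frontal_hz,freq_posterior_hz mean and SD of the event
#'   frequency per type, Hz.
#' @param amplitude_uV mean and SD of the event peak amplitude, microvolts;
#'   ignored when `target_snr` is set.
#' @param spread_sigma topographic Gaussian width in azimuthal-projection
#'   units (radians of arc; the projected head radius is ~pi/2).
#' @param p_posterior fraction of posterior-type events.
#' @param noise_alpha 1/f^alpha background exponent.
#' @param noise_rms background RMS per channel, microvolts.
#' @param target_snr if set, event amplitudes are scaled so the event RMS
#'   over the 10-16 Hz band at the center channel is `target_snr` times
#'   the background band RMS.
#' @param seed RNG seed.
#' @return list of class `spd_sim_config`.
#' @export
sim_config <- function(n_channels = 64, fs = 500, duration_min = 20,
                       spindle_rate = 18, duration_range_s = c(0.5, 2.0),
                       freq_frontal_hz = c(11.5, 0.5),
                       freq_posterior_hz = c(13.5, 0.5),
                       amplitude_uV = c(15, 5), spread_sigma = 0.45,
                       p_posterior = 0.5, noise_alpha = 1, noise_rms = 20,
                       target_snr = NULL, seed = NULL) {
  stopifnot(n_channels >= 9, fs > 0, duration_min > 0, spindle_rate > 0,
            diff(duration_range_s) >= 0, duration_range_s[1] > 0,
            p_posterior >= 0, p_posterior <= 1, noise_rms > 0)
  structure(list(n_channels = n_channels, fs = fs, duration_min = duration_min,
                 spindle_rate = spindle_rate,
                 duration_range_s = duration_range_s,
                 freq_frontal_hz = freq_frontal_hz,
                 freq_posterior_hz = freq_posterior_hz,
                 amplitude_uV = amplitude_uV, spread_sigma = spread_sigma,
                 p_posterior = p_posterior, noise_alpha = noise_alpha,
                 noise_rms = noise_rms, target_snr = target_snr, seed = seed),
            class = "spd_sim_config")
}

.one_over_f <- function(n, fs, alpha, f0 = 0.5) {
  # spectral-shaping weights for an n-point real FFT grid
  f <- seq.int(0L, n - 1L) * fs / n
  f <- pmin(f, fs - f)            # two-sided grid folded
  w <- pmax(f, f0)^(-alpha / 2)
  w[1L] <- 0                      # no DC
  w
}

#' Generate a synthetic hd-EEG recording with ground-truth spindles
#'
#' Background: independent per-channel 1/f^alpha noise (white noise shaped
#' in the frequency domain) at the configured RMS. Events: a Poisson
#' process at the configured rate; each event is a sinusoid at its drawn
#' frequency under a Hann (waxing-waning) envelope, weighted across
#' channels by a Gaussian centred on the frontal-midline or
#' posterior-midline sensor according to its type. Overlap between events
#' sharing a center channel is rejected (resampled); overlap across
#' centers is allowed, which is exactly what cross-region merging must
#' absorb.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (a [recording()]) and `truth` (data.frame
#'   of injected events: 0-based half-open `start_sample`/`end_sample`,
#'   `center_channel`, `type`, `freq_hz`, `amplitude_uV`).
#' @export
generate_recording <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "spd_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mont <- synthetic_montage(cfg$n_channels)
  n <- round(cfg$duration_min * 60 * cfg$fs)
  w <- .one_over_f(n, cfg$fs, cfg$noise_alpha)
  dat <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * w, inverse = TRUE)) / n
    dat[ch, ] <- x * (cfg$noise_rms / stats::sd(x))
  }
  # fraction of the noise RMS that lives in the 10-16 Hz detection band,
  # from the shaping weights (deterministic)
  f <- seq.int(0L, n - 1L) * cfg$fs / n
  f <- pmin(f, cfg$fs - f)
  in_band <- f >= 10 & f <= 16
  band_frac <- sqrt(sum(w[in_band]^2) / sum(w^2))
  band_rms <- cfg$noise_rms * band_frac
  pr <- project_scalp(mont$positions)
  R <- max(sqrt(rowSums(pr^2)))
  center_for <- function(target) unname(which.min((pr[, 1] - target[1])^2 +
                                                    (pr[, 2] - target[2])^2))
  centers <- c(frontal = center_for(c(0, 0.5 * R)),
               posterior = center_for(c(0, -0.5 * R)))
  n_ev <- stats::rpois(1L, cfg$spindle_rate * cfg$duration_min)
  occupied <- list(frontal = NULL, posterior = NULL)
  truth <- vector("list", n_ev)
  max_dur_samp <- cfg$duration_range_s[2] * cfg$fs
  if (max_dur_samp >= n) stop("recording shorter than one event")
  for (e in seq_len(n_ev)) {
    type <- if (stats::runif(1) < cfg$p_posterior) "posterior" else "frontal"
    dur_s <- stats::runif(1, cfg$duration_range_s[1], cfg$duration_range_s[2])
    L <- round(dur_s * cfg$fs)
    fr_par <- if (type == "frontal") cfg$freq_frontal_hz else cfg$freq_posterior_hz
    freq <- stats::rnorm(1, fr_par[1], fr_par[2])
    placed <- FALSE
    for (try in 1:100) {
      s0 <- floor(stats::runif(1, 0, n - L))
      iv <- occupied[[type]]
      if (is.null(iv) || all(s0 + L <= iv[, 1] | s0 >= iv[, 2])) {
        occupied[[type]] <- rbind(iv, c(s0, s0 + L))
        placed <- TRUE
        break
      }
    }
    if (!placed) { truth[[e]] <- NULL; next }
    A <- if (!is.null(cfg$target_snr)) {
      # event band RMS under a Hann envelope is A * sqrt(3/16)
      cfg$target_snr * band_rms / sqrt(3 / 16)
    } else max(1, stats::rnorm(1, cfg$amplitude_uV[1], cfg$amplitude_uV[2]))
    k <- seq_len(L) - 1L
    hann <- 0.5 * (1 - cos(2 * pi * k / (L - 1L)))
    phase <- stats::runif(1, 0, 2 * pi)
    sig <- A * sin(2 * pi * freq * k / cfg$fs + phase) * hann
    ctr <- centers[[type]]
    d2 <- (pr[, 1] - pr[ctr, 1])^2 + (pr[, 2] - pr[ctr, 2])^2
    wch <- exp(-d2 / (2 * cfg$spread_sigma^2))
    dat[, (s0 + 1L):(s0 + L)] <- dat[, (s0 + 1L):(s0 + L)] + outer(wch, sig)
    truth[[e]] <- data.frame(start_sample = s0, end_sample = s0 + L,
                             center_channel = mont$labels[ctr], type = type,
                             freq_hz = freq, amplitude_uV = A)
  }
  truth <- truth[!vapply(truth, is.null, TRUE)]
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(start_sample = numeric(), end_sample = numeric(),
               center_channel = character(), type = character(),
               freq_hz = numeric(), amplitude_uV = numeric())
  truth <- truth[order(truth$start_sample), , drop = FALSE]
  rownames(truth) <- NULL
  list(recording = recording(dat, cfg$fs, labels = mont$labels,
                             positions = mont$positions),
       truth = truth)
}

#' Generate a synthetic individual-spindle table with known mixed-model
#' structure
#'
#' Builds a table of individual spindles across participants with a known
#' fixed-effect structure, Normal participant random intercepts and Normal
#' residuals, for validating the mixed-model machinery by parameter
#' recovery.
#'
#' @param n_participants number of participants.
#' @param spindles_per spindles per participant.
#' @param beta named fixed-effect vector; names must match columns of
#'   `model.matrix(formula, data)`. Unnamed effects are zero.
#' @param sigma_u SD of the participant random intercept.
#' @param sigma_e residual SD.
#' @param formula fixed-effect design for the dependent variable.
#' @param dependent name of the generated dependent column.
#' @param seed RNG seed.
#' @return data.frame with columns `participant`, `time_of_night`,
#'   `spindle_type`, covariates `duration`, `amplitude`, `globality`, and
#'   the dependent; attribute `"truth"` records `beta`, `sigma_u`,
#'   `sigma_e` and the participant intercepts.
#' @export
generate_spindle_table <- function(n_participants = 9, spindles_per = 1000,
                                   beta = c("(Intercept)" = 0),
                                   sigma_u = 1, sigma_e = 1,
                                   formula = ~ time_of_night + duration,
                                   dependent = "power", seed = NULL) {
  stopifnot(sigma_u >= 0, sigma_e > 0, n_participants >= 1, spindles_per >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_participants * spindles_per
  df <- data.frame(
    participant = factor(rep(sprintf("P%02d", seq_len(n_participants)),
                             each = spindles_per)),
    time_of_night = factor(sample(c("early", "late"), n, replace = TRUE),
                           levels = c("early", "late")),
    spindle_type = factor(sample(c("frontal", "posterior", "co_occurring"),
                                 n, replace = TRUE, prob = c(0.4, 0.4, 0.2)),
                          levels = c("frontal", "posterior", "co_occurring")),
    duration = stats::rnorm(n), amplitude = stats::rnorm(n),
    globality = stats::rnorm(n))
  X <- stats::model.matrix(formula, df)
  bad <- setdiff(names(beta), colnames(X))
  if (length(bad)) stop("beta names not in design: ", paste(bad, collapse = ", "))
  b <- stats::setNames(rep(0, ncol(X)), colnames(X))
  b[names(beta)] <- beta
  u <- stats::rnorm(n_participants, 0, sigma_u)
  df[[dependent]] <- as.numeric(X %*% b) + u[as.integer(df$participant)] +
    stats::rnorm(n, 0, sigma_e)
  attr(df, "truth") <- list(beta = b, sigma_u = sigma_u, sigma_e = sigma_e,
                            intercepts = u, formula = formula,
                            dependent = dependent)
  df
}

#' Score detected events against the injected ground truth
#'
#' A detected event matches a truth event when their intervals overlap by
#' at least half the shorter one's length; matches are assigned greedily,
#' one-to-one, by decreasing overlap. With no detected events precision is
#' 1 by convention (no false positives were produced).
#'
#' @param detected data.frame with `start_sample`/`end_sample` (0-based
#'   half-open), e.g. the `events` table of [detect_spindles()].
#' @param truth truth data.frame from [generate_recording()].
#' @param min_frac required overlap as a fraction of the shorter interval.
#' @return list with `precision`, `recall`, `f1`, `n_matched` and `matches`
#'   (data.frame of `det_idx`, `truth_idx`, `overlap` row indices).
#' @export
score_detection <- function(detected, truth, min_frac = 0.5) {
  nd <- nrow(detected); nt <- nrow(truth)
  matches <- data.frame(det_idx = integer(), truth_idx = integer(),
                        overlap = numeric())
  if (nd > 0L && nt > 0L) {
    ov <- outer(detected$end_sample, truth$end_sample, pmin) -
      outer(detected$start_sample, truth$start_sample, pmax)
    len_d <- detected$end_sample - detected$start_sample
    len_t <- truth$end_sample - truth$start_sample
    shorter <- outer(len_d, len_t, pmin)
    ok <- which(ov >= min_frac * shorter & ov > 0, arr.ind = TRUE)
    if (nrow(ok)) {
      ord <- order(ov[ok], decreasing = TRUE)
      used_d <- logical(nd); used_t <- logical(nt)
      for (r in ord) {
        i <- ok[r, 1L]; j <- ok[r, 2L]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE; used_t[j] <- TRUE
          matches <- rbind(matches,
                           data.frame(det_idx = i, truth_idx = j,
                                      overlap = ov[i, j]))
        }
      }
    }
  }
  tp <- nrow(matches)
  precision <- if (nd == 0L) 1 else tp / nd
  recall <- if (nt == 0L) 1 else tp / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, n_matched = tp,
       matches = matches)
}
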