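#' Welch power spectral density for one or many channels
#'
#' Averaged-periodogram PSD estimate with a Hamming window and 50% segment
#' overlap. Segments are zero-padded so the frequency grid is at least as
#' fine as `df_max`. All channels of a matrix are transformed together, so
#' per-event channel spectra are cheap even on dense montages.
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param window_s segment length in seconds; truncated to the signal
#'   length. Default 0.256 s, so even a 300 ms event holds one full window.
#' @param overlap fractional overlap between consecutive segments.
#' @param df_max maximum frequency-bin spacing in Hz (zero-padding target).
#' @return list with `freq` (Hz) and `psd` (channels x frequencies matrix,
#'   one-sided density in input-units^2/Hz).
#' @examples
#' x <- sin(2 * pi * 13 * seq(0, 2, by = 1/500))
#' w <- welch_psd(x, fs = 500)
#' w$freq[which.max(w$psd[1, ])]   # ~13 Hz
#' @export
welch_psd <- function(x, fs, window_s = 0.256, overlap = 0.5, df_max = 0.25) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (n < 2L) stop("signal too short for a PSD estimate")
  nw <- min(n, max(8L, round(window_s * fs)))
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq.int(1L, n - nw + 1L, by = step)
  nfft <- .next_pow2(max(nw, ceiling(fs / df_max)))
  win <- .hamming(nw)
  u <- fs * sum(win^2)  # density normalisation
  nfreq <- nfft %/% 2L + 1L
  acc <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nw - 1L), drop = FALSE] * rep(win, each = nrow(x))
    seg <- cbind(seg, matrix(0, nrow(x), nfft - nw))
    ft <- t(stats::mvfft(t(seg)))
    p <- (Mod(ft[, seq_len(nfreq), drop = FALSE])^2) / u
    acc <- acc + p
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and Nyquist
  if (nfreq > 2L) psd[, 2:(nfreq - 1L)] <- 2 * psd[, 2:(nfreq - 1L), drop = FALSE]
  list(freq = seq.int(0L, nfreq - 1L) * fs / nfft, psd = psd)
}

#' Mean band power from a Welch PSD
#'
#' @param w result of [welch_psd()].
#' @param band length-2 numeric, Hz (inclusive).
#' @return numeric vector, mean PSD per channel over the band.
#' @export
band_power <- function(w, band) {
  idx <- which(w$freq >= band[1] & w$freq <= band[2])
  if (!length(idx)) stop("band [", band[1], ", ", band[2], "] Hz outside PSD grid")
  rowMeans(w$psd[, idx, drop = FALSE])
}

#' Peak frequency within a band from a Welch PSD
#'
#' @inheritParams band_power
#' @return numeric vector, per-channel frequency (Hz) of the PSD maximum
#'   inside the band.
#' @export
peak_frequency <- function(w, band) {
  idx <- which(w$freq >= band[1] & w$freq <= band[2])
  if (!length(idx)) stop("band outside PSD grid")
  w$freq[idx[apply(w$psd[, idx, drop = FALSE], 1L, which.max)]]
}

.hamming <- function(n) {
  if (n == 1L) return(1)
  k <- seq.int(0L, n - 1L)
  0.54 - 0.46 * cos(2 * pi * k / (n - 1L))
}

.next_pow2 <- function(n) 2L^ceiling(log2(n))
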