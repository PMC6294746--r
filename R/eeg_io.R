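#' Construct a multi-channel EEG recording
#'
#' The container used throughout the pipeline: a channels x samples matrix
#' in microvolts, the sampling rate, channel labels, unit-sphere sensor
#' positions and a per-sample artifact mask (`TRUE` = excluded).
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param labels character vector of channel names, one per row.
#' @param positions channels x 3 matrix of sensor xyz; normalized to the
#'   unit sphere on construction.
#' @param artifact_mask logical vector, one per sample; `TRUE` marks samples
#'   excluded from detection. Defaults to all `FALSE`.
#' @return object of class `spd_recording`.
#' @export
recording <- function(data, fs, labels = rownames(data), positions,
                      artifact_mask = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("E", seq_len(nrow(data)))
  positions <- as.matrix(positions)
  if (nrow(data) != length(labels) || nrow(data) != nrow(positions))
    stop("data rows, labels and positions must agree in length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop("zero-length sensor position")
  positions <- positions / nrm
  colnames(positions) <- c("x", "y", "z")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, ncol(data))
  if (length(artifact_mask) != ncol(data))
    stop("artifact_mask length must equal sample count")
  rownames(data) <- labels
  rownames(positions) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 positions = positions,
                 artifact_mask = as.logical(artifact_mask)),
            class = "spd_recording")
}

#' @exportS3Method base::print
print.spd_recording <- function(x, ...) {
  cat(sprintf("<spd_recording> %d channels x %d samples @ %g Hz (%.1f min), %.1f%% masked\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs / 60,
              100 * mean(x$artifact_mask)))
  invisible(x)
}

# ---- EDF ---------------------------------------------------------------

.edf_str <- function(x, width) {
  s <- formatC(substr(as.character(x), 1L, width), width = -width)
  charToRaw(paste(s, collapse = ""))
}

.edf_num <- function(x) {
  # shortest decimal form that fits EDF's 8-character numeric fields
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- sprintf(paste0("%.", d, "g"), v)
      if (nchar(s) <= 8L) return(s)
    }
    stop("value does not fit EDF numeric field: ", v)
  }, "")
}

#' Write a recording to an EDF file
#'
#' Minimal continuous-EDF writer: one data record per second, 16-bit
#' samples, per-channel physical scaling from the data range. The sampling
#' rate must be a whole number of samples per second; trailing samples
#' beyond the last whole second are dropped.
#'
#' @param r a [recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(r, path) {
  fs <- r$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nrec <- ncol(r$data) %/% fs
  if (nrec < 1L) stop("recording shorter than one EDF record (1 s)")
  nch <- nrow(r$data)
  dat <- r$data[, seq_len(nrec * fs), drop = FALSE]
  pmin <- apply(dat, 1L, min); pmax <- apply(dat, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- c(.edf_str("0", 8L), .edf_str("synthetic", 80L), .edf_str("spindlehd", 80L),
           .edf_str("01.01.00", 8L), .edf_str("00.00.00", 8L),
           .edf_str(256L * (1L + nch), 8L), .edf_str("", 44L),
           .edf_str(nrec, 8L), .edf_str(1L, 8L), .edf_str(nch, 4L))
  fld <- function(v, w) do.call(c, lapply(v, .edf_str, width = w))
  hdr <- c(hdr, fld(r$labels, 16L), fld(rep("", nch), 80L), fld(rep("uV", nch), 8L),
           fld(.edf_num(pmin), 8L), fld(.edf_num(pmax), 8L),
           fld(rep(dmin, nch), 8L), fld(rep(dmax, nch), 8L),
           fld(rep("", nch), 80L), fld(rep(fs, nch), 8L), fld(rep("", nch), 32L))
  writeBin(hdr, con)
  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((dat - pmin) * scale + dmin)
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  storage.mode(dig) <- "integer"
  for (k in seq_len(nrec)) {
    block <- t(dig[, ((k - 1L) * fs + 1L):(k * fs), drop = FALSE])
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf_header <- function(con) {
  gets <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- gets(8L); gets(80L); gets(80L); gets(8L); gets(8L)
  hbytes <- as.integer(gets(8L)); gets(44L)
  nrec <- as.integer(gets(8L)); recdur <- as.numeric(gets(8L))
  nch <- as.integer(gets(4L))
  fld <- function(w) vapply(seq_len(nch), function(i) gets(w), "")
  labels <- fld(16L); fld(80L); unit <- fld(8L)
  pmin <- as.numeric(fld(8L)); pmax <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L); nsamp <- as.integer(fld(8L)); fld(32L)
  list(nrec = nrec, recdur = recdur, nch = nch, labels = labels,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, nsamp = nsamp,
       hbytes = hbytes)
}

#' Read an EDF file together with sensor locations
#'
#' @param path EDF/EDF+ file (continuous signals only; any "EDF Annotations"
#'   channel is skipped).
#' @param locs_path CSV with columns `label,x,y,z`; every EEG channel in the
#'   EDF must have a row. Positions are normalized to the unit sphere.
#' @return a [recording()] with an all-`FALSE` artifact mask.
#' @export
read_recording <- function(path, locs_path) {
  locs <- utils::read.csv(locs_path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(locs))) stop("locations CSV must have columns label,x,y,z")
  con <- file(path, "rb"); on.exit(close(con))
  h <- .read_edf_header(con)
  keep <- which(h$labels != "EDF Annotations")
  fs <- h$nsamp[keep] / h$recdur
  if (length(unique(fs)) != 1L)
    stop("sampling rate differs across channels: ", paste(unique(fs), collapse = ", "))
  fs <- fs[1L]
  missing <- setdiff(h$labels[keep], locs$label)
  if (length(missing))
    stop("no sensor location for channel(s): ", paste(missing, collapse = ", "))
  total <- sum(h$nsamp)
  dat <- matrix(0, length(keep), h$nrec * h$nsamp[keep[1L]])
  gain <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  offs <- cumsum(c(0L, h$nsamp))
  for (k in seq_len(h$nrec)) {
    rec <- readBin(con, "integer", total, size = 2L, signed = TRUE, endian = "little")
    for (j in seq_along(keep)) {
      ch <- keep[j]
      v <- rec[(offs[ch] + 1L):offs[ch + 1L]]
      dat[j, ((k - 1L) * h$nsamp[ch] + 1L):(k * h$nsamp[ch])] <-
        (v - h$dmin[ch]) * gain[ch] + h$pmin[ch]
    }
  }
  pos <- as.matrix(locs[match(h$labels[keep], locs$label), c("x", "y", "z")])
  recording(dat, fs, labels = h$labels[keep], positions = pos)
}

# ---- Hypnogram and NREM cycles ----------------------------------------

#' Read a hypnogram CSV
#'
#' Expects columns `epoch,stage`. Stage labels are case-insensitive and the
#' aliases `NREM1/2/3`, `S1/2/3`, `WAKE`, `R` and AASM digits (0 = wake,
#' 1-3 = N1-N3, 5 = REM) are accepted.
#'
#' @param path CSV file.
#' @param epoch_s epoch length in seconds.
#' @return object of class `spd_hypnogram`: list of `stages`, `epoch_s`.
#' @export
read_hypnogram <- function(path, epoch_s = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"stage" %in% names(df)) stop("hypnogram CSV must have a 'stage' column")
  if ("epoch" %in% names(df)) df <- df[order(df$epoch), , drop = FALSE]
  hypnogram(df$stage, epoch_s = epoch_s)
}

#' Construct a hypnogram from stage labels
#'
#' @param stages vector of per-epoch labels (see [read_hypnogram()] for
#'   accepted aliases).
#' @param epoch_s epoch length in seconds.
#' @return object of class `spd_hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  if (!length(stages)) stop("empty hypnogram")
  if (epoch_s <= 0) stop("epoch_s must be positive")
  map <- c(W = "W", WAKE = "W", "0" = "W",
           N1 = "N1", S1 = "N1", NREM1 = "N1", "1" = "N1",
           N2 = "N2", S2 = "N2", NREM2 = "N2", "2" = "N2",
           N3 = "N3", S3 = "N3", NREM3 = "N3", "3" = "N3", "4" = "N3",
           REM = "REM", R = "REM", "5" = "REM")
  key <- toupper(trimws(as.character(stages)))
  bad <- setdiff(unique(key), names(map))
  if (length(bad)) stop("unknown sleep stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = unname(map[key]), epoch_s = epoch_s),
            class = "spd_hypnogram")
}

#' Find NREM cycles in a hypnogram
#'
#' A cycle is a maximal run of consecutive N2/N3 epochs, tolerating at most
#' one N1 epoch inside the run; any wake (or REM) epoch, or a second N1,
#' terminates the run. Runs are trimmed to start and end on an N2/N3 epoch
#' and kept only if they last at least `min_duration_min` minutes.
#'
#' @param h a [hypnogram()].
#' @param fs sampling rate used to convert epoch bounds to sample indices.
#' @param min_duration_min minimum cycle duration, minutes.
#' @return data.frame with columns `index`, `start_epoch`, `end_epoch`
#'   (1-based inclusive), `start_sample`, `end_sample` (0-based half-open),
#'   `minutes`.
#' @export
find_nrem_cycles <- function(h, fs, min_duration_min = 30) {
  stopifnot(inherits(h, "spd_hypnogram"))
  st <- h$stages
  n <- length(st)
  core <- st %in% c("N2", "N3")
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!core[i]) { i <- i + 1L; next }
    start <- i; last_core <- i; n1 <- 0L
    j <- i + 1L
    while (j <= n) {
      if (core[j]) { last_core <- j }
      else if (st[j] == "N1" && n1 == 0L) { n1 <- 1L }
      else break
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- c(start, last_core)
    i <- j + 1L
  }
  if (!length(runs))
    return(data.frame(index = integer(), start_epoch = integer(),
                      end_epoch = integer(), start_sample = numeric(),
                      end_sample = numeric(), minutes = numeric()))
  m <- do.call(rbind, runs)
  minutes <- (m[, 2L] - m[, 1L] + 1L) * h$epoch_s / 60
  keep <- minutes >= min_duration_min
  m <- m[keep, , drop = FALSE]; minutes <- minutes[keep]
  data.frame(index = seq_len(nrow(m)),
             start_epoch = m[, 1L], end_epoch = m[, 2L],
             start_sample = (m[, 1L] - 1L) * h$epoch_s * fs,
             end_sample = m[, 2L] * h$epoch_s * fs,
             minutes = minutes)
}

#' Build an artifact mask from marked intervals
#'
#' @param intervals data.frame with columns `start_s`, `end_s` (half-open,
#'   seconds), or a CSV path to one.
#' @param fs sampling rate, Hz.
#' @param n_samples total sample count of the recording.
#' @return logical vector; `TRUE` inside any interval.
#' @export
artifact_mask <- function(intervals, fs, n_samples) {
  if (is.character(intervals)) intervals <- utils::read.csv(intervals)
  mask <- rep(FALSE, n_samples)
  for (k in seq_len(nrow(intervals))) {
    a <- max(0, floor(intervals$start_s[k] * fs))
    b <- min(n_samples, ceiling(intervals$end_s[k] * fs))
    if (b > a) mask[(a + 1L):b] <- TRUE
  }
  mask
}

# ---- Preprocessing -----------------------------------------------------

.legendre_sum <- function(x, m, nterms) {
  # sum_{n=1}^{nterms} (2n+1) / (n (n+1))^m * P_n(x), vectorised over x
  pnm1 <- rep(1, length(x))   # P_0
  pn <- x                     # P_1
  acc <- 3 / 2^m * pn
  if (nterms >= 2L) for (n in 2L:nterms) {
    pnext <- ((2 * n - 1) * x * pn - (n - 1) * pnm1) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * pnext
    pnm1 <- pn; pn <- pnext
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels by spherical-spline estimates from the
#' remaining good channels (Perrin-style surface spline on the unit
#' sphere). Good-channel rows are returned untouched. Run this before
#' [average_reference()] so artifactual channels cannot bias the reference.
#'
#' @param r a [recording()].
#' @param bad character vector of channel labels to replace; may be empty.
#' @param m spline order (stiffness) of the spherical spline.
#' @param nterms number of Legendre terms in the kernel expansion.
#' @param lambda ridge regularization added to the kernel matrix diagonal.
#' @return a [recording()] with bad rows replaced.
#' @export
interpolate_bad_channels <- function(r, bad, m = 4, nterms = 7, lambda = 1e-5) {
  stopifnot(inherits(r, "spd_recording"))
  if (!length(bad)) return(r)
  bad <- unique(bad)
  unknown <- setdiff(bad, r$labels)
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  bidx <- match(bad, r$labels)
  gidx <- setdiff(seq_along(r$labels), bidx)
  if (length(gidx) < 4L) stop("need at least 4 good channels to interpolate")
  pg <- r$positions[gidx, , drop = FALSE]
  pb <- r$positions[bidx, , drop = FALSE]
  G <- .legendre_sum(pmin(pmax(tcrossprod(pg), -1), 1), m, nterms)
  ng <- length(gidx)
  A <- rbind(cbind(G + lambda * diag(ng), 1), c(rep(1, ng), 0))
  Gi <- .legendre_sum(pmin(pmax(tcrossprod(pb, pg), -1), 1), m, nterms)
  W <- cbind(Gi, 1) %*% solve(A)[, seq_len(ng), drop = FALSE]
  out <- r
  out$data[bidx, ] <- W %*% r$data[gidx, , drop = FALSE]
  out
}

#' Re-reference a recording to the channel average
#'
#' Subtracts the instantaneous mean over all channels from every channel,
#' so the channel mean of the output is zero at every sample.
#'
#' @param r a [recording()].
#' @return re-referenced [recording()].
#' @export
average_reference <- function(r) {
  stopifnot(inherits(r, "spd_recording"))
  if (nrow(r$data) < 2L) stop("average reference needs at least 2 channels")
  r$data <- sweep(r$data, 2L, colMeans(r$data))
  r
}
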