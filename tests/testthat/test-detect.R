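test_that("wavelet filter passes the spindle band and rejects neighbours", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  mid <- 2000:3000
  gain <- function(f) {
    y <- bspline_wavelet_filter(sin(2 * pi * f * t), fs)
    max(abs(y[mid]))
  }
  expect_gt(gain(13), 0.7); expect_lt(gain(13), 1.1)   # pass band
  expect_lt(gain(5), 0.1)                               # stop band
  expect_lt(gain(25), 0.1)
  expect_equal(bspline_wavelet_filter(numeric(100), fs), numeric(100))
  expect_error(bspline_wavelet_filter(t, fs = 30), "Nyquist")
})

test_that("wavelet filter -3 dB points sit on the band edges within 1 Hz", {
  fs <- 500
  kern <- spindlehd:::.bspline_kernel(fs, 10, 16)
  tt <- (seq_along(kern) - (length(kern) + 1) / 2) / fs
  resp <- function(f) abs(sum(kern * exp(-2i * pi * f * tt)))
  fr <- seq(5, 25, by = 0.01)
  g <- vapply(fr, resp, 0)
  edges <- range(fr[g >= 1 / sqrt(2)])
  expect_equal(edges[1], 10, tolerance = 1)
  expect_equal(edges[2], 16, tolerance = 1)
})

test_that("power envelope matches the closed form for a sinusoid and is quadratic", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  A <- 3
  x <- A * sin(2 * pi * 13 * t)
  env <- power_envelope(x, fs, 200)   # window covers >2 periods
  interior <- env[500:1500]
  expect_true(all(abs(interior - A^2 / 2) <= 0.05 * A^2 / 2))
  expect_equal(power_envelope(numeric(50), fs, 100), numeric(50))
  expect_equal(power_envelope(2 * x, fs, 200), 4 * env)
  expect_true(all(env >= 0))
})

test_that("MAD thresholds reproduce hand computations in every mode", {
  env <- c(0, 2, 4, 6, 8)
  th <- mad_thresholds(env, mode = "mad_only")           # median 4, MAD 2
  expect_equal(th, c(high = 8, low = 4))
  th2 <- mad_thresholds(env, mode = "median_plus_mad")
  expect_equal(th2, c(high = 4 + 8, low = 4 + 4))
  xf <- c(-3, -1, 0, 1, 3)                               # median 0, MAD 1
  th3 <- mad_thresholds(env, mode = "mad_amplitude", filtered = xf)
  expect_equal(th3, c(high = 16, low = 4))
  # homogeneity: scaling the envelope scales the thresholds
  expect_equal(mad_thresholds(7 * env, mode = "mad_only"), 7 * th)
  expect_error(mad_thresholds(rep(2, 10), mode = "mad_only"), "MAD")
  expect_error(mad_thresholds(env, mode = "mad_amplitude"), "filtered")
})

test_that("event extraction follows low-threshold crossings and the duration rule", {
  env <- c(0, 5, 9, 9, 5, 5, 3)
  ev <- detect_region_events(env, fs = 10, high = 8, low = 4,
                             min_ms = 300, max_ms = 3000)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start_sample, ev$end_sample), c(1, 6))
  expect_equal(ev$duration_ms, 500)
  expect_equal(ev$peak_envelope, 9)
  # never reaching the high threshold yields nothing
  expect_equal(nrow(detect_region_events(env, 10, high = 20, low = 4)), 0L)
  # low-span shorter than min_ms is discarded
  env2 <- c(0, 0, 9, 9, 0, 0)   # 200 ms span at 10 Hz
  expect_equal(nrow(detect_region_events(env2, 10, 8, 4, min_ms = 300)), 0L)
  # over-long events are discarded too
  env3 <- c(0, rep(9, 40), 0)
  expect_equal(nrow(detect_region_events(env3, 10, 8, 4, max_ms = 3000)), 0L)
  # artifact overlap of a single sample drops the event
  vm <- rep(TRUE, 7); vm[3] <- FALSE
  expect_equal(nrow(detect_region_events(env, 10, 8, 4, valid_mask = vm)), 0L)
})

test_that("event extraction equals a brute-force scan on random envelopes", {
  set.seed(99)
  for (trial in seq_len(1000)) {
    env <- abs(rnorm(500))^2
    th <- sort(runif(2, 0.2, 4))
    got <- detect_region_events(env, fs = 100, high = th[2], low = th[1],
                                min_ms = 30, max_ms = 1000)
    want <- brute_force_events(env, fs = 100, high = th[2], low = th[1],
                               min_ms = 30, max_ms = 1000)
    expect_equal(got[, c("start_sample", "end_sample")], want,
                 ignore_attr = TRUE)
  }
})

test_that("cross-region merging takes the transitive closure of overlaps", {
  mk <- function(s, e, pk) data.frame(start_sample = s, end_sample = e,
                                      peak_envelope = pk, peak_sample = s,
                                      duration_ms = (e - s) * 2)
  # overlapping events in two regions merge into one span
  m1 <- merge_region_events(list(A = mk(100, 600, 5), B = mk(500, 900, 7)))
  expect_equal(nrow(m1), 1L)
  expect_equal(c(m1$start_sample, m1$end_sample), c(100, 900))
  expect_equal(m1$peak_envelope, 7)    # largest power among regions
  expect_setequal(m1$regions[[1]], c("A", "B"))
  # disjoint events stay separate
  m2 <- merge_region_events(list(A = mk(0, 400, 1), B = mk(500, 900, 2)))
  expect_equal(nrow(m2), 2L)
  # transitive chain A-B-C collapses to one event
  m3 <- merge_region_events(list(A = mk(0, 500, 1), B = mk(400, 700, 2),
                                 C = mk(650, 1000, 3)))
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start_sample, m3$end_sample), c(0, 1000))
  expect_equal(m3$n_regions, 3L)
  # abutting half-open intervals do not merge
  m4 <- merge_region_events(list(A = mk(0, 400, 1), B = mk(400, 600, 2)))
  expect_equal(nrow(m4), 2L)
  expect_equal(nrow(merge_region_events(list(A = mk(0, 0, 0)[0, ]))), 0L)
})

test_that("merging equals a brute-force interval union on random inputs", {
  set.seed(17)
  for (trial in 1:50) {
    evs <- lapply(1:3, function(k) {
      s <- sort(sample(0:200, 5)) * 10
      data.frame(start_sample = s, end_sample = s + sample(50:200, 5),
                 peak_envelope = runif(5), peak_sample = s, duration_ms = 0)
    })
    # within-region events must be non-overlapping: enforce by spacing
    evs <- lapply(evs, function(e) {
      keep <- c(TRUE, e$start_sample[-1] >= cummax(e$end_sample[-5]))
      e[keep, ]
    })
    got <- merge_region_events(setNames(evs, c("A", "B", "C")))
    all_iv <- do.call(rbind, evs)
    # brute force: count connected components of the half-open interval set
    ord <- order(all_iv$start_sample, all_iv$end_sample)
    n_comp <- 0L; cur_end <- -Inf
    for (i in ord) {
      if (all_iv$start_sample[i] >= cur_end) n_comp <- n_comp + 1L
      cur_end <- max(cur_end, all_iv$end_sample[i])
    }
    expect_equal(nrow(got), n_comp)
    expect_true(all(got$end_sample >= got$start_sample))
  }
})
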