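# Shared fixtures, built in code at test time.

# positions whose azimuthal projection lands exactly at the given 2-d points
positions_from_projection <- function(px, py) {
  theta <- sqrt(px^2 + py^2)
  phi <- atan2(py, px)
  cbind(x = sin(theta) * cos(phi), y = sin(theta) * sin(phi), z = cos(theta))
}

# small recording: 1/f-ish noise plus optional injected sinusoidal bursts
tiny_recording <- function(n_channels = 16, seconds = 30, fs = 500,
                           seed = 42) {
  set.seed(seed)
  mont <- synthetic_montage(n_channels)
  dat <- matrix(stats::rnorm(n_channels * seconds * fs), n_channels)
  recording(dat, fs, labels = mont$labels, positions = mont$positions)
}

# memoised study-scale synthetic recording + detection, shared by the
# acceptance tests (20 min, 64 channels, 18 spindles/min, band SNR 2)
.accept_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (is.null(.accept_cache$res)) {
    cfg <- sim_config(n_channels = 64, duration_min = 20, target_snr = 2,
                      seed = 20180101)
    gen <- generate_recording(cfg)
    hyp <- hypnogram(rep("N2", 40))
    t0 <- Sys.time()
    res <- detect_spindles(gen$recording, hyp, min_cycle_min = 15)
    .accept_cache$runtime_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .accept_cache$gen <- gen
    .accept_cache$res <- res
  }
  list(gen = .accept_cache$gen, res = .accept_cache$res,
       runtime_s = .accept_cache$runtime_s)
}

# independent brute-force event scanner (oracle for detect_region_events):
# literal per-sample walk, no vectorisation shared with the implementation
brute_force_events <- function(env, fs, high, low, min_ms = 300,
                               max_ms = 3000) {
  n <- length(env)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (env[i] >= high) {
      s <- i
      while (s > 1L && env[s - 1L] >= low) s <- s - 1L
      e <- i
      while (e < n && env[e + 1L] >= low) e <- e + 1L
      dur <- (e - s + 1L) / fs * 1000
      if (dur >= min_ms && dur <= max_ms)
        out <- rbind(out, c(s - 1L, e))
      i <- e + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) return(data.frame(start_sample = numeric(),
                                      end_sample = numeric()))
  out <- unique(out)
  data.frame(start_sample = out[, 1L], end_sample = out[, 2L])
}

# independent TFCE oracle: explicit threshold loop with its own BFS
brute_force_tfce <- function(map, adj, E = 0.5, H = 2, dh) {
  n <- length(map)
  out <- numeric(n)
  signs <- list(1, -1)
  for (sg in signs) {
    m <- pmax(sg * map, 0)
    mx <- max(m)
    if (mx <= 0) next
    n_steps <- floor(mx / dh + 1e-9)
    for (k in seq_len(n_steps)) {
      h <- k * dh
      supra <- which(m >= h)
      unvisited <- rep(TRUE, n)
      for (v0 in supra) {
        if (!unvisited[v0]) next
        comp <- v0
        unvisited[v0] <- FALSE
        frontier <- v0
        while (length(frontier)) {
          nxt <- integer()
          for (v in frontier) for (u in adj[[v]])
            if (unvisited[u] && m[u] >= h) {
              unvisited[u] <- FALSE
              nxt <- c(nxt, u)
            }
          comp <- c(comp, nxt)
          frontier <- nxt
        }
        out[comp] <- out[comp] + sg * length(comp)^E * h^H * dh
      }
    }
  }
  out
}

# random small connected graph as an spd_adjacency object
random_adjacency <- function(n) {
  repeat {
    amat <- matrix(stats::runif(n * n) < 0.35, n, n)
    amat <- amat | t(amat)
    diag(amat) <- FALSE
    adj <- lapply(seq_len(n), function(i) which(amat[i, ]))
    seen <- logical(n); stack <- 1L; seen[1L] <- TRUE
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
    }
    if (all(seen)) return(structure(adj, class = "spd_adjacency"))
  }
}
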