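test_that("channel adjacency is symmetric, self-free and distance-driven", {
  mont <- synthetic_montage(32)
  adj <- channel_adjacency(mont$positions)
  for (i in seq_along(adj)) {
    expect_false(i %in% adj[[i]])
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])
  }
  expect_true(all(lengths(adj) >= 1))
  # an isolated far-away sensor triggers the connectivity warning
  pos2 <- rbind(mont$positions, c(0, 0, -1))
  expect_warning(channel_adjacency(pos2), "not connected")
})

test_that("TFCE matches the closed form on uniform maps and zero on zero maps", {
  mont <- synthetic_montage(24)
  adj <- channel_adjacency(mont$positions)
  expect_equal(tfce(rep(0, 24), adj), rep(0, 24))
  for (h in c(0.5, 2, 7)) {
    e <- tfce(rep(h, 24), adj, E = 0.5, H = 2)
    closed <- 24^0.5 * h^3 / 3
    expect_true(all(abs(e - closed) / closed < 0.02))
  }
  # sign structure: negated maps give negated enhancement
  set.seed(51)
  m <- rnorm(24)
  expect_equal(tfce(-m, adj), -tfce(m, adj))
})

test_that("TFCE equals the brute-force threshold scan on small random graphs", {
  set.seed(52)
  for (trial in 1:100) {
    n <- sample(4:10, 1)
    adj <- random_adjacency(n)
    map <- rnorm(n) * sample(c(1, 5), 1)
    dh <- max(abs(map)) / 37   # shared, deliberately odd grid
    got <- tfce(map, adj, dh = dh)
    want <- brute_force_tfce(map, adj, dh = dh)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("TFCE is monotone for pointwise-ordered non-negative maps", {
  set.seed(53)
  mont <- synthetic_montage(16)
  adj <- channel_adjacency(mont$positions)
  for (trial in 1:20) {
    a <- abs(rnorm(16)); b <- a + runif(16, 0, 0.5)
    dh <- max(b) / 100
    expect_true(all(tfce(b, adj, dh = dh) >= tfce(a, adj, dh = dh) - 1e-12))
  }
})

test_that("permutations preserve the factor structure they must preserve", {
  set.seed(54)
  tbl <- data.frame(participant = rep(c("P1", "P2", "P3", "P4"), times = c(5, 3, 6, 2)),
                    cond = NA, grp = NA)
  tbl$cond <- unlist(lapply(c(5, 3, 6, 2), function(k)
    sample(rep(c("frontal", "posterior"), length.out = k))))
  tbl$grp <- c("a", "b", "a", "b")[match(tbl$participant,
                                         c("P1", "P2", "P3", "P4"))]
  for (i in 1:20) {
    pw <- permute_table(tbl, permutation_scheme("cond", "within_subject"))
    expect_equal(table(pw$participant, pw$cond), table(tbl$participant, tbl$cond))
    pb <- permute_table(tbl, permutation_scheme("grp", "between_subject"))
    # blocks stay intact and group sizes at participant level are kept
    lab <- tapply(pb$grp, pb$participant, function(v) unique(v))
    expect_true(all(lengths(lab) == 1))
    expect_equal(sort(as.vector(unlist(lab))), c("a", "a", "b", "b"))
    expect_equal(nrow(pb), nrow(tbl))
  }
  # a participant with a constant within-subject factor is left unchanged
  tbl2 <- tbl; tbl2$cond[tbl2$participant == "P4"] <- "frontal"
  pw2 <- permute_table(tbl2, permutation_scheme("cond", "within_subject"))
  expect_equal(pw2$cond[pw2$participant == "P4"], c("frontal", "frontal"))
  # between-subject permutation refuses factors varying within participant
  expect_error(permute_table(tbl, permutation_scheme("cond", "between_subject")),
               "varies within")
})

test_that("max-statistic p-values count null maxima with add-one correction", {
  mp <- max_perm_pvalues(c(5, 0.5), rep(c(1, 2, 3, 4, 6), 20))
  expect_equal(mp$p[1], (1 + 20) / 101)
  expect_equal(mp$p[2], 1)
  raw <- max_perm_pvalues(c(5, 0.5), rep(c(1, 2, 3, 4, 6), 20), add_one = FALSE)
  expect_equal(raw$p[1], 0.2)
  # invariance under monotone rescaling of observed and null together
  obs <- c(0.3, 1.2, 2.5); null <- runif(200, 0, 3)
  f <- function(x) x^3
  expect_equal(max_perm_pvalues(obs, null)$p,
               max_perm_pvalues(f(obs), f(null))$p)
  expect_error(max_perm_pvalues(1, 1:50), "100")
})

test_that("paired-t maps handle identical and degenerate inputs", {
  x <- matrix(rnorm(5 * 8), 5, 8)
  arr <- array(c(x, x), dim = c(5, 8, 2))
  t0 <- paired_t_tmap(arr)
  expect_equal(unname(as.numeric(t0)), rep(0, 8))
  d <- matrix(0.5, 4, 3)        # constant difference, zero variance
  td <- paired_t_tmap(d)
  expect_true(all(is.finite(td)))
  expect_true(all(td == 1e6))
  expect_true(all(attr(td, "capped")))
  expect_error(paired_t_tmap(matrix(1, 1, 3)), "2 participants")
})

test_that("a localized injected difference survives TFCE correction", {
  set.seed(55)
  mont <- synthetic_montage(32)
  adj <- channel_adjacency(mont$positions)
  diffs <- matrix(rnorm(9 * 32), 9, 32)
  target <- c(10, adj[[10]])
  diffs[, target] <- diffs[, target] + 2.5
  res <- topo_paired_test(diffs, adj, n_perm = 300, seed = 1)
  expect_lt(res$p_corrected[10], 0.05)
  # significant channels should lie in or near the injected cluster
  sig <- which(res$p_corrected < 0.05)
  expect_gt(length(intersect(sig, target)) / length(sig), 0.5)
})

test_that("channel-wise mixed T-maps agree with single fits and flag failures", {
  tbl <- generate_spindle_table(5, 60, beta = c("(Intercept)" = 1,
                                                time_of_nightlate = 0.5),
                                sigma_u = 1, sigma_e = 1, seed = 56)
  cv <- cbind(ch1 = tbl$power, ch2 = tbl$power + rnorm(nrow(tbl)))
  tm <- channelwise_lmm_tmap(tbl, cv, "time_of_night")
  single <- fit_lmm(transform(tbl, .dependent = cv[, 2]), ".dependent",
                    "time_of_night")
  expect_equal(tm["time_of_nightlate", "ch2"],
               single$coefficients$t[single$coefficients$term == "time_of_nightlate"])
  # identical dependents give identical T everywhere
  tm2 <- channelwise_lmm_tmap(tbl, cbind(tbl$power, tbl$power), "time_of_night")
  expect_equal(tm2[, 1], tm2[, 2])
})

test_that("the channel-space mixed-model permutation test flags an injected effect", {
  set.seed(57)
  n_ch <- 9
  mont <- synthetic_montage(n_ch)
  adj <- channel_adjacency(mont$positions)
  tbl <- generate_spindle_table(6, 40, sigma_u = 1, sigma_e = 1, seed = 57)
  cv <- matrix(rnorm(nrow(tbl) * n_ch), ncol = n_ch) +
    matrix(tbl$power, nrow(tbl), n_ch)
  # inject a condition effect at channels 4 and its neighbours
  eff <- as.integer(tbl$time_of_night == "late") * 1.5
  for (ch in c(4, adj[[4]])) cv[, ch] <- cv[, ch] + eff
  res <- topo_lmm_test(tbl, cv, "time_of_night",
                       test_terms = "time_of_nightlate",
                       schemes = permutation_scheme("time_of_night",
                                                    "within_subject"),
                       adj = adj, n_perm = 120, seed = 3)
  expect_lt(res$time_of_nightlate$p_corrected[4], 0.05)
})
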