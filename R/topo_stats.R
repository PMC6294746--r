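#' Channel adjacency graph from sensor positions
#'
#' Two channels are neighbours when their (chord) distance is within
#' `factor` times the median nearest-neighbour distance of the montage — a
#' montage-independent rule that adapts to sensor density.
#'
#' @param positions channels x 3 unit-sphere sensor positions.
#' @param factor multiple of the median nearest-neighbour distance.
#' @return object of class `spd_adjacency`: list of integer neighbour
#'   vectors (1-based), symmetric, no self-neighbours. A warning is issued
#'   if the graph is not connected.
#' @export
channel_adjacency <- function(positions, factor = 1.3) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 channels")
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  thr <- factor * stats::median(apply(d, 1L, min))
  adj <- lapply(seq_len(n), function(i) which(d[i, ] <= thr))
  # connectivity check
  seen <- logical(n); stack <- 1L; seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
  }
  if (!all(seen))
    warning("adjacency graph is not connected (", sum(!seen),
            " unreachable channel(s))")
  structure(adj, class = "spd_adjacency")
}

#' Threshold-free cluster enhancement of a channel statistic map
#'
#' Integrates, over an evenly spaced ladder of thresholds up to the map
#' maximum, each channel's suprathreshold cluster extent (to power `E`)
#' times the threshold height (to power `H`). Negative map values are
#' enhanced on the negated map and re-negated, so signed statistics keep
#' their sign.
#'
#' @param stat_map numeric statistic per channel (e.g. T-values).
#'   Non-finite values are set to 0 with a warning.
#' @param adj [channel_adjacency()] graph.
#' @param E cluster-extent exponent.
#' @param H threshold-height exponent.
#' @param dh threshold step; by default `max(|map|)/n_steps`.
#' @param n_steps number of threshold steps when `dh` is not given.
#' @return enhanced map, same length and sign structure as `stat_map`.
#' @export
tfce <- function(stat_map, adj, E = 0.5, H = 2, dh = NULL, n_steps = 100L) {
  stopifnot(inherits(adj, "spd_adjacency"))
  if (!length(adj) || length(adj) != length(stat_map))
    stop("adjacency size must match the statistic map")
  if (any(!is.finite(stat_map))) {
    warning("non-finite statistic values set to 0")
    stat_map[!is.finite(stat_map)] <- 0
  }
  adj0 <- lapply(adj, function(v) as.integer(v - 1L))
  enhance <- function(m) {
    mx <- max(m)
    if (mx <= 0) return(numeric(length(m)))
    step <- if (is.null(dh)) mx / n_steps else dh
    k <- max(1L, floor(mx / step + 1e-9))
    .tfce_core(m, adj0, E, H, step, as.integer(k))
  }
  pos <- pmax(stat_map, 0)
  neg <- pmax(-stat_map, 0)
  enhance(pos) - enhance(neg)
}

#' Permutation scheme for one experimental factor
#'
#' @param factor column to permute.
#' @param level `"within_subject"` (labels shuffled inside each
#'   participant, preserving per-participant level counts exactly) or
#'   `"between_subject"` (participants relabelled as whole blocks).
#' @return list of class `spd_perm_scheme`.
#' @export
permutation_scheme <- function(factor,
                               level = c("within_subject", "between_subject")) {
  level <- match.arg(level)
  structure(list(factor = factor, level = level), class = "spd_perm_scheme")
}

#' Permute factor labels of a spindle table
#'
#' Applies each scheme in turn with independent draws. Between-subject
#' factors are permuted at the participant level (all spindles of a
#' participant are relabelled together); within-subject factors are
#' shuffled inside each participant so the per-participant level counts
#' are preserved exactly.
#'
#' @param tbl data.frame with a participant column.
#' @param schemes one [permutation_scheme()] or a list of them.
#' @param participant grouping column name.
#' @return permuted copy of `tbl`.
#' @export
permute_table <- function(tbl, schemes, participant = "participant") {
  if (inherits(schemes, "spd_perm_scheme")) schemes <- list(schemes)
  stopifnot(participant %in% names(tbl))
  pid <- as.character(tbl[[participant]])
  for (sc in schemes) {
    stopifnot(inherits(sc, "spd_perm_scheme"), sc$factor %in% names(tbl))
    if (sc$level == "within_subject") {
      for (p in unique(pid)) {
        idx <- which(pid == p)
        vals <- tbl[[sc$factor]][idx]
        tbl[[sc$factor]][idx] <- vals[sample.int(length(vals))]
      }
    } else {
      ups <- unique(pid)
      lab <- vapply(ups, function(p) {
        v <- unique(tbl[[sc$factor]][pid == p])
        if (length(v) != 1L)
          stop("between-subject factor '", sc$factor,
               "' varies within participant ", p)
        as.character(v)
      }, "")
      newlab <- lab[sample.int(length(lab))]
      names(newlab) <- ups
      was_factor <- is.factor(tbl[[sc$factor]])
      lv <- levels(tbl[[sc$factor]])
      tbl[[sc$factor]] <- unname(newlab[pid])
      if (was_factor) tbl[[sc$factor]] <- factor(tbl[[sc$factor]], levels = lv)
    }
  }
  tbl
}

#' Per-channel linear mixed model T-maps
#'
#' Fits the identical mixed model at every channel, taking the dependent
#' variable from that channel's column, and stores the fixed-effect
#' T-value per term. A channel whose fit fails yields `NA` T-values (with
#' a warning) and is excluded from permutation maxima downstream.
#'
#' @param tbl data.frame of individual spindles (covariates and grouping).
#' @param channel_values events x channels matrix of the per-channel
#'   dependent variable (e.g. log band power).
#' @param terms fixed-effect terms.
#' @param grouping random-intercept column.
#' @return terms x channels matrix of T-values (rows named by coefficient).
#' @export
channelwise_lmm_tmap <- function(tbl, channel_values, terms,
                                 grouping = "participant") {
  channel_values <- as.matrix(channel_values)
  stopifnot(nrow(channel_values) == nrow(tbl))
  n_ch <- ncol(channel_values)
  tmap <- NULL
  for (ch in seq_len(n_ch)) {
    tbl$.dependent <- channel_values[, ch]
    t_ch <- tryCatch({
      f <- fit_lmm(tbl, ".dependent", terms, grouping)
      stats::setNames(f$coefficients$t, f$coefficients$term)
    }, error = function(e) {
      warning("channel ", ch, " fit failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(tmap) && !is.null(t_ch))
      tmap <- matrix(NA_real_, length(t_ch), n_ch,
                     dimnames = list(names(t_ch),
                                     colnames(channel_values)))
    if (!is.null(t_ch)) tmap[names(t_ch), ch] <- t_ch
  }
  if (is.null(tmap)) stop("mixed model failed at every channel")
  tmap
}

#' Paired-t topographic map
#'
#' Per-channel dependent t-statistic of the condition difference across
#' participants. A channel with zero difference variance but a non-zero
#' mean difference receives a large finite capped value (flagged via the
#' `"capped"` attribute) rather than an infinity.
#'
#' @param diffs participants x channels matrix of condition differences
#'   (condition 2 minus condition 1), or a 3-d array
#'   participants x channels x 2 of condition means.
#' @param cap magnitude assigned to zero-variance channels.
#' @return per-channel T vector; attribute `"capped"` marks degenerate
#'   channels.
#' @export
paired_t_tmap <- function(diffs, cap = 1e6) {
  if (length(dim(diffs)) == 3L) {
    stopifnot(dim(diffs)[3L] == 2L)
    diffs <- diffs[, , 2L] - diffs[, , 1L]
  }
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2L) stop("paired t needs at least 2 participants")
  m <- colMeans(diffs)
  s <- apply(diffs, 2L, stats::sd)
  t <- m / (s / sqrt(n))
  capped <- s == 0
  t[capped & m != 0] <- sign(m[capped & m != 0]) * cap
  t[capped & m == 0] <- 0
  attr(t, "capped") <- capped
  t
}

#' Family-wise corrected p-values from permutation maxima
#'
#' One null distribution is built from the maximum absolute enhanced
#' statistic over channels within each permutation; each channel's
#' p-value is the proportion of null maxima at or above its observed
#' absolute value. The default add-one correction `(1 + count)/(n + 1)`
#' keeps p-values strictly positive; `add_one = FALSE` gives the raw
#' proportion.
#'
#' @param observed_enhanced enhanced observed map (per channel).
#' @param null_enhanced n_perm x channels matrix of enhanced permutation
#'   maps, or a vector of precomputed per-permutation maxima.
#' @param add_one use the add-one correction.
#' @return list with `p` (per channel) and `null_max`.
#' @export
max_perm_pvalues <- function(observed_enhanced, null_enhanced,
                             add_one = TRUE) {
  null_max <- if (is.matrix(null_enhanced))
    apply(abs(null_enhanced), 1L, max, na.rm = TRUE)
  else as.numeric(null_enhanced)
  n_perm <- length(null_max)
  if (n_perm < 100L) stop("need at least 100 permutations")
  cnt <- vapply(abs(observed_enhanced),
                function(o) sum(null_max >= o), 0)
  p <- if (add_one) (1 + cnt) / (n_perm + 1) else cnt / n_perm
  list(p = p, null_max = null_max)
}

#' Paired-condition topographic test with TFCE and sign-flip permutation
#'
#' Computes the observed paired-t map over channels, enhances it with
#' TFCE, builds the null by flipping the sign of each participant's
#' difference map (the within-subject exchangeability under no condition
#' effect), and corrects family-wise with the max-statistic rule.
#'
#' @param diffs participants x channels matrix of condition differences,
#'   or a participants x channels x 2 array of condition means.
#' @param adj [channel_adjacency()].
#' @param n_perm number of sign-flip permutations.
#' @param E,H TFCE exponents.
#' @param seed RNG seed.
#' @param add_one add-one p-value correction.
#' @return object of class `spd_topo_result`: `observed_t`, `tfce_map`,
#'   `p_corrected`, `null_max`, `n_perm`.
#' @export
topo_paired_test <- function(diffs, adj, n_perm = 2500, E = 0.5, H = 2,
                             seed = NULL, add_one = TRUE) {
  if (length(dim(diffs)) == 3L) diffs <- diffs[, , 2L] - diffs[, , 1L]
  diffs <- as.matrix(diffs)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(diffs)
  obs_t <- paired_t_tmap(diffs)
  obs_e <- tfce(as.numeric(obs_t), adj, E = E, H = H)
  sumsq <- colSums(diffs^2)        # invariant under sign flips
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    m <- colMeans(diffs * s)
    sd_p <- sqrt(pmax(sumsq - n * m^2, 0) / (n - 1))
    t_p <- ifelse(sd_p > 0, m / (sd_p / sqrt(n)), 0)
    null_max[i] <- max(abs(tfce(t_p, adj, E = E, H = H)))
  }
  mp <- max_perm_pvalues(obs_e, null_max, add_one = add_one)
  structure(list(observed_t = obs_t, tfce_map = obs_e, p_corrected = mp$p,
                 null_max = mp$null_max, n_perm = n_perm),
            class = "spd_topo_result")
}

#' Channel-space mixed-model test with TFCE and max-permutation correction
#'
#' The full topographic pipeline for individual-spindle data: per-channel
#' mixed-model T-maps for each term of interest, factor relabelling
#' according to the within-/between-subject permutation schemes, TFCE
#' enhancement, and family-wise correction from the per-permutation
#' maximum enhanced statistic.
#'
#' @param tbl data.frame of individual spindles.
#' @param channel_values events x channels dependent matrix.
#' @param terms fixed-effect terms of the per-channel model.
#' @param test_terms coefficient names whose maps are tested (default: all
#'   non-intercept coefficients).
#' @param schemes [permutation_scheme()] or list of them.
#' @param adj [channel_adjacency()].
#' @param n_perm number of relabelled datasets.
#' @param grouping participant column.
#' @param E,H TFCE exponents.
#' @param seed RNG seed.
#' @param add_one add-one p-value correction.
#' @return named list (one `spd_topo_result` per tested term).
#' @export
topo_lmm_test <- function(tbl, channel_values, terms, test_terms = NULL,
                          schemes, adj, n_perm = 2500,
                          grouping = "participant", E = 0.5, H = 2,
                          seed = NULL, add_one = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  obs <- channelwise_lmm_tmap(tbl, channel_values, terms, grouping)
  if (is.null(test_terms))
    test_terms <- setdiff(rownames(obs), "(Intercept)")
  missing <- setdiff(test_terms, rownames(obs))
  if (length(missing)) stop("term(s) not in the model: ",
                            paste(missing, collapse = ", "))
  null_max <- matrix(NA_real_, n_perm, length(test_terms),
                     dimnames = list(NULL, test_terms))
  for (i in seq_len(n_perm)) {
    ptbl <- permute_table(tbl, schemes, participant = grouping)
    pt <- suppressWarnings(
      channelwise_lmm_tmap(ptbl, channel_values, terms, grouping))
    for (tm in test_terms) {
      row <- pt[tm, ]
      row[!is.finite(row)] <- 0
      null_max[i, tm] <- max(abs(tfce(row, adj, E = E, H = H)))
    }
  }
  out <- lapply(test_terms, function(tm) {
    o <- obs[tm, ]
    oe <- tfce(ifelse(is.finite(o), o, 0), adj, E = E, H = H)
    mp <- max_perm_pvalues(oe, null_max[, tm], add_one = add_one)
    structure(list(observed_t = o, tfce_map = oe, p_corrected = mp$p,
                   null_max = mp$null_max, n_perm = n_perm),
              class = "spd_topo_result")
  })
  names(out) <- test_terms
  out
}

#' @exportS3Method base::print
print.spd_topo_result <- function(x, ...) {
  cat(sprintf("<spd_topo_result> %d channels, %d permutations; %d significant at p < 0.05\n",
              length(x$p_corrected), x$n_perm, sum(x$p_corrected < 0.05)))
  invisible(x)
}
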