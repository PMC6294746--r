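#' Azimuthal (polar) projection of sensor positions
#'
#' Projects unit-sphere sensor positions to the plane with an azimuthal
#' equidistant projection about the vertex (+z): radial distance equals the
#' arc length from the vertex, so distances near the top of the head are
#' preserved. Axes follow the montage convention x = right, y = anterior.
#'
#' @param positions channels x 3 matrix of unit-sphere xyz.
#' @return channels x 2 matrix of projected coordinates.
#' @export
project_scalp <- function(positions) {
  positions <- as.matrix(positions)
  z <- pmin(1, pmax(-1, positions[, 3L]))
  theta <- acos(z)
  rho <- sqrt(positions[, 1L]^2 + positions[, 2L]^2)
  ux <- ifelse(rho > 1e-12, positions[, 1L] / rho, 0)
  uy <- ifelse(rho > 1e-12, positions[, 2L] / rho, 0)
  cbind(x = theta * ux, y = theta * uy)
}

#' Build the 3x3 grid of canonical scalp regions
#'
#' Places 9 seed points on a regular 3 x 3 grid in the azimuthal projection
#' of the scalp (rows anterior/central/posterior, columns left/mid/right)
#' and assigns every channel within `radius_frac` of the projected head
#' radius to its nearest seed. Channels farther than that from every seed
#' stay unassigned, which keeps the regions compact and non-touching.
#'
#' @param positions channels x 3 unit-sphere sensor positions.
#' @param radius_frac assignment radius as a fraction of the projected head
#'   radius; at the default grid spacing of 0.5 the regions cannot touch
#'   for any value below 0.25.
#' @param head_radius projected head radius used to place the seeds; by
#'   default the largest projected sensor distance from the vertex.
#' @param labels optional channel labels.
#' @return object of class `spd_regions`: list with `assignment` (integer
#'   region id 1..9 or `NA` per channel), `seeds` (9 x 2 projected
#'   coordinates), `row_labels`, `col_labels`, `region_names`,
#'   `midline_ids`, `frontal_ids`, `posterior_ids`, `labels`.
#' @export
build_grid_regions <- function(positions, radius_frac = 0.25,
                               head_radius = NULL, labels = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 9L) stop("need at least 9 channels to build 9 regions")
  if (is.null(labels)) labels <- rownames(positions)
  if (is.null(labels)) labels <- paste0("E", seq_len(nrow(positions)))
  pr <- project_scalp(positions)
  R <- if (is.null(head_radius)) max(sqrt(rowSums(pr^2))) else head_radius
  grid <- expand.grid(col = c(-0.5, 0, 0.5), row = c(0.5, 0, -0.5))
  seeds <- cbind(x = grid$col * R, y = grid$row * R)
  rows <- rep(c("frontal", "central", "posterior"), each = 3L)
  cols <- rep(c("left", "mid", "right"), times = 3L)
  d2 <- outer(rowSums(pr^2), rep(1, 9L)) - 2 * pr %*% t(seeds) +
    outer(rep(1, nrow(pr)), rowSums(seeds^2))
  nearest <- max.col(-d2, ties.method = "first")
  dist_near <- sqrt(d2[cbind(seq_len(nrow(pr)), nearest)])
  assignment <- ifelse(dist_near <= radius_frac * R, nearest, NA_integer_)
  empty <- setdiff(1:9, unique(stats::na.omit(assignment)))
  if (length(empty))
    stop("empty region(s): ", paste(paste(rows[empty], cols[empty]), collapse = ", "))
  structure(list(assignment = as.integer(assignment), seeds = seeds,
                 row_labels = rows, col_labels = cols,
                 region_names = paste(rows, cols, sep = "_"),
                 midline_ids = which(cols == "mid"),
                 frontal_ids = which(rows == "frontal"),
                 posterior_ids = which(rows == "posterior"),
                 labels = labels),
            class = "spd_regions")
}

#' @exportS3Method base::print
print.spd_regions <- function(x, ...) {
  cnt <- tabulate(x$assignment, 9L)
  cat("<spd_regions> 3x3 grid;", sum(!is.na(x$assignment)), "of",
      length(x$assignment), "channels assigned\n")
  cat(sprintf("  %-18s %d channels\n", x$region_names, cnt), sep = "")
  invisible(x)
}

#' Serialize a region set to JSON (region name -> channel labels)
#'
#' @param rs an `spd_regions` object.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
regions_to_json <- function(rs, path = NULL) {
  lst <- lapply(1:9, function(k) rs$labels[which(rs$assignment == k)])
  names(lst) <- rs$region_names
  js <- jsonlite::toJSON(lst, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Compute canonical (region-mean) time series
#'
#' Row k of the result is the arithmetic mean over the member channels of
#' region k at every sample. These 9 traces carry the initial spindle
#' detection: averaging boosts the signal-to-noise ratio of spindles, which
#' are spatially coherent within a region, relative to channel noise.
#'
#' @param r a [recording()].
#' @param rs regions from [build_grid_regions()].
#' @return object of class `spd_canonical`: list with `data` (9 x samples),
#'   `fs`, `regions`.
#' @export
compute_canonical_series <- function(r, rs) {
  stopifnot(inherits(r, "spd_recording"), inherits(rs, "spd_regions"))
  idx <- match(rs$labels, r$labels)
  if (anyNA(idx)) stop("region channel(s) absent from recording: ",
                       paste(rs$labels[is.na(idx)], collapse = ", "))
  out <- matrix(0, 9L, ncol(r$data),
                dimnames = list(rs$region_names, NULL))
  for (k in 1:9) {
    members <- idx[which(rs$assignment == k)]
    out[k, ] <- colMeans(r$data[members, , drop = FALSE])
  }
  structure(list(data = out, fs = r$fs, regions = rs), class = "spd_canonical")
}
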