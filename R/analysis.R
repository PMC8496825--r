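#' Population-vector decoding
#'
#' Decodes the represented head direction from a rate vector as the
#' firing-rate-weighted circular mean of the preferred directions:
#' `atan2(sum(f sin), sum(f cos))`, in degrees in \[-180, 180).
#'
#' @param rates firing-rate vector.
#' @param preferred_dirs preferred directions in degrees, same length.
#' @return decoded direction in degrees.
#' @export
#' @examples
#' population_vector(c(0, 1, 0, 0), c(0, 90, 180, -90))
population_vector <- function(rates, preferred_dirs) {
  stopifnot(length(rates) == length(preferred_dirs))
  s <- sum(rates * sin(deg2rad(preferred_dirs)))
  c <- sum(rates * cos(deg2rad(preferred_dirs)))
  if (sqrt(s^2 + c^2) < 1e-9 * max(sum(abs(rates)), 1e-12) ||
      all(rates == 0)) {
    stop("undefined decode: zero resultant (silent or perfectly symmetric rates)")
  }
  atan2(s, c) * 180 / pi
}

#' Tuning-curve representation map
#'
#' Builds the per-cell tuning matrix from a test-phase rate log aligned to
#' the true head direction: the mean rate of each cell in each HD bin, plus
#' the recruited-cell flags at threshold `epsilon`.
#'
#' @param rate_log `n_steps x n_cells` rate matrix.
#' @param true_hd true-HD series in degrees, length `n_steps`.
#' @param bins number of HD bins over \[-180, 180).
#' @param epsilon recruitment threshold.
#' @return an object of class `hd_representation`: list with `tuning`
#'   (`n_cells x bins` matrix), `bin_centers`, `recruited`, `epsilon`.
#' @export
build_representation <- function(rate_log, true_hd, bins = 360,
                                 epsilon = 0.5) {
  stopifnot(nrow(rate_log) == length(true_hd))
  idx <- floor((wrap_angle(true_hd) + 180) / (360 / bins)) + 1
  idx[idx > bins] <- bins
  n_cells <- ncol(rate_log)
  tuning <- matrix(0, n_cells, bins)
  counts <- tabulate(idx, bins)
  for (b in which(counts > 0)) {
    rows <- idx == b
    tuning[, b] <- colMeans(rate_log[rows, , drop = FALSE])
  }
  # recruitment judged on the binned tuning itself, so recruited cells
  # always have at least one supra-threshold bin (lobe)
  peak <- apply(tuning, 1, max)
  recruited <- which(peak >= epsilon & peak > 0)
  # union coverage: the strongest momentary rate over recruited cells per
  # bin. Distinguishes a direction no recruited cell ever encodes from a
  # bin that merely straddles a winner handover.
  union_peak <- rep(0, bins)
  if (length(recruited) > 0) {
    step_max <- do.call(pmax, c(as.data.frame(
      rate_log[, recruited, drop = FALSE]), list(0)))
    for (b in which(counts > 0)) {
      union_peak[b] <- max(step_max[idx == b])
    }
  }
  structure(
    list(
      tuning = tuning,
      bin_centers = -180 + (seq_len(bins) - 0.5) * 360 / bins,
      counts = counts,
      recruited = recruited,
      union_peak = union_peak,
      coverage = mean(union_peak >= epsilon),
      epsilon = epsilon
    ),
    class = "hd_representation"
  )
}

#' @export
print.hd_representation <- function(x, ...) {
  cat(sprintf("<hd_representation> %d cells x %d bins, %d recruited (eps = %g)\n",
              nrow(x$tuning), ncol(x$tuning), length(x$recruited), x$epsilon))
  invisible(x)
}

#' @export
plot.hd_representation <- function(x, main = "aLB representation", ...) {
  rec <- x$recruited
  if (length(rec) == 0) rec <- seq_len(nrow(x$tuning))
  m <- x$tuning[rec, , drop = FALSE]
  ord <- order(apply(m, 1, which.max))
  graphics::image(
    x = x$bin_centers, y = seq_along(rec), z = t(m[ord, , drop = FALSE]),
    xlab = "true HD (deg)", ylab = "recruited cell (sorted)", main = main,
    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...
  )
  invisible(x)
}

#' Jaccard similarity of recruited-cell sets
#'
#' Intersection over union of two sets of cell ids; 1 for identical
#' non-empty sets, 0 for disjoint sets. Two empty sets give 0 (a silent
#' population carries no similarity evidence).
#'
#' @param set_a,set_b vectors of cell ids.
#' @return scalar in \[0, 1\].
#' @export
iou <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Signed circular heading error
#'
#' Per-sample error `wrap(decoded - true)` in \[-180, 180); returns the
#' circular mean and the standard error of the mean (from the circular
#' deviations around the mean).
#'
#' @param decoded decoded HD series in degrees.
#' @param true_hd true HD series in degrees, same length.
#' @return named numeric vector `c(mean = , sem = )`.
#' @export
heading_error <- function(decoded, true_hd) {
  stopifnot(length(decoded) == length(true_hd))
  err <- circ_diff(decoded, true_hd)
  m <- circ_mean(err)
  if (is.na(m)) m <- 180 # antipodal resultant; pick the boundary value
  dev <- circ_diff(err, m)
  sem <- stats::sd(dev) / sqrt(length(dev))
  if (is.na(sem)) sem <- 0
  c(mean = m, sem = sem)
}

#' Lobe count of a circular tuning curve
#'
#' Counts maximal contiguous circular runs of bins at or above `epsilon`.
#' A cell is unimodal iff it has exactly one lobe.
#'
#' @param tuning_row rates per HD bin (circular).
#' @param epsilon rate threshold.
#' @return list with `n_lobes` and `is_unimodal`.
#' @export
unimodality_score <- function(tuning_row, epsilon = 0.5) {
  above <- tuning_row >= epsilon
  if (!any(above)) return(list(n_lobes = 0L, is_unimodal = FALSE))
  if (all(above)) return(list(n_lobes = 1L, is_unimodal = TRUE))
  prev <- c(above[length(above)], above[-length(above)])
  n <- sum(above & !prev)
  list(n_lobes = as.integer(n), is_unimodal = n == 1L)
}

#' Weight-convergence diagnostics
#'
#' For each snapshot, the Euclidean distance between the flattened snapshot
#' and final weights and their Pearson correlation (0 when undefined).
#'
#' @param snapshots list of weight matrices (or lists of matrices).
#' @param final the final weights, same shape as each snapshot.
#' @return data frame with columns `distance` and `correlation`.
#' @export
weight_convergence <- function(snapshots, final) {
  fvec <- unlist(final, use.names = FALSE)
  res <- t(vapply(snapshots, function(s) {
    svec <- unlist(s, use.names = FALSE)
    if (length(svec) != length(fvec)) {
      stop("snapshot shape does not match final weights")
    }
    d <- sqrt(sum((svec - fvec)^2))
    r <- if (stats::sd(svec) == 0 || stats::sd(fvec) == 0) {
      0
    } else {
      stats::cor(svec, fvec)
    }
    c(distance = d, correlation = r)
  }, numeric(2)))
  as.data.frame(res)
}

#' Preferred-direction shift between two representations
#'
#' The circular mean, over cells recruited in both representations, of the
#' signed shift in tuning-curve peak position. Used to quantify how HD
#' firing fields move after a scene manipulation.
#'
#' @param rep_before,rep_after `hd_representation` objects on the same bins.
#' @param cells optional cell ids to compare (default: all cells).
#' @return mean signed shift in degrees (anticlockwise positive).
#' @export
field_shift <- function(rep_before, rep_after, cells = NULL) {
  stopifnot(ncol(rep_before$tuning) == ncol(rep_after$tuning))
  if (is.null(cells)) cells <- seq_len(nrow(rep_before$tuning))
  pk_b <- rep_before$bin_centers[apply(rep_before$tuning[cells, , drop = FALSE], 1, which.max)]
  pk_a <- rep_after$bin_centers[apply(rep_after$tuning[cells, , drop = FALSE], 1, which.max)]
  active <- apply(rep_before$tuning[cells, , drop = FALSE], 1, max) > 0 &
    apply(rep_after$tuning[cells, , drop = FALSE], 1, max) > 0
  circ_mean(circ_diff(pk_a[active], pk_b[active]))
}
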