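# Intra-colony location statistics: normalized centroid distances,
# normalized mutual distances, the Monte-Carlo uniform-repopulation null
# model, two-sample Kolmogorov-Smirnov testing and the final
# PREFERENTIAL / INNER-OUTER / CLUSTERED classification.
#
# The radial normalization maps each colony onto a unit circle: a cell at
# position P with colony centroid C gets delta = |P - C| / |b - C| where b
# is the colony edge point on the semirect from C through P, so delta = 0
# at the centroid and 1 at the edge whatever the colony's shape.

#' Euclidean distance(s) to the colony centroid
#'
#' @param P numeric vector `c(x, y)` or an n x 2 matrix of positions.
#' @param C centroid `c(x, y)`.
#' @return numeric vector of distances.
#' @export
distance_to_centroid <- function(P, C) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 2)
  sqrt((P[, 1] - C[1])^2 + (P[, 2] - C[2])^2)
}

#' Edge point on the centroid-to-cell semirect
#'
#' Among all boundary points `E`, selects the one maximizing the cosine
#' similarity between `b - C` and `P - C`; ties (within 1e-12) are broken
#' by the largest `|b - C|` (outermost).  Vectorized over rows of `P`.
#'
#' @param C colony centroid `c(x, y)`.
#' @param P position `c(x, y)` or n x 2 matrix; no row may equal `C`
#'   (callers must short-circuit cells at the centroid to `delta = 0`).
#' @param E m x 2 matrix of boundary points (columns x, y).
#' @return list with `b` (n x 2 matrix of edge points) and `D` (numeric
#'   vector of centroid-to-edge distances, Euclidean).
#' @export
edge_intersection <- function(C, P, E) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 2)
  stopifnot(nrow(E) >= 1)
  U <- cbind(P[, 1] - C[1], P[, 2] - C[2])
  un <- sqrt(U[, 1]^2 + U[, 2]^2)
  if (any(un < 1e-12))
    stop("edge_intersection is undefined for a cell at the centroid")
  U <- U / un
  B <- cbind(E[, 1] - C[1], E[, 2] - C[2])
  bn <- sqrt(B[, 1]^2 + B[, 2]^2)
  bn_safe <- pmax(bn, 1e-12)
  S <- U %*% t(B / bn_safe)              # n x m cosine similarities
  # break exact cosine ties toward the outermost boundary point by a bias
  # (~1e-9) far below the boundary's angular resolution in cosine units
  S <- S + rep(1e-9 * bn / max(bn), each = nrow(S))
  win <- max.col(S, ties.method = "first")
  list(b = E[win, , drop = FALSE], D = bn[win])
}

#' Normalized centroid distance
#'
#' @param d distance(s) from the centroid.
#' @param D centroid-to-edge distance(s) along the same ray (> 0).
#' @return `min(d / D, 1)`; the clamp absorbs discretization overshoot of
#'   the pixelated boundary.
#' @export
normalize_distance <- function(d, D) {
  if (any(D <= 0)) stop("degenerate colony: centroid-to-edge distance is 0")
  pmin(d / D, 1)
}

#' Truncate unreliable edge-extremity distances
#'
#' Removes normalized distances at or above `lower_cut`.  Segmentation
#' tends to overshoot slightly beyond the real colony edge, making the
#' extreme-delta observations unreliable; the same cut must be applied to
#' real and null samples.
#'
#' @param deltas numeric vector of normalized distances.
#' @param lower_cut cut point in (0, 1).
#' @return the filtered vector.
#' @export
truncate_extremes <- function(deltas, lower_cut = 0.95) {
  stopifnot(lower_cut > 0, lower_cut < 1)
  deltas[deltas < lower_cut]
}

#' Normalized mutual distances of the cells in one colony
#'
#' All `n (n - 1) / 2` unordered pair distances, each divided by the
#' colony's major-axis length `M`.
#'
#' @param points n x 2 matrix of cell positions (columns x, y).
#' @param M colony major-axis length in pixels (> 0).
#' @return data frame with columns `i`, `j` (1-based cell indices, i < j),
#'   `m_px`, `mhat`; empty (zero rows) when fewer than 2 cells.
#' @export
mutual_distances <- function(points, M) {
  stopifnot(M > 0)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  n <- nrow(points)
  if (n < 2)
    return(data.frame(i = integer(), j = integer(),
                      m_px = numeric(), mhat = numeric()))
  d <- as.vector(stats::dist(points))
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # (row > col)
  ord <- order(ij[, 2], ij[, 1])
  data.frame(i = ij[ord, 2], j = ij[ord, 1],
             m_px = d[ord], mhat = d[ord] / M)
}

#' Monte-Carlo null points inside a colony
#'
#' Repopulates the colony with location-indifferent points: uniform
#' real-valued coordinate pairs are drawn in the colony's bounding box and
#' draws falling outside the mask are discarded, until
#' `multiplier * n_real` points are retained.  Deterministic for a fixed
#' seed.
#'
#' @param colony a `colony` object (needs `mask` and `bbox`).
#' @param n_real number of real detections in the colony (>= 1).
#' @param multiplier null-to-real ratio (default 10).
#' @param seed integer seed.
#' @return `multiplier * n_real` x 2 matrix (columns x, y) of points on
#'   mask pixels.
#' @export
generate_null_points <- function(colony, n_real, multiplier = 10, seed = 1L) {
  stopifnot(n_real >= 1, multiplier >= 1)
  mask <- colony$mask
  bb <- colony$bbox
  if (!any(mask)) stop("colony mask is empty")
  target <- as.integer(multiplier * n_real)
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    drawn <- 0
    batch <- max(4L * target, 256L)
    repeat {
      cx <- runif(batch, bb["x_min"] - 0.5, bb["x_max"] + 0.5)
      cy <- runif(batch, bb["y_min"] - 0.5, bb["y_max"] + 0.5)
      drawn <- drawn + batch
      ok <- mask_contains(mask, cx, cy)
      xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
      if (length(xs) >= target) break
      if (drawn > 1e4 && length(xs) / drawn < 1e-3)
        stop("null sampling acceptance rate below 1e-3: pathological ",
             "colony mask relative to its bounding box")
    }
    cbind(x = xs[seq_len(target)], y = ys[seq_len(target)])
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over pooled sample points of the absolute
#' difference of the two empirical CDFs.  The p-value uses the asymptotic
#' Kolmogorov distribution with effective size
#' `n_eff = n_a n_b / (n_a + n_b)`:
#' `p = 2 sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2)` with
#' `lambda = (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) D`, truncated at
#' 100 terms and clamped to `[0, 1]`.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list of class `ks_result` with `statistic`, `p_value`, `n_a`,
#'   `n_b`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  n_a <- length(sample_a); n_b <- length(sample_b)
  if (n_a == 0 || n_b == 0) stop("both samples must be non-empty")
  pooled <- sort(unique(c(sample_a, sample_b)))
  Fa <- findInterval(pooled, sort(sample_a)) / n_a
  Fb <- findInterval(pooled, sort(sample_b)) / n_b
  D <- max(abs(Fa - Fb))
  n_eff <- n_a * n_b / (n_a + n_b)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  if (lambda < 0.05) {
    # truncated alternating series is numerically meaningless here;
    # the lambda -> 0 limit of the Kolmogorov tail is 1
    p <- 1
  } else {
    k <- seq_len(100)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  structure(list(statistic = D, p_value = p, n_a = n_a, n_b = n_b),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.3g (n = %d vs %d)\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Moving-average smoothing of a distribution curve
#'
#' Centered moving average of odd window size; edge bins average over
#' their available neighbours (shrinking window).  Intended for the
#' plotted/reported density curves only: significance testing always runs
#' on the raw samples.
#'
#' @param histogram numeric vector of bin heights.
#' @param window odd window size >= 1.
#' @return smoothed vector of the same length.
#' @export
smooth_distribution <- function(histogram, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(histogram)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(histogram[lo:hi])
  }, numeric(1))
}

#' Classify an intra-colony location pattern
#'
#' Runs the two KS tests (real vs null normalized centroid distances;
#' real vs null normalized mutual distances) and assigns the labels:
#' \itemize{
#'   \item `PREFERENTIAL` iff the centroid-distance KS p-value is below
#'     `alpha`, else `NON_PREFERENTIAL`;
#'   \item sub-label `INNER` (`OUTER`) when preferential and the real mean
#'     delta is below (above) the null mean; `NONE` otherwise;
#'   \item `CLUSTERED` iff the mutual-distance KS p-value is below `alpha`
#'     *and* the real mean normalized mutual distance is below the null
#'     mean (a significant difference with larger distances indicates
#'     over-dispersion, which keeps the `NON_CLUSTERED` label with a
#'     diagnostic note).
#' }
#' Truncation of edge-extremity deltas must already have been applied to
#' both delta samples (see [truncate_extremes()]).
#'
#' @param real_deltas,null_deltas truncated normalized centroid distances,
#'   pooled across colonies.
#' @param real_mhat,null_mhat normalized mutual distances, pooled across
#'   colonies (may be empty when colonies hold fewer than 2 cells; the
#'   cluster label is then `NON_CLUSTERED` with a note).
#' @param alpha significance level (default 0.001).
#' @param truncation_interval the `(lower_cut, 1]` interval removed from
#'   the delta samples (recorded in the report).
#' @param smoothing_window window recorded for reported curves (default 3).
#' @return a list of class `location_report`.
#' @export
classify_location <- function(real_deltas, null_deltas, real_mhat,
                              null_mhat, alpha = 0.001,
                              truncation_interval = c(0.95, 1),
                              smoothing_window = 3) {
  stopifnot(length(real_deltas) >= 1, length(null_deltas) >= 1)
  notes <- character(0)
  if (length(real_deltas) < 30)
    notes <- c(notes, paste0(
      "only ", length(real_deltas), " pooled real observations; the KS ",
      "test is reliable from a few hundred samples upward"))
  centroid_ks <- ks_two_sample(real_deltas, null_deltas)
  preferential <- centroid_ks$p_value < alpha
  label_location <- if (preferential) "PREFERENTIAL" else "NON_PREFERENTIAL"
  label_radial <- "NONE"
  if (preferential) {
    label_radial <- if (mean(real_deltas) < mean(null_deltas)) "INNER"
                    else "OUTER"
  }
  if (length(real_mhat) >= 1 && length(null_mhat) >= 1) {
    mutual_ks <- ks_two_sample(real_mhat, null_mhat)
    sig <- mutual_ks$p_value < alpha
    smaller <- mean(real_mhat) < mean(null_mhat)
    label_cluster <- if (sig && smaller) "CLUSTERED" else "NON_CLUSTERED"
    if (sig && !smaller)
      notes <- c(notes, paste0(
        "mutual distances differ significantly from the null but are ",
        "larger on average (over-dispersion); labeled NON_CLUSTERED"))
  } else {
    mutual_ks <- NULL
    label_cluster <- "NON_CLUSTERED"
    notes <- c(notes, "no mutual distances available (colonies with < 2 cells)")
  }
  structure(list(
    alpha = alpha,
    centroid_ks = centroid_ks,
    mutual_ks = mutual_ks,
    mean_delta_real = mean(real_deltas),
    mean_delta_null = mean(null_deltas),
    mean_mhat_real = if (length(real_mhat)) mean(real_mhat) else NA_real_,
    mean_mhat_null = if (length(null_mhat)) mean(null_mhat) else NA_real_,
    label_location = label_location,
    label_radial = label_radial,
    label_cluster = label_cluster,
    truncation_interval = truncation_interval,
    smoothing_window = smoothing_window,
    n_real = length(real_deltas),
    n_null = length(null_deltas),
    notes = notes
  ), class = "location_report")
}

#' @export
print.location_report <- function(x, ...) {
  cat("Intra-colony location report\n")
  cat(sprintf("  location: %s", x$label_location))
  if (x$label_radial != "NONE") cat(sprintf(" (%s)", x$label_radial))
  cat(sprintf("\n  cluster:  %s\n", x$label_cluster))
  cat(sprintf("  centroid-distance KS: D = %.4f, p = %.3g (n = %d real vs %d null)\n",
              x$centroid_ks$statistic, x$centroid_ks$p_value,
              x$n_real, x$n_null))
  if (!is.null(x$mutual_ks))
    cat(sprintf("  mutual-distance KS:   D = %.4f, p = %.3g\n",
                x$mutual_ks$statistic, x$mutual_ks$p_value))
  cat(sprintf("  mean delta: real %.3f vs null %.3f; alpha = %g\n",
              x$mean_delta_real, x$mean_delta_null, x$alpha))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Per-pixel normalized centroid distance of a mask
#'
#' The delta of every mask pixel center via the exact
#' [edge_intersection()] rule (`NA` outside the mask).  Used by the
#' phantom point sampler and by repeated statistical simulations, where
#' it is worth computing once per mask.
#'
#' @param mask logical matrix.
#' @return numeric matrix of deltas, `NA` off-mask.
#' @export
delta_map <- function(mask) {
  C <- mask_centroid(mask)
  E <- boundary_points(mask)
  idx <- which(mask, arr.ind = TRUE)
  P <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  d <- distance_to_centroid(P, C)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  ctr <- d < 1e-12
  res <- rep(0, nrow(P))
  if (any(!ctr)) {
    ei <- edge_intersection(C, P[!ctr, , drop = FALSE], E)
    res[!ctr] <- normalize_distance(d[!ctr], ei$D)
  }
  out[idx] <- res
  out
}

#' Compute location records for one colony
#'
#' For every cell, the centroid distance `d`, the edge point and
#' centroid-to-edge distance `D` on the same semirect, and the normalized
#' distance `delta` (cells exactly at the centroid short-circuit to
#' `delta = 0`).
#'
#' @param colony a `colony` object.
#' @param points n x 2 matrix of cell positions (columns x, y).
#' @return data frame `cell_id`, `x`, `y`, `d_px`, `D_px`, `delta`.
#' @export
location_records <- function(colony, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  n <- nrow(points)
  C <- colony$centroid
  d <- distance_to_centroid(points, C)
  D <- rep(NA_real_, n); delta <- rep(0, n)
  off <- d >= 1e-12
  if (any(off)) {
    ei <- edge_intersection(C, points[off, , drop = FALSE], colony$boundary)
    D[off] <- ei$D
    delta[off] <- normalize_distance(d[off], ei$D)
  }
  data.frame(cell_id = seq_len(n), x = points[, 1], y = points[, 2],
             d_px = d, D_px = D, delta = delta)
}

#' Pooled location analysis over a set of colonies
#'
#' The full statistical stage: per colony, computes real normalized
#' centroid distances and mutual distances, generates the 10x Monte-Carlo
#' null (per-colony seeds derived from `seed` and the colony label by a
#' fixed counter scheme, so colony order is irrelevant), pools across
#' colonies, truncates the delta samples, and classifies.
#'
#' @param colonies list of `colony` objects.
#' @param detections data frame with at least `colony_id`, `x`, `y`.
#' @param alpha significance level (default 0.001).
#' @param multiplier null-to-real point ratio (default 10).
#' @param lower_cut truncation cut for delta samples (default 0.95).
#' @param smoothing_window moving-average window for reported curves.
#' @param seed integer seed for the null generation.
#' @return a `location_report` with extra fields: `per_colony` (list of
#'   per-colony diagnostics), `records` (pooled real location records),
#'   `curves` (smoothed real/null delta histograms on 20 bins), and
#'   `seed`.
#' @export
analyze_locations <- function(colonies, detections, alpha = 0.001,
                              multiplier = 10, lower_cut = 0.95,
                              smoothing_window = 3, seed = 1L) {
  real_deltas <- numeric(0); null_deltas <- numeric(0)
  real_mhat <- numeric(0); null_mhat <- numeric(0)
  per_colony <- list(); rec_all <- list()
  for (col in colonies) {
    pts <- detections[!is.na(detections$colony_id) &
                        detections$colony_id == col$label, , drop = FALSE]
    n_real <- nrow(pts)
    if (n_real == 0) next
    P <- as.matrix(pts[, c("x", "y")])
    rec <- location_records(col, P)
    rec$colony_id <- col$label
    rec_all[[length(rec_all) + 1]] <- rec
    nullp <- generate_null_points(col, n_real, multiplier,
                                  derive_seed(seed, col$label))
    nrec <- location_records(col, nullp)
    rmut <- mutual_distances(P, col$major_axis_px)
    nmut <- mutual_distances(nullp, col$major_axis_px)
    real_deltas <- c(real_deltas, rec$delta)
    null_deltas <- c(null_deltas, nrec$delta)
    real_mhat <- c(real_mhat, rmut$mhat)
    null_mhat <- c(null_mhat, nmut$mhat)
    per_colony[[length(per_colony) + 1]] <- list(
      colony_id = col$label, n_real = n_real,
      n_null = nrow(nullp),
      mean_delta_real = mean(rec$delta),
      mean_delta_null = mean(nrec$delta))
  }
  if (length(real_deltas) == 0)
    stop("no detections fall inside any colony; nothing to analyze")
  rd <- truncate_extremes(real_deltas, lower_cut)
  nd <- truncate_extremes(null_deltas, lower_cut)
  if (length(rd) == 0 || length(nd) == 0)
    stop("truncation removed all delta observations (lower_cut = ",
         lower_cut, ")")
  rep <- classify_location(rd, nd, real_mhat, null_mhat, alpha,
                           truncation_interval = c(lower_cut, 1),
                           smoothing_window = smoothing_window)
  breaks <- seq(0, 1, length.out = 21)
  hr <- graphics::hist(rd, breaks = breaks, plot = FALSE)$density
  hn <- graphics::hist(nd, breaks = breaks, plot = FALSE)$density
  rep$curves <- list(
    breaks = breaks,
    real = smooth_distribution(hr, smoothing_window),
    null = smooth_distribution(hn, smoothing_window))
  rep$per_colony <- per_colony
  rep$records <- do.call(rbind, rec_all)
  rep$seed <- seed
  rep
}
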