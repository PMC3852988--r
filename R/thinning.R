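#' Average nearest neighbor statistic
#'
#' Classical (uncorrected) clustering diagnostic: the observed mean
#' distance from each point to its nearest neighbor, against the value
#' `0.5 / sqrt(n / A)` expected under complete spatial randomness over an
#' area `A`. A ratio below 1 indicates clustering, above 1 inhibition.
#'
#' @param points two-column matrix/data.frame of projected x, y in m.
#' @param area study area in m^2; when `NULL` the minimum bounding
#'   rectangle of the points is used.
#' @return list of class `ann_result`: `n`, `observed_mean_nn`,
#'   `expected_mean_nn`, `ratio`, `area_used`.
#' @export
ann_statistic <- function(points, area = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points")
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  observed <- mean(apply(d, 1, min))
  if (is.null(area)) {
    area <- diff(range(pts[, 1])) * diff(range(pts[, 2]))
  }
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  expected <- 0.5 / sqrt(n / area)
  structure(list(n = n, observed_mean_nn = observed,
                 expected_mean_nn = expected,
                 ratio = observed / expected, area_used = area),
            class = "ann_result")
}

#' @export
print.ann_result <- function(x, ...) {
  cat(sprintf(
    "<ann_result> n=%d observed=%.1f m expected=%.1f m ratio=%.3f\n",
    x$n, x$observed_mean_nn, x$expected_mean_nn, x$ratio))
  invisible(x)
}

#' Distance-based decimation of points
#'
#' Greedy single pass in a seeded random order: a point is kept iff it
#' lies at least `min_distance` from every point already kept. All
#' retained pairs are therefore `>= min_distance` apart; the result is
#' deterministic given the seed.
#'
#' @param points two-column matrix/data.frame of x, y in m.
#' @param min_distance minimum allowed pairwise distance, m (`>= 0`).
#' @param seed integer RNG seed for the visiting order.
#' @return matrix of retained points with attribute `kept` (row indices
#'   into the input).
#' @export
decimate <- function(points, min_distance, seed = 1L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (min_distance < 0) stop("min_distance must be >= 0")
  n <- nrow(pts)
  if (n == 0L || min_distance == 0) {
    out <- pts
    attr(out, "kept") <- seq_len(n)
    return(out)
  }
  ord <- local({
    set.seed(seed)
    sample.int(n)
  })
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept)) {
      kept <- i
      next
    }
    dd <- sqrt((pts[kept, 1] - pts[i, 1])^2 + (pts[kept, 2] - pts[i, 2])^2)
    if (all(dd >= min_distance)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  out <- pts[kept, , drop = FALSE]
  attr(out, "kept") <- kept
  out
}

#' Thin one month of sightings at the expected ANN distance
#'
#' Computes the average nearest neighbor statistic for the month's
#' locations and decimates them at the expected mean nearest-neighbor
#' distance. Months whose retained count would be at or below
#' `skip_threshold` (low sample sizes, as for October) are returned
#' unthinned with a `skipped` flag.
#'
#' @param points two-column matrix/data.frame of x, y in m.
#' @param area study area in m^2 (`NULL` = bounding rectangle).
#' @param seed integer seed for the decimation order.
#' @param skip_threshold retained-count threshold at or below which
#'   thinning is skipped (default 5).
#' @return list: `points` (retained), `ann` ([ann_statistic] result),
#'   `skipped` flag, `n_input`, `n_retained`, and `n_decimated` (the
#'   count decimation would have kept; equals `n_retained` when not
#'   skipped).
#' @export
thin_month <- function(points, area = NULL, seed = 1L, skip_threshold = 5L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 1) stop("need at least 1 point")
  if (n < 2) {
    return(list(points = pts, ann = NULL, skipped = TRUE,
                n_input = n, n_retained = n, n_decimated = n))
  }
  ann <- ann_statistic(pts, area)
  ret <- decimate(pts, ann$expected_mean_nn, seed)
  if (nrow(ret) <= skip_threshold) {
    return(list(points = pts, ann = ann, skipped = TRUE,
                n_input = n, n_retained = n, n_decimated = nrow(ret)))
  }
  list(points = ret, ann = ann, skipped = FALSE,
       n_input = n, n_retained = nrow(ret), n_decimated = nrow(ret))
}

pair_distance_matrix <- function(points) {
  as.matrix(stats::dist(as.matrix(points)[, 1:2, drop = FALSE]))
}

#' Binned Moran's I correlogram
#'
#' Moran's I with binary weights per distance bin: pairs whose separation
#' falls in `[lo, hi)` get weight 1. Under no spatial autocorrelation the
#' expectation is `-1/(n-1)`.
#'
#' @param points two-column matrix/data.frame of x, y in m.
#' @param values numeric vector, one value per point.
#' @param bin_edges increasing numeric vector of bin edges in m.
#' @return data.frame: `lo`, `hi`, `n_pairs`, `morans_i` (bins without
#'   pairs are omitted). Constant values yield `NA` with a warning.
#' @export
morans_i_correlogram <- function(points, values, bin_edges) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  if (length(values) != n) stop("values must match points")
  if (length(bin_edges) < 2 || is.unsorted(bin_edges))
    stop("bin_edges must be increasing with length >= 2")
  z <- values - mean(values)
  ss <- sum(z^2)
  const <- ss == 0
  if (const) warning("constant values: Moran's I undefined")
  d <- pair_distance_matrix(pts)
  res <- lapply(seq_len(length(bin_edges) - 1L), function(b) {
    w <- d >= bin_edges[b] & d < bin_edges[b + 1L]
    diag(w) <- FALSE
    np <- sum(w) / 2
    if (np == 0) return(NULL)
    I <- if (const) NA_real_ else
      (n / sum(w)) * sum(w * outer(z, z)) / ss
    data.frame(lo = bin_edges[b], hi = bin_edges[b + 1L],
               n_pairs = np, morans_i = I)
  })
  do.call(rbind, res)
}

#' Empirical semivariogram
#'
#' Per distance bin, the mean over pairs of half the squared value
#' difference.
#'
#' @inheritParams morans_i_correlogram
#' @return data.frame: `lo`, `hi`, `n_pairs`, `gamma` (empty bins
#'   omitted).
#' @export
semivariogram <- function(points, values, bin_edges) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  if (length(values) != n) stop("values must match points")
  if (length(bin_edges) < 2 || is.unsorted(bin_edges))
    stop("bin_edges must be increasing with length >= 2")
  d <- pair_distance_matrix(pts)
  sq <- 0.5 * outer(values, values, function(a, b) (a - b)^2)
  ut <- upper.tri(d)
  res <- lapply(seq_len(length(bin_edges) - 1L), function(b) {
    sel <- ut & d >= bin_edges[b] & d < bin_edges[b + 1L]
    np <- sum(sel)
    if (np == 0) return(NULL)
    data.frame(lo = bin_edges[b], hi = bin_edges[b + 1L], n_pairs = np,
               gamma = mean(sq[sel]))
  })
  do.call(rbind, res)
}
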