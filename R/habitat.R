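#' Percent of total area that is suitable
#'
#' @param suitable_area suitable habitat area (km^2).
#' @param total_area total study area (km^2), `> 0`.
#' @return percentage `100 * suitable_area / total_area`.
#' @export
percent_suitable <- function(suitable_area, total_area) {
  if (any(total_area <= 0)) stop("total_area must be positive")
  100 * suitable_area / total_area
}

#' Binary habitat from a suitability threshold
#'
#' A cell is suitable iff its cumulative score is at or above the
#' threshold (so threshold 0 marks everything suitable). Areas count
#' unmasked cells only, at `cell_size^2` per cell.
#'
#' @param map a [suitability_map] (the replicate-mean surface is used
#'   when present, else the single-fit cumulative surface).
#' @param threshold cumulative score in \[0, 100\], typically the maximum
#'   sensitivity+specificity value from [roc_auc].
#' @return list of class `habitat_summary`: `threshold`, `binary`
#'   (grid_layer of 0/1), `suitable_area`, `percent_suitable`,
#'   `total_area` (km^2).
#' @export
binarize <- function(map, threshold) {
  if (!inherits(map, "suitability_map")) stop("expected a suitability_map")
  if (threshold < 0 || threshold > 100)
    stop("threshold must lie in [0, 100]")
  g <- if (!is.null(map$replicate_mean)) map$replicate_mean else map$cumulative
  bin <- ifelse(is.na(g$values), NA_real_, as.numeric(g$values >= threshold))
  cell_km2 <- (g$cell_size / 1000)^2
  n_total <- sum(!is.na(bin))
  n_suit <- sum(bin == 1, na.rm = TRUE)
  suitable_area <- n_suit * cell_km2
  total_area <- n_total * cell_km2
  structure(
    list(threshold = threshold,
         binary = grid_layer(bin, g$x_origin, g$y_origin, g$cell_size,
                             g$crs_label),
         suitable_area = suitable_area,
         percent_suitable = percent_suitable(suitable_area, total_area),
         total_area = total_area),
    class = "habitat_summary")
}

#' @export
print.habitat_summary <- function(x, ...) {
  cat(sprintf(
    "<habitat_summary> threshold %.2f: %.0f of %.0f km^2 suitable (%.2f%%)\n",
    x$threshold, x$suitable_area, x$total_area, x$percent_suitable))
  invisible(x)
}

# sample distance correlation of two numeric vectors (Szekely's dCor):
# double-center the pairwise absolute-distance matrices, then
# dCor^2 = mean(A*B) / sqrt(mean(A*A) * mean(B*B))
dcor_vectors <- function(a, b) {
  n <- length(a)
  center <- function(v) {
    d <- abs(outer(v, v, "-"))
    rm_ <- rowMeans(d)
    d - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(d)
  }
  A <- center(a); B <- center(b)
  dvar_a <- mean(A * A); dvar_b <- mean(B * B)
  if (dvar_a <= 0 || dvar_b <= 0) return(0)
  dcov2 <- mean(A * B)
  sqrt(max(0, dcov2) / sqrt(dvar_a * dvar_b))
}

#' Brownian distance correlation between two suitability surfaces
#'
#' The sample distance correlation of the jointly unmasked cell values:
#' pairwise absolute-difference matrices of each surface are
#' double-centered and combined as `sqrt(dCov^2 / sqrt(dVarA * dVarB))`.
#' The coefficient lies in \[0, 1\], equals 1 for surfaces related by a
#' non-degenerate affine map, and 0 when either surface is constant; in
#' the population it is 0 exactly under independence.
#'
#' @param map_a,map_b co-registered [suitability_map]s (replicate-mean
#'   surfaces when present).
#' @return distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(map_a, map_b) {
  ga <- if (!is.null(map_a$replicate_mean)) map_a$replicate_mean else map_a$cumulative
  gb <- if (!is.null(map_b$replicate_mean)) map_b$replicate_mean else map_b$cumulative
  if (!grids_coregistered(ga, gb))
    stop("suitability maps are not co-registered")
  ok <- !is.na(ga$values) & !is.na(gb$values)
  if (sum(ok) < 2) stop("need at least 2 jointly unmasked cells")
  dcor_vectors(ga$values[ok], gb$values[ok])
}

#' Pairwise distribution comparison across months
#'
#' Symmetric matrix of Brownian distance correlation coefficients between
#' all pairs of monthly suitability surfaces; diagonal 1.
#'
#' @param maps named list of [suitability_map]s, length >= 2.
#' @return numeric matrix with dimnames from `names(maps)`.
#' @export
compare_months <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 months")
  nm <- names(maps)
  if (is.null(nm)) nm <- paste0("month", seq_along(maps))
  k <- length(maps)
  out <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    out[i, j] <- out[j, i] <- distance_correlation(maps[[i]], maps[[j]])
  }
  out
}
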