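# standardized smooth random field (sum of seeded Gaussian bumps),
# returned as an nr x nc matrix with mean ~0, sd ~1
smooth_field <- function(nr, nc, seed, n_bumps = 12L,
                         sigma_range = c(0.1, 0.3)) {
  set.seed(seed)
  cx <- stats::runif(n_bumps); cy <- stats::runif(n_bumps)
  amp <- stats::rnorm(n_bumps)
  sig <- stats::runif(n_bumps, sigma_range[1], sigma_range[2])
  xs <- (seq_len(nc) - 0.5) / nc
  ys <- (seq_len(nr) - 0.5) / nr
  f <- matrix(0, nr, nc)
  for (k in seq_len(n_bumps)) {
    gx <- exp(-(xs - cx[k])^2 / (2 * sig[k]^2))
    gy <- exp(-(ys - cy[k])^2 / (2 * sig[k]^2))
    f <- f + amp[k] * outer(gy, gx)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Synthetic basin-and-ledge bathymetry
#'
#' A seeded depth grid emulating the study domain: a shallow western
#' coastal margin (land interior masked, with a narrow unmasked
#' intertidal strip of negative depths so the 0 m shore contour exists),
#' a shelf deepening eastward, superimposed smooth ledges and a basin
#' exceeding 200 m, so the 0/50/100/150/200 m isobaths are all present.
#'
#' @param rows,cols grid dimensions, `>= 20` each.
#' @param cell_size cell side in m (default 2500, i.e. 6.25 km^2 cells).
#' @param seed integer RNG seed.
#' @return list: `depth` ([grid_layer], m positive down, land interior
#'   `NA`), `land` (logical matrix, above sea level).
#' @export
synth_bathymetry <- function(rows = 40L, cols = 50L, cell_size = 2500,
                             seed = 1L) {
  if (rows < 20 || cols < 20) stop("rows and cols must each be >= 20")
  xnorm <- (seq_len(cols) - 0.5) / cols
  ramp <- -15 + 300 * xnorm^1.15
  z <- matrix(rep(ramp, each = rows), rows, cols)
  bumps <- 32 * smooth_field(rows, cols, seed, n_bumps = 10L)
  # taper the bumps near the western shore so the intertidal strip survives
  taper <- pmin(1, 3 * xnorm)
  z <- z + sweep(bumps, 2, taper, "*")
  land <- z < 0
  z[z < -8] <- NA_real_  # land interior: no data
  depth <- grid_layer(z, 0, 0, cell_size, "synthetic-planar-m")
  list(depth = depth, land = land)
}

#' Synthetic chlorophyll-a and SST fields for a month
#'
#' Seeded smooth fields co-registered with the depth grid: chlorophyll-a
#' is a lognormal field with a month-shifted mean (late-summer maximum),
#' SST a north-south gradient plus smooth anomaly with monthly offsets
#' that cool from July through October.
#'
#' @param depth bathymetry [grid_layer] (its mask propagates).
#' @param month month name (July-October).
#' @param seed integer RNG seed.
#' @return list with `chl_a` (mg m^-3, strictly positive) and `sst` (deg
#'   C) grid_layers.
#' @export
synth_env <- function(depth, month, seed = 1L) {
  stopifnot_grid(depth)
  month <- match.arg(month, STUDY_MONTHS)
  d <- dim(depth$values)
  mseed <- seed * 17L + match(month, STUDY_MONTHS)
  chl_mu <- c(July = 2.5, August = 3.5, September = 3.0, October = 1.5)
  sst_mu <- c(July = 13.5, August = 15.0, September = 14.0, October = 10.5)
  f1 <- smooth_field(d[1], d[2], mseed, n_bumps = 14L)
  f2 <- smooth_field(d[1], d[2], mseed + 1000L, n_bumps = 14L)
  chl <- chl_mu[[month]] * exp(0.35 * f1 - 0.35^2 / 2)
  northing <- matrix(rep((d[1] - seq_len(d[1]) + 0.5) / d[1], d[2]),
                     d[1], d[2])
  sst <- sst_mu[[month]] - 1.6 * northing + 0.8 * f2
  na <- is.na(depth$values)
  chl[na] <- NA_real_; sst[na] <- NA_real_
  mk <- function(v) grid_layer(v, depth$x_origin, depth$y_origin,
                               depth$cell_size, depth$crs_label)
  list(chl_a = mk(chl), sst = mk(sst))
}

# full 10-layer stack for one month from a bathymetry grid, with a
# near-shore exclusion (depth <= exclusion_depth masked from modelling)
synth_stack <- function(bathy, month, seed = 1L, exclusion_depth = 0) {
  depth <- bathy$depth
  sa <- slope_aspect(depth)
  # aspect is undefined on flat cells; fill with 0 (north) so the
  # intersection mask reflects data coverage, not terrain flatness
  asp <- sa$aspect
  flat <- is.na(asp$values) & !is.na(sa$slope$values)
  asp$values[flat] <- 0
  dist <- lapply(c(0, 50, 100, 150, 200), function(l)
    distance_to_contour(depth, l))
  names(dist) <- c("dist_0", "dist_50", "dist_100", "dist_150", "dist_200")
  env <- synth_env(depth, month, seed)
  dmod <- depth
  dmod$values[!is.na(dmod$values) & dmod$values <= exclusion_depth] <- NA_real_
  env_stack(month, c(list(depth = dmod, aspect = asp, slope = sa$slope),
                     dist, env))
}

#' True raw suitability surface from known coefficients
#'
#' Builds a known-truth Gibbs density over the unmasked cells:
#' `raw ~ exp(sum coef_v * scaled_v)` with each named variable scaled to
#' \[0,1\] over unmasked cells, normalized to sum to 1. Zero coefficients
#' give the uniform truth.
#'
#' @param stack an [env_stack].
#' @param coefficients named numeric vector over predictor variables
#'   (missing names get coefficient 0).
#' @return [grid_layer] of true raw probability (sums to 1 over unmasked
#'   cells).
#' @export
synth_truth <- function(stack, coefficients = numeric(0)) {
  if (!is_env_stack(stack)) stop("expected an env_stack")
  cells <- stack_unmasked_cells(stack)
  env <- stack_env_matrix(stack, cells)
  eta <- numeric(length(cells))
  for (v in names(coefficients)) {
    if (!v %in% colnames(env)) stop("unknown variable: ", v)
    x <- env[, v]
    r <- range(x)
    sv <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
    eta <- eta + coefficients[[v]] * sv
  }
  w <- exp(eta - max(eta))
  values_to_grid(w / sum(w), cells, stack$layers$depth)
}

# smooth positive effort surface peaked near the western coast, emulating
# shore-based whale-watch survey effort
effort_field <- function(template, seed = 1L, strength = 3) {
  d <- dim(template$values)
  xnorm <- matrix(rep((seq_len(d[2]) - 0.5) / d[2], each = d[1]), d[1], d[2])
  f <- smooth_field(d[1], d[2], seed + 99L, n_bumps = 8L)
  e <- exp(-strength * xnorm + 0.4 * f)
  e[is.na(template$values)] <- NA_real_
  grid_layer(e, template$x_origin, template$y_origin, template$cell_size,
             template$crs_label)
}

#' Draw synthetic sightings from a truth surface
#'
#' Presence cells are drawn with probability proportional to
#' `truth * effort_bias` (uniform effort when no bias grid is given);
#' each presence is jittered uniformly within its cell so thinning
#' distances are continuous. Records carry `count = 1` each.
#'
#' @param truth [grid_layer] of raw probability (from [synth_truth]).
#' @param n number of presences, `>= 1`.
#' @param month month name for the records.
#' @param effort_bias optional co-registered effort [grid_layer].
#' @param seed integer RNG seed.
#' @param years year range to sample records from.
#' @return a `sighting_table` of `n` records.
#' @export
synth_sightings <- function(truth, n, month = "August", effort_bias = NULL,
                            seed = 1L, years = 2002:2011) {
  stopifnot_grid(truth)
  if (n < 1) stop("n must be >= 1")
  cells <- which(!is.na(truth$values))
  pr <- truth$values[cells]
  if (!is.null(effort_bias)) {
    if (!grids_coregistered(truth, effort_bias))
      stop("effort_bias not co-registered with truth")
    pr <- pr * effort_bias$values[cells]
  }
  pr <- pr / sum(pr)
  set.seed(seed)
  pick <- sample(cells, n, replace = TRUE, prob = pr)
  nr <- nrow(truth$values)
  row <- (pick - 1L) %% nr + 1L
  col <- (pick - 1L) %/% nr + 1L
  cs <- truth$cell_size
  x <- truth$x_origin + (col - 1L) * cs + stats::runif(n) * cs
  y <- truth$y_origin + (nr - row) * cs + stats::runif(n) * cs
  as_sighting_table(data.frame(
    x = x, y = y, year = sample(years, n, replace = TRUE), month = month,
    count = 1L,
    source = sample(c("whalewatch", "survey"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Default scenario configuration
#'
#' The generator's defaults mirror the study conditions: a domain of
#' 40 x 50 cells at 2.5 km (7539 km^2 of it modelled is approximated by
#' the unmasked portion), monthly presence counts 90/554/221/19 for
#' July-October, shore-biased sampling effort, and a truth surface
#' loading on distance to shore, the 150 m and 200 m isobaths,
#' chlorophyll-a and SST.
#'
#' @return named list of generator settings.
#' @export
scenario_defaults <- function() {
  list(rows = 40L, cols = 50L, cell_size = 2500,
       months = STUDY_MONTHS,
       monthly_n = c(July = 90L, August = 554L, September = 221L,
                     October = 19L),
       coefficients = c(dist_0 = -2.5, dist_150 = -4, dist_200 = -1.5,
                        chl_a = 1.5, sst = 1),
       effort_bias = TRUE, effort_strength = 3)
}

#' Generate a full synthetic scenario
#'
#' Composes bathymetry, monthly environmental stacks, per-month truth
#' surfaces and biased sightings for July-October. Setting all
#' coefficients to zero gives the null scenario (uniform truth) used for
#' type-I-style AUC checks. When `dir` is given, all artifacts (rasters,
#' sightings CSV, truth rasters, manifest) are written there.
#'
#' @param config named list overriding [scenario_defaults()] entries.
#' @param seed integer RNG seed controlling every random draw.
#' @param dir optional output directory.
#' @return list of class `scenario`: `stacks` (per-month [env_stack]),
#'   `truth` (per-month grid_layer), `sightings` (`sighting_table`),
#'   `effort`, `seed`, `params`.
#' @export
make_scenario <- function(config = list(), seed = 1L, dir = NULL) {
  params <- scenario_defaults()
  unknown <- setdiff(names(config), names(params))
  if (length(unknown))
    stop("unknown config entr(y/ies): ", paste(unknown, collapse = ", "))
  params[names(config)] <- config
  months <- match.arg(params$months, STUDY_MONTHS, several.ok = TRUE)
  if (is.null(names(params$monthly_n)) ||
      !all(months %in% names(params$monthly_n)))
    stop("monthly_n must be named by month")
  bathy <- synth_bathymetry(params$rows, params$cols, params$cell_size, seed)
  stacks <- list(); truth <- list(); tabs <- list()
  effort <- NULL
  for (m in months) {
    st <- synth_stack(bathy, m, seed)
    tr <- synth_truth(st, params$coefficients)
    if (is.null(effort) && isTRUE(params$effort_bias))
      effort <- effort_field(st$layers$depth, seed, params$effort_strength)
    eb <- if (isTRUE(params$effort_bias)) {
      e <- effort
      e$values[is.na(tr$values)] <- NA_real_
      e
    } else NULL
    tabs[[m]] <- synth_sightings(tr, params$monthly_n[[m]], m, eb,
                                 seed = seed + match(m, STUDY_MONTHS))
    stacks[[m]] <- st
    truth[[m]] <- tr
  }
  sightings <- do.call(rbind, c(tabs, make.row.names = FALSE))
  sightings <- as_sighting_table(sightings)
  sc <- structure(list(stacks = stacks, truth = truth, sightings = sightings,
                       effort = effort, seed = seed, params = params),
                  class = "scenario")
  if (!is.null(dir)) write_scenario(sc, dir)
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> seed %d: months %s, %d sightings\n", x$seed,
              paste(names(x$stacks), collapse = "/"), nrow(x$sightings)))
  invisible(x)
}

#' Write a scenario's artifacts to a directory
#'
#' @param scenario a [make_scenario] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(scenario$stacks)) {
    write_env_stack(scenario$stacks[[m]], dir)
    write_ascii_grid(scenario$truth[[m]],
                     file.path(dir, sprintf("truth_%s.asc", m)))
  }
  utils::write.csv(as.data.frame(scenario$sightings),
                   file.path(dir, "sightings.csv"), row.names = FALSE)
  p <- scenario$params
  manifest <- c(
    sprintf("seed: %d", scenario$seed),
    sprintf("rows: %d", p$rows), sprintf("cols: %d", p$cols),
    sprintf("cell_size: %g", p$cell_size),
    sprintf("months: %s", paste(names(scenario$stacks), collapse = ",")),
    sprintf("monthly_n: %s",
            paste(sprintf("%s=%d", names(p$monthly_n), p$monthly_n),
                  collapse = ",")),
    sprintf("coefficients: %s",
            if (length(p$coefficients))
              paste(sprintf("%s=%g", names(p$coefficients), p$coefficients),
                    collapse = ",") else "none"),
    sprintf("effort_bias: %s", p$effort_bias))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
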