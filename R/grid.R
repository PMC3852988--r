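#' Raster grid layer
#'
#' Rectangular raster in a projected planar coordinate system, the unit of
#' all spatial layers in the package. Values are stored row-major with row 1
#' at the north edge; missing data (land, no satellite coverage) is encoded
#' as `NA` and excluded from every statistic. Cells are square;
#' `(x_origin, y_origin)` is the lower-left corner of the lower-left cell,
#' so a `cell_size` of 2500 m gives the 6.25 km^2 cells of the monthly
#' environmental climatologies.
#'
#' @param values numeric matrix, `NA` for nodata; row 1 is the north edge.
#' @param x_origin,y_origin lower-left corner of the lower-left cell (m).
#' @param cell_size side length of the square cells (m), `> 0`.
#' @param crs_label free-text label for the projected CRS (e.g. "UTM 19N").
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, x_origin = 0, y_origin = 0, cell_size = 2500,
                       crs_label = "local-planar-m") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size),
         crs_label = crs_label),
    class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_layer> %d x %d cells @ %g m (%s)\n", d[1], d[2],
              x$cell_size, x$crs_label))
  cat(sprintf("  origin (%g, %g); %d nodata cells\n", x$x_origin, x$y_origin,
              sum(is.na(x$values))))
  invisible(x)
}

is_grid <- function(x) inherits(x, "grid_layer")

stopifnot_grid <- function(x) {
  if (!is_grid(x)) stop("expected a grid_layer object")
  invisible(x)
}

#' Check that two grids share shape, origin and cell size
#' @param a,b grid_layer objects
#' @return logical
#' @export
grids_coregistered <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$x_origin, b$x_origin)) &&
    isTRUE(all.equal(a$y_origin, b$y_origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

# cell-center coordinates; row 1 = north edge so y decreases with row index
grid_cell_centers <- function(g) {
  d <- dim(g$values)
  xs <- g$x_origin + (seq_len(d[2]) - 0.5) * g$cell_size
  ys <- g$y_origin + (d[1] - seq_len(d[1]) + 0.5) * g$cell_size
  list(x = xs, y = ys)
}

# row/col of the cell containing each point; NA when outside the extent
grid_locate <- function(g, x, y) {
  d <- dim(g$values)
  cs <- g$cell_size
  col <- floor((x - g$x_origin) / cs) + 1
  row_from_bottom <- floor((y - g$y_origin) / cs) + 1
  row <- d[1] - row_from_bottom + 1
  # points exactly on the top/right outer boundary belong to the edge cell
  col[x == g$x_origin + d[2] * cs] <- d[2]
  row[y == g$y_origin + d[1] * cs] <- 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`) followed by `nrows` whitespace-separated rows of values,
#' north row first. Cells equal to the declared nodata value become `NA`.
#'
#' @param path path to an `.asc` file.
#' @param crs_label CRS label to attach (the format itself carries none).
#' @return a [grid_layer].
#' @export
read_ascii_grid <- function(path, crs_label = "local-planar-m") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed header line ", i, ": '", lines[i], "'")
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val))
      stop("malformed header line ", i, ": '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- val
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("header missing required field(s): ", paste(miss, collapse = ", "))
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
         else stop("header missing xllcorner/xllcenter")
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
         else stop("header missing yllcorner/yllcenter")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  body <- lines[seq(i, length.out = length(lines) - i + 1L)]
  if (length(body) != nrows)
    stop("expected ", nrows, " data rows, found ", length(body))
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != ncols)
      stop("data row ", r, " (file line ", i + r - 1L, ") has ",
           length(row), " values, expected ", ncols)
    if (anyNA(row))
      stop("data row ", r, " (file line ", i + r - 1L,
           ") contains unparseable values")
    vals[r, ] <- row
  }
  if (!is.na(nodata)) vals[vals == nodata] <- NA_real_
  grid_layer(vals, xll, yll, hdr$cellsize, crs_label)
}

#' Write an ESRI ASCII grid
#'
#' Canonical formatting: lower-case header keys, `%.10g` numbers, one data
#' row per raster row (north first). Re-reading the file yields an equal
#' grid.
#'
#' @param grid a [grid_layer].
#' @param path output path.
#' @param nodata value serialized for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot_grid(grid)
  if (any(grid$values == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata, " as a real value")
  d <- dim(grid$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid$x_origin),
    sprintf("yllcorner %.10g", grid$y_origin),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  v <- grid$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Slope and aspect of a bathymetry grid
#'
#' Central-difference gradient on the 4-neighborhood. Slope is
#' `atan(|grad|)` in degrees; aspect is the compass direction of steepest
#' descent of the seafloor (the direction in which depth increases), in
#' degrees clockwise from north. Cells with zero gradient, edge cells and
#' cells next to nodata get `NA` aspect (and `NA` slope for edge/nodata
#' neighborhoods).
#'
#' @param depth grid_layer of depth in m, positive down.
#' @return list with `slope` and `aspect` grid_layers (degrees).
#' @export
slope_aspect <- function(depth) {
  stopifnot_grid(depth)
  d <- dim(depth$values)
  if (d[1] < 3 || d[2] < 3) stop("grid must be at least 3x3 for derivatives")
  z <- depth$values
  cs <- depth$cell_size
  nr <- d[1]; nc <- d[2]
  gx <- matrix(NA_real_, nr, nc)  # east component of grad(depth)
  gy <- matrix(NA_real_, nr, nc)  # north component
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  gx[ri, ci] <- (z[ri, ci + 1] - z[ri, ci - 1]) / (2 * cs)
  # row index increases southward, so the northward difference flips sign
  gy[ri, ci] <- (z[ri - 1, ci] - z[ri + 1, ci]) / (2 * cs)
  mag <- sqrt(gx^2 + gy^2)
  slope <- atan(mag) * 180 / pi
  aspect <- (atan2(gx, gy) * 180 / pi) %% 360
  aspect[!is.na(mag) & mag == 0] <- NA_real_
  list(slope = grid_layer(slope, depth$x_origin, depth$y_origin,
                          depth$cell_size, depth$crs_label),
       aspect = grid_layer(aspect, depth$x_origin, depth$y_origin,
                           depth$cell_size, depth$crs_label))
}

# logical matrix marking contour cells for a depth level: a cell exactly
# on the level, or any unmasked cell whose 4-neighbor lies strictly on
# the opposite side (both cells of a strictly straddling pair count)
contour_cells <- function(z, level) {
  nr <- nrow(z); nc <- ncol(z)
  s <- sign(z - level)
  on <- !is.na(s) & s == 0
  straddle <- matrix(FALSE, nr, nc)
  chk <- function(a, b) !is.na(a) & !is.na(b) & a * b < 0
  if (nc > 1) {
    h <- chk(s[, -nc, drop = FALSE], s[, -1, drop = FALSE])
    straddle[, -nc] <- straddle[, -nc] | h
    straddle[, -1] <- straddle[, -1] | h
  }
  if (nr > 1) {
    v <- chk(s[-nr, , drop = FALSE], s[-1, , drop = FALSE])
    straddle[-nr, ] <- straddle[-nr, ] | v
    straddle[-1, ] <- straddle[-1, ] | v
  }
  (on | straddle) & !is.na(s)
}

#' Distance to a depth contour
#'
#' Euclidean distance (m) from every unmasked cell center to the nearest
#' contour cell center. A contour cell is any unmasked cell lying exactly
#' on the level or having a 4-neighbor strictly on the opposite side of
#' the level; both cells of a strictly straddling pair count, keeping the
#' layer symmetric about the isobath. Contour cells get distance 0.
#'
#' @param depth grid_layer of depth (m, positive down).
#' @param level contour depth in m (0 = shore, 50, 100, 150, 200 ...).
#' @return grid_layer of distances in m (`NA` where depth is `NA`).
#' @export
distance_to_contour <- function(depth, level) {
  stopifnot_grid(depth)
  z <- depth$values
  cc <- contour_cells(z, level)
  if (!any(cc))
    stop("contour absent: no cell pair straddles the ", level, " m level")
  cs <- depth$cell_size
  idx <- which(cc, arr.ind = TRUE)
  tgt <- which(!is.na(z), arr.ind = TRUE)
  # min over contour cells of center-to-center distance, vectorized per block
  dx <- outer(tgt[, 2], idx[, 2], "-") * cs
  dy <- outer(tgt[, 1], idx[, 1], "-") * cs
  dmin <- sqrt(apply(dx * dx + dy * dy, 1, min))
  out <- matrix(NA_real_, nrow(z), ncol(z))
  out[tgt] <- dmin
  grid_layer(out, depth$x_origin, depth$y_origin, depth$cell_size,
             depth$crs_label)
}

#' Nearest-neighbor resampling
#'
#' Regrids to a new square cell size over the same extent anchored at the
#' same origin; each output cell takes the value of the input cell
#' containing its center, `NA` propagating.
#'
#' @param grid a [grid_layer].
#' @param target_cell_size new cell size in m, `> 0`.
#' @return a [grid_layer] at the new resolution.
#' @export
resample_nearest <- function(grid, target_cell_size) {
  stopifnot_grid(grid)
  if (!is.numeric(target_cell_size) || target_cell_size <= 0)
    stop("target_cell_size must be positive")
  if (isTRUE(all.equal(target_cell_size, grid$cell_size))) return(grid)
  d <- dim(grid$values)
  ext_x <- d[2] * grid$cell_size
  ext_y <- d[1] * grid$cell_size
  nc_out <- max(1L, as.integer(round(ext_x / target_cell_size)))
  nr_out <- max(1L, as.integer(round(ext_y / target_cell_size)))
  xc <- grid$x_origin + (seq_len(nc_out) - 0.5) * target_cell_size
  yc <- grid$y_origin + (nr_out - seq_len(nr_out) + 0.5) * target_cell_size
  loc <- grid_locate(grid, rep(xc, each = nr_out), rep(yc, times = nc_out))
  vals <- matrix(grid$values[cbind(loc$row, loc$col)], nr_out, nc_out)
  grid_layer(vals, grid$x_origin, grid$y_origin, target_cell_size,
             grid$crs_label)
}

#' Cellwise climatology mean
#'
#' Mean across co-registered monthly grids, computed per cell over the
#' inputs where that cell is observed; a cell is `NA` only when masked in
#' every input.
#'
#' @param grids list of co-registered grid_layers (length >= 1).
#' @return a [grid_layer] of means.
#' @export
climatology_mean <- function(grids) {
  if (!length(grids)) stop("need at least one grid")
  lapply(grids, stopifnot_grid)
  g1 <- grids[[1]]
  for (g in grids[-1])
    if (!grids_coregistered(g1, g)) stop("grids are not co-registered")
  arr <- vapply(grids, function(g) g$values, g1$values)
  dim(arr) <- c(dim(g1$values), length(grids))
  s <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  grid_layer(s, g1$x_origin, g1$y_origin, g1$cell_size, g1$crs_label)
}
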