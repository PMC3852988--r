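#' Collate sighting records from CSV
#'
#' Reads shark surface-sighting records pooled irrespective of source
#' (whale-watch and survey platforms). The CSV must carry the columns
#' `x, y, year, month, count, source`; coordinates are projected meters.
#' Each record stands for `count` individual animals sighted at that
#' location, and expands to `count` presences downstream.
#'
#' @param csv path to the sightings CSV.
#' @return a `sighting_table`: data.frame with validated columns.
#' @export
collate_sightings <- function(csv) {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("x", "y", "year", "month", "count", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sightings CSV missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  as_sighting_table(df)
}

#' Construct a sighting table from a data.frame
#'
#' @param df data.frame with columns `x, y, year, month, count, source`.
#' @return a `sighting_table`.
#' @export
as_sighting_table <- function(df) {
  df$month <- as.character(df$month)
  bad_month <- which(!df$month %in% month.name)
  if (length(bad_month))
    stop("unparseable month in row(s): ", paste(bad_month, collapse = ", "))
  df$count <- as.integer(df$count)
  bad_count <- which(is.na(df$count) | df$count < 1L)
  if (length(bad_count))
    stop("nonpositive or missing count in row(s): ",
         paste(bad_count, collapse = ", "))
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  df$year <- as.integer(df$year)
  class(df) <- c("sighting_table", "data.frame")
  df
}

is_sighting_table <- function(x) inherits(x, "sighting_table")

#' Monthly sighting counts and percentages
#'
#' Animal counts per month (summing record `count`s) and each month's
#' share of the total, rounded to two decimals.
#'
#' @param table a `sighting_table`.
#' @return data.frame with `month`, `count`, `percent`; attribute `total`.
#' @export
monthly_summary <- function(table) {
  if (!nrow(table)) stop("empty sighting table")
  months <- intersect(month.name, unique(table$month))
  counts <- vapply(months, function(m) sum(table$count[table$month == m]), 0)
  total <- sum(counts)
  out <- data.frame(month = months, count = as.integer(counts),
                    percent = round(100 * counts / total, 2),
                    row.names = NULL)
  attr(out, "total") <- as.integer(total)
  out
}

#' Horizontal displacement during a dive phase
#'
#' Sharks sighted at the surface are taken as markers of suitable habitat
#' at depth; this trigonometric check bounds how far an animal drifts
#' horizontally during an average descent or ascent. With vertical rate
#' `r` (m/s), phase duration `t` (s) and pitch `p` (degrees from the
#' horizontal), the horizontal distance is `|r| * t * tan(90 - |p|)`.
#'
#' @param vertical_rate signed vertical movement rate, m/s.
#' @param duration phase duration in s, `> 0`.
#' @param pitch signed pitch angle in degrees, `0 < |pitch| < 90`.
#' @return horizontal displacement in meters.
#' @export
horizontal_displacement <- function(vertical_rate, duration, pitch) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  ap <- abs(pitch)
  if (!is.finite(ap) || ap <= 0 || ap >= 90)
    stop("pitch must satisfy 0 < |pitch| < 90 degrees")
  abs(vertical_rate) * duration * tan((90 - ap) * pi / 180)
}

#' Map expanded presences onto grid cells
#'
#' Expands each record to `count` presences and assigns each to the grid
#' cell containing it. Presences outside the grid extent or on masked
#' cells are dropped with a warning; drop counts are recorded in
#' attributes.
#'
#' @param table a `sighting_table`.
#' @param grid reference [grid_layer] (its mask defines valid cells).
#' @param month optional month name to subset to before expansion.
#' @return integer vector of linear (column-major) cell indices, one per
#'   retained presence, with attributes `n_outside` and `n_masked`.
#' @export
presences_to_cells <- function(table, grid, month = NULL) {
  stopifnot_grid(grid)
  df <- table
  if (!is.null(month)) df <- df[df$month == month, , drop = FALSE]
  idx <- rep(seq_len(nrow(df)), df$count)
  x <- df$x[idx]; y <- df$y[idx]
  loc <- grid_locate(grid, x, y)
  outside <- is.na(loc$row)
  cells <- rep(NA_integer_, length(idx))
  keep <- !outside
  cells[keep] <- (loc$col[keep] - 1L) * nrow(grid$values) + loc$row[keep]
  masked <- !outside & is.na(grid$values[cells])
  n_out <- sum(outside); n_mask <- sum(masked)
  if (n_out) warning(n_out, " presence(s) outside grid extent dropped")
  if (n_mask) warning(n_mask, " presence(s) on masked cells dropped")
  out <- cells[!outside & !masked]
  attr(out, "n_outside") <- n_out
  attr(out, "n_masked") <- n_mask
  out
}
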