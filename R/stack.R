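#' @keywords internal
"_PACKAGE"

ENV_VARS <- c("depth", "aspect", "slope", "dist_0", "dist_50", "dist_100",
              "dist_150", "dist_200", "chl_a", "sst")

STUDY_MONTHS <- c("July", "August", "September", "October")

#' Monthly environmental stack
#'
#' The named, co-registered set of predictor layers used by one monthly
#' model: depth, aspect, slope, distance to the 0/50/100/150/200 m
#' contours, chlorophyll-a and sea surface temperature. A cell masked in
#' any layer is masked in all (intersection mask), mirroring the exclusion
#' of data-less cells near land.
#'
#' @param month one of "July", "August", "September", "October".
#' @param layers named list of [grid_layer]s; names must be exactly
#'   `depth, aspect, slope, dist_0, dist_50, dist_100, dist_150, dist_200,
#'   chl_a, sst`.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(month, layers) {
  month <- match.arg(month, STUDY_MONTHS)
  if (!setequal(names(layers), ENV_VARS))
    stop("layers must be named exactly: ", paste(ENV_VARS, collapse = ", "))
  layers <- layers[ENV_VARS]
  lapply(layers, stopifnot_grid)
  ref <- layers[[1]]
  for (nm in names(layers))
    if (!grids_coregistered(ref, layers[[nm]]))
      stop("layer '", nm, "' is not co-registered with 'depth'")
  mask <- Reduce(`|`, lapply(layers, function(g) is.na(g$values)))
  layers <- lapply(layers, function(g) {
    g$values[mask] <- NA_real_
    g
  })
  structure(list(month = month, layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]]$values)
  cat(sprintf("<env_stack> %s: %d layers, %d x %d cells, %d modelled cells\n",
              x$month, length(x$layers), d[1], d[2],
              sum(!is.na(x$layers[[1]]$values))))
  invisible(x)
}

is_env_stack <- function(x) inherits(x, "env_stack")

# linear (column-major) indices of unmasked cells
stack_unmasked_cells <- function(stack) which(!is.na(stack$layers[[1]]$values))

# cells x variables matrix of predictor values at the given cell indices
stack_env_matrix <- function(stack, cells) {
  out <- vapply(stack$layers, function(g) g$values[cells],
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, 1L, dimnames = list(NULL, names(stack$layers)))
  out
}

#' Read an environmental stack from a directory of ASCII grids
#'
#' Expects files named `<var>_<month>.asc` (e.g. `depth_July.asc`) for all
#' ten predictor variables.
#'
#' @param dir directory containing the `.asc` files.
#' @param month month name.
#' @return an [env_stack].
#' @export
read_env_stack <- function(dir, month) {
  month <- match.arg(month, STUDY_MONTHS)
  paths <- file.path(dir, sprintf("%s_%s.asc", ENV_VARS, month))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing raster file(s): ", paste(missing, collapse = ", "))
  layers <- lapply(paths, read_ascii_grid)
  names(layers) <- ENV_VARS
  env_stack(month, layers)
}

#' Write an environmental stack as ASCII grids
#'
#' @param stack an [env_stack].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_env_stack <- function(stack, dir) {
  if (!is_env_stack(stack)) stop("expected an env_stack")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]],
                     file.path(dir, sprintf("%s_%s.asc", nm, stack$month)))
  invisible(dir)
}
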