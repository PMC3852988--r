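test_that("ESRI ASCII grids round-trip through write and read", {
  g <- mk_grid(matrix(c(1.5, 2, NA, -4.25), 2, 2), cell_size = 2500,
               x0 = 100, y0 = -200)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  g2 <- read_ascii_grid(p)
  expect_equal(g2$values, g$values)
  expect_equal(g2$cell_size, 2500)
  expect_equal(g2$x_origin, 100)
  expect_equal(g2$y_origin, -200)
  # canonical formatting is stable: write(read(f)) equals f byte for byte
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g2, p2)
  expect_identical(readLines(p), readLines(p2))
  # masked cell serialized as the nodata sentinel
  expect_true(any(grepl("-9999", readLines(p))))
})

test_that("fully-nodata files read as fully masked grids", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "NODATA_value -1", "-1 -1", "-1 -1"), p)
  g <- read_ascii_grid(p)
  expect_true(all(is.na(g$values)))
})

test_that("malformed ASCII grids are rejected with the offending line", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "NODATA_value -1", "1 2 3", "4 5"), p)
  expect_error(read_ascii_grid(p), "row 2.*2 values, expected 3")
  writeLines(c("ncols 2", "nrows 1", "cellsize 10", "1 2"), p)
  expect_error(read_ascii_grid(p), "xllcorner")
  expect_error(suppressWarnings(
    write_ascii_grid(mk_grid(matrix(1, 2, 2)),
                     file.path(tempdir(), "no/such/dir/x.asc"))),
    "cannot write")
})

test_that("slope and aspect recover analytic planes", {
  cs <- 100
  nr <- 7; nc <- 9
  xs <- (seq_len(nc) - 0.5) * cs
  # plane deepening eastward at 0.1 m per m
  z <- matrix(rep(0.1 * xs, each = nr), nr, nc)
  sa <- slope_aspect(mk_grid(z, cell_size = cs))
  interior <- sa$slope$values[2:(nr - 1), 2:(nc - 1)]
  expect_equal(interior, matrix(atan(0.1) * 180 / pi, nr - 2, nc - 2),
               tolerance = 1e-9)
  # steepest descent points east
  expect_equal(unique(as.vector(sa$aspect$values[2:(nr - 1), 2:(nc - 1)])),
               90)
  # plane deepening northward: aspect 0 (north); row 1 is the north edge
  zn <- matrix(rep((nr:1) * 5, times = nc), nr, nc)
  san <- slope_aspect(mk_grid(zn, cell_size = cs))
  expect_equal(unique(as.vector(san$aspect$values[2:(nr - 1), 2:(nc - 1)])),
               0)
  # constant depth: slope 0, aspect undefined
  saf <- slope_aspect(mk_grid(matrix(7, 5, 5)))
  expect_true(all(saf$slope$values[2:4, 2:4] == 0))
  expect_true(all(is.na(saf$aspect$values)))
  expect_error(slope_aspect(mk_grid(matrix(1, 2, 5))), "3x3")
})

test_that("distance to contour matches the row example and brute force", {
  cs <- 2500
  g <- mk_grid(matrix(c(90, 95, 100, 105, 110), 1, 5), cell_size = cs)
  d <- distance_to_contour(g, 100)
  expect_equal(as.vector(d$values), c(2, 1, 0, 1, 2) * cs)
  expect_error(distance_to_contour(g, 500), "contour absent.*500")

  # brute-force oracle: enumerate contour cells from the definition, then
  # min center-to-center distance over all pairs
  oracle <- function(g, level) {
    z <- g$values; nr <- nrow(z); nc <- ncol(z); cs <- g$cell_size
    is_contour <- matrix(FALSE, nr, nc)
    nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(z[i, j])) next
      if (z[i, j] == level) { is_contour[i, j] <- TRUE; next }
      for (k in 1:4) {
        ii <- i + nb[k, 1]; jj <- j + nb[k, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || is.na(z[ii, jj])) next
        if ((z[i, j] - level) * (z[ii, jj] - level) < 0)
          is_contour[i, j] <- TRUE
      }
    }
    cc <- which(is_contour, arr.ind = TRUE)
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(z[i, j])) next
      out[i, j] <- sqrt(min((cc[, 1] - i)^2 + (cc[, 2] - j)^2)) * cs
    }
    out
  }
  set.seed(31)
  for (rep in 1:3) {
    z <- matrix(runif(400, 0, 250), 20, 20)
    z[sample(400, 30)] <- NA
    g <- mk_grid(z, cell_size = 1000)
    for (lev in c(50, 150))
      expect_equal(distance_to_contour(g, lev)$values, oracle(g, lev))
  }
})

test_that("nearest-neighbor resampling matches center lookup", {
  g <- mk_grid(matrix(1:16, 4, 4), cell_size = 10)
  expect_identical(resample_nearest(g, 10), g)
  gc <- mk_grid(matrix(5, 4, 4), cell_size = 10)
  expect_true(all(resample_nearest(gc, 20)$values == 5))

  # checkerboard coarsened 2x: each output center falls in a known cell
  cb <- mk_grid(outer(1:6, 1:6, function(i, j) (i + j) %% 2), cell_size = 5)
  out <- resample_nearest(cb, 10)
  expect_equal(dim(out$values), c(3, 3))
  for (i in 1:3) for (j in 1:3) {
    xc <- (j - 0.5) * 10; yc <- (3 - i + 0.5) * 10
    src_col <- floor(xc / 5) + 1
    src_row <- 6 - floor(yc / 5)
    expect_equal(out$values[i, j], cb$values[src_row, src_col])
  }
  # integer-ratio round trip is idempotent
  back <- resample_nearest(resample_nearest(cb, 10), 5)
  expect_equal(resample_nearest(back, 10)$values, out$values)
  expect_error(resample_nearest(g, -5), "positive")
})

test_that("climatology mean pools observed cells only", {
  a <- mk_grid(matrix(c(1, NA, 3, 4), 2, 2))
  b <- mk_grid(matrix(c(3, 6, 5, NA), 2, 2))
  m <- climatology_mean(list(a, b))
  expect_equal(m$values, matrix(c(2, 6, 4, 4), 2, 2))
  expect_identical(climatology_mean(list(a))$values, a$values)
  lay <- lapply(1:3, function(k) mk_grid(matrix(k, 2, 2)))
  expect_true(all(climatology_mean(lay)$values == 2))
  expect_error(climatology_mean(list()), "at least one")
  expect_error(climatology_mean(list(a, mk_grid(matrix(1, 3, 3)))),
               "co-registered")
})

test_that("env_stack enforces naming, registration and intersection mask", {
  b <- synth_bathymetry(20, 20, 1000, seed = 2)
  st <- fundysdm:::synth_stack(b, "July", seed = 2)
  masks <- lapply(st$layers, function(g) is.na(g$values))
  for (m in masks[-1]) expect_identical(m, masks[[1]])
  expect_error(env_stack("July", st$layers[-1]), "named exactly")
  expect_error(env_stack("March", st$layers))
})
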