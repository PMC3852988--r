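test_that("background sampling caps, unions presences and is seeded", {
  b <- synth_bathymetry(20, 20, 1000, seed = 4)
  st <- fundysdm:::synth_stack(b, "July", seed = 4)
  all_cells <- which(!is.na(st$layers$depth$values))
  expect_identical(sample_background(st, 10000L, 1L), sort(all_cells))
  s50 <- sample_background(st, 50L, seed = 5)
  expect_length(s50, 50)
  expect_true(all(s50 %in% all_cells))
  expect_identical(s50, sample_background(st, 50L, seed = 5))
  pres <- setdiff(all_cells, s50)[1:3]
  expect_true(all(pres %in% sample_background(st, 50L, 5, pres)))
})

test_that("feature expansion counts and scales features as declared", {
  b <- synth_bathymetry(20, 20, 1000, seed = 4)
  st <- fundysdm:::synth_stack(b, "July", seed = 4)
  cells <- sample_background(st, 200L, 1L)
  pres <- cells[1:5]
  env <- fundysdm:::stack_env_matrix(st, cells)[, c("depth", "chl_a", "sst")]
  fe1 <- fundysdm:::build_features_matrix(env[, "depth", drop = FALSE],
                                          cells, pres, "linear")
  expect_equal(ncol(fe1$design), 1)
  fe9 <- fundysdm:::build_features_matrix(
    env, cells, pres, c("linear", "quadratic", "product"))
  expect_equal(ncol(fe9$design), 9)  # 3 linear + 3 quadratic + 3 products
  expect_true(all(fe9$design >= 0 & fe9$design <= 1))
  # constant variable dropped with a warning
  envc <- env; envc[, "sst"] <- 2
  expect_warning(
    fec <- fundysdm:::build_features_matrix(envc, cells, pres, "linear"),
    "constant variable")
  expect_equal(ncol(fec$design), 2)
  # knots lie strictly inside the background range
  feh <- build_features(st, cells, pres, c("threshold", "hinge"), 5L)
  expect_true(all(unlist(feh$scaling$knots) > 0 &
                    unlist(feh$scaling$knots) < 1))
})

test_that("the fitter matches a one-dimensional likelihood oracle", {
  # one binary feature: 80% of presences at f=1, half the background at
  # f=1; the penalized problem at beta=0 has the closed-form optimum
  # lambda = log(0.8/0.2)
  f <- rep(c(1, 0), each = 50)
  pres <- c(rep(1L, 8), rep(51L, 2))
  fe <- manual_fe(matrix(f, ncol = 1), pres)
  fit <- fit_maxent(fe, beta = 0, max_iter = 2000L, tol = 1e-9)
  oracle <- stats::optimize(function(l)
    0.8 * l - log((50 * exp(l) + 50) / 100), c(-10, 10), maximum = TRUE)
  expect_equal(unname(fit$lambdas), oracle$maximum, tolerance = 1e-3)
  expect_equal(unname(fit$lambdas), log(4), tolerance = 1e-3)
})

test_that("full shrinkage at huge beta gives the uniform model", {
  set.seed(66)
  X <- matrix(runif(200), 50, 4)
  fe <- manual_fe(X, sample(50, 10))
  fit <- fit_maxent(fe, beta = 1e6)
  expect_true(all(fit$lambdas == 0))
  expect_equal(fit$raw, rep(1 / 50, 50))
  expect_equal(fit$training_gain, 0)
  expect_equal(fit$n_params, 0)
})

test_that("penalty reduces training gain and sparsifies monotonically", {
  sc <- sparse_scenario()
  st <- sc$stacks$August
  cells <- scenario_presences(sc)
  f0 <- fit_month(st, cells, beta = 0, seed = 1,
                  classes = c("linear", "quadratic"))
  f1 <- fit_month(st, cells, beta = 1, seed = 1,
                  classes = c("linear", "quadratic"))
  expect_gte(f0$fit$training_gain, f1$fit$training_gain)
  ks <- vapply(c(0.5, 1, 2, 4, 8), function(b)
    fit_month(st, cells, beta = b, seed = 1)$fit$n_params, 0)
  expect_true(all(diff(ks) <= 0))
})

test_that("optimization is deterministic", {
  set.seed(13)
  X <- matrix(runif(300), 60, 5)
  fe <- manual_fe(X, sample(60, 15))
  expect_identical(fit_maxent(fe, beta = 1)$lambdas,
                   fit_maxent(fe, beta = 1)$lambdas)
})

test_that("raw distribution is a shift-invariant softmax summing to one", {
  set.seed(19)
  X <- matrix(runif(30), 10, 3)
  fe <- manual_fe(X, c(2L, 5L))
  fit <- fit_maxent(fe, beta = 0.5)
  raw <- raw_distribution(fit, fe)
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  eta <- drop(X %*% fit$lambdas)
  expect_equal(raw, exp(eta) / sum(exp(eta)))       # direct oracle
  expect_equal(raw, exp(eta + 3) / sum(exp(eta + 3)))  # shift invariance
  fit0 <- fit_maxent(fe, beta = 1e9)
  expect_equal(raw_distribution(fit0, fe), rep(0.1, 10))
})

test_that("cumulative output follows the equal-or-lower-probability rule", {
  expect_equal(cumulative_output(c(0.5, 0.3, 0.2)), c(100, 50, 20))
  for (n in c(3, 17)) {
    expect_equal(cumulative_output(rep(1 / n, n)), rep(100, n))
  }
  oracle <- function(raw) 100 * vapply(raw, function(r)
    sum(raw[raw <= r]), 0)
  set.seed(23)
  for (i in 1:10) {
    raw <- runif(40)
    raw[sample(40, 5)] <- raw[1]  # force ties
    raw <- raw / sum(raw)
    expect_equal(cumulative_output(raw), oracle(raw), tolerance = 1e-12)
  }
  expect_error(cumulative_output(c(0.5, 0.2)), "sum to 1")
})

test_that("training gain matches its likelihood oracle and limits", {
  set.seed(29)
  X <- matrix(runif(30), 10, 3)
  fe <- manual_fe(X, c(1L, 1L, 4L))
  fit <- fit_maxent(fe, beta = 0.3)
  raw <- raw_distribution(fit, fe)
  expect_equal(training_gain(fit, fe),
               mean(log(raw[c(1, 1, 4)])) + log(10))
  # uniform model has zero gain
  expect_equal(fit_maxent(fe, beta = 1e9)$training_gain, 0)
  # a perfectly separating binary feature drives gain toward log(N/N_f1)
  fsep <- c(rep(1, 5), rep(0, 15))
  fes <- manual_fe(matrix(fsep, ncol = 1), which(fsep == 1))
  fits <- fit_maxent(fes, beta = 0, max_iter = 5000L)
  expect_gt(fits$training_gain, 0.9 * log(20 / 5))
  expect_lte(fits$training_gain, log(20 / 5) + 1e-6)
})

test_that("fitted maps recover a known two-feature truth", {
  sc <- fixture("two_feature", function()
    make_scenario(list(months = "July", monthly_n = c(July = 500L),
                       coefficients = c(dist_150 = -4, sst = 2),
                       effort_bias = FALSE), seed = 5))
  st <- sc$stacks$July
  cells <- scenario_presences(sc, "July")
  fm <- fit_month(st, cells, beta = 0.5, seed = 1, classes = "linear",
                  variables = c("dist_150", "sst"))
  cum <- cumulative_output(fm$fit$raw)
  truth <- sc$truth$July$values[fm$fe$cells[fm$fe$background_rows]]
  expect_gt(stats::cor(cum, truth, method = "spearman"), 0.9)
})
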