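test_that("standardized likelihood multiplies presence-cell scores", {
  expect_equal(standardized_likelihood(rep(1 / 8, 8), c(1, 5, 7)),
               3 * log(1 / 8))
  expect_equal(standardized_likelihood(c(0.5, 0.3, 0.2), c(1, 1, 3)),
               log(0.5 * 0.5 * 0.2))
  # a zero-probability cell nobody visits changes nothing
  expect_equal(standardized_likelihood(c(0.5, 0.3, 0.2, 0), c(1, 1, 3)),
               log(0.5 * 0.5 * 0.2))
  ll <- standardized_likelihood(c(0.5, 0.5, 0), c(1, 3))
  expect_equal(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_probability_presences"), 1)
})

test_that("AICc follows the small-sample closed form with its guard", {
  expect_equal(aicc(-7, 0, 10)$aicc, 14)
  r <- aicc(-10, 2, 10)
  expect_equal(r$aicc, 4 + 20 + 12 / 7)
  u <- aicc(-10, 9, 10)
  expect_false(u$defined)
  expect_true(is.na(u$aicc))
})

test_that("regularization selection prefers intermediate smoothing", {
  sc <- sparse_scenario()
  st <- sc$stacks$August
  cells <- scenario_presences(sc)
  cls <- c("linear", "quadratic", "product")
  sel <- select_regularization(st, cells, seed = 1, classes = cls)
  expect_equal(sel$table$beta, c(1, 3, 5, 7, 9, 11, 13, 15, 17))
  expect_equal(nrow(sel$table), 9)
  best_aicc <- sel$table$aicc[sel$table$beta == sel$best_beta]
  at <- function(b) {
    f <- fit_month(st, cells, beta = b, seed = 1, classes = cls)
    aicc(standardized_likelihood(f$fit$raw, f$fe$presence_rows),
         f$fit$n_params, length(cells))$aicc
  }
  expect_lte(best_aicc, at(0.01))  # overfit endpoint
  expect_lte(best_aicc, at(100))   # underfit endpoint
  one <- select_regularization(st, cells, beta_grid = 5, seed = 1,
                               classes = cls)
  expect_equal(one$best_beta, 5)
})

test_that("ROC AUC equals all-pairs concordance and picks thresholds", {
  r <- roc_auc(c(0.9, 0.4), c(0.5, 0.1))
  expect_equal(r$auc, 0.75)
  same <- roc_auc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$auc, 0.5)
  r2 <- roc_auc(c(0.8, 0.6), c(0.7, 0.2, 0.1))
  expect_equal(r2$max_ss_threshold, 0.6)
  i <- which(r2$thresholds == 0.6)
  expect_equal(r2$sensitivity[i], 1)
  expect_equal(r2$specificity[i], 2 / 3)

  concordance <- function(p, b) {
    tot <- 0
    for (x in p) for (y in b)
      tot <- tot + (x > y) + 0.5 * (x == y)
    tot / (length(p) * length(b))
  }
  set.seed(37)
  for (i in 1:8) {
    p <- sample(seq(0, 1, 0.05), sample(5:120, 1), replace = TRUE)
    b <- sample(seq(0, 1, 0.05), sample(5:80, 1), replace = TRUE)
    expect_equal(roc_auc(p, b)$auc, concordance(p, b))
  }
  expect_error(roc_auc(numeric(0), 1), "nonempty")
})

test_that("AUC discrimination labels follow the published bins", {
  expect_equal(classify_auc(0.796), "better than random")
  expect_equal(classify_auc(0.5), "no discrimination")
  expect_equal(classify_auc(1.0), "perfect discrimination")
  expect_equal(classify_auc(0.3), "worse than random")
  expect_equal(classify_auc(0.7), "no discrimination")
  expect_error(classify_auc(1.2), "\\[0, 1\\]")
})

test_that("replicated fitting honors its fold semantics and determinism", {
  sc <- sparse_scenario()
  st <- sc$stacks$August
  cells <- scenario_presences(sc)
  small <- cells[1:4]
  cv <- fit_replicates(st, small, beta = 3, mode = "crossvalidation",
                       replicates = 100L, seed = 2,
                       classes = c("linear", "quadratic"))
  expect_equal(cv$replicates, 4)  # leave-one-out when n < replicates
  cv2 <- fit_replicates(st, small, beta = 3, mode = "crossvalidation",
                        replicates = 100L, seed = 2,
                        classes = c("linear", "quadratic"))
  expect_identical(cv$auc, cv2$auc)
  expect_error(fit_replicates(st, cells, mode = "mystery"), "arg")
  expect_error(fit_replicates(st, cells, mode = "subsampling",
                              test_fraction = 1.5), "test_fraction")
  # requested replicates cap at 100
  expect_lte(fundysdm:::fit_replicates(
    st, cells[1:6], beta = 3, mode = "bootstrap", replicates = 300L,
    seed = 1, classes = "linear")$replicates, 100)
  boot1 <- fit_replicates(st, cells[1:10], beta = 3, mode = "bootstrap",
                          replicates = 1L, seed = 4, classes = "linear")
  sdv <- boot1$map$replicate_sd$values
  expect_true(all(sdv[!is.na(sdv)] == 0))
  sub <- fit_replicates(st, cells[1:20], beta = 3, mode = "subsampling",
                        replicates = 2L, seed = 4, classes = "linear")
  expect_equal(sub$fits[[1]]$n_test, 5)   # 25% of 20
  expect_equal(sub$fits[[1]]$n_train, 15)
})

test_that("percent contribution conserves mass across variables", {
  sc <- sparse_scenario()
  st <- sc$stacks$August
  cells <- scenario_presences(sc)
  fm <- fit_month(st, cells, beta = 1, seed = 1,
                  classes = c("linear", "quadratic"))
  pc <- percent_contribution(fm$fit)
  expect_equal(sum(pc), 100, tolerance = 0.01)
  expect_true(all(pc >= 0))
  # single-variable model concentrates all contribution
  f1 <- fit_month(st, cells, beta = 1, seed = 1, classes = "linear",
                  variables = "dist_150")
  pc1 <- percent_contribution(f1$fit)
  expect_equal(unname(pc1["dist_150"]), 100)
  # a variable whose features never move contributes nothing: duplicate
  # columns split the total while conserving 100
  X <- cbind(a = rep(c(0, 1), 25), b = rep(c(0, 1), 25))
  fe <- manual_fe(X, which(X[, 1] == 1)[1:10],
                  meta = data.frame(class = "linear", var1 = c("a", "b"),
                                    var2 = NA, knot = NA,
                                    id = c("f001", "f002")))
  fit <- fit_maxent(fe, beta = 0.1)
  pcd <- percent_contribution(fit)
  expect_equal(sum(pcd), 100, tolerance = 0.01)
  expect_equal(unname(pcd["a"]), unname(pcd["b"]), tolerance = 1)
})

test_that("permutation importance flags informative variables", {
  sc <- sparse_scenario()
  st <- sc$stacks$August
  cells <- scenario_presences(sc)
  fm <- fit_month(st, cells, beta = 1, seed = 1,
                  classes = c("linear", "quadratic"),
                  variables = c("dist_150", "chl_a", "aspect"))
  pi_ <- permutation_importance(fm$fit, fm$fe, seed = 2)
  expect_equal(sum(pi_), 100, tolerance = 0.01)
  # the dominant truth variable outranks the noise variable
  expect_gt(pi_["dist_150"], pi_["aspect"])
  # a variable with all-zero weights has exactly zero importance: a
  # constant feature has zero gradient, so its weight never leaves zero
  X <- cbind(a = rep(c(1, 0), each = 25), b = rep(0.5, 50))
  fe <- manual_fe(X, rep(which(X[, 1] == 1)[1:8], 2),
                  meta = data.frame(class = "linear", var1 = c("a", "b"),
                                    var2 = NA, knot = NA,
                                    id = c("f001", "f002")))
  fit <- fit_maxent(fe, beta = 0.05)
  expect_equal(unname(fit$lambdas["f002"]), 0)
  pz <- permutation_importance(fit, fe, seed = 2)
  expect_equal(unname(pz["b"]), 0)
  expect_equal(unname(pz["a"]), 100)
})

test_that("jackknife gains respect nesting of the feature sets", {
  sc <- sparse_scenario()
  st <- sc$stacks$August
  cells <- scenario_presences(sc)
  jk <- jackknife_gain(st, cells, beta = 3, seed = 1, classes = "linear")
  expect_equal(nrow(jk$table), 10)
  expect_true(all(jk$table$gain_alone >= 0))
  expect_true(all(jk$table$gain_alone <= jk$full_gain + 1e-3))
  # dropping a pure-noise variable barely moves the full gain
  noise <- jk$table$gain_without[jk$table$variable == "aspect"]
  expect_lt(abs(noise - jk$full_gain), 0.05 * max(jk$full_gain, 1))
})
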