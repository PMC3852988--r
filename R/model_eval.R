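#' Fit one monthly maxent model
#'
#' Convenience wrapper tying background sampling, feature expansion and
#' the regularized fit together for a single month.
#'
#' @param stack an [env_stack].
#' @param presence_cells linear cell indices of presences (with
#'   multiplicity).
#' @param beta regularization multiplier.
#' @param classes feature classes to use.
#' @param knots_per_variable knots for threshold/hinge features.
#' @param max_background background cell cap (default 10000).
#' @param seed RNG seed for background sampling.
#' @param variables optional character subset of predictor variables
#'   (used by the jackknife); `NULL` = all ten.
#' @param max_iter,tol optimizer controls, see [fit_maxent].
#' @return list with `fit` ([fit_maxent] result), `fe` (feature
#'   expansion) and `cells` (design cells).
#' @export
fit_month <- function(stack, presence_cells, beta = 1,
                      classes = FEATURE_CLASSES, knots_per_variable = 10L,
                      max_background = 10000L, seed = 1L, variables = NULL,
                      max_iter = 500L, tol = 1e-5) {
  cells <- sample_background(stack, max_background, seed, presence_cells)
  env <- stack_env_matrix(stack, cells)
  if (!is.null(variables)) {
    bad <- setdiff(variables, colnames(env))
    if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
    env <- env[, variables, drop = FALSE]
  }
  fe <- build_features_matrix(env, cells, presence_cells, classes,
                              knots_per_variable)
  fit <- fit_maxent(fe, beta, max_iter, tol)
  list(fit = fit, fe = fe, cells = cells)
}

#' Log-likelihood of presences under a standardized suitability surface
#'
#' The surface is re-normalized to sum to 1 across cells and the
#' log-likelihood is the sum of log standardized scores at the presence
#' cells, presences in the same cell counting multiply.
#'
#' @param raw nonnegative per-cell scores (re-normalized defensively).
#' @param presence_idx indices into `raw`, one per presence.
#' @return log-likelihood in nats; `-Inf` with attribute
#'   `zero_probability_presences` when a presence sits on a
#'   zero-probability cell.
#' @export
standardized_likelihood <- function(raw, presence_idx) {
  p <- raw / sum(raw)
  ll <- sum(log(p[presence_idx]))
  nz <- sum(p[presence_idx] == 0)
  if (nz) attr(ll, "zero_probability_presences") <- nz
  ll
}

#' Small-sample corrected AIC
#'
#' `AICc = 2k - 2 logL + 2k(k+1)/(n - k - 1)`, with `k` the number of
#' nonzero feature weights and `n` the presence count. Undefined (flagged,
#' not an error) when `n <= k + 1`.
#'
#' @param loglik log-likelihood in nats.
#' @param k parameter count, `>= 0`.
#' @param n presence count, `>= 1`.
#' @return list of class `aicc_record`: `beta` (NA here), `log_likelihood`,
#'   `k`, `n`, `aicc` (`NA` when undefined), `defined`.
#' @export
aicc <- function(loglik, k, n) {
  if (k < 0 || n < 1) stop("need k >= 0 and n >= 1")
  defined <- (n - k - 1) > 0
  val <- if (defined)
    2 * k - 2 * as.numeric(loglik) + 2 * k * (k + 1) / (n - k - 1)
  else NA_real_
  structure(list(beta = NA_real_, log_likelihood = as.numeric(loglik),
                 k = k, n = n, aicc = val, defined = defined),
            class = "aicc_record")
}

#' Select the regularization multiplier by AICc
#'
#' Fits one model per candidate `beta` on all presences, scores each by
#' the standardized likelihood of the presence cells and the nonzero
#' parameter count from the lambdas, and returns the `beta` minimizing
#' AICc (ties going to the smaller, more regularized grid value first in
#' sorted order).
#'
#' @inheritParams fit_month
#' @param beta_grid candidate multipliers; default the nine-value grid
#'   `1, 3, 5, ..., 17`.
#' @param ... passed to [fit_month] (classes, knots, background cap).
#' @return list: `best_beta`, `table` (data.frame of beta, log_likelihood,
#'   k, n, aicc, defined), `fits` (per-beta fit_month results).
#' @export
select_regularization <- function(stack, presence_cells,
                                  beta_grid = seq(1, 17, by = 2),
                                  seed = 1L, ...) {
  if (!length(beta_grid)) stop("beta_grid must be nonempty")
  beta_grid <- sort(beta_grid)
  n <- length(presence_cells)
  fits <- lapply(beta_grid, function(b)
    fit_month(stack, presence_cells, beta = b, seed = seed, ...))
  recs <- lapply(seq_along(beta_grid), function(i) {
    f <- fits[[i]]
    raw <- f$fit$raw
    ll <- standardized_likelihood(raw, f$fe$presence_rows)
    r <- aicc(ll, f$fit$n_params, n)
    r$beta <- beta_grid[i]
    r
  })
  tab <- data.frame(
    beta = beta_grid,
    log_likelihood = vapply(recs, function(r) r$log_likelihood, 0),
    k = vapply(recs, function(r) r$k, 0),
    n = n,
    aicc = vapply(recs, function(r) r$aicc, 0),
    defined = vapply(recs, function(r) r$defined, TRUE))
  if (!any(tab$defined))
    stop("AICc undefined for every candidate: presence count too small ",
         "relative to parameter counts; increase n or regularization")
  ok <- which(tab$defined)
  best <- ok[which.min(tab$aicc[ok])]  # which.min takes the first = smaller beta
  list(best_beta = beta_grid[best], table = tab, fits = fits)
}

#' ROC curve, AUC and the maximum sensitivity+specificity threshold
#'
#' Background cells serve as pseudo-negatives. AUC is the probability
#' that a presence outscores a background cell, counting ties half
#' (Mann-Whitney form). The threshold sweep runs over the distinct
#' observed scores with "predicted suitable" meaning score >= threshold;
#' the reported threshold maximizes sensitivity + specificity, ties going
#' to the lowest threshold (the more inclusive habitat map).
#'
#' @param presence_scores scores at presence cells.
#' @param background_scores scores at background cells.
#' @return list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `max_ss_threshold`.
#' @export
roc_auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("both score vectors must be nonempty")
  m <- length(presence_scores); n <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  th <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(th, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(th, function(t) mean(background_scores < t), 0)
  best <- which.max(sens + spec)  # first index = lowest threshold on ties
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 auc = auc, max_ss_threshold = th[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC=%.3f, max sens+spec threshold=%.4g\n",
              x$auc, x$max_ss_threshold))
  invisible(x)
}

#' Discrimination label for an AUC value
#'
#' Bins: below 0.5 worse than random; 0.5-0.7 no discrimination; above
#' 0.7 better than random; exactly 1 perfect discrimination.
#'
#' @param auc value in \[0, 1\].
#' @return character label.
#' @export
classify_auc <- function(auc) {
  if (!is.finite(auc) || auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  if (auc == 1) "perfect discrimination"
  else if (auc > 0.7) "better than random"
  else if (auc >= 0.5) "no discrimination"
  else "worse than random"
}

#' Ensemble model fitting: cross-validation, bootstrap or subsampling
#'
#' Replicated fits of the monthly model under one of the three
#' model-fitting routines. Cross-validation partitions the presences into
#' `k = min(replicates, n)` folds and reports test AUC per fold;
#' bootstrapping refits on `n`-out-of-`n` resamples and reports training
#' AUC; subsampling refits on seeded random 75/25 train/test splits and
#' reports test AUC. All routines cap at 100 replicates. Ensemble
#' summaries are the mean and SD of the AUC vector and the cellwise mean
#' and SD of the cumulative suitability maps.
#'
#' @inheritParams fit_month
#' @param mode one of "crossvalidation", "bootstrap", "subsampling".
#' @param replicates requested replicate count (capped at 100).
#' @param test_fraction held-out fraction for subsampling (default 0.25).
#' @param template grid_layer giving map geometry (default: the stack's
#'   depth layer).
#' @param ... passed to [fit_month].
#' @return list of class `maxent_ensemble`: `mode`, `auc` (per
#'   replicate), `auc_mean`, `auc_sd`, `map` ([suitability_map] with
#'   replicate mean/SD layers), `fits`.
#' @export
fit_replicates <- function(stack, presence_cells, beta = 1,
                           mode = c("crossvalidation", "bootstrap",
                                    "subsampling"),
                           replicates = 100L, test_fraction = 0.25,
                           seed = 1L, template = NULL, ...) {
  mode <- match.arg(mode)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  n <- length(presence_cells)
  if (mode == "crossvalidation" && n < 2)
    stop("cross-validation needs at least 2 presences")
  replicates <- min(as.integer(replicates), 100L)
  if (is.null(template)) template <- stack$layers$depth

  k <- if (mode == "crossvalidation") min(replicates, n) else replicates
  folds <- NULL
  if (mode == "crossvalidation")
    folds <- local({
      set.seed(seed)
      sample(rep_len(seq_len(k), n))
    })
  splits <- lapply(seq_len(k), function(i) {
    switch(mode,
      crossvalidation = {
        list(train = presence_cells[folds != i],
             test = presence_cells[folds == i])
      },
      bootstrap = local({
        set.seed(seed + i)
        idx <- sample.int(n, n, replace = TRUE)
        list(train = presence_cells[idx], test = presence_cells[idx])
      }),
      subsampling = local({
        set.seed(seed + i)
        n_test <- max(1L, round(test_fraction * n))
        te <- sample.int(n, n_test)
        list(train = presence_cells[-te], test = presence_cells[te])
      }))
  })
  cum_mats <- NULL
  aucs <- numeric(k)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- splits[[i]]
    f <- fit_month(stack, sp$train, beta = beta, seed = seed, ...)
    cum <- cumulative_output(f$fit$raw)
    bg_cells <- f$fe$cells[f$fe$background_rows]
    test_idx <- match(sp$test, bg_cells)
    if (anyNA(test_idx))
      stop("test presence cell absent from the background sample")
    roc <- roc_auc(cum[test_idx], cum)
    aucs[i] <- roc$auc
    if (is.null(cum_mats))
      cum_mats <- matrix(NA_real_, length(template$values), k)
    cum_mats[bg_cells, i] <- cum
    fits[[i]] <- list(fit = f$fit, roc = roc, n_train = length(sp$train),
                      n_test = length(sp$test))
  }
  mean_v <- rowMeans(cum_mats, na.rm = TRUE)
  mean_v[is.nan(mean_v)] <- NA_real_
  sd_v <- apply(cum_mats, 1, stats::sd, na.rm = TRUE)
  sd_v[!is.na(mean_v) & is.na(sd_v)] <- 0  # single-replicate cells
  if (k == 1) sd_v <- ifelse(is.na(mean_v), NA_real_, 0)
  mk_grid <- function(v) grid_layer(matrix(v, nrow(template$values),
                                           ncol(template$values)),
                                    template$x_origin, template$y_origin,
                                    template$cell_size, template$crs_label)
  map <- suitability_map(mk_grid(mean_v), mk_grid(mean_v), mk_grid(sd_v))
  structure(list(mode = mode, auc = aucs, auc_mean = mean(aucs),
                 auc_sd = stats::sd(aucs), map = map, fits = fits,
                 replicates = k),
            class = "maxent_ensemble")
}

#' @export
print.maxent_ensemble <- function(x, ...) {
  cat(sprintf("<maxent_ensemble> %s, %d replicates, AUC %.3f +/- %.3f\n",
              x$mode, x$replicates, x$auc_mean,
              if (is.na(x$auc_sd)) 0 else x$auc_sd))
  invisible(x)
}

#' Percent contribution of each variable
#'
#' Allocates each optimizer iteration's training-gain increase to
#' variables in proportion to the penalty-scaled weight movement of their
#' features (products split evenly between their two variables), then
#' normalizes to percentages summing to 100.
#'
#' @param fit a [fit_maxent] result (carries the gain trace).
#' @return named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(fit) {
  tot <- colSums(fit$gain_trace)
  s <- sum(tot)
  if (s <= 0) {
    warning("no gain accumulated; splitting contribution uniformly")
    return(stats::setNames(rep(100 / length(tot), length(tot)), names(tot)))
  }
  100 * tot / s
}

#' Permutation importance of each variable
#'
#' For each variable, its raw values are permuted across the design rows
#' (seeded), the feature expansion is rebuilt with the frozen scaling and
#' knots, and the drop in training AUC relative to the unpermuted model is
#' recorded. Drops are floored at zero and normalized to percentages
#' summing to 100.
#'
#' @param fit a [fit_maxent] result.
#' @param fe the matching feature expansion.
#' @param seed RNG seed for the permutations.
#' @return named numeric vector of percentages summing to 100 (all zero,
#'   with a warning, when no permutation changes the AUC).
#' @export
permutation_importance <- function(fit, fe, seed = 1L) {
  raw0 <- raw_distribution(fit, fe)
  pres_idx <- fe$presence_rows
  auc0 <- roc_auc(raw0[pres_idx], raw0)$auc
  drops <- stats::setNames(numeric(length(fe$variables)), fe$variables)
  for (v in fe$variables) {
    env_p <- fe$env
    env_p[, v] <- local({
      set.seed(seed + match(v, fe$variables))
      sample(env_p[, v])
    })
    fe_p <- build_features_matrix(env_p, fe$cells,
                                  fe$cells[fe$presence_rows],
                                  fe$classes, fe$knots_per_variable,
                                  frozen = fe$scaling)
    raw_p <- raw_distribution(fit, fe_p)
    auc_p <- roc_auc(raw_p[pres_idx], raw_p)$auc
    drops[v] <- max(0, auc0 - auc_p)
  }
  s <- sum(drops)
  if (s <= 0) {
    warning("no permutation changed the AUC; importance undefined (zeros)")
    return(drops)
  }
  100 * drops / s
}

#' Jackknife of variable training gain
#'
#' Refits the monthly model with each variable alone and with each
#' variable omitted, reporting training gains next to the full model's
#' gain. High gain alone marks a variable carrying useful information by
#' itself; a large drop when omitted marks information held nowhere else.
#'
#' @inheritParams fit_month
#' @param ... passed to [fit_month].
#' @return list: `full_gain`, and `table` (data.frame of variable,
#'   gain_alone, gain_without; `gain_without` is `NA` for a single
#'   variable stack).
#' @export
jackknife_gain <- function(stack, presence_cells, beta = 1, seed = 1L, ...) {
  vars <- names(stack$layers)
  full <- fit_month(stack, presence_cells, beta = beta, seed = seed, ...)
  alone <- vapply(vars, function(v)
    fit_month(stack, presence_cells, beta = beta, seed = seed,
              variables = v, ...)$fit$training_gain, 0)
  without <- if (length(vars) < 2) stats::setNames(rep(NA_real_, length(vars)), vars)
  else vapply(vars, function(v)
    fit_month(stack, presence_cells, beta = beta, seed = seed,
              variables = setdiff(vars, v), ...)$fit$training_gain, 0)
  list(full_gain = full$fit$training_gain,
       table = data.frame(variable = vars, gain_alone = unname(alone),
                          gain_without = unname(without),
                          row.names = NULL))
}
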