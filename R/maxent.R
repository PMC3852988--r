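FEATURE_CLASSES <- c("linear", "quadratic", "product", "threshold", "hinge")

#' Sample background cells
#'
#' Background (available-environment) cells for presence-only estimation:
#' all unmasked cells when at most `max_points`, otherwise a seeded
#' uniform sample without replacement. Presence cells are always unioned
#' in, following the convention that presence sites are part of the
#' background.
#'
#' @param stack an [env_stack].
#' @param max_points cap on background cells (default 10000).
#' @param seed integer RNG seed.
#' @param presence_cells linear cell indices to union into the sample.
#' @return sorted integer vector of linear cell indices.
#' @export
sample_background <- function(stack, max_points = 10000L, seed = 1L,
                              presence_cells = integer(0)) {
  if (!is_env_stack(stack)) stop("expected an env_stack")
  cells <- stack_unmasked_cells(stack)
  if (!length(cells)) stop("stack is fully masked")
  if (length(cells) > max_points) {
    cells <- local({
      set.seed(seed)
      sort(sample(cells, max_points))
    })
  }
  sort(unique(c(cells, unique(presence_cells))))
}

# knot values for one scaled variable: evenly spaced background quantiles
# strictly inside the (0, 1) range, deduplicated
feature_knots <- function(sv_bg, k) {
  if (k < 1) return(numeric(0))
  q <- unique(unname(stats::quantile(sv_bg, probs = seq_len(k) / (k + 1),
                                     type = 7)))
  q[q > 0 & q < 1]
}

#' Expand environmental variables into maxent features
#'
#' Builds the design matrix over the given cells from the five feature
#' classes: linear (the variable scaled to \[0,1\] over background rows),
#' quadratic (scaled square), product (pairwise products of scaled
#' variables), threshold (step indicators at background-quantile knots)
#' and hinge (rescaled ramps at the same knots). Variables constant over
#' the background are skipped with a warning. Scaling ranges and knots are
#' frozen into the object so features can be rebuilt for permuted inputs.
#'
#' @param stack an [env_stack].
#' @param cells linear indices of the design cells (background union
#'   presence cells).
#' @param presence_cells presence cell indices (with multiplicity, one
#'   entry per individual shark); must all appear in `cells`.
#' @param classes subset of
#'   `c("linear","quadratic","product","threshold","hinge")`.
#' @param knots_per_variable maximum knots per variable for threshold and
#'   hinge features (default 10).
#' @return an object of class `feature_expansion`: design matrix,
#'   per-feature metadata, presence/background row indices, frozen
#'   scaling.
#' @export
build_features <- function(stack, cells, presence_cells,
                           classes = FEATURE_CLASSES,
                           knots_per_variable = 10L) {
  if (!is_env_stack(stack)) stop("expected an env_stack")
  env <- stack_env_matrix(stack, cells)
  build_features_matrix(env, cells, presence_cells, classes,
                        knots_per_variable)
}

# matrix-level worker so permutation importance can rebuild features from
# a permuted copy of the raw environmental matrix
build_features_matrix <- function(env, cells, presence_cells,
                                  classes = FEATURE_CLASSES,
                                  knots_per_variable = 10L,
                                  frozen = NULL) {
  classes <- match.arg(classes, FEATURE_CLASSES, several.ok = TRUE)
  if (!length(cells)) stop("cells must be nonempty")
  if (anyNA(env)) stop("non-finite feature values: NA in environment matrix")
  presence_rows <- match(presence_cells, cells)
  if (anyNA(presence_rows))
    stop("presence cell(s) missing from the design cells")
  background_rows <- seq_along(cells)
  vars <- colnames(env)

  if (is.null(frozen)) {
    vmin <- apply(env, 2, min); vmax <- apply(env, 2, max)
  } else {
    vmin <- frozen$vmin; vmax <- frozen$vmax
  }
  usable <- vmax > vmin
  if (any(!usable) && is.null(frozen))
    warning("constant variable(s) skipped: ",
            paste(vars[!usable], collapse = ", "))
  sv <- sweep(sweep(env, 2, vmin), 2, pmax(vmax - vmin, 1e-300), "/")

  cols <- list(); meta <- list()
  add <- function(col, class, var1, var2 = NA_character_, knot = NA_real_) {
    cols[[length(cols) + 1L]] <<- col
    meta[[length(meta) + 1L]] <<- data.frame(
      class = class, var1 = var1, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)
  }
  uvars <- vars[usable]
  if ("linear" %in% classes)
    for (v in uvars) add(sv[, v], "linear", v)
  if ("quadratic" %in% classes)
    for (v in uvars) add(sv[, v]^2, "quadratic", v)
  if ("product" %in% classes && length(uvars) >= 2) {
    for (a in seq_len(length(uvars) - 1L))
      for (b in seq(a + 1L, length(uvars)))
        add(sv[, uvars[a]] * sv[, uvars[b]], "product",
            uvars[a], uvars[b])
  }
  knots <- if (is.null(frozen)) {
    ks <- lapply(uvars, function(v)
      feature_knots(sv[background_rows, v], knots_per_variable))
    names(ks) <- uvars
    ks
  } else frozen$knots
  if ("threshold" %in% classes)
    for (v in uvars) for (q in knots[[v]])
      add(as.numeric(sv[, v] > q), "threshold", v, knot = q)
  if ("hinge" %in% classes)
    for (v in uvars) for (q in knots[[v]])
      add(pmax(0, sv[, v] - q) / (1 - q), "hinge", v, knot = q)

  if (!length(cols)) stop("no usable features (all variables constant?)")
  design <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  meta$id <- sprintf("f%03d", seq_len(nrow(meta)))
  structure(
    list(design = design, feature_meta = meta,
         presence_rows = presence_rows, background_rows = background_rows,
         cells = cells, env = env, variables = vars,
         classes = classes, knots_per_variable = knots_per_variable,
         scaling = list(vmin = vmin, vmax = vmax, knots = knots)),
    class = "feature_expansion")
}

# p x nvars allocation matrix: each feature row sums to 1, products split
# evenly between their two source variables
feature_variable_weights <- function(fe) {
  meta <- fe$feature_meta
  W <- matrix(0, nrow(meta), length(fe$variables),
              dimnames = list(meta$id, fe$variables))
  for (j in seq_len(nrow(meta))) {
    if (!is.na(meta$var2[j])) {
      W[j, meta$var1[j]] <- 0.5
      W[j, meta$var2[j]] <- 0.5
    } else W[j, meta$var1[j]] <- 1
  }
  W
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a regularized maximum-entropy distribution
#'
#' Estimates the Gibbs distribution over background cells closest to
#' uniform subject to the presence feature constraints: maximizes the
#' penalized average log probability of the presences,
#' `mean(log p(i)) - beta * sum_j s_j |lambda_j|`, with
#' `p(i) = exp(sum_j lambda_j f_j(i)) / Z` normalized over background
#' cells and per-feature penalty scale
#' `s_j = sd_background(f_j) / sqrt(m)` for `m` presences. Solved by
#' proximal-gradient (soft-threshold) ascent with backtracking line
#' search, which produces exact zeros so the nonzero-weight count used by
#' AICc is well defined. The optimization is deterministic.
#'
#' @param fe a [build_features] expansion with at least one presence row.
#' @param beta regularization multiplier, `>= 0`.
#' @param max_iter iteration cap (default 500); hitting it returns the
#'   current iterate with `converged = FALSE`.
#' @param tol convergence tolerance on `max |delta lambda|` (default 1e-5).
#' @return object of class `maxent_fit`: `lambdas`, `beta`, `raw`
#'   (probability over background cells, sums to 1), `training_gain`
#'   (nats), `n_params`, `iterations`, `converged`, `penalty_scale`, and a
#'   per-iteration `gain_trace` allocated to variables (for percent
#'   contribution).
#' @export
fit_maxent <- function(fe, beta = 1, max_iter = 500L, tol = 1e-5) {
  if (!inherits(fe, "feature_expansion")) stop("expected a feature_expansion")
  X <- fe$design
  pres <- fe$presence_rows
  bg <- fe$background_rows
  if (!length(pres)) stop("need at least one presence row")
  if (length(bg) < 2) stop("need at least two background rows")
  if (any(!is.finite(X))) stop("non-finite feature values in design matrix")
  m <- length(pres)
  p <- ncol(X)
  s <- apply(X[bg, , drop = FALSE], 2, stats::sd) / sqrt(m)
  fpres <- colMeans(X[pres, , drop = FALSE])
  Xbg <- X[bg, , drop = FALSE]

  smooth_obj <- function(lam) {
    eta <- drop(X %*% lam)
    mean(eta[pres]) - log_sum_exp(eta[bg])
  }
  lam <- rep(0, p)
  f_cur <- smooth_obj(lam)  # = -log(N_bg)
  gain0 <- f_cur + log(length(bg))
  Wfv <- feature_variable_weights(fe)
  gain_trace <- matrix(0, 0, length(fe$variables),
                       dimnames = list(NULL, fe$variables))
  step <- 1
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    eta_bg <- drop(Xbg %*% lam)
    w <- exp(eta_bg - max(eta_bg))
    pr <- w / sum(w)
    grad <- fpres - drop(crossprod(Xbg, pr))
    t_ <- step
    repeat {
      lam_new <- soft_threshold(lam + t_ * grad, t_ * beta * s)
      delta <- lam_new - lam
      f_new <- smooth_obj(lam_new)
      if (f_new >= f_cur + sum(grad * delta) - sum(delta^2) / (2 * t_) - 1e-12)
        break
      t_ <- t_ / 2
      if (t_ < 1e-13) { lam_new <- lam; delta <- delta * 0; f_new <- f_cur; break }
    }
    step <- min(t_ * 2, 16)
    gain_inc <- max(f_new - f_cur, 0)
    alloc <- drop(crossprod(Wfv, abs(delta) * s))
    tot <- sum(alloc)
    gain_trace <- rbind(gain_trace,
                        if (tot > 0) gain_inc * alloc / tot else alloc * 0)
    lam <- lam_new
    f_cur <- f_new
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  eta_bg <- drop(Xbg %*% lam)
  w <- exp(eta_bg - max(eta_bg))
  raw <- w / sum(w)
  structure(
    list(lambdas = stats::setNames(lam, fe$feature_meta$id), beta = beta,
         raw = raw, training_gain = f_cur + log(length(bg)),
         n_params = sum(lam != 0), iterations = it, converged = converged,
         penalty_scale = s, gain_trace = gain_trace),
    class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf(
    "<maxent_fit> beta=%g gain=%.4f nats, %d/%d nonzero weights, %d iter%s\n",
    x$beta, x$training_gain, x$n_params, length(x$lambdas), x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Raw probability distribution over background cells
#'
#' Softmax of the fitted linear predictor over background cells; sums to
#' 1 and is invariant to adding a constant to the predictor.
#'
#' @param fit a [fit_maxent] result.
#' @param fe the matching [build_features] expansion.
#' @return numeric vector over background rows, summing to 1.
#' @export
raw_distribution <- function(fit, fe) {
  eta <- drop(fe$design[fe$background_rows, , drop = FALSE] %*% fit$lambdas)
  w <- exp(eta - max(eta))
  w / sum(w)
}

#' Cumulative suitability output
#'
#' Converts a raw probability vector to the 0-100 cumulative scale: the
#' value at a cell is 100 times the total raw probability of that cell
#' and all cells of equal or lower probability. Tied cells share a value
#' and the most probable cell(s) always score 100.
#'
#' @param raw nonnegative vector summing to 1.
#' @return numeric vector in (0, 100], same length as `raw`.
#' @export
cumulative_output <- function(raw) {
  if (abs(sum(raw) - 1) > 1e-6) stop("raw must sum to 1")
  o <- order(raw)
  cs <- cumsum(raw[o])
  cum_sorted <- stats::ave(cs, factor(raw[o]), FUN = max)
  out <- numeric(length(raw))
  out[o] <- 100 * cum_sorted
  out
}

#' Training gain of a fitted model
#'
#' Mean log ratio, over presences, of fitted presence-cell probability to
#' the uniform baseline `1/N_background`, in nats. Zero for the uniform
#' model; nonnegative at the unpenalized optimum.
#'
#' @inheritParams raw_distribution
#' @return gain in nats.
#' @export
training_gain <- function(fit, fe) {
  raw <- raw_distribution(fit, fe)
  idx <- match(fe$presence_rows, fe$background_rows)
  mean(log(raw[idx])) + log(length(fe$background_rows))
}

#' Suitability map container
#'
#' Wraps a cumulative suitability surface (0-100) with optional
#' replicate mean and SD layers from ensemble fits.
#'
#' @param cumulative grid_layer of cumulative scores in \[0, 100\].
#' @param replicate_mean,replicate_sd optional grid_layers.
#' @return object of class `suitability_map`.
#' @export
suitability_map <- function(cumulative, replicate_mean = NULL,
                            replicate_sd = NULL) {
  stopifnot_grid(cumulative)
  rng <- range(cumulative$values, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 100 + 1e-9)
    stop("cumulative values must lie in [0, 100]")
  structure(list(cumulative = cumulative, replicate_mean = replicate_mean,
                 replicate_sd = replicate_sd),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  d <- dim(x$cumulative$values)
  cat(sprintf("<suitability_map> %d x %d cells, %s replicate layers\n",
              d[1], d[2],
              if (is.null(x$replicate_mean)) "no" else "with"))
  invisible(x)
}

# grid_layer holding values at the given cells of a template grid
values_to_grid <- function(values, cells, template) {
  v <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  v[cells] <- values
  grid_layer(v, template$x_origin, template$y_origin, template$cell_size,
             template$crs_label)
}

#' Cumulative suitability map from a single fit
#'
#' @param fit a [fit_maxent] result.
#' @param fe the matching feature expansion.
#' @param template grid_layer giving geometry (e.g. the depth layer).
#' @return a [suitability_map].
#' @export
cumulative_map <- function(fit, fe, template) {
  cum <- cumulative_output(raw_distribution(fit, fe))
  suitability_map(values_to_grid(cum, fe$cells[fe$background_rows], template))
}

#' Write fitted feature weights as a plain-text lambdas table
#'
#' @param fit a [fit_maxent] result.
#' @param fe the matching feature expansion.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_lambdas <- function(fit, fe, path) {
  tab <- cbind(fe$feature_meta[, c("id", "class", "var1", "var2", "knot")],
               lambda = unname(fit$lambdas),
               scale = unname(fit$penalty_scale))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
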