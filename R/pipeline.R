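#' Run configuration
#'
#' Bundles the paths and settings of a full monthly analysis. Defaults
#' follow the study design: the nine-value regularization grid 1-17, at
#' most 10000 background points, at most 100 replicates, 25% test / 75%
#' training splits for subsampling, cross-validation as the model-fitting
#' routine, and thinning skipped at retained counts of 5 or fewer.
#'
#' @param raster_dir directory of `<var>_<month>.asc` rasters.
#' @param sightings_csv path to the sightings CSV.
#' @param out_dir output directory for all artifacts.
#' @param months months to analyse.
#' @param beta_grid AICc candidate regularization multipliers.
#' @param max_background background cell cap.
#' @param replicates replicate cap for [fit_replicates].
#' @param test_fraction held-out fraction for subsampling.
#' @param mode model-fitting routine.
#' @param skip_threshold thinning skip threshold.
#' @param classes maxent feature classes.
#' @param knots_per_variable threshold/hinge knots per variable.
#' @param jackknife run the per-variable jackknife (2 refits per
#'   variable)?
#' @param seed integer seed governing all randomness.
#' @return named list of class `run_config`.
#' @export
run_config <- function(raster_dir = NULL, sightings_csv = NULL,
                       out_dir = NULL, months = STUDY_MONTHS,
                       beta_grid = seq(1, 17, by = 2),
                       max_background = 10000L, replicates = 100L,
                       test_fraction = 0.25,
                       mode = c("crossvalidation", "bootstrap",
                                "subsampling"),
                       skip_threshold = 5L, classes = FEATURE_CLASSES,
                       knots_per_variable = 10L, jackknife = TRUE,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  structure(list(raster_dir = raster_dir, sightings_csv = sightings_csv,
                 out_dir = out_dir, months = months, beta_grid = beta_grid,
                 max_background = as.integer(max_background),
                 replicates = as.integer(replicates),
                 test_fraction = test_fraction, mode = mode,
                 skip_threshold = as.integer(skip_threshold),
                 classes = classes,
                 knots_per_variable = as.integer(knots_per_variable),
                 jackknife = isTRUE(jackknife), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a plain-text `key: value` file
#'
#' Unknown keys error; list-valued fields (`months`, `beta_grid`,
#' `classes`) are comma-separated.
#'
#' @param path config file path.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ":"), "")
  args <- list()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- trimws(vals[i])
    args[[k]] <- switch(k,
      months = , classes = strsplit(v, ",\\s*")[[1]],
      beta_grid = as.numeric(strsplit(v, ",\\s*")[[1]]),
      max_background = , replicates = , skip_threshold = ,
      knots_per_variable = , seed = as.integer(v),
      test_fraction = as.numeric(v),
      jackknife = as.logical(v),
      v)
  }
  do.call(run_config, args)
}

pipeline_log <- function(...) message(sprintf(...))

#' Run the full monthly analysis
#'
#' Executes, in order: sighting ingestion and pooling, spatial thinning
#' at the expected average nearest neighbor distance, AICc regularization
#' selection over the beta grid, replicated model fitting, ROC/threshold
#' evaluation, habitat binarization and variable importance. All outputs
#' (suitability mean/SD rasters, binary habitat, selection/ROC/importance
#' tables, manifest) are written under `out_dir/<month>/` when `out_dir`
#' is set.
#'
#' @param config a [run_config].
#' @param month month name.
#' @param stack optional pre-loaded [env_stack] (else read from
#'   `config$raster_dir`).
#' @param sightings optional pre-loaded `sighting_table` (else read from
#'   `config$sightings_csv`).
#' @return list of class `month_run` with every stage's result.
#' @export
run_month <- function(config, month, stack = NULL, sightings = NULL) {
  stopifnot(inherits(config, "run_config"))
  month <- match.arg(month, STUDY_MONTHS)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for ", month, ": ",
           conditionMessage(e), call. = FALSE))
  }
  if (is.null(stack))
    stack <- stage("read_rasters", read_env_stack(config$raster_dir, month))
  if (is.null(sightings))
    sightings <- stage("read_sightings", collate_sightings(config$sightings_csv))

  template <- stack$layers$depth
  cell_km2 <- (template$cell_size / 1000)^2
  area_m2 <- sum(!is.na(template$values)) * template$cell_size^2

  msub <- sightings[sightings$month == month, , drop = FALSE]
  if (!nrow(msub)) stop("no sightings for ", month)
  pts <- unique(as.matrix(msub[, c("x", "y")]))
  thin <- stage("thinning",
                thin_month(pts, area = area_m2, seed = config$seed,
                           skip_threshold = config$skip_threshold))
  if (thin$skipped)
    pipeline_log("[%s] thinning skipped (would retain %d <= %d); %d locations kept",
                 month, thin$n_decimated, config$skip_threshold,
                 thin$n_retained)
  else
    pipeline_log("[%s] thinned %d -> %d locations at %.0f m", month,
                 thin$n_input, thin$n_retained, thin$ann$expected_mean_nn)

  thin_tab <- as_sighting_table(data.frame(
    x = thin$points[, 1], y = thin$points[, 2], year = NA_integer_,
    month = month, count = 1L, source = "thinned"))
  presence_cells <- stage("presences",
                          presences_to_cells(thin_tab, template, month))
  if (!length(presence_cells)) stop("no presences on modelled cells")

  sel <- stage("select_regularization",
               select_regularization(stack, presence_cells,
                                     beta_grid = config$beta_grid,
                                     seed = config$seed,
                                     classes = config$classes,
                                     knots_per_variable =
                                       config$knots_per_variable,
                                     max_background = config$max_background))
  pipeline_log("[%s] selected beta = %g by AICc", month, sel$best_beta)
  best <- sel$fits[[match(sel$best_beta, sel$table$beta)]]

  ens <- stage("fit_replicates",
               fit_replicates(stack, presence_cells, beta = sel$best_beta,
                              mode = config$mode,
                              replicates = config$replicates,
                              test_fraction = config$test_fraction,
                              seed = config$seed, template = template,
                              classes = config$classes,
                              knots_per_variable =
                                config$knots_per_variable,
                              max_background = config$max_background))
  pipeline_log("[%s] %s AUC %.3f +/- %.3f over %d replicates (%s)", month,
               ens$mode, ens$auc_mean,
               if (is.na(ens$auc_sd)) 0 else ens$auc_sd, ens$replicates,
               classify_auc(ens$auc_mean))

  cum <- stage("roc", cumulative_output(best$fit$raw))
  pres_idx <- match(best$fe$presence_rows, best$fe$background_rows)
  roc <- stage("roc", roc_auc(cum[pres_idx], cum))
  habitat <- stage("binarize", binarize(ens$map, roc$max_ss_threshold))
  pipeline_log("[%s] threshold %.2f -> %.0f km^2 suitable (%.2f%%)", month,
               roc$max_ss_threshold, habitat$suitable_area,
               habitat$percent_suitable)

  pc <- stage("percent_contribution", percent_contribution(best$fit))
  pi_ <- stage("permutation_importance",
               permutation_importance(best$fit, best$fe, config$seed))
  jk <- if (config$jackknife)
    stage("jackknife", jackknife_gain(stack, presence_cells,
                                      beta = sel$best_beta,
                                      seed = config$seed,
                                      classes = config$classes,
                                      knots_per_variable =
                                        config$knots_per_variable,
                                      max_background = config$max_background))
  else NULL

  out <- structure(
    list(month = month, thin = thin, selection = sel$table,
         best_beta = sel$best_beta, best_fit = best$fit, best_fe = best$fe,
         ensemble = ens, roc = roc, threshold = roc$max_ss_threshold,
         habitat = habitat, percent_contribution = pc,
         permutation_importance = pi_, jackknife = jk,
         seed = config$seed),
    class = "month_run")
  if (!is.null(config$out_dir)) write_month_run(out, config)
  out
}

write_month_run <- function(run, config) {
  dir <- file.path(config$out_dir, run$month)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- run$ensemble$map
  write_ascii_grid(map$replicate_mean, file.path(dir, "suitability_mean.asc"))
  write_ascii_grid(map$replicate_sd, file.path(dir, "suitability_sd.asc"))
  write_ascii_grid(run$habitat$binary, file.path(dir, "habitat_binary.asc"))
  utils::write.csv(run$selection, file.path(dir, "selection.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(threshold = run$roc$thresholds,
                              sensitivity = run$roc$sensitivity,
                              specificity = run$roc$specificity),
                   file.path(dir, "roc.csv"), row.names = FALSE)
  imp <- data.frame(variable = names(run$percent_contribution),
                    percent_contribution = unname(run$percent_contribution),
                    permutation_importance =
                      unname(run$permutation_importance[
                        names(run$percent_contribution)]))
  if (!is.null(run$jackknife))
    imp <- merge(imp, run$jackknife$table, by = "variable", sort = FALSE)
  utils::write.csv(imp, file.path(dir, "importance.csv"), row.names = FALSE)
  write_lambdas(run$best_fit, run$best_fe, file.path(dir, "lambdas.tsv"))
  manifest <- c(
    sprintf("month: %s", run$month),
    sprintf("seed: %d", run$seed),
    sprintf("mode: %s", config$mode),
    sprintf("beta_grid: %s", paste(config$beta_grid, collapse = ",")),
    sprintf("best_beta: %g", run$best_beta),
    sprintf("replicates: %d", run$ensemble$replicates),
    sprintf("thinning_skipped: %s", run$thin$skipped),
    sprintf("n_presences: %d", length(run$best_fe$presence_rows)),
    sprintf("auc_mean: %.6f", run$ensemble$auc_mean),
    sprintf("threshold: %.6f", run$threshold),
    sprintf("suitable_km2: %.6f", run$habitat$suitable_area),
    sprintf("percent_suitable: %.6f", run$habitat$percent_suitable))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Compare completed monthly runs
#'
#' Assembles the habitat summary table (threshold, suitable km^2, percent
#' suitable per month) and the symmetric matrix of Brownian distance
#' correlation coefficients between the monthly replicate-mean
#' suitability surfaces.
#'
#' @param runs named list of [run_month] results (length >= 2).
#' @param out_dir optional directory for `habitat_summary.csv` and
#'   `bdcc.csv`.
#' @return list: `summary` (data.frame), `bdcc` (matrix).
#' @export
run_compare <- function(runs, out_dir = NULL) {
  if (length(runs) < 2) stop("need at least 2 completed month runs")
  if (is.null(names(runs)))
    names(runs) <- vapply(runs, function(r) r$month, "")
  summary <- do.call(rbind, lapply(runs, function(r)
    data.frame(month = r$month, threshold = r$threshold,
               suitable_km2 = r$habitat$suitable_area,
               percent_suitable = r$habitat$percent_suitable,
               auc_mean = r$ensemble$auc_mean)))
  rownames(summary) <- NULL
  maps <- lapply(runs, function(r) r$ensemble$map)
  bdcc <- compare_months(maps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "habitat_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(bdcc), file.path(out_dir, "bdcc.csv"))
  }
  list(summary = summary, bdcc = bdcc)
}

#' Run every configured month and the cross-month comparison
#'
#' @param config a [run_config].
#' @param stacks optional named list of pre-loaded stacks.
#' @param sightings optional pre-loaded `sighting_table`.
#' @return list: `runs` (per month), `compare` ([run_compare] result).
#' @export
run_all <- function(config, stacks = NULL, sightings = NULL) {
  runs <- lapply(config$months, function(m)
    run_month(config, m,
              stack = if (!is.null(stacks)) stacks[[m]] else NULL,
              sightings = sightings))
  names(runs) <- config$months
  cmp <- run_compare(runs, out_dir = config$out_dir)
  list(runs = runs, compare = cmp)
}
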