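# End-to-end orchestration: extract features from a cohort directory,
# reduce, cross-validate, and write the report files; plus the
# decomposition-level sweep and a debug dump of one image's subbands.

#' Assemble and validate a pipeline configuration
#'
#' @param data_dir Cohort directory ([make_cohort()] layout).
#' @param n_slices Centre slices per subject (default 32).
#' @param image_size Square slice extent after resizing (default 256).
#' @param levels DTCWT depth (default 5).
#' @param variance_threshold Cumulative-variance fraction for component
#'   selection (default 0.90).
#' @param pcs_override Fixed component count instead of the threshold
#'   rule (e.g. 14), or `NULL`.
#' @param hidden_units Hidden-layer size (default 10).
#' @param runs,folds Cross-validation protocol (defaults 50 and 10).
#' @param seed Master seed.
#' @param pca_mode `"per-fold"` or `"global"`.
#' @param class_costs `"balanced"`, `NULL`, or a named pair.
#' @param max_iterations,mse_goal SCG stopping rule.
#' @param out_dir Where [run_pipeline()] writes `report.json`,
#'   `per_run_metrics.csv` and `pipeline.log`.
#' @return Validated list of class `cad_config`.
#' @export
pipeline_config <- function(data_dir, n_slices = 32L, image_size = 256L,
                            levels = 5L, variance_threshold = 0.90,
                            pcs_override = NULL, hidden_units = 10L,
                            runs = 50L, folds = 10L, seed = 1L,
                            pca_mode = c("per-fold", "global"),
                            class_costs = "balanced",
                            max_iterations = 300L, mse_goal = 1e-4,
                            out_dir = file.path(data_dir, "results")) {
  pca_mode <- match.arg(pca_mode)
  stopifnot(n_slices >= 1L, image_size >= 2L, levels >= 1L,
            variance_threshold > 0, variance_threshold <= 1,
            hidden_units >= 1L, runs >= 1L, folds >= 2L)
  structure(list(data_dir = data_dir, n_slices = as.integer(n_slices),
                 image_size = as.integer(image_size), levels = as.integer(levels),
                 variance_threshold = variance_threshold,
                 pcs_override = pcs_override,
                 hidden_units = as.integer(hidden_units),
                 runs = as.integer(runs), folds = as.integer(folds),
                 seed = as.integer(seed), pca_mode = pca_mode,
                 class_costs = class_costs,
                 max_iterations = as.integer(max_iterations),
                 mse_goal = mse_goal, out_dir = out_dir),
            class = "cad_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full classification pipeline
#'
#' Stages: read the cohort (`extract`), build the wavelet feature
#' matrix, cross-validate the reduce + train + classify chain
#' (`evaluate`), and write `report.json`, `per_run_metrics.csv` and a
#' log recording the fully resolved configuration and fold sizes.
#'
#' @param config A [pipeline_config()] object.
#' @param features Optional precomputed `cad_features` (skips
#'   extraction; used by [sweep_levels()] and the tests).
#' @return Invisibly, a list with `cv` (the `cad_cv` report),
#'   `features`, and the paths written.
#' @export
run_pipeline <- function(config, features = NULL) {
  stopifnot(inherits(config, "cad_config"))
  if (is.null(features)) {
    subjects <- .stage("extract", read_subjects(config$data_dir))
    features <- .stage("extract", build_feature_matrix(
      subjects, n_slices = config$n_slices,
      target = c(config$image_size, config$image_size),
      levels = config$levels))
  }
  cv <- .stage("evaluate", run_cv(
    features, runs = config$runs, k = config$folds, seed = config$seed,
    pca = TRUE, pca_mode = config$pca_mode,
    variance = config$variance_threshold, pcs = config$pcs_override,
    hidden = config$hidden_units, max_iterations = config$max_iterations,
    mse_goal = config$mse_goal, class_costs = config$class_costs))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(config$out_dir, "report.json")
  csv_path <- file.path(config$out_dir, "per_run_metrics.csv")
  log_path <- file.path(config$out_dir, "pipeline.log")
  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    n_subjects = nrow(features$values),
    n_features = ncol(features$values),
    metrics_mean = as.list(cv$mean),
    metrics_sd_runs = as.list(cv$sd),
    metrics_sd_folds = as.list(cv$sd_folds),
    confusion_total = cv$counts,
    per_run = cv$per_run)
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(cbind(run = seq_len(nrow(cv$per_run)), cv$per_run),
                   csv_path, row.names = FALSE)
  lines <- c(sprintf("pipeline run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("config: %s", jsonlite::toJSON(
               config[setdiff(names(config), "out_dir")], auto_unbox = TRUE)),
             sprintf("subjects: %d, features: %d",
                     nrow(features$values), ncol(features$values)),
             vapply(seq_along(cv$folds), function(r)
               sprintf("run %d fold sizes: %s", r,
                       paste(tabulate(cv$folds[[r]], config$folds),
                             collapse = " ")), character(1)))
  writeLines(lines, log_path)
  invisible(list(cv = cv, features = features,
                 report = report_path, csv = csv_path, log = log_path))
}

#' Mean accuracy as a function of decomposition depth
#'
#' Re-extracts the features at each requested depth `s` (the per-slice
#' feature count changes with `s`) and cross-validates each, tabulating
#' the mean and SD of accuracy.  Depths that are infeasible for the
#' configured image size are recorded as skipped with the reason.
#'
#' @param config A [pipeline_config()] object.
#' @param s_values Integer vector of decomposition depths.
#' @return Data frame with columns `level`, `n_features`,
#'   `mean_accuracy`, `sd_accuracy`, `best`, `skipped`, `reason`.
#' @export
sweep_levels <- function(config, s_values) {
  stopifnot(inherits(config, "cad_config"))
  rows <- lapply(s_values, function(s) {
    res <- tryCatch({
      cfg <- config
      cfg$levels <- as.integer(s)
      out <- run_pipeline(cfg)
      data.frame(level = s, n_features = ncol(out$features$values),
                 mean_accuracy = unname(out$cv$mean["accuracy"]),
                 sd_accuracy = unname(out$cv$sd["accuracy"]),
                 skipped = FALSE, reason = "")
    }, error = function(e)
      data.frame(level = s, n_features = NA_integer_,
                 mean_accuracy = NA_real_, sd_accuracy = NA_real_,
                 skipped = TRUE, reason = conditionMessage(e)))
    res
  })
  if (length(rows) == 0L)
    return(data.frame(level = integer(), n_features = integer(),
                      mean_accuracy = numeric(), sd_accuracy = numeric(),
                      best = logical(), skipped = logical(),
                      reason = character()))
  tab <- do.call(rbind, rows)
  tab$best <- FALSE
  if (any(!tab$skipped & !is.na(tab$mean_accuracy)))
    tab$best[which.max(replace(tab$mean_accuracy, tab$skipped, -Inf))] <- TRUE
  tab[, c("level", "n_features", "mean_accuracy", "sd_accuracy",
          "best", "skipped", "reason")]
}

#' Dump the subbands of one image for inspection
#'
#' Decomposes a PNG image and writes, per level and orientation, a
#' magnitude image (`magnitude_l<level>_<orient>.png`, magnitudes
#' rescaled to the 8-bit range) and the raw coefficients
#' (`coeff_l<level>_<orient>.csv`, one row per subband row, columns
#' alternating `Re,Im` per coefficient), plus the final low-pass array
#' (`lowpass.csv`).
#'
#' @param image_path Input PNG.
#' @param levels Decomposition depth.
#' @param out_dir Output directory (created if needed).
#' @param filters Filter set.
#' @return Invisibly, the output directory.
#' @export
dtcwt_decompose_to_dir <- function(image_path, levels = 5L, out_dir,
                                   filters = dtcwt_filters()) {
  img <- .read_slice(image_path, "(decompose)")
  pyr <- dtcwt_forward(img, levels, filters)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_len(levels)) {
    for (o in names(pyr$levels[[j]])) {
      b <- pyr$levels[[j]][[o]]
      tag <- sub("+", "p", sub("-", "m", o, fixed = TRUE), fixed = TRUE)
      mg <- Mod(b)
      rng <- max(mg)
      png::writePNG(if (rng > 0) mg / rng else mg,
                    file.path(out_dir, sprintf("magnitude_l%d_%s.png", j, tag)))
      inter <- matrix(NA_real_, nrow(b), 2L * ncol(b))
      inter[, seq(1L, 2L * ncol(b), 2L)] <- Re(b)
      inter[, seq(2L, 2L * ncol(b), 2L)] <- Im(b)
      utils::write.table(inter,
                         file.path(out_dir, sprintf("coeff_l%d_%s.csv", j, tag)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  utils::write.table(pyr$lowpass, file.path(out_dir, "lowpass.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(out_dir)
}
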