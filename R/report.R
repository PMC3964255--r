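#' End-to-end OFAT analysis report
#'
#' Runs the full pipeline for one screening factor: obtain the balanced
#' curve family (simulated via [generate_ofat_dataset()], or supplied as a
#' dataset / tidy CSV path), fit both per-level kinetic models, run the
#' balanced two-way ANOVA, rank the factor levels with the Newman-Keuls
#' procedure (level means over the time grid, error term from the ANOVA),
#' and — for the power and ethanol factors — fit the generalized-logistic
#' joint model. Identical configuration and seed give byte-identical JSON
#' output.
#'
#' @param factor_name `"power"`, `"ethanol"` or `"preleach"`.
#' @param input Optional data source: an [ofat_dataset()] or a tidy CSV
#'   path for [read_curves()]. When `NULL`, data are simulated.
#' @param noise_sd,seed Simulation settings (ignored when `input` given).
#' @param alpha Significance level for the ANOVA and post hoc ranking.
#' @param exclusions Levels excluded from the joint fit (default 900 for
#'   power).
#' @param tol Optimizer tolerance, see [fit_curve()].
#' @param out_dir Optional directory; when given, writes
#'   `curves.csv`, `fit_<model>.csv`, `anova.csv`, `report.json` and a
#'   plain-text `summary.txt` there.
#' @return A list of class `mae_report`: `dataset`, `fits_first_order`,
#'   `fits_logistic`, `table_first_order`, `table_logistic`, `anova`,
#'   `snk`, `global` (or NULL), `config`.
#' @examples
#' rep <- run_report("power", noise_sd = 0.01, seed = 11)
#' rep$table_logistic
#' @export
run_report <- function(factor_name = c("power", "ethanol", "preleach"),
                       input = NULL, noise_sd = 0.01, seed = 1,
                       alpha = 0.05, exclusions = NULL, tol = 1e-10,
                       out_dir = NULL) {
  factor_name <- match.arg(factor_name)
  if (!(0 < alpha && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)

  dataset <- if (is.null(input)) {
    generate_ofat_dataset(factor_name, noise_sd = noise_sd, seed = seed)
  } else if (inherits(input, "ofat_dataset")) {
    input
  } else {
    as_ofat_dataset(read_curves(input))
  }
  if (dataset$factor_name != factor_name) {
    stop("input dataset is for factor '", dataset$factor_name, "'",
         call. = FALSE)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  fits_fo <- stage("fit", fit_levels(dataset, "first_order", tol = tol))
  fits_lg <- stage("fit", fit_levels(dataset, "logistic", tol = tol))
  aov_tab <- stage("anova", two_way_anova(dataset, alpha = alpha))
  ms_err <- aov_tab$ms[aov_tab$source == "error"]
  df_err <- aov_tab$df[aov_tab$source == "error"]
  level_means <- rowMeans(dataset$yields)
  names(level_means) <- format(dataset$levels, trim = TRUE)
  snk <- stage("posthoc",
               snk_test(level_means, n_per_mean = length(dataset$times),
                        ms_error = ms_err, df_error = df_err,
                        alpha = alpha))
  glob <- if (factor_name %in% c("power", "ethanol")) {
    stage("global-fit", fit_global(dataset, exclusions = exclusions,
                                   tol = tol))
  }

  out <- structure(
    list(dataset = dataset,
         fits_first_order = fits_fo, fits_logistic = fits_lg,
         table_first_order = fit_table(fits_fo),
         table_logistic = fit_table(fits_lg),
         anova = aov_tab, snk = snk, global = glob,
         config = list(factor = factor_name, noise_sd = noise_sd,
                       seed = seed, alpha = alpha, tol = tol,
                       simulated = is.null(input))),
    class = "mae_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.mae_report <- function(x, ...) {
  cat(sprintf("MAE analysis report: factor '%s'%s\n", x$config$factor,
              if (x$config$simulated)
                sprintf(" (simulated, seed %d, noise sd %g mg/g)",
                        x$config$seed, x$config$noise_sd) else ""))
  cat("\nPer-level delayed logistic fits:\n")
  print(x$table_logistic, row.names = FALSE)
  cat("\n")
  print(x$anova)
  cat("\n")
  print(x$snk)
  if (!is.null(x$global)) {
    cat("\nJoint fit:\n")
    print(x$global)
  }
  invisible(x)
}

report_json <- function(report) {
  strip_fit <- function(f) {
    p <- as.list(f$params)
    list(model = f$model, y_max = p$y_max, k_m = p$k_m, tau = p$tau,
         ref = p$ref, amplitude = p$amplitude, rms = f$rms, gof = f$gof,
         converged = f$converged, n_iter = f$n_iter)
  }
  payload <- list(
    config = report$config,
    fits_first_order = lapply(report$fits_first_order, strip_fit),
    fits_logistic = lapply(report$fits_logistic, strip_fit),
    anova = as.data.frame(report$anova),
    snk = list(means = as.list(report$snk$means),
               subsets = report$snk$subsets,
               alpha = report$snk$alpha),
    global = if (!is.null(report$global)) strip_fit(report$global)
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                   na = "null", digits = NA, pretty = TRUE)
}

#' Write a report bundle to disk
#'
#' Emits the simulated/input curves, both per-level parameter tables
#' (level, `y_max`, `k_m`[, `tau`], gof), the ANOVA table, the homogeneous
#' subsets and joint-fit summary as CSV + JSON + plain text. Logging
#' (seed, tolerances, package version) goes to `summary.txt`.
#'
#' @param report An object from [run_report()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "mae_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_curves(report$dataset, file.path(out_dir, "curves.csv"))
  utils::write.csv(report$table_first_order,
                   file.path(out_dir, "fit_first_order.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table_logistic,
                   file.path(out_dir, "fit_logistic.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$anova),
                   file.path(out_dir, "anova.csv"), row.names = FALSE)
  writeLines(report_json(report), file.path(out_dir, "report.json"))
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con)
  cat(sprintf("maekin %s\n",
              as.character(utils::packageVersion("maekin"))))
  cat(sprintf("config: factor=%s seed=%s noise_sd=%s alpha=%s tol=%s\n",
              report$config$factor, format(report$config$seed),
              format(report$config$noise_sd), format(report$config$alpha),
              format(report$config$tol)))
  print(report)
  sink()
  invisible(out_dir)
}
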