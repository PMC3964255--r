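#' Default OFAT design grids
#'
#' The screening design varies one factor at a time around the reference
#' condition (550 W, 80\% v/v ethanol, 1 min pre-leach): microwave power
#' over 250-550 W (a 900 W level exists but degrades the analyte and is
#' excluded from kinetic validation), aqueous-ethanol concentration over
#' 50-100\% v/v, pre-leaching time over 1-30 min, each observed on a
#' 25-point extraction-time grid \{1, 5, 10, ..., 120\} s.
#'
#' @param factor_name `"power"`, `"ethanol"` or `"preleach"`.
#' @param include_900 For the power factor, also include the 900 W level.
#' @return Numeric vector of design levels / times.
#' @export
default_levels <- function(factor_name = c("power", "ethanol", "preleach"),
                           include_900 = FALSE) {
  factor_name <- match.arg(factor_name)
  switch(factor_name,
    power = if (include_900) c(250, 350, 450, 500, 550, 900)
            else c(250, 350, 450, 500, 550),
    ethanol = seq(50, 100, by = 10),
    preleach = c(1, seq(5, 30, by = 5))
  )
}

#' @rdname default_levels
#' @export
extraction_time_grid <- function() c(1, seq(5, 120, by = 5))

params_fixture <- function() {
  path <- system.file("extdata", "mae_fitted_params.csv", package = "maekin",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

global_params_fixture <- function() {
  path <- system.file("extdata", "mae_global_params.csv", package = "maekin",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference kinetic parameter estimates per design level
#'
#' Returns the study's reference parameter estimates (shipped as a
#' plain-text fixture) for every level of one screening factor: the
#' per-level `(y_max, k_m)` pairs of the modified first-order model or
#' `(y_max, k_m, tau)` triplets of the delayed logistic, together with the
#' published \eqn{Y_{RMS}/Y_{max}} indicator. These serve as the default
#' ground truth of the synthetic-data generator.
#'
#' @param factor_name `"power"`, `"ethanol"` or `"preleach"`.
#' @param model `"logistic"` (default) or `"first_order"`.
#' @return A data.frame with columns `level`, `y_max`, `k_m`, `tau`
#'   (logistic only) and `gof_printed`, ordered by level.
#' @examples
#' default_truth("power")
#' @export
default_truth <- function(factor_name = c("power", "ethanol", "preleach"),
                          model = c("logistic", "first_order")) {
  factor_name <- match.arg(factor_name)
  model <- match.arg(model)
  tab <- params_fixture()
  tab <- tab[tab$model == model & tab$factor == factor_name, , drop = FALSE]
  tab <- tab[order(tab$level), c("level", "y_max", "k_m", "tau",
                                 "gof_printed")]
  if (model == "first_order") tab$tau <- NULL
  rownames(tab) <- NULL
  tab
}

#' Reference generalized-logistic parameters
#'
#' The reference joint-fit parameters `(ref, k_m, tau)` for the power and
#' ethanol factors, with unit amplitude, used as synthetic truths for the
#' [fit_global()] round trip.
#'
#' @param factor_name `"power"` or `"ethanol"`.
#' @return Named vector `c(ref, k_m, tau, amplitude)`.
#' @export
default_global_truth <- function(factor_name = c("power", "ethanol")) {
  factor_name <- match.arg(factor_name)
  tab <- global_params_fixture()
  row <- tab[tab$factor == factor_name, ]
  c(ref = row$ref, k_m = row$k_m, tau = row$tau, amplitude = 1)
}

#' Simulate one extraction time course
#'
#' Evaluates a kinetic forward model on a time grid and adds i.i.d.
#' additive Gaussian noise (truncated below at zero, since yields are
#' nonnegative). With `proportional = TRUE` the noise standard deviation
#' scales with the local mean yield instead (heteroscedastic option).
#' Reproducible for a fixed seed; with `seed = NULL` the current RNG
#' stream is used, which is how [generate_ofat_dataset()] keeps a single
#' stream per dataset.
#'
#' @param params Named vector: `c(y_max, k_m)` for `"first_order"`,
#'   `c(y_max, k_m, tau)` for `"logistic"`.
#' @param model `"logistic"` or `"first_order"`.
#' @param times Sampling grid, s.
#' @param noise_sd Additive noise standard deviation, mg/g (>= 0). Under
#'   `proportional = TRUE` it is the relative standard deviation instead.
#' @param seed Optional integer seed.
#' @param proportional Logical; heteroscedastic (proportional) noise.
#' @param factor_name,level Labels stored on the curve.
#' @return An [extraction_curve()].
#' @examples
#' generate_curve(c(y_max = 0.714, k_m = 0.126, tau = 10.92),
#'                noise_sd = 0.01, seed = 42)
#' @export
generate_curve <- function(params, model = c("logistic", "first_order"),
                           times = extraction_time_grid(), noise_sd = 0.01,
                           seed = NULL, proportional = FALSE,
                           factor_name = "power", level = NA_real_) {
  model <- match.arg(model)
  stopifnot(noise_sd >= 0, length(times) >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- model_yield(model, times, params)
  sd_t <- if (proportional) noise_sd * mu else rep(noise_sd, length(mu))
  y <- mu + stats::rnorm(length(mu), 0, sd_t)
  y <- pmax(y, 0)
  extraction_curve(times, y, factor_name = factor_name, level = level)
}

#' Simulate a balanced OFAT dataset
#'
#' Generates the full curve family of one screening factor on the shared
#' extraction-time grid, with per-level truth parameters defaulting to
#' the reference estimates of [default_truth()] (or, with
#' `truth_model = "global"`, from the single generalized-logistic
#' parameter set of [default_global_truth()]). One RNG stream is used for
#' the whole dataset, seeded once; the seed and noise level are recorded
#' on the returned object.
#'
#' The optional 900 W level is simulated as a rise-then-decay stress
#' curve (logistic rise multiplied by exponential decay past the yield
#' peak) mimicking analyte degradation at excessive power; it is a
#' synthetic stress fixture only, not an estimate from the study.
#'
#' @param factor_name `"power"`, `"ethanol"` or `"preleach"`.
#' @param levels Design levels (default [default_levels()]).
#' @param times Shared time grid, s.
#' @param truth Optional truth data.frame (columns `level`, `y_max`,
#'   `k_m`[, `tau`]) overriding the defaults.
#' @param truth_model `"logistic"`, `"first_order"` or `"global"`.
#' @param global_params Truth for `truth_model = "global"`; defaults to
#'   [default_global_truth()].
#' @param noise_sd Additive Gaussian noise sd, mg/g. The default 0.01
#'   mg/g places the per-curve fitted goodness indicator near the
#'   published range (about 0.02) for the reference truths.
#' @param seed Integer seed for the dataset's RNG stream.
#' @param include_900 Add the degradation stress level (power only).
#' @param proportional Heteroscedastic noise flag, see [generate_curve()].
#' @return An [ofat_dataset()]; simulation metadata (`truth`, `noise_sd`,
#'   `seed`) is stored on the object.
#' @examples
#' generate_ofat_dataset("power", noise_sd = 0.01, seed = 1)
#' @export
generate_ofat_dataset <- function(factor_name = c("power", "ethanol",
                                                  "preleach"),
                                  levels = NULL,
                                  times = extraction_time_grid(),
                                  truth = NULL,
                                  truth_model = c("logistic", "first_order",
                                                  "global"),
                                  global_params = NULL,
                                  noise_sd = 0.01, seed = NULL,
                                  include_900 = FALSE,
                                  proportional = FALSE) {
  factor_name <- match.arg(factor_name)
  truth_model <- match.arg(truth_model)
  if (is.null(levels)) levels <- default_levels(factor_name, include_900)
  if (!is.null(seed)) set.seed(seed)

  if (truth_model == "global") {
    if (is.null(global_params)) {
      global_params <- default_global_truth(factor_name)
    }
    mu <- outer(levels, times, function(x, t) {
      global_yield(t, x, global_params[["ref"]], global_params[["k_m"]],
                   global_params[["tau"]], global_params[["amplitude"]])
    })
    truth_tab <- data.frame(level = levels,
                            t(replicate(length(levels), global_params)))
  } else {
    if (is.null(truth)) {
      truth <- default_truth(factor_name, truth_model)
      truth <- truth[truth$level %in% levels, , drop = FALSE]
    }
    base_levels <- setdiff(levels, if (include_900) 900 else numeric(0))
    miss <- setdiff(base_levels, truth$level)
    if (length(miss)) {
      stop("no truth parameters for level(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    mu <- matrix(0, length(levels), length(times))
    for (i in seq_along(levels)) {
      lv <- levels[i]
      if (include_900 && lv == 900) {
        mu[i, ] <- degradation_curve(times)
      } else {
        row <- truth[truth$level == lv, ][1, ]
        pars <- if (truth_model == "logistic") {
          c(y_max = row$y_max, k_m = row$k_m, tau = row$tau)
        } else {
          c(y_max = row$y_max, k_m = row$k_m)
        }
        mu[i, ] <- model_yield(truth_model, times, pars)
      }
    }
    truth_tab <- truth
  }

  sd_mat <- if (proportional) noise_sd * mu else
    matrix(noise_sd, nrow(mu), ncol(mu))
  y <- mu + matrix(stats::rnorm(length(mu), 0, as.vector(sd_mat)),
                   nrow(mu), ncol(mu))
  y <- pmax(y, 0)
  ofat_dataset(y, levels, times, factor_name,
               truth = truth_tab, noise_sd = noise_sd, seed = seed)
}

# Rise-then-decay stress curve standing in for analyte degradation at
# 900 W; a synthetic construct, not an estimate from any dataset.
degradation_curve <- function(times, y_max = 0.9, k_m = 0.15, tau = 10,
                              decay = 0.015, peak = 50) {
  logistic_yield(times, y_max, k_m, tau) * exp(-decay * pmax(times - peak, 0))
}
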