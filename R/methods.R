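#' @export
print.kinetic_fit <- function(x, digits = 6, ...) {
  lab <- switch(x$model, first_order = "modified first-order",
                logistic = "delayed logistic",
                global = "generalized logistic (joint)")
  cat(sprintf("Kinetic fit: %s model\n", lab))
  print(signif(x$params, digits))
  cat(sprintf("  rms = %.6g mg/g, Y_RMS/Y_max = %.6g, %s in %d iterations\n",
              x$rms, x$gof,
              if (x$converged) "converged" else "DID NOT CONVERGE",
              x$n_iter))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  se <- sqrt(diag(object$covariance))
  out <- list(fit = object,
              table = data.frame(estimate = object$params,
                                 std_error = se),
              n = length(object$residuals),
              singular = isTRUE(attr(object$covariance, "singular")))
  class(out) <- "summary.kinetic_fit"
  out
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  n = %d observations\n", x$n))
  print(signif(x$table, 6))
  if (x$singular) cat("  note: singular Jacobian; standard errors unavailable\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$params

#' @export
vcov.kinetic_fit <- function(object, ...) object$covariance

#' @export
fitted.kinetic_fit <- function(object, ...) object$fitted

#' @export
residuals.kinetic_fit <- function(object, ...) object$residuals

#' @export
deviance.kinetic_fit <- function(object, ...) sum(object$residuals^2)

#' Predict yields from a kinetic fit
#'
#' @param object A `kinetic_fit`.
#' @param times Times (s) at which to evaluate; defaults to the fitted
#'   grid.
#' @param x Design-variable value(s), required for joint (`global`) fits;
#'   defaults to the fitted levels.
#' @param ... Unused.
#' @return Numeric vector (or levels x times matrix for joint fits).
#' @export
predict.kinetic_fit <- function(object, times = NULL, x = NULL, ...) {
  if (object$model == "global") {
    if (is.null(times)) times <- object$data$times
    if (is.null(x)) x <- object$data$levels
    p <- object$params
    out <- outer(x, times, function(xx, tt) {
      p[["amplitude"]] * object$shape(tt, xx, p[["ref"]], p[["k_m"]],
                                      p[["tau"]])
    })
    if (length(x) == 1L) as.vector(out) else out
  } else {
    if (is.null(times)) times <- object$data$times
    model_yield(object$model, times, object$params)
  }
}

#' Plot a kinetic fit
#'
#' Observed yields (points) with the fitted curve; for joint fits, one
#' panelled overlay per design level.
#'
#' @param x A `kinetic_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kinetic_fit <- function(x, ...) {
  if (x$model == "global") {
    ds <- x$data
    grid <- seq(min(ds$times), max(ds$times), length.out = 200)
    graphics::matplot(ds$times, t(ds$yields), pch = 1,
                      xlab = "time (s)", ylab = "yield (mg/g)",
                      main = "Generalized logistic joint fit", ...)
    for (i in seq_along(ds$levels)) {
      graphics::lines(grid, predict(x, times = grid, x = ds$levels[i]),
                      col = i)
    }
    graphics::legend("bottomright", legend = paste(ds$levels, ds$unit),
                     col = seq_along(ds$levels), lty = 1, cex = 0.8)
  } else {
    cv <- x$data
    grid <- seq(min(cv$times), max(cv$times), length.out = 200)
    graphics::plot(cv$times, cv$yields, xlab = "time (s)",
                   ylab = "yield (mg/g)",
                   main = sprintf("%s fit (%s = %s)", x$model,
                                  cv$factor_name, format(cv$level)), ...)
    graphics::lines(grid, predict(x, times = grid), col = 2)
  }
  invisible(x)
}

#' Simulate new curves from a fitted kinetic model
#'
#' Parametric simulation: draws `nsim` noisy realizations of the fitted
#' curve on its own time grid, with noise sd defaulting to the fit's RMS
#' residual.
#'
#' @param object A per-curve `kinetic_fit` (not a joint fit).
#' @param nsim Number of curves.
#' @param seed Optional integer seed.
#' @param noise_sd Noise standard deviation, mg/g; default the fit RMS.
#' @param ... Unused.
#' @return List of [extraction_curve()] objects.
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_sd = NULL, ...) {
  if (object$model == "global") {
    stop("simulate() supports per-curve fits; use generate_ofat_dataset() ",
         "with truth_model = 'global' for joint simulations", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- object$rms
  lapply(seq_len(nsim), function(i) {
    generate_curve(object$params, object$model, object$data$times,
                   noise_sd = noise_sd, seed = NULL,
                   factor_name = object$data$factor_name,
                   level = object$data$level)
  })
}

#' Serialize a kinetic fit as a JSON record
#'
#' Flat record with fields `model`, `y_max`, `k_m`, `tau`, `ref`,
#' `amplitude`, `rms`, `gof`, `converged`, `n_iter` (absent parameters are
#' null).
#'
#' @param fit A `kinetic_fit`.
#' @return A JSON string.
#' @export
fit_json <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  p <- as.list(fit$params)
  rec <- list(model = fit$model,
              y_max = p$y_max, k_m = p$k_m, tau = p$tau, ref = p$ref,
              amplitude = p$amplitude,
              rms = fit$rms, gof = fit$gof,
              converged = fit$converged, n_iter = fit$n_iter)
  jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
}
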