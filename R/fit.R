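#' Goodness-of-fit indicator: RMS residual over asymptotic yield
#'
#' The dimensionless indicator used to judge kinetic fits is the ratio of
#' the root-mean-square residual to the model's asymptotic (limit) yield,
#' \eqn{Y_{RMS}/Y_{max}}. The fitted asymptote is used in the denominator
#' (not the observed maximum), since it is reported as a model parameter
#' alongside the indicator. The ratio is invariant to rescaling yields and
#' asymptote by a common factor.
#'
#' @param rms Root-mean-square residual, mg/g; >= 0.
#' @param y_max Fitted asymptotic yield, mg/g; must be > 0.
#' @return The ratio `rms / y_max` (dimensionless).
#' @examples
#' gof_ratio(0.014, 0.714)
#' @export
gof_ratio <- function(rms, y_max) {
  if (!is.finite(y_max) || y_max <= 0) {
    stop("y_max must be > 0 for the goodness-of-fit ratio", call. = FALSE)
  }
  if (!is.finite(rms) || rms < 0) stop("rms must be >= 0", call. = FALSE)
  rms / y_max
}

rms_of <- function(residuals) sqrt(mean(residuals^2))

#' Heuristic starting values for kinetic fits
#'
#' Derives starting parameters from the shape of the observed curve:
#' the asymptote starts at the maximum observed yield; the rate constant at
#' `3 / t95`, where `t95` is the first time the yield exceeds 95\% of the
#' observed plateau (falling back to `3 / median(times)` when the curve
#' never reaches 95\%); and, for the delayed logistic, the delay at the
#' first time the yield exceeds half the plateau.
#'
#' @param curve An [extraction_curve()].
#' @param model `"first_order"` or `"logistic"`.
#' @return Named numeric vector of starting parameters.
#' @export
initial_guess <- function(curve, model = c("first_order", "logistic")) {
  stopifnot(inherits(curve, "extraction_curve"))
  model <- match.arg(model)
  y <- curve$yields
  t <- curve$times
  plateau <- max(y)
  if (plateau <= 0) {
    stop("degenerate data: all yields are zero, nothing to fit",
         call. = FALSE)
  }
  i95 <- which(y >= 0.95 * plateau)[1]
  k0 <- if (!is.na(i95) && t[i95] > 0) 3 / t[i95] else 3 / stats::median(t)
  if (model == "first_order") {
    c(y_max = plateau, k_m = k0)
  } else {
    i50 <- which(y >= 0.5 * plateau)[1]
    tau0 <- if (!is.na(i50)) t[i50] else stats::median(t)
    c(y_max = plateau, k_m = k0, tau = tau0)
  }
}

# Transform between the natural parameter scale and the optimizer scale:
# positive parameters (y_max, k_m, ref) are log-transformed so the
# Levenberg-Marquardt steps can never propose a negative value; tau stays
# untransformed.
to_opt_scale <- function(pars) {
  out <- pars
  for (nm in intersect(names(pars), c("y_max", "k_m", "ref"))) {
    out[[nm]] <- log(pars[[nm]])
  }
  out
}

from_opt_scale <- function(theta) {
  out <- theta
  for (nm in intersect(names(theta), c("y_max", "k_m", "ref"))) {
    out[[nm]] <- exp(theta[[nm]])
  }
  out
}

new_kinetic_fit <- function(model, params, curve, fitted, residuals,
                            n_iter, converged, message, covariance,
                            objective) {
  rms <- rms_of(residuals)
  denom <- if (model == "global") max(fitted) else params[["y_max"]]
  structure(
    list(model = model, params = params, rms = rms,
         gof = gof_ratio(rms, denom),
         n_iter = n_iter, converged = converged, message = message,
         covariance = covariance, objective = objective,
         fitted = fitted, residuals = residuals, data = curve),
    class = c(if (model == "global") "global_fit", "kinetic_fit")
  )
}

#' Fit a kinetic model to one extraction curve
#'
#' Estimates the parameters of the modified first-order or delayed logistic
#' model by unweighted nonlinear least squares, using the
#' Levenberg-Marquardt algorithm (via \pkg{minpack.lm}). Positive
#' parameters (`y_max`, `k_m`) are log-transformed during optimization so
#' negative proposals cannot occur; the delay `tau` is untransformed.
#' Convergence tolerances default to 1e-10 on both the relative step and the
#' gradient, with at most 500 iterations; non-convergence is flagged on the
#' returned object (`converged = FALSE`), never silent.
#'
#' By default a single heuristic start from [initial_guess()] is used. With
#' `multistart = TRUE`, 8 additional starts are drawn from a fixed
#' Latin-hypercube-style grid around the heuristic and the best objective
#' wins, ties broken by the smallest `k_m`.
#'
#' @param curve An [extraction_curve()]; at least 4 points for the
#'   first-order model, 5 for the logistic.
#' @param model `"first_order"` or `"logistic"`.
#' @param init Optional named starting values (otherwise [initial_guess()]).
#' @param tol Convergence tolerance applied to the relative step, objective
#'   reduction and gradient norm.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param multistart Logical; try 8 deterministic extra starts.
#' @return An object of class `kinetic_fit` with components `model`,
#'   `params` (named vector on the natural scale), `rms` (root-mean-square
#'   residual, mg/g), `gof` (the \eqn{Y_{RMS}/Y_{max}} indicator),
#'   `n_iter`, `converged`, `covariance` (parameter covariance from the
#'   Jacobian at the optimum, natural scale), and the data, fitted values
#'   and residuals. Methods: `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `fitted`, `residuals`, `deviance`, `plot`, `simulate`.
#' @examples
#' tg <- extraction_time_grid()
#' cv <- extraction_curve(tg, logistic_yield(tg, 0.714, 0.126, 10.92))
#' fit_curve(cv, "logistic")
#' @export
fit_curve <- function(curve, model = c("first_order", "logistic"),
                      init = NULL, tol = 1e-10, max_iter = 500L,
                      multistart = FALSE) {
  stopifnot(inherits(curve, "extraction_curve"))
  model <- match.arg(model)
  npar <- model_npar(model)
  n <- length(curve$times)
  if (n < npar + 2L) {
    stop(sprintf(
      "insufficient data: %d points for a %d-parameter model (need >= %d)",
      n, npar, npar + 2L), call. = FALSE)
  }
  start <- if (is.null(init)) initial_guess(curve, model) else init
  starts <- list(start)
  if (multistart) starts <- c(starts, spread_starts(start, model))

  runs <- lapply(starts, function(s) {
    lm_run(
      theta0 = to_opt_scale(s),
      resid_fn = function(theta) {
        p <- from_opt_scale(theta)
        model_yield(model, curve$times, p) - curve$yields
      },
      tol = tol, max_iter = max_iter
    )
  })
  obj <- vapply(runs, function(r) r$objective, numeric(1))
  km <- vapply(runs, function(r) from_opt_scale(r$theta)[["k_m"]], numeric(1))
  best <- order(obj, km)[1]
  run <- runs[[best]]

  params <- from_opt_scale(run$theta)
  fitted <- model_yield(model, curve$times, params)
  res <- fitted - curve$yields
  covar <- natural_covariance(
    function(p) model_yield(model, curve$times, p), params, res)
  if (model == "logistic" && params[["tau"]] < 0) {
    warning("fitted time delay tau is negative: degenerate fit",
            call. = FALSE)
  }
  new_kinetic_fit(model, params, curve, fitted, res,
                  run$n_iter, run$converged, run$message, covar,
                  run$objective)
}

# Deterministic spread of alternative starts (factors of the heuristic on
# the positive parameters, shifts on tau) used by multistart = TRUE.
spread_starts <- function(start, model) {
  mult <- c(0.25, 0.5, 2, 4)
  out <- list()
  for (m in mult) {
    s <- start
    s[["k_m"]] <- start[["k_m"]] * m
    out <- c(out, list(s))
  }
  for (m in c(0.5, 2)) {
    s <- start
    s[["y_max"]] <- start[["y_max"]] * m
    out <- c(out, list(s))
  }
  if (model == "logistic") {
    for (d in c(-10, 10)) {
      s <- start
      s[["tau"]] <- start[["tau"]] + d
      out <- c(out, list(s))
    }
  } else {
    for (m in c(0.1, 10)) {
      s <- start
      s[["k_m"]] <- start[["k_m"]] * m
      out <- c(out, list(s))
    }
  }
  out
}

# Shared Levenberg-Marquardt driver. info codes 1-4 and 8 indicate a met
# convergence criterion in MINPACK; 5-7 are iteration/tolerance exhaustion.
lm_run <- function(theta0, resid_fn, tol, max_iter) {
  ctl <- minpack.lm::nls.lm.control(
    ftol = tol, ptol = tol, gtol = tol,
    maxiter = as.integer(max_iter), maxfev = 100L * (length(theta0) + 1L) * 10L
  )
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn, control = ctl)
  theta <- stats::coef(fit)
  list(theta = theta,
       objective = sum(resid_fn(theta)^2),
       n_iter = fit$niter,
       converged = fit$info %in% c(1L, 2L, 3L, 4L, 8L),
       message = fit$message)
}

# Parameter covariance on the natural scale from a forward-difference
# Jacobian at the optimum: sigma^2 (J'J)^{-1}, sigma^2 = SSE / (n - p).
# A numerically singular J'J yields a covariance of NAs plus a flag; the
# fit itself is still returned.
natural_covariance <- function(fwd, params, residuals) {
  n <- length(residuals)
  p <- length(params)
  J <- matrix(0, n, p, dimnames = list(NULL, names(params)))
  f0 <- fwd(params)
  for (j in seq_len(p)) {
    h <- max(abs(params[[j]]), 1e-4) * 1e-7
    pj <- params
    pj[[j]] <- pj[[j]] + h
    J[, j] <- (fwd(pj) - f0) / h
  }
  jtj <- crossprod(J)
  sigma2 <- if (n > p) sum(residuals^2) / (n - p) else NA_real_
  inv <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(inv)) {
    cov <- matrix(NA_real_, p, p, dimnames = list(names(params), names(params)))
    attr(cov, "singular") <- TRUE
  } else {
    cov <- sigma2 * inv
    dimnames(cov) <- list(names(params), names(params))
    attr(cov, "singular") <- FALSE
  }
  cov
}

#' Fit every level of an OFAT dataset
#'
#' Convenience wrapper running [fit_curve()] on each level's curve.
#'
#' @param dataset An [ofat_dataset()].
#' @param model `"first_order"` or `"logistic"`.
#' @param ... Passed to [fit_curve()].
#' @return Named list of `kinetic_fit` objects, one per level.
#' @export
fit_levels <- function(dataset, model = c("first_order", "logistic"), ...) {
  stopifnot(inherits(dataset, "ofat_dataset"))
  model <- match.arg(model)
  fits <- lapply(dataset$levels, function(lv) {
    fit_curve(dataset_curve(dataset, lv), model, ...)
  })
  names(fits) <- format(dataset$levels, trim = TRUE)
  fits
}

#' Tabulate per-level kinetic fits
#'
#' Collects a list of per-level fits into the standard reporting layout:
#' level, `y_max`, `k_m` (and `tau` for the logistic model), and the
#' \eqn{Y_{RMS}/Y_{max}} goodness indicator.
#'
#' @param fits Named list of `kinetic_fit` objects as from [fit_levels()].
#' @return A data.frame, one row per level.
#' @export
fit_table <- function(fits) {
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, logical(1),
                                         "kinetic_fit")))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    d <- as.data.frame(as.list(f$params))
    cbind(data.frame(level = as.numeric(nm)), d,
          data.frame(gof = f$gof, converged = f$converged))
  })
  do.call(rbind, rows)
}
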