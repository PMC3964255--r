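#' Joint generalized-logistic fit of an OFAT curve family
#'
#' Fits the design-variable-dependent generalized logistic model
#' \eqn{Y(t,x) = A (1 - e^{-x/x_{ref}}) / (1 + e^{-k_m(t-\tau)})} to an
#' entire curve family at once (all power levels, or all ethanol levels),
#' minimizing the pooled squared residuals over every retained
#' (level, time) cell. The amplitude \eqn{A} is profiled out by exact
#' linear least squares at every evaluation of the nonlinear residual
#' (variable projection), so only \eqn{(x_{ref}, k_m, \tau)} are iterated
#' by Levenberg-Marquardt; `ref` and `k_m` are log-transformed during
#' optimization.
#'
#' The pooled goodness indicator divides the pooled RMS residual by the
#' maximum fitted yield over all cells (the single scalar "limit" yield of
#' the joint fit).
#'
#' For the power factor the 900 W level, where yield degrades instead of
#' saturating, is excluded by default before fitting.
#'
#' @param dataset An [ofat_dataset()] with at least 2 retained levels.
#' @param exclusions Numeric levels to drop before fitting. Default: 900
#'   for the power factor, none otherwise.
#' @param shape Model strategy: a function `f(t, x, ref, k_m, tau)`
#'   returning the unit-amplitude yield. Defaults to the separable form
#'   above; any callable with that signature can be injected.
#' @param init Optional named start for `c(ref, k_m, tau)`.
#' @param fix_ref Optional fixed value of `ref`; only `(k_m, tau)` are then
#'   optimized (with the amplitude still profiled).
#' @param tol,max_iter Levenberg-Marquardt tolerances, as in [fit_curve()].
#' @return An object of class `c("global_fit", "kinetic_fit")` whose
#'   `params` are `c(ref, k_m, tau, amplitude)` (amplitude from the final
#'   linear solve), with pooled `rms`, `gof`, convergence info and
#'   residuals over the retained cells. The retained dataset is stored as
#'   `$data`.
#' @examples
#' ds <- generate_ofat_dataset("power", noise_sd = 0, seed = 1,
#'                             truth_model = "global")
#' fit_global(ds)
#' @export
fit_global <- function(dataset, exclusions = NULL, shape = NULL,
                       init = NULL, fix_ref = NULL, tol = 1e-10,
                       max_iter = 500L) {
  stopifnot(inherits(dataset, "ofat_dataset"))
  if (is.null(exclusions)) {
    exclusions <- if (dataset$factor_name == "power") 900 else numeric(0)
  }
  if (length(exclusions) && any(dataset$levels %in% exclusions)) {
    dataset <- exclude_levels(dataset, exclusions)
  }
  if (length(dataset$levels) < 2L && is.null(fix_ref)) {
    stop("need >= 2 retained levels to identify ref", call. = FALSE)
  }
  if (is.null(shape)) shape <- global_shape_separable

  tt <- rep(dataset$times, times = length(dataset$levels))
  xx <- rep(dataset$levels, each = length(dataset$times))
  yy <- as.vector(t(dataset$yields))

  # profile the amplitude: for unit-amplitude shape g, A* = <g,y>/<g,g>
  profile_amplitude <- function(g) {
    gg <- sum(g * g)
    if (gg <= 0) 0 else sum(g * yy) / gg
  }
  resid_at <- function(ref, k_m, tau) {
    g <- shape(tt, xx, ref, k_m, tau)
    profile_amplitude(g) * g - yy
  }

  if (is.null(init)) init <- global_initial_guess(dataset, fix_ref)
  free <- if (is.null(fix_ref)) c("ref", "k_m", "tau") else c("k_m", "tau")
  theta0 <- to_opt_scale(init[free])

  run <- lm_run(
    theta0 = theta0,
    resid_fn = function(theta) {
      p <- from_opt_scale(theta)
      ref <- if (is.null(fix_ref)) p[["ref"]] else fix_ref
      resid_at(ref, p[["k_m"]], p[["tau"]])
    },
    tol = tol, max_iter = max_iter
  )

  p <- from_opt_scale(run$theta)
  ref <- if (is.null(fix_ref)) p[["ref"]] else fix_ref
  g <- shape(tt, xx, ref, p[["k_m"]], p[["tau"]])
  amplitude <- profile_amplitude(g)
  fitted <- amplitude * g
  res <- fitted - yy
  params <- c(ref = ref, k_m = p[["k_m"]], tau = p[["tau"]],
              amplitude = amplitude)
  covar <- natural_covariance(
    function(q) q[["amplitude"]] *
      shape(tt, xx, q[["ref"]], q[["k_m"]], q[["tau"]]),
    params, res)
  out <- new_kinetic_fit("global", params, dataset, fitted, res,
                         run$n_iter, run$converged, run$message, covar,
                         run$objective)
  out$shape <- shape
  out
}

# Start the joint fit from the top level's logistic fit (k_m, tau) and a
# ref at the median design level; with ref fixed only (k_m, tau) are needed.
global_initial_guess <- function(dataset, fix_ref = NULL) {
  top <- dataset$levels[which.max(rowMeans(dataset$yields))]
  cv <- dataset_curve(dataset, top)
  lg <- initial_guess(cv, "logistic")
  c(ref = if (is.null(fix_ref)) stats::median(dataset$levels) else fix_ref,
    k_m = lg[["k_m"]], tau = lg[["tau"]])
}
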