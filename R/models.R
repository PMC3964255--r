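#' Kinetic forward models for microwave-assisted extraction
#'
#' Three yield-versus-time models describe the sigmoidal rise of mangiferin
#' content during microwave-assisted extraction (MAE):
#'
#' \describe{
#'   \item{modified first-order}{\eqn{Y(t) = Y_{max}(1 - e^{-k_m t})}, the
#'     two-parameter pseudo-first-order washout curve. \eqn{Y_{max}} is the
#'     asymptotic yield (mg/g dry matter) as \eqn{t \to \infty}; \eqn{k_m}
#'     (1/s) is the apparent extraction rate constant.}
#'   \item{delayed logistic}{\eqn{Y(t) = Y_{max} / (1 + e^{-k_m (t - \tau)})},
#'     a three-parameter sigmoid whose inflection is shifted by the time
#'     delay \eqn{\tau} (s). Without the delay the yield at \eqn{t = 0} would
#'     always equal half the asymptote, an unjustified restriction for
#'     extraction data.}
#'   \item{generalized logistic}{\eqn{Y(t, x) = A\,(1 - e^{-x/x_{ref}}) /
#'     (1 + e^{-k_m (t - \tau)})}, a separable design-variable-dependent form
#'     that couples the delayed logistic time course with a saturating
#'     dependence on a design variable \eqn{x} (microwave power in W, or
#'     ethanol concentration in \% v/v). \eqn{x_{ref}} sets the scale of the
#'     design variable; the amplitude \eqn{A} (mg/g) is an overall yield
#'     scale that [fit_global()] profiles out by linear least squares.}
#' }
#'
#' All three are nondecreasing in \eqn{t} (and in \eqn{x}) and bounded by
#' their asymptote.
#'
#' @param t Extraction (irradiation) time in seconds; must be >= 0.
#' @param y_max Asymptotic yield, mg/g; must be >= 0.
#' @param k_m Rate constant, 1/s; must be > 0.
#' @param tau Time delay, s (delayed logistic / generalized logistic). May be
#'   zero or negative for degenerate fits; a warning is issued when negative.
#' @param x Design-variable value (W or \% v/v); must be > 0.
#' @param ref Reference design-variable scale, same units as `x`; must be > 0.
#' @param amplitude Overall yield scale, mg/g; must be >= 0.
#' @return Numeric vector of yields, mg/g, recycled over `t` (and `x`).
#' @examples
#' first_order_yield(50, y_max = 0.718, k_m = 0.073)
#' logistic_yield(c(0, 10.9, 120), y_max = 0.714, k_m = 0.126, tau = 10.9)
#' global_yield(50, x = 550, ref = 759.42, k_m = 0.14, tau = 11.68)
#' @name kinetic_models
NULL

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t)) {
    stop("extraction time must be numeric and non-missing", call. = FALSE)
  }
  if (any(t < 0)) stop("extraction time must be >= 0", call. = FALSE)
  invisible(t)
}

check_first_order_params <- function(y_max, k_m) {
  stopifnot(length(y_max) == 1L, length(k_m) == 1L)
  if (!is.finite(y_max) || y_max < 0) stop("y_max must be >= 0", call. = FALSE)
  if (!is.finite(k_m) || k_m <= 0) stop("k_m must be > 0", call. = FALSE)
  invisible(NULL)
}

check_logistic_params <- function(y_max, k_m, tau) {
  check_first_order_params(y_max, k_m)
  if (!is.finite(tau)) stop("tau must be finite", call. = FALSE)
  if (tau < 0) warning("negative time delay tau: degenerate fit", call. = FALSE)
  invisible(NULL)
}

#' @rdname kinetic_models
#' @export
first_order_yield <- function(t, y_max, k_m) {
  check_time(t)
  check_first_order_params(y_max, k_m)
  y_max * (1 - exp(-k_m * t))
}

#' @rdname kinetic_models
#' @export
logistic_yield <- function(t, y_max, k_m, tau) {
  check_time(t)
  check_logistic_params(y_max, k_m, tau)
  y_max / (1 + exp(-k_m * (t - tau)))
}

#' @rdname kinetic_models
#' @export
global_yield <- function(t, x, ref, k_m, tau, amplitude = 1) {
  check_time(t)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("design-variable value x must be > 0", call. = FALSE)
  }
  if (!is.finite(ref) || ref <= 0) stop("ref must be > 0", call. = FALSE)
  if (!is.finite(k_m) || k_m <= 0) stop("k_m must be > 0", call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("amplitude must be >= 0", call. = FALSE)
  }
  amplitude * (1 - exp(-x / ref)) / (1 + exp(-k_m * (t - tau)))
}

# Unit-amplitude shape of the generalized logistic; the strategy slot used by
# fit_global(), so an alternative published algebra can be swapped in without
# touching the fitting code. Signature: f(t, x, ref, k_m, tau) -> yield for
# amplitude 1.
global_shape_separable <- function(t, x, ref, k_m, tau) {
  (1 - exp(-x / ref)) / (1 + exp(-k_m * (t - tau)))
}

# Validation-free evaluation used inside optimizer residual functions,
# where transient parameter proposals (e.g. negative tau) are legitimate.
model_yield <- function(model, t, pars) {
  switch(model,
    first_order = pars[["y_max"]] * (1 - exp(-pars[["k_m"]] * t)),
    logistic = pars[["y_max"]] /
      (1 + exp(-pars[["k_m"]] * (t - pars[["tau"]]))),
    stop("unknown model tag: ", model, call. = FALSE)
  )
}

model_npar <- function(model) {
  switch(model, first_order = 2L, logistic = 3L,
         stop("unknown model tag: ", model, call. = FALSE))
}
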