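#' DPPH radical-scavenging percentage
#'
#' Percent inhibition of the DPPH radical, computed from absorbances at
#' 517 nm as \eqn{100 (A_{control} - A_{sample}) / A_{control}}. Negative
#' values (sample absorbing more than the blank, e.g. pro-oxidant or
#' turbidity artifacts) are returned as-is with a warning.
#'
#' @param a_control Absorbance of the DPPH blank at 517 nm; must be > 0.
#' @param a_sample Sample absorbance(s) at 517 nm; >= 0.
#' @return Percent scavenging, same length as `a_sample`.
#' @examples
#' scavenging_percent(0.80, 0.42)
#' @export
scavenging_percent <- function(a_control, a_sample) {
  if (!is.finite(a_control) || a_control <= 0) {
    stop("control absorbance must be > 0", call. = FALSE)
  }
  if (any(!is.finite(a_sample)) || any(a_sample < 0)) {
    stop("sample absorbance must be >= 0", call. = FALSE)
  }
  pct <- 100 * (a_control - a_sample) / a_control
  if (any(pct < 0)) {
    warning("negative scavenging percentage: sample absorbance exceeds control",
            call. = FALSE)
  }
  pct
}

#' Dose-response container for the DPPH assay
#'
#' Holds extract concentrations, measured absorbances, the DPPH control
#' absorbance, and the derived percent inhibition (always computed here,
#' never supplied).
#'
#' @param concentrations Extract concentrations, ug/ml; strictly
#'   increasing, > 0.
#' @param absorbances Sample absorbances at 517 nm, one per concentration.
#' @param control_absorbance DPPH blank absorbance at 517 nm; > 0.
#' @return An object of class `dose_response` with an `inhibition`
#'   component (percent).
#' @export
dose_response <- function(concentrations, absorbances, control_absorbance) {
  concentrations <- as.numeric(concentrations)
  absorbances <- as.numeric(absorbances)
  if (length(concentrations) != length(absorbances)) {
    stop("concentrations and absorbances must have equal length",
         call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  inh <- scavenging_percent(control_absorbance, absorbances)
  structure(list(concentrations = concentrations,
                 absorbances = absorbances,
                 control_absorbance = control_absorbance,
                 inhibition = inh),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("DPPH dose-response: %d concentrations, control A517 = %g\n",
              length(x$concentrations), x$control_absorbance))
  print(data.frame(conc_ug_ml = x$concentrations,
                   absorbance = x$absorbances,
                   inhibition_pct = round(x$inhibition, 2)),
        row.names = FALSE)
  invisible(x)
}

#' IC50 from a DPPH dose-response
#'
#' Concentration at which the scavenging percentage reaches 50\%. The
#' default estimator interpolates inhibition linearly against
#' log10(concentration) between the pair of tested concentrations that
#' bracket 50\% (assumption-light). `method = "logistic4p"` instead fits a
#' four-parameter logistic curve
#' \eqn{y = b + (a - b) / (1 + 10^{h (\log_{10} c_{mid} - \log_{10} c)}}
#' by Levenberg-Marquardt and solves the fitted curve for 50\%.
#'
#' Because only the derived inhibition percentages enter, the estimate is
#' invariant to a uniform rescaling of all absorbances (control included).
#'
#' @param dr A [dose_response()] whose inhibition crosses 50\% within the
#'   tested range; otherwise an error names the failing side
#'   (all-below/all-above).
#' @param method `"interpolation"` (default) or `"logistic4p"`.
#' @return Estimated IC50, ug/ml.
#' @examples
#' dr <- dose_response(c(5, 10, 20, 40), c(0.70, 0.52, 0.35, 0.18), 0.80)
#' ic50(dr)
#' @export
ic50 <- function(dr, method = c("interpolation", "logistic4p")) {
  stopifnot(inherits(dr, "dose_response"))
  method <- match.arg(method)
  inh <- dr$inhibition
  conc <- dr$concentrations

  hit <- which(inh == 50)
  if (method == "interpolation") {
    if (length(hit)) return(conc[hit[1]])
    below <- inh < 50
    if (all(below)) {
      stop("inhibition never reaches 50% within the tested range (all below)",
           call. = FALSE)
    }
    if (!any(below)) {
      stop("inhibition exceeds 50% at the lowest tested concentration (all above)",
           call. = FALSE)
    }
    i <- which(!below)[1]          # first concentration at/above 50%
    if (i == 1L) {
      stop("no bracketing pair below 50% on the low-concentration side",
           call. = FALSE)
    }
    lo <- i - 1L
    frac <- (50 - inh[lo]) / (inh[i] - inh[lo])
    10^(log10(conc[lo]) + frac * (log10(conc[i]) - log10(conc[lo])))
  } else {
    fit_4pl_ic50(conc, inh)
  }
}

# 4PL fit on log10 concentration, then solve the fitted curve for 50%.
fit_4pl_ic50 <- function(conc, inh) {
  lx <- log10(conc)
  start <- c(bottom = min(inh), top = max(inh),
             logmid = stats::median(lx), h = 1)
  f4 <- function(p, x) {
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["h"]] * (p[["logmid"]] - x)))
  }
  run <- lm_run(start, function(p) f4(p, lx) - inh,
                tol = 1e-10, max_iter = 500L)
  p <- run$theta
  lo <- f4(p, min(lx) - 3)
  hi <- f4(p, max(lx) + 3)
  if (min(lo, hi) > 50 || max(lo, hi) < 50) {
    stop("fitted dose-response curve does not cross 50% inhibition",
         call. = FALSE)
  }
  root <- stats::uniroot(function(x) f4(p, x) - 50,
                         lower = min(lx) - 3, upper = max(lx) + 3,
                         tol = 1e-12)$root
  10^root
}
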