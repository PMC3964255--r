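#' Extraction time-course container
#'
#' An `extraction_curve` holds one yield-versus-time series measured at a
#' fixed design point of the one-factor-at-a-time (OFAT) screen: a factor
#' name (`"power"`, `"ethanol"` or `"preleach"`), the numeric level of that
#' factor (W, \% v/v, or min), strictly increasing sampling times in seconds
#' and the observed mangiferin yields in mg/g. It is the unit of model
#' fitting.
#'
#' @param times Sampling times, s; strictly increasing, >= 0.
#' @param yields Mangiferin content at each time, mg/g; >= 0.
#' @param factor_name One of `"power"`, `"ethanol"`, `"preleach"` (or any
#'   label for ad hoc data).
#' @param level Numeric factor level (units per factor).
#' @param replicate Optional integer replicate id.
#' @return An object of class `extraction_curve`.
#' @examples
#' extraction_curve(c(1, 5, 10, 20), c(0.05, 0.2, 0.4, 0.6),
#'                  factor_name = "power", level = 550)
#' @export
extraction_curve <- function(times, yields, factor_name = "power",
                             level = NA_real_, replicate = NA_integer_) {
  times <- as.numeric(times)
  yields <- as.numeric(yields)
  if (length(times) != length(yields)) {
    stop("times and yields must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(yields)) {
    stop("times and yields must be non-missing", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(yields < 0)) stop("yields must be >= 0", call. = FALSE)
  structure(
    list(factor_name = factor_name, level = as.numeric(level),
         times = times, yields = yields,
         replicate = as.integer(replicate)),
    class = "extraction_curve"
  )
}

#' @export
print.extraction_curve <- function(x, ...) {
  cat(sprintf("Extraction curve: %s = %s, %d time points (%g-%g s)\n",
              x$factor_name, format(x$level), length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  yield range %.4g-%.4g mg/g\n",
              min(x$yields), max(x$yields)))
  invisible(x)
}

#' @export
as.data.frame.extraction_curve <- function(x, ...) {
  data.frame(factor = x$factor_name, level = x$level,
             time_s = x$times, yield_mg_per_g = x$yields,
             stringsAsFactors = FALSE)
}

factor_unit <- function(factor_name) {
  switch(factor_name, power = "W", ethanol = "% v/v", preleach = "min",
         "")
}

#' Balanced one-factor-at-a-time dataset
#'
#' An `ofat_dataset` collects the full curve family of one screening factor:
#' every level of the factor observed on a shared extraction-time grid
#' (balanced by construction). It is the unit of the two-way ANOVA and of
#' the generalized-logistic joint fit.
#'
#' @param yields Numeric matrix, levels x times, mg/g.
#' @param levels Ordered numeric factor levels.
#' @param times Shared time grid, s, strictly increasing.
#' @param factor_name Factor label (`"power"`, `"ethanol"`, `"preleach"`).
#' @param truth Optional per-level truth parameters (simulation metadata).
#' @param noise_sd,seed Optional simulation metadata.
#' @return An object of class `ofat_dataset`.
#' @seealso [generate_ofat_dataset()], [two_way_anova()], [fit_global()]
#' @export
ofat_dataset <- function(yields, levels, times, factor_name = "power",
                         truth = NULL, noise_sd = NULL, seed = NULL) {
  yields <- as.matrix(yields)
  levels <- as.numeric(levels)
  times <- as.numeric(times)
  if (nrow(yields) != length(levels) || ncol(yields) != length(times)) {
    stop("yield matrix must be levels x times", call. = FALSE)
  }
  if (anyNA(yields)) {
    stop("unbalanced dataset: every level must be observed at every time",
         call. = FALSE)
  }
  if (any(yields < 0)) stop("yields must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  if (anyDuplicated(levels)) stop("duplicate factor levels", call. = FALSE)
  dimnames(yields) <- list(format(levels, trim = TRUE),
                           format(times, trim = TRUE))
  structure(
    list(factor_name = factor_name, levels = levels, times = times,
         yields = yields, unit = factor_unit(factor_name),
         truth = truth, noise_sd = noise_sd, seed = seed),
    class = "ofat_dataset"
  )
}

#' @export
print.ofat_dataset <- function(x, ...) {
  cat(sprintf("OFAT dataset: factor '%s', %d levels x %d times\n",
              x$factor_name, length(x$levels), length(x$times)))
  cat("  levels:", paste(format(x$levels, trim = TRUE), collapse = ", "),
      x$unit, "\n")
  cat(sprintf("  time grid %g-%g s; yields %.4g-%.4g mg/g\n",
              min(x$times), max(x$times), min(x$yields), max(x$yields)))
  if (!is.null(x$seed)) {
    cat(sprintf("  simulated: noise_sd = %g mg/g, seed = %d\n",
                x$noise_sd, x$seed))
  }
  invisible(x)
}

#' @export
as.data.frame.ofat_dataset <- function(x, ...) {
  data.frame(
    factor = x$factor_name,
    level = rep(x$levels, each = length(x$times)),
    time_s = rep(x$times, times = length(x$levels)),
    yield_mg_per_g = as.vector(t(x$yields)),
    stringsAsFactors = FALSE
  )
}

#' Extract one level's curve from an OFAT dataset
#'
#' @param dataset An [ofat_dataset()].
#' @param level Factor level to extract (must be present).
#' @return An [extraction_curve()].
#' @export
dataset_curve <- function(dataset, level) {
  stopifnot(inherits(dataset, "ofat_dataset"))
  i <- match(level, dataset$levels)
  if (is.na(i)) stop("level not present in dataset", call. = FALSE)
  extraction_curve(dataset$times, dataset$yields[i, ],
                   factor_name = dataset$factor_name, level = level)
}

#' Drop factor levels from an OFAT dataset
#'
#' Used e.g. to exclude the 900 W power level, where yield degrades rather
#' than saturates, before kinetic validation.
#'
#' @param dataset An [ofat_dataset()].
#' @param exclude Numeric levels to drop (levels not present are ignored).
#' @return The reduced `ofat_dataset`.
#' @export
exclude_levels <- function(dataset, exclude) {
  stopifnot(inherits(dataset, "ofat_dataset"))
  keep <- !(dataset$levels %in% exclude)
  if (!any(keep)) stop("all levels excluded: empty dataset", call. = FALSE)
  ofat_dataset(dataset$yields[keep, , drop = FALSE], dataset$levels[keep],
               dataset$times, dataset$factor_name,
               truth = if (!is.null(dataset$truth)) dataset$truth[keep, , drop = FALSE],
               noise_sd = dataset$noise_sd, seed = dataset$seed)
}
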