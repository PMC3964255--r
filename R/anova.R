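#' Balanced two-way ANOVA for an OFAT curve family
#'
#' Tests the effect of the screening factor and of extraction time on the
#' mangiferin yield with a balanced two-way layout and one observation per
#' cell (replicates are averaged upstream). With a single observation per
#' cell the interaction is not separable from error, so the error term is
#' the residual from the additive fit, with \eqn{(a-1)(b-1)} degrees of
#' freedom — the layout implied by the error df of the published tables
#' (e.g. 120 = 5 x 24). On a balanced grid Type I and Type III sums of
#' squares coincide, so the additive [stats::aov()] decomposition is used
#' directly; unbalanced input is rejected outright.
#'
#' Each effect row additionally reports the noncentrality parameter
#' \eqn{\lambda = df \cdot F} and the observed power, i.e. the probability
#' that a noncentral \eqn{F(df_1, df_2, \lambda)} variate exceeds the
#' central critical value at `alpha` (the convention of standard
#' statistical packages, "computed using alpha").
#'
#' @param dataset An [ofat_dataset()] (balanced by construction), or a
#'   numeric matrix levels x times.
#' @param alpha Significance level used for the observed-power column.
#' @return An object of class `anova_table`: a data.frame with one row per
#'   source (`factor`, `time`, `error`, `total`) and columns `source`,
#'   `ss`, `df`, `ms`, `f`, `p`, `noncent`, `power`. When every cell holds
#'   the same value all SS are zero and F is undefined; the result is
#'   returned with `f = NA` and attribute `zero_variance = TRUE` rather
#'   than an error.
#' @examples
#' ds <- generate_ofat_dataset("power", noise_sd = 0.01, seed = 7)
#' two_way_anova(ds)
#' @export
two_way_anova <- function(dataset, alpha = 0.05) {
  if (inherits(dataset, "ofat_dataset")) {
    y <- dataset$yields
    a_lab <- dataset$factor_name
  } else if (is.matrix(dataset) && is.numeric(dataset)) {
    y <- dataset
    a_lab <- "factor"
  } else {
    stop("dataset must be an ofat_dataset or a numeric matrix",
         call. = FALSE)
  }
  if (anyNA(y)) stop("unbalanced grid: missing cells are not supported",
                     call. = FALSE)
  a <- nrow(y)
  b <- ncol(y)
  if (a < 2L || b < 2L) stop("need >= 2 levels of each factor", call. = FALSE)
  if (!(0 < alpha && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)

  d <- data.frame(
    y = as.vector(y),
    A = factor(rep(seq_len(a), times = b)),
    B = factor(rep(seq_len(b), each = a))
  )
  ss_total <- sum((d$y - mean(d$y))^2)
  if (ss_total <= .Machine$double.eps * max(1, mean(d$y)^2) * length(d$y)) {
    tab <- anova_from_ss(0, a - 1L, 0, b - 1L, 0, (a - 1L) * (b - 1L),
                         alpha = alpha, labels = c(a_lab, "time"))
    attr(tab, "zero_variance") <- TRUE
    return(tab)
  }
  fit <- stats::aov(y ~ A + B, data = d)
  sm <- summary(fit)[[1]]
  ss <- sm[["Sum Sq"]]
  dfs <- sm[["Df"]]
  anova_from_ss(ss[1], dfs[1], ss[2], dfs[2], ss[3], dfs[3],
                alpha = alpha, labels = c(a_lab, "time"))
}

#' Assemble an ANOVA table from sums of squares
#'
#' Completes mean squares, F ratios, upper-tail p values, noncentrality
#' parameters (\eqn{\lambda = df \cdot F}) and observed power from given
#' Type III sums of squares and degrees of freedom. This is the entry
#' point for reproducing published between-subjects tables from their
#' printed SS/df entries.
#'
#' @param ss_a,df_a First main effect sum of squares and df.
#' @param ss_b,df_b Optional second main effect (omit for a one-effect
#'   table).
#' @param ss_err,df_err Error sum of squares and df; `df_err` must be >= 1.
#' @param alpha Significance level for the observed-power column.
#' @param labels Character labels for the effect rows.
#' @return An `anova_table` data.frame (see [two_way_anova()]).
#' @examples
#' anova_from_ss(10.067, 5, 1.464, 24, 0.762120, 120)
#' @export
anova_from_ss <- function(ss_a, df_a, ss_b = NULL, df_b = NULL,
                          ss_err, df_err, alpha = 0.05,
                          labels = c("factor", "time")) {
  stopifnot(df_a >= 1, df_err >= 1, ss_a >= 0, ss_err >= 0)
  srcs <- list(list(labels[1], ss_a, as.integer(df_a)))
  if (!is.null(ss_b)) {
    stopifnot(df_b >= 1, ss_b >= 0)
    srcs <- c(srcs, list(list(labels[2], ss_b, as.integer(df_b))))
  }
  ms_err <- ss_err / df_err
  rows <- lapply(srcs, function(s) {
    ms <- s[[2]] / s[[3]]
    f <- if (ms_err > 0) ms / ms_err else NA_real_
    lam <- if (is.na(f)) NA_real_ else s[[3]] * f
    data.frame(
      source = s[[1]], ss = s[[2]], df = s[[3]], ms = ms, f = f,
      p = if (is.na(f)) NA_real_ else
        stats::pf(f, s[[3]], df_err, lower.tail = FALSE),
      noncent = lam,
      power = if (is.na(lam)) NA_real_ else
        observed_power(lam, s[[3]], df_err, alpha),
      stringsAsFactors = FALSE
    )
  })
  err <- data.frame(source = "error", ss = ss_err, df = as.integer(df_err),
                    ms = ms_err, f = NA_real_, p = NA_real_,
                    noncent = NA_real_, power = NA_real_,
                    stringsAsFactors = FALSE)
  tot_ss <- ss_a + (if (is.null(ss_b)) 0 else ss_b) + ss_err
  tot_df <- df_a + (if (is.null(df_b)) 0L else as.integer(df_b)) +
    as.integer(df_err)
  tot <- data.frame(source = "total", ss = tot_ss, df = tot_df,
                    ms = NA_real_, f = NA_real_, p = NA_real_,
                    noncent = NA_real_, power = NA_real_,
                    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), err, tot)
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"), alpha = alpha)
}

#' Observed power of an F test
#'
#' Probability that a noncentral \eqn{F(df_1, df_2, \lambda)} variate
#' exceeds the central critical value \eqn{F_{1-\alpha}(df_1, df_2)}:
#' the "observed power, computed using alpha" column of standard ANOVA
#' output. Monotone increasing in \eqn{\lambda}; equals `alpha` when
#' \eqn{\lambda = 0}.
#'
#' @param lambda Noncentrality parameter, >= 0.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param alpha Significance level.
#' @return Power in \[0, 1\].
#' @examples
#' observed_power(1584.685, 5, 120)
#' @export
observed_power <- function(lambda, df1, df2, alpha = 0.05) {
  stopifnot(lambda >= 0, df1 >= 1, df2 >= 1, 0 < alpha, alpha < 1)
  # beyond this the noncentral beta series underflows; power is 1 to
  # double precision long before
  if (lambda > 5e4) return(1)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  cat(sprintf("Two-way ANOVA (balanced, one observation per cell; alpha = %g)\n",
              attr(x, "alpha")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "zero_variance"))) {
    cat("note: zero variance across all cells; F undefined\n")
  }
  invisible(x)
}
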