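#' Student-Newman-Keuls (SNK) post hoc ranking
#'
#' Ranks treatment means into homogeneous subsets with the stepwise
#' studentized-range procedure. Means are sorted in decreasing order; a
#' stretch of `r` consecutive ordered means is declared homogeneous when
#' its range does not exceed the critical value
#' \eqn{q_{\alpha}(r, df_{err}) \sqrt{MS_{err}/n}}, where the studentized
#' range quantile shrinks with the span `r`. Testing proceeds step-down
#' from the full span: once a stretch is accepted as homogeneous no
#' stretch inside it is tested (the standard non-testing rule), otherwise
#' its two maximal sub-stretches are examined. Every mean belongs to at
#' least one (maximal) subset; subsets are contiguous runs of the ordered
#' means. Adding a constant to all means leaves the subsets unchanged.
#'
#' The error mean square normally comes from the ANOVA of the same layout
#' (so per-group `n` may be the number of observations averaged into each
#' mean). A zero `ms_error` is degenerate: exactly equal means group
#' together and every distinct mean becomes its own subset.
#'
#' @param means Per-level mean yields, mg/g (named or unnamed).
#' @param n_per_mean Number of observations per mean.
#' @param ms_error Error mean square from the ANOVA, >= 0.
#' @param df_error Error degrees of freedom.
#' @param alpha Significance level.
#' @return An object of class `snk_result`: list with `means` (sorted
#'   decreasing, named), `subsets` (list of character vectors of level
#'   names), `critical_ranges` (per span r = 2..k), `alpha`.
#' @examples
#' snk_test(c(`550` = 0.71, `500` = 0.64, `450` = 0.62, `250` = 0.014),
#'          n_per_mean = 25, ms_error = 0.006353, df_error = 120)
#' @export
snk_test <- function(means, n_per_mean, ms_error, df_error, alpha = 0.05) {
  k <- length(means)
  if (k < 2L) stop("need >= 2 means", call. = FALSE)
  stopifnot(ms_error >= 0, df_error >= 1, n_per_mean >= 1,
            0 < alpha, alpha < 1)
  if (is.null(names(means))) names(means) <- as.character(seq_len(k))
  m <- sort(means, decreasing = TRUE)
  se <- sqrt(ms_error / n_per_mean)
  crit <- vapply(2:k, function(r) {
    if (se == 0) 0 else stats::qtukey(1 - alpha, r, df_error) * se
  }, numeric(1))
  names(crit) <- paste0("r", 2:k)

  accepted <- list()
  # step-down recursion over ordered stretches [i, j]
  test_stretch <- function(i, j) {
    if (j <= i) {
      accepted[[length(accepted) + 1L]] <<- c(i, i)
      return(invisible(NULL))
    }
    r <- j - i + 1L
    if (m[i] - m[j] <= crit[[r - 1L]]) {
      accepted[[length(accepted) + 1L]] <<- c(i, j)
    } else {
      test_stretch(i, j - 1L)
      test_stretch(i + 1L, j)
    }
    invisible(NULL)
  }
  test_stretch(1L, k)

  # keep maximal stretches only
  iv <- unique(accepted)
  maximal <- Filter(function(s) {
    !any(vapply(iv, function(o) {
      (o[1] <= s[1] && s[2] <= o[2]) && !(o[1] == s[1] && o[2] == s[2])
    }, logical(1)))
  }, iv)
  ord <- order(vapply(maximal, `[`, numeric(1), 1))
  subsets <- lapply(maximal[ord], function(s) names(m)[s[1]:s[2]])

  structure(list(means = m, subsets = subsets, critical_ranges = crit,
                 n_per_mean = n_per_mean, ms_error = ms_error,
                 df_error = df_error, alpha = alpha),
            class = "snk_result")
}

#' @export
print.snk_result <- function(x, ...) {
  cat(sprintf("Newman-Keuls ranking (alpha = %g, df_error = %g)\n",
              x$alpha, x$df_error))
  memb <- vapply(names(x$means), function(nm) {
    paste(vapply(seq_along(x$subsets),
                 function(i) if (nm %in% x$subsets[[i]]) letters[i] else "",
                 character(1)), collapse = "")
  }, character(1))
  print(data.frame(level = names(x$means),
                   mean = unname(x$means),
                   subset = unname(memb)),
        row.names = FALSE)
  invisible(x)
}
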