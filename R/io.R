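#' Read extraction curves from tidy CSV
#'
#' Reads a tidy time-course table with header exactly
#' `factor,level,time_s,yield_mg_per_g` and an optional trailing
#' `replicate` column (UTF-8, comma separator, period decimal, no
#' thousands separators). Rows sharing (factor, level, time) across
#' replicates are averaged unless `keep_replicates = TRUE`. Malformed
#' input — a missing column, a non-numeric cell, or a duplicated
#' (level, time, replicate) row — raises a parse error naming the
#' offending line.
#'
#' @param path CSV file path.
#' @param keep_replicates Keep one curve per replicate id instead of
#'   averaging.
#' @return A list of [extraction_curve()] objects (one per factor level,
#'   or per level x replicate).
#' @seealso [write_curves()], [as_ofat_dataset()]
#' @export
read_curves <- function(path, keep_replicates = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("factor", "level", "time_s", "yield_mg_per_g")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("parse error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_rep <- "replicate" %in% names(raw)
  if (nrow(raw) == 0) stop("parse error: no data rows", call. = FALSE)

  num_cols <- c("level", "time_s", "yield_mg_per_g",
                if (has_rep) "replicate")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !(cl == "replicate" & raw[[cl]] == ""))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value '%s' in column '%s' at line %d",
                   raw[[cl]][bad[1]], cl, bad[1] + 1L), call. = FALSE)
    }
    raw[[cl]] <- v
  }
  if (!has_rep) raw$replicate <- NA_integer_

  key <- paste(raw$factor, raw$level, raw$time_s, raw$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("parse error: duplicated (level, time%s) row at line %d",
                 if (has_rep) ", replicate" else "", dup[1] + 1L),
         call. = FALSE)
  }

  if (!keep_replicates) {
    agg <- stats::aggregate(yield_mg_per_g ~ factor + level + time_s,
                            data = raw, FUN = mean)
    agg$replicate <- NA_integer_
    raw <- agg
  }
  split_key <- paste(raw$factor, raw$level, raw$replicate, sep = "\r")
  parts <- split(raw, split_key)
  curves <- lapply(parts, function(d) {
    d <- d[order(d$time_s), ]
    extraction_curve(d$time_s, d$yield_mg_per_g,
                     factor_name = d$factor[1], level = d$level[1],
                     replicate = d$replicate[1])
  })
  ord <- order(vapply(curves, function(cv) cv$level, numeric(1)))
  unname(curves[ord])
}

#' Write curves or a dataset to tidy CSV
#'
#' Inverse of [read_curves()]; writes the tidy
#' `factor,level,time_s,yield_mg_per_g` layout.
#'
#' @param x An [ofat_dataset()], an [extraction_curve()], or a list of
#'   curves.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(x, path) {
  if (inherits(x, "extraction_curve")) x <- list(x)
  df <- if (inherits(x, "ofat_dataset")) {
    as.data.frame(x)
  } else {
    do.call(rbind, lapply(x, as.data.frame))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble curves into a balanced OFAT dataset
#'
#' @param curves List of [extraction_curve()] objects sharing one factor
#'   and one time grid (e.g. from [read_curves()]).
#' @return An [ofat_dataset()]; errors if the grids differ (unbalanced).
#' @export
as_ofat_dataset <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "extraction_curve")))
  fac <- unique(vapply(curves, function(cv) cv$factor_name, character(1)))
  if (length(fac) != 1L) {
    stop("curves span multiple factors: ", paste(fac, collapse = ", "),
         call. = FALSE)
  }
  times <- curves[[1]]$times
  same <- vapply(curves, function(cv) {
    length(cv$times) == length(times) && all(cv$times == times)
  }, logical(1))
  if (!all(same)) {
    stop("unbalanced curve family: time grids differ across levels",
         call. = FALSE)
  }
  levels <- vapply(curves, function(cv) cv$level, numeric(1))
  y <- do.call(rbind, lapply(curves, function(cv) cv$yields))
  ord <- order(levels)
  ofat_dataset(y[ord, , drop = FALSE], levels[ord], times, fac)
}
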