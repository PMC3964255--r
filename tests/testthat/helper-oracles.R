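# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Definitional two-way ANOVA sums of squares by explicit double sums over
# the a x b grid (one observation per cell; error = interaction residual).
bf_anova_ss <- function(y) {
  a <- nrow(y); b <- ncol(y)
  grand <- mean(y)
  ss_a <- 0; ss_b <- 0; ss_err <- 0; ss_tot <- 0
  for (i in seq_len(a)) {
    for (j in seq_len(b)) {
      mi <- mean(y[i, ]); mj <- mean(y[, j])
      ss_a <- ss_a + (mi - grand)^2
      ss_b <- ss_b + (mj - grand)^2
      ss_err <- ss_err + (y[i, j] - mi - mj + grand)^2
      ss_tot <- ss_tot + (y[i, j] - grand)^2
    }
  }
  list(ss_a = ss_a, df_a = a - 1L, ss_b = ss_b, df_b = b - 1L,
       ss_err = ss_err, df_err = (a - 1L) * (b - 1L), ss_total = ss_tot)
}

# Step-down Newman-Keuls by exhaustive iteration over contiguous spans of
# the descending-sorted means, largest span first, with the standard
# non-testing rule inside accepted spans.
bf_snk_subsets <- function(means, n, ms_error, df_error, alpha = 0.05) {
  m <- sort(means, decreasing = TRUE)
  k <- length(m)
  accepted <- matrix(FALSE, k, k)  # accepted[i, j]: span i..j homogeneous
  for (r in k:2) {
    for (i in seq_len(k - r + 1L)) {
      j <- i + r - 1L
      inside <- FALSE
      for (ii in seq_len(k)) for (jj in seq_len(k)) {
        if (accepted[ii, jj] && ii <= i && j <= jj) inside <- TRUE
      }
      if (inside) next
      crit <- if (ms_error == 0) 0 else
        qtukey(1 - alpha, r, df_error) * sqrt(ms_error / n)
      if (m[i] - m[j] <= crit) accepted[i, j] <- TRUE
    }
  }
  subs <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if ((i == j || accepted[i, j])) {
      contained <- FALSE
      for (ii in seq_len(k)) for (jj in ii:k) {
        if ((ii != i || jj != j) && (ii == jj || accepted[ii, jj]) &&
            ii <= i && j <= jj) contained <- TRUE
      }
      if (!contained) subs[[length(subs) + 1L]] <- names(m)[i:j]
    }
  }
  subs[order(vapply(subs, function(s) match(s[1], names(m)), integer(1)))]
}

# Exhaustive grid search over a parameter bounding box; returns the best
# sum-of-squares objective found.
bf_grid_objective <- function(times, yields, model, box, n_grid = 41L) {
  grids <- lapply(box, function(b) seq(b[1], b[2], length.out = n_grid))
  best <- Inf
  if (model == "first_order") {
    for (ym in grids$y_max) for (km in grids$k_m) {
      r <- ym * (1 - exp(-km * times)) - yields
      best <- min(best, sum(r^2))
    }
  } else {
    for (ym in grids$y_max) for (km in grids$k_m) for (tu in grids$tau) {
      r <- ym / (1 + exp(-km * (times - tu))) - yields
      best <- min(best, sum(r^2))
    }
  }
  best
}

ref_logistic_550 <- c(y_max = 0.713695, k_m = 0.125821, tau = 10.917342)
ref_first_order_550 <- c(y_max = 0.718277, k_m = 0.073040)
ref_global_power <- c(ref = 759.42, k_m = 0.14, tau = 11.68, amplitude = 1)

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
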