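test_that("sums of squares match definitional double sums on random grids", {
  set.seed(42)
  for (rep in 1:10) {
    y <- matrix(rnorm(12, mean = 1), nrow = 3, ncol = 4)
    y <- abs(y)
    tab <- two_way_anova(y)
    bf <- bf_anova_ss(y)
    expect_equal(tab$ss[tab$source == "factor"], bf$ss_a, tolerance = 1e-9)
    expect_equal(tab$ss[tab$source == "time"], bf$ss_b, tolerance = 1e-9)
    expect_equal(tab$ss[tab$source == "error"], bf$ss_err, tolerance = 1e-9)
    expect_equal(tab$df[1:3], c(bf$df_a, bf$df_b, bf$df_err))
    # decomposition: ss_A + ss_B + ss_error = ss_total
    expect_equal(sum(tab$ss[tab$source != "total"]),
                 tab$ss[tab$source == "total"], tolerance = 1e-9)
    expect_equal(tab$ss[tab$source == "total"], bf$ss_total,
                 tolerance = 1e-9)
  }
})

test_that("the factor/time orientation of a dataset is preserved", {
  ds <- generate_ofat_dataset("power", noise_sd = 0.01, seed = 15)
  tab <- two_way_anova(ds)
  bf <- bf_anova_ss(ds$yields)
  expect_equal(tab$ss[tab$source == "power"], bf$ss_a, tolerance = 1e-9)
  expect_equal(tab$df[tab$source == "power"], length(ds$levels) - 1L)
  expect_equal(tab$df[tab$source == "time"], length(ds$times) - 1L)
})

test_that("degenerate grids are handled: constant cells and exact additivity", {
  flat <- matrix(0.5, 4, 6)
  tab <- two_way_anova(flat)
  expect_true(isTRUE(attr(tab, "zero_variance")))
  expect_true(all(tab$ss == 0))
  expect_true(is.na(tab$f[1]))

  a_eff <- c(0.1, 0.4, 0.9)
  b_eff <- c(0.0, 0.2, 0.3, 0.5)
  additive <- outer(a_eff, b_eff, `+`)
  tab2 <- two_way_anova(additive)
  expect_lt(tab2$ss[tab2$source == "error"], 1e-12)
})

test_that("published between-subjects tables are reproduced from their SS and df", {
  # power x time layout
  t1 <- anova_from_ss(10.067, 5, 1.464, 24, 0.762120, 120)
  expect_equal(t1$f[1], 316.937, tolerance = 5e-3)
  expect_equal(t1$f[2], 9.604, tolerance = 5e-3)
  expect_equal(t1$df[1] * t1$f[1], 1584.685, tolerance = 5e-3)
  expect_equal(round(t1$power[1], 3), 1)
  # ethanol x time layout
  t2 <- anova_from_ss(0.373, 5, 4.499, 24, 2.278e-2, 120)
  expect_equal(t2$f[1], 392.693, tolerance = 5e-3)
  expect_equal(t2$f[2], 987.452, tolerance = 5e-3)
  # pre-leach x time layout
  t3 <- anova_from_ss(3.711e-2, 6, 10.311, 24, 3.506e-3, 144)
  expect_equal(t3$f[1], 254.053, tolerance = 5e-3)
  expect_equal(t3$f[2], 17644.599, tolerance = 5e-3)
  # trivial check of the F ratio arithmetic
  expect_equal(anova_from_ss(1, 1, ss_err = 1, df_err = 1)$f[1], 1)
})

test_that("observed power behaves like the noncentral F upper tail", {
  expect_equal(observed_power(0, 5, 120, alpha = 0.05), 0.05)
  expect_equal(round(observed_power(1584.685, 5, 120), 3), 1)
  lam <- seq(0, 30, by = 5)
  pow <- vapply(lam, observed_power, numeric(1), df1 = 2, df2 = 10)
  expect_true(all(diff(pow) > 0))
  expect_true(all(pow >= 0 & pow <= 1))
  # Monte-Carlo oracle (reduced draw count; full-size check in acceptance)
  set.seed(8)
  n_mc <- 2e5
  fcrit <- qf(0.95, 2, 10)
  draws <- rf(n_mc, 2, 10, ncp = 5)
  mc <- mean(draws > fcrit)
  se <- sqrt(mc * (1 - mc) / n_mc)
  expect_lt(abs(observed_power(5, 2, 10) - mc), 3 * se)
})

test_that("unbalanced or undersized grids are rejected", {
  y <- matrix(rnorm(12), 3, 4)
  y[2, 3] <- NA
  expect_error(two_way_anova(y), "unbalanced")
  expect_error(two_way_anova(matrix(1:4, 1, 4)), ">= 2 levels")
  expect_error(anova_from_ss(1, 1, ss_err = 1, df_err = 0), "df_err")
})
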