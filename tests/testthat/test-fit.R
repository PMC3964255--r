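test_that("heuristic starting values track the curve shape", {
  tg <- extraction_time_grid()
  cv <- extraction_curve(tg, logistic_yield(tg, 0.714, 0.126, 10.92))
  g <- initial_guess(cv, "logistic")
  # delay guess within one grid step (5 s) of the true midpoint
  expect_lte(abs(g[["tau"]] - 10.92), 5)
  expect_equal(g[["y_max"]], max(cv$yields))

  # monotone noiseless first-order curve: asymptote guess = last yield
  cf <- extraction_curve(tg, first_order_yield(tg, 0.72, 0.073))
  expect_equal(initial_guess(cf, "first_order")[["y_max"]],
               cf$yields[length(cf$yields)])

  expect_error(initial_guess(extraction_curve(1:5, rep(0, 5))),
               "degenerate")
})

test_that("noiseless curves at the reference parameters are recovered to 1e-6", {
  tg <- extraction_time_grid()
  cv_fo <- extraction_curve(tg, first_order_yield(tg,
    ref_first_order_550[["y_max"]], ref_first_order_550[["k_m"]]))
  f_fo <- fit_curve(cv_fo, "first_order")
  expect_true(f_fo$converged)
  expect_true(all(rel_err(coef(f_fo), ref_first_order_550) < 1e-6))
  expect_lt(f_fo$gof, 1e-8)

  cv_lg <- extraction_curve(tg, logistic_yield(tg,
    ref_logistic_550[["y_max"]], ref_logistic_550[["k_m"]],
    ref_logistic_550[["tau"]]))
  f_lg <- fit_curve(cv_lg, "logistic")
  expect_true(all(rel_err(coef(f_lg), ref_logistic_550) < 1e-6))
  expect_lt(f_lg$gof, 1e-8)
})

test_that("too few points raise an insufficient-data error", {
  expect_error(fit_curve(extraction_curve(c(1, 5, 10), c(0.1, 0.2, 0.3)),
                         "first_order"), "insufficient")
  expect_error(fit_curve(extraction_curve(c(1, 5, 10, 15), c(0.1, 0.2, 0.3, 0.33)),
                         "logistic"), "insufficient")
})

test_that("fits are deterministic for identical inputs and tolerances", {
  cv <- generate_curve(ref_logistic_550, "logistic", noise_sd = 0.01,
                       seed = 99)
  f1 <- fit_curve(cv, "logistic")
  f2 <- fit_curve(cv, "logistic")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rms, f2$rms)
  expect_identical(f1$n_iter, f2$n_iter)
})

test_that("optimizer objective beats an exhaustive grid search on short curves", {
  set.seed(7)
  for (model in c("first_order", "logistic")) {
    tg <- c(2, 10, 25, 45, 70, 110)
    truth <- if (model == "first_order") c(y_max = 0.7, k_m = 0.08)
             else c(y_max = 0.7, k_m = 0.13, tau = 11)
    mu <- switch(model,
        first_order = first_order_yield(tg, truth[["y_max"]], truth[["k_m"]]),
        logistic = logistic_yield(tg, truth[["y_max"]], truth[["k_m"]],
                                  truth[["tau"]]))
    y <- pmax(mu + rnorm(6, 0, 0.02), 0)
    cv <- extraction_curve(tg, y)
    fit <- fit_curve(cv, model)
    box <- list(y_max = c(0.2, 1.5), k_m = c(0.02, 0.4), tau = c(0, 30))
    grid_best <- bf_grid_objective(tg, y, model, box, n_grid = 31L)
    # the continuous optimizer must do at least as well as any grid point
    expect_lte(deviance(fit), grid_best + 1e-12)
  }
})

test_that("goodness ratio matches hand arithmetic and is scale invariant", {
  expect_identical(gof_ratio(0, 0.5), 0)
  expect_identical(gof_ratio(0.5, 0.5), 1)
  r <- c(0.01, -0.01, 0.02, 0, -0.02)
  rms <- sqrt(mean(r^2))
  expect_equal(rms, 0.014142135623730950, tolerance = 1e-15)
  expect_equal(gof_ratio(rms, 0.5), 0.028284271247461901, tolerance = 1e-15)
  expect_error(gof_ratio(0.1, 0), "y_max")
  for (c_scale in c(0.1, 3, 1e4)) {
    expect_equal(gof_ratio(c_scale * rms, c_scale * 0.5),
                 gof_ratio(rms, 0.5))
  }
})

test_that("stochastic replicates recover parameters with the expected noise floor", {
  # reduced-size version of the 200-replicate study in the acceptance suite
  set.seed(11)
  tg <- extraction_time_grid()
  errs <- replicate(40, {
    cv <- generate_curve(ref_logistic_550, "logistic", tg, noise_sd = 0.01)
    f <- fit_curve(cv, "logistic")
    c(rel_err(coef(f), ref_logistic_550), gof = f$gof)
  })
  expect_lt(median(errs["y_max", ]), 0.05)
  expect_lt(median(errs["k_m", ]), 0.05)
  expect_lt(median(errs["tau", ]), 0.05)
  expect_gt(mean(errs["gof", ]), 0.005)
  expect_lt(mean(errs["gof", ]), 0.05)
})

test_that("multistart keeps the best objective and reports covariance", {
  cv <- generate_curve(ref_logistic_550, "logistic", noise_sd = 0.01,
                       seed = 5)
  f1 <- fit_curve(cv, "logistic")
  fm <- fit_curve(cv, "logistic", multistart = TRUE)
  expect_lte(deviance(fm), deviance(f1) + 1e-12)
  expect_false(isTRUE(attr(vcov(fm), "singular")))
  expect_equal(dim(vcov(fm)), c(3, 3))
})
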