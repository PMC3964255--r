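make_global_dataset <- function(noise_sd = 0, seed = 1, levels = NULL,
                                include_900 = FALSE) {
  generate_ofat_dataset("power", levels = levels, noise_sd = noise_sd,
                        seed = seed, truth_model = "global",
                        include_900 = include_900)
}

test_that("noiseless joint data at the reference truth are recovered to 1e-6", {
  ds <- make_global_dataset()
  fit <- fit_global(ds)
  expect_true(fit$converged)
  expect_true(all(rel_err(coef(fit), ref_global_power) < 1e-6))
})

test_that("amplitude re-solve at the optimum leaves the objective unchanged", {
  ds <- make_global_dataset(noise_sd = 0.01, seed = 3)
  fit <- fit_global(ds)
  p <- coef(fit)
  tt <- rep(ds$times, times = length(ds$levels))
  xx <- rep(ds$levels, each = length(ds$times))
  yy <- as.vector(t(ds$yields))
  g <- (1 - exp(-xx / p[["ref"]])) / (1 + exp(-p[["k_m"]] * (tt - p[["tau"]])))
  a_star <- sum(g * yy) / sum(g * g)
  obj_resolved <- sum((a_star * g - yy)^2)
  expect_lt(abs(obj_resolved - deviance(fit)), 1e-12)
  expect_equal(a_star, p[["amplitude"]], tolerance = 1e-10)
})

test_that("explicit 900 W exclusion equals a dataset never containing 900 W", {
  with_900 <- generate_ofat_dataset("power", noise_sd = 0.01, seed = 21,
                                    include_900 = TRUE)
  without <- exclude_levels(with_900, 900)
  f1 <- fit_global(with_900, exclusions = 900)
  f2 <- fit_global(without, exclusions = numeric(0))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rms, f2$rms)
})

test_that("with ref fixed, a single-level joint fit reduces to the per-level logistic", {
  ds <- generate_ofat_dataset("power", levels = 550, noise_sd = 0.01,
                              seed = 9)
  cv <- dataset_curve(ds, 550)
  gf <- fit_global(ds, exclusions = numeric(0), fix_ref = 759.42)
  lf <- fit_curve(cv, "logistic")
  expect_lt(abs(deviance(gf) - deviance(lf)), 1e-10)
})

test_that("the constrained joint objective is never below the free per-level fits", {
  for (seed in c(2, 12)) {
    ds <- make_global_dataset(noise_sd = 0.015, seed = seed)
    gf <- fit_global(ds)
    per_level <- sum(vapply(ds$levels, function(lv) {
      deviance(fit_curve(dataset_curve(ds, lv), "logistic"))
    }, numeric(1)))
    expect_gte(deviance(gf), per_level - 1e-10)
  }
})

test_that("pooled goodness indicator uses the maximum fitted yield", {
  ds <- make_global_dataset(noise_sd = 0.01, seed = 4)
  fit <- fit_global(ds)
  expect_equal(fit$gof, fit$rms / max(fitted(fit)))
})

test_that("an injected alternative shape strategy is honoured", {
  # same separable algebra passed explicitly must reproduce the default
  ds <- make_global_dataset(noise_sd = 0.01, seed = 6)
  shape <- function(t, x, ref, k_m, tau) {
    (1 - exp(-x / ref)) / (1 + exp(-k_m * (t - tau)))
  }
  f1 <- fit_global(ds)
  f2 <- fit_global(ds, shape = shape)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("excluding every level is an error", {
  ds <- make_global_dataset()
  expect_error(exclude_levels(ds, ds$levels), "all levels excluded")
})
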