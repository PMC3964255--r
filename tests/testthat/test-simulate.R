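test_that("reference parameter tables have the published shape and entries", {
  pw <- default_truth("power")
  expect_equal(pw$level, c(250, 350, 450, 500, 550))
  row550 <- pw[pw$level == 550, ]
  expect_equal(unlist(row550[c("y_max", "k_m", "tau")], use.names = FALSE),
               c(0.713695, 0.125821, 10.917342))
  et <- default_truth("ethanol")
  row80 <- et[et$level == 80, ]
  expect_equal(unlist(row80[c("y_max", "k_m", "tau")], use.names = FALSE),
               c(0.885108, 0.126128, 10.886925))
  expect_equal(nrow(default_truth("preleach")), 7)
  expect_equal(nrow(default_truth("preleach", "first_order")), 7)
  expect_null(default_truth("power", "first_order")$tau)
  expect_error(default_truth("humidity"), "arg")
})

test_that("noiseless generation reproduces the forward model exactly", {
  tg <- extraction_time_grid()
  cv <- generate_curve(ref_logistic_550, "logistic", tg, noise_sd = 0)
  expect_equal(cv$yields,
               logistic_yield(tg, ref_logistic_550[["y_max"]],
                              ref_logistic_550[["k_m"]],
                              ref_logistic_550[["tau"]]))
})

test_that("generation is reproducible for a fixed seed", {
  c1 <- generate_curve(ref_logistic_550, "logistic", noise_sd = 0.01,
                       seed = 123)
  c2 <- generate_curve(ref_logistic_550, "logistic", noise_sd = 0.01,
                       seed = 123)
  expect_identical(c1$yields, c2$yields)
  d1 <- generate_ofat_dataset("ethanol", noise_sd = 0.01, seed = 5)
  d2 <- generate_ofat_dataset("ethanol", noise_sd = 0.01, seed = 5)
  expect_identical(d1$yields, d2$yields)
})

test_that("the realized noise matches its nominal standard deviation", {
  set.seed(2024)
  mu <- logistic_yield(60, 0.713695, 0.125821, 10.917342)
  # generator route at a single time, many replicates
  reps <- replicate(1e4, generate_curve(ref_logistic_550, "logistic",
                                        times = 60, noise_sd = 0.01)$yields)
  expect_lt(abs(sd(reps) - 0.01) / 0.01, 0.03)
  expect_lt(abs(mean(reps) - mu), 5e-4)
})

test_that("default designs have the published layout", {
  dp <- generate_ofat_dataset("power", noise_sd = 0.01, seed = 1)
  expect_equal(dim(dp$yields), c(5, 25))
  expect_equal(dp$times, c(1, seq(5, 120, by = 5)))
  dl <- generate_ofat_dataset("preleach", noise_sd = 0.01, seed = 1)
  # error df (a-1)(b-1) = 6 x 24 = 144 for the pre-leach layout
  tab <- two_way_anova(dl)
  expect_equal(tab$df[tab$source == "error"], 144L)
  d9 <- generate_ofat_dataset("power", noise_sd = 0.01, seed = 1,
                              include_900 = TRUE)
  expect_equal(d9$levels, c(250, 350, 450, 500, 550, 900))
  # the stress level peaks and then decays
  y900 <- d9$yields["900", ]
  expect_gt(max(y900), y900[length(y900)])
})

test_that("noiseless default ethanol curves refit to the reference parameters", {
  ds <- generate_ofat_dataset("ethanol", noise_sd = 0, seed = 1)
  truth <- default_truth("ethanol")
  for (lv in ds$levels) {
    f <- fit_curve(dataset_curve(ds, lv), "logistic")
    row <- truth[truth$level == lv, ]
    expect_true(all(rel_err(coef(f),
      c(row$y_max, row$k_m, row$tau)) < 1e-6), label = paste("level", lv))
  }
})

test_that("truncation at zero is negligible where yields dominate the noise", {
  # the weakest-signal default truth (250 W) sits at the noise floor and is
  # exempt by construction; all other defaults satisfy mu >> sd everywhere
  truth <- default_truth("power")
  truth <- truth[truth$y_max > 0.1, ]
  tg <- extraction_time_grid()
  for (i in seq_len(nrow(truth))) {
    mu <- logistic_yield(tg, truth$y_max[i], truth$k_m[i], truth$tau[i])
    z <- mu / 0.01
    bias <- 0.01 * dnorm(z) - mu * pnorm(-z)  # E[max(X,0)] - mu, closed form
    expect_true(all(bias < 1e-4))
  }
})

test_that("simulation pipeline finds the factor effect and the top level", {
  hits <- 0L
  signif_all <- TRUE
  for (seed in 1:100) {
    ds <- generate_ofat_dataset("power", noise_sd = 0.01, seed = seed)
    tab <- two_way_anova(ds)
    signif_all <- signif_all && tab$p[tab$source == "power"] < 0.05
    means <- rowMeans(ds$yields)
    names(means) <- format(ds$levels, trim = TRUE)
    s <- snk_test(means, n_per_mean = length(ds$times),
                  ms_error = tab$ms[tab$source == "error"],
                  df_error = tab$df[tab$source == "error"])
    if ("550" %in% s$subsets[[1]]) hits <- hits + 1L
  }
  expect_true(signif_all)
  expect_gte(hits, 95L)
  # per-level fits converge on a spot-check seed
  ds <- generate_ofat_dataset("power", noise_sd = 0.01, seed = 1)
  fits <- fit_levels(ds, "logistic")
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
})
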