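test_that("the default design produces the full sampled-plantation layout", {
  sim <- simulate_taper_data(seed = 17)
  expect_equal(n_trees(sim$data), 396)          # 132 plots x 3 trees
  expect_equal(nrow(sim$data), 4356)            # 11 sections per tree
  counts <- dplyr::count(sim$data, .data$plot_id, .data$tree_id)
  expect_true(all(counts$n == 11))
  expect_equal(dplyr::n_distinct(sim$data$plot_id), 132)
  # covariates stay inside their design ranges
  expect_true(all(sim$data$D_cm >= 15.1 & sim$data$D_cm <= 28.8))
  expect_true(all(sim$data$H_m >= 10.4 & sim$data$H_m <= 22.8))
  expect_true(all(sim$data$Sd_trees_ha >= 90 & sim$data$Sd_trees_ha <= 2580))
  expect_true(all(sim$data$Cd >= 0.2 & sim$data$Cd <= 0.9))
})

test_that("generation is exactly reproducible by seed", {
  a <- simulate_taper_data(n_plots = 6, seed = 23)
  b <- simulate_taper_data(n_plots = 6, seed = 23)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$effects, b$truth$effects)
  c <- simulate_taper_data(n_plots = 6, seed = 24)
  expect_false(identical(a$data$d_cm, c$data$d_cm))
})

test_that("noiseless degenerate configuration lies exactly on the truth curve", {
  sim <- simulate_taper_data(n_plots = 4, re_sd = c(0, 0), sigma = 0,
                             seed = 25)
  mu <- eval_taper("kozak2004_inv_Sd", sim$truth$params, sim$data)
  expect_equal(sim$data$d_cm, pmax(mu, 0), tolerance = 1e-12)
})

test_that("DBH marginals match the design statistics across seeds", {
  stats <- t(vapply(1:5, function(s) {
    sim <- simulate_taper_data(seed = 100 + s)
    tr <- dplyr::distinct(tibble::as_tibble(sim$data),
                          .data$plot_id, .data$tree_id, .data$D_cm)
    c(mean(tr$D_cm), sd(tr$D_cm))
  }, numeric(2)))
  expect_lt(abs(mean(stats[, 1]) - 21.0), 0.2)
  expect_lt(abs(mean(stats[, 2]) - 3.4), 0.2)
})

test_that("section noise is calibrated to the configured sigma", {
  sim <- simulate_taper_data(re_sd = c(0, 0), seed = 26)
  mu <- eval_taper("kozak2004_inv_Sd", sim$truth$params, sim$data)
  resid_sd <- sd(sim$data$d_cm - mu)
  expect_lt(abs(resid_sd / sqrt(0.5791) - 1), 0.03)
})

test_that("a b6 perturbation shifts the mid-stem one-sidedly against a paired stream", {
  base <- simulate_profile(D = 21, H = 17.2, Sd = 787, sigma = 0)
  bumped <- simulate_profile(D = 21, H = 17.2, Sd = 787, sigma = 0,
                             random = 6L, effects = 0.05)
  mid <- base$h_m / base$H_m >= 0.2 & base$h_m / base$H_m <= 0.8
  # above breast height Z < 1, so d mu / d b6 = mu ln(Z) Z^0.1 < 0: a
  # positive b6 effect systematically narrows the mid-stem
  expect_true(all(bumped$d_cm[mid] < base$d_cm[mid]))
  expect_gt(mean(base$d_cm[mid] - bumped$d_cm[mid]), 0.05)
  expect_error(simulate_profile(D = 21, H = 17.2, Sd = 787,
                                heights = c(5, 18)),
               class = "stemtaper_domain_error")
})

test_that("full-loop recovery: the generator is a faithful oracle for fitting", {
  # noiseless loop recovers the truth vector essentially exactly
  sim0 <- simulate_taper_data(re_sd = c(0, 0), sigma = 0, seed = 27)
  fit0 <- fit_taper_nls(sim0$data, "kozak2004_inv_Sd",
                        start = sim0$truth$params * 0.95)
  expect_lt(max(abs(fit0$estimates - sim0$truth$params) /
                  abs(sim0$truth$params)), 1e-4)
  # at the default noise every estimate sits within 3 approximate SEs
  sim1 <- simulate_taper_data(re_sd = c(0, 0), seed = 27)
  fit1 <- fit_taper_nls(sim1$data, "kozak2004_inv_Sd")
  z <- abs(fit1$estimates - sim1$truth$params) / fit1$std_errors
  expect_true(all(z < 3))
})

test_that("invalid configurations fail before any draw", {
  expect_error(simulate_taper_data(rel_heights = c(0.5, 0.2), seed = 1),
               class = "stemtaper_config_error")
  expect_error(simulate_taper_data(re_sd = c(0.1), seed = 1),
               class = "stemtaper_config_error")
  expect_error(simulate_taper_data(dbh_range = c(30, 20), seed = 1),
               class = "stemtaper_config_error")
  expect_error(simulate_taper_data(truth = 1:3, seed = 1),
               class = "stemtaper_config_error")
  d <- simulation_defaults()
  expect_equal(d$n_plots, 132L)
  expect_length(d$rel_heights, 11)
})

test_that("simulations serialise with their truth sidecar", {
  sim <- simulate_taper_data(n_plots = 3, seed = 29)
  f <- withr::local_tempfile(fileext = ".csv")
  paths <- write_simulation(sim, f)
  expect_true(all(file.exists(paths)))
  back <- read_stem_csv(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(sim$data),
               tolerance = 1e-12)
  side <- readLines(paths[2])
  expect_match(side[1], "kozak2004_inv_Sd")
  expect_match(side[4], "6,8")
  expect_length(grep("^effect ", side), 9)
})
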