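test_that("check loss evaluates the pinball formula", {
  expect_equal(check_loss(c(1, -1), 0.5), 1)
  expect_equal(check_loss(2, 0.9), 1.8)
  expect_equal(check_loss(c(0, 0, 0), 0.3), 0)
  expect_error(check_loss(1, 1.2), class = "stemtaper_domain_error")
  expect_error(check_loss(c(1, NA), 0.5), class = "stemtaper_domain_error")
  # tau = 0.5 halves the absolute-error sum, for arbitrary residuals
  set.seed(5)
  for (i in 1:20) {
    r <- rnorm(sample(2:30, 1), 0, 3)
    expect_equal(check_loss(r, 0.5), 0.5 * sum(abs(r)))
  }
})

test_that("location fits reproduce empirical quantiles (grid-search oracle)", {
  obs <- as.numeric(1:9)
  dat <- location_data(obs)
  stub <- stub_location_model()

  f5 <- fit_taper_quantile(dat, stub, tau = 0.5, start = 7)
  expect_equal(unname(f5$estimates), 5, tolerance = 1e-6)

  f25 <- fit_taper_quantile(dat, stub, tau = 0.25, start = 7)
  # independent oracle: dense grid search of the exact loss
  grid <- seq(0, 10, by = 0.001)
  loss <- vapply(grid, function(b) check_loss(obs - b, 0.25), numeric(1))
  oracle <- grid[which.min(loss)]
  expect_equal(oracle, 3, tolerance = 1e-9)
  expect_equal(unname(f25$estimates), oracle, tolerance = 1e-3)
})

test_that("median regression approximates NLS under symmetric noise", {
  sim <- simulate_taper_data(n_plots = 30, re_sd = c(0, 0), seed = 71)
  nls_fit <- fit_taper_nls(sim$data, "kozak2004_inv_Sd")
  q5 <- fit_taper_quantile(sim$data, tau = 0.5,
                           start = unname(nls_fit$estimates))
  # compare surfaces rather than raw coefficients (the exponent terms are
  # collinear; the fitted curves are the estimand)
  expect_lt(mean(abs(q5$fitted - nls_fit$fitted)), 0.05)
  expect_equal(q5$coverage, 0.5, tolerance = 0.04)
})

test_that("the returned point never has higher exact loss than its start", {
  sim <- simulate_taper_data(n_plots = 8, seed = 72)
  start <- kozak_ref()
  r0 <- sim$data$d_cm - eval_taper("kozak2004_inv_Sd", start, sim$data)
  for (tau in c(0.2, 0.5, 0.8)) {
    f <- fit_taper_quantile(sim$data, tau = tau, start = start)
    expect_lte(f$check_loss, check_loss(r0, tau))
  }
})

test_that("quantile sweeps return one fit per level with coverage ordering", {
  sim <- simulate_taper_data(n_plots = 15, re_sd = c(0, 0), seed = 73)
  sw <- quantile_sweep(sim$data, taus = c(0.25, 0.5, 0.75))
  expect_length(sw$fits, 3)
  expect_true(all(diff(sw$summary$coverage) >= 0))
  expect_gte(sw$crossings, 0)

  # a single-level sweep behaves as a direct fit
  start <- unname(fit_taper_nls(sim$data, "kozak2004_inv_Sd")$estimates)
  sw1 <- quantile_sweep(sim$data, taus = 0.5, start = start)
  direct <- fit_taper_quantile(sim$data, tau = 0.5, start = start)
  expect_equal(sw1$fits[[1]]$check_loss, direct$check_loss,
               tolerance = 1e-8)
  expect_error(quantile_sweep(sim$data, taus = c(0.5, 0.2)),
               class = "stemtaper_domain_error")
})
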