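test_that("random-effect subset enumeration is exhaustive and ordered", {
  expect_length(enumerate_random_subsets(10), 55)
  expect_identical(enumerate_random_subsets(3),
                   list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_length(enumerate_random_subsets(1), 1)
  # brute-force count for a range of sizes
  for (n in 2:8) {
    expect_length(enumerate_random_subsets(n), n + choose(n, 2))
  }
})

test_that("Laplace likelihood equals the closed-form LMM value on linear stubs", {
  set.seed(14)
  M <- 10; nj <- 6
  dat <- taper_data(tibble::tibble(
    plot_id = rep(sprintf("p%02d", 1:M), each = nj), tree_id = "t1",
    D_cm = 20, H_m = 15, h_m = rep(seq_len(nj), M),
    d_cm = rep(5 + rnorm(M, 0, 0.4), each = nj) +
      rep(rnorm(M, 0, 0.1), each = nj) * rep(seq_len(nj), M) +
      rnorm(M * nj, 0, 0.5),
    Sd_trees_ha = 500))
  grpv <- rep(1:M, each = nj)

  # one random intercept
  stub1 <- function(bl, data) bl[[1]] + 0 * data$h_m
  n_all <- nrow(dat)
  ll1 <- laplace_marginal_loglik(dat, fixed = c(5.1, 0), random = 1L,
                                 D = matrix(0.16, 1, 1), sigma_sq = 0.3,
                                 mean_fun = stub1)
  cf1 <- lmm_loglik(dat$d_cm, X = matrix(1, n_all, 1),
                    Z = matrix(1, n_all, 1),
                    group = grpv, beta = 5.1,
                    Dmat = matrix(0.16, 1, 1), sigma2 = 0.3)
  expect_lt(abs(as.numeric(ll1) - cf1), 1e-8)

  # random intercept and slope with covariance
  stub2 <- function(bl, data) bl[[1]] + bl[[2]] * data$h_m
  Dm <- matrix(c(0.2, 0.03, 0.03, 0.05), 2, 2)
  ll2 <- laplace_marginal_loglik(dat, fixed = c(4.8, 0.12),
                                 random = c(1L, 2L), D = Dm,
                                 sigma_sq = 0.25, mean_fun = stub2)
  cf2 <- lmm_loglik(dat$d_cm, X = cbind(1, dat$h_m),
                    Z = cbind(1, dat$h_m), group = grpv,
                    beta = c(4.8, 0.12), Dmat = Dm, sigma2 = 0.25)
  expect_lt(abs(as.numeric(ll2) - cf2), 1e-8)

  # additivity over trees is exact
  expect_equal(sum(attr(ll2, "by_tree")), as.numeric(ll2))
})

test_that("a vanishing random-effect variance degenerates to the fixed-effect likelihood", {
  sim <- simulate_taper_data(n_plots = 5, seed = 61)
  b <- kozak_ref()
  s2 <- 0.6
  ll <- laplace_marginal_loglik(sim$data, fixed = b, random = 1L,
                                D = matrix(1e-14, 1, 1), sigma_sq = s2)
  r <- sim$data$d_cm - eval_taper("kozak2004_inv_Sd", b, sim$data)
  n <- length(r)
  gauss <- -(n / 2) * log(2 * pi * s2) - sum(r^2) / (2 * s2)
  expect_equal(as.numeric(ll), gauss, tolerance = 1e-6)
})

test_that("the log-Cholesky parameterisation always yields a symmetric PD matrix", {
  set.seed(3)
  for (i in 1:50) {
    th <- c(rep(0, 3), rnorm(3, 0, 2), 0)  # p = 3, q = 2 packing
    un <- stemtaper:::unpack_theta(th, p = 3, q = 2)
    expect_equal(un$Dmat, t(un$Dmat))
    expect_true(all(eigen(un$Dmat, only.values = TRUE)$values > 0))
  }
})

test_that("the mixed fit recovers a well-identified variance structure", {
  # random effect on b1 scales whole tree profiles: cleanly identified
  sim <- simulate_taper_data(n_plots = 25, random = 1L, re_sd = 0.05,
                             seed = 62)
  fit <- fit_taper_nlme(sim$data, random = 1L)
  expect_true(fit$converged)
  expect_equal(fit$components$sigma1_sq, 0.05^2, tolerance = 0.5)
  expect_equal(fit$components$sigma_sq, 0.5791, tolerance = 0.15)
  # EBLUPs track the generating tree effects and centre near zero
  ef <- dplyr::inner_join(fit$eblups, sim$truth$effects,
                          by = c("plot_id", "tree_id"),
                          suffix = c("_hat", "_true"))
  expect_gt(cor(ef$u_b1_hat, ef$u_b1_true), 0.8)
  expect_lt(abs(mean(ef$u_b1_hat)), 0.02)
})

test_that("boundary fits are reported, and AIC then prefers plain NLS", {
  sim <- simulate_taper_data(n_plots = 12, re_sd = c(0, 0), seed = 63)
  nls_fit <- fit_taper_nls(sim$data, "kozak2004_inv_Sd")
  fit <- fit_taper_nlme(sim$data, random = 6L,
                        start = unname(nls_fit$estimates))
  # data carry no tree effects: the variance collapses toward zero
  expect_lt(fit$components$sigma1_sq, 1e-4)
  nls_aic <- -2 * nls_fit$loglik + 2 * (10 + 1)
  expect_gt(fit$AIC, nls_aic - 2.1)  # no spurious likelihood gain
})

test_that("population and calibrated predictions behave as documented", {
  sim <- simulate_taper_data(n_plots = 15, seed = 64)
  fit <- fit_taper_nlme(sim$data, random = c(6L, 8L))
  pop <- predict(fit, sim$data, mode = "population")
  expect_equal(pop, eval_taper(fit$spec, fit$fixed, sim$data),
               tolerance = 1e-12)
  # calibrating on the training trees reproduces the stored EBLUPs
  u <- estimate_tree_effects(fit, sim$data)
  expect_equal(unname(u),
               unname(as.matrix(fit$eblups[, c("u_b6", "u_b8")])),
               tolerance = 1e-6)
})

test_that("calibration recovers the signs of a synthetic tree's effects", {
  # truth-parameterised model object; tree generated noiselessly at
  # u = (0.05, 0.001) on (b6, b8)
  m <- taper_model("kozak2004_inv_Sd")
  truth_fit <- structure(list(
    model = m$key, spec = m, random = c(6L, 8L),
    fixed = setNames(kozak_ref(), m$param_names),
    D = diag(c(0.02^2, 0.002^2)),
    components = tibble::tibble(sigma1_sq = 4e-4, sigma2_sq = 4e-6,
                                sigma12 = 0, sigma_sq = 0.5791)),
    class = "taper_nlme")
  tree <- simulate_profile(D = 21, H = 17.2, Sd = 787,
                           random = c(6L, 8L), effects = c(0.05, 0.001),
                           sigma = 0)
  u_hat <- estimate_tree_effects(truth_fit, tree)
  expect_gt(u_hat[1, 1], 0)
  expect_gt(u_hat[1, 2], 0)
  expect_error(estimate_tree_effects(truth_fit, tree[0, ]),
               class = "stemtaper_validation_error")
})

test_that("placement ranking tabulates, flags and marks the AIC winner", {
  sim <- simulate_taper_data(n_plots = 12, seed = 65)
  tab <- rank_placements(sim$data,
                         placements = list(1L, c(6L, 8L)),
                         control = list(outer_maxit = 150))
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$best), 1)
  expect_true(all(c("placement", "AIC", "BIC", "minus2LL",
                    "converged") %in% names(tab)))
  # single placement reproduces the direct fit's statistics
  one <- rank_placements(sim$data, placements = list(c(6L, 8L)),
                         control = list(outer_maxit = 150))
  direct <- fit_taper_nlme(sim$data, random = c(6L, 8L),
                           control = list(outer_maxit = 150))
  expect_equal(one$AIC, direct$AIC, tolerance = 1e-6)
})
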