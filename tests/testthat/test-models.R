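# Reference coefficient sets for the density-augmented model reported by
# the three estimation routes (supported NLS fit, mixed-model fixed
# effects, and the nine quantile-regression columns); used to probe the
# structural identities of the taper function across realistic
# parameterisations.
nlme_fixed <- c(0.9362, 0.9393, 0.0785, 0.6241, -0.6534, 0.5247,
                1.6302, 0.0140, -0.1247, 0.2578)
tau_columns <- list(
  c(0.9973, 0.8909, 0.0924, 0.6845, -0.6077, 0.5806, 1.2804, 0.0056,
    -0.1013, 0.3096),
  c(1.0006, 0.9004, 0.0926, 0.6562, -0.6248, 0.5309, 1.2770, 0.0111,
    -0.1004, 0.3265),
  c(1.0072, 0.9105, 0.0967, 0.6238, -0.6408, 0.4837, 1.2749, 0.0183,
    -0.0924, 0.3395))

test_that("golden-point evaluation matches the independent hand computation", {
  # frozen from a step-by-step arithmetic evaluation outside the package:
  # T = 0.5, X = 1.3/17.2, Z = 0.3574161994747491, E = 0.3677277498155512
  b <- kozak_ref()
  expect_equal(eval_kozak2004(b, D = 21, H = 17.2, h = 8.6, Sd = 787),
               13.706007733789747, tolerance = 1e-12)
})

test_that("breast-height identity d(1.3) = b1 D^b2 H^b3 holds across parameter sets", {
  sets <- c(list(kozak_ref(), nlme_fixed), tau_columns)
  for (b in sets) {
    for (D in c(15.1, 21, 28.8)) {
      for (H in c(10.5, 17.2, 22.6)) {
        expect_equal(eval_kozak2004(b, D, H, h = 1.3, Sd = 787),
                     b[1] * D^b[2] * H^b[3], tolerance = 1e-12)
      }
    }
  }
  # and for the base (9-coefficient) model
  b9 <- unname(taper_model("kozak2004")$ref_params)
  expect_equal(eval_kozak2004(b9, 21, 17.2, 1.3),
               b9[1] * 21^b9[2] * 17.2^b9[3], tolerance = 1e-12)
})

test_that("tip diameter is exactly zero where the model structure forces it", {
  sets <- c(list(kozak_ref(), nlme_fixed), tau_columns)
  for (b in sets) {
    expect_identical(eval_kozak2004(b, 21, 17.2, h = 17.2, Sd = 787), 0)
  }
  # every registry model flagged tip_zero vanishes at the tip under its
  # reference coefficients; flagged exceptions are documented in the
  # registry (their adopted algebra has a negative tip exponent)
  reg <- list_models()
  for (k in reg$key) {
    m <- taper_model(k)
    tip <- m$fn(as.list(unname(m$ref_params)), D = 21, H = 17.2, h = 17.2,
                Sd = 787, BA = 25.3, Cd = 0.7)
    if (m$tip_zero) expect_equal(tip, 0, tolerance = 1e-12)
  }
  expect_false(all(reg$tip_zero))  # the exceptions are recorded, not hidden
})

test_that("density terms follow their declared transforms", {
  expect_equal(density_term("inv_Sd", 0.3470, Sd = 1000), 0.000347)
  expect_equal(density_term("mul_Sd", -0.0005, Sd = 2000), -1.0)
  expect_equal(density_term("mul_BA", 0.0004, BA = 25), 0.01)
  expect_equal(density_term("inv_sqrt_Sd", 0.9711, Sd = 400),
               0.9711 / 20)
  expect_equal(density_term("inv_log_Sd", 0.2433, Sd = exp(2)),
               0.2433 / 2)
  expect_equal(density_term("inv_cbrt_Sd", -0.0105, Sd = 8^3),
               -0.0105 / 8)
  expect_error(density_term("inv_log_Sd", 1, Sd = 1),
               class = "stemtaper_domain_error")
  expect_error(density_term("mul_BA", 1, Sd = 100),
               class = "stemtaper_covariate_error")
})

test_that("b10 = 0 collapses every augmented variant onto the base model", {
  b9 <- unname(taper_model("kozak2004")$ref_params)
  set.seed(42)
  grid <- tibble::tibble(
    plot_id = sprintf("p%02d", 1:40), tree_id = "t1",
    D_cm = runif(40, 15.1, 28.8), H_m = runif(40, 10.5, 22.6),
    Sd_trees_ha = runif(40, 90, 2580), BA_m2_ha = runif(40, 12, 60),
    Cd = runif(40, 0.2, 0.9), age_yr = 30)
  grid$h_m <- runif(40, 0.01, 0.99) * grid$H_m
  grid$d_cm <- 1
  grid <- taper_data(grid)
  base <- eval_taper("kozak2004", b9, grid)
  for (form in setdiff(stemtaper:::DENSITY_FORMS, "none")) {
    aug <- eval_taper(paste0("kozak2004_", form), c(b9, 0), grid)
    expect_lt(max(abs(aug - base)), 1e-12)
  }
})

test_that("registry lists 12 base forms and 8 density variants with correct sizes", {
  base <- list_models(include_density = FALSE)
  expect_equal(nrow(base), 12)
  expect_equal(nrow(list_models()), 20)
  expect_equal(taper_model("kozak2004_inv_Sd")$n_params, 10)
  expect_equal(taper_model("kozak2004")$n_params, 9)
  expect_equal(taper_model("sharma_zhang_a")$n_params, 4)
  expect_equal(taper_model("kozak1988")$n_params, 9)   # b1..b8 + p
  expect_setequal(
    base$n_params, c(9, 10, 8, 8, 7, 6, 9, 5, 10, 4, 5, 4))
  expect_error(taper_model("nope"), class = "stemtaper_registry_error")
})

test_that("evaluators are finite, non-negative and continuous along the stem", {
  Tg <- seq(0.01, 0.99, by = 0.005)
  for (k in list_models()$key) {
    m <- taper_model(k)
    ev <- function(h) m$fn(as.list(unname(m$ref_params)), D = 21,
                           H = 17.2, h = h, Sd = 787, BA = 25.3,
                           Cd = 0.7)
    d <- ev(Tg * 17.2)
    expect_true(all(is.finite(d)), info = k)
    expect_true(all(d >= 0), info = k)
    # continuity: perturbing h by 1e-8 m moves d by a vanishing relative
    # amount everywhere on the interior grid (no jumps from the exponent
    # terms)
    expect_lt(max(abs(ev(Tg * 17.2 + 1e-8) - d) / (1 + abs(d))), 1e-6)
  }
})

test_that("eval_taper dispatches over dataset rows with validation", {
  td <- one_tree()
  pred <- eval_taper("kozak2004_inv_Sd", kozak_ref(), td)
  expect_length(pred, 11)
  expect_equal(pred, td$d_cm, tolerance = 1e-12)  # fixture built from model

  # identity configuration: b = (1, 1, 0, 0, ..., 0) gives d = D at every h
  ident <- c(1, 1, rep(0, 7))
  expect_equal(eval_taper("kozak2004", ident, td), rep(21, 11),
               tolerance = 1e-12)

  expect_error(eval_taper("kozak2004", kozak_ref(), td),
               class = "stemtaper_domain_error")  # 10 coefs vs 9
  no_sd <- tibble::as_tibble(td)
  no_sd$Sd_trees_ha <- NA_real_
  expect_error(eval_taper("kozak2004_inv_Sd", kozak_ref(),
                          structure(no_sd, class = class(td))),
               class = "stemtaper_covariate_error")
})

test_that("eval_kozak2004 rejects out-of-domain input", {
  b <- kozak_ref()
  expect_error(eval_kozak2004(b, 21, 17.2, h = 18, Sd = 787),
               class = "stemtaper_domain_error")
  expect_error(eval_kozak2004(b, -1, 17.2, h = 2, Sd = 787),
               class = "stemtaper_domain_error")
  expect_error(eval_kozak2004(b, 21, 17.2, h = 2),
               class = "stemtaper_covariate_error")  # density form needs Sd
  expect_error(eval_kozak2004(b[1:5], 21, 17.2, 2),
               class = "stemtaper_domain_error")
})
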