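# Variable-exponent taper model registry.
#
# Every model predicts over-bark diameter d (cm) at stem height h (m) from
# DBH D (cm), total height H (m) and, for density-augmented variants, a
# stand-density covariate. All evaluators are vectorised over sections and
# defined for relative height T = h/H in (0, 1]; most force d = 0 at the
# tip (T = 1) because their taper ratio term vanishes there with a positive
# exponent. Forms whose published algebra does not force a zero tip carry
# `tip_zero = FALSE` in the registry.
#
# Several of the twelve classical forms circulate in slightly different
# typographic variants; the algebra adopted here for each registry entry is
# stated verbatim in its `formula` string, and entries where the adopted
# reading involved a judgement call are marked `transcription = "flagged"`.

DENSITY_FORMS <- c("none", "mul_BA", "mul_Cd", "mul_Sd", "inv_Sd",
                   "inv_Sd_sq", "inv_sqrt_Sd", "inv_log_Sd", "inv_cbrt_Sd")

#' Additive stand-density contribution to the variable exponent
#'
#' The density-augmented Kozak (2004) model adds a single term `g(density)`
#' scaled by coefficient `b10` to its variable exponent. Eight functional
#' forms are supported: proportional terms in basal area, canopy density
#' and stand density, and five damped transforms of stand density
#' (reciprocal, reciprocal square, reciprocal square root, reciprocal log,
#' reciprocal cube root).
#'
#' @param form One of `"mul_BA"`, `"mul_Cd"`, `"mul_Sd"`, `"inv_Sd"`,
#'   `"inv_Sd_sq"`, `"inv_sqrt_Sd"`, `"inv_log_Sd"`, `"inv_cbrt_Sd"`
#'   (or `"none"`, which returns 0).
#' @param b10 Coefficient scaling the density term.
#' @param Sd Stand density, trees/ha. Must exceed 1 for `"inv_log_Sd"`.
#' @param BA Basal area, m2/ha (required by `"mul_BA"`).
#' @param Cd Canopy density, fraction in (0, 1] (required by `"mul_Cd"`).
#' @return The additive exponent contribution (recycled to the common
#'   length of the covariate inputs).
#' @examples
#' density_term("inv_Sd", 0.3470, Sd = 1000)
#' @export
density_term <- function(form, b10, Sd = NULL, BA = NULL, Cd = NULL) {
  form <- match.arg(form, DENSITY_FORMS)
  if (form == "none") return(0)
  need <- function(v, nm) {
    if (is.null(v) || anyNA(v)) {
      abort(sprintf("density form '%s' requires covariate %s", form, nm),
            class = "stemtaper_covariate_error")
    }
    if (any(v <= 0)) {
      abort(sprintf("covariate %s must be positive", nm),
            class = "stemtaper_domain_error")
    }
    v
  }
  switch(form,
    mul_BA      = b10 * need(BA, "BA"),
    mul_Cd      = b10 * need(Cd, "Cd"),
    mul_Sd      = b10 * need(Sd, "Sd"),
    inv_Sd      = b10 / need(Sd, "Sd"),
    inv_Sd_sq   = b10 / need(Sd, "Sd")^2,
    inv_sqrt_Sd = b10 / sqrt(need(Sd, "Sd")),
    inv_log_Sd  = {
      Sd <- need(Sd, "Sd")
      if (any(Sd <= 1)) {
        abort("inv_log_Sd requires Sd > 1", class = "stemtaper_domain_error")
      }
      b10 / log(Sd)
    },
    inv_cbrt_Sd = b10 / need(Sd, "Sd")^(1 / 3)
  )
}

#' Evaluate the Kozak (2004) variable-exponent taper equation
#'
#' The model is
#' \deqn{d = b_1 D^{b_2} H^{b_3} Z^{E}, \quad
#'       Z = \frac{1 - T^{1/3}}{1 - X^{1/3}},}
#' with relative height \eqn{T = h/H}, relative breast height
#' \eqn{X = 1.3/H}, \eqn{Q = 1 - T^{1/3}} and variable exponent
#' \deqn{E = b_4 T^4 + b_5 e^{-D/H} + b_6 Z^{0.1} + b_7 / D + b_8 H^{Q}
#'       + b_9 Z \;[+\, b_{10}\, g(\mathrm{density})].}
#' At breast height (h = 1.3) the ratio Z equals 1 exactly, so
#' \eqn{d = b_1 D^{b_2} H^{b_3}} regardless of the exponent coefficients;
#' at the tip (h = H) Z = 0 and d = 0 whenever E > 0 there.
#'
#' With nine coefficients the base model is evaluated; a tenth coefficient
#' activates the stand-density term `b10 * g(density)` selected by
#' `density_form` (default `"inv_Sd"`, the reciprocal of stand density,
#' the form with the best supported fit).
#'
#' @param b Numeric coefficient vector `b1..b9` (base model) or `b1..b10`
#'   (density-augmented model).
#' @param D Diameter at breast height, cm (> 0).
#' @param H Total tree height, m (> 1.3).
#' @param h Section height above ground, m, with `0 < h <= H`. Vectorised.
#' @param Sd,BA,Cd Stand covariates passed to [density_term()] when
#'   `length(b) == 10`.
#' @param density_form Density term used when `length(b) == 10`; one of
#'   the forms documented in [density_term()]. Ignored for 9-coefficient
#'   calls.
#' @return Predicted diameters, cm, same length as `h` (after recycling).
#' @examples
#' b <- c(0.9913, 0.9227, 0.0688, 0.6625, -0.7874, 0.5001,
#'        2.4607, 0.0099, -0.0785, 0.3470)
#' eval_kozak2004(b, D = 21, H = 17.2, h = c(1.3, 8.6, 17.2), Sd = 787)
#' @export
eval_kozak2004 <- function(b, D, H, h, Sd = NULL, BA = NULL, Cd = NULL,
                           density_form = "inv_Sd") {
  if (!length(b) %in% c(9L, 10L)) {
    abort("b must have 9 (base) or 10 (density-augmented) coefficients",
          class = "stemtaper_domain_error")
  }
  if (any(D <= 0) || any(H <= 1.3) || any(h <= 0)) {
    abort("require D > 0, H > 1.3, h > 0", class = "stemtaper_domain_error")
  }
  if (any(h > H + 1e-12)) {
    abort("section height h exceeds total height H",
          class = "stemtaper_domain_error")
  }
  dens <- if (length(b) == 10L) {
    density_term(density_form, b[[10]], Sd = Sd, BA = BA, Cd = Cd)
  } else 0
  kozak2004_core(b, D, H, h, dens)
}

# shared core: `dens` is the precomputed additive exponent term
kozak2004_core <- function(b, D, H, h, dens) {
  T_ <- pmin(h / H, 1)
  X <- 1.3 / H
  Q <- 1 - T_^(1 / 3)
  Z <- Q / (1 - X^(1 / 3))
  E <- b[[4]] * T_^4 + b[[5]] * exp(-D / H) + b[[6]] * Z^0.1 +
    b[[7]] / D + b[[8]] * H^Q + b[[9]] * Z + dens
  b[[1]] * D^b[[2]] * H^b[[3]] * Z^E
}

# analytic partial derivatives of the Kozak-2004 family mean with respect
# to single coefficients (used by the mixed-effects inner optimiser; the
# chain rule through the variable exponent gives d mu / d b_k =
# mu * ln(Z) * (exponent term k) for k in 4..10).
kozak2004_dcoef <- function(b, D, H, h, k, density_form = "none",
                            Sd = NULL, BA = NULL, Cd = NULL) {
  T_ <- pmin(h / H, 1)
  X <- 1.3 / H
  Q <- 1 - T_^(1 / 3)
  Z <- Q / (1 - X^(1 / 3))
  dens <- if (density_form != "none") {
    density_term(density_form, b[[10]], Sd = Sd, BA = BA, Cd = Cd)
  } else 0
  E <- b[[4]] * T_^4 + b[[5]] * exp(-D / H) + b[[6]] * Z^0.1 +
    b[[7]] / D + b[[8]] * H^Q + b[[9]] * Z + dens
  mu <- b[[1]] * D^b[[2]] * H^b[[3]] * Z^E
  lz <- ifelse(Z > 0, log(Z), 0)   # mu = 0 at the tip; derivative is 0
  out <- switch(as.character(k),
    "1" = mu / b[[1]],
    "2" = mu * log(D),
    "3" = mu * log(H),
    "4" = mu * lz * T_^4,
    "5" = mu * lz * exp(-D / H),
    "6" = mu * lz * Z^0.1,
    "7" = mu * lz / D,
    "8" = mu * lz * H^Q,
    "9" = mu * lz * Z,
    "10" = mu * lz * density_term(density_form, 1, Sd = Sd, BA = BA,
                                  Cd = Cd))
  ifelse(is.finite(out), out, 0)
}

# ---- registry ----------------------------------------------------------

# helper used by several classic forms: guard log/power domains
.asinq <- function(T_) asin(sqrt(pmax(1 - T_, 0)))

make_registry <- function() {
  reg <- list()
  add <- function(key, label, param_names, fn, formula, ref, tip_zero,
                  density_form = "none", covariates = character(),
                  transcription = "canonical") {
    reg[[key]] <<- list(
      key = key, label = label, param_names = param_names,
      n_params = length(param_names), fn = fn, formula = formula,
      ref_params = setNames(ref, param_names), tip_zero = tip_zero,
      density_form = density_form, required_covariates = covariates,
      transcription = transcription)
  }

  add("kozak1988",
      "Kozak (1988) variable-exponent model with inflection constant p",
      c(paste0("b", 1:8), "p"),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        Q <- (1 - sqrt(T_)) / (1 - sqrt(b[[9]]))
        E <- b[[4]] * T_^2 + b[[5]] * log(T_ + 0.001) + b[[6]] * sqrt(T_) +
          b[[7]] * exp(T_) + b[[8]] * (D / H)
        b[[1]] * D^b[[2]] * b[[3]]^D * Q^E
      },
      "d = b1 D^b2 b3^D [(1-sqrt(T))/(1-sqrt(p))]^(b4 T^2 + b5 ln(T+0.001) + b6 sqrt(T) + b7 e^T + b8 D/H)",
      c(1.2172, 0.9603, 1.0001, -0.0010, -0.0104, -1.1003, 0.6149,
        0.1421, 0.0386),
      tip_zero = TRUE)

  add("kozak2002",
      "Kozak (2002)-type ten-parameter variable-exponent model",
      paste0("b", 1:10),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        Q <- (1 - T_) / (1 - 0.01)
        E <- b[[4]] + b[[5]] * T_^(1 / 4) + b[[6]] * T_^(1 / 3) +
          b[[7]] * sqrt(T_) + b[[8]] * .asinq(T_) + b[[9]] / (D / H + T_) +
          b[[10]] * H
        b[[1]] * D^b[[2]] * b[[3]]^D * Q^E
      },
      "d = b1 D^b2 b3^D [(1-T)/(1-0.01)]^(b4 + b5 T^(1/4) + b6 T^(1/3) + b7 sqrt(T) + b8 asin(sqrt(1-T)) + b9/(D/H + T) + b10 H)",
      c(1.2963, 0.9765, 0.9994, 34.8072, -31.8123, 5.2744, -7.3781,
        -21.4034, -0.3146, -0.0012),
      tip_zero = TRUE, transcription = "flagged")

  add("varexp_dh8a",
      "Eight-parameter power-exponent model with D and H exponent terms",
      paste0("b", 1:8),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        E <- b[[4]] * T_^2 + b[[5]] * sqrt(T_) + b[[6]] * D + b[[7]] * H +
          b[[8]] * D / H
        b[[1]] * D^b[[2]] * b[[3]]^D * (1 - T_)^E
      },
      "d = b1 D^b2 b3^D (1-T)^(b4 T^2 + b5 sqrt(T) + b6 D + b7 H + b8 D/H)",
      c(0.8995, 1.0026, 1.0001, 0.5125, 0.5125, 0.0035, -0.0020, 0.0925),
      tip_zero = TRUE, transcription = "flagged")

  add("varexp_dh8b",
      "Eight-parameter power-exponent model with cubic height polynomial",
      paste0("b", 1:8),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        E <- b[[3]] * T_ + b[[4]] * T_^2 + b[[5]] * sqrt(T_) + b[[6]] * T_^3 +
          b[[7]] * D + b[[8]] * D / H
        b[[1]] * D^b[[2]] * (1 - T_)^E
      },
      "d = b1 D^b2 (1-T)^(b3 T + b4 T^2 + b5 sqrt(T) + b6 T^3 + b7 D + b8 D/H)",
      c(1.2601, 0.8333, -1.3978, 0.8206, 0.2197, -0.2733, 0.0082, -0.1675),
      # reference exponent is negative at T = 1: tip diameter diverges
      tip_zero = FALSE, transcription = "flagged")

  add("bi2000",
      "Bi (2000) trigonometric variable-exponent model",
      paste0("b", 1:7),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        V <- log(sin(pi / 2 * T_)) / log(sin(pi / 2 * 1.3 / H))
        E <- b[[1]] + b[[2]] * sin(pi / 2 * T_) + b[[3]] * cos(3 * pi / 2 * T_) +
          b[[4]] * sin(pi / 2 * T_) / T_ + b[[5]] * D + b[[6]] * T_ * sqrt(D) +
          b[[7]] * T_ * sqrt(H)
        D * ifelse(V == 0 & E == 0, 1, V^E)
      },
      "d = D [ln sin(pi T/2) / ln sin(pi (1.3/H)/2)]^(b1 + b2 sin(pi T/2) + b3 cos(3 pi T/2) + b4 sin(pi T/2)/T + b5 D + b6 T sqrt(D) + b7 T sqrt(H))",
      c(0.1664, 0.2166, -0.1138, 0.0607, 0.0024, -0.1273, 0.1113),
      tip_zero = TRUE)

  add("kozak2004_simple",
      "Kozak (2004) Model I: six-parameter quarter-power form",
      paste0("b", 1:6),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        Q <- (1 - T_^(1 / 4)) / (1 - 0.01^(1 / 4))
        E <- b[[3]] + b[[4]] * exp(-D / H) + b[[5]] * D^Q + b[[6]] * Q^(D / H)
        b[[1]] * D^b[[2]] * Q^E
      },
      "d = b1 D^b2 Q^(b3 + b4 e^(-D/H) + b5 D^Q + b6 Q^(D/H)), Q = (1-T^(1/4))/(1-0.01^(1/4))",
      c(1.4006, 0.9302, 0.4269, 0.0408, 0.0072, -0.4517),
      tip_zero = TRUE)

  add("kozak2004",
      "Kozak (2004) Model II: nine-parameter cube-root form (base model)",
      paste0("b", 1:9),
      function(b, D, H, h, ...) kozak2004_core(b, D, H, h, 0),
      "d = b1 D^b2 H^b3 Z^(b4 T^4 + b5 e^(-D/H) + b6 Z^0.1 + b7/D + b8 H^(1-T^(1/3)) + b9 Z), Z = (1-T^(1/3))/(1-(1.3/H)^(1/3))",
      c(1.0051, 0.9281, 0.0814, 0.5253, -0.5630, 0.4918, 1.4737,
        0.0123, -0.1085),
      tip_zero = TRUE)

  add("lee2003",
      "Lee et al. (2003) five-parameter polynomial-exponent model",
      paste0("b", 1:5),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        b[[1]] * D^b[[2]] * (1 - T_)^(b[[3]] * T_^2 + b[[4]] * T_ + b[[5]])
      },
      "d = b1 D^b2 (1-T)^(b3 T^2 + b4 T + b5)",
      c(1.5644, 0.9154, 2.8508, -3.7376, 1.9411),
      tip_zero = TRUE)

  add("kozak2004_p",
      "Kozak (2004)-type cube-root form with estimable inflection p",
      c(paste0("b", 1:9), "p"),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        Q <- 1 - T_^(1 / 3)
        Z <- Q / (1 - b[[10]]^(1 / 3))
        E <- b[[4]] * T_^4 + b[[5]] * exp(-D / H) + b[[6]] * Z^0.1 +
          b[[7]] / D + b[[8]] * H^Q + b[[9]] * Z
        b[[1]] * D^b[[2]] * H^b[[3]] * Z^E
      },
      "d = b1 D^b2 H^b3 Zp^(b4 T^4 + b5 e^(-D/H) + b6 Zp^0.1 + b7/D + b8 H^(1-T^(1/3)) + b9 Zp), Zp = (1-T^(1/3))/(1-p^(1/3))",
      c(1.2350, 1.0495, -0.0597, 0.2652, -0.1566, 0.3251, 0.2736,
        0.0935, -0.0536, 0.0386),
      tip_zero = TRUE, transcription = "flagged")

  add("sharma_zhang_a",
      "Sharma-Zhang-type dimensionally compatible form (2 - poly exponent)",
      paste0("b", 1:4),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        ex <- 2 - (b[[2]] + b[[3]] * T_ + b[[4]] * T_^2)
        b[[1]] * D * sqrt((h / 1.3)^ex * pmax(H - h, 0) / (H - 1.3))
      },
      "d = b1 D sqrt((h/1.3)^(2 - (b2 + b3 T + b4 T^2)) (H-h)/(H-1.3))",
      c(0.8659, 1.8759, 0.2822, 0.0368),
      tip_zero = TRUE, transcription = "flagged")

  add("varexp_poly5_sqrt",
      "Five-parameter polynomial-exponent model on (1 - sqrt(T))",
      paste0("b", 1:5),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        b[[1]] * D^b[[2]] * (1 - sqrt(T_))^(b[[3]] * T_^2 + b[[4]] * T_ + b[[5]])
      },
      "d = b1 D^b2 (1-sqrt(T))^(b3 T^2 + b4 T + b5)",
      c(1.6648, 0.9157, 1.1894, -1.2103, 0.7941),
      tip_zero = TRUE, transcription = "flagged")

  add("sharma_zhang_b",
      "Sharma-Zhang-type dimensionally compatible form (direct poly exponent)",
      paste0("b", 1:4),
      function(b, D, H, h, ...) {
        T_ <- pmin(h / H, 1)
        ex <- b[[2]] + b[[3]] * T_ + b[[4]] * T_^2
        b[[1]] * D * sqrt((h / 1.3)^ex * pmax(H - h, 0) / (H - 1.3))
      },
      "d = b1 D sqrt((h/1.3)^(b2 + b3 T + b4 T^2) (H-h)/(H-1.3))",
      c(0.0602, -0.1910, 0.5990, -1.1416),
      tip_zero = TRUE, transcription = "flagged")

  # density-augmented Kozak (2004) variants; reference coefficients are the
  # supported fits of the augmented model under each density form
  dens_ref <- list(
    mul_BA      = c(1.0034, 0.9293, 0.0807, 0.5225, -0.5600, 0.4945,
                    1.4259, 0.0120, -0.1152, 0.0004),
    mul_Cd      = c(1.0003, 0.9302, 0.0777, 0.5492, -0.5646, 0.4981,
                    1.4140, 0.0120, -0.1117, 0.0180),
    mul_Sd      = c(1.0632, 0.9056, 0.0930, 0.4818, -0.5548, 0.5035,
                    1.1312, 0.0121, -0.1186, -0.0005),
    inv_Sd      = c(0.9913, 0.9227, 0.0688, 0.6625, -0.7874, 0.5001,
                    2.4607, 0.0099, -0.0785, 0.3470),
    inv_Sd_sq   = c(1.0369, 0.9088, 0.0876, 0.5449, -0.5805, 0.5113,
                    1.2530, 0.0119, -0.1124, 11.1720),
    inv_sqrt_Sd = c(1.0339, 0.9002, 0.0917, 0.5873, -0.6003, 0.5227,
                    1.2105, 0.0116, -0.1074, 0.9711),
    inv_log_Sd  = c(0.9694, 0.9080, 0.0918, 0.6913, -0.6302, 0.5280,
                    1.3957, 0.0110, -0.0945, 0.2433),
    inv_cbrt_Sd = c(1.0635, 0.9167, 0.0863, 0.4517, -0.5328, 0.4905,
                    1.1870, 0.0123, -0.1218, -0.0105))
  cov_for <- function(form) {
    switch(form, mul_BA = "BA", mul_Cd = "Cd", "Sd")
  }
  for (form in names(dens_ref)) {
    local({
      f <- form
      add(paste0("kozak2004_", f),
          paste0("Kozak (2004) Model II augmented with density term ", f),
          paste0("b", 1:10),
          function(b, D, H, h, Sd = NULL, BA = NULL, Cd = NULL) {
            dens <- density_term(f, b[[10]], Sd = Sd, BA = BA, Cd = Cd)
            kozak2004_core(b, D, H, h, dens)
          },
          paste0("base kozak2004 exponent + ",
                 switch(f, mul_BA = "b10 BA", mul_Cd = "b10 Cd",
                        mul_Sd = "b10 Sd", inv_Sd = "b10/Sd",
                        inv_Sd_sq = "b10/Sd^2", inv_sqrt_Sd = "b10/sqrt(Sd)",
                        inv_log_Sd = "b10/ln(Sd)",
                        inv_cbrt_Sd = "b10/Sd^(1/3)")),
          dens_ref[[f]],
          # mul_Sd's exponent at the tip turns negative at moderate
          # densities under the reference coefficients (b10*Sd < 0 term),
          # so a zero tip is not guaranteed there
          tip_zero = (f != "mul_Sd"), density_form = f,
          covariates = cov_for(f))
    })
  }
  reg
}

.registry <- NULL

registry <- function() {
  if (is.null(.registry)) {
    utils::assignInMyNamespace(".registry", make_registry())
  }
  .registry
}

#' Look up a taper model specification
#'
#' @param model A registry key (see [list_models()]) or a spec returned by
#'   a previous call (returned unchanged).
#' @return A `taper_model` object: a list with elements `key`, `label`,
#'   `param_names`, `n_params`, `fn` (the evaluator), `formula` (the
#'   adopted algebra as text), `ref_params` (published reference
#'   coefficients used as default starting values), `tip_zero`,
#'   `density_form` and `required_covariates`.
#' @export
taper_model <- function(model) {
  if (inherits(model, "taper_model")) return(model)
  reg <- registry()
  if (!is.character(model) || length(model) != 1 || !model %in% names(reg)) {
    abort(paste0("Unknown taper model '", paste(model, collapse = ","),
                 "'. See list_models()."),
          class = "stemtaper_registry_error")
  }
  structure(reg[[model]], class = "taper_model")
}

#' @export
print.taper_model <- function(x, ...) {
  cat("<taper_model> ", x$key, "\n  ", x$label, "\n", sep = "")
  cat("  d =", sub("^d = ", "", x$formula), "\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (x$density_form != "none") {
    cat("  density form:", x$density_form, "| requires:",
        paste(x$required_covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' List the registered taper models
#'
#' Twelve base variable-exponent forms plus the eight density-augmented
#' variants of the Kozak (2004) Model II base form.
#'
#' @param include_density Include the density-augmented variants
#'   (default `TRUE`).
#' @return A tibble with one row per registered model: `key`, `label`,
#'   `n_params`, `density_form`, `required_covariates` (comma-separated),
#'   `tip_zero` (whether the adopted algebra forces d = 0 at the tip for
#'   its reference coefficients) and `transcription`.
#' @export
list_models <- function(include_density = TRUE) {
  reg <- registry()
  tb <- purrr::map_dfr(reg, function(m) {
    tibble::tibble(
      key = m$key, label = m$label, n_params = m$n_params,
      density_form = m$density_form,
      required_covariates = paste(m$required_covariates, collapse = ","),
      tip_zero = m$tip_zero, transcription = m$transcription)
  })
  if (!include_density) tb <- tb[tb$density_form == "none", , drop = FALSE]
  tb
}

#' Evaluate a registered taper model over a dataset's sections
#'
#' @param model Registry key or [taper_model] spec.
#' @param b Coefficient vector conforming to the model (length
#'   `n_params`).
#' @param data A [taper_data] tibble (or any data frame with the
#'   interchange columns).
#' @return Numeric vector of predicted diameters (cm), aligned with the
#'   rows of `data`.
#' @examples
#' m <- taper_model("kozak2004")
#' sim <- simulate_taper_data(n_plots = 2, seed = 1)
#' head(eval_taper(m, m$ref_params, sim$data))
#' @export
eval_taper <- function(model, b, data) {
  m <- taper_model(model)
  if (length(b) != m$n_params) {
    abort(sprintf("model %s expects %d parameters, got %d",
                  m$key, m$n_params, length(b)),
          class = "stemtaper_domain_error")
  }
  if (!all(is.finite(b))) {
    abort("all parameters must be finite", class = "stemtaper_domain_error")
  }
  for (cv in m$required_covariates) {
    col <- switch(cv, Sd = "Sd_trees_ha", BA = "BA_m2_ha", Cd = "Cd")
    if (!col %in% names(data) || anyNA(data[[col]])) {
      abort(sprintf("model %s requires covariate column %s (no missing values)",
                    m$key, col),
            class = "stemtaper_covariate_error")
    }
  }
  m$fn(unname(b), D = data$D_cm, H = data$H_m, h = data$h_m,
       Sd = data$Sd_trees_ha, BA = data$BA_m2_ha, Cd = data$Cd)
}
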