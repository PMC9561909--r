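# Tree-level nonlinear mixed-effects estimation.
#
# Model: d_jk = f(D_j, H_j, h_jk; beta + Z u_j) + e_jk, with u_j ~ N(0, D)
# a per-tree perturbation of one or two selected coefficients and
# e_jk ~ N(0, sigma^2) i.i.d. within tree (homoscedastic, uncorrelated:
# the default within-tree covariance is sigma^2 I; see the methods
# vignette for why no variance function or correlation structure is
# fitted by default).
#
# The marginal likelihood integrates u_j out per tree with a Laplace
# approximation around the posterior mode; the mode is found by a damped
# Gauss-Newton iteration vectorised across all trees (finite-difference
# Jacobians in the random-effect directions are shared across trees, so
# one full-data model evaluation serves every tree at once). The
# Gauss-Newton Hessian J'J/sigma^2 + D^-1 is used in the Laplace
# determinant; it is exact whenever the model is linear in u.

#' Enumerate candidate random-effect placements
#'
#' All subsets of size 1, then all subsets of size 2, of the coefficient
#' indices `1..n_params`, in lexicographic order — the exhaustive
#' candidate set for deciding which coefficients receive tree-level
#' random effects. For `n` parameters there are `n + n(n-1)/2`
#' placements (55 for a ten-parameter model).
#'
#' @param n_params Number of fixed coefficients.
#' @return A list of sorted integer vectors.
#' @examples
#' length(enumerate_random_subsets(10))  # 55
#' @export
enumerate_random_subsets <- function(n_params) {
  stopifnot(n_params >= 1)
  singles <- lapply(seq_len(n_params), function(i) i)
  if (n_params < 2) return(singles)
  pairs <- utils::combn(n_params, 2, simplify = FALSE)
  c(singles, pairs)
}

placement_label <- function(idx, param_names = paste0("b", seq_len(max(idx)))) {
  paste(param_names[idx], collapse = ",")
}

# ---- Laplace engine ----------------------------------------------------

# group structure precomputed once per dataset
make_groups <- function(data) {
  key <- tree_key(data)
  uk <- unique(key)
  g <- match(key, uk)
  list(g = g, n_groups = length(uk), keys = uk,
       n_j = as.vector(table(factor(g, levels = seq_along(uk)))))
}

# mean_fun(coef_list, data): coefficient list entries may be scalars or
# per-row vectors; returns the mean diameter for every row. For the
# Kozak-2004 family an analytic coefficient gradient is attached (attr
# "dcoef": function(bl, data, k) -> d mu / d b_k per row); other models
# fall back to finite differences in the inner optimiser.
taper_mean_fun <- function(m) {
  f <- function(bl, data) {
    m$fn(bl, D = data$D_cm, H = data$H_m, h = data$h_m,
         Sd = data$Sd_trees_ha, BA = data$BA_m2_ha, Cd = data$Cd)
  }
  if (m$key == "kozak2004" || m$density_form != "none") {
    dform <- m$density_form
    attr(f, "dcoef") <- function(bl, data, k) {
      if (length(bl) == 9) bl <- c(bl, list(0))
      kozak2004_dcoef(bl, D = data$D_cm, H = data$H_m, h = data$h_m,
                      k = k, density_form = dform,
                      Sd = data$Sd_trees_ha, BA = data$BA_m2_ha,
                      Cd = data$Cd)
    }
  }
  f
}

# One Laplace evaluation: per-tree inner mode search + log-likelihood.
# beta: fixed effects; random: indices; Dmat: q x q covariance; sigma: SD.
# U0: warm-start modes (M x q). Returns total loglik, per-tree pieces,
# final modes and a count of Hessian regularisations.
laplace_eval <- function(mean_fun, data, y, grp, beta, random, Dmat, sigma,
                         U0 = NULL, inner_tol = 1e-9, inner_maxit = 100) {
  q <- length(random)
  M <- grp$n_groups
  g <- grp$g
  if (is.null(U0)) U0 <- matrix(0, M, q)
  U <- U0
  Dinv <- solve(Dmat)
  s2 <- sigma^2
  dcoef <- attr(mean_fun, "dcoef")

  coef_list <- function(U) {
    bl <- as.list(unname(beta))
    for (k in seq_len(q)) {
      bl[[random[k]]] <- beta[random[k]] + U[g, k]
    }
    bl
  }
  quad_by_tree <- function(U) rowSums((U %*% Dinv) * U)
  obj_of <- function(r, U) {
    as.vector(rowsum(r * r, g, reorder = FALSE)) / (2 * s2) +
      quad_by_tree(U) / 2
  }

  mu <- mean_fun(coef_list(U), data)
  r <- y - mu
  if (!all(is.finite(r))) return(NULL)
  obj <- obj_of(r, U)

  eps_k <- vapply(seq_len(q), function(k) {
    1e-6 * max(abs(beta[random[k]]), 0.01)
  }, numeric(1))

  jacobian_u <- function(U, bl) {
    if (!is.null(dcoef)) {
      J <- matrix(0, length(y), q)
      for (k in seq_len(q)) J[, k] <- dcoef(bl, data, random[k])
      return(J)
    }
    J <- matrix(0, length(y), q)
    for (k in seq_len(q)) {
      Up <- U; Up[, k] <- Up[, k] + eps_k[k]
      Um <- U; Um[, k] <- Um[, k] - eps_k[k]
      J[, k] <- (mean_fun(coef_list(Up), data) -
                   mean_fun(coef_list(Um), data)) / (2 * eps_k[k])
    }
    J
  }

  nwarn <- 0L

  # per-tree Gauss-Newton system pieces (batched in one rowsum pass)
  gn_system <- function(J, r) {
    if (q == 1) {
      acc <- rowsum(cbind(J[, 1]^2, J[, 1] * r), g, reorder = FALSE)
      list(A11 = acc[, 1] / s2 + Dinv[1, 1],
           g1 = acc[, 2] / s2 - U[, 1] * Dinv[1, 1])
    } else {
      acc <- rowsum(cbind(J[, 1]^2, J[, 2]^2, J[, 1] * J[, 2],
                          J[, 1] * r, J[, 2] * r), g, reorder = FALSE)
      list(A11 = acc[, 1] / s2 + Dinv[1, 1],
           A22 = acc[, 2] / s2 + Dinv[2, 2],
           A12 = acc[, 3] / s2 + Dinv[1, 2],
           g1 = acc[, 4] / s2 -
             (U[, 1] * Dinv[1, 1] + U[, 2] * Dinv[1, 2]),
           g2 = acc[, 5] / s2 -
             (U[, 1] * Dinv[2, 1] + U[, 2] * Dinv[2, 2]))
    }
  }

  for (iter in seq_len(inner_maxit)) {
    J <- jacobian_u(U, coef_list(U))
    if (!all(is.finite(J))) return(NULL)
    sys <- gn_system(J, r)
    if (q == 1) {
      A11 <- sys$A11
      bad <- A11 <= 1e-12
      if (any(bad)) { A11[bad] <- abs(A11[bad]) + 1e-8; nwarn <- nwarn + sum(bad) }
      step <- cbind(sys$g1 / A11)
    } else {
      A11 <- sys$A11; A22 <- sys$A22; A12 <- sys$A12
      det_ <- A11 * A22 - A12^2
      bad <- det_ <= 1e-12 | A11 <= 0
      if (any(bad)) {
        ridge <- pmax(abs(det_)^0.5, 1e-8)
        A11[bad] <- A11[bad] + ridge[bad]
        A22[bad] <- A22[bad] + ridge[bad]
        det_ <- A11 * A22 - A12^2
        nwarn <- nwarn + sum(bad)
      }
      step <- cbind((A22 * sys$g1 - A12 * sys$g2) / det_,
                    (A11 * sys$g2 - A12 * sys$g1) / det_)
    }

    # per-tree damped update: halve steps that do not decrease the
    # penalised objective
    alpha <- rep(1, M)
    for (half in seq_len(12)) {
      U_try <- U + step * alpha
      r_try <- y - mean_fun(coef_list(U_try), data)
      nf <- !is.finite(r_try)
      if (any(nf)) r_try[nf] <- 1e6
      obj_try <- obj_of(r_try, U_try)
      worse <- obj_try > obj + 1e-14
      if (!any(worse)) { r <- r_try; obj <- obj_try; break }
      alpha[worse] <- alpha[worse] / 2
      if (half == 12) {
        alpha[worse] <- 0
        U_try <- U + step * alpha
        r_try <- y - mean_fun(coef_list(U_try), data)
        r_try[!is.finite(r_try)] <- 1e6
        obj_try <- obj_of(r_try, U_try)
        r <- r_try; obj <- obj_try
      }
    }
    U <- U + step * alpha
    moved <- max(abs(step * alpha))
    if (moved < inner_tol) break
  }

  # Laplace pieces at the mode (Gauss-Newton Hessian at the final U)
  J <- jacobian_u(U, coef_list(U))
  sys <- gn_system(J, r)
  if (q == 1) {
    A11 <- sys$A11
    bad <- A11 <= 0
    if (any(bad)) { A11[bad] <- 1e-8; nwarn <- nwarn + sum(bad) }
    ldetA <- log(A11)
  } else {
    det_ <- sys$A11 * sys$A22 - sys$A12^2
    bad <- det_ <= 0 | sys$A11 <= 0
    if (any(bad)) { det_[bad] <- 1e-12; nwarn <- nwarn + sum(bad) }
    ldetA <- log(det_)
  }
  ldetD <- determinant(Dmat, logarithm = TRUE)$modulus[1]
  ll_tree <- -(grp$n_j / 2) * log(2 * pi * s2) - ldetD / 2 - obj - ldetA / 2
  list(loglik = sum(ll_tree), by_tree = ll_tree, U = U, nwarn = nwarn,
       resid = r)
}

rowsum_safe <- function(r, g) {
  as.vector(rowsum(ifelse(is.finite(r), r, NA_real_), g, reorder = FALSE))
}

#' Laplace-approximated marginal log-likelihood
#'
#' Evaluates, at fixed parameter values, the marginal log-likelihood of a
#' taper model with tree-level random effects on selected coefficients,
#' integrating the random effects out by a Laplace approximation around
#' each tree's posterior mode. The total is the sum of independent
#' per-tree contributions (returned in the `"by_tree"` attribute,
#' together with the per-tree modes in `"modes"`).
#'
#' @param data A [taper_data] tibble.
#' @param model Registry key or [taper_model] spec. Ignored when
#'   `mean_fun` is supplied.
#' @param fixed Fixed-effect coefficient vector.
#' @param random Integer indices of the coefficients carrying random
#'   effects (length 1 or 2).
#' @param D Random-effect covariance matrix (`q x q`, positive definite),
#'   or a scalar variance for `q = 1`.
#' @param sigma_sq Residual variance, cm^2.
#' @param mean_fun Optional replacement mean function
#'   `function(coef_list, data) -> mu`, mainly for validating the
#'   approximation against closed forms on models linear in `u`.
#' @return The scalar log-likelihood, with attributes `by_tree` and
#'   `modes`.
#' @export
laplace_marginal_loglik <- function(data, model = "kozak2004_inv_Sd",
                                    fixed, random, D, sigma_sq,
                                    mean_fun = NULL) {
  data <- taper_data(data)
  random <- as.integer(random)
  q <- length(random)
  stopifnot(q %in% c(1L, 2L))
  Dmat <- if (is.matrix(D)) D else matrix(D, q, q) * diag(q)
  stopifnot(nrow(Dmat) == q, isTRUE(all.equal(Dmat, t(Dmat))),
            all(eigen(Dmat, only.values = TRUE)$values > 0),
            sigma_sq > 0)
  if (is.null(mean_fun)) mean_fun <- taper_mean_fun(taper_model(model))
  grp <- make_groups(data)
  res <- laplace_eval(mean_fun, data, data$d_cm, grp, fixed, random,
                      Dmat, sqrt(sigma_sq))
  if (is.null(res)) {
    abort("inner optimisation produced non-finite values",
          class = "stemtaper_numeric_error")
  }
  out <- res$loglik
  attr(out, "by_tree") <- setNames(res$by_tree, grp$keys)
  attr(out, "modes") <- res$U
  out
}

# ---- full fit ----------------------------------------------------------

# theta packing: c(beta[1..p], t_diag[1..q] (log Cholesky diagonals),
# t_off (q = 2 only), log_sigma)
unpack_theta <- function(theta, p, q) {
  beta <- theta[seq_len(p)]
  if (q == 1) {
    L <- matrix(exp(theta[p + 1]), 1, 1)
    ls <- theta[p + 2]
  } else {
    L <- matrix(c(exp(theta[p + 1]), theta[p + 3], 0, exp(theta[p + 2])),
                2, 2)
    ls <- theta[p + 4]
  }
  list(beta = beta, L = L, Dmat = L %*% t(L), sigma = exp(ls))
}

#' Fit a taper model with tree-level random effects (Laplace NLME)
#'
#' Maximises the Laplace-approximated marginal likelihood over the fixed
#' coefficients, the random-effect covariance matrix (log-Cholesky
#' parameterised, so positive definiteness holds for every iterate) and
#' the residual variance (log parameterised). Random effects enter
#' additively on the coefficients selected by `random` (`beta + u`),
#' grouped by tree.
#'
#' The information-criterion parameter count is
#' `lambda = p + q(q+1)/2 + 1`: fixed effects, free covariance
#' components, and the residual variance.
#'
#' @param data A [taper_data] tibble (>= 10 trees recommended; at least 2
#'   required).
#' @param model Registry key or [taper_model] spec.
#' @param random Coefficient indices (length 1 or 2) receiving tree-level
#'   random effects. Default `c(6, 8)`.
#' @param start Fixed-effect start; default the NLS estimates on the same
#'   data (computed internally).
#' @param re_sd_start Starting SDs for the random effects; default 5% of
#'   the corresponding |coefficient| (floored at 1e-3).
#' @param control List: `inner_tol` (mode tolerance, default 1e-9),
#'   `inner_maxit` (100), `outer_rel_tol` (relative log-likelihood
#'   tolerance, default 1e-6), `outer_maxit` (300).
#' @return An object of class `taper_nlme`: `fixed`, `random` (indices),
#'   `D` (covariance matrix), `components` (tibble with `sigma1_sq`,
#'   `sigma2_sq`, `sigma12`, `sigma_sq`), `eblups` (per-tree predicted
#'   random effects), `loglik`, `lambda`, `AIC`, `BIC`, `minus2LL`,
#'   `converged`, `boundary` (TRUE when a random-effect variance
#'   collapsed to ~0), `n_hessian_regularisations`, and the fitting data.
#' @examples
#' \donttest{
#' sim <- simulate_taper_data(n_plots = 20, seed = 3)
#' fit <- fit_taper_nlme(sim$data, random = c(6, 8))
#' glance(fit)
#' }
#' @export
fit_taper_nlme <- function(data, model = "kozak2004_inv_Sd",
                           random = c(6L, 8L), start = NULL,
                           re_sd_start = NULL, control = list()) {
  m <- taper_model(model)
  data <- taper_data(data)
  random <- sort(as.integer(random))
  q <- length(random)
  if (!q %in% c(1L, 2L) || any(random < 1) || any(random > m$n_params)) {
    abort("random must name 1 or 2 coefficient indices of the model",
          class = "stemtaper_domain_error")
  }
  ctrl <- modifyList(list(inner_tol = 1e-9, inner_maxit = 100,
                          outer_rel_tol = 1e-6, outer_maxit = 300),
                     control)
  grp <- make_groups(data)
  if (grp$n_groups < 2) {
    abort("need at least 2 trees for a mixed fit",
          class = "stemtaper_domain_error")
  }

  if (is.null(start)) {
    nls0 <- fit_taper_nls(data, m)
    start <- unname(nls0$estimates)
    sigma0 <- sqrt(nls0$rss / max(nls0$n_obs - m$n_params, 1))
  } else {
    start <- unname(start)
    r0 <- data$d_cm - eval_taper(m, start, data)
    sigma0 <- sd(r0)
  }
  p <- m$n_params
  if (is.null(re_sd_start)) {
    re_sd_start <- pmax(0.05 * abs(start[random]), 1e-3)
  }

  mean_fun <- taper_mean_fun(m)
  y <- data$d_cm

  # precondition the fixed-effect directions by their approximate NLS
  # standard-error scales: the variable-exponent coefficients are highly
  # collinear, and stepping in raw coefficient units makes the outer
  # optimiser crawl along the likelihood ridge
  fn_pred <- function(b) {
    m$fn(as.list(b), D = data$D_cm, H = data$H_m, h = data$h_m,
         Sd = data$Sd_trees_ha, BA = data$BA_m2_ha, Cd = data$Cd)
  }
  sc_beta <- tryCatch({
    J <- fd_jacobian(fn_pred, start)
    cv <- chol2inv(chol(crossprod(J))) * sigma0^2
    sc <- sqrt(pmax(diag(cv), 0))
    ifelse(is.finite(sc) & sc > 0, sc, pmax(0.1 * abs(start), 0.01))
  }, error = function(e) pmax(0.1 * abs(start), 0.01))

  env <- new.env()
  env$U <- matrix(0, grp$n_groups, q)
  env$nwarn <- 0L

  n_theta <- p + q * (q + 1) / 2 + 1
  expand <- function(z) {
    c(start + sc_beta * z[seq_len(p)], z[(p + 1):n_theta])
  }
  nll <- function(z) {
    th <- unpack_theta(expand(z), p, q)
    res <- laplace_eval(mean_fun, data, y, grp, th$beta, random, th$Dmat,
                        th$sigma, U0 = env$U, inner_tol = ctrl$inner_tol,
                        inner_maxit = ctrl$inner_maxit)
    if (is.null(res) || !is.finite(res$loglik)) return(1e10)
    env$U <- res$U
    env$nwarn <- env$nwarn + res$nwarn
    -res$loglik
  }

  z0 <- c(rep(0, p), log(re_sd_start),
          if (q == 2) 0 else NULL, log(sigma0))
  lowb <- c(rep(-Inf, p), rep(log(1e-6), q),
            if (q == 2) -Inf else NULL, log(1e-4))
  opt <- nlminb(z0, nll, lower = lowb,
                control = list(rel.tol = ctrl$outer_rel_tol,
                               iter.max = ctrl$outer_maxit,
                               eval.max = 4 * ctrl$outer_maxit))

  th <- unpack_theta(expand(opt$par), p, q)
  final <- laplace_eval(mean_fun, data, y, grp, th$beta, random, th$Dmat,
                        th$sigma, U0 = env$U, inner_tol = ctrl$inner_tol,
                        inner_maxit = ctrl$inner_maxit)
  loglik <- final$loglik
  lambda <- p + q * (q + 1) / 2 + 1
  n <- nrow(data)

  comp <- tibble::tibble(
    sigma1_sq = th$Dmat[1, 1],
    sigma2_sq = if (q == 2) th$Dmat[2, 2] else NA_real_,
    sigma12 = if (q == 2) th$Dmat[1, 2] else NA_real_,
    sigma_sq = th$sigma^2)
  boundary <- any(diag(th$Dmat) < 1e-10)

  eblups <- tibble::as_tibble(
    setNames(as.data.frame(final$U),
             paste0("u_", m$param_names[random])))
  key_parts <- strsplit(grp$keys, "\r", fixed = TRUE)
  eblups <- dplyr::bind_cols(
    tibble::tibble(plot_id = vapply(key_parts, `[`, "", 1),
                   tree_id = vapply(key_parts, `[`, "", 2)),
    eblups)

  structure(list(
    model = m$key, spec = m, random = random,
    placement = placement_label(random, m$param_names),
    fixed = setNames(th$beta, m$param_names),
    D = th$Dmat, components = comp, eblups = eblups,
    loglik = loglik, lambda = lambda,
    AIC = -2 * loglik + 2 * lambda,
    BIC = -2 * loglik + lambda * log(n),
    minus2LL = -2 * loglik,
    converged = opt$convergence == 0, boundary = boundary,
    opt_message = opt$message,
    n_hessian_regularisations = env$nwarn,
    n_obs = n, n_trees = grp$n_groups,
    data = data),
    class = "taper_nlme")
}

#' @export
print.taper_nlme <- function(x, ...) {
  cat("<taper_nlme> model", x$model, "| random effects on",
      x$placement, "\n")
  cat(sprintf("  %d trees, %d sections | logLik %.2f  AIC %.1f  BIC %.1f%s\n",
              x$n_trees, x$n_obs, x$loglik, x$AIC, x$BIC,
              if (x$converged) "" else "  [NOT converged]"))
  cat("  fixed effects:\n")
  print(round(x$fixed, 5))
  cat("  D:\n"); print(signif(x$D, 5))
  cat(sprintf("  sigma^2 = %.5f%s\n", x$components$sigma_sq,
              if (x$boundary) "  [variance at boundary]" else ""))
  invisible(x)
}

#' @export
coef.taper_nlme <- function(object, ...) object$fixed

#' Predict diameters from a mixed-effects taper fit
#'
#' `mode = "population"` sets the random effects to zero (fixed effects
#' only); `mode = "calibrated"` first predicts each tree's random effect
#' from its observed sections in `newdata` (posterior mode under the
#' fitted covariance components), then predicts with the calibrated
#' coefficients.
#'
#' @param object A `taper_nlme` fit.
#' @param newdata A [taper_data] tibble (defaults to the fitting data).
#' @param mode `"population"` or `"calibrated"`.
#' @param ... Unused.
#' @return Numeric vector of predicted diameters (cm).
#' @export
predict.taper_nlme <- function(object, newdata = NULL,
                               mode = c("population", "calibrated"), ...) {
  mode <- match.arg(mode)
  data <- taper_data(newdata %||% object$data)
  if (mode == "population") {
    return(eval_taper(object$spec, object$fixed, data))
  }
  u <- estimate_tree_effects(object, data)
  mean_fun <- taper_mean_fun(object$spec)
  grp <- make_groups(data)
  bl <- as.list(unname(object$fixed))
  for (k in seq_along(object$random)) {
    bl[[object$random[k]]] <- object$fixed[object$random[k]] +
      u[grp$g, k]
  }
  mean_fun(bl, data)
}

#' Predict tree-level random effects for new trees
#'
#' Computes each tree's posterior-mode random effect under the fitted
#' covariance components, from that tree's observed sections — the
#' calibration step for applying a mixed taper model to trees outside the
#' fitting sample. Requires at least one observed section per tree.
#'
#' @param object A `taper_nlme` fit.
#' @param newdata A [taper_data] tibble with observed `d_cm`.
#' @return A matrix of predicted effects, one row per tree (in the order
#'   of the tree keys in `newdata`), columns matching `object$random`.
#' @export
estimate_tree_effects <- function(object, newdata) {
  data <- taper_data(newdata)
  grp <- make_groups(data)
  if (any(grp$n_j < 1)) {
    abort("calibration requires at least one section per tree",
          class = "stemtaper_domain_error")
  }
  mean_fun <- taper_mean_fun(object$spec)
  res <- laplace_eval(mean_fun, data, data$d_cm, grp,
                      unname(object$fixed), object$random, object$D,
                      sqrt(object$components$sigma_sq))
  if (is.null(res)) {
    abort("calibration failed (non-finite model values)",
          class = "stemtaper_numeric_error")
  }
  rownames(res$U) <- grp$keys
  res$U
}

#' Rank candidate random-effect placements
#'
#' Fits the mixed model once per candidate placement and tabulates the
#' information criteria, mirroring the coefficient-subset search used to
#' decide where tree-level random effects act. Placements whose fit fails
#' or does not converge are retained and flagged, never dropped. The best
#' placement is the converged minimum-AIC row, ties broken by BIC and
#' then by fewer random effects.
#'
#' @param data A [taper_data] tibble.
#' @param model Registry key or [taper_model] spec.
#' @param placements List of integer index vectors; default every 1- and
#'   2-coefficient subset from [enumerate_random_subsets()].
#' @param start Optional shared fixed-effect start (default: one NLS fit,
#'   reused across placements).
#' @param control Passed to [fit_taper_nlme()].
#' @param verbose Emit one progress line per placement.
#' @return A tibble with columns `placement`, `indices` (list), `q`,
#'   `AIC`, `BIC`, `minus2LL`, `converged`, `boundary`, `best`.
#' @export
rank_placements <- function(data, model = "kozak2004_inv_Sd",
                            placements = NULL, start = NULL,
                            control = list(), verbose = FALSE) {
  m <- taper_model(model)
  data <- taper_data(data)
  if (is.null(placements)) {
    placements <- enumerate_random_subsets(m$n_params)
  }
  if (length(placements) == 0) {
    abort("placements must be nonempty", class = "stemtaper_domain_error")
  }
  if (is.null(start)) {
    start <- unname(fit_taper_nls(data, m)$estimates)
  }
  rows <- purrr::map(placements, function(idx) {
    fit <- tryCatch(
      fit_taper_nlme(data, m, random = idx, start = start,
                     control = control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      if (verbose) message("placement ", placement_label(idx, m$param_names),
                           ": failed (", conditionMessage(fit), ")")
      return(tibble::tibble(
        placement = placement_label(idx, m$param_names),
        indices = list(as.integer(idx)), q = length(idx),
        AIC = NA_real_, BIC = NA_real_, minus2LL = NA_real_,
        converged = FALSE, boundary = NA))
    }
    if (verbose) {
      message(sprintf("placement %s: AIC %.1f (%s)",
                      fit$placement, fit$AIC,
                      if (fit$converged) "converged" else "not converged"))
    }
    tibble::tibble(
      placement = fit$placement, indices = list(as.integer(idx)),
      q = length(idx), AIC = fit$AIC, BIC = fit$BIC,
      minus2LL = fit$minus2LL, converged = fit$converged,
      boundary = fit$boundary)
  })
  tab <- dplyr::bind_rows(rows)
  if (!any(tab$converged, na.rm = TRUE)) {
    abort("no placement converged; inspect the per-placement diagnostics",
          class = "stemtaper_fit_error")
  }
  ok <- which(tab$converged)
  ord <- ok[order(tab$AIC[ok], tab$BIC[ok], tab$q[ok])]
  tab$best <- seq_len(nrow(tab)) == ord[1]
  tab
}

#' @method tidy taper_nlme
#' @export
tidy.taper_nlme <- function(x, ...) {
  fx <- tibble::tibble(term = names(x$fixed), estimate = unname(x$fixed),
                       type = "fixed")
  q <- length(x$random)
  vc_terms <- c("sigma1_sq",
                if (q == 2) c("sigma2_sq", "sigma12"), "sigma_sq")
  vc <- tibble::tibble(
    term = vc_terms,
    estimate = unlist(x$components[vc_terms], use.names = FALSE),
    type = "variance")
  dplyr::bind_rows(fx, vc)
}

#' @method glance taper_nlme
#' @export
glance.taper_nlme <- function(x, ...) {
  tibble::tibble(model = x$model, placement = x$placement,
                 n_obs = x$n_obs, n_trees = x$n_trees,
                 lambda = x$lambda, logLik = x$loglik, AIC = x$AIC,
                 BIC = x$BIC, minus2LL = x$minus2LL,
                 sigma_sq = x$components$sigma_sq,
                 converged = x$converged, boundary = x$boundary)
}
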