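#' Fit a taper model by pooled nonlinear least squares
#'
#' Minimises the pooled residual sum of squares
#' \eqn{\sum_k (d_k - f(D_k, H_k, h_k; b))^2} over all section
#' measurements by Levenberg-Marquardt iteration. Sections of all trees
#' are pooled; within-tree correlation is ignored at this stage (that is
#' what the mixed-effects engine is for).
#'
#' Approximate standard errors come from the Jacobian-based covariance
#' \eqn{s^2 (J^\top J)^{-1}} with \eqn{s^2 = RSS/(n - p)}. The reported
#' log-likelihood is the concentrated Gaussian value
#' \eqn{-(n/2)[\ln 2\pi + \ln(RSS/n) + 1]}.
#'
#' @param data A [taper_data] tibble with every covariate the model needs.
#' @param model Registry key or [taper_model] spec. Default the Kozak
#'   (2004) base form.
#' @param start Named or positional start vector; defaults to the model's
#'   published reference coefficients (a warm start close to realistic
#'   taper surfaces).
#' @param lower,upper Optional box bounds per coefficient. By default
#'   unbounded except that an inflection parameter `p`, where a model has
#'   one, is kept inside (0, 1).
#' @param control List of tolerances: `ftol` (relative RSS change,
#'   default 1e-10), `gtol` (gradient test, default 1e-8), `maxiter`
#'   (default 500).
#' @return An object of class `taper_nls`: a list with `model`, `spec`,
#'   `estimates`, `std_errors`, `rss`, `n_obs`, `loglik`, `converged`,
#'   `n_iter`, `fitted`, and the fitting `data`. Non-convergence is
#'   reported in `converged`, never silently.
#' @seealso [tidy()][generics::tidy] and [glance()][generics::glance]
#'   methods, [predict.taper_nls()].
#' @examples
#' sim <- simulate_taper_data(n_plots = 5, re_sd = c(0, 0), seed = 7)
#' fit <- fit_taper_nls(sim$data, "kozak2004_inv_Sd")
#' glance(fit)
#' @export
fit_taper_nls <- function(data, model = "kozak2004", start = NULL,
                          lower = NULL, upper = NULL, control = list()) {
  m <- taper_model(model)
  data <- taper_data(data)
  ctrl <- modifyList(list(ftol = 1e-10, gtol = 1e-8, maxiter = 500),
                     control)
  p <- m$n_params
  n <- nrow(data)
  if (n < p + 1) {
    abort(sprintf("need at least %d sections to fit %d parameters",
                  p + 1, p),
          class = "stemtaper_domain_error")
  }
  if (is.null(start)) start <- m$ref_params
  start <- unname(start)
  stopifnot(length(start) == p)

  if (is.null(lower)) lower <- rep(-Inf, p)
  if (is.null(upper)) upper <- rep(Inf, p)
  is_p <- m$param_names == "p"
  lower[is_p] <- pmax(lower[is_p], 1e-6)
  upper[is_p] <- pmin(upper[is_p], 0.999)

  y <- data$d_cm
  fn_pred <- function(b) {
    m$fn(as.list(b), D = data$D_cm, H = data$H_m, h = data$h_m,
         Sd = data$Sd_trees_ha, BA = data$BA_m2_ha, Cd = data$Cd)
  }
  # validate covariates once up front (clear error instead of NA residuals)
  eval_taper(m, start, data)

  resid_fn <- function(b) {
    r <- y - fn_pred(b)
    r[!is.finite(r)] <- 1e6
    r
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = ctrl$ftol, gtol = ctrl$gtol,
      maxiter = min(ctrl$maxiter, 1024)))

  est <- setNames(coef(fit), m$param_names)
  fitted <- fn_pred(est)
  rss <- sum((y - fitted)^2)
  converged <- fit$info %in% 1:4

  # Jacobian-based covariance at the optimum
  J <- fd_jacobian(fn_pred, unname(est))
  qrJ <- qr(J)
  se <- rep(NA_real_, p)
  if (qrJ$rank < p) {
    aliased <- m$param_names[qrJ$pivot[(qrJ$rank + 1):p]]
    abort(paste0("singular Jacobian; aliased coefficient(s): ",
                 paste(aliased, collapse = ", ")),
          class = "stemtaper_rank_error")
  }
  s2 <- rss / (n - p)
  covb <- tryCatch(chol2inv(qr.R(qrJ)) * s2, error = function(e) NULL)
  if (!is.null(covb)) {
    se[qrJ$pivot] <- sqrt(pmax(diag(covb), 0))
  }

  structure(list(
    model = m$key, spec = m,
    estimates = est,
    std_errors = setNames(se, m$param_names),
    rss = rss, n_obs = n,
    loglik = gaussian_loglik(rss, n),
    converged = converged, n_iter = fit$niter,
    info = fit$info, message = fit$message,
    fitted = fitted, data = data),
    class = "taper_nls")
}

# central-difference Jacobian of a vector-valued function of b
fd_jacobian <- function(f, b, eps = 1e-6) {
  p <- length(b)
  f0 <- f(b)
  J <- matrix(0, length(f0), p)
  for (k in seq_len(p)) {
    dk <- eps * max(abs(b[k]), 1)
    bp <- b; bp[k] <- b[k] + dk
    bm <- b; bm[k] <- b[k] - dk
    J[, k] <- (f(bp) - f(bm)) / (2 * dk)
  }
  J
}

#' @export
print.taper_nls <- function(x, ...) {
  cat("<taper_nls> model", x$model, "\n")
  cat(sprintf("  n = %d sections, RSS = %.4f, logLik = %.2f, %s (%d iter)\n",
              x$n_obs, x$rss, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(round(rbind(estimate = x$estimates, std.error = x$std_errors), 5))
  invisible(x)
}

#' @export
coef.taper_nls <- function(object, ...) object$estimates

#' Predict section diameters from a fitted taper model
#'
#' @param object A `taper_nls` fit.
#' @param newdata A [taper_data] tibble (defaults to the fitting data).
#' @param ... Unused.
#' @return Numeric vector of predicted diameters (cm).
#' @export
predict.taper_nls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  eval_taper(object$spec, object$estimates, taper_data(newdata))
}

#' @method tidy taper_nls
#' @export
tidy.taper_nls <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 std.error = unname(x$std_errors))
}

#' @method glance taper_nls
#' @export
glance.taper_nls <- function(x, ...) {
  stats <- fit_statistics(x$data$d_cm, x$fitted,
                          lambda = x$spec$n_params + 1)
  dplyr::bind_cols(tibble::tibble(model = x$model),
                   stats,
                   tibble::tibble(converged = x$converged,
                                  n_iter = x$n_iter))
}
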