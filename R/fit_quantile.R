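# Nonlinear quantile regression for taper models.
#
# The tau-th quantile surface minimises the check (pinball) loss of the
# model residuals. The loss kink is handled by a smoothing continuation:
# the smooth convex surrogate tau*r + delta*log(1 + exp(-r/delta))
# converges to the check loss as delta -> 0, so the surrogate is
# minimised at decreasing delta (warm-starting each stage), and a final
# derivative-free polish runs on the exact loss. The reported objective
# and coverage always use the exact loss.

#' Check (pinball) loss
#'
#' \deqn{\rho_\tau(r) = \sum_{r_i \ge 0} \tau r_i +
#'       \sum_{r_i < 0} (1-\tau)(-r_i).}
#' Its minimiser over a location parameter is the empirical
#' \eqn{\tau}-quantile; \eqn{\tau = 0.5} gives half the absolute-error
#' sum (median regression).
#'
#' @param residuals Vector of residuals `y - yhat`.
#' @param tau Quantile level in (0, 1).
#' @return The scalar loss (zero iff all residuals are zero).
#' @examples
#' check_loss(c(1, -1), 0.5)  # 1
#' check_loss(2, 0.9)         # 1.8
#' @export
check_loss <- function(residuals, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    abort("tau must lie in (0, 1)", class = "stemtaper_domain_error")
  }
  if (!all(is.finite(residuals))) {
    abort("residuals must be finite", class = "stemtaper_domain_error")
  }
  sum(residuals * (tau - (residuals < 0)))
}

# smooth surrogate: tau*r + delta*log(1 + exp(-r/delta)), computed stably
smooth_check <- function(residuals, tau, delta) {
  x <- -residuals / delta
  sum(tau * residuals + delta * (pmax(x, 0) + log1p(exp(-abs(x)))))
}

#' Fit a taper model at one quantile
#'
#' Estimates the coefficient vector whose taper surface is the
#' \eqn{\tau}-th conditional quantile of section diameter, by minimising
#' the check loss of the pooled residuals. Optimisation runs a smoothing
#' continuation (surrogate bandwidths `deltas`, each stage warm-started
#' and BFGS-minimised) followed by a Nelder-Mead polish on the exact
#' loss; the returned point is never worse (in exact loss) than the
#' starting point.
#'
#' @param data A [taper_data] tibble.
#' @param model Registry key or [taper_model] spec.
#' @param tau Quantile level in (0, 1).
#' @param start Start vector; default the NLS estimates on `data`.
#' @param control List: `deltas` (continuation schedule, default
#'   `c(0.1, 0.01, 0.001)` cm), `maxit` (per BFGS stage, default 200),
#'   `polish_maxit` (Nelder-Mead, default 2000).
#' @return An object of class `taper_rq`: `tau`, `estimates`,
#'   `check_loss` (exact loss at the optimum), `coverage` (fraction of
#'   observations strictly below the fitted surface), `converged`,
#'   `fitted`, and the fitting data.
#' @examples
#' sim <- simulate_taper_data(n_plots = 5, seed = 11)
#' fit <- fit_taper_quantile(sim$data, tau = 0.5)
#' fit$coverage
#' @export
fit_taper_quantile <- function(data, model = "kozak2004_inv_Sd", tau = 0.5,
                               start = NULL, control = list()) {
  m <- taper_model(model)
  data <- taper_data(data)
  if (tau <= 0 || tau >= 1) {
    abort("tau must lie in (0, 1)", class = "stemtaper_domain_error")
  }
  ctrl <- modifyList(list(deltas = c(0.1, 0.01, 0.001), maxit = 200,
                          polish_maxit = 2000), control)
  if (is.null(start)) start <- unname(fit_taper_nls(data, m)$estimates)
  start <- unname(start)
  stopifnot(length(start) == m$n_params)

  y <- data$d_cm
  fn_pred <- function(b) {
    m$fn(as.list(b), D = data$D_cm, H = data$H_m, h = data$h_m,
         Sd = data$Sd_trees_ha, BA = data$BA_m2_ha, Cd = data$Cd)
  }
  eval_taper(m, start, data)  # covariate validation up front

  exact <- function(b) {
    r <- y - fn_pred(b)
    if (!all(is.finite(r))) return(1e10)
    check_loss(r, tau)
  }
  smooth_obj <- function(b, delta) {
    r <- y - fn_pred(b)
    if (!all(is.finite(r))) return(1e10)
    smooth_check(r, tau, delta)
  }

  par <- start
  ok <- TRUE
  for (delta in ctrl$deltas) {
    o <- optim(par, smooth_obj, delta = delta, method = "BFGS",
               control = list(maxit = ctrl$maxit, reltol = 1e-12))
    # keep the stage result only if it helps the exact objective trail
    if (is.finite(o$value)) par <- o$par else ok <- FALSE
  }
  polish <- if (length(par) == 1) {
    spread <- max(1, diff(range(y)), abs(par - start))
    optim(par, exact, method = "Brent", lower = par - spread,
          upper = par + spread)
  } else {
    optim(par, exact, method = "Nelder-Mead",
          control = list(maxit = ctrl$polish_maxit, reltol = 1e-8))
  }
  # never return a point worse than the start (exact-loss contract)
  candidates <- list(start = start, continuation = par,
                     polish = polish$par)
  losses <- vapply(candidates, exact, numeric(1))
  best <- which.min(losses)
  est <- candidates[[best]]
  loss <- losses[best]
  if (loss > losses["start"] + 1e-12) {
    abort("internal error: optimiser returned a worse point than its start",
          class = "stemtaper_internal_error")
  }
  fitted <- fn_pred(est)
  structure(list(
    model = m$key, spec = m, tau = tau,
    estimates = setNames(est, m$param_names),
    check_loss = loss,
    coverage = mean(y < fitted),
    converged = ok && polish$convergence == 0,
    n_obs = length(y), fitted = fitted, data = data),
    class = "taper_rq")
}

#' @export
print.taper_rq <- function(x, ...) {
  cat(sprintf("<taper_rq> model %s | tau = %.2f\n", x$model, x$tau))
  cat(sprintf("  check loss %.4f | coverage %.3f | %s\n", x$check_loss,
              x$coverage,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$estimates, 5))
  invisible(x)
}

#' @export
coef.taper_rq <- function(object, ...) object$estimates

#' @export
predict.taper_rq <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  eval_taper(object$spec, object$estimates, taper_data(newdata))
}

#' @method tidy taper_rq
#' @export
tidy.taper_rq <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates),
                 tau = x$tau)
}

#' @method glance taper_rq
#' @export
glance.taper_rq <- function(x, ...) {
  stats <- fit_statistics(x$data$d_cm, x$fitted,
                          lambda = x$spec$n_params + 1)
  dplyr::bind_cols(
    tibble::tibble(model = x$model, tau = x$tau,
                   check_loss = x$check_loss, coverage = x$coverage),
    stats[c("MAB", "RMSE", "MPB", "Bias", "R2", "R2_adj")],
    tibble::tibble(converged = x$converged))
}

#' Fit a taper model across a grid of quantiles
#'
#' One [fit_taper_quantile()] fit per level of `taus`. The first fit is
#' initialised from the NLS estimates; each subsequent fit is
#' warm-started from the adjacent (previous) quantile's estimates. A
#' failing level is flagged and the sweep continues.
#'
#' Quantile crossing — a lower-\eqn{\tau} surface exceeding a
#' higher-\eqn{\tau} one somewhere — is diagnosed (counted over all
#' section rows and all ordered quantile pairs) but never corrected: the
#' fitted surfaces are reported as estimated.
#'
#' @param data A [taper_data] tibble.
#' @param model Registry key or [taper_model] spec.
#' @param taus Strictly increasing quantile levels in (0, 1); default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @param start Optional start for the first fit (default: internal NLS).
#' @param control Passed to each [fit_taper_quantile()].
#' @return An object of class `taper_rq_sweep`: list with `fits` (one
#'   `taper_rq` or `NULL` per level), `summary` (tibble: `tau`,
#'   `check_loss`, `coverage`, `MAB`, `RMSE`, `MPB`, `R2`, `R2_adj`,
#'   `converged`), and `crossings` (violation count).
#' @export
quantile_sweep <- function(data, model = "kozak2004_inv_Sd",
                           taus = seq(0.1, 0.9, by = 0.1), start = NULL,
                           control = list()) {
  m <- taper_model(model)
  data <- taper_data(data)
  if (any(diff(taus) <= 0) || any(taus <= 0) || any(taus >= 1)) {
    abort("taus must be strictly increasing in (0, 1)",
          class = "stemtaper_domain_error")
  }
  if (is.null(start)) start <- unname(fit_taper_nls(data, m)$estimates)

  fits <- vector("list", length(taus))
  prev <- start
  for (i in seq_along(taus)) {
    fits[[i]] <- tryCatch(
      fit_taper_quantile(data, m, tau = taus[i], start = prev,
                         control = control),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) prev <- unname(fits[[i]]$estimates)
  }

  summary <- purrr::map2_dfr(fits, taus, function(f, tau) {
    if (is.null(f)) {
      return(tibble::tibble(tau = tau, check_loss = NA_real_,
                            coverage = NA_real_, MAB = NA_real_,
                            RMSE = NA_real_, MPB = NA_real_,
                            R2 = NA_real_, R2_adj = NA_real_,
                            converged = FALSE))
    }
    g <- glance(f)
    tibble::tibble(tau = tau, check_loss = f$check_loss,
                   coverage = f$coverage, MAB = g$MAB, RMSE = g$RMSE,
                   MPB = g$MPB, R2 = g$R2, R2_adj = g$R2_adj,
                   converged = f$converged)
  })

  pred <- purrr::map(fits, function(f) if (is.null(f)) NULL else f$fitted)
  crossings <- 0L
  idx <- which(!vapply(pred, is.null, logical(1)))
  if (length(idx) >= 2) {
    for (a in head(seq_along(idx), -1)) {
      for (b in (a + 1):length(idx)) {
        crossings <- crossings +
          sum(pred[[idx[a]]] > pred[[idx[b]]] + 1e-10)
      }
    }
  }
  structure(list(fits = fits, taus = taus, summary = summary,
                 crossings = crossings, model = m$key),
            class = "taper_rq_sweep")
}

#' @export
print.taper_rq_sweep <- function(x, ...) {
  cat("<taper_rq_sweep> model", x$model, "|", length(x$taus),
      "quantiles |", x$crossings, "crossing points\n")
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method tidy taper_rq_sweep
#' @export
tidy.taper_rq_sweep <- function(x, ...) {
  purrr::map_dfr(x$fits[!vapply(x$fits, is.null, logical(1))],
                 function(f) {
    dplyr::bind_cols(tibble::tibble(tau = f$tau),
                     tibble::as_tibble(as.list(f$estimates)))
  })
}

#' @method glance taper_rq_sweep
#' @export
glance.taper_rq_sweep <- function(x, ...) x$summary
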