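#' Taper-model evaluation statistics
#'
#' Computes the standard suite of goodness-of-fit statistics used for
#' comparing stem taper equations on one set of (observed, predicted)
#' section diameters:
#' \itemize{
#'   \item `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`
#'   \item `R2_adj = 1 - (1 - R2) (n - 1) / (n - lambda)`
#'   \item `MAB = sum(|y - yhat|) / n` (mean absolute bias, cm)
#'   \item `RMSE = sqrt(sum((y - yhat)^2) / (n - 1))` — note the `n - 1`
#'     denominator, kept deliberately so values are comparable with the
#'     taper literature that defines RMSE this way; tools using `n` will
#'     differ slightly.
#'   \item `MPB = 100 sum(|y - yhat|) / sum(y)` (mean percentage bias, %)
#'   \item `Bias = sum(y - yhat) / n` (signed mean deviation, cm)
#'   \item `lnL = -(n/2) (ln(2 pi) + ln(RSS/n) + 1)`, the concentrated
#'     Gaussian log-likelihood
#'   \item `AIC = -2 lnL + 2 lambda`, `BIC = -2 lnL + lambda ln(n)` with
#'     `n` the number of section observations
#' }
#'
#' @param observed Observed diameters, cm.
#' @param predicted Predicted diameters, cm; same length as `observed`.
#' @param lambda Number of estimated parameters counted by the
#'   information criteria.
#' @return A one-row tibble with columns `n`, `lambda`, `MAB`, `RMSE`,
#'   `MPB`, `Bias`, `R2`, `R2_adj`, `lnL`, `AIC`, `BIC`, `minus2LL`.
#' @examples
#' fit_statistics(c(1, 2, 3), c(2, 2, 2), lambda = 1)
#' @export
fit_statistics <- function(observed, predicted, lambda) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 2) abort("need at least 2 observations",
                   class = "stemtaper_domain_error")
  if (n <= lambda) abort("need n > lambda",
                         class = "stemtaper_domain_error")
  if (anyNA(observed) || anyNA(predicted)) {
    abort("observed/predicted must not contain NA",
          class = "stemtaper_domain_error")
  }
  r <- observed - predicted
  rss <- sum(r^2)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) {
    abort("observed values have zero variance; R2 undefined",
          class = "stemtaper_domain_error")
  }
  R2 <- 1 - rss / tss
  lnL <- gaussian_loglik(rss, n)
  tibble::tibble(
    n = n, lambda = lambda,
    MAB = sum(abs(r)) / n,
    RMSE = sqrt(rss / (n - 1)),
    MPB = 100 * sum(abs(r)) / sum(observed),
    Bias = sum(r) / n,
    R2 = R2,
    R2_adj = 1 - (1 - R2) * (n - 1) / (n - lambda),
    lnL = lnL,
    AIC = -2 * lnL + 2 * lambda,
    BIC = -2 * lnL + lambda * log(n),
    minus2LL = -2 * lnL)
}

# concentrated Gaussian log-likelihood at the MLE sigma^2 = RSS/n
gaussian_loglik <- function(rss, n) {
  if (rss <= 0) rss <- .Machine$double.xmin  # perfect fit guard
  -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
}

#' Prediction errors by relative-height class
#'
#' Summarises residuals in bins of relative height T = h/H, matching the
#' convention that a bin `(a, b]` is left-open and right-closed (e.g. the
#' upper stem is `0.7 < T <= 1`). Empty bins are retained with `n = 0`.
#'
#' @param data A [taper_data] tibble.
#' @param predicted Predicted diameters aligned with the rows of `data`.
#' @param edges Strictly increasing bin edges spanning (0, 1];
#'   default `seq(0, 1, by = 0.1)`.
#' @return A tibble with one row per bin: `class` (label), `lower`,
#'   `upper`, `n`, `MAB`, `Bias`.
#' @export
error_by_height_class <- function(data, predicted,
                                  edges = seq(0, 1, by = 0.1)) {
  stopifnot(nrow(data) == length(predicted),
            all(diff(edges) > 0), edges[1] >= 0,
            abs(edges[length(edges)] - 1) < 1e-12)
  T_ <- data$h_m / data$H_m
  if (any(T_ <= 0 | T_ > 1)) {
    abort("relative heights must lie in (0, 1]",
          class = "stemtaper_domain_error")
  }
  r <- data$d_cm - predicted
  bin <- cut(T_, breaks = edges, include.lowest = FALSE, right = TRUE)
  out <- tibble::tibble(bin = bin, r = r)
  out <- dplyr::group_by(out, .data$bin, .drop = FALSE)
  out <- dplyr::summarise(out,
                          n = dplyr::n(),
                          MAB = ifelse(dplyr::n() > 0,
                                       mean(abs(.data$r)), NA_real_),
                          Bias = ifelse(dplyr::n() > 0,
                                        mean(.data$r), NA_real_),
                          .groups = "drop")
  tibble::tibble(
    class = as.character(out$bin),
    lower = edges[-length(edges)],
    upper = edges[-1],
    n = out$n, MAB = out$MAB, Bias = out$Bias)
}
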