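# Diagnostic graphics. Figures follow the conventions of the taper
# literature: relative height on the x axis, diameters or errors on y.

#' Plot observed and fitted stem profiles
#'
#' Observed section diameters against relative height, with the fitted
#' taper curve overlaid per tree, for a (sampled) subset of trees.
#'
#' @param fit A fitted `taper_nls`, `taper_nlme` or `taper_rq` object.
#' @param trees Number of trees to draw (sampled deterministically: the
#'   first `trees` trees of the data).
#' @param grid_n Evaluation points along the stem per tree.
#' @return A ggplot object.
#' @export
plot_taper_profiles <- function(fit, trees = 6, grid_n = 60) {
  data <- fit$data
  keys <- unique(tree_key(data))
  keep <- keys[seq_len(min(trees, length(keys)))]
  sub <- data[tree_key(data) %in% keep, , drop = FALSE]
  sub$tree <- paste(sub$plot_id, sub$tree_id, sep = "/")

  curves <- purrr::map_dfr(unique(sub$tree), function(tr) {
    one <- sub[sub$tree == tr, ][1, ]
    hh <- seq(0.02, 0.999, length.out = grid_n) * one$H_m
    nd <- tibble::tibble(
      plot_id = one$plot_id, tree_id = one$tree_id, D_cm = one$D_cm,
      H_m = one$H_m, h_m = hh, d_cm = 0, Sd_trees_ha = one$Sd_trees_ha,
      BA_m2_ha = one$BA_m2_ha, Cd = one$Cd, age_yr = one$age_yr)
    pred <- if (inherits(fit, "taper_nlme")) {
      predict(fit, nd, mode = "population")
    } else {
      eval_taper(fit$spec, fit$estimates, taper_data(nd))
    }
    tibble::tibble(tree = tr, T = hh / one$H_m, d = pred)
  })

  ggplot2::ggplot() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$T, y = .data$d),
                       colour = "steelblue") +
    ggplot2::geom_point(data = sub,
                        ggplot2::aes(x = .data$h_m / .data$H_m,
                                     y = .data$d_cm),
                        size = 1, alpha = 0.8) +
    ggplot2::facet_wrap(~tree) +
    ggplot2::labs(x = "relative height h/H", y = "diameter (cm)",
                  title = paste("Stem profiles:", fit$model)) +
    ggplot2::theme_minimal()
}

#' Plot errors by relative-height class
#'
#' @param hce A tibble from [error_by_height_class()] (optionally with a
#'   `fit` column to facet by, as produced by [run_validation()]).
#' @return A ggplot object showing per-class MAB (bars) and Bias (points).
#' @export
plot_height_class_errors <- function(hce) {
  hce$mid <- (hce$lower + hce$upper) / 2
  p <- ggplot2::ggplot(hce, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$MAB), fill = "grey70",
                      width = 0.08) +
    ggplot2::geom_point(ggplot2::aes(y = .data$Bias), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "relative height class (midpoint)",
                  y = "MAB (bars) and Bias (points), cm") +
    ggplot2::theme_minimal()
  if ("fit" %in% names(hce)) p <- p + ggplot2::facet_wrap(~fit)
  p
}

#' @method autoplot taper_rq_sweep
#' @export
autoplot.taper_rq_sweep <- function(object, ...) {
  s <- tidyr::pivot_longer(object$summary,
                           cols = c("MAB", "RMSE", "coverage"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(tau), y = NULL,
                  title = "Quantile sweep diagnostics") +
    ggplot2::theme_minimal()
}

#' @method autoplot taper_nls
#' @export
autoplot.taper_nls <- function(object, ...) {
  df <- tibble::tibble(T = object$data$h_m / object$data$H_m,
                       residual = object$data$d_cm - object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$T, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "relative height h/H", y = "residual (cm)",
                  title = paste("Residuals:", object$model)) +
    ggplot2::theme_minimal()
}
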