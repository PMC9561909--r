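# Comparison and validation workflow: base-model comparison, density-form
# comparison, and held-out validation of the four estimation variants.
# Model selection throughout is minimum AIC among converged fits, ties
# broken by BIC, then by parsimony (fewer parameters).

rank_best <- function(tab, n_params_col = "lambda") {
  ok <- which(tab$converged & is.finite(tab$AIC))
  best <- rep(FALSE, nrow(tab))
  if (length(ok) > 0) {
    ord <- ok[order(tab$AIC[ok], tab$BIC[ok], tab[[n_params_col]][ok])]
    best[ord[1]] <- TRUE
  }
  best
}

#' Compare the base taper models by pooled NLS
#'
#' Fits every requested base model on the fitting data by nonlinear least
#' squares and tabulates the evaluation statistics. A model whose fit
#' fails is kept as a flagged row. The information-criterion parameter
#' count is the model's coefficient count plus one (the residual
#' variance).
#'
#' @param data Fitting [taper_data].
#' @param models Character vector of registry keys; default the twelve
#'   base (density-free) models.
#' @param control Passed to [fit_taper_nls()].
#' @return A tibble with one row per model: `model`, `n_params`, the
#'   [fit_statistics()] columns, `converged` and `best` (minimum-AIC
#'   marker).
#' @export
run_base_comparison <- function(data, models = NULL, control = list()) {
  data <- taper_data(data)
  if (is.null(models)) models <- list_models(include_density = FALSE)$key
  rows <- purrr::map(models, function(key) {
    m <- taper_model(key)
    fit <- tryCatch(fit_taper_nls(data, m, control = control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warn(paste0("model ", key, " failed: ", conditionMessage(fit)))
      return(tibble::tibble(model = key, n_params = m$n_params,
                            converged = FALSE))
    }
    dplyr::bind_cols(
      tibble::tibble(model = key, n_params = m$n_params),
      fit_statistics(data$d_cm, fit$fitted, lambda = m$n_params + 1),
      tibble::tibble(converged = fit$converged))
  })
  tab <- dplyr::bind_rows(rows)
  tab$best <- rank_best(tab, "n_params")
  tab
}

#' Compare stand-density forms of the Kozak (2004) model
#'
#' Fits the base Kozak (2004) model and its eight density-augmented
#' variants on the same data and tabulates the evaluation statistics, to
#' identify which functional form of the stand-density effect best
#' explains taper variation.
#'
#' @param data Fitting [taper_data].
#' @param forms Density forms to try; default all eight.
#' @param include_base Also fit the density-free base model
#'   (default `TRUE`).
#' @param control Passed to [fit_taper_nls()].
#' @return A tibble as in [run_base_comparison()], with a `density_form`
#'   column.
#' @export
run_density_comparison <- function(data,
                                   forms = setdiff(DENSITY_FORMS, "none"),
                                   include_base = TRUE, control = list()) {
  keys <- paste0("kozak2004_", forms)
  if (include_base) keys <- c("kozak2004", keys)
  tab <- run_base_comparison(data, models = keys, control = control)
  tab$density_form <- vapply(tab$model,
                             function(k) taper_model(k)$density_form,
                             character(1))
  dplyr::relocate(tab, "density_form", .after = "model")
}

#' Validate fitted taper models on held-out trees
#'
#' Computes held-out goodness-of-fit (Bias, MAB, MPB, R2, adjusted R2)
#' for a set of fitted models on a validation dataset, plus
#' relative-height-class error summaries per fit. Any tree present in a
#' fit's training data must be absent from the validation data; overlap
#' aborts the run (leakage guard).
#'
#' @param fits Named list of fitted objects (`taper_nls`, `taper_nlme`,
#'   `taper_rq`); names label the output rows.
#' @param validation Held-out [taper_data].
#' @param nlme_mode Prediction mode for mixed fits: `"population"`
#'   (default; validation trees carry no calibration measurements in the
#'   standard protocol) or `"calibrated"`.
#' @return A list with `metrics` (tibble: one row per fit) and
#'   `by_height_class` (tibble: per fit x relative-height bin).
#' @export
run_validation <- function(fits, validation,
                           nlme_mode = c("population", "calibrated")) {
  nlme_mode <- match.arg(nlme_mode)
  validation <- taper_data(validation)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("fit", seq_along(fits))
  }
  val_keys <- unique(tree_key(validation))
  rows <- list(); hc <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (is.null(f)) abort(paste0("missing fit: ", nm),
                          class = "stemtaper_domain_error")
    if (!is.null(f$data)) {
      overlap <- intersect(unique(tree_key(f$data)), val_keys)
      if (length(overlap) > 0) {
        abort(sprintf(
          "leakage: %d validation tree(s) appear in the training data of '%s'",
          length(overlap), nm),
          class = "stemtaper_leakage_error")
      }
    }
    pred <- if (inherits(f, "taper_nlme")) {
      predict(f, validation, mode = nlme_mode)
    } else {
      predict(f, validation)
    }
    lam <- f$spec$n_params + 1
    st <- fit_statistics(validation$d_cm, pred, lambda = lam)
    rows[[nm]] <- dplyr::bind_cols(
      tibble::tibble(fit = nm, model = f$model),
      st[c("n", "Bias", "MAB", "MPB", "R2", "R2_adj")])
    hc[[nm]] <- dplyr::bind_cols(
      tibble::tibble(fit = nm),
      error_by_height_class(validation, pred))
  }
  list(metrics = dplyr::bind_rows(rows),
       by_height_class = dplyr::bind_rows(hc))
}

#' Run the full taper-modelling workflow
#'
#' End-to-end orchestration: tree-level fitting/validation split, base
#' model comparison, density-form comparison, random-effect placement
#' search on the winning density form, quantile sweep, and held-out
#' validation of the four estimation variants (base NLS, density NLS,
#' mixed model, median regression). All stochastic steps derive from
#' `seed`, so the complete run is reproducible.
#'
#' @param data A [taper_data] tibble.
#' @param fraction Validation fraction for the tree-level split.
#' @param seed Seed for the split.
#' @param placements Random-effect placements searched (default: the
#'   full 55-candidate set; pass a subset to bound runtime).
#' @param taus Quantile grid for the sweep.
#' @param nlme_control,nls_control,rq_control Engine controls.
#' @param verbose Progress messages.
#' @return A list: `split`, `base_comparison`, `density_comparison`,
#'   `placement_search`, `nlme_fit`, `quantile_sweep`, `validation`,
#'   each as documented in the respective function.
#' @export
run_taper_pipeline <- function(data, fraction = 0.25, seed = 1,
                               placements = NULL,
                               taus = seq(0.1, 0.9, by = 0.1),
                               nlme_control = list(),
                               nls_control = list(),
                               rq_control = list(),
                               verbose = FALSE) {
  data <- taper_data(data)
  say <- function(...) if (verbose) message(...)
  split <- split_fit_validation(data, fraction = fraction, seed = seed)
  fit_dat <- split$fitting

  say("Base model comparison (NLS) ...")
  base_tab <- run_base_comparison(fit_dat, control = nls_control)
  base_key <- base_tab$model[base_tab$best][1]

  say("Density-form comparison ...")
  dens_tab <- run_density_comparison(fit_dat, control = nls_control)
  dens_key <- dens_tab$model[dens_tab$best][1]

  nls_base <- fit_taper_nls(fit_dat, base_key, control = nls_control)
  nls_dens <- fit_taper_nls(fit_dat, dens_key, control = nls_control)

  say("Random-effect placement search ...")
  search <- rank_placements(fit_dat, dens_key, placements = placements,
                            start = unname(nls_dens$estimates),
                            control = nlme_control, verbose = verbose)
  best_idx <- search$indices[search$best][[1]]
  nlme_fit <- fit_taper_nlme(fit_dat, dens_key, random = best_idx,
                             start = unname(nls_dens$estimates),
                             control = nlme_control)

  say("Quantile sweep ...")
  sweep <- quantile_sweep(fit_dat, dens_key, taus = taus,
                          start = unname(nls_dens$estimates),
                          control = rq_control)
  i_med <- which.min(abs(sweep$taus - 0.5))
  rq_med <- sweep$fits[[i_med]]
  if (is.null(rq_med)) {
    rq_med <- fit_taper_quantile(fit_dat, dens_key, tau = 0.5,
                                 start = unname(nls_dens$estimates),
                                 control = rq_control)
  }

  say("Validation ...")
  validation <- run_validation(
    list(nls_base = nls_base, nls_density = nls_dens,
         nlme = nlme_fit, rq_median = rq_med),
    split$validation)

  list(split = split, base_comparison = base_tab,
       density_comparison = dens_tab, placement_search = search,
       nlme_fit = nlme_fit, quantile_sweep = sweep,
       validation = validation)
}
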