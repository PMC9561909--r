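# Synthetic stem-analysis data generator.
#
# Emulates a destructively sampled plantation design: plots with a
# stand-density gradient, a fixed number of sample trees per plot, and
# diameters measured at fixed relative heights. Section diameters are
# generated from the density-augmented Kozak (2004) model with tree-level
# random effects on selected coefficients and Gaussian section noise.

# DBH is drawn from a normal truncated to the observed range; the
# pre-truncation moments below were calibrated once (offline,
# root-finding on the truncated-normal moment equations) so that the
# *truncated* distribution has mean 21.0 cm and SD 3.4 cm.
.DBH_CAL <- c(mu = 20.02656, sd = 4.894809)
# Height from a Chapman-Richards-style curve H = 1.3 + a (1 - e^{-k D})^c
# with multiplicative lognormal noise; constants calibrated once so the H
# marginal approximates mean 17.2 m, SD 2.5 m over the DBH distribution.
.HD_CAL <- c(a = 19.6512, k = 0.09, c = 1.234934, tau = 0.140955)

#' Default simulation design
#'
#' Returns the default configuration of [simulate_taper_data()]: the
#' sampled-plantation study design (132 plots, 3 destructively sampled
#' trees per plot, diameters at 11 relative heights between 5% and 90% of
#' total height), generating coefficients equal to the reference fit of
#' the density-augmented Kozak (2004) model with a `1/Sd` density term,
#' tree-level random effects on coefficients b6 and b8, and residual SD
#' `sqrt(0.5791)` cm.
#'
#' The random-effect SDs (0.02 on b6, 0.002 on b8, uncorrelated) are set
#' at roughly 4% and 20% of the respective coefficient magnitudes —
#' scales at which between-tree profile variation is visible but does not
#' overwhelm section noise. Covariate ranges reproduce the observed
#' plantation ranges (DBH 15.1–28.8 cm, H 10.4–22.8 m, Sd 90–2580
#' trees/ha, BA 10.6–67.7 m2/ha, Cd 0.2–0.9, age 18–59 yr).
#'
#' @return A named list of defaults, suitable for modifying and passing
#'   as arguments to [simulate_taper_data()].
#' @export
simulation_defaults <- function() {
  list(
    n_plots = 132L,
    trees_per_plot = 3L,
    rel_heights = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50,
                    0.60, 0.70, 0.80, 0.90),
    truth = taper_model("kozak2004_inv_Sd")$ref_params,
    model = "kozak2004_inv_Sd",
    random = c(6L, 8L),
    re_sd = c(0.02, 0.002),
    re_corr = 0,
    sigma = sqrt(0.5791),
    dbh_range = c(15.1, 28.8),
    h_range = c(10.4, 22.8),
    sd_range = c(90, 2580),
    ba_range = c(10.6, 67.7),
    cd_range = c(0.2, 0.9),
    age_range = c(18, 59),
    include_dbh_section = FALSE)
}

#' Simulate a stem-analysis dataset
#'
#' Generates a complete stem-analysis dataset with known truth, for
#' testing estimators and pipelines. Per plot, stand density Sd is drawn
#' uniformly over `sd_range`; basal area and canopy density are monotone
#' noisy functions of Sd mapped into their ranges. Per tree, DBH is drawn
#' from a truncated normal whose truncated moments match the design
#' marginals (mean 21.0, SD 3.4), and height from a Chapman-Richards-type
#' height-diameter curve with multiplicative lognormal noise, clamped to
#' `h_range`. Section diameters at the configured relative heights are
#'
#' \deqn{d = f(D, H, h; \beta + Z u_j) + \varepsilon,\quad
#'       u_j \sim N(0, \Sigma),\ \varepsilon \sim N(0, \sigma^2),}
#'
#' where `f` is the configured taper model, `u_j` perturbs the
#' coefficients listed in `random`, and negative draws are truncated at
#' zero (rare at the default noise scale; near the tip only).
#'
#' @param n_plots,trees_per_plot Design size (defaults 132 and 3).
#' @param rel_heights Relative section heights in (0, 1); default the
#'   11-height measurement protocol (5%–90% of H).
#' @param truth Generating coefficient vector for `model`.
#' @param model Registry key of the generating taper model.
#' @param random Integer indices of coefficients receiving tree-level
#'   random effects (may be `integer(0)` for none).
#' @param re_sd Random-effect SDs, one per entry of `random`.
#' @param re_corr Correlation between the two random effects (ignored for
#'   fewer than two).
#' @param sigma Residual SD of section diameters, cm.
#' @param dbh_range,h_range,sd_range,ba_range,cd_range,age_range Covariate
#'   ranges.
#' @param include_dbh_section Also emit a breast-height section row at
#'   h = 1.3 m (off by default; the measurement protocol lists only
#'   relative heights).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A list with elements:
#'   \describe{
#'     \item{data}{a [taper_data] tibble
#'       (`n_plots * trees_per_plot * length(rel_heights)` rows).}
#'     \item{truth}{a list carrying the generating vector (`params`),
#'       `sigma`, `random`, the per-tree random-effect draws (`effects`, a
#'       tibble), and the full configuration echo (`config`).}
#'   }
#' @examples
#' sim <- simulate_taper_data(n_plots = 3, seed = 42)
#' dplyr::count(sim$data, plot_id)
#' @export
simulate_taper_data <- function(n_plots = 132L, trees_per_plot = 3L,
                                rel_heights = c(0.05, 0.10, 0.15, 0.20,
                                                0.30, 0.40, 0.50, 0.60,
                                                0.70, 0.80, 0.90),
                                truth = NULL, model = "kozak2004_inv_Sd",
                                random = c(6L, 8L),
                                re_sd = c(0.02, 0.002), re_corr = 0,
                                sigma = sqrt(0.5791),
                                dbh_range = c(15.1, 28.8),
                                h_range = c(10.4, 22.8),
                                sd_range = c(90, 2580),
                                ba_range = c(10.6, 67.7),
                                cd_range = c(0.2, 0.9),
                                age_range = c(18, 59),
                                include_dbh_section = FALSE,
                                seed = 1L) {
  m <- taper_model(model)
  if (is.null(truth)) truth <- m$ref_params
  if (length(truth) != m$n_params) {
    abort("truth length does not match the model's parameter count",
          class = "stemtaper_config_error")
  }
  if (!all(diff(rel_heights) > 0) || any(rel_heights <= 0) ||
      any(rel_heights >= 1)) {
    abort("rel_heights must be strictly increasing in (0, 1)",
          class = "stemtaper_config_error")
  }
  random <- as.integer(random)
  if (length(random) != length(re_sd) || any(re_sd < 0) ||
      abs(re_corr) >= 1) {
    abort("invalid random-effect configuration",
          class = "stemtaper_config_error")
  }
  if (length(random) > 0 &&
      (any(random < 1) || any(random > m$n_params))) {
    abort("random-effect indices outside the parameter vector",
          class = "stemtaper_config_error")
  }
  for (rg in list(dbh_range, h_range, sd_range, ba_range, cd_range,
                  age_range)) {
    if (length(rg) != 2 || rg[1] >= rg[2]) {
      abort("covariate ranges must be (min, max) with min < max",
            class = "stemtaper_config_error")
    }
  }
  if (sigma < 0 || n_plots < 1 || trees_per_plot < 1) {
    abort("invalid design configuration", class = "stemtaper_config_error")
  }

  config <- list(n_plots = n_plots, trees_per_plot = trees_per_plot,
                 rel_heights = rel_heights, truth = truth, model = m$key,
                 random = random, re_sd = re_sd, re_corr = re_corr,
                 sigma = sigma, dbh_range = dbh_range, h_range = h_range,
                 sd_range = sd_range, ba_range = ba_range,
                 cd_range = cd_range, age_range = age_range,
                 include_dbh_section = include_dbh_section, seed = seed)

  with_local_seed(seed, {
    n_trees <- n_plots * trees_per_plot

    # plot covariates: Sd uniform; BA, Cd monotone noisy in Sd
    Sd <- runif(n_plots, sd_range[1], sd_range[2])
    frac <- (Sd - sd_range[1]) / diff(sd_range)
    BA <- ba_range[1] + diff(ba_range) * frac * exp(rnorm(n_plots, 0, 0.15))
    BA <- pmin(pmax(BA, ba_range[1]), ba_range[2])
    Cd <- cd_range[1] + diff(cd_range) * sqrt(frac) +
      rnorm(n_plots, 0, 0.05)
    Cd <- pmin(pmax(Cd, cd_range[1]), cd_range[2])
    age <- round(runif(n_plots, age_range[1], age_range[2]))

    # tree covariates
    D <- rtruncnorm(n_trees, .DBH_CAL["mu"], .DBH_CAL["sd"],
                    dbh_range[1], dbh_range[2])
    eps_h <- rnorm(n_trees, 0, .HD_CAL["tau"]) - .HD_CAL["tau"]^2 / 2
    H <- 1.3 + .HD_CAL["a"] * (1 - exp(-.HD_CAL["k"] * D))^.HD_CAL["c"] *
      exp(eps_h)
    H <- pmin(pmax(H, h_range[1]), h_range[2])

    # tree random effects
    q <- length(random)
    U <- matrix(0, n_trees, max(q, 1))
    if (q == 1) {
      U <- matrix(rnorm(n_trees, 0, re_sd), ncol = 1)
    } else if (q == 2) {
      z1 <- rnorm(n_trees); z2 <- rnorm(n_trees)
      U <- cbind(re_sd[1] * z1,
                 re_sd[2] * (re_corr * z1 + sqrt(1 - re_corr^2) * z2))
    }

    plot_ids <- sprintf("p%03d", seq_len(n_plots))
    trees <- tibble::tibble(
      plot_id = rep(plot_ids, each = trees_per_plot),
      tree_id = rep(sprintf("t%d", seq_len(trees_per_plot)), n_plots),
      D_cm = D, H_m = H,
      Sd_trees_ha = rep(Sd, each = trees_per_plot),
      BA_m2_ha = rep(BA, each = trees_per_plot),
      Cd = rep(Cd, each = trees_per_plot),
      age_yr = rep(age, each = trees_per_plot))

    heights_of <- function(Hi) {
      hh <- rel_heights * Hi
      if (include_dbh_section) sort(unique(c(hh, 1.3))) else hh
    }

    rows <- vector("list", n_trees)
    eff <- if (q > 0) U[, seq_len(q), drop = FALSE] else
      matrix(0, n_trees, 0)
    for (i in seq_len(n_trees)) {
      bi <- truth
      if (q > 0) bi[random] <- bi[random] + eff[i, ]
      hh <- heights_of(trees$H_m[i])
      mu <- m$fn(unname(bi), D = trees$D_cm[i], H = trees$H_m[i], h = hh,
                 Sd = trees$Sd_trees_ha[i], BA = trees$BA_m2_ha[i],
                 Cd = trees$Cd[i])
      d <- pmax(mu + rnorm(length(hh), 0, sigma), 0)
      rows[[i]] <- tibble::tibble(
        plot_id = trees$plot_id[i], tree_id = trees$tree_id[i],
        D_cm = trees$D_cm[i], H_m = trees$H_m[i], h_m = hh, d_cm = d,
        Sd_trees_ha = trees$Sd_trees_ha[i], BA_m2_ha = trees$BA_m2_ha[i],
        Cd = trees$Cd[i], age_yr = trees$age_yr[i])
    }
    data <- taper_data(dplyr::bind_rows(rows))

    effects <- tibble::tibble(plot_id = trees$plot_id,
                              tree_id = trees$tree_id)
    if (q > 0) {
      for (j in seq_len(q)) {
        effects[[paste0("u_", m$param_names[random[j]])]] <- eff[, j]
      }
    }
    list(data = data,
         truth = list(params = truth, sigma = sigma, random = random,
                      effects = effects, config = config))
  })
}

# inverse-CDF truncated normal draw (no extra dependency needed)
rtruncnorm <- function(n, mu, sd, lo, hi) {
  plo <- pnorm((lo - mu) / sd)
  phi <- pnorm((hi - mu) / sd)
  qnorm(runif(n, plo, phi)) * sd + mu
}

#' Simulate a single tree profile
#'
#' Single-tree kernel of [simulate_taper_data()], exposed for targeted
#' tests: generates one tree's sections at given heights from a taper
#' model with optional coefficient perturbations and Gaussian noise.
#'
#' @param D,H,Sd,BA,Cd Tree and stand covariates.
#' @param truth Generating coefficient vector.
#' @param model Registry key (default the density-augmented Kozak 2004).
#' @param random,effects Indices of perturbed coefficients and the
#'   per-coefficient perturbations to add.
#' @param sigma Residual SD, cm.
#' @param heights Absolute section heights, m; all must be `< H`.
#' @return A [taper_data] tibble of one tree.
#' @export
simulate_profile <- function(D, H, Sd, truth = NULL,
                             model = "kozak2004_inv_Sd",
                             random = integer(), effects = numeric(),
                             sigma = 0,
                             heights = c(0.05, 0.10, 0.15, 0.20, 0.30,
                                         0.40, 0.50, 0.60, 0.70, 0.80,
                                         0.90) * H,
                             BA = NA_real_, Cd = NA_real_) {
  m <- taper_model(model)
  if (is.null(truth)) truth <- m$ref_params
  if (any(heights >= H)) {
    abort("all section heights must be below H",
          class = "stemtaper_domain_error")
  }
  b <- truth
  if (length(random) > 0) b[random] <- b[random] + effects
  mu <- m$fn(unname(b), D = D, H = H, h = heights, Sd = Sd, BA = BA,
             Cd = Cd)
  d <- pmax(mu + rnorm(length(heights), 0, sigma), 0)
  taper_data(tibble::tibble(
    plot_id = "p1", tree_id = "t1", D_cm = D, H_m = H, h_m = heights,
    d_cm = d, Sd_trees_ha = Sd, BA_m2_ha = BA, Cd = Cd,
    age_yr = NA_real_))
}

#' Write a simulated dataset with its truth sidecar
#'
#' Writes the dataset CSV (interchange format) plus a plain-text key-value
#' sidecar `<basename>_truth.txt` recording the seed, generating
#' coefficients, noise scale and per-tree random-effect draws, so a
#' simulation written to disk remains usable for parameter-recovery
#' checks.
#'
#' @param sim A list as returned by [simulate_taper_data()].
#' @param path Output CSV path; the sidecar is derived from it.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_simulation <- function(sim, path) {
  write_stem_csv(sim$data, path)
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, "_truth.txt")
  tr <- sim$truth
  lines <- c(
    paste0("model: ", tr$config$model),
    paste0("seed: ", tr$config$seed),
    paste0("sigma: ", format(tr$sigma, digits = 17)),
    paste0("random: ", paste(tr$random, collapse = ",")),
    paste0("params: ", paste(format(unname(tr$params), digits = 17),
                             collapse = ",")))
  eff_cols <- setdiff(names(tr$effects), c("plot_id", "tree_id"))
  eff_lines <- vapply(seq_len(nrow(tr$effects)), function(i) {
    paste0("effect ", tr$effects$plot_id[i], "/", tr$effects$tree_id[i],
           ": ", paste(format(unlist(tr$effects[i, eff_cols]),
                              digits = 17), collapse = ","))
  }, character(1))
  writeLines(c(lines, eff_lines), side)
  invisible(c(path, side))
}
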