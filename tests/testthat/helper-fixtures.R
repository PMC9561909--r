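# Fixtures are built in code, never stored on disk.

# the eleven-relative-height measurement protocol
protocol_heights <- c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50,
                      0.60, 0.70, 0.80, 0.90)

# one hand-written tree close to the design means
one_tree <- function(D = 21, H = 17.2, Sd = 787, plot = "p1", tree = "t1") {
  h <- protocol_heights * H
  taper_data(tibble::tibble(
    plot_id = plot, tree_id = tree, D_cm = D, H_m = H, h_m = h,
    d_cm = pmax(eval_kozak2004(kozak_ref(), D, H, h, Sd = Sd), 0),
    Sd_trees_ha = Sd, BA_m2_ha = 25.3, Cd = 0.7, age_yr = 36))
}

# reference coefficients of the density-augmented model (inv_Sd form)
kozak_ref <- function() unname(taper_model("kozak2004_inv_Sd")$ref_params)

# a single-coefficient "location" model: d = b1 everywhere; used to test
# the estimators against closed-form location-fit oracles
stub_location_model <- function() {
  structure(list(
    key = "stub_location", label = "intercept-only test stub",
    param_names = "b1", n_params = 1L,
    fn = function(b, D, H, h, ...) b[[1]] + 0 * h,
    formula = "d = b1", ref_params = c(b1 = 1), tip_zero = FALSE,
    density_form = "none", required_covariates = character(),
    transcription = "canonical"), class = "taper_model")
}

# dataset whose d_cm values are an arbitrary numeric vector (one tree)
location_data <- function(values) {
  n <- length(values)
  taper_data(tibble::tibble(
    plot_id = "p1", tree_id = "t1", D_cm = 20, H_m = n + 2,
    h_m = seq_len(n), d_cm = values, Sd_trees_ha = 500,
    BA_m2_ha = NA_real_, Cd = NA_real_, age_yr = NA_real_))
}

# closed-form marginal log-likelihood of a linear mixed model
# y_j ~ N(X_j beta, sigma2 I + Z_j D Z_j'), summed over trees
lmm_loglik <- function(y, X, Z, group, beta, Dmat, sigma2) {
  total <- 0
  for (j in unique(group)) {
    i <- group == j
    Vj <- diag(sigma2, sum(i)) +
      Z[i, , drop = FALSE] %*% Dmat %*% t(Z[i, , drop = FALSE])
    r <- y[i] - X[i, , drop = FALSE] %*% beta
    total <- total - 0.5 * (sum(i) * log(2 * pi) +
                              determinant(Vj)$modulus[1] +
                              drop(t(r) %*% solve(Vj) %*% r))
  }
  total
}
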