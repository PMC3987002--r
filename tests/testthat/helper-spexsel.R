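# shared helpers for the test suite

# independent haversine oracle for great-circle distances
haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371.0) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# modest MCMC settings for unit tests (acceptance tests set their own)
quick_mcmc <- list(n_iter = 2000, burnin = 800, thin = 2, chains = 1)

quick_fit <- function(y, terms, seed = 1, ...) {
  fit_ssvs_logistic(y, terms, n_iter = quick_mcmc$n_iter,
                    burnin = quick_mcmc$burnin, thin = quick_mcmc$thin,
                    chains = quick_mcmc$chains, seed = seed, ...)
}

# minimal hand-built ssvs_fit for exercising summary/classification logic
fake_ssvs_fit <- function(incl_probs, coef_mean = 2, coef_sd = 1,
                          n_draws = 10000, v0 = 0.00025) {
  nms <- names(incl_probs)
  eta <- sapply(incl_probs, function(p) {
    k <- round(p * n_draws)
    c(rep(1, k), rep(v0, n_draws - k))
  })
  colnames(eta) <- nms
  set.seed(99)
  beta <- cbind("(Intercept)" = rnorm(n_draws),
                sapply(nms, function(x) rnorm(n_draws, coef_mean, coef_sd)))
  structure(list(
    draws = list(beta = beta, eta = eta,
                 tau2 = matrix(1, n_draws, length(nms),
                               dimnames = list(NULL, nms)),
                 w = rep(0.5, n_draws), chain = rep(1L, n_draws)),
    blocks = as.list(1L + seq_along(nms)),
    block_names = nms, eta_names = nms,
    col_names = colnames(beta), v0 = v0,
    mcmc = list(n_recorded = n_draws)), class = "ssvs_fit")
}

# site-measurement table on arbitrary coordinates
make_measurements <- function(lon, lat, concentration, chemical = "Pb",
                              medium = "strip") {
  data.frame(site_id = sprintf("s%02d", seq_along(lon)), lon = lon,
             lat = lat, medium = medium, chemical = chemical,
             concentration = concentration)
}
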