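# Bayesian Kriging of strip soil metals and the two-stage
# measurement-error health model.
#
# Stage 1 fits a Gaussian process with exponential covariance
#   Cov(z_s, z_t) = sill * exp(-d_st / range) + nugget * 1{s = t}
# to log-concentrations at the dense strip sites (posterior over mean,
# sill, range, nugget by Metropolis-within-Gibbs) and interpolates to
# participant addresses.  Stage 2 feeds the predictive means into the
# NMIG spike-and-slab logistic model and carries the predictive
# uncertainty as an additive measurement-error term with known variance.

exp_cov <- function(D, sill, range_km, nugget) {
  C <- sill * exp(-D / range_km)
  diag(C) <- diag(C) + nugget
  C
}

km_distance_matrix <- function(lon1, lat1, lon2 = lon1, lat2 = lat1) {
  outer(seq_along(lon1), seq_along(lon2), function(i, j)
    great_circle_distance(lon1[i], lat1[i], lon2[j], lat2[j]))
}

#' Priors for Bayesian Kriging
#'
#' Weakly informative priors on the Gaussian-process hyperparameters:
#' Gaussian on the mean and independent log-normals on sill, range and
#' nugget.  Location defaults are set from the data inside
#' [fit_kriging()] (empirical mean/variance and median inter-site
#' distance) with wide spreads, so they scale the problem without
#' constraining it.
#'
#' @param mu_sd prior SD multiplier on the mean (times the data SD).
#' @param log_sd prior SD of the log-normal priors on sill, range, nugget.
#' @return list of class `kriging_priors`.
#' @export
kriging_priors <- function(mu_sd = 10, log_sd = 1.5) {
  structure(list(mu_sd = mu_sd, log_sd = log_sd), class = "kriging_priors")
}

#' Fit a Bayesian Kriging model to one chemical
#'
#' Posterior over (mean, sill, range, nugget) of an exponential-covariance
#' Gaussian process on log-concentrations at the measurement sites.  The
#' mean is updated by its conjugate Gaussian conditional; the covariance
#' parameters by random-walk Metropolis on the log scale.  Reproducible
#' from the seed.
#'
#' @param measurements site-measurement data frame (site_id, lon, lat,
#'   chemical, concentration) for a single chemical, >= 5 sites.
#' @param priors a [kriging_priors()] object.
#' @param n_iter,burnin,thin MCMC settings (defaults 4000 / 1500 / 5).
#' @param seed integer seed.
#' @param proposal_sd random-walk proposal SD on log(sill), log(range),
#'   log(nugget).
#' @param fixed optional named list fixing any of mu, sill, range_km,
#'   nugget (fixed parameters are not sampled; fixing all four skips the
#'   MCMC entirely, giving a plug-in model).
#' @param log_transform model log(concentration) (default TRUE).
#' @return object of class `kriging_model` with posterior `draws`
#'   (data frame: mu, sill, range_km, nugget), the training coordinates
#'   and (transformed) values, and acceptance rates.
#' @export
fit_kriging <- function(measurements, priors = kriging_priors(),
                        n_iter = 4000, burnin = 1500, thin = 5,
                        seed = 1, proposal_sd = 0.35,
                        fixed = list(), log_transform = TRUE) {
  chem <- unique(measurements$chemical)
  if (length(chem) > 1)
    stop("fit_kriging expects a single chemical, got: ",
         paste(chem, collapse = ", "), call. = FALSE)
  n <- nrow(measurements)
  all_fixed <- all(c("mu", "sill", "range_km", "nugget") %in% names(fixed))
  if (n < 5 && !all_fixed) stop("need at least 5 sites", call. = FALSE)
  z <- if (log_transform) log(measurements$concentration)
       else measurements$concentration
  if (sd(z) == 0 && !all_fixed)
    stop("constant field: no spatial signal to krige; ",
         "consider a nugget-only (pure noise) model", call. = FALSE)
  D <- km_distance_matrix(measurements$lon, measurements$lat)

  make_model <- function(draws, acc = NULL) {
    structure(list(draws = draws, lon = measurements$lon,
                   lat = measurements$lat, z = z, D = D,
                   chemical = if (length(chem)) chem else NA_character_,
                   log_transform = log_transform, acceptance = acc),
              class = "kriging_model")
  }
  if (all_fixed) {
    return(make_model(data.frame(mu = fixed$mu, sill = fixed$sill,
                                 range_km = fixed$range_km,
                                 nugget = fixed$nugget)))
  }

  set.seed(seed %% .Machine$integer.max)
  # data-scaled prior locations
  m0 <- mean(z); s0 <- priors$mu_sd * max(sd(z), 1e-6)
  l_sill0 <- log(max(var(z), 1e-6))
  l_range0 <- log(max(median(D[upper.tri(D)]) / 2, 1e-3))
  l_nug0 <- log(max(var(z) / 10, 1e-8))
  lsd <- priors$log_sd

  chol_or_null <- function(C) tryCatch(chol(C), error = function(e) NULL)
  loglik <- function(R, mu) {
    if (is.null(R)) return(-Inf)
    r <- z - mu
    u <- forwardsolve(t(R), r)
    -sum(log(diag(R))) - 0.5 * sum(u^2)
  }

  mu <- if (!is.null(fixed$mu)) fixed$mu else m0
  th <- c(sill = if (!is.null(fixed$sill)) log(fixed$sill) else l_sill0,
          range_km = if (!is.null(fixed$range_km)) log(fixed$range_km)
                     else l_range0,
          nugget = if (!is.null(fixed$nugget)) {
            if (fixed$nugget <= 0) -Inf else log(fixed$nugget)
          } else l_nug0)
  par_free <- setdiff(c("sill", "range_km", "nugget"), names(fixed))
  prior_loc <- c(sill = l_sill0, range_km = l_range0, nugget = l_nug0)
  cov_of <- function(th) exp_cov(D, exp(th["sill"]), exp(th["range_km"]),
                                 if (is.finite(th["nugget"]))
                                   exp(th["nugget"]) else 0)
  R <- chol_or_null(cov_of(th))
  if (is.null(R))
    stop("covariance matrix numerically singular at the initial state ",
         "(duplicated sites with nugget fixed at 0?)", call. = FALSE)
  ll <- loglik(R, mu)
  lprior <- function(th) sum(dnorm(th[par_free], prior_loc[par_free],
                                   lsd, log = TRUE))
  lp <- lprior(th)

  n_rec <- floor((n_iter - burnin) / thin)
  draws <- data.frame(mu = numeric(n_rec), sill = numeric(n_rec),
                      range_km = numeric(n_rec), nugget = numeric(n_rec))
  acc <- setNames(numeric(length(par_free)), par_free)
  ones <- rep(1, n)
  for (it in seq_len(n_iter)) {
    # conjugate Gaussian update of the mean
    if (is.null(fixed$mu)) {
      u1 <- forwardsolve(t(R), ones); uz <- forwardsolve(t(R), z)
      prec <- sum(u1^2) + 1 / s0^2
      mmean <- (sum(u1 * uz) + m0 / s0^2) / prec
      mu <- rnorm(1, mmean, 1 / sqrt(prec))
      ll <- loglik(R, mu)
    }
    # random-walk Metropolis on the log covariance parameters
    for (pn in par_free) {
      th_p <- th
      th_p[pn] <- th[pn] + rnorm(1, 0, proposal_sd)
      R_p <- chol_or_null(cov_of(th_p))
      ll_p <- loglik(R_p, mu)
      lp_p <- lprior(th_p)
      if (is.finite(ll_p) &&
          log(runif(1)) < (ll_p + lp_p) - (ll + lp)) {
        th <- th_p; R <- R_p; ll <- ll_p; lp <- lp_p
        acc[pn] <- acc[pn] + 1
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      r <- (it - burnin) %/% thin
      draws$mu[r] <- mu
      draws$sill[r] <- exp(th["sill"])
      draws$range_km[r] <- exp(th["range_km"])
      draws$nugget[r] <- if (is.finite(th["nugget"])) exp(th["nugget"]) else 0
    }
  }
  make_model(draws, acc = acc / n_iter)
}

#' @export
print.kriging_model <- function(x, ...) {
  cat("Bayesian Kriging model",
      if (!is.na(x$chemical)) paste0("(", x$chemical, ")"), ":",
      length(x$z), "training sites,", nrow(x$draws), "posterior draws\n")
  qs <- apply(x$draws, 2, quantile, c(0.05, 0.5, 0.95))
  print(round(qs, 4))
  invisible(x)
}

#' Posterior-predictive interpolation at target addresses
#'
#' For each (thinned) posterior hyperparameter draw, computes the
#' Gaussian-process conditional mean and variance at every target and
#' marginalizes over the draws (law of total variance), giving a
#' predictive mean and standard deviation per address on the model
#' (log-concentration) scale; `conc_mean` back-transforms the mean to the
#' concentration scale.
#'
#' @param model a [fit_kriging()] model.
#' @param targets data frame with columns lon, lat and an id column
#'   (`participant_id` or `site_id`).
#' @param max_draws cap on the number of posterior draws used.
#' @return data frame of class `kriging_prediction`: id, chemical, lon,
#'   lat, mean, sd (model scale), conc_mean.
#' @export
krige_predict <- function(model, targets, max_draws = 200) {
  stopifnot(inherits(model, "kriging_model"))
  nd <- nrow(model$draws)
  use <- if (nd > max_draws)
    round(seq(1, nd, length.out = max_draws)) else seq_len(nd)
  n <- length(model$z); m <- nrow(targets)
  Dt <- outer(seq_len(m), seq_len(n), function(i, j)
    great_circle_distance(targets$lon[i], targets$lat[i],
                          model$lon[j], model$lat[j]))
  means <- matrix(NA_real_, length(use), m)
  vars <- matrix(NA_real_, length(use), m)
  for (k in seq_along(use)) {
    d <- model$draws[use[k], ]
    C <- exp_cov(model$D, d$sill, d$range_km, d$nugget)
    R <- chol(C)
    Kt <- d$sill * exp(-Dt / d$range_km)            # m x n
    # A = C^{-1} Kt'
    A <- backsolve(R, forwardsolve(t(R), t(Kt)))
    means[k, ] <- d$mu + as.vector(Kt %*%
      backsolve(R, forwardsolve(t(R), model$z - d$mu)))
    vars[k, ] <- pmax(d$sill + d$nugget - colSums(t(Kt) * A), 0)
  }
  pm <- colMeans(means)
  pv <- colMeans(vars) +
    if (length(use) > 1) apply(means, 2, var) else 0
  idcol <- intersect(c("participant_id", "site_id", "id"), names(targets))[1]
  out <- data.frame(id = targets[[idcol]], chemical = model$chemical,
                    lon = targets$lon, lat = targets$lat,
                    mean = pm, sd = sqrt(pv),
                    conc_mean = if (model$log_transform)
                      exp(pm + pv / 2) else pm)
  class(out) <- c("kriging_prediction", "data.frame")
  out
}

# local equirectangular projection to km, adequate for a ~30 km region
project_km <- function(lon, lat, lon0, lat0) {
  cbind(x = (lon - lon0) * 111.195 * cos(lat0 * pi / 180),
        y = (lat - lat0) * 111.195)
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  wx <- px - ax; wy <- py - ay
  t <- pmin(pmax((wx * vx + wy * vy) / (vx^2 + vy^2), 0), 1)
  sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
}

#' Restrict addresses to the strip buffer
#'
#' Keeps addresses lying inside the convex hull of the strip sites or
#' within `radius_km` of the hull boundary — the eligibility rule for the
#' validation analysis (interpolation error stays small up to ~1 km
#' outside the sampled strip).
#'
#' @param addresses address data frame (participant_id, address_class,
#'   lon, lat).
#' @param strip_sites strip site data frame (site_id, lon, lat).
#' @param radius_km buffer radius around the hull boundary, default 1 km.
#' @return the eligible subset of `addresses` (same columns).
#' @export
buffer_filter <- function(addresses, strip_sites, radius_km = 1.0) {
  if (nrow(strip_sites) < 1) stop("need at least one strip site",
                                  call. = FALSE)
  lon0 <- mean(strip_sites$lon); lat0 <- mean(strip_sites$lat)
  S <- project_km(strip_sites$lon, strip_sites$lat, lon0, lat0)
  A <- project_km(addresses$lon, addresses$lat, lon0, lat0)
  hull <- grDevices::chull(S)
  H <- S[hull, , drop = FALSE]
  if (nrow(H) >= 3) {
    inside <- mgcv::in.out(rbind(H, H[1, ]), A)
  } else {
    inside <- rep(FALSE, nrow(A))
  }
  nh <- nrow(H)
  nxt <- c(seq_len(nh)[-1], 1L)
  dmin <- rep(Inf, nrow(A))
  for (e in seq_len(nh)) {
    dmin <- pmin(dmin, point_segment_distance(A[, 1], A[, 2],
                                              H[e, 1], H[e, 2],
                                              H[nxt[e], 1], H[nxt[e], 2]))
  }
  addresses[inside | dmin <= radius_km, , drop = FALSE]
}

#' Two-stage measurement-error health model
#'
#' Stage-2 logistic spike-and-slab fit on Kriged exposures: predictive
#' means (log scale, standardized) enter as candidate terms alongside the
#' personal covariates, and the Kriging predictive uncertainty enters the
#' linear predictor as an additive measurement-error term
#' \eqn{\omega_{i} \sim N(0, \sum_j s_{ij}^2)} with known (plug-in)
#' variance accumulated over the modeled chemicals on the standardized
#' scale.  When every predictive sd is zero the model collapses exactly to
#' the plain spike-and-slab fit on the predictive means.
#'
#' @param y binary outcomes for the eligible participants.
#' @param kriged named list (one element per chemical) of
#'   [krige_predict()] data frames, row-aligned with `y`.
#' @param personal data frame of personal covariates for the same
#'   participants (numeric columns), or NULL.
#' @param hyper a [nmig_hyperparams()] object.
#' @param smooth_exposures if TRUE, chemicals enter as first-order
#'   random-walk smooth blocks S(x) rather than linear terms.
#' @param n_basis basis size for smooth exposure terms.
#' @param ... MCMC settings passed to [fit_ssvs_logistic()]
#'   (n_iter, burnin, thin, chains, seed, ...).
#' @return object of class `two_stage_fit`: the underlying `ssvs_fit`
#'   plus the measurement-error variances and an inclusion summary.
#' @export
two_stage_fit <- function(y, kriged, personal = NULL,
                          hyper = nmig_hyperparams(),
                          smooth_exposures = FALSE, n_basis = 6, ...) {
  n <- length(y)
  if (!length(kriged)) stop("no kriged chemicals supplied", call. = FALSE)
  if (is.null(names(kriged)))
    names(kriged) <- vapply(kriged, function(k) k$chemical[1], "")
  E <- matrix(NA_real_, n, length(kriged),
              dimnames = list(NULL, names(kriged)))
  S <- E
  for (j in seq_along(kriged)) {
    kj <- kriged[[j]]
    if (nrow(kj) != n || anyNA(kj$mean))
      stop("missing prediction for chemical '", names(kriged)[j],
           "' (participant ",
           paste(which(is.na(kj$mean)), collapse = ","), ")", call. = FALSE)
    E[, j] <- kj$mean
    S[, j] <- kj$sd
  }
  # standardize exposures; scale the sds identically
  cs <- apply(E, 2, sd)
  if (any(cs == 0)) stop("constant kriged exposure column", call. = FALSE)
  Es <- scale(E)
  Ss <- sweep(S, 2, cs, "/")
  me_var <- rowSums(Ss^2)

  terms <- list()
  for (j in seq_len(ncol(Es))) {
    terms[[length(terms) + 1L]] <- if (smooth_exposures)
      term_smooth(colnames(Es)[j], Es[, j], n_basis = n_basis)
    else term_linear(colnames(Es)[j], Es[, j])
  }
  if (!is.null(personal)) {
    for (nm in names(personal)) {
      if (sd(personal[[nm]]) > 0)
        terms[[length(terms) + 1L]] <- term_linear(nm, personal[[nm]])
    }
  }
  fit <- fit_ssvs_logistic(y, terms, hyper = hyper,
                           me_variance = me_var, ...)
  structure(list(fit = fit, me_variance = me_var,
                 exposure_means = Es, exposure_sds = Ss,
                 summary = inclusion_summary(fit)),
            class = "two_stage_fit")
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("Two-stage Kriging validation fit",
      sprintf("(mean measurement-error sd %.3f)\n",
              mean(sqrt(x$me_variance))))
  print(x$summary)
  invisible(x)
}
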