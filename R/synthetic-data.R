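# Synthetic study generator: site networks, correlated chemical surfaces,
# participants and outcomes with known truth, so every downstream stage is
# testable without confidential data.

soil_gw_chemicals <- c("mercury", "arsenic", "lead", "atrazine", "dintolu",
                       "toluene", "DDT", "acetone", "endo1", "endo2")
strip_metals <- c("As", "Ba", "Cr", "Cu", "Mn", "Pb")

# fixed per-stage seed offsets so each generator is deterministic given the
# master seed yet stages draw from distinct streams
stage_seed <- function(cfg, stage) {
  off <- c(sites_soil = 11L, sites_groundwater = 12L, sites_strip = 13L,
           surfaces_soil = 21L, surfaces_groundwater = 22L,
           surfaces_strip = 23L, addresses = 31L, truth = 41L,
           participants = 51L)
  (cfg$seed + off[[stage]]) %% .Machine$integer.max
}

#' Generate a monitoring-site network
#'
#' Regional soil and groundwater sites are sparse and irregular (uniform
#' over the region).  Strip sites form a dense, narrow, elongated band
#' (jittered regular grid across the horizontal middle of the region),
#' emulating a validation strip of ~110 closely spaced soil-metal sites.
#'
#' @param config a [sim_config()] object.
#' @param medium one of "soil", "groundwater", "strip".
#' @return data frame with columns site_id, lon, lat, medium.
#' @export
generate_sites <- function(config,
                           medium = c("soil", "groundwater", "strip")) {
  medium <- match.arg(medium)
  validate_sim_config(config)
  rb <- config$region_bounds
  n <- switch(medium, soil = config$n_soil_sites,
              groundwater = config$n_gw_sites,
              strip = config$n_strip_sites)
  set.seed(stage_seed(config, paste0("sites_", medium)))
  if (n == 0L) {
    return(data.frame(site_id = character(0), lon = numeric(0),
                      lat = numeric(0), medium = character(0)))
  }
  if (medium == "strip") {
    # narrow band: full longitude extent, ~6% of the latitude extent,
    # centred vertically; near-regular spacing with small jitter
    lat_mid <- (rb["lat_min"] + rb["lat_max"]) / 2
    band <- 0.03 * (rb["lat_max"] - rb["lat_min"])
    lon <- seq(rb["lon_min"], rb["lon_max"], length.out = n) +
      runif(n, -0.002, 0.002)
    lat <- runif(n, lat_mid - band, lat_mid + band)
    lon <- pmin(pmax(lon, rb["lon_min"]), rb["lon_max"])
  } else {
    lon <- runif(n, rb["lon_min"], rb["lon_max"])
    lat <- runif(n, rb["lat_min"], rb["lat_max"])
  }
  data.frame(site_id = sprintf("%s_%03d", substr(medium, 1, 2), seq_len(n)),
             lon = unname(lon), lat = unname(lat), medium = medium,
             stringsAsFactors = FALSE)
}

chemical_panel <- function(config, medium) {
  if (medium == "strip") strip_metals
  else soil_gw_chemicals[seq_len(min(config$n_chemicals_per_medium,
                                     length(soil_gw_chemicals)))]
}

#' Simulate correlated chemical concentration surfaces at sites
#'
#' Each chemical's log-concentration is a Gaussian process over the sites
#' with exponential covariance (sill, range, nugget from the config) and
#' an exchangeable cross-chemical correlation, so concentrations are
#' log-normal, spatially structured, and correlated across chemicals —
#' the structure the PCA and Kriging stages assume.  Duplicate site
#' coordinates receive identical spatial signal (plus independent nugget
#' noise if the nugget is positive).
#'
#' @param sites site data frame from [generate_sites()] (single medium).
#' @param config a [sim_config()] object.
#' @param log_mean mean of log-concentration (default log 10).
#' @return data frame with columns site_id, lon, lat, medium, chemical,
#'   concentration (one row per site-chemical pair).
#' @export
generate_chemical_surfaces <- function(sites, config, log_mean = log(10)) {
  validate_sim_config(config)
  if (nrow(sites) < 1L) stop("need at least one site", call. = FALSE)
  medium <- sites$medium[1]
  chems <- chemical_panel(config, medium)
  m <- length(chems)
  rho <- config$chem_cross_correlation
  if (m > 1 && (rho <= -1 / (m - 1) || rho > 1))
    stop("chem_cross_correlation = ", rho, " with ", m,
         " chemicals gives a non-positive-definite cross-chemical ",
         "covariance (need rho in (-1/(m-1), 1])", call. = FALSE)
  set.seed(stage_seed(config, paste0("surfaces_", medium)))
  n <- nrow(sites)

  # spatial signal simulated on unique coordinates and copied to
  # duplicates, so a zero nugget makes co-located values identical
  key <- paste(sites$lon, sites$lat)
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  cu <- sites[uniq, , drop = FALSE]
  nu <- nrow(cu)

  if (config$gp_sill > 0) {
    D <- outer(seq_len(nu), seq_len(nu), function(i, j)
      great_circle_distance(cu$lon[i], cu$lat[i], cu$lon[j], cu$lat[j]))
    Cs <- config$gp_sill * exp(-D / config$gp_range_km)
    Ls <- tryCatch(t(chol(Cs + diag(1e-8 * config$gp_sill, nu))),
                   error = function(e)
                     stop("spatial covariance not positive definite ",
                          "(sill = ", config$gp_sill, ", range = ",
                          config$gp_range_km, " km)", call. = FALSE))
  } else {
    Ls <- matrix(0, nu, nu)
  }
  # independent-in-chemical fields: spatial signal (copied to duplicate
  # coordinates) plus nugget noise; the cross-chemical factor is applied
  # to the sum so chem_cross_correlation is the marginal correlation of
  # the full log-surfaces
  G <- (Ls %*% matrix(rnorm(nu * m), nu, m))[idx, , drop = FALSE]
  if (config$gp_nugget > 0)
    G <- G + matrix(rnorm(n * m, sd = sqrt(config$gp_nugget)), n, m)
  if (m > 1 && rho < 1) {
    Cc <- matrix(rho, m, m); diag(Cc) <- 1
    field <- G %*% chol(Cc)
  } else if (m > 1) {                    # rho == 1: one shared field
    field <- G[, 1] %*% matrix(1, 1, m)
  } else {
    field <- G
  }

  out <- data.frame(
    site_id = rep(sites$site_id, times = m),
    lon = rep(sites$lon, times = m),
    lat = rep(sites$lat, times = m),
    medium = medium,
    chemical = rep(chems, each = n),
    concentration = exp(log_mean + as.vector(field)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate residential addresses for participants
#'
#' Base addresses are uniform over the central 70% of the region (keeping
#' most address-to-site distances within ~15 km).  The first (birth)
#' address is the base; the longest-held address jitters it by ~0.3 km and
#' the last (current) address by ~1.5 km, reflecting residential moves of
#' increasing recency without a formal mobility model.
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns participant_id, address_class, lon, lat
#'   (three rows per participant).
#' @export
generate_addresses <- function(config) {
  validate_sim_config(config)
  rb <- config$region_bounds
  set.seed(stage_seed(config, "addresses"))
  n <- config$n_participants
  shrink <- 0.70
  lon_c <- (rb["lon_min"] + rb["lon_max"]) / 2
  lat_c <- (rb["lat_min"] + rb["lat_max"]) / 2
  lon_h <- shrink * (rb["lon_max"] - rb["lon_min"]) / 2
  lat_h <- shrink * (rb["lat_max"] - rb["lat_min"]) / 2
  lon0 <- runif(n, lon_c - lon_h, lon_c + lon_h)
  lat0 <- runif(n, lat_c - lat_h, lat_c + lat_h)

  km_per_deg_lat <- 111.195
  jitter_deg <- function(lon, lat, sd_km) {
    dlat <- rnorm(n, sd = sd_km) / km_per_deg_lat
    dlon <- rnorm(n, sd = sd_km) / (km_per_deg_lat * cos(lat * pi / 180))
    cbind(lon + dlon, lat + dlat)
  }
  longest <- jitter_deg(lon0, lat0, 0.3)
  last <- jitter_deg(lon0, lat0, 1.5)
  ids <- sprintf("p%03d", seq_len(n))
  out <- rbind(
    data.frame(participant_id = ids, address_class = "first",
               lon = unname(lon0), lat = unname(lat0)),
    data.frame(participant_id = ids, address_class = "longest",
               lon = longest[, 1], lat = longest[, 2]),
    data.frame(participant_id = ids, address_class = "last",
               lon = last[, 1], lat = last[, 2]))
  rownames(out) <- NULL
  out
}

#' Known truth underlying a synthetic study
#'
#' Draws the per-participant random intercepts and records the true sparse
#' coefficient vector; downstream recovery tests compare selection output
#' against `true_included`.
#'
#' @param config a [sim_config()] object.
#' @return object of class `synthetic_truth`: list with true_beta,
#'   true_included, true_gamma, chemical_fields.
#' @export
synthetic_truth <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, "truth"))
  gamma <- rnorm(config$n_participants, 0, config$random_intercept_sd)
  structure(list(
    true_beta = config$true_beta,
    true_included = names(config$true_beta)[config$true_beta != 0],
    true_gamma = gamma,
    chemical_fields = list(sill = config$gp_sill,
                           range_km = config$gp_range_km,
                           nugget = config$gp_nugget,
                           cross_correlation = config$chem_cross_correlation)),
    class = "synthetic_truth")
}

# personal covariates emulating the study questionnaire panel
simulate_personal_covariates <- function(n) {
  data.frame(
    tTermites = rpois(n, 1.5),
    tInsects = rpois(n, 2),
    tWalls = rpois(n, 1),
    tPaint = rpois(n, 1.5),
    education = pmin(pmax(round(rnorm(n, 12, 3)), 0), 20),
    CurAge = round(runif(n, 18, 85)),
    dHeatK = rbinom(n, 1, 0.3),
    dHeatG = rbinom(n, 1, 0.2),
    Work = rbinom(n, 1, 0.5),
    Smoke = rbinom(n, 1, 0.25),
    gendernum = rbinom(n, 1, 0.15),
    Saltfin = rpois(n, 20),
    well_water = rbinom(n, 1, 0.4))
}

# intercept alpha solving mean(plogis(alpha + lp)) = target, by bisection
calibrate_intercept <- function(lp, target) {
  f <- function(a) mean(plogis(a + lp)) - target
  uniroot(f, interval = c(-40, 40), tol = 1e-10)$root
}

#' Generate participants and binary ANA outcomes
#'
#' Simulates the personal covariate panel (counts as Poisson, binaries as
#' Bernoulli, age uniform over an adult range), forms the linear predictor
#' \eqn{\alpha + z_i^T \beta + \gamma_i} on standardized covariates with
#' the truth's sparse coefficients and random intercepts, calibrates the
#' intercept \eqn{\alpha} so the mean outcome probability matches the
#' target prevalence, and draws Bernoulli outcomes.
#'
#' @param config a [sim_config()] object.
#' @param truth a [synthetic_truth()] object.
#' @param exposures exposure matrix row-aligned with participants (may be
#'   NULL when no exposure effects are in `true_beta`).
#' @return data frame with participant_id, ana, and the personal
#'   covariates; attributes `intercept` and `lin_pred`.
#' @export
generate_participants <- function(config, truth, exposures = NULL) {
  validate_sim_config(config)
  n <- config$n_participants
  set.seed(stage_seed(config, "participants"))
  pers <- simulate_personal_covariates(n)

  Z <- as.matrix(pers)
  if (!is.null(exposures)) {
    if (nrow(exposures) != n)
      stop("exposures not row-aligned with participants", call. = FALSE)
    Z <- cbind(Z, exposures)
  }
  beta <- truth$true_beta
  if (length(beta)) {
    unmatched <- setdiff(names(beta), colnames(Z))
    if (length(unmatched))
      stop("true_beta names not among available covariates: ",
           paste(unmatched, collapse = ", "), call. = FALSE)
  }
  Zs <- scale(Z)
  Zs[, attr(Zs, "scaled:scale") == 0] <- 0   # constant columns drop out
  lp <- as.vector(if (length(beta))
    Zs[, names(beta), drop = FALSE] %*% beta else rep(0, n))
  lp <- lp + truth$true_gamma
  alpha <- calibrate_intercept(lp, config$target_prevalence)
  y <- rbinom(n, 1, plogis(alpha + lp))

  out <- cbind(data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                          ana = y), pers)
  attr(out, "intercept") <- alpha
  attr(out, "lin_pred") <- alpha + lp
  out
}

#' Simulate a complete synthetic study
#'
#' Orchestrates sites, chemical surfaces, addresses, exposure matrices and
#' outcomes with one master seed: everything downstream of a fixed config
#' is bit-reproducible.
#'
#' @param config a [sim_config()] object.
#' @param address_class address class used for the exposure matrix fed to
#'   the outcome model (default "first").
#' @param power distance-weighting power for that matrix.
#' @return list of class `sim_study` with elements config, truth, sites
#'   (all media), measurements (all media), addresses, exposures,
#'   participants.
#' @export
simulate_study <- function(config, address_class = "first", power = 1) {
  validate_sim_config(config)
  media <- c("soil", "groundwater", "strip")
  sites <- do.call(rbind, lapply(media, function(mm) generate_sites(config, mm)))
  meas <- do.call(rbind, lapply(media, function(mm) {
    s <- sites[sites$medium == mm, , drop = FALSE]
    if (nrow(s) == 0L) NULL else generate_chemical_surfaces(s, config)
  }))
  if (is.null(meas) || nrow(meas) == 0L)
    stop("no site measurements generated (all site counts zero?)",
         call. = FALSE)
  addresses <- generate_addresses(config)
  truth <- synthetic_truth(config)
  exposures <- build_exposure_matrix(addresses, meas,
                                     address_class = address_class,
                                     media = c("soil", "groundwater"),
                                     p = power)
  participants <- generate_participants(config, truth, exposures)
  structure(list(config = config, truth = truth, sites = sites,
                 measurements = meas, addresses = addresses,
                 exposures = exposures, participants = participants),
            class = "sim_study")
}
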