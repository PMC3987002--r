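test_that("kriging with zero nugget interpolates training sites exactly", {
  m <- make_measurements(c(0, 0.01, 0.02, 0.03), c(0, 0.005, 0.01, 0),
                         exp(c(1, 2, 1.5, 0.5)))
  km <- fit_kriging(m, fixed = list(mu = 1, sill = 1, range_km = 5,
                                    nugget = 0))
  pr <- krige_predict(km, data.frame(id = 1:4, lon = m$lon, lat = m$lat))
  expect_equal(pr$mean, log(m$concentration), tolerance = 1e-8)
  expect_true(all(pr$sd < 1e-4))
})

test_that("far-field predictions revert to the process mean and prior sd", {
  m <- make_measurements(c(0, 0.01, 0.02), c(0, 0.005, 0.01),
                         exp(c(1, 2, 1.5)))
  km <- fit_kriging(m, fixed = list(mu = 0.7, sill = 2, range_km = 3,
                                    nugget = 0.5))
  pr <- krige_predict(km, data.frame(id = 1, lon = 90, lat = 40))
  expect_equal(pr$mean, 0.7, tolerance = 1e-6)
  expect_equal(pr$sd, sqrt(2 + 0.5), tolerance = 1e-6)
})

test_that("two-point kriging matches the closed-form GP regression oracle", {
  z <- c(0.7, -0.2); mu <- 0.1; sill <- 2; rng <- 3; nug <- 0.5
  m <- make_measurements(c(0, 0.02), c(0, 0), exp(z))
  km <- fit_kriging(m, fixed = list(mu = mu, sill = sill, range_km = rng,
                                    nugget = nug))
  tg <- data.frame(id = 1, lon = 0.011, lat = 0.004)
  pr <- krige_predict(km, tg)
  d12 <- great_circle_distance(0, 0, 0.02, 0)
  Sig <- matrix(c(sill + nug, sill * exp(-d12 / rng),
                  sill * exp(-d12 / rng), sill + nug), 2)
  kv <- sill * exp(-great_circle_distance(tg$lon, tg$lat,
                                          c(0, 0.02), c(0, 0)) / rng)
  mean_o <- mu + sum(kv * solve(Sig, z - mu))
  var_o <- sill + nug - sum(kv * solve(Sig, kv))
  expect_equal(pr$mean, mean_o, tolerance = 1e-8)
  expect_equal(pr$sd, sqrt(var_o), tolerance = 1e-8)
})

test_that("predictive sd grows with distance from the training set", {
  m <- make_measurements(c(0, 0.005, 0.01), c(0, 0, 0), exp(c(0.5, 1, 0)))
  km <- fit_kriging(m, fixed = list(mu = 0, sill = 1, range_km = 4,
                                    nugget = 0))
  tg <- data.frame(id = 1:6, lon = seq(0.012, 0.2, length.out = 6), lat = 0)
  pr <- krige_predict(km, tg)
  expect_true(all(diff(pr$sd) >= -1e-10))
})

test_that("posterior fitting is seed-reproducible and flags bad inputs", {
  cfg <- sim_config(seed = 5)
  mm <- generate_chemical_surfaces(generate_sites(cfg, "strip"), cfg)
  pb <- mm[mm$chemical == "Pb", ][1:30, ]
  f1 <- fit_kriging(pb, n_iter = 400, burnin = 100, thin = 2, seed = 2)
  f2 <- fit_kriging(pb, n_iter = 400, burnin = 100, thin = 2, seed = 2)
  expect_identical(f1$draws, f2$draws)

  const <- make_measurements(c(0, 0.01, 0.02, 0.03, 0.04), rep(0, 5),
                             rep(3, 5))
  expect_error(fit_kriging(const), "constant field")

  # duplicated site with conflicting values and a zero nugget cannot fit
  dup <- make_measurements(c(0, 0, 0.01, 0.02, 0.03), rep(0, 5),
                           exp(c(1, 2, 1.5, 0.5, 1)))
  expect_error(fit_kriging(dup, fixed = list(nugget = 0)), "singular")

  two_chem <- rbind(make_measurements(0:4 / 100, rep(0, 5), rep(1, 5), "As"),
                    make_measurements(0:4 / 100, rep(0, 5), rep(1, 5), "Ba"))
  expect_error(fit_kriging(two_chem), "single chemical")
})

test_that("posterior intervals cover generating sill and range", {
  # light calibration check (the fuller replicate study runs in the
  # acceptance suite)
  cfg <- sim_config(seed = 301, gp_sill = 1, gp_range_km = 5,
                    gp_nugget = 0.1)
  mm <- generate_chemical_surfaces(generate_sites(cfg, "strip"), cfg)
  fit <- fit_kriging(mm[mm$chemical == "Pb", ], n_iter = 2000,
                     burnin = 800, thin = 4, seed = 401)
  qs <- apply(fit$draws[, c("sill", "range_km")], 2, quantile,
              c(0.05, 0.95))
  expect_true(qs[1, "sill"] <= 1 && 1 <= qs[2, "sill"])
  expect_true(qs[1, "range_km"] <= 5 && 5 <= qs[2, "range_km"])
})

test_that("buffer filter keeps on-strip addresses and drops far ones", {
  cfg <- sim_config(seed = 6)
  strip <- generate_sites(cfg, "strip")
  near <- data.frame(participant_id = "on", address_class = "first",
                     lon = strip$lon[5], lat = strip$lat[5])
  far <- data.frame(participant_id = "far", address_class = "first",
                    lon = strip$lon[5], lat = strip$lat[5] + 0.5)
  kept <- buffer_filter(rbind(near, far), strip, 1.0)
  expect_equal(kept$participant_id, "on")
})

test_that("buffer filter agrees with a brute-force geometric oracle", {
  cfg <- sim_config(seed = 16)
  strip <- generate_sites(cfg, "strip")
  set.seed(17)
  rb <- cfg$region_bounds
  addr <- data.frame(participant_id = sprintf("p%03d", 1:150),
                     address_class = "first",
                     lon = runif(150, rb["lon_min"], rb["lon_max"]),
                     lat = runif(150, rb["lat_min"], rb["lat_max"]))
  kept <- buffer_filter(addr, strip, 1.0)

  # oracle: point-in-hull via the chull trick plus distance to densely
  # discretized hull edges
  lon0 <- mean(strip$lon); lat0 <- mean(strip$lat)
  proj <- function(lon, lat)
    cbind((lon - lon0) * 111.195 * cos(lat0 * pi / 180),
          (lat - lat0) * 111.195)
  S <- proj(strip$lon, strip$lat)
  H <- S[grDevices::chull(S), ]
  edge_pts <- do.call(rbind, lapply(seq_len(nrow(H)), function(i) {
    j <- if (i == nrow(H)) 1 else i + 1
    t <- seq(0, 1, length.out = 400)
    cbind(H[i, 1] + t * (H[j, 1] - H[i, 1]),
          H[i, 2] + t * (H[j, 2] - H[i, 2]))
  }))
  in_hull <- function(p) {
    idx <- grDevices::chull(rbind(H, p))
    !((nrow(H) + 1) %in% idx)
  }
  A <- proj(addr$lon, addr$lat)
  d_edge <- apply(A, 1, function(p)
    sqrt(min((edge_pts[, 1] - p[1])^2 + (edge_pts[, 2] - p[2])^2)))
  oracle <- vapply(seq_len(nrow(A)), function(i)
    in_hull(A[i, ]) || d_edge[i] <= 1.0, TRUE)
  # ignore addresses within 50 m of the decision boundary (discretization)
  clear <- abs(d_edge - 1.0) > 0.05
  expect_equal(addr$participant_id[oracle & clear],
               kept$participant_id[kept$participant_id %in%
                                     addr$participant_id[clear]])
})

test_that("two-stage fit collapses to the plain fit when kriging sds are 0", {
  set.seed(21)
  n <- 40
  E <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("Pb", "Cu", "Cr")))
  y <- rbinom(n, 1, plogis(1.5 * E[, 1]))
  mk <- function(sds) lapply(setNames(colnames(E), colnames(E)), function(ch)
    data.frame(id = 1:n, chemical = ch, lon = 0, lat = 0, mean = E[, ch],
               sd = sds, conc_mean = exp(E[, ch])))
  f0 <- two_stage_fit(y, mk(0), n_iter = 2000, burnin = 800, thin = 2,
                      chains = 1, seed = 9)
  Es <- scale(E)
  terms <- lapply(colnames(E), function(ch) term_linear(ch, Es[, ch]))
  fp <- fit_ssvs_logistic(y, terms, n_iter = 2000, burnin = 800, thin = 2,
                          chains = 1, seed = 9)
  expect_equal(f0$fit$draws$beta, fp$draws$beta)
  expect_equal(f0$fit$draws$eta, fp$draws$eta)
})

test_that("credible intervals widen as measurement-error sd grows", {
  set.seed(22)
  n <- 40
  E <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("Pb", "Cu")))
  y <- rbinom(n, 1, plogis(1.5 * E[, 1]))
  mk <- function(sds) lapply(setNames(colnames(E), colnames(E)), function(ch)
    data.frame(id = 1:n, chemical = ch, lon = 0, lat = 0, mean = E[, ch],
               sd = sds, conc_mean = exp(E[, ch])))
  widths <- sapply(c(0, 0.5, 1.5), function(s) {
    f <- two_stage_fit(y, mk(s), n_iter = 2500, burnin = 1000, thin = 2,
                       chains = 1, seed = 23)
    mean(apply(f$fit$draws$beta[, 2:3, drop = FALSE], 2, function(d)
      diff(quantile(d, c(0.025, 0.975)))))
  })
  expect_true(all(diff(widths) > 0))
})

test_that("missing predictions are reported by participant and chemical", {
  y <- rbinom(10, 1, 0.5)
  k <- list(Pb = data.frame(id = 1:10, chemical = "Pb", lon = 0, lat = 0,
                            mean = c(NA, rnorm(9)), sd = 0.1,
                            conc_mean = 1))
  expect_error(two_stage_fit(y, k), "Pb")
})

test_that("the true metal ranks top in the small-sample strip experiment", {
  # mirrors the validation design: ~15 participants on a 110-site strip,
  # one truly associated metal among five candidates, five seeds
  strip_recovery <- function(seed, n_part = 15, beta_true = 2.5) {
    cfg <- sim_config(seed = seed, chem_cross_correlation = 0.1)
    ss <- generate_sites(cfg, "strip")
    set.seed(seed + 900)
    idx <- sample(nrow(ss), n_part)
    addr <- data.frame(participant_id = sprintf("p%02d", 1:n_part),
                       address_class = "first",
                       lon = ss$lon[idx] + runif(n_part, -0.003, 0.003),
                       lat = ss$lat[idx] + runif(n_part, -0.003, 0.003))
    combined <- rbind(ss[, c("site_id", "lon", "lat", "medium")],
                      data.frame(site_id = addr$participant_id,
                                 lon = addr$lon, lat = addr$lat,
                                 medium = "strip"))
    meas <- generate_chemical_surfaces(combined, cfg)
    metals <- c("As", "Ba", "Cr", "Cu", "Pb")
    site_meas <- meas[meas$site_id %in% ss$site_id &
                        meas$chemical %in% metals, ]
    true_expo <- log(meas$concentration[
      meas$site_id %in% addr$participant_id & meas$chemical == "Pb"])
    set.seed(seed + 901)
    y <- rbinom(n_part, 1, plogis(beta_true * as.vector(scale(true_expo))))
    kriged <- lapply(setNames(metals, metals), function(ch) {
      km <- fit_kriging(site_meas[site_meas$chemical == ch, ],
                        n_iter = 1500, burnin = 600, thin = 4,
                        seed = seed + 7)
      krige_predict(km, addr, max_draws = 60)
    })
    f <- two_stage_fit(y, kriged, n_iter = 2500, burnin = 1000, thin = 2,
                       chains = 1, seed = seed + 13)
    setNames(f$summary$incl_mean[match(metals, f$summary$term)], metals)
  }
  R <- sapply(1:5, strip_recovery)
  means <- rowMeans(R)
  expect_equal(names(which.max(means)), "Pb")
})
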