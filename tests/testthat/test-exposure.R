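test_that("spherical law of cosines matches closed forms and haversine", {
  expect_equal(great_circle_distance(12.3, 45.6, 12.3, 45.6), 0)
  # one equatorial degree: R * pi / 180
  expect_equal(great_circle_distance(0, 0, 1, 0), 6371 * pi / 180,
               tolerance = 1e-9)
  expect_lt(abs(great_circle_distance(0, 0, 1, 0) - 111.195), 0.001)
  # antipodal: R * pi
  expect_lt(abs(great_circle_distance(0, 0, 180, 0) - 20015.087), 0.01)
  # haversine oracle on random pairs
  set.seed(1)
  lon <- runif(50, -180, 180); lat <- runif(50, -85, 85)
  lon2 <- runif(50, -180, 180); lat2 <- runif(50, -85, 85)
  expect_equal(great_circle_distance(lon, lat, lon2, lat2),
               haversine_km(lon, lat, lon2, lat2), tolerance = 1e-6)
})

test_that("distance errors on out-of-range coordinates", {
  expect_error(great_circle_distance(0, 95, 0, 0), "latitude")
  expect_error(great_circle_distance(-190, 0, 0, 0), "longitude")
})

test_that("distance satisfies symmetry and triangle inequality", {
  set.seed(42)
  for (i in 1:40) {
    lon <- runif(3, -79.9, -79.6); lat <- runif(3, 32.4, 32.9)
    dab <- great_circle_distance(lon[1], lat[1], lon[2], lat[2])
    dba <- great_circle_distance(lon[2], lat[2], lon[1], lat[1])
    dbc <- great_circle_distance(lon[2], lat[2], lon[3], lat[3])
    dac <- great_circle_distance(lon[1], lat[1], lon[3], lat[3])
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-6)
  }
})

test_that("distance_weight matches hand computations", {
  expect_equal(distance_weight(10, 2, p = 1), 5.0)
  expect_equal(distance_weight(c(4, 9), c(2, 3), p = 2), 4 / 4 + 9 / 9)
  expect_equal(distance_weight(c(0, 0, 0), c(1, 2, 3), p = 1), 0)
  # normalized variant is the inverse-distance-weighted mean
  expect_equal(distance_weight(c(4, 9), c(2, 3), p = 2, normalize = TRUE),
               (4 / 4 + 9 / 9) / (1 / 4 + 1 / 9))
  expect_error(distance_weight(numeric(0), numeric(0)), "unmeasured")
  expect_error(distance_weight(1, 1, p = 3), "must be 1 or 2")
})

test_that("distance_weight is linear in concentrations, decreasing in distance,
           and clamps near-zero distances", {
  c1 <- c(2, 5, 1); d <- c(1.5, 3, 7)
  expect_equal(distance_weight(3 * c1, d, p = 2),
               3 * distance_weight(c1, d, p = 2))
  d2 <- d; d2[2] <- d[2] + 1
  expect_lt(distance_weight(c1, d2, p = 1), distance_weight(c1, d, p = 1))
  # participant on a site: clamp keeps the exposure finite
  expect_equal(distance_weight(10, 0, p = 2), 10 / 0.1^2)
})

test_that("exposure matrix has one row per participant and respects media", {
  set.seed(3)
  sites <- make_measurements(runif(6, -79.9, -79.8), runif(6, 32.55, 32.65),
                             rlnorm(6), chemical = "mercury", medium = "soil")
  gw <- make_measurements(runif(4, -79.9, -79.8), runif(4, 32.55, 32.65),
                          rlnorm(4), chemical = "arsenic",
                          medium = "groundwater")
  meas <- rbind(sites, gw)
  addr <- data.frame(participant_id = c("a", "b"), address_class = "first",
                     lon = c(-79.85, -79.85), lat = c(32.6, 32.6))
  Xs <- build_exposure_matrix(addr, meas, "first", media = "soil")
  expect_equal(colnames(Xs), "mercuryS")
  Xj <- build_exposure_matrix(addr, meas, "first",
                              media = c("soil", "groundwater"))
  expect_setequal(colnames(Xj), c("mercuryS", "arsenicW"))
  # identical addresses give identical rows
  expect_equal(unname(Xj[1, ]), unname(Xj[2, ]))
})

test_that("moving a participant farther from all sites decreases exposures", {
  set.seed(4)
  meas <- rbind(
    make_measurements(runif(5, -79.90, -79.88), runif(5, 32.59, 32.61),
                      rlnorm(5), chemical = "lead", medium = "soil"),
    make_measurements(runif(5, -79.90, -79.88), runif(5, 32.59, 32.61),
                      rlnorm(5), chemical = "DDT", medium = "soil"))
  # sites cluster near (-79.89, 32.60); walk the address away eastwards
  lons <- seq(-79.85, -79.60, length.out = 5)
  rows <- t(sapply(lons, function(l) {
    a <- data.frame(participant_id = "a", address_class = "first",
                    lon = l, lat = 32.60)
    build_exposure_matrix(a, meas, "first", media = "soil")[1, ]
  }))
  expect_true(all(diff(rows[, 1]) < 0))
  expect_true(all(diff(rows[, 2]) < 0))
})

test_that("inverse-quadratic exposures never exceed inverse-linear beyond 1 km", {
  set.seed(5)
  meas <- make_measurements(runif(8, -79.9, -79.7), runif(8, 32.7, 32.9),
                            rlnorm(8), chemical = "lead", medium = "soil")
  addr <- data.frame(participant_id = letters[1:3], address_class = "first",
                     lon = runif(3, -79.9, -79.7), lat = runif(3, 32.4, 32.5))
  # all distances > 20 km by construction
  X1 <- build_exposure_matrix(addr, meas, "first", media = "soil", p = 1)
  X2 <- build_exposure_matrix(addr, meas, "first", media = "soil", p = 2)
  expect_true(all(X2 <= X1))
})

test_that("missing address class drops rows with a warning", {
  meas <- make_measurements(-79.8, 32.6, 5, chemical = "lead",
                            medium = "soil")
  addr <- data.frame(participant_id = c("a", "b"),
                     address_class = c("first", "longest"),
                     lon = -79.8, lat = 32.6)
  expect_warning(X <- build_exposure_matrix(addr, meas, "first",
                                            media = "soil"),
                 "missing address class")
  expect_equal(rownames(X), "a")
  expect_error(build_exposure_matrix(addr, meas, "last", media = "soil"),
               "no participant")
})

test_that("distance histogram conserves pair counts", {
  addr <- data.frame(participant_id = "a", address_class = "first",
                     lon = -79.8, lat = 32.6)
  sites <- data.frame(site_id = "s1", lon = -79.81, lat = 32.61)
  h <- distance_histogram(addr, sites)
  expect_equal(sum(h$count), 1)
  expect_equal(sum(h$count > 0), 1)

  set.seed(6)
  addr2 <- data.frame(participant_id = sprintf("p%d", 1:7),
                      address_class = rep(c("first", "last"), length.out = 7),
                      lon = runif(7, -79.9, -79.8), lat = runif(7, 32.5, 32.7))
  sites2 <- data.frame(site_id = sprintf("s%d", 1:5),
                       lon = runif(5, -79.9, -79.8),
                       lat = runif(5, 32.5, 32.7))
  h2 <- distance_histogram(addr2, sites2)
  expect_equal(sum(h2$count), 7 * 5)
})

test_that("default generator keeps most address-site pairs within 15 km", {
  st <- simulate_study(sim_config(seed = 77))
  soil <- st$sites[st$sites$medium == "soil", ]
  h <- distance_histogram(st$addresses, soil, breaks_km = seq(0, 60, 5))
  expect_gte(sum(h$count[h$bin_hi <= 15]) / sum(h$count), 0.5)
})
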