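#' Great-circle distance by the spherical law of cosines
#'
#' Distance in kilometres between points given as WGS84 decimal-degree
#' longitude/latitude, computed as
#' \deqn{d = R \arccos(\sin\phi_1 \sin\phi_2 +
#'   \cos\phi_1 \cos\phi_2 \cos(\lambda_2 - \lambda_1))}
#' with mean Earth radius \eqn{R = 6371} km.  The arccos argument is
#' clipped to \eqn{[-1, 1]} to guard against round-off for near-identical
#' points.  Arguments are recycled to a common length.
#'
#' @param lon1,lat1 coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 coordinates of the second point(s), decimal degrees.
#' @return numeric vector of distances in km.
#' @examples
#' great_circle_distance(0, 0, 1, 0)   # one equatorial degree, ~111.195 km
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  arg <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos((lon2 - lon1) * rad)
  6371.0 * acos(pmin(1, pmax(-1, arg)))
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude out of range [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Inverse-distance weighted exposure for one chemical
#'
#' Aggregates per-site concentrations into a single exposure value for one
#' address, using inverse-linear (`p = 1`) or inverse-quadratic (`p = 2`)
#' distance weights.  The default is the unnormalized sum
#' \eqn{\sum_j c_j / d_j^p}; setting `normalize = TRUE` returns the
#' inverse-distance-weighted mean \eqn{\sum_j w_j c_j / \sum_j w_j}
#' with \eqn{w_j = d_j^{-p}}.  Distances below `clamp_km` are clamped so
#' an address coinciding with a site cannot yield an infinite exposure.
#'
#' @param concentrations nonnegative per-site concentrations.
#' @param distances_km per-site distances in km (same length).
#' @param p weighting power, 1 (inverse linear) or 2 (inverse quadratic).
#' @param normalize if TRUE return the weighted mean rather than the sum.
#' @param clamp_km lower clamp on distances, km (default 0.1).
#' @return scalar exposure value.
#' @export
distance_weight <- function(concentrations, distances_km, p = 1,
                            normalize = FALSE, clamp_km = 0.1) {
  if (length(concentrations) == 0L)
    stop("chemical unmeasured in medium: empty site set", call. = FALSE)
  if (length(concentrations) != length(distances_km))
    stop("concentrations and distances differ in length", call. = FALSE)
  if (!p %in% c(1, 2)) stop("weighting power p must be 1 or 2", call. = FALSE)
  if (any(concentrations < 0)) stop("negative concentration", call. = FALSE)
  d <- pmax(distances_km, clamp_km)
  w <- d^(-p)
  if (normalize) sum(w * concentrations) / sum(w) else sum(w * concentrations)
}

# suffix used to label chemical columns by medium
medium_suffix <- c(soil = "S", groundwater = "W", strip = "")

exposure_label <- function(chemical, medium) {
  paste0(chemical, unname(medium_suffix[medium]))
}

#' Build a participants-by-chemicals exposure matrix
#'
#' For each participant holding an address of the requested class, computes
#' the distance-weighted exposure to every chemical measured in the
#' requested media.  Column labels append a medium suffix ("S" soil,
#' "W" groundwater, none for the strip) to the chemical name.
#'
#' @param addresses data frame with columns participant_id, address_class,
#'   lon, lat.
#' @param measurements data frame with columns site_id, lon, lat, medium,
#'   chemical, concentration.
#' @param address_class one of "first", "longest", "last".
#' @param media character vector of media to include
#'   (subset of "soil", "groundwater", "strip").
#' @param p weighting power, 1 or 2.
#' @param normalize,clamp_km passed to [distance_weight()].
#' @return numeric matrix (participants x chemical-medium labels) with
#'   attributes `address_class` and `power`.
#' @export
build_exposure_matrix <- function(addresses, measurements,
                                  address_class = c("first", "longest", "last"),
                                  media = c("soil", "groundwater"),
                                  p = 1, normalize = FALSE, clamp_km = 0.1) {
  address_class <- match.arg(address_class)
  media <- match.arg(media, c("soil", "groundwater", "strip"),
                     several.ok = TRUE)
  addr <- addresses[addresses$address_class == address_class, , drop = FALSE]
  if (nrow(addr) == 0L)
    stop("no participant has an address of class '", address_class, "'",
         call. = FALSE)
  missing_ids <- setdiff(unique(addresses$participant_id), addr$participant_id)
  if (length(missing_ids))
    warning(length(missing_ids), " participant(s) missing address class '",
            address_class, "'; rows omitted", call. = FALSE)
  meas <- measurements[measurements$medium %in% media, , drop = FALSE]
  if (nrow(meas) == 0L)
    stop("no measurements in requested media", call. = FALSE)

  combos <- unique(meas[, c("chemical", "medium")])
  labels <- exposure_label(combos$chemical, combos$medium)
  X <- matrix(NA_real_, nrow(addr), nrow(combos),
              dimnames = list(addr$participant_id, labels))
  for (k in seq_len(nrow(combos))) {
    mk <- meas[meas$chemical == combos$chemical[k] &
               meas$medium == combos$medium[k], , drop = FALSE]
    for (i in seq_len(nrow(addr))) {
      d <- great_circle_distance(addr$lon[i], addr$lat[i], mk$lon, mk$lat)
      X[i, k] <- distance_weight(mk$concentration, d, p = p,
                                 normalize = normalize, clamp_km = clamp_km)
    }
  }
  structure(X, address_class = address_class, power = p, media = media)
}

#' Histogram of address-to-site distances
#'
#' Counts all address-site pairs into fixed-width distance bins, per
#' address class; used to check that exposures are dominated by nearby
#' sites (most pairs within ~15 km in the study design).
#'
#' @param addresses address data frame (participant_id, address_class,
#'   lon, lat).
#' @param sites site data frame (site_id, lon, lat).
#' @param breaks_km bin edges in km; the last bin is open-ended.
#' @return data frame with columns address_class, bin_lo, bin_hi, count.
#' @export
distance_histogram <- function(addresses, sites,
                               breaks_km = seq(0, 50, by = 5)) {
  if (nrow(addresses) == 0L || nrow(sites) == 0L)
    stop("empty addresses or sites", call. = FALSE)
  breaks <- c(breaks_km, Inf)
  out <- lapply(unique(addresses$address_class), function(cl) {
    a <- addresses[addresses$address_class == cl, , drop = FALSE]
    d <- as.vector(outer(seq_len(nrow(a)), seq_len(nrow(sites)),
      function(i, j) great_circle_distance(a$lon[i], a$lat[i],
                                           sites$lon[j], sites$lat[j])))
    cnt <- as.vector(table(cut(d, breaks, right = FALSE)))
    data.frame(address_class = cl,
               bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1],
               count = cnt)
  })
  do.call(rbind, out)
}
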