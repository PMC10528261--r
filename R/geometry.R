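C0 <- 299792458 # vacuum speed of light, m/s

#' Wave propagation speed in a homogeneous dielectric
#'
#' Plane-wave phase speed `c0 / sqrt(eps_r)` used for all delay
#' computations. The phantom gel has `eps_r ~ 30` at the 3.25 GHz center
#' frequency, giving roughly 5.47e7 m/s.
#'
#' @param rel_permittivity relative permittivity (dimensionless, >= 1).
#' @return speed in m/s.
#' @export
propagation_speed <- function(rel_permittivity) {
  if (!is.numeric(rel_permittivity) || any(rel_permittivity < 1))
    stop("rel_permittivity must be >= 1")
  C0 / sqrt(rel_permittivity)
}

#' Cylindrical tissue phantom model
#'
#' @param radius cylinder radius in metres (default 0.065, a 13 cm bowl).
#' @param height cylinder height in metres.
#' @param rel_permittivity relative permittivity of the gel.
#' @param top_surface_z z of the top surface; z is negative downward.
#' @return an object of class `mw_phantom`.
#' @export
phantom_model <- function(radius = 0.065, height = 0.10,
                          rel_permittivity = 30, top_surface_z = 0) {
  stopifnot(radius > 0, height > 0)
  if (rel_permittivity < 1) stop("rel_permittivity must be >= 1")
  structure(list(radius = radius, height = height,
                 rel_permittivity = rel_permittivity,
                 top_surface_z = top_surface_z),
            class = "mw_phantom")
}

#' Pulsating artery surrogate model
#'
#' An elastic tube of rest radius `d0` whose radius is modulated by a
#' sinusoidal pressure `P = P0 + dP*cos(2*pi*nu*T)`; the radial excursion
#' is `delta_d = dP / K` where `K` is the tube stiffness. The invariant
#' `delta_d == dP / K` is enforced by construction: `dP` is derived from
#' the requested `delta_d` and `K`.
#'
#' @param center_xy lateral (x, y) of the tube axis in metres.
#' @param d0 rest radius in metres (5 mm diameter tube -> 2.5e-3).
#' @param delta_d radial pulsation amplitude in metres (< 0.2 mm in the
#'   phantom; default 0.15 mm).
#' @param nu pulsation frequency in Hz.
#' @param fill tube filling, `"air"` or `"water"`.
#' @param pulsating logical; a clipped tube is rigid (`FALSE`).
#' @param stiffness K, pressure units per metre.
#' @param p0 static pressure offset (arbitrary units).
#' @param z_extent `(z_top, z_bottom)` of the vertical tube segment.
#' @return an object of class `mw_artery`.
#' @export
artery_model <- function(center_xy, d0 = 2.5e-3, delta_d = 0.15e-3,
                         nu = 0.08, fill = c("air", "water"),
                         pulsating = TRUE, stiffness = 1000, p0 = 100,
                         z_extent = c(0, -0.10)) {
  fill <- match.arg(fill)
  stopifnot(length(center_xy) == 2, d0 > 0, delta_d >= 0, nu >= 0)
  if (d0 <= delta_d) stop("rest radius d0 must exceed pulsation amplitude")
  delta_p <- delta_d * stiffness   # so that delta_d = dP / K exactly
  structure(list(center_xy = as.numeric(center_xy),
                 z_extent = as.numeric(z_extent),
                 d0 = d0, delta_d = delta_d,
                 stiffness = stiffness, p0 = p0, delta_p = delta_p,
                 nu = nu, fill = fill, pulsating = isTRUE(pulsating)),
            class = "mw_artery")
}

#' Build the two-ring MIMO antenna array
#'
#' 32 small antennas in two rings on the phantom wall (z = -4 cm and
#' -6 cm), 16 transmitters and 16 receivers, giving 16 x 16 = 256
#' bistatic channels. Roles alternate TX, RX, TX, ... around each ring,
#' with the pattern offset by one slot between rings so that bistatic
#' coverage is azimuthally uniform.
#'
#' @param n_tx,n_rx transmitter / receiver counts (must be equal).
#' @param ring_z ring heights in metres (one or more rings).
#' @param ring_radius ring radius in metres (antennas sit on the
#'   phantom wall, so this defaults to the phantom radius).
#' @return an object of class `mw_array` with elements `antennas`
#'   (n x 3 matrix), `role`, `kT`, `kR`, `tx_idx`, `rx_idx` and
#'   `channels` (data.frame with antenna indices `tx`, `rx`).
#' @export
build_default_array <- function(n_tx = 16, n_rx = 16,
                                ring_z = c(-0.04, -0.06),
                                ring_radius = 0.065) {
  if (n_tx != n_rx)
    stop("alternating TX/RX layout requires n_tx == n_rx")
  n_ant <- n_tx + n_rx
  n_ring <- length(ring_z)
  if (n_ant %% n_ring != 0 || (n_ant / n_ring) %% 2 != 0)
    stop("odd antenna count per ring: choose counts divisible by 2 per ring")
  per <- n_ant / n_ring
  pos <- matrix(NA_real_, n_ant, 3, dimnames = list(NULL, c("x", "y", "z")))
  role <- character(n_ant)
  k <- 1L
  for (r in seq_len(n_ring)) {
    ang <- 2 * pi * (seq_len(per) - 1L) / per
    for (s in seq_len(per)) {
      pos[k, ] <- c(ring_radius * cos(ang[s]), ring_radius * sin(ang[s]),
                    ring_z[r])
      role[k] <- if ((s + r) %% 2 == 0L) "TX" else "RX"
      k <- k + 1L
    }
  }
  tx_idx <- which(role == "TX")
  rx_idx <- which(role == "RX")
  stopifnot(length(tx_idx) == n_tx, length(rx_idx) == n_rx)
  channels <- expand.grid(rx = rx_idx, tx = tx_idx)[, c("tx", "rx")]
  rownames(channels) <- NULL
  structure(list(antennas = pos, role = role,
                 kT = n_tx, kR = n_rx,
                 tx_idx = tx_idx, rx_idx = rx_idx,
                 ring_z = ring_z, ring_radius = ring_radius,
                 channels = channels),
            class = "mw_array")
}

#' @export
print.mw_array <- function(x, ...) {
  cat(sprintf("MIMO array: %d antennas (%d TX, %d RX), %d channels\n",
              nrow(x$antennas), x$kT, x$kR, nrow(x$channels)))
  cat(sprintf("  rings at z = %s m, radius %.3f m\n",
              paste(format(x$ring_z), collapse = ", "), x$ring_radius))
  invisible(x)
}

# default lateral artery coordinates (m): tube ends at (5,0), (0,4),
# (-3,0), (0,-2) cm
DEFAULT_ARTERY_XY <- matrix(c(0.05, 0, 0, 0.04, -0.03, 0, 0, -0.02),
                            ncol = 2, byrow = TRUE)

#' Build one of the six experimental scenarios
#'
#' Four 5 mm artery surrogates in the gel phantom, pulsating at 0.08 Hz
#' with 0.15 mm radial amplitude. Scenario 1: all four pulsating,
#' air-filled. Scenarios 2-5: exactly one artery clipped (rigid),
#' cycling through arteries 1-4. Scenario 6: all four pulsating,
#' water-filled.
#'
#' @param id scenario id, 1..6.
#' @param delta_d pulsation amplitude in metres.
#' @param nu pulsation frequency in Hz.
#' @param phantom a [phantom_model()].
#' @return an object of class `mw_scenario`.
#' @export
build_scenario <- function(id, delta_d = 0.15e-3, nu = 0.08,
                           phantom = phantom_model()) {
  if (!(is.numeric(id) && length(id) == 1 && id %in% 1:6))
    stop("unknown scenario id (must be 1..6)")
  id <- as.integer(id)
  fill <- if (id == 6L) "water" else "air"
  pulsating <- rep(TRUE, 4)
  if (id >= 2L && id <= 5L) pulsating[id - 1L] <- FALSE
  arteries <- lapply(1:4, function(a) {
    artery_model(center_xy = DEFAULT_ARTERY_XY[a, ],
                 delta_d = delta_d, nu = nu, fill = fill,
                 pulsating = pulsating[a],
                 z_extent = c(phantom$top_surface_z,
                              phantom$top_surface_z - phantom$height))
  })
  for (a in arteries) {
    if (sqrt(sum(a$center_xy^2)) >= phantom$radius)
      stop("artery axis outside the phantom cylinder")
  }
  desc <- sprintf("scenario %d: %s-filled tubes, pulsating = {%s}",
                  id, fill, paste(ifelse(pulsating, "yes", "no"),
                                  collapse = ", "))
  structure(list(id = id, phantom = phantom, arteries = arteries,
                 description = desc),
            class = "mw_scenario")
}

#' Assemble a scenario from explicit arteries
#'
#' The six numbered scenarios cover the standard phantom; this
#' constructor builds arbitrary configurations (e.g. a single short
#' pulsating segment for point-response studies).
#'
#' @param arteries list of [artery_model()] objects.
#' @param phantom a [phantom_model()].
#' @param id numeric tag (default 0 = custom).
#' @param description text.
#' @return an `mw_scenario`.
#' @export
custom_scenario <- function(arteries, phantom = phantom_model(), id = 0,
                            description = "custom scenario") {
  stopifnot(is.list(arteries),
            all(vapply(arteries, inherits, TRUE, "mw_artery")))
  for (a in arteries) {
    if (sqrt(sum(a$center_xy^2)) >= phantom$radius)
      stop("artery axis outside the phantom cylinder")
  }
  structure(list(id = id, phantom = phantom, arteries = arteries,
                 description = description),
            class = "mw_scenario")
}

#' @export
print.mw_scenario <- function(x, ...) {
  cat(x$description, "\n")
  for (a in x$arteries)
    cat(sprintf("  artery at (%+.3f, %+.3f) m, d0=%.1f mm, dd=%.2f mm, %s%s\n",
                a$center_xy[1], a$center_xy[2], 1e3 * a$d0, 1e3 * a$delta_d,
                a$fill, if (a$pulsating) ", pulsating" else " (clipped)"))
  invisible(x)
}

#' Minimum distance from a point to the antenna array
#'
#' @param point position vector (x, y, z) in metres.
#' @param geom an `mw_array`.
#' @return minimum Euclidean distance in metres.
#' @export
min_distance_to_array <- function(point, geom) {
  stopifnot(inherits(geom, "mw_array"), nrow(geom$antennas) > 0)
  d <- sqrt(colSums((t(geom$antennas) - as.numeric(point))^2))
  min(d)
}

#' Lateral distance from a point to the antenna ring circle
#'
#' Distance in the (x, y) plane from a lateral point to the circle of
#' the antenna rings, i.e. the "depth" of an artery below the array
#' surface. The deepest default artery, at (0, -2) cm, is 4.5 cm from
#' the 6.5 cm ring; the other three are at most 3.5 cm away.
#'
#' @param xy lateral coordinates (x, y) in metres.
#' @param ring_radius ring radius in metres.
#' @return lateral distance in metres.
#' @export
lateral_ring_distance <- function(xy, ring_radius = 0.065) {
  abs(ring_radius - sqrt(sum(as.numeric(xy)^2)))
}
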