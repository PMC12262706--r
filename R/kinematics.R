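# Rotation-referenced kinematics of tracks within a condensate: angle
# series relative to the initial position vector, angular velocity and
# acceleration, persistence statistics and phase-space area.

#' Condensate geometry
#'
#' @param center condensate centre (x, y) in micrometres.
#' @param radius condensate radius in micrometres.
#' @return an object of class \code{condensate_geometry}.
#' @export
condensate_geometry <- function(center = c(0, 0), radius) {
  assert_scalar_positive(radius, "radius")
  if (length(center) != 2L || !all(is.finite(center)))
    stop_domain("center must be a finite length-2 vector")
  structure(list(center = as.numeric(center), radius = radius),
            class = "condensate_geometry")
}

#' Estimate condensate geometry from localisations
#'
#' For experimental data without a known centre, uses the centroid of all
#' spot localisations and the maximal centroid distance as radius.
#'
#' @param tracks list of \code{smt_trajectory}.
#' @export
estimate_geometry <- function(tracks) {
  if (inherits(tracks, "smt_condensate")) tracks <- tracks$tracks
  xs <- unlist(lapply(tracks, `[[`, "x"))
  ys <- unlist(lapply(tracks, `[[`, "y"))
  ctr <- c(mean(xs), mean(ys))
  r <- max(sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2), .Machine$double.eps)
  condensate_geometry(ctr, r)
}

#' Rotation-angle series of a track
#'
#' Signed angle (four-quadrant arctangent) between the position vector of the
#' molecule relative to the condensate centre and its initial position
#' vector, unwrapped so consecutive values differ by less than pi;
#' \code{theta[1] = 0} by construction. Samples coinciding with the centre
#' (distance below \code{floor}) are flagged and linearly interpolated from
#' their neighbours; a track entirely at the centre is an error.
#'
#' @param traj an \code{smt_trajectory}.
#' @param geom a \code{\link{condensate_geometry}}.
#' @param floor numeric distance floor in um below which a sample counts as
#'   "at the centre".
#' @return numeric vector of angles (radians, one per frame) with attribute
#'   \code{flagged} giving indices of interpolated samples.
#' @export
angular_series <- function(traj, geom, floor = 1e-9) {
  px <- traj$x - geom$center[1L]
  py <- traj$y - geom$center[2L]
  d <- sqrt(px^2 + py^2)
  bad <- d <= floor
  if (all(bad)) stop_domain("all samples coincide with the condensate center")
  ref <- which(!bad)[1L]
  rx <- px[ref]; ry <- py[ref]
  # signed angle from the (first valid) reference vector to each sample
  raw <- atan2(rx * py - ry * px, rx * px + ry * py)
  raw[bad] <- NA_real_
  # unwrap across the +/- pi branch cut before any differencing
  good <- which(!is.na(raw))
  dphi <- diff(raw[good])
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  unwrapped <- raw
  unwrapped[good] <- cumsum(c(raw[good][1L], dphi))
  if (any(bad)) {
    unwrapped[bad] <- stats::approx(x = good, y = unwrapped[good],
                                    xout = which(bad), rule = 2)$y
  }
  theta <- unwrapped - unwrapped[1L]
  attr(theta, "flagged") <- which(bad)
  theta
}

#' Angular velocity and acceleration from an angle series
#'
#' First differences: \code{omega = diff(theta) / dt} and
#' \code{accel = diff(omega) / dt}.
#'
#' @param theta angle series in radians (length >= 3).
#' @param dt frame interval in seconds.
#' @return list with \code{omega} (rad/s) and \code{accel} (rad/s^2).
#' @export
kinematics <- function(theta, dt) {
  assert_scalar_positive(dt, "dt")
  if (length(theta) < 3L) stop_domain("kinematics requires >= 3 angles")
  omega <- diff(as.numeric(theta)) / dt
  list(omega = omega, accel = diff(omega) / dt)
}

#' Angular velocity autocorrelation summary
#'
#' \code{g(tau) = mean_t omega(t) omega(t + tau)}; the scalar summary is the
#' mean of \code{g(tau) / Var(omega)} over the lag window (default lags
#' 1..5), quantifying the persistence of rotational motion: near 0 for
#' uncorrelated motion, positive for persistent rotation, negative for
#' anti-persistent motion. Series whose variance is below \code{var_floor}
#' (e.g. constant omega) return 0 with \code{flag = "zero_variance"}. The
#' raw unnormalised mean of g(tau) is available with
#' \code{normalize = FALSE}.
#'
#' @param omega angular velocity series (rad/s).
#' @param lags integer lag window; lags beyond the series length are dropped.
#' @param normalize divide by the variance of omega (default TRUE).
#' @param var_floor degeneracy floor for the variance.
#' @return list with \code{value}, \code{g} (per-lag values) and \code{flag}
#'   (\code{NA} when clean).
#' @export
velocity_autocorrelation <- function(omega, lags = 1:5, normalize = TRUE,
                                     var_floor = 1e-12) {
  m <- length(omega)
  lags <- lags[lags < m]
  if (length(lags) == 0L)
    stop_domain("omega is too short for the requested lag window")
  g <- vapply(lags, function(k)
    mean(omega[1:(m - k)] * omega[(1 + k):m]), numeric(1))
  if (!normalize)
    return(list(value = mean(g), g = stats::setNames(g, lags), flag = NA_character_))
  v <- stats::var(omega) * (m - 1) / m
  if (!is.finite(v) || v < var_floor)
    return(list(value = 0, g = stats::setNames(g, lags), flag = "zero_variance"))
  list(value = mean(g / v), g = stats::setNames(g, lags), flag = NA_character_)
}

#' Velocity-acceleration correlation
#'
#' Pearson correlation between the angular velocity and acceleration series
#' after aligning them in time (\code{omega} trimmed to the acceleration
#' length). Bounded in [-1, 1]: negative values indicate damped or restrained
#' motion, positive values driven or self-reinforcing motion. The raw lagged
#' mean product is available with \code{method = "raw"}.
#'
#' @param omega angular velocity series (rad/s).
#' @param accel angular acceleration series (rad/s^2), length
#'   \code{length(omega) - 1} as produced by \code{\link{kinematics}} (equal
#'   lengths are also accepted).
#' @param method \code{"pearson"} (default) or \code{"raw"}.
#' @return list with \code{value} and \code{flag} (\code{"zero_variance"}
#'   when either series is degenerate, value 0).
#' @export
vel_accel_correlation <- function(omega, accel,
                                  method = c("pearson", "raw")) {
  method <- match.arg(method)
  if (length(accel) == length(omega) - 1L) omega <- omega[seq_along(accel)]
  if (length(accel) != length(omega))
    stop_domain("omega and accel lengths are incompatible")
  if (length(accel) < 2L) stop_domain("need >= 2 aligned points")
  if (method == "raw")
    return(list(value = mean(omega * accel), flag = NA_character_))
  if (stats::sd(omega) == 0 || stats::sd(accel) == 0)
    return(list(value = 0, flag = "zero_variance"))
  list(value = stats::cor(omega, accel), flag = NA_character_)
}

#' Phase-space area explored in velocity-acceleration space
#'
#' Area of the convex hull of the aligned (omega, accel) point cloud,
#' quantifying the territory explored by the molecule in velocity-
#' acceleration space. Degenerate (collinear or repeated) clouds give 0.
#'
#' @param omega angular velocity series (rad/s).
#' @param accel angular acceleration series (rad/s^2); aligned as in
#'   \code{\link{vel_accel_correlation}}.
#' @return area in rad^2/s^3 (>= 0).
#' @export
phase_space_area <- function(omega, accel) {
  if (length(accel) == length(omega) - 1L) omega <- omega[seq_along(accel)]
  if (length(accel) != length(omega))
    stop_domain("omega and accel lengths are incompatible")
  if (length(accel) < 3L) stop_domain("phase_space_area needs >= 3 points")
  pts <- unique(cbind(omega, accel))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  hx <- pts[h, 1L]; hy <- pts[h, 2L]
  # shoelace formula on the hull vertices
  j <- c(seq_along(h)[-1L], 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

#' Maximum rotational amplitude of an angle series
#'
#' @param theta angle series in radians.
#' @return max absolute angle in degrees.
#' @export
max_rotation_amplitude <- function(theta) {
  if (length(theta) == 0L) stop_domain("theta must be nonempty")
  max(abs(theta)) * 180 / pi
}

#' Per-track kinematic summary table
#'
#' Computes the rotation-referenced series and scalar summaries for every
#' track of a condensate: maximum rotation amplitude, velocity
#' autocorrelation, velocity-acceleration correlation and phase-space area.
#'
#' @param tracks list of \code{smt_trajectory} or an \code{smt_condensate}.
#' @param geom condensate geometry; defaults to the simulation centre for an
#'   \code{smt_condensate} and to \code{\link{estimate_geometry}} otherwise.
#' @param lags autocorrelation lag window.
#' @param normalize_vacf variance-normalize the autocorrelation summary
#'   (default); FALSE reports the raw mean lagged product, whose magnitude
#'   scales with the angular-velocity amplitude.
#' @return data frame with one row per track: \code{track_id},
#'   \code{max_theta_deg}, \code{vacf}, \code{va_corr}, \code{ps_area}.
#' @export
kinematic_summary <- function(tracks, geom = NULL, lags = 1:5,
                              normalize_vacf = TRUE) {
  if (inherits(tracks, "smt_condensate")) {
    geom <- geom %||% condensate_geometry(tracks$center, tracks$radius)
    tracks <- tracks$tracks
  }
  geom <- geom %||% estimate_geometry(tracks)
  rows <- lapply(tracks, function(tr) {
    th <- angular_series(tr, geom)
    kin <- kinematics(th, tr$dt)
    data.frame(track_id = as.character(tr$track_id),
               max_theta_deg = max_rotation_amplitude(th),
               vacf = velocity_autocorrelation(kin$omega, lags,
                                               normalize = normalize_vacf)$value,
               va_corr = vel_accel_correlation(kin$omega, kin$accel)$value,
               ps_area = phase_space_area(kin$omega, kin$accel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
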