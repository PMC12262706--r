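# Monte Carlo engine: FBM guest molecules inside a spherical condensate,
# with optional whole-condensate Brownian rotation.

#' Simulation parameters
#'
#' Bundles all physical and numerical parameters of one simulated condensate
#' condition. Defaults follow typical intra-condensate SMT conditions: 50 ms
#' frames, 20 steps per track, 1000 molecules, room temperature, and a 5 mPa s
#' medium viscosity representative of a ~10 mg/ml protein solution.
#'
#' @param D generalized diffusion coefficient (um^2/s^alpha; um^2/s at
#'   alpha = 1). Must be >= 0 (0 gives frozen molecules, useful for tests).
#' @param alpha anomalous exponent in (0, 2); 1 = Brownian, 0.5 = the
#'   confined/subdiffusive regime.
#' @param diameter condensate diameter in micrometres.
#' @param dt time step (frame interval) in seconds.
#' @param n_steps number of steps per track (track has n_steps + 1 samples).
#' @param n_molecules number of tracks per condition.
#' @param temperature bath temperature in kelvin.
#' @param viscosity medium viscosity in Pa s.
#' @param rotation_enabled logical; TRUE simulates an untethered condensate
#'   whose whole body undergoes Brownian rotation, FALSE a tethered one.
#' @param seed RNG master seed (integer below 2^31).
#' @param init initial-position rule: \code{"square"} draws uniformly from the
#'   axis-aligned square of side \code{diameter} centred on the condensate
#'   centre; \code{"disc"} restricts to the inscribed disc.
#' @param rotation_geometry \code{"small_angle"} (default) displaces each
#'   molecule by the drawn angle scaled by its distance from the condensate
#'   centre, perpendicular to its position vector -- the first-order scheme
#'   whose rotational contribution stays Brownian-like and leaves the
#'   apparent exponent of free diffusion untouched; \code{"exact"} applies
#'   the exact rigid rotation matrix instead (preserves radii exactly, at
#'   the cost of saturating displacements when per-step angles are large).
#' @param theta_model per-step rotation-angle convention. \code{"speed"}
#'   (default) treats the Stokes-Einstein rate as a mean angular speed and
#'   draws \code{theta ~ N(0, sd = omega * dt)}; \code{"diffusive"} treats it
#'   as a planar rotational diffusivity, \code{theta ~ N(0, var = 2 omega dt)}.
#'   See the methods vignette for why \code{"speed"} is the default.
#' @param rotation_denominator the constant in the Stokes-Einstein denominator
#'   (\code{4} as printed for this system; textbook rotational diffusion about
#'   one axis uses \code{8}).
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(D, alpha = 1, diameter = 1, dt = 0.05, n_steps = 20L,
                       n_molecules = 1000L, temperature = 298,
                       viscosity = 0.005, rotation_enabled = TRUE, seed = 1L,
                       init = c("square", "disc"),
                       rotation_geometry = c("small_angle", "exact"),
                       theta_model = c("speed", "diffusive"),
                       rotation_denominator = 4) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0)
    stop_domain("D must be a single finite number >= 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 2)
    stop_domain("alpha must lie in (0, 2)")
  assert_scalar_positive(diameter, "diameter")
  assert_scalar_positive(dt, "dt")
  if (n_steps < 2) stop_domain("n_steps must be >= 2")
  if (n_molecules < 1) stop_domain("n_molecules must be >= 1")
  assert_scalar_positive(temperature, "temperature")
  assert_scalar_positive(viscosity, "viscosity")
  assert_flag(rotation_enabled, "rotation_enabled")
  structure(
    list(D = D, alpha = alpha, diameter = diameter, dt = dt,
         n_steps = as.integer(n_steps), n_molecules = as.integer(n_molecules),
         temperature = temperature, viscosity = viscosity,
         rotation_enabled = rotation_enabled, seed = as.integer(seed),
         init = match.arg(init),
         rotation_geometry = match.arg(rotation_geometry),
         theta_model = match.arg(theta_model),
         rotation_denominator = rotation_denominator),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_params> D=%g um^2/s^a, alpha=%g, diameter=%g um, dt=%g s,\n",
           "  %d steps x %d molecules, T=%g K, eta=%g Pa.s, rotation=%s, seed=%d\n"),
    x$D, x$alpha, x$diameter, x$dt, x$n_steps, x$n_molecules,
    x$temperature, x$viscosity,
    if (x$rotation_enabled) "on (untethered)" else "off (tethered)", x$seed))
  invisible(x)
}

#' Rotational rate of a spherical condensate
#'
#' Stokes-Einstein rate for a sphere of the given radius,
#' \code{omega = kB T / (4 pi eta r^3)} with the radius converted to metres.
#' Strictly decreasing in radius; doubling the radius divides the rate by 8.
#'
#' @param radius condensate radius in micrometres.
#' @param temperature temperature in kelvin.
#' @param viscosity medium viscosity in Pa s.
#' @param denominator_factor denominator constant (default 4 as used for this
#'   system; the textbook rotational diffusivity about one axis uses 8).
#' @return rotational rate in rad^2/s.
#' @examples
#' rotational_diffusivity(0.5) # ~0.524 for a 1 um condensate at 298 K, 5 mPa.s
#' @export
rotational_diffusivity <- function(radius, temperature = 298,
                                   viscosity = 0.005,
                                   denominator_factor = 4) {
  assert_scalar_positive(radius, "radius")
  assert_scalar_positive(temperature, "temperature")
  assert_scalar_positive(viscosity, "viscosity")
  r_m <- radius * 1e-6
  .kB * temperature / (denominator_factor * pi * viscosity * r_m^3)
}

# Per-step rotation-angle standard deviation under the chosen convention.
theta_step_sd <- function(omega, dt, theta_model) {
  switch(theta_model,
         speed = omega * dt,
         diffusive = sqrt(2 * omega * dt),
         stop_domain("unknown theta_model: ", theta_model))
}

#' Apply one shared rotation step to a set of positions
#'
#' Draws a single angle theta (shared by every molecule in the condensate at
#' this step) and rotates all positions about the condensate centre. With the
#' exact geometry, distances to the centre are preserved to machine precision;
#' the small-angle geometry instead displaces each point by \code{theta}
#' scaled by its distance from the centre, perpendicular to its position
#' vector (first-order equivalent).
#'
#' @param positions numeric n x 2 matrix of (x, y) in micrometres.
#' @param center condensate centre, length-2 numeric.
#' @param omega rotational rate in rad^2/s (>= 0).
#' @param dt time step in seconds.
#' @param theta optional fixed angle (radians); if NULL one draw is taken
#'   from the R RNG stream under \code{theta_model}.
#' @param geometry \code{"exact"} or \code{"small_angle"}.
#' @param theta_model \code{"speed"} or \code{"diffusive"}; see
#'   \code{\link{sim_params}}.
#' @return rotated positions matrix with the applied angle in
#'   \code{attr(, "theta")}.
#' @export
apply_rotation_step <- function(positions, center = c(0, 0), omega, dt,
                                theta = NULL,
                                geometry = c("exact", "small_angle"),
                                theta_model = c("speed", "diffusive")) {
  geometry <- match.arg(geometry)
  theta_model <- match.arg(theta_model)
  if (!is.matrix(positions) || ncol(positions) != 2L)
    positions <- matrix(positions, ncol = 2L)
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0)
    stop_domain("omega must be a single number >= 0")
  assert_scalar_positive(dt, "dt")
  if (is.null(theta)) {
    sdth <- theta_step_sd(omega, dt, theta_model)
    theta <- if (sdth > 0) stats::rnorm(1L, 0, sdth) else 0
  }
  px <- positions[, 1L] - center[1L]
  py <- positions[, 2L] - center[2L]
  if (geometry == "exact") {
    co <- cos(theta); si <- sin(theta)
    out <- cbind(center[1L] + co * px - si * py,
                 center[2L] + si * px + co * py)
  } else {
    out <- cbind(center[1L] + px - theta * py,
                 center[2L] + py + theta * px)
  }
  attr(out, "theta") <- theta
  out
}

#' Generate one FBM track
#'
#' A single guest-molecule trajectory with no condensate rotation: each axis
#' is an independent FBM path with Hurst exponent \code{alpha/2}, scaled so
#' the ensemble 2D MSD is \code{4 D tau^alpha}. The initial position is drawn
#' per \code{params$init}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param track_id identifier for the returned trajectory.
#' @param seed RNG seed for this track; defaults to \code{params$seed}.
#' @return an \code{smt_trajectory} carrying ground-truth provenance.
#' @export
generate_fbm_track <- function(params, track_id = 1L, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  p0 <- draw_initial_positions(1L, params)
  n <- params$n_steps
  inc <- if (params$D > 0)
    fgn_sample(n, params$alpha / 2, params$dt, 2L) * sqrt(2 * params$D)
  else matrix(0, n, 2L)
  trajectory(track_id, frames = 0:n,
             x = p0[1L] + c(0, cumsum(inc[, 1L])),
             y = p0[2L] + c(0, cumsum(inc[, 2L])),
             dt = params$dt,
             ground_truth = list(D = params$D, alpha = params$alpha,
                                 diameter = params$diameter,
                                 rotation_enabled = FALSE))
}

draw_initial_positions <- function(n, params) {
  h <- params$diameter / 2
  if (params$init == "square") {
    cbind(stats::runif(n, -h, h), stats::runif(n, -h, h))
  } else {
    # rejection-free disc sampling
    r <- h * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  }
}

#' Simulate all guest molecules of one condensate
#'
#' At each time step every molecule receives its own FBM increment; if
#' rotation is enabled, one shared random rotation about the condensate
#' centre is then applied to all molecules (rigid-body motion of the whole
#' condensate). Molecular increments are generated from per-molecule child
#' seeds and the rotation angles from a separate child stream, so the
#' tethered output is a deterministic function of the molecular seed alone:
#' toggling \code{rotation_enabled} cannot change tethered results, and a
#' tethered/untethered pair sharing \code{params$seed} shares its molecular
#' noise exactly.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return an object of class \code{smt_condensate}: a list with
#'   \code{tracks} (list of \code{smt_trajectory}), \code{center},
#'   \code{radius}, \code{params}, \code{omega} (rotational rate) and
#'   \code{rotation_angles} (the per-step drawn angles; zeros when tethered).
#' @export
simulate_condensate <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_steps
  nm <- params$n_molecules
  scale <- sqrt(2 * params$D)
  R <- if (params$D > 0) fgn_chol_factor(params$alpha / 2, n, params$dt)
       else NULL

  X <- matrix(0, n + 1L, nm)
  Y <- matrix(0, n + 1L, nm)
  incX <- matrix(0, n, nm)
  incY <- matrix(0, n, nm)
  for (i in seq_len(nm)) {
    set.seed(child_seed(params$seed, i))
    p0 <- draw_initial_positions(1L, params)
    X[1L, i] <- p0[1L]; Y[1L, i] <- p0[2L]
    if (params$D > 0) {
      z <- matrix(stats::rnorm(2L * n), n, 2L)
      inc <- crossprod(R, z) * scale
      incX[, i] <- inc[, 1L]; incY[, i] <- inc[, 2L]
    }
  }

  omega <- rotational_diffusivity(params$diameter / 2, params$temperature,
                                  params$viscosity,
                                  params$rotation_denominator)
  thetas <- numeric(n)
  if (params$rotation_enabled) {
    set.seed(child_seed(params$seed, 536870911L)) # dedicated rotation stream
    sdth <- theta_step_sd(omega, params$dt, params$theta_model)
    if (sdth > 0) thetas <- stats::rnorm(n, 0, sdth)
  }

  cx <- X[1L, ]; cy <- Y[1L, ]
  for (s in seq_len(n)) {
    cx <- cx + incX[s, ]
    cy <- cy + incY[s, ]
    if (params$rotation_enabled && thetas[s] != 0) {
      rot <- apply_rotation_step(cbind(cx, cy), c(0, 0), omega, params$dt,
                                 theta = thetas[s],
                                 geometry = params$rotation_geometry)
      cx <- rot[, 1L]; cy <- rot[, 2L]
    }
    X[s + 1L, ] <- cx
    Y[s + 1L, ] <- cy
  }

  gt <- list(D = params$D, alpha = params$alpha, diameter = params$diameter,
             rotation_enabled = params$rotation_enabled)
  tracks <- lapply(seq_len(nm), function(i)
    trajectory(i, frames = 0:n, x = X[, i], y = Y[, i], dt = params$dt,
               ground_truth = gt))
  structure(list(tracks = tracks, center = c(0, 0),
                 radius = params$diameter / 2, params = params,
                 omega = omega, rotation_angles = thetas),
            class = "smt_condensate")
}

#' @export
print.smt_condensate <- function(x, ...) {
  cat(sprintf("<smt_condensate> %d tracks, diameter %g um, rotation %s\n",
              length(x$tracks), x$params$diameter,
              if (x$params$rotation_enabled) "on" else "off"))
  invisible(x)
}
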