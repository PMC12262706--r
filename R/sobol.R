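# Two-dimensional Sobol low-discrepancy sequence (Gray-code construction).
# Only the first two dimensions are needed for the (log10 D, diameter) sweep,
# so the direction numbers are hard-wired: dimension 1 is the van der Corput
# sequence in base 2; dimension 2 uses the degree-1 primitive polynomial
# x + 1 (initial direction integer m1 = 1), giving the classic Sobol pairing.

#' Generate points of the 2D Sobol sequence
#'
#' @param n number of points to return.
#' @param skip number of initial points to drop (default 1 skips the origin).
#' @return an \code{n x 2} matrix of points in the unit square.
#' @export
sobol_2d <- function(n, skip = 1L) {
  if (n < 1) stop_domain("n must be >= 1")
  total <- n + skip
  nb <- 30L                                   # enough for < 2^30 points
  m <- integer(nb); m[1L] <- 1L
  for (k in 2:nb) m[k] <- bitwXor(bitwShiftL(m[k - 1L], 1L), m[k - 1L])
  # direction vectors as bit columns (row j = weight 2^-j)
  V1 <- diag(nb)
  V2 <- vapply(seq_len(nb), function(k) {
    bits <- integer(nb); val <- m[k]
    for (j in k:1) { bits[j] <- val %% 2L; val <- val %/% 2L }
    bits
  }, integer(nb))
  w <- 2^-(seq_len(nb))
  b1 <- integer(nb); b2 <- integer(nb)
  out <- matrix(NA_real_, total, 2L)
  out[1L, ] <- 0
  for (i in 2:max(total, 2L)) {
    # Gray-code index: position of the rightmost zero bit of i - 2
    n0 <- i - 2L; c_ <- 1L
    while (n0 %% 2L == 1L) { n0 <- n0 %/% 2L; c_ <- c_ + 1L }
    b1 <- bitwXor(b1, V1[, c_])
    b2 <- bitwXor(b2, V2[, c_])
    out[i, 1L] <- sum(b1 * w)
    out[i, 2L] <- sum(b2 * w)
  }
  out[(skip + 1L):total, , drop = FALSE]
}

#' Sweep design over (log10 D, diameter) space
#'
#' @param n_points number of Sobol sample points (default 200).
#' @param log10D_range range of log10 ground-truth D (um^2/s), default
#'   \code{c(-3, 0)} covering 0.001 to 1.
#' @param diameter_range condensate diameter range in um, default
#'   \code{c(0.3, 5)}.
#' @param alpha_values anomalous exponents simulated at every point,
#'   default \code{c(1, 0.5)} (normal and subdiffusive regimes).
#' @return an object of class \code{sweep_design}.
#' @export
sweep_design <- function(n_points = 200L, log10D_range = c(-3, 0),
                         diameter_range = c(0.3, 5),
                         alpha_values = c(1, 0.5)) {
  if (n_points < 1) stop_domain("n_points must be >= 1")
  if (length(log10D_range) != 2L || diff(log10D_range) <= 0)
    stop_domain("log10D_range must be an increasing pair")
  if (length(diameter_range) != 2L || diff(diameter_range) <= 0 ||
      diameter_range[1L] <= 0)
    stop_domain("diameter_range must be an increasing positive pair")
  if (length(alpha_values) < 1L || any(alpha_values <= 0 | alpha_values >= 2))
    stop_domain("alpha_values must lie in (0, 2)")
  structure(list(n_points = as.integer(n_points),
                 log10D_range = log10D_range,
                 diameter_range = diameter_range,
                 alpha_values = alpha_values),
            class = "sweep_design")
}

#' Run a paired tethered/untethered parameter sweep
#'
#' For every Sobol point in (log10 D, diameter) space and every alpha regime,
#' runs two simulations that share identical per-molecule FBM noise (same
#' molecular seed) and differ only in whether whole-condensate rotation is
#' enabled. This side-by-side pairing isolates the bias introduced by the
#' lack of tethering.
#'
#' @param design a \code{\link{sweep_design}}.
#' @param base a \code{\link{sim_params}} giving the shared numerical
#'   settings (dt, n_steps, n_molecules, temperature, viscosity, seed, ...);
#'   its D, alpha, diameter and rotation flag are overridden per condition.
#' @param reduce optional function applied to each record (a list with
#'   \code{log10D}, \code{diameter}, \code{alpha}, \code{tethered},
#'   \code{untethered}) whose return value replaces the record; use it to
#'   summarise on the fly and avoid keeping every trajectory in memory.
#' @param n_condensates number of independent condensates per condition;
#'   \code{base$n_molecules} is split across them. With 1 (default) every
#'   molecule of a condition shares one rotation path, as in the original
#'   scheme; larger values average over condensate rotation histories the
#'   way experiments pooling many condensates do.
#' @return list of records (or reduced records), with the design and the
#'   Sobol points attached as attributes. With \code{n_condensates = 1} the
#'   \code{tethered}/\code{untethered} entries are \code{smt_condensate}
#'   objects; otherwise flat lists of trajectories pooled across
#'   condensates.
#' @export
run_sweep <- function(design, base, reduce = NULL, n_condensates = 1L) {
  stopifnot(inherits(design, "sweep_design"), inherits(base, "sim_params"))
  if (n_condensates < 1L) stop_domain("n_condensates must be >= 1")
  u <- sobol_2d(design$n_points)
  log10D <- design$log10D_range[1L] + u[, 1L] * diff(design$log10D_range)
  diam <- design$diameter_range[1L] + u[, 2L] * diff(design$diameter_range)
  records <- vector("list", design$n_points * length(design$alpha_values))
  k <- 0L
  for (i in seq_len(design$n_points)) {
    for (j in seq_along(design$alpha_values)) {
      k <- k + 1L
      seed_ij <- child_seed(base$seed, i * 131L + j)
      mk <- function(rot) {
        p <- base
        p$D <- 10^log10D[i]; p$alpha <- design$alpha_values[j]
        p$diameter <- diam[i]; p$rotation_enabled <- rot; p$seed <- seed_ij
        if (n_condensates == 1L) simulate_condensate(p)
        else simulate_condensates(p, n_condensates)
      }
      rec <- list(log10D = log10D[i], diameter = diam[i],
                  alpha = design$alpha_values[j],
                  tethered = mk(FALSE), untethered = mk(TRUE))
      records[[k]] <- if (is.null(reduce)) rec else reduce(rec)
    }
  }
  attr(records, "design") <- design
  attr(records, "points") <- cbind(log10D = log10D, diameter = diam)
  records
}

#' Simulate several independent condensates of one condition
#'
#' Splits \code{params$n_molecules} evenly over \code{n_condensates}
#' condensates with independent molecular noise and independent rotation
#' histories (seeds derived from \code{params$seed} by counter, so
#' tethered/untethered pairing per condensate still holds) and pools all
#' tracks.
#'
#' @param params a \code{\link{sim_params}}.
#' @param n_condensates number of condensates.
#' @return flat list of \code{smt_trajectory}.
#' @export
simulate_condensates <- function(params, n_condensates) {
  per <- max(1L, params$n_molecules %/% n_condensates)
  tracks <- list()
  for (k in seq_len(n_condensates)) {
    p <- params
    p$n_molecules <- per
    p$seed <- child_seed(params$seed, 7919L * k)
    s <- simulate_condensate(p)
    for (tr in s$tracks) {
      tr$track_id <- sprintf("c%d_%s", k, tr$track_id)
      tracks[[length(tracks) + 1L]] <- tr
    }
  }
  tracks
}
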