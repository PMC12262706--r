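# Trajectory container: one tracked particle as ordered (frame, t, x, y)
# samples in um / s. Deliberately a plain list-of-vectors (cheap to create in
# Monte Carlo loops) with a light S3 veneer.

#' Construct a trajectory
#'
#' @param track_id identifier (integer or character).
#' @param frames strictly increasing integer frame indices.
#' @param x,y coordinates in micrometres.
#' @param dt frame interval in seconds.
#' @param times sample times in seconds; defaults to \code{frames * dt}.
#' @param ground_truth optional named list carrying simulation provenance
#'   (D, alpha, diameter, rotation_enabled, ...).
#' @return an object of class \code{smt_trajectory}.
#' @export
trajectory <- function(track_id, frames, x, y, dt,
                       times = NULL, ground_truth = NULL) {
  frames <- as.integer(frames)
  if (length(frames) == 0L) stop_domain("trajectory must have >= 1 sample")
  if (any(diff(frames) <= 0L)) stop_domain("frames must be strictly increasing")
  if (length(x) != length(frames) || length(y) != length(frames))
    stop_domain("x, y and frames must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_domain("coordinates must be finite")
  assert_scalar_positive(dt, "dt")
  if (is.null(times)) times <- frames * dt
  structure(
    list(track_id = track_id, frames = frames, times = as.numeric(times),
         x = as.numeric(x), y = as.numeric(y), dt = dt,
         ground_truth = ground_truth),
    class = "smt_trajectory")
}

#' @export
print.smt_trajectory <- function(x, ...) {
  cat(sprintf("<smt_trajectory> id=%s, %d frames, dt=%g s\n",
              as.character(x$track_id), length(x$frames), x$dt))
  invisible(x)
}

#' @export
length.smt_trajectory <- function(x) length(x$frames)

#' Coerce a trajectory to a spot-table data frame
#'
#' One row per localisation, in the TrackMate-style dialect used by
#' \code{\link{write_spot_table}}.
#'
#' @param x an \code{smt_trajectory}.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @export
as.data.frame.smt_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(TRACK_ID = x$track_id, FRAME = x$frames,
             POSITION_X = x$x, POSITION_Y = x$y, POSITION_T = x$times)
}

n_frames <- function(traj) length(traj$frames)

#' Down-sample a trajectory in time
#'
#' Keeps every \code{factor}-th frame starting at the first, rescaling the
#' frame interval accordingly; mirrors the down-sampling of 20/100 ms
#' experimental movies to 200 ms for diffusion analysis.
#'
#' @param traj an \code{smt_trajectory}.
#' @param factor positive integer decimation factor; 1 is the identity.
#' @return the down-sampled \code{smt_trajectory} with \code{dt * factor}.
#' @export
downsample <- function(traj, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop_domain("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(traj)
  rel <- traj$frames - traj$frames[1L]
  keep <- rel %% factor == 0L
  trajectory(traj$track_id, frames = rel[keep] %/% factor,
             x = traj$x[keep], y = traj$y[keep], dt = traj$dt * factor,
             times = traj$times[keep], ground_truth = traj$ground_truth)
}
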