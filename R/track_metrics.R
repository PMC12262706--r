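# Per-track diffusion analysis: time-averaged MSD, anomalous-exponent and
# apparent-D fitting with motion-blur correction, step-size summaries, and
# the track filters applied before ensemble analysis.

#' Time-averaged MSD curve of a track
#'
#' Averages squared displacements over all ordered sample pairs at each
#' integer frame lag. Frame gaps are respected: pairs are matched on true
#' frame differences, so gapped tracks remain valid and lags are expressed in
#' seconds via the frame interval.
#'
#' @param traj an \code{smt_trajectory} with at least 2 samples.
#' @return an object of class \code{msd_curve}: data frame with columns
#'   \code{lag} (frames), \code{tau} (s), \code{msd} (um^2), \code{n_pairs}.
#' @export
compute_msd <- function(traj) {
  n <- n_frames(traj)
  if (n < 2L) stop_domain("MSD requires a track with >= 2 samples")
  rel <- traj$frames - traj$frames[1L]
  span <- rel[n]
  xs <- rep(NA_real_, span + 1L)
  ys <- rep(NA_real_, span + 1L)
  xs[rel + 1L] <- traj$x
  ys[rel + 1L] <- traj$y
  lags <- seq_len(span)
  msd <- numeric(span)
  npairs <- integer(span)
  for (k in lags) {
    d2 <- (xs[(k + 1L):(span + 1L)] - xs[1:(span + 1L - k)])^2 +
          (ys[(k + 1L):(span + 1L)] - ys[1:(span + 1L - k)])^2
    ok <- !is.na(d2)
    npairs[k] <- sum(ok)
    msd[k] <- if (npairs[k] > 0L) mean(d2[ok]) else NA_real_
  }
  keep <- npairs > 0L
  structure(data.frame(lag = lags[keep], tau = lags[keep] * traj$dt,
                       msd = msd[keep], n_pairs = npairs[keep]),
            class = c("msd_curve", "data.frame"))
}

# Fitting window: the first max(floor(track_length/2), 4) lags, following the
# half-length rule with a 4-point floor for short tracks.
fit_window <- function(msd, track_length) {
  n_use <- max(floor(track_length / 2), 4L)
  utils::head(seq_len(nrow(msd)), n_use)
}

#' Fit the anomalous exponent from an MSD curve
#'
#' Ordinary least squares of log MSD on log tau over the half-length lag
#' window: the slope is the apparent anomalous exponent alpha_app and the
#' intercept is log(2 n D) (n = 2 tracking dimensions). Lags with MSD = 0 are
#' dropped from the log domain; tracks with fewer than 4 usable lags fail.
#'
#' @param msd an \code{msd_curve}.
#' @param track_length track length in frames (controls the lag window).
#' @param r2_min minimum R-squared below which the fit is flagged
#'   (\code{alpha_rejected_r2}); default 0.7.
#' @param alpha_min exponents below this are flagged
#'   (\code{alpha_rejected_small}); default 0.01.
#' @return list with \code{alpha_app}, \code{r_squared}, \code{n_fit_points}
#'   and a character vector \code{status} of rejection flags (empty when the
#'   fit is accepted).
#' @export
fit_alpha <- function(msd, track_length, r2_min = 0.7, alpha_min = 0.01) {
  w <- fit_window(msd, track_length)
  m <- msd$msd[w]; tau <- msd$tau[w]
  ok <- m > 0
  if (sum(ok) < 4L)
    return(list(alpha_app = NA_real_, r_squared = NA_real_,
                n_fit_points = sum(ok), status = "fit_failed"))
  fit <- ols_line(log(tau[ok]), log(m[ok]))
  status <- character()
  if (is.na(fit$r2) || fit$r2 < r2_min) status <- c(status, "alpha_rejected_r2")
  if (fit$slope < alpha_min) status <- c(status, "alpha_rejected_small")
  list(alpha_app = fit$slope, r_squared = fit$r2,
       n_fit_points = sum(ok), status = status)
}

#' Fit the apparent diffusion coefficient with motion-blur correction
#'
#' Least-squares line \code{MSD = m tau + b} over the same lag window as
#' \code{\link{fit_alpha}}, inverted through the motion-blur model
#' \code{MSD = 2 n D tau + 2 sigma^2 - 4 D R tau}: for n = 2 dimensions and
#' continuous-exposure blur coefficient R = 1/6, \code{D_app = 3 m / 10} and
#' \code{sigma_loc = sqrt(b / 2)}. Negative intercepts clamp sigma to 0 with
#' a \code{dapp_negative_intercept} flag; non-positive slopes floor D_app at
#' \code{eps} with a \code{dapp_nonpositive_slope} flag so the value stays
#' usable under log transforms.
#'
#' @param msd an \code{msd_curve}.
#' @param track_length track length in frames; defaults to one more than the
#'   largest lag (gapless track).
#' @param R motion blur coefficient (1/6 for continuous imaging).
#' @param n_dim tracking dimension (2).
#' @param eps positive floor for D_app.
#' @return list with \code{D_app} (um^2/s), \code{sigma_loc} (um),
#'   \code{slope}, \code{intercept} and \code{status} flags.
#' @export
fit_dapp <- function(msd, track_length = max(msd$lag) + 1L, R = 1 / 6,
                     n_dim = 2L, eps = 1e-6) {
  w <- fit_window(msd, track_length)
  if (length(w) < 2L)
    return(list(D_app = NA_real_, sigma_loc = NA_real_, slope = NA_real_,
                intercept = NA_real_, status = "fit_failed"))
  fit <- ols_line(msd$tau[w], msd$msd[w])
  status <- character()
  denom <- 2 * n_dim - 4 * R
  D <- fit$slope / denom
  if (!is.finite(D) || D <= 0) {
    D <- eps
    status <- c(status, "dapp_nonpositive_slope")
  } else if (D < eps) {
    D <- eps
    status <- c(status, "dapp_floored")
  }
  if (is.finite(fit$intercept) && fit$intercept >= 0) {
    sigma <- sqrt(fit$intercept / 2)
  } else {
    sigma <- 0
    status <- c(status, "dapp_negative_intercept")
  }
  list(D_app = D, sigma_loc = sigma, slope = fit$slope,
       intercept = fit$intercept, status = status)
}

#' Step-size and fluctuation summary of a track
#'
#' Frame-to-frame displacement magnitudes (consecutive samples only) reported
#' in nanometres, plus the start-to-end displacement in micrometres.
#'
#' @param traj an \code{smt_trajectory} with >= 2 samples.
#' @return list with \code{mean_step_nm}, \code{avg_fluct_nm},
#'   \code{max_fluct_nm}, \code{total_displacement_um}, \code{track_length}.
#' @export
track_summary <- function(traj) {
  n <- n_frames(traj)
  if (n < 2L) stop_domain("track_summary requires >= 2 samples")
  steps_um <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  list(mean_step_nm = mean(steps_um) * 1e3,
       avg_fluct_nm = mean(steps_um) * 1e3,
       max_fluct_nm = max(steps_um) * 1e3,
       total_displacement_um =
         sqrt((traj$x[n] - traj$x[1L])^2 + (traj$y[n] - traj$y[1L])^2),
       track_length = n)
}

#' Per-track metrics table
#'
#' Runs \code{\link{compute_msd}}, \code{\link{fit_alpha}},
#' \code{\link{fit_dapp}} and \code{\link{track_summary}} on every track and
#' assembles one row per track. This is the table consumed by
#' \code{\link{filter_tracks}} and the sweep analysis.
#'
#' @param tracks list of \code{smt_trajectory} (or an \code{smt_condensate}).
#' @param r2_min,alpha_min,R,n_dim,eps passed to the fitting functions.
#' @return data frame with columns \code{track_id}, \code{n_frames},
#'   \code{mean_step_nm}, \code{avg_fluct_nm}, \code{max_fluct_nm},
#'   \code{total_displacement_um}, \code{alpha_app}, \code{r_squared},
#'   \code{D_app}, \code{log10_Dapp}, \code{sigma_nm} and the flag columns
#'   \code{alpha_ok}, \code{dapp_flags}.
#' @export
analyze_tracks <- function(tracks, r2_min = 0.7, alpha_min = 0.01, R = 1 / 6,
                           n_dim = 2L, eps = 1e-6) {
  if (inherits(tracks, "smt_condensate")) tracks <- tracks$tracks
  # column-wise accumulation: building one data.frame per track is too slow
  # for sweep-scale inputs (tens of thousands of tracks)
  rows <- lapply(tracks, function(tr) {
    s <- track_summary(tr)
    msd <- compute_msd(tr)
    fa <- fit_alpha(msd, s$track_length, r2_min, alpha_min)
    fd <- fit_dapp(msd, s$track_length, R, n_dim, eps)
    list(id = as.character(tr$track_id), n = s$track_length,
         ms = s$mean_step_nm, af = s$avg_fluct_nm, mf = s$max_fluct_nm,
         td = s$total_displacement_um, a = fa$alpha_app, r2 = fa$r_squared,
         D = fd$D_app, sig = fd$sigma_loc * 1e3,
         aok = length(fa$status) == 0L,
         dfl = paste(fd$status, collapse = ";"))
  })
  g <- function(f, mode) vapply(rows, `[[`, vector(mode, 1L), f)
  data.frame(track_id = g("id", "character"),
             n_frames = g("n", "integer"),
             mean_step_nm = g("ms", "numeric"),
             avg_fluct_nm = g("af", "numeric"),
             max_fluct_nm = g("mf", "numeric"),
             total_displacement_um = g("td", "numeric"),
             alpha_app = g("a", "numeric"),
             r_squared = g("r2", "numeric"),
             D_app = g("D", "numeric"),
             log10_Dapp = log10(g("D", "numeric")),
             sigma_nm = g("sig", "numeric"),
             alpha_ok = g("aok", "logical"),
             dapp_flags = g("dfl", "character"),
             stringsAsFactors = FALSE)
}

#' Filter a per-track metrics table
#'
#' Named filter profiles mirroring the analysis pipeline:
#' \describe{
#'   \item{\code{ensemble_msd}}{length >= \code{min_length} frames,
#'     \code{log10_Dapp} above the static-error threshold, and start-to-end
#'     displacement >= \code{min_total_disp} um (mobility rules applied
#'     before ensemble MSD averaging).}
#'   \item{\code{alpha}}{mean step >= \code{min_mean_step_nm} nm, fit
#'     R-squared >= \code{r2_min} and alpha_app >= \code{alpha_min}
#'     (rules applied before reporting exponent distributions).}
#'   \item{\code{stepsize}}{all tracks with >= 2 frames.}
#' }
#' The static-error threshold is \code{log10(sigma_static^2 / (2 dt))}
#' derived from a stationary-fixture calibration \code{sigma_static}; its
#' value is recorded in the audit attribute. Rules are conjunctive, so the
#' surviving set is independent of rule order.
#'
#' @param metrics data frame from \code{\link{analyze_tracks}}.
#' @param profile one of \code{"ensemble_msd"}, \code{"alpha"},
#'   \code{"stepsize"}.
#' @param dt frame interval in seconds (needed for the static threshold).
#' @param sigma_static_nm static localization error calibration, nm.
#' @param min_length,min_total_disp,min_mean_step_nm,r2_min,alpha_min rule
#'   thresholds.
#' @return the surviving subset of \code{metrics}, with an \code{audit}
#'   attribute: data frame of per-rule removal counts plus the threshold
#'   values used.
#' @export
filter_tracks <- function(metrics,
                          profile = c("ensemble_msd", "alpha", "stepsize"),
                          dt = 0.05, sigma_static_nm = 30,
                          min_length = 10L, min_total_disp = 0.2,
                          min_mean_step_nm = 30, r2_min = 0.7,
                          alpha_min = 0.01) {
  profile <- match.arg(profile)
  static_threshold <- log10((sigma_static_nm * 1e-3)^2 / (2 * dt))
  rules <- switch(profile,
    ensemble_msd = list(
      min_length = metrics$n_frames >= min_length,
      static_error = metrics$log10_Dapp > static_threshold,
      min_displacement = metrics$total_displacement_um >= min_total_disp),
    alpha = list(
      min_mean_step = metrics$mean_step_nm >= min_mean_step_nm,
      r_squared = !is.na(metrics$r_squared) & metrics$r_squared >= r2_min,
      alpha_min = !is.na(metrics$alpha_app) & metrics$alpha_app >= alpha_min),
    stepsize = list(min_two_frames = metrics$n_frames >= 2L))
  pass <- Reduce(`&`, lapply(rules, function(r) !is.na(r) & r))
  audit <- data.frame(
    rule = names(rules),
    n_removed = vapply(rules, function(r) sum(!(!is.na(r) & r)),
                       integer(1)),
    row.names = NULL)
  out <- metrics[pass, , drop = FALSE]
  attr(out, "audit") <- audit
  attr(out, "static_threshold_log10D") <- static_threshold
  attr(out, "profile") <- profile
  out
}

#' Ensemble-averaged MSD across tracks
#'
#' Lag-wise mean and standard error of the time-averaged MSD over a filtered
#' track set, restricted to the lag set common to all tracks.
#'
#' @param tracks nonempty list of \code{smt_trajectory}.
#' @return data frame with \code{lag}, \code{tau}, \code{mean_msd},
#'   \code{sem}, \code{n}; with a single track the SEM is 0 by convention and
#'   the result carries attribute \code{n1_flag = TRUE}.
#' @export
ensemble_msd <- function(tracks) {
  if (inherits(tracks, "smt_condensate")) tracks <- tracks$tracks
  if (length(tracks) == 0L) stop_domain("ensemble_msd needs >= 1 track")
  curves <- lapply(tracks, compute_msd)
  common <- Reduce(intersect, lapply(curves, function(cv) cv$lag))
  if (length(common) == 0L) stop_domain("tracks share no common lag")
  dt <- tracks[[1L]]$dt
  mat <- vapply(curves, function(cv) cv$msd[match(common, cv$lag)],
                numeric(length(common)))
  mat <- matrix(mat, nrow = length(common))
  n <- ncol(mat)
  out <- data.frame(lag = common, tau = common * dt,
                    mean_msd = rowMeans(mat),
                    sem = if (n > 1L) apply(mat, 1L, stats::sd) / sqrt(n)
                          else rep(0, length(common)),
                    n = n)
  attr(out, "n1_flag") <- n == 1L
  out
}
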