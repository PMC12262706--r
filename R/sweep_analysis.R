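# Turns paired tethered/untethered sweep simulations into bias heatmaps
# and the tethering-necessity guideline.

#' Untethered/tethered bias ratio of apparent metrics
#'
#' Ratio of the per-condition median apparent diffusion coefficient and of
#' the median apparent anomalous exponent, untethered over tethered. Fits
#' are filtered before summarising; by default only the fit-quality rules
#' are applied (\code{profile = "sim"}: R-squared and minimum-alpha, plus
#' valid-fit status), because simulated tracks carry no localization noise
#' and the experimental mobility rules (30 nm mean step, static-error
#' threshold) would empty the slow-D conditions the sweep is designed to
#' probe. \code{profile = "standard"} applies the experimental \code{alpha}
#' and \code{ensemble_msd} profiles of \code{\link{filter_tracks}} instead.
#'
#' @param tethered_fits,untethered_fits per-track metric tables from
#'   \code{\link{analyze_tracks}} for the paired condition.
#' @param profile \code{"sim"} (default) or \code{"standard"}.
#' @param r2_min,alpha_min fit-quality thresholds.
#' @param dt frame interval (s), used by the standard profile thresholds.
#' @return list with \code{ratio_Dapp}, \code{ratio_alpha}, \code{n_teth},
#'   \code{n_unteth} and \code{missing} (TRUE when either side has no
#'   surviving tracks; ratios are NA then, never silently 1).
#' @export
bias_ratio <- function(tethered_fits, untethered_fits,
                       profile = c("sim", "standard"),
                       r2_min = 0.7, alpha_min = 0.01, dt = 0.05) {
  profile <- match.arg(profile)
  keep <- function(df, prof) {
    if (profile == "sim") {
      ok <- !is.na(df$alpha_app) & !is.na(df$r_squared) &
        df$r_squared >= r2_min & df$alpha_app >= alpha_min
      df[ok, , drop = FALSE]
    } else {
      filter_tracks(df, prof, dt = dt, r2_min = r2_min, alpha_min = alpha_min)
    }
  }
  ta <- keep(tethered_fits, "alpha"); ua <- keep(untethered_fits, "alpha")
  td <- if (profile == "sim") ta else keep(tethered_fits, "ensemble_msd")
  ud <- if (profile == "sim") ua else keep(untethered_fits, "ensemble_msd")
  missing <- nrow(ta) == 0L || nrow(ua) == 0L || nrow(td) == 0L || nrow(ud) == 0L
  list(
    ratio_Dapp = if (missing) NA_real_ else
      stats::median(ud$D_app) / stats::median(td$D_app),
    ratio_alpha = if (missing) NA_real_ else
      stats::median(ua$alpha_app) / stats::median(ta$alpha_app),
    n_teth = nrow(ta), n_unteth = nrow(ua), missing = missing)
}

#' Summarise a paired sweep into per-point bias ratios
#'
#' Fits every trajectory of every tethered/untethered pair and computes the
#' per-point \code{\link{bias_ratio}}. Accepts the raw records of
#' \code{\link{run_sweep}} or records already reduced to
#' \code{tethered_fits}/\code{untethered_fits} tables.
#'
#' @param sweep list of records from \code{\link{run_sweep}}.
#' @param ... passed to \code{\link{bias_ratio}}.
#' @return long-format data frame: \code{log10D}, \code{diameter},
#'   \code{alpha}, \code{ratio_Dapp}, \code{ratio_alpha}, \code{n_teth},
#'   \code{n_unteth}.
#' @export
analyze_sweep <- function(sweep, ...) {
  rows <- lapply(sweep, function(rec) {
    tf <- rec$tethered_fits %||% analyze_tracks(rec$tethered)
    uf <- rec$untethered_fits %||% analyze_tracks(rec$untethered)
    br <- bias_ratio(tf, uf, ...)
    data.frame(log10D = rec$log10D, diameter = rec$diameter,
               alpha = rec$alpha, ratio_Dapp = br$ratio_Dapp,
               ratio_alpha = br$ratio_alpha, n_teth = br$n_teth,
               n_unteth = br$n_unteth)
  })
  do.call(rbind, rows)
}

#' Bin sweep bias ratios onto a regular grid
#'
#' Maps the Sobol points onto a regular (log10 D, diameter) grid. With the
#' default nearest-neighbour assignment each point contributes to the cell
#' containing it and cell values are medians of their member points;
#' \code{method = "idw"} fills every cell by inverse-distance weighting of
#' all points instead. Cells without support under nearest-neighbour
#' assignment stay NA and are flagged, never silently filled with 1.
#'
#' @param summaries data frame from \code{\link{analyze_sweep}} (one alpha
#'   regime at a time; filter first or pass \code{alpha_regime}).
#' @param alpha_regime keep only rows with this alpha (default: the single
#'   alpha present; error if mixed and unspecified).
#' @param n_bins grid size per axis (default 5).
#' @param method \code{"nearest"} or \code{"idw"}.
#' @return object of class \code{bias_grid}: list with \code{log10D_axis},
#'   \code{diameter_axis} (cell centres, ascending), matrices
#'   \code{ratio_Dapp}, \code{ratio_alpha}, \code{n} (points per cell),
#'   \code{alpha_regime}, \code{missing} (logical matrix).
#' @export
build_heatmap <- function(summaries, alpha_regime = NULL, n_bins = 5L,
                          method = c("nearest", "idw")) {
  method <- match.arg(method)
  if (is.null(alpha_regime)) {
    av <- unique(summaries$alpha)
    if (length(av) != 1L)
      stop_domain("summaries contain several alpha regimes; pick one")
    alpha_regime <- av
  }
  s <- summaries[summaries$alpha == alpha_regime &
                   stats::complete.cases(summaries[, c("ratio_Dapp",
                                                       "ratio_alpha")]), ,
                 drop = FALSE]
  if (nrow(s) == 0L) stop_domain("no valid sweep points for this regime")
  brk <- function(v) {
    if (nrow(s) == 1L) return(c(v[1L] - 0.5, v[1L] + 0.5))
    seq(min(v), max(v), length.out = n_bins + 1L)
  }
  bx <- brk(s$log10D); by <- brk(s$diameter)
  nbx <- length(bx) - 1L; nby <- length(by) - 1L
  cut_idx <- function(v, b) pmin(pmax(findInterval(v, b,
                                                   rightmost.closed = TRUE),
                                      1L), length(b) - 1L)
  ix <- cut_idx(s$log10D, bx); iy <- cut_idx(s$diameter, by)
  rd <- matrix(NA_real_, nbx, nby)
  ra <- matrix(NA_real_, nbx, nby)
  nn <- matrix(0L, nbx, nby)
  ctr <- function(b) (utils::head(b, -1L) + utils::tail(b, -1L)) / 2
  cx <- ctr(bx); cy <- ctr(by)
  if (method == "nearest") {
    for (i in seq_len(nbx)) for (j in seq_len(nby)) {
      in_cell <- ix == i & iy == j
      nn[i, j] <- sum(in_cell)
      if (nn[i, j] > 0L) {
        rd[i, j] <- stats::median(s$ratio_Dapp[in_cell])
        ra[i, j] <- stats::median(s$ratio_alpha[in_cell])
      }
    }
  } else {
    sx <- diff(range(s$log10D)) %||% 1
    sy <- diff(range(s$diameter)) %||% 1
    for (i in seq_len(nbx)) for (j in seq_len(nby)) {
      d2 <- ((s$log10D - cx[i]) / max(sx, 1e-12))^2 +
            ((s$diameter - cy[j]) / max(sy, 1e-12))^2
      wgt <- 1 / pmax(d2, 1e-12)
      rd[i, j] <- sum(wgt * s$ratio_Dapp) / sum(wgt)
      ra[i, j] <- sum(wgt * s$ratio_alpha) / sum(wgt)
      nn[i, j] <- nrow(s)
    }
  }
  structure(list(log10D_axis = cx, diameter_axis = cy, ratio_Dapp = rd,
                 ratio_alpha = ra, n = nn, alpha_regime = alpha_regime,
                 missing = is.na(rd)),
            class = "bias_grid")
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("<bias_grid> alpha=%g, %d x %d cells (%d populated)\n",
              x$alpha_regime, nrow(x$ratio_Dapp), ncol(x$ratio_Dapp),
              sum(!x$missing)))
  invisible(x)
}

#' Plot a bias heatmap
#'
#' Diverging scale centred at a ratio of 1: red = overestimation under the
#' lack of tethering, blue = underestimation.
#'
#' @param x a \code{bias_grid}.
#' @param metric \code{"ratio_Dapp"} or \code{"ratio_alpha"}.
#' @param ... passed to \code{image}.
#' @export
plot.bias_grid <- function(x, metric = c("ratio_Dapp", "ratio_alpha"), ...) {
  metric <- match.arg(metric)
  z <- log2(x[[metric]])
  lim <- max(abs(z), na.rm = TRUE)
  graphics::image(x$log10D_axis, x$diameter_axis, z,
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(33, "Blue-Red 2"),
                  xlab = expression(log[10] ~ D ~ (mu * m^2 / s)),
                  ylab = expression(diameter ~ (mu * m)),
                  main = sprintf("%s (alpha = %g)", metric, x$alpha_regime),
                  ...)
  invisible(x)
}

#' Tethering-necessity guideline check
#'
#' Labels each populated cell unbiased when \code{|ratio - 1| <= tolerance}
#' for both metrics, and reports (a) the fraction of cells with diameter
#' above \code{large_diameter} that are unbiased, and (b) the bias frontier:
#' for each log10 D row, the smallest diameter from which all larger-
#' diameter cells in that row are unbiased. Physically the frontier should
#' be non-increasing in D (faster molecules outrun the condensate motion at
#' smaller sizes).
#'
#' @param grid a \code{bias_grid}.
#' @param tolerance relative tolerance on the ratio (default 0.10).
#' @param large_diameter diameter cut for the headline fraction (2 um).
#' @return list with \code{cell_unbiased} (logical matrix, NA = missing),
#'   \code{fraction_unbiased_large}, \code{frontier} (data frame log10D,
#'   frontier_diameter), \code{frontier_monotone}.
#' @export
guideline_check <- function(grid, tolerance = 0.10, large_diameter = 2) {
  stopifnot(inherits(grid, "bias_grid"))
  if (all(grid$missing)) stop_domain("grid has no populated cells")
  unb <- abs(grid$ratio_Dapp - 1) <= tolerance &
         abs(grid$ratio_alpha - 1) <= tolerance
  large <- grid$diameter_axis > large_diameter
  frac <- if (any(large)) mean(unb[, large], na.rm = TRUE) else NA_real_
  frontier <- vapply(seq_along(grid$log10D_axis), function(i) {
    row <- unb[i, ]
    ok <- which(!is.na(row))
    if (length(ok) == 0L) return(NA_real_)
    # smallest diameter whose populated tail is entirely unbiased
    for (j in ok) {
      tail_ok <- ok[ok >= j]
      if (all(row[tail_ok])) return(grid$diameter_axis[j])
    }
    Inf
  }, numeric(1))
  fr <- frontier[!is.na(frontier)]          # keep Inf (= never unbiased) rows
  dfr <- diff(fr)
  monotone <- length(fr) < 2L ||
    all(dfr <= .Machine$double.eps^0.5 | is.nan(dfr)) # Inf -> Inf diffs are NaN

  list(cell_unbiased = unb, fraction_unbiased_large = frac,
       frontier = data.frame(log10D = grid$log10D_axis,
                             frontier_diameter = frontier),
       frontier_monotone = monotone)
}
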