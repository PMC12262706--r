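# Fractional Gaussian noise (FGN) generation.
#
# Molecular motion is modelled per axis as fractional Brownian motion with
# Hurst exponent H = alpha/2, so that the ensemble 2D MSD obeys
# MSD(tau) = 4 D tau^alpha with tau in seconds (D in um^2/s^alpha).
# Increments on the regular grid dt are stationary Gaussians with the exact
# FGN autocovariance; we synthesise them either by Cholesky factorisation of
# the (small) covariance matrix, which is exact, or by circulant embedding
# (Davies-Harte) for long tracks.

# FGN autocovariance at lags 0..nlag for grid spacing dt (unit-amplitude FBM).
fgn_gamma <- function(H, nlag, dt) {
  k <- 0:nlag
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H)) *
    dt^(2 * H)
}

# Cache of Cholesky factors keyed by (H, n, dt): within one simulation all
# molecules share the factor, so the O(n^3) factorisation happens once.
.fbm_cache <- new.env(parent = emptyenv())

fgn_chol_factor <- function(H, n, dt) {
  key <- paste(format(H, digits = 17), n, format(dt, digits = 17), sep = "|")
  got <- .fbm_cache[[key]]
  if (!is.null(got)) return(got)
  R <- chol(stats::toeplitz(fgn_gamma(H, n - 1, dt)[seq_len(n)]))
  .fbm_cache[[key]] <- R
  R
}

#' Sample fractional Gaussian noise paths
#'
#' Draws stationary FGN increment vectors for fractional Brownian motion with
#' Hurst exponent \code{H} on a regular grid of spacing \code{dt}. Cumulative
#' sums of the returned columns are standard FBM paths with
#' \code{Var(B(k dt)) = (k dt)^(2H)}.
#'
#' @param n number of increments per path.
#' @param H Hurst exponent in (0, 1).
#' @param dt grid spacing in seconds.
#' @param n_paths number of independent paths (columns).
#' @param method \code{"chol"} (exact, default for short tracks),
#'   \code{"davies-harte"} (circulant embedding, default above 256 steps) or
#'   \code{"auto"}.
#' @return numeric matrix \code{n x n_paths} of increments. Uses the R RNG
#'   stream, so results are reproducible under \code{set.seed}.
#' @export
fgn_sample <- function(n, H, dt, n_paths = 1L,
                       method = c("auto", "chol", "davies-harte")) {
  method <- match.arg(method)
  if (!is.numeric(H) || length(H) != 1L || H <= 0 || H >= 1)
    stop_domain("H must lie in (0, 1): got ", H)
  assert_scalar_positive(dt, "dt")
  if (n < 1) stop_domain("n must be >= 1")
  if (method == "auto") method <- if (n <= 256) "chol" else "davies-harte"
  if (method == "chol") {
    R <- fgn_chol_factor(H, n, dt)
    crossprod(R, matrix(stats::rnorm(n * n_paths), n, n_paths))
  } else {
    fgn_davies_harte(n, H, dt, n_paths)
  }
}

# Circulant embedding sampler. The embedding of the FGN covariance is
# nonnegative definite for all H in (0,1); tiny negative eigenvalues from
# floating point roundoff are clipped to zero.
fgn_davies_harte <- function(n, H, dt, n_paths) {
  m <- 2^ceiling(log2(2 * n))
  half <- m / 2
  g <- fgn_gamma(H, half, dt)
  row1 <- c(g, g[half:2])                      # circulant first row, length m
  lam <- Re(stats::fft(row1))
  lam[lam < 0] <- 0
  out <- matrix(0, n, n_paths)
  for (j in seq_len(n_paths)) {
    z1 <- stats::rnorm(half - 1)
    z2 <- stats::rnorm(half - 1)
    w <- complex(length.out = m)
    w[1] <- sqrt(lam[1] / m) * stats::rnorm(1)
    w[half + 1] <- sqrt(lam[half + 1] / m) * stats::rnorm(1)
    w[2:half] <- sqrt(lam[2:half] / (2 * m)) * complex(real = z1, imaginary = z2)
    w[m:(half + 2)] <- Conj(w[2:half])
    out[, j] <- Re(stats::fft(w))[seq_len(n)]
  }
  out
}
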