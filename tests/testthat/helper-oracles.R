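# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle deliberately shares no code with the functions it
# checks.

make_traj <- function(x, y, dt = 1, frames = seq_along(x) - 1L, id = 1L) {
  trajectory(id, frames = frames, x = x, y = y, dt = dt)
}

# O(n^2) double-loop time-averaged MSD (gap-aware, matched on frame diffs)
brute_msd <- function(traj) {
  n <- length(traj$frames)
  recs <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- traj$frames[j] - traj$frames[i]
    d2 <- (traj$x[j] - traj$x[i])^2 + (traj$y[j] - traj$y[i])^2
    recs[[length(recs) + 1L]] <- c(k, d2)
  }
  m <- do.call(rbind, recs)
  lags <- sort(unique(m[, 1]))
  data.frame(lag = lags,
             msd = vapply(lags, function(k) mean(m[m[, 1] == k, 2]),
                          numeric(1)),
             n_pairs = vapply(lags, function(k) sum(m[, 1] == k),
                              integer(1)))
}

# Exhaustive pair counting for U and Cliff's delta
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}
brute_delta <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# Brute-force convex hull area for <= 10 points: a point is a hull vertex
# iff it is not strictly inside (or on the boundary of) the triangle of any
# three other points; vertices are then ordered by angle about the centroid
# and the polygon area taken by the shoelace formula.
brute_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  tri_contains <- function(a, b, c, p) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 >= -1e-12 && s2 >= -1e-12 && s3 >= -1e-12) ||
      (s1 <= 1e-12 && s2 <= 1e-12 && s3 <= 1e-12)
  }
  is_vertex <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    if (length(others) < 3) next
    combs <- utils::combn(others, 3)
    for (c_ in seq_len(ncol(combs))) {
      a <- pts[combs[1, c_], ]; b <- pts[combs[2, c_], ]
      cc <- pts[combs[3, c_], ]
      inside <- tri_contains(a, b, cc, pts[p, ]) &&
        !any(apply(rbind(a, b, cc), 1, function(v)
          isTRUE(all.equal(unname(v), unname(pts[p, ])))))
      if (inside) { is_vertex[p] <- FALSE; break }
    }
    if (!is_vertex[p]) next
  }
  v <- pts[is_vertex, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  ord <- order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1]))
  v <- v[ord, , drop = FALSE]
  j <- c(2:nrow(v), 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Noise-free MSD curve following the fitting model exactly
model_msd <- function(D, alpha, lags, dt, sigma = 0, R = 1 / 6, n_dim = 2) {
  tau <- lags * dt
  if (alpha == 1) {
    msd <- 2 * n_dim * D * tau + 2 * sigma^2 - 4 * D * R * tau
  } else {
    msd <- 2 * n_dim * D * tau^alpha
  }
  structure(data.frame(lag = lags, tau = tau, msd = msd,
                       n_pairs = rev(seq_along(lags))),
            class = c("msd_curve", "data.frame"))
}
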