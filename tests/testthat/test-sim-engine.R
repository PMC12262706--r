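# Simulation engine: Stokes-Einstein rate, FBM scaling, rigid rotation,
# tethered/untethered pairing, Sobol sweep bookkeeping.

test_that("rotational_diffusivity matches direct arithmetic and r^-3 scaling", {
  # direct evaluation of kB*T/(4 pi eta r^3), kB = 1.380649e-23
  expect_equal(rotational_diffusivity(0.5, 298, 0.005), 0.5238533,
               tolerance = 1e-6)
  expect_equal(rotational_diffusivity(2.5, 298, 0.005), 4.190827e-3,
               tolerance = 1e-6)
  expect_equal(rotational_diffusivity(1.0), rotational_diffusivity(0.5) / 8)
  r <- c(0.3, 0.7, 1.4, 3)
  w <- vapply(r, rotational_diffusivity, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(rotational_diffusivity(-1), "positive")
  expect_error(rotational_diffusivity(1, temperature = 0), "positive")
})

test_that("sim_params validates its domain", {
  expect_error(sim_params(D = -1), "D must")
  expect_error(sim_params(D = 1, alpha = 2), "alpha")
  expect_error(sim_params(D = 1, dt = 0), "dt")
  expect_error(sim_params(D = 1, n_steps = 1), "n_steps")
  p <- sim_params(D = 0.1, seed = 7)
  expect_s3_class(p, "sim_params")
})

test_that("zero diffusion gives frozen tracks; D>0 FBM has the right MSD", {
  p0 <- sim_params(D = 0, alpha = 0.5, n_steps = 10, n_molecules = 3,
                   rotation_enabled = FALSE, seed = 1)
  s <- simulate_condensate(p0)
  for (tr in s$tracks) {
    expect_true(all(tr$x == tr$x[1]))
    expect_true(all(tr$y == tr$y[1]))
  }
  # ensemble MSD at lag 1 for alpha = 1: 4 D dt
  n <- 6000
  set.seed(11)
  inc <- fgn_sample(1, H = 0.5, dt = 0.05, n_paths = n) * sqrt(2 * 0.1)
  inc2 <- fgn_sample(1, H = 0.5, dt = 0.05, n_paths = n) * sqrt(2 * 0.1)
  msd1 <- mean(inc^2 + inc2^2)
  expect_equal(msd1, 4 * 0.1 * 0.05, tolerance = 0.05)
})

test_that("FBM scaling: log-log ensemble MSD slope is within 3 SE of alpha", {
  for (alpha in c(0.5, 1.0)) {
    p <- sim_params(D = 0.05, alpha = alpha, n_steps = 16,
                    n_molecules = 1500, rotation_enabled = FALSE, seed = 42)
    s <- simulate_condensate(p)
    X <- vapply(s$tracks, `[[`, numeric(17), "x")
    Y <- vapply(s$tracks, `[[`, numeric(17), "y")
    lags <- 1:8
    msd <- vapply(lags, function(k)
      mean((X[k + 1, ] - X[1, ])^2 + (Y[k + 1, ] - Y[1, ])^2), numeric(1))
    fit <- summary(lm(log(msd) ~ log(lags * p$dt)))
    slope <- fit$coefficients[2, 1]
    se <- fit$coefficients[2, 2]
    # sampling error on the ensemble estimate dominates the regression SE
    expect_equal(slope, alpha, tolerance = 0.05)
    expect_lt(abs(slope - alpha), max(3 * se, 0.05))
  }
})

test_that("apply_rotation_step is an exact rigid rotation", {
  pos <- cbind(c(1, 0, -0.3), c(0, 2, 0.7))
  out <- apply_rotation_step(pos, c(0, 0), omega = 0.5, dt = 0.05,
                             theta = 0.3)
  # radii conserved exactly
  expect_equal(sqrt(rowSums(out^2)), sqrt(rowSums(pos^2)))
  # pairwise angles conserved (rigid-body property)
  ang <- function(m) atan2(m[, 2], m[, 1])
  expect_equal(diff(ang(out)) %% (2 * pi), diff(ang(pos)) %% (2 * pi))
  # omega = 0 is the identity
  id <- apply_rotation_step(pos, c(0, 0), omega = 0, dt = 0.05)
  expect_equal(id[, 1:2], pos[, 1:2], ignore_attr = TRUE)
  expect_error(apply_rotation_step(pos, c(0, 0), omega = 1, dt = 0),
               "dt")
})

test_that("frozen molecules under rotation keep exact radii and the stated
           angle variance", {
  p <- sim_params(D = 0, diameter = 1, n_steps = 30, n_molecules = 20,
                  rotation_enabled = TRUE, seed = 5,
                  theta_model = "diffusive", rotation_geometry = "exact")
  s <- simulate_condensate(p)
  d0 <- sqrt(s$tracks[[1]]$x^2 + s$tracks[[1]]$y^2)
  expect_equal(d0, rep(d0[1], length(d0)), tolerance = 1e-12)
  # multiset of distances-to-center invariant across the whole simulation
  dists <- vapply(s$tracks, function(tr) sqrt(tr$x^2 + tr$y^2),
                  numeric(31))
  expect_equal(apply(dists, 2, max) - apply(dists, 2, min),
               rep(0, 20), tolerance = 1e-12)
  # cumulative drawn-angle variance ~ 2 omega dt k under the diffusive model
  k <- 30
  reps <- 400
  omega <- s$omega
  finals <- vapply(seq_len(reps), function(i) {
    pp <- p; pp$seed <- i + 1000L
    sum(simulate_condensate(pp)$rotation_angles)
  }, numeric(1))
  expect_equal(var(finals), 2 * omega * p$dt * k,
               tolerance = 3 * sqrt(2 / reps) * 1.2)
})

test_that("tethered output is a deterministic function of the molecular seed", {
  mk <- function(rot, seed) {
    p <- sim_params(D = 0.02, alpha = 0.8, n_steps = 12, n_molecules = 8,
                    rotation_enabled = rot, seed = seed)
    simulate_condensate(p)
  }
  a <- mk(FALSE, 9); b <- mk(FALSE, 9)
  expect_identical(lapply(a$tracks, `[[`, "x"), lapply(b$tracks, `[[`, "x"))
  # an untethered run in between must not perturb a later tethered run:
  # rotation draws live on their own child stream
  u <- mk(TRUE, 9)
  c2 <- mk(FALSE, 9)
  expect_identical(lapply(a$tracks, `[[`, "y"), lapply(c2$tracks, `[[`, "y"))
  expect_false(identical(lapply(a$tracks, `[[`, "x"),
                         lapply(u$tracks, `[[`, "x")))
  # generate_fbm_track reproducibility
  t1 <- generate_fbm_track(sim_params(D = 0.1, seed = 4), seed = 77)
  t2 <- generate_fbm_track(sim_params(D = 0.1, seed = 4), seed = 77)
  expect_identical(t1$x, t2$x)
})

test_that("rotation adds displacement for slow molecules (paired seeds)", {
  p <- sim_params(D = 0.001, alpha = 0.5, diameter = 0.5, n_molecules = 150,
                  seed = 21, rotation_enabled = FALSE)
  teth <- simulate_condensate(p)
  p$rotation_enabled <- TRUE
  unteth <- simulate_condensate(p)
  ms <- function(s) vapply(s$tracks, function(tr)
    mean(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), numeric(1))
  expect_gt(mean(ms(unteth) > ms(teth)), 0.9)
  expect_gt(median(ms(unteth)) / median(ms(teth)), 1)
})

test_that("sobol_2d is deterministic, well spread, and run_sweep pairs runs", {
  u1 <- sobol_2d(64); u2 <- sobol_2d(64)
  expect_identical(u1, u2)
  expect_true(all(u1 >= 0 & u1 < 1))
  # (0,1)-sequence stratification: the first full 2^6 block (skip = 0)
  # hits every 8x8 box exactly once
  u0 <- sobol_2d(64, skip = 0)
  boxes <- table(floor(u0[, 1] * 8), floor(u0[, 2] * 8))
  expect_true(all(boxes == 1))
  d <- sweep_design(n_points = 1, alpha_values = c(1, 0.5))
  base <- sim_params(D = 0.1, n_molecules = 4, n_steps = 6, seed = 2)
  sw <- run_sweep(d, base)
  expect_length(sw, 2)                    # n_points * |alpha_values|
  rec <- sw[[1]]
  expect_s3_class(rec$tethered, "smt_condensate")
  expect_false(rec$tethered$params$rotation_enabled)
  expect_true(rec$untethered$params$rotation_enabled)
  # paired molecular noise: tethered coordinates are embedded in the
  # untethered run up to the (shared-angle) rotation, so frame-0 positions
  # agree exactly
  expect_equal(rec$tethered$tracks[[1]]$x[1], rec$untethered$tracks[[1]]$x[1])
})

test_that("circulant-embedding FGN matches theory for long tracks", {
  set.seed(61)
  n <- 300; H <- 0.3; dt <- 0.05
  inc <- fgn_sample(n, H, dt, n_paths = 400, method = "davies-harte")
  expect_equal(dim(inc), c(300, 400))
  # empirical autocovariance matches the FGN covariance at the first lags
  # (lag-wise averages over n*paths terms have low estimator variance; the
  # variance of long-lag sums does not and is not asserted)
  emp <- vapply(0:3, function(k)
    mean(inc[1:(n - k), ] * inc[(1 + k):n, ]), numeric(1))
  theo <- tetherSMT:::fgn_gamma(H, 3, dt)
  expect_equal(emp[1], theo[1], tolerance = 0.03)
  expect_equal(emp[2], theo[2], tolerance = 0.1)
  # anti-correlated successive increments for H < 1/2
  expect_lt(emp[2], 0)
})
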