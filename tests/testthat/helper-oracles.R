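# Independent numerical oracles used across the suite. These deliberately
# avoid the implementation paths they check.

MU0_ORACLE <- 4e-7 * pi

# Radial field component at point x (m) from the PRIMARY dipole alone, by
# plain Biot-Savart. For a spherical conductor the ohmic volume currents
# contribute nothing to the radial component outside, so this is the exact
# radial field of the full problem.
biot_savart_radial <- function(x, r0_m, q_am) {
  d <- x - r0_m
  qxd <- c(q_am[2] * d[3] - q_am[3] * d[2],
           q_am[3] * d[1] - q_am[1] * d[3],
           q_am[1] * d[2] - q_am[2] * d[1])
  sum(qxd * x / sqrt(sum(x^2))) * MU0_ORACLE / (4 * pi * sum(d^2)^1.5)
}

# Magnetic scalar potential U(r) outside the conductor, reconstructed by
# integrating the Biot-Savart radial field along the outward ray
# (B = -mu0 grad U, so U(r) = (1/mu0) int_r^inf Br(s rhat) ds).
scalar_potential_oracle <- function(r_m, r0_m, q_am) {
  rn <- sqrt(sum(r_m^2))
  rhat <- r_m / rn
  f <- function(u) {
    vapply(u, function(ui) {
      s <- rn / ui
      biot_savart_radial(s * rhat, r0_m, q_am) * rn / ui^2
    }, numeric(1))
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value / MU0_ORACLE
}

# Full vector field at r_m via the oracle: exact radial part from
# Biot-Savart, tangential parts from angular finite differences of U.
oracle_sphere_field <- function(r_m, r0_m, q_am, theta = 1e-4) {
  rn <- sqrt(sum(r_m^2))
  rhat <- r_m / rn
  h <- if (abs(rhat[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- h - sum(h * rhat) * rhat; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(rhat[2] * t1[3] - rhat[3] * t1[2],
          rhat[3] * t1[1] - rhat[1] * t1[3],
          rhat[1] * t1[2] - rhat[2] * t1[1])
  br <- biot_savart_radial(r_m, r0_m, q_am)
  du <- function(tv) {
    up <- scalar_potential_oracle(rn * (cos(theta) * rhat + sin(theta) * tv),
                                  r0_m, q_am)
    um <- scalar_potential_oracle(rn * (cos(theta) * rhat - sin(theta) * tv),
                                  r0_m, q_am)
    (up - um) / (2 * rn * theta)
  }
  br * rhat - MU0_ORACLE * (du(t1) * t1 + du(t2) * t2)
}

# Brute-force Spearman via an explicit midrank table.
spearman_midrank_oracle <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i]); ties <- sum(v == v[i])
      less + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All permutations of 1..n by simple recursion (independent of the
# package's internal generator).
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Closed-form Gaussian log marginal likelihood for y = Xw + e with
# w ~ N(0, I/alpha), e ~ N(0, I/lambda): log N(y; 0, C),
# C = I/lambda + X X^T / alpha.
log_marginal_oracle <- function(y, X, alpha, lambda) {
  n <- length(y)
  C <- diag(n) / lambda + X %*% t(X) / alpha
  ch <- chol(C)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2))
}

# Random rotation matrices for the moment-magnitude plane scan.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force scan for the maximal-variance axis of a covariance: coarse
# random directions, then progressively finer local perturbations. The
# minimal-variance plane is its orthogonal complement.
max_variance_axis_scan <- function(S, seed = 1) {
  withr::with_seed(seed, {
    best <- NULL; best_var <- -Inf
    cand <- matrix(rnorm(3 * 4000), ncol = 3)
    cand <- cand / sqrt(rowSums(cand^2))
    v <- rowSums((cand %*% S) * cand)
    best <- cand[which.max(v), ]; best_var <- max(v)
    for (scale in c(0.1, 0.01, 0.001, 1e-4, 1e-5)) {
      cand <- matrix(rnorm(3 * 2000, sd = scale), ncol = 3) +
        matrix(best, 2000, 3, byrow = TRUE)
      cand <- cand / sqrt(rowSums(cand^2))
      v <- rowSums((cand %*% S) * cand)
      if (max(v) > best_var) {
        best <- cand[which.max(v), ]; best_var <- max(v)
      }
    }
    best
  })
}

# Small synthetic topography fixture: two tangential dipoles at the default
# bilateral locations, optional additive noise at a given topography SNR.
make_topo_fixture <- function(seed, n_channels = 64, snr_db = Inf) {
  cfg <- sim_config(seed = seed, n_channels = n_channels)
  arr <- make_sensor_array(n_channels, cfg$helmet_radius_mm)
  con <- conductor_model(radius_mm = cfg$conductor_radius_mm)
  truth <- make_auditory_truth(cfg)
  topo <- dipole_field(truth$dipole_locations_mm[1, ],
                       truth$dipole_moments_nAm[1, ], con, arr) +
    dipole_field(truth$dipole_locations_mm[2, ],
                 truth$dipole_moments_nAm[2, ], con, arr)
  if (is.finite(snr_db)) {
    topo <- topo + withr::with_seed(seed + 5000L, {
      rnorm(n_channels, sd = sqrt(mean(topo^2) / 10^(snr_db / 10)))
    })
  }
  list(topo = topo, truth = truth, array = arr, conductor = con, cfg = cfg)
}
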