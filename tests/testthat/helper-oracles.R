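# Independent oracles and fixture builders. These deliberately avoid the code
# paths they check: polynomial fits via explicit normal equations, eigenvalues
# via characteristic-polynomial roots, quantiles via direct order-statistic
# interpolation.

# Polynomial least squares through the normal equations (oracle for the
# QR-based fit in fit_spline).
polyfit_normal_equations <- function(z, y, degree) {
  v <- outer(z, 0:degree, `^`)
  as.numeric(solve(t(v) %*% v, t(v) %*% y))
}

# Perpendicular distance from points (rows of p) to the line through `a`
# with unit direction `dir`.
point_line_distances <- function(p, a, dir) {
  dir <- dir / sqrt(sum(dir^2))
  rel <- sweep(p, 2L, a)
  proj <- rel %*% dir
  perp <- rel - proj %*% t(dir)
  sqrt(rowSums(perp^2))
}

# Eigenvalues of a symmetric 3x3 matrix via the characteristic polynomial
# (independent of base eigen()).
eigvals_charpoly <- function(s) {
  # det(s - x I) = -x^3 + tr x^2 - m2 x + det
  tr <- sum(diag(s))
  m2 <- sum(diag(s)[c(1, 1, 2)] * diag(s)[c(2, 3, 3)]) -
    s[1, 2]^2 - s[1, 3]^2 - s[2, 3]^2
  dt <- det(s)
  r <- polyroot(c(dt, -m2, tr, -1))
  sort(Re(r), decreasing = TRUE)
}

# Type-7 quantile by hand: linear interpolation between order statistics.
quantile_sorted <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
  }, numeric(1))
}

# Deterministic random rotation matrix (det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Straight-line C-alpha trace between two points.
line_trace <- function(from, to, n = 21L, ...) {
  u <- seq(0, 1, length.out = n)
  helix_trace(cbind(from[1] + u * (to[1] - from[1]),
                    from[2] + u * (to[2] - from[2]),
                    from[3] + u * (to[3] - from[3])), ...)
}

# Identity reference frame for fitting data already expressed in local
# coordinates.
identity_frame <- function() {
  structure(list(origin = c(0, 0, 0), axes = diag(3),
                 eigenvalues = c(1, 0, 0)),
            class = "reference_frame")
}

# Single-frame convenience: run the per-frame geometry chain and return the
# area plus the full distance profile.
analyze_frame_quantities <- function(frame, M = 1500L, degree = 2L) {
  m1 <- fit_spline(frame$helix1, degree_m = degree)
  m2 <- fit_spline(frame$helix2, degree_m = degree)
  rul <- build_rulings(evaluate_spline(m1, M), evaluate_spline(m2, M))
  list(area = ruled_surface_area(rul)$total_area, distances = rul$distances)
}

# A gently curved helix pair with quadratic axis bend, used by several
# surface and pipeline tests.
curved_pair <- function(n_frames = 1L, n_residues = 30L, noise = 0,
                        seed = 42L) {
  generate_pair_trajectory(pair_trajectory_spec(
    helix_spec(n_residues, bend_coeffs_y = c(0, 0, 0.002),
               bend_coeffs_z = c(0, 0, -0.0008), noise_sigma = noise,
               seed = seed),
    helix_spec(n_residues, bend_coeffs_y = c(0, 0, -0.0016),
               bend_coeffs_z = c(0, 0, 0.001), noise_sigma = noise,
               seed = seed + 1L),
    separation = 12, antiparallel = TRUE, n_frames = n_frames,
    seed = seed + 2L))
}
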