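test_that("an axis-aligned trace gets the expected frame and eigenvalues", {
  tr <- line_trace(c(0, 0, 0), c(30, 0, 0), n = 21)
  fr <- compute_frame(tr)
  expect_equal(fr$origin, c(15, 0, 0), ignore_attr = TRUE)
  expect_equal(fr$axes[1, ], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$eigenvalues[2:3], c(0, 0), tolerance = 1e-10)
  expect_equal(fr$eigenvalues[1], var(tr$coords[, 1]))
  # orthonormal right-handed frame
  expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-10)
  expect_error(compute_frame(helix_trace(matrix(1, 4, 3))), "coincident")
})

test_that("frame eigenvalues match a characteristic-polynomial eigensolve", {
  for (seed in 1:10) {
    set.seed(seed)
    h <- generate_helix(helix_spec(25, bend_coeffs_y = c(0, runif(1, -0.3, 0.3)),
                                   noise_sigma = 0.4, seed = seed))
    tr <- transform_trace(h, random_rotation(seed + 100), rnorm(3, sd = 20))
    fr <- compute_frame(tr)
    s <- cov(tr$coords)
    expect_equal(fr$eigenvalues, eigvals_charpoly(s), tolerance = 1e-8)
    expect_equal(fr$axes %*% t(fr$axes), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(det(fr$axes), 1, tolerance = 1e-10)
    # PC1 points N -> C
    expect_gt(sum((tr$coords[25, ] - tr$coords[1, ]) * fr$axes[1, ]), 0)
  }
})

test_that("frames are equivariant under rigid motion up to sign conventions", {
  h <- generate_helix(helix_spec(30, bend_coeffs_y = c(0, 0, 0.01),
                                 noise_sigma = 0.2, seed = 11L))
  fr <- compute_frame(h)
  for (seed in 1:5) {
    r <- random_rotation(seed)
    shift <- c(5, -3, 8) * seed
    fr2 <- compute_frame(transform_trace(h, r, shift))
    expect_equal(fr2$origin, as.numeric(r %*% fr$origin + shift),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(fr2$axes, fr$axes %*% t(r), tolerance = 1e-9)
    expect_equal(fr2$eigenvalues, fr$eigenvalues, tolerance = 1e-9)
  }
})

test_that("collinear data fits to the zero polynomial with zero rss", {
  tr <- line_trace(c(1, 2, 3), c(31, 17, -6), n = 15)
  m <- fit_spline(tr, degree_m = 3)
  expect_lt(max(abs(c(m$coeffs_f2, m$coeffs_f3))), 1e-10)
  expect_lt(m$rss, 1e-10)
  expect_lt(m$z_min, m$z_max)
})

test_that("known quadratic shape is recovered exactly in a given frame", {
  z <- seq(-15, 15, length.out = 25)
  tr <- helix_trace(cbind(z, 0.01 * z^2, -0.004 * z^2))
  m <- fit_spline(tr, frame = identity_frame(), degree_m = 2)
  expect_equal(m$coeffs_f2, c(0, 0, 0.01), tolerance = 1e-8)
  expect_equal(m$coeffs_f3, c(0, 0, -0.004), tolerance = 1e-8)
  expect_lt(m$rss, 1e-10)
  # against the normal-equation oracle
  expect_equal(m$coeffs_f2, polyfit_normal_equations(z, 0.01 * z^2, 2),
               tolerance = 1e-8)
  expect_equal(m$coeffs_f3, polyfit_normal_equations(z, -0.004 * z^2, 2),
               tolerance = 1e-8)
})

test_that("fitted coefficients agree with the normal-equation oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    h <- generate_helix(helix_spec(
      20 + seed %% 10, bend_coeffs_y = c(0, runif(1, -0.2, 0.2), runif(1, -0.01, 0.01)),
      bend_coeffs_z = c(0, runif(1, -0.2, 0.2)), noise_sigma = 0.3,
      seed = seed))
    tr <- transform_trace(h, random_rotation(seed + 50), rnorm(3, sd = 10))
    fr <- compute_frame(tr)
    deg <- 2L + seed %% 3L
    m <- fit_spline(tr, fr, deg)
    local <- sweep(tr$coords, 2, fr$origin) %*% t(fr$axes)
    expect_equal(m$coeffs_f2,
                 polyfit_normal_equations(local[, 1], local[, 2], deg),
                 tolerance = 1e-8)
    expect_equal(m$coeffs_f3,
                 polyfit_normal_equations(local[, 1], local[, 3], deg),
                 tolerance = 1e-8)
  }
})

test_that("rss is nonincreasing in polynomial degree on fixed data", {
  h <- generate_helix(helix_spec(30, noise_sigma = 0.5, seed = 13L))
  fr <- compute_frame(h)
  rss <- vapply(2:4, function(m) fit_spline(h, fr, m)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-12))
  expect_true(all(rss >= 0))
})

test_that("fit preconditions and conditioning are enforced", {
  tr <- helix_trace(cbind(1:5 * 1.5, rnorm(5), rnorm(5)))
  expect_error(fit_spline(tr, degree_m = 4), "at least degree_m \\+ 2")
  # all z duplicated: points in a plane orthogonal to given PC1
  dup <- helix_trace(cbind(rep(0, 6), 1:6, rnorm(6)))
  expect_error(fit_spline(dup, frame = identity_frame(), degree_m = 2),
               "ill-conditioned")
})

test_that("discretisation spans [z_min, z_max] uniformly and round-trips", {
  h <- generate_helix(helix_spec(25, bend_coeffs_y = c(0, 0, 0.01),
                                 seed = 5L))
  m <- fit_spline(h, degree_m = 2)
  c2 <- evaluate_spline(m, 2L)
  expect_equal(c2$u_values, c(0, 1))
  # endpoints at z_min and z_max in the local frame
  local <- sweep(c2$points_global, 2, m$frame$origin) %*% t(m$frame$axes)
  expect_equal(local[, 1], c(m$z_min, m$z_max), tolerance = 1e-10)

  cc <- evaluate_spline(m, 200L)
  expect_equal(cc$u_values, seq(0, 1, length.out = 200))
  expect_true(all(diff(cc$arc_lengths) >= 0))
  # global points map back to (z, f2(z), f3(z)) through the frame inverse
  loc <- sweep(cc$points_global, 2, m$frame$origin) %*% t(m$frame$axes)
  z <- loc[, 1]
  f2 <- sapply(z, function(x) sum(m$coeffs_f2 * x^(0:2)))
  expect_equal(loc[, 2], f2, tolerance = 1e-10)

  # straight line: total chord length equals the z extent
  line <- fit_spline(line_trace(c(0, 0, 0), c(30, 0, 0)), degree_m = 2)
  cl <- evaluate_spline(line, 1500L)
  expect_equal(cl$arc_lengths[1500], line$z_max - line$z_min,
               tolerance = 1e-9)
})

test_that("AIC behaves as the closed form dictates", {
  h <- generate_helix(helix_spec(30, noise_sigma = 0.4, seed = 21L))
  fr <- compute_frame(h)
  m2 <- fit_spline(h, fr, 2)
  m4 <- fit_spline(h, fr, 4)
  # equal-rss comparison: penalty alone orders the models
  m4_eq <- m4; m4_eq$rss <- m2$rss
  expect_lt(aic_score(m2), aic_score(m4_eq))
  expect_equal(aic_score(m4_eq) - aic_score(m2), 2 * (2 * 5 - 2 * 3))
  # halving rss at fixed n, p lowers AIC by n log 2
  half <- m2; half$rss <- m2$rss / 2
  expect_equal(aic_score(m2) - aic_score(half), 2 * m2$n_points * log(2))
  # perfect fit
  perfect <- m2; perfect$rss <- 0
  expect_warning(v <- aic_score(perfect), "perfect fit")
  expect_identical(v, -Inf)
})

test_that("AIC selects the quadratic model on quadratically bent helices", {
  n_rep <- 100L
  picks <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    h <- generate_helix(helix_spec(36, bend_coeffs_y = c(0, 0, 0.012),
                                   bend_coeffs_z = c(0, 0, -0.006),
                                   noise_sigma = 0.3, seed = 1000L + r))
    fr <- compute_frame(h)
    aics <- vapply(2:4, function(m) aic_score(fit_spline(h, fr, m)),
                   numeric(1))
    picks[r] <- c(2:4)[which.min(aics)]
  }
  expect_gte(mean(picks == 2L), 0.90)
})

test_that("spline models serialise to full-precision JSON", {
  m <- fit_spline(generate_helix(helix_spec(20, seed = 2L)), degree_m = 3)
  parsed <- jsonlite::fromJSON(spline_to_json(m))
  expect_equal(parsed$degree_m, 3L)
  expect_equal(parsed$knots_K, 0L)
  expect_equal(parsed$coeffs_f2, m$coeffs_f2)
  expect_equal(parsed$rss, m$rss)
  expect_equal(parsed$frame$origin, m$frame$origin, ignore_attr = TRUE)
})
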