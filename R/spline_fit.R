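#' Build the PCA reference frame of a helix trace
#'
#' Principal component analysis of the C-alpha coordinates yields the helix's
#' local coordinate system: the centroid as origin and the three principal
#' axes PC1, PC2, PC3 (descending variance), PC1 approximating the helix
#' axis.  Signs are fixed deterministically: PC1 points N- to C-terminus
#' (`(last - first) . PC1 > 0`), PC2 so that the first residue has
#' non-negative PC2 coordinate, and PC3 = PC1 x PC2, making the frame
#' right-handed.  The fitted global curve is invariant to these conventions;
#' they only pin down coefficient-level reproducibility.
#'
#' @param trace a [helix_trace()] with at least 4 non-coincident points.
#' @return An object of class `reference_frame`: list with `origin` (length-3
#'   centroid), `axes` (3 x 3 orthonormal matrix, rows PC1..PC3), and
#'   `eigenvalues` (descending coordinate variances, Angstrom^2).
#' @export
compute_frame <- function(trace) {
  stopifnot(inherits(trace, "helix_trace"))
  x <- trace$coords
  origin <- colMeans(x)
  centred <- sweep(x, 2L, origin)
  if (max(abs(centred)) < 1e-12)
    stop("degenerate geometry: all points coincident", call. = FALSE)
  e <- eigen(cov(x), symmetric = TRUE)
  axes <- t(e$vectors)            # rows PC1, PC2, PC3, descending variance
  nc <- x[nrow(x), ] - x[1L, ]
  if (sum(nc * axes[1L, ]) < 0) axes[1L, ] <- -axes[1L, ]
  if (sum((x[1L, ] - origin) * axes[2L, ]) < 0) axes[2L, ] <- -axes[2L, ]
  axes[3L, ] <- cross3(axes[1L, ], axes[2L, ])
  structure(
    list(origin = origin, axes = axes,
         eigenvalues = pmax(e$values, 0)),
    class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame>\n  origin:", sprintf("%.3f", x$origin),
      "\n  eigenvalues (A^2):", sprintf("%.4g", x$eigenvalues), "\n")
  invisible(x)
}

# Global -> local frame coordinates (columns z = PC1, y2 = PC2, y3 = PC3).
to_local <- function(frame, coords) {
  sweep(coords, 2L, frame$origin) %*% t(frame$axes)
}

# Local frame coordinates -> global.
to_global <- function(frame, local) {
  sweep(local %*% frame$axes, 2L, frame$origin, "+")
}

#' Fit the polynomial spline of a helix in its reference frame
#'
#' Represents the helix by the parametric curve c(z) = (z, f2(z), f3(z)) in
#' the local frame: z is the PC1 coordinate, f2 the shape in the PC1-PC2
#' plane and f3 in the PC1-PC3 plane.  Both are single-segment polynomials of
#' degree `degree_m` (no interior knots) fitted by two independent 1-D least
#' squares over the C-alpha points, solved through a QR factorisation (the
#' explicit normal equations exist only as a test oracle).
#'
#' @param trace a [helix_trace()].
#' @param frame its [compute_frame()] reference frame (computed if `NULL`).
#' @param degree_m polynomial degree, >= 1; degrees 2-4 are the ones of
#'   practical interest for helix shape.
#' @return An object of class `spline_model`: `degree_m`, `knots_K` (always
#'   0), `coeffs_f2`, `coeffs_f3` (increasing powers, length `degree_m + 1`),
#'   `z_min`, `z_max`, `frame`, `rss` (summed over both planes, Angstrom^2),
#'   `n_points`.
#' @export
fit_spline <- function(trace, frame = NULL, degree_m = 2L) {
  stopifnot(inherits(trace, "helix_trace"))
  check_scalar(degree_m, "degree_m", lower = 1, integer = TRUE)
  if (is.null(frame)) frame <- compute_frame(trace)
  stopifnot(inherits(frame, "reference_frame"))
  n <- nrow(trace$coords)
  if (n < degree_m + 2L)
    stop(sprintf("need at least degree_m + 2 = %d points, got %d",
                 degree_m + 2L, n), call. = FALSE)
  local <- to_local(frame, trace$coords)
  z <- local[, 1L]
  design <- outer(z, 0:degree_m, `^`)
  fit <- lm.fit(design, local[, 2:3])
  if (fit$rank < degree_m + 1L)
    stop("ill-conditioned fit: duplicate z values exceed degrees of freedom",
         call. = FALSE)
  coef <- fit$coefficients
  structure(
    list(degree_m = as.integer(degree_m), knots_K = 0L,
         coeffs_f2 = unname(coef[, 1L]), coeffs_f3 = unname(coef[, 2L]),
         z_min = min(z), z_max = max(z), frame = frame,
         rss = sum(fit$residuals^2), n_points = n),
    class = "spline_model")
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf(
    "<spline_model> degree m=%d (K=0 knots), %d points, z in [%.2f, %.2f] A, rss %.4g A^2\n",
    x$degree_m, x$n_points, x$z_min, x$z_max, x$rss))
  invisible(x)
}

#' Discretise a fitted spline in global coordinates
#'
#' Evaluates the curve at `M` positions uniform in the curve parameter z
#' (1-based position i at `z_min + (i-1)/(M-1) * (z_max - z_min)`), maps the
#' local points through the reference frame back to global coordinates, and
#' records the common parameter `u_i = (i-1)/(M-1)` together with cumulative
#' chord lengths.
#'
#' @param model a [fit_spline()] result.
#' @param M number of positions, >= 2; 1500 is the conventional default for
#'   groove analyses.
#' @return An object of class `discretized_curve`: `u_values`,
#'   `points_global` (M x 3), `arc_lengths` (cumulative chord length,
#'   starting at 0).
#' @export
evaluate_spline <- function(model, M = 1500L) {
  stopifnot(inherits(model, "spline_model"))
  check_scalar(M, "M", lower = 2, integer = TRUE)
  u <- (seq_len(M) - 1) / (M - 1)
  z <- model$z_min + u * (model$z_max - model$z_min)
  local <- cbind(z, polyval_asc(model$coeffs_f2, z),
                 polyval_asc(model$coeffs_f3, z))
  pts <- to_global(model$frame, local)
  seg <- row_norms(pts[-1L, , drop = FALSE] - pts[-M, , drop = FALSE])
  structure(
    list(u_values = u, points_global = pts, arc_lengths = c(0, cumsum(seg))),
    class = "discretized_curve")
}

#' Akaike information criterion of a spline model
#'
#' Model-selection score across polynomial degrees, using the Gaussian
#' least-squares form `AIC = n * log(rss / n) + 2 * p` with `n = 2 *
#' n_points` residuals (both planes) and `p = 2 * (degree_m + 1)` fitted
#' coefficients.  Lower is better.  This is the package's documented
#' convention for comparing nested single-segment polynomial models.
#'
#' @param model a [fit_spline()] result.
#' @return The AIC value; `-Inf` with a warning for a perfect fit
#'   (`rss == 0`).
#' @export
aic_score <- function(model) {
  stopifnot(inherits(model, "spline_model"))
  n <- 2 * model$n_points
  p <- 2 * (model$degree_m + 1L)
  if (model$rss <= 0) {
    warning("perfect fit (rss = 0): AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(model$rss / n) + 2 * p
}

#' Serialise a spline model to JSON
#'
#' Full-precision provenance record of a fit: degree, coefficients, z-range,
#' rss and the reference frame.
#'
#' @param model a [fit_spline()] result.
#' @return A JSON string.
#' @export
spline_to_json <- function(model) {
  stopifnot(inherits(model, "spline_model"))
  jsonlite::toJSON(
    list(degree_m = model$degree_m, knots_K = model$knots_K,
         coeffs_f2 = model$coeffs_f2, coeffs_f3 = model$coeffs_f3,
         z_min = model$z_min, z_max = model$z_max, rss = model$rss,
         n_points = model$n_points,
         frame = list(origin = model$frame$origin,
                      axes = model$frame$axes,
                      eigenvalues = model$frame$eigenvalues)),
    digits = NA, auto_unbox = TRUE)
}
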