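#' Per-frame geometric analysis of a helix-pair trajectory
#'
#' For every frame: build each helix's PCA frame, fit the degree-`degree_m`
#' spline, discretise both splines at `M` common positions, span the rulings
#' and record the interhelical distances at the probe `positions`, the total
#' ruled-surface area A, and the summed fit rss.  Frames are processed
#' independently — no state leaks between frames.
#'
#' @param frames a `pair_trajectory` from [generate_pair_trajectory()], or a
#'   list of frames as returned by [read_frames()] (each frame a list of two
#'   [helix_trace()]s).
#' @param degree_m spline polynomial degree.
#' @param M number of discretisation positions per spline.
#' @param positions 1-based probe positions for the distance profile;
#'   defaults to [default_positions()] of `M`.
#' @param times optional per-frame time stamps (ns); metadata only, never
#'   used in computation.
#' @param skip_bad_frames if `TRUE`, frames that fail (e.g. too few residues
#'   for the requested degree) are dropped with a warning instead of
#'   aborting; dropped frame indices are recorded in `skipped`.
#' @return An object of class `geometry_timeseries`: `degree_m`, `M`,
#'   `positions`, `frames` (count), `times`, `area_series` (Angstrom^2),
#'   `distance_series` (frames x positions matrix, Angstrom), `rss_series`
#'   (Angstrom^2), `orientation_reversed` (per frame), `skipped`.
#' @export
analyze_trajectory <- function(frames, degree_m = 2L, M = 1500L,
                               positions = NULL, times = NULL,
                               skip_bad_frames = FALSE) {
  if (inherits(frames, "pair_trajectory")) frames <- frames$frames
  stopifnot(is.list(frames), length(frames) >= 1L)
  check_scalar(degree_m, "degree_m", lower = 1, integer = TRUE)
  check_scalar(M, "M", lower = 2, integer = TRUE)
  if (is.null(positions)) positions <- default_positions(M)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > M))
    stop(sprintf("positions must lie in [1, %d]", M), call. = FALSE)
  if (!is.null(times) && length(times) != length(frames))
    stop("times must have one entry per frame", call. = FALSE)

  n <- length(frames)
  area <- rss <- rep(NA_real_, n)
  rev_flag <- rep(NA, n)
  dmat <- matrix(NA_real_, n, length(positions),
                 dimnames = list(NULL, paste0("pos", positions)))
  failed <- integer(0)
  for (k in seq_len(n)) {
    res <- tryCatch(
      analyze_frame(frames[[k]], degree_m, M, positions),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("frame %d failed: %s", k - 1L, conditionMessage(res))
      if (!skip_bad_frames) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      failed <- c(failed, k)
      next
    }
    area[k] <- res$area
    rss[k] <- res$rss
    rev_flag[k] <- res$orientation_reversed
    dmat[k, ] <- res$distances
  }
  if (length(failed) > 0L) {
    area <- area[-failed]; rss <- rss[-failed]
    rev_flag <- rev_flag[-failed]
    dmat <- dmat[-failed, , drop = FALSE]
    if (!is.null(times)) times <- times[-failed]
  }
  if (length(area) == 0L)
    stop("all frames failed analysis", call. = FALSE)
  structure(
    list(degree_m = as.integer(degree_m), M = as.integer(M),
         positions = positions, frames = length(area), times = times,
         area_series = area, distance_series = dmat, rss_series = rss,
         orientation_reversed = rev_flag, skipped = failed - 1L),
    class = "geometry_timeseries")
}

# One frame: traces -> frames -> splines -> curves -> rulings -> quantities.
analyze_frame <- function(frame, degree_m, M, positions) {
  stopifnot(is.list(frame), length(frame) >= 2L)
  tr1 <- frame[[1L]]; tr2 <- frame[[2L]]
  m1 <- fit_spline(tr1, compute_frame(tr1), degree_m)
  m2 <- fit_spline(tr2, compute_frame(tr2), degree_m)
  rul <- build_rulings(evaluate_spline(m1, M), evaluate_spline(m2, M))
  list(area = ruled_surface_area(rul)$total_area,
       distances = rul$distances[positions],
       rss = m1$rss + m2$rss,
       orientation_reversed = rul$orientation_reversed)
}

#' Analyse a trajectory at several polynomial degrees
#'
#' Runs [analyze_trajectory()] once per degree on the same frames — the
#' standard design for assessing how spline flexibility affects the global
#' quantities.
#'
#' @inheritParams analyze_trajectory
#' @param degrees integer vector of polynomial degrees, conventionally
#'   `c(2, 3, 4)`.
#' @return A named list of `geometry_timeseries`, names `"m2"`, `"m3"`, ...
#' @export
analyze_degrees <- function(frames, degrees = c(2L, 3L, 4L), M = 1500L,
                            positions = NULL, times = NULL,
                            skip_bad_frames = FALSE) {
  out <- lapply(degrees, function(m)
    analyze_trajectory(frames, m, M, positions, times, skip_bad_frames))
  names(out) <- paste0("m", degrees)
  out
}

#' @export
print.geometry_timeseries <- function(x, ...) {
  cat(sprintf(
    "<geometry_timeseries> m=%d, %d frames, M=%d\n  A: mean %.2f (sd %.2f) A^2\n  d at positions %s: %s A (time means)\n",
    x$degree_m, x$frames, x$M, mean(x$area_series), sd(x$area_series),
    paste(x$positions, collapse = ","),
    paste(sprintf("%.2f", colMeans(x$distance_series)), collapse = ", ")))
  invisible(x)
}

#' Boxplot summaries of a geometry time series
#'
#' Per probe position, the five-number summary of the interhelical distance
#' over time — min, lower quartile, median, upper quartile, max, with
#' whiskers as true extremes and quartiles by linear interpolation between
#' order statistics ([stats::quantile()] type 7) — plus the time-averaged
#' area and its sd.
#'
#' @param series a [analyze_trajectory()] result.
#' @return An object of class `geometry_summary`: `distance_fivenum` (5 x
#'   positions matrix with rows min, q1, median, q3, max),
#'   `time_averaged_area`, `area_sd`, `degree_m`, `frames`.
#' @export
summarize_geometry <- function(series) {
  stopifnot(inherits(series, "geometry_timeseries"))
  fv <- apply(series$distance_series, 2L, quantile,
              probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  rownames(fv) <- c("min", "q1", "median", "q3", "max")
  structure(
    list(distance_fivenum = fv,
         time_averaged_area = mean(series$area_series),
         area_sd = if (series$frames > 1L) sd(series$area_series) else 0,
         degree_m = series$degree_m, frames = series$frames),
    class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("<geometry_summary> m=%d over %d frames\n", x$degree_m, x$frames))
  cat(sprintf("  time-averaged A: %.2f A^2 (sd %.2f)\n",
              x$time_averaged_area, x$area_sd))
  print(round(x$distance_fivenum, 3))
  invisible(x)
}

#' Percent change of time-averaged area across polynomial degrees
#'
#' For each degree, `100 * (A_m - A_ref) / A_ref` of the time-averaged
#' ruled-surface area relative to the reference degree — the standard way of
#' quantifying how much extra spline flexibility inflates the apparent
#' groove area.
#'
#' @param summaries named list of [summarize_geometry()] results (names
#'   `"m2"`, ... as from [analyze_degrees()]), or of `geometry_timeseries`
#'   which are summarised on the fly.
#' @param reference_degree degree used as baseline (default 2).
#' @return An object of class `degree_comparison`: `reference_degree` and a
#'   data frame `comparisons` with `degree`, `time_averaged_area`,
#'   `percent_change`.
#' @export
compare_degrees <- function(summaries, reference_degree = 2L) {
  stopifnot(is.list(summaries), length(summaries) >= 1L)
  summaries <- lapply(summaries, function(s) {
    if (inherits(s, "geometry_timeseries")) summarize_geometry(s) else s
  })
  stopifnot(all(vapply(summaries, inherits, logical(1L), "geometry_summary")))
  degs <- vapply(summaries, `[[`, numeric(1L), "degree_m")
  areas <- vapply(summaries, `[[`, numeric(1L), "time_averaged_area")
  ref <- which(degs == reference_degree)
  if (length(ref) != 1L)
    stop(sprintf("reference degree %d not among fitted degrees (%s)",
                 reference_degree, paste(degs, collapse = ", ")),
         call. = FALSE)
  structure(
    list(reference_degree = as.integer(reference_degree),
         comparisons = data.frame(
           degree = as.integer(degs),
           time_averaged_area = areas,
           percent_change = 100 * (areas - areas[ref]) / areas[ref],
           row.names = NULL)),
    class = "degree_comparison")
}

#' @export
print.degree_comparison <- function(x, ...) {
  cat(sprintf("<degree_comparison> reference m=%d\n", x$reference_degree))
  df <- x$comparisons
  for (i in seq_len(nrow(df)))
    cat(sprintf("  m=%d: A = %.2f A^2 (%+.2f%%)\n", df$degree[i],
                df$time_averaged_area[i], df$percent_change[i]))
  invisible(x)
}

#' Write a geometry time series to CSV
#'
#' One row per frame: frame index, optional time stamp, area, the distance at
#' each probe position and the fit rss, at 6 significant digits.  Distances
#' and areas are written in Angstrom / Angstrom^2 by default, or nm / nm^2.
#'
#' @param series a [analyze_trajectory()] result.
#' @param path output CSV path.
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path, units = c("angstrom", "nm")) {
  stopifnot(inherits(series, "geometry_timeseries"))
  units <- match.arg(units)
  s <- if (units == "nm") 0.1 else 1
  df <- data.frame(
    frame = seq_len(series$frames) - 1L,
    time_ns = if (is.null(series$times)) NA_real_ else series$times,
    area = signif(series$area_series * s^2, 6))
  dd <- signif(series$distance_series * s, 6)
  colnames(dd) <- paste0("d_", colnames(series$distance_series))
  df <- cbind(df, dd, rss = signif(series$rss_series * s^2, 6))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a geometry summary (and optional comparison) to JSON
#'
#' Full-precision JSON mirror of [summarize_geometry()] output, suitable for
#' downstream oracle checks.
#'
#' @param summary a [summarize_geometry()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "geometry_summary"))
  jsonlite::write_json(
    list(degree_m = summary$degree_m, frames = summary$frames,
         time_averaged_area = summary$time_averaged_area,
         area_sd = summary$area_sd,
         distance_fivenum = as.data.frame(t(summary$distance_fivenum))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
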