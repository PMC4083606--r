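#' Specify a synthetic alpha-helix
#'
#' Describes an ideal alpha-helix C-alpha trace: residues advance along the
#' helix axis at `rise_per_residue` and wind around it at `helix_radius` with
#' `residues_per_turn` residues per full turn.  The axis itself may be bent:
#' `bend_coeffs_y` and `bend_coeffs_z` are polynomial coefficients (increasing
#' powers, units Angstrom per Angstrom^k) giving the lateral displacement of
#' the axis in two perpendicular directions as a function of the axial
#' coordinate, so a degree-m spline fit has an exact ground truth to recover.
#' Isotropic Gaussian noise of sd `noise_sigma` is added per coordinate as the
#' simplest stand-in for thermal fluctuation.
#'
#' Defaults are textbook alpha-helix backbone geometry: 1.5 Angstrom rise per
#' residue, 3.6 residues per turn, 2.3 Angstrom C-alpha radius.
#'
#' @param n_residues number of residues (>= 4).
#' @param rise_per_residue axial rise per residue in Angstrom (> 0).
#' @param residues_per_turn residues per helical turn (> 1).
#' @param helix_radius C-alpha distance from the axis in Angstrom (>= 0).
#' @param bend_coeffs_y,bend_coeffs_z polynomial coefficients of the axis
#'   bend, increasing powers; `0` means a straight axis.
#' @param noise_sigma sd of isotropic Gaussian coordinate noise (Angstrom).
#' @param seed integer seed making generation reproducible.
#' @return An object of class `helix_spec`.
#' @seealso [generate_helix()]
#' @export
helix_spec <- function(n_residues, rise_per_residue = 1.5,
                       residues_per_turn = 3.6, helix_radius = 2.3,
                       bend_coeffs_y = 0, bend_coeffs_z = 0,
                       noise_sigma = 0, seed = 1L) {
  check_scalar(n_residues, "n_residues", lower = 4, integer = TRUE)
  check_scalar(rise_per_residue, "rise_per_residue", lower = 0, strict = TRUE)
  check_scalar(residues_per_turn, "residues_per_turn", lower = 1, strict = TRUE)
  check_scalar(helix_radius, "helix_radius", lower = 0)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  if (!is.numeric(bend_coeffs_y) || !all(is.finite(bend_coeffs_y)))
    stop_field("bend_coeffs_y", "must be finite numeric coefficients")
  if (!is.numeric(bend_coeffs_z) || !all(is.finite(bend_coeffs_z)))
    stop_field("bend_coeffs_z", "must be finite numeric coefficients")
  structure(
    list(n_residues = as.integer(n_residues),
         rise_per_residue = rise_per_residue,
         residues_per_turn = residues_per_turn,
         helix_radius = helix_radius,
         bend_coeffs_y = bend_coeffs_y,
         bend_coeffs_z = bend_coeffs_z,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "helix_spec")
}

#' Generate a synthetic helix C-alpha trace
#'
#' Residue i (0-based) sits at axial coordinate `i * rise_per_residue` with
#' angular phase `2 * pi * i / residues_per_turn`, at `helix_radius` from the
#' (possibly bent) axis, plus isotropic Gaussian noise.  The helix axis runs
#' along +x; the bend polynomials displace it in y and z.
#'
#' @param spec a [helix_spec()].
#' @param chain_id,frame_index,label passed to [helix_trace()].
#' @return A [helix_trace()] with `n_residues` ordered points.
#' @examples
#' h <- generate_helix(helix_spec(36))
#' nrow(h$coords)
#' @export
generate_helix <- function(spec, chain_id = "A", frame_index = 0L,
                           label = NA_character_) {
  stopifnot(inherits(spec, "helix_spec"))
  coords <- helix_coords(spec)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    coords <- coords + matrix(rnorm(length(coords), sd = spec$noise_sigma),
                              ncol = 3L)
  }
  helix_trace(coords, seq_len(spec$n_residues), chain_id, frame_index, label)
}

# Deterministic (noise-free) coordinates of a helix_spec.
helix_coords <- function(spec) {
  i <- seq_len(spec$n_residues) - 1L
  ax <- i * spec$rise_per_residue
  phase <- 2 * pi * i / spec$residues_per_turn
  cbind(ax,
        polyval_asc(spec$bend_coeffs_y, ax) + spec$helix_radius * cos(phase),
        polyval_asc(spec$bend_coeffs_z, ax) + spec$helix_radius * sin(phase))
}

#' Specify a synthetic helix-pair trajectory
#'
#' Two helices are laid out side by side, the second optionally antiparallel
#' (residue order reversed relative to the first helix's axial direction, as
#' in the MHC binding groove).  Across frames the centroid-to-centroid
#' separation, measured perpendicular to the shared axis direction, follows
#' `separation + breathing_amplitude * sin(2 * pi * t / breathing_period)`
#' with t the 0-based frame index, emulating groove "breathing"; independent
#' isotropic Gaussian noise of sd `frame_noise_sigma` is added to every atom
#' in every frame.
#'
#' @param helix1,helix2 [helix_spec()] objects for the two helices.
#' @param separation baseline centroid separation in Angstrom (> 0).
#' @param antiparallel logical; reverse helix2's residue direction.
#' @param n_frames number of frames (>= 1).
#' @param breathing_amplitude sinusoidal separation amplitude (Angstrom).
#' @param breathing_period period of the breathing motion in frames (>= 1).
#' @param frame_noise_sigma per-frame coordinate noise sd (Angstrom).
#' @param seed integer seed for the per-frame noise.
#' @return An object of class `pair_trajectory_spec`.
#' @export
pair_trajectory_spec <- function(helix1, helix2, separation,
                                 antiparallel = TRUE, n_frames = 1L,
                                 breathing_amplitude = 0,
                                 breathing_period = 1L,
                                 frame_noise_sigma = 0, seed = 1L) {
  if (!inherits(helix1, "helix_spec")) stop_field("helix1", "must be a helix_spec")
  if (!inherits(helix2, "helix_spec")) stop_field("helix2", "must be a helix_spec")
  check_scalar(separation, "separation", lower = 0, strict = TRUE)
  check_scalar(n_frames, "n_frames", lower = 1, integer = TRUE)
  check_scalar(breathing_amplitude, "breathing_amplitude", lower = 0)
  check_scalar(breathing_period, "breathing_period", lower = 1, integer = TRUE)
  check_scalar(frame_noise_sigma, "frame_noise_sigma", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  if (!is.logical(antiparallel) || length(antiparallel) != 1L ||
      is.na(antiparallel))
    stop_field("antiparallel", "must be TRUE or FALSE")
  structure(
    list(helix1 = helix1, helix2 = helix2, separation = separation,
         antiparallel = antiparallel, n_frames = as.integer(n_frames),
         breathing_amplitude = breathing_amplitude,
         breathing_period = as.integer(breathing_period),
         frame_noise_sigma = frame_noise_sigma, seed = as.integer(seed)),
    class = "pair_trajectory_spec")
}

#' Generate a synthetic helix-pair trajectory
#'
#' Builds the two base helices once from their own specs and seeds, then for
#' each frame t (0-based) shifts helix2 so that the centroid-to-centroid
#' offset is purely lateral and equal to the ground-truth separation
#' `separation + breathing_amplitude * sin(2 * pi * t / breathing_period)`,
#' finally adding per-frame noise.  The ground-truth separations are returned
#' alongside the frames so recovery tests have an analytic reference.
#'
#' @param spec a [pair_trajectory_spec()].
#' @return An object of class `pair_trajectory`: list with `frames` (each a
#'   list of two [helix_trace()]s named `helix1`, `helix2`), `truth` (data
#'   frame with `frame` and `separation`), and `spec`.
#' @examples
#' ps <- pair_trajectory_spec(helix_spec(24), helix_spec(24), separation = 12,
#'                            n_frames = 4, breathing_amplitude = 2,
#'                            breathing_period = 8)
#' traj <- generate_pair_trajectory(ps)
#' traj$truth
#' @export
generate_pair_trajectory <- function(spec) {
  stopifnot(inherits(spec, "pair_trajectory_spec"))
  base1 <- generate_helix(spec$helix1, chain_id = "A", label = "G-ALPHA1")
  base2 <- generate_helix(spec$helix2, chain_id = "B", label = "G-ALPHA2")
  c2 <- base2$coords
  if (spec$antiparallel) {
    # 180 degree rotation about the y axis through the helix2 midpoint:
    # reverses the axial direction while preserving residue order and
    # chirality, so residue 1 of helix2 ends up opposite the C-terminus of
    # helix1.
    extent <- (spec$helix2$n_residues - 1L) * spec$helix2$rise_per_residue
    c2 <- cbind(extent - c2[, 1L], c2[, 2L], -c2[, 3L])
  }
  cen1 <- colMeans(base1$coords)
  cen2 <- colMeans(c2)
  t_idx <- seq_len(spec$n_frames) - 1L
  sep_t <- spec$separation +
    spec$breathing_amplitude * sin(2 * pi * t_idx / spec$breathing_period)
  set.seed(spec$seed)
  frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    # align centroids axially; offset laterally (y) by the target separation
    shift <- c(cen1[1L] - cen2[1L], cen1[2L] - cen2[2L] + sep_t[k],
               cen1[3L] - cen2[3L])
    f1 <- base1$coords
    f2 <- sweep(c2, 2L, shift, "+")
    if (spec$frame_noise_sigma > 0) {
      f1 <- f1 + matrix(rnorm(length(f1), sd = spec$frame_noise_sigma), ncol = 3L)
      f2 <- f2 + matrix(rnorm(length(f2), sd = spec$frame_noise_sigma), ncol = 3L)
    }
    frames[[k]] <- list(
      helix1 = helix_trace(f1, base1$residue_ids, "A", k - 1L, "G-ALPHA1"),
      helix2 = helix_trace(f2, base2$residue_ids, "B", k - 1L, "G-ALPHA2"))
  }
  structure(
    list(frames = frames,
         truth = data.frame(frame = t_idx, separation = sep_t),
         spec = spec),
    class = "pair_trajectory")
}

#' @export
print.pair_trajectory <- function(x, ...) {
  cat(sprintf(
    "<pair_trajectory> %d frames, %d + %d residues, mean separation %.2f A\n",
    length(x$frames), x$spec$helix1$n_residues, x$spec$helix2$n_residues,
    mean(x$truth$separation)))
  invisible(x)
}

#' Write a helix-pair trajectory as a multi-model PDB file
#'
#' Emits one MODEL per frame with CA atoms only: helix1 on chain A, helix2 on
#' chain B, occupancy 1.00, B-factor 0.00, so [read_frames()] can round-trip
#' the trajectory.  Writing goes through [bio3d::write.pdb()].
#'
#' @param traj a `pair_trajectory` from [generate_pair_trajectory()], or any
#'   list of frames each holding two [helix_trace()]s.
#' @param path output PDB file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  frames <- if (inherits(traj, "pair_trajectory")) traj$frames else traj
  stopifnot(length(frames) >= 1L)
  f1 <- frames[[1L]]
  n1 <- nrow(f1$helix1$coords)
  n2 <- nrow(f1$helix2$coords)
  xyz <- t(vapply(frames, function(fr) {
    c(as.numeric(t(fr$helix1$coords)), as.numeric(t(fr$helix2$coords)))
  }, numeric(3L * (n1 + n2))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", n1 + n2),
    resno = c(f1$helix1$residue_ids, f1$helix2$residue_ids),
    resid = rep("ALA", n1 + n2),
    elety = rep("CA", n1 + n2),
    chain = c(rep(f1$helix1$chain_id, n1), rep(f1$helix2$chain_id, n2)),
    o = rep(1, n1 + n2), b = rep(0, n1 + n2))
  invisible(path)
}
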