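#' Construct a C-alpha helix trace
#'
#' The elementary fit input: the ordered C-alpha coordinates of one helix in
#' one trajectory frame.  Traces are produced by [read_frames()] from PDB
#' input or by [generate_helix()] synthetically; the constructor is exported
#' so that programmatic callers can build traces from arbitrary coordinates.
#'
#' @param coords numeric n x 3 matrix of C-alpha coordinates (Angstrom),
#'   ordered N- to C-terminus.
#' @param residue_ids integer vector of residue numbers, strictly increasing,
#'   one per row of `coords`.  Defaults to `1:n`.
#' @param chain_id single chain identifier string.
#' @param frame_index 0-based index of the trajectory frame the trace belongs
#'   to.
#' @param label optional helix label (e.g. `"G-ALPHA1"`).
#'
#' @return An object of class `helix_trace`: a list with elements `coords`,
#'   `residue_ids`, `chain_id`, `frame_index`, `label`.
#' @export
helix_trace <- function(coords, residue_ids = NULL, chain_id = "A",
                        frame_index = 0L, label = NA_character_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop_field("coords", "must have 3 columns (x, y, z)")
  n <- nrow(coords)
  if (n < 4L)
    stop_field("coords", "needs at least 4 points")
  if (!all(is.finite(coords)))
    stop_field("coords", "contains non-finite values")
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n)
    stop_field("residue_ids", "length must match number of coordinate rows")
  if (any(diff(residue_ids) <= 0L))
    stop_field("residue_ids", "must be strictly increasing")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(coords = coords, residue_ids = residue_ids,
         chain_id = as.character(chain_id),
         frame_index = as.integer(frame_index),
         label = as.character(label)),
    class = "helix_trace")
}

#' @export
print.helix_trace <- function(x, ...) {
  cat(sprintf("<helix_trace> %s: chain %s, residues %d-%d (%d CA), frame %d\n",
              x$label, x$chain_id, min(x$residue_ids), max(x$residue_ids),
              nrow(x$coords), x$frame_index))
  invisible(x)
}

#' Apply a rigid motion to a helix trace
#'
#' Convenience used for invariance checks: returns the same trace with
#' coordinates rotated by `rotation` and shifted by `translation`.
#'
#' @param trace a [helix_trace()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric shift (Angstrom).
#' @return A transformed `helix_trace`.
#' @export
transform_trace <- function(trace, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(trace, "helix_trace"))
  coords <- trace$coords %*% t(rotation)
  coords <- sweep(coords, 2L, translation, "+")
  helix_trace(coords, trace$residue_ids, trace$chain_id, trace$frame_index,
              trace$label)
}
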