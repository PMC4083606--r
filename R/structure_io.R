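#' Define a helix selection
#'
#' Names the chain and author residue range of one helix inside a PDB file.
#' For MHC class I analyses the two groove helices are conventionally
#' labelled `G-ALPHA1` and `G-ALPHA2`.  Residue ranges are fixed user input,
#' constant across frames: per-frame secondary-structure reclassification
#' would change the spline support length between frames and is deliberately
#' not done.
#'
#' @param chain_id chain identifier in the PDB file.
#' @param first_residue,last_residue author residue numbers bounding the
#'   helix, `first_residue < last_residue`.
#' @param label helix label, e.g. `"G-ALPHA1"`.
#' @return An object of class `helix_selection`.
#' @export
helix_selection <- function(chain_id, first_residue, last_residue,
                            label = "helix") {
  check_scalar(first_residue, "first_residue", integer = TRUE)
  check_scalar(last_residue, "last_residue", integer = TRUE)
  if (first_residue >= last_residue)
    stop_field("first_residue", "must be < last_residue")
  if (!is.character(chain_id) || length(chain_id) != 1L || nchar(chain_id) < 1L)
    stop_field("chain_id", "must be a non-empty string")
  structure(
    list(chain_id = chain_id, first_residue = as.integer(first_residue),
         last_residue = as.integer(last_residue), label = as.character(label)),
    class = "helix_selection")
}

#' Read helix selections from a YAML config
#'
#' The config maps helix labels to chain and residue range, e.g.
#' \preformatted{
#' helices:
#'   G-ALPHA1: {chain: A, first_residue: 50, last_residue: 84}
#'   G-ALPHA2: {chain: A, first_residue: 138, last_residue: 175}
#' }
#' An illustrative example ships in
#' `system.file("extdata", "example_selection.yaml", package = "groovegeom")`.
#'
#' @param path YAML file path.
#' @return A list of [helix_selection()] objects, named by label.
#' @export
read_selection_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$helices) || length(cfg$helices) < 1L)
    stop("config must contain a non-empty 'helices' mapping", call. = FALSE)
  sels <- lapply(names(cfg$helices), function(lab) {
    h <- cfg$helices[[lab]]
    for (fld in c("chain", "first_residue", "last_residue"))
      if (is.null(h[[fld]]))
        stop(sprintf("helix '%s' is missing field '%s'", lab, fld),
             call. = FALSE)
    helix_selection(as.character(h$chain), h$first_residue, h$last_residue,
                    label = lab)
  })
  names(sels) <- names(cfg$helices)
  sels
}

#' Read helix C-alpha traces from a (multi-model) PDB file
#'
#' Parses the file with bio3d, one MODEL at a time, and extracts the CA atoms
#' of every selection in every frame.  Files without MODEL records yield a
#' single frame.  ATOM records with an altloc other than blank or `'A'` are
#' ignored; insertion codes within a selected range are rejected rather than
#' silently ordered.  Residue numbering follows the file's author numbering.
#'
#' @param path PDB file path.
#' @param selections a list of [helix_selection()] objects (or a single one).
#' @return A list with one element per frame; each element is a list of
#'   [helix_trace()]s named by selection label, with 0-based `frame_index`
#'   following MODEL order.
#' @examples
#' \donttest{
#' pdb <- tempfile(fileext = ".pdb")
#' traj <- generate_pair_trajectory(pair_trajectory_spec(
#'   helix_spec(24), helix_spec(24), separation = 12, n_frames = 3))
#' write_trajectory_pdb(traj, pdb)
#' sels <- list(helix_selection("A", 1, 24, "G-ALPHA1"),
#'              helix_selection("B", 1, 24, "G-ALPHA2"))
#' frames <- read_frames(pdb, sels)
#' length(frames)
#' }
#' @export
read_frames <- function(path, selections) {
  if (inherits(selections, "helix_selection")) selections <- list(selections)
  stopifnot(length(selections) >= 1L,
            all(vapply(selections, inherits, logical(1L), "helix_selection")))
  if (!file.exists(path))
    stop(sprintf("PDB file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blocks <- split_models(lines)
  labels <- vapply(selections, `[[`, character(1L), "label")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  frames <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    writeLines(c(blocks[[k]], "END"), tmp)
    pdb <- tryCatch(bio3d::read.pdb(tmp, verbose = FALSE),
                    error = function(e) {
                      stop(sprintf("frame %d of '%s' failed to parse as PDB: %s",
                                   k - 1L, path, conditionMessage(e)),
                           call. = FALSE)
                    })
    traces <- lapply(selections, extract_trace, pdb = pdb,
                     frame_index = k - 1L, path = path)
    names(traces) <- labels
    frames[[k]] <- traces
  }
  frames
}

# Split PDB lines into per-MODEL blocks; a file with no MODEL records is a
# single block.
split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
  Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
}

# Pull one selection's CA trace out of a parsed single-model bio3d pdb.
extract_trace <- function(sel, pdb, frame_index, path) {
  a <- pdb$atom
  keep <- a$type == "ATOM" & a$elety == "CA" &
    !is.na(a$chain) & a$chain == sel$chain_id &
    a$resno >= sel$first_residue & a$resno <= sel$last_residue &
    (is.na(a$alt) | a$alt == "A")
  a <- a[keep, , drop = FALSE]
  if (any(!is.na(a$insert)))
    stop(sprintf(
      "frame %d: insertion codes within %s (chain %s %d-%d) are not supported",
      frame_index, sel$label, sel$chain_id, sel$first_residue,
      sel$last_residue), call. = FALSE)
  wanted <- sel$first_residue:sel$last_residue
  missing <- setdiff(wanted, a$resno)
  if (length(missing) > 0L)
    stop(sprintf(
      "frame %d: no CA atom for chain %s residue(s) %s (selection %s)",
      frame_index, sel$chain_id, paste(missing, collapse = ", "), sel$label),
      call. = FALSE)
  if (anyDuplicated(a$resno))
    stop(sprintf("frame %d: duplicate CA atoms in chain %s (selection %s)",
                 frame_index, sel$chain_id, sel$label), call. = FALSE)
  a <- a[order(a$resno), , drop = FALSE]
  helix_trace(cbind(a$x, a$y, a$z), a$resno, sel$chain_id, frame_index,
              sel$label)
}
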