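#' Construct a single-conformation structure frame
#'
#' A `structure_frame` couples per-atom metadata with an N x 3 matrix of
#' Cartesian coordinates in Angstrom, aligned row-for-row. It is the unit
#' object all single-structure analyses (lip distances, hinge angles,
#' hydrogen-bond detection) operate on.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `residue_number`, `insertion_code`, `chain_id`,
#'   `altloc`, `occupancy`, `is_hetatm`. Missing optional columns
#'   (`insertion_code`, `altloc`, `is_hetatm`) are filled with defaults.
#' @param coords numeric matrix, N x 3, Angstrom.
#' @return An object of class `structure_frame`: a list with elements
#'   `atoms` and `coords`.
#' @examples
#' fr <- structure_frame(
#'   data.frame(serial = 1:2, atom_name = "CA", element = "C",
#'              residue_name = "ALA", residue_number = 1:2,
#'              chain_id = "A", occupancy = 1),
#'   rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' n_atoms(fr)
#' @export
structure_frame <- function(atoms, coords) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    hs_stop("invalid_frame", "coords must have 3 columns, got %d", ncol(coords))
  if (nrow(atoms) != nrow(coords))
    hs_stop("invalid_frame", "atoms (%d rows) and coords (%d rows) differ in length",
            nrow(atoms), nrow(coords))
  if (!all(is.finite(coords)))
    hs_stop("invalid_frame", "non-finite coordinates present")
  for (col in c("serial", "atom_name", "element", "residue_name",
                "residue_number", "chain_id", "occupancy")) {
    if (is.null(atoms[[col]]))
      hs_stop("invalid_frame", "atoms is missing required column '%s'", col)
  }
  if (is.null(atoms$insertion_code)) atoms$insertion_code <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$is_hetatm)) atoms$is_hetatm <- FALSE
  if (anyDuplicated(atoms$serial))
    hs_stop("invalid_frame", "duplicate atom serial numbers within a frame")
  if (any(!nzchar(atoms$element)))
    hs_stop("invalid_frame", "empty element symbols present")
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms (%d HETATM), chains: %s\n",
              nrow(x$atoms), sum(x$atoms$is_hetatm),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a frame or trajectory topology
#' @param x a `structure_frame` or `trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "structure_frame")) return(nrow(x$atoms))
  if (inherits(x, "trajectory")) return(nrow(x$topology))
  hs_stop("invalid_input", "n_atoms expects a structure_frame or trajectory")
}

#' Construct a trajectory
#'
#' An ordered series of conformations sharing one topology. Coordinates are
#' held as a T x N x 3 array; `times` carries the frame times in
#' nanoseconds and must be strictly increasing.
#'
#' @param topology data.frame of atom metadata (see [structure_frame()]).
#' @param frames numeric array T x N x 3 (Angstrom), or a list of N x 3
#'   matrices.
#' @param times numeric vector of frame times, ns. Defaults to
#'   `(seq_len(T) - 1) * timestep`.
#' @param timestep frame spacing in ns used when `times` is absent.
#' @return An object of class `trajectory` with elements `topology`,
#'   `frames`, `times`.
#' @export
trajectory <- function(topology, frames, times = NULL, timestep = 1) {
  if (is.list(frames) && !is.array(frames)) {
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    hs_stop("invalid_trajectory", "frames must be a T x N x 3 array")
  nt <- dim(frames)[1]
  if (nt < 1L) hs_stop("invalid_trajectory", "trajectory needs at least one frame")
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  if (nrow(topology) != dim(frames)[2])
    hs_stop("invalid_trajectory",
            "topology has %d atoms but frames carry %d coordinate rows",
            nrow(topology), dim(frames)[2])
  if (is.null(times)) times <- (seq_len(nt) - 1) * timestep
  times <- as.numeric(times)
  if (length(times) != nt)
    hs_stop("invalid_trajectory", "times length (%d) != frame count (%d)",
            length(times), nt)
  if (nt > 1L && any(diff(times) <= 0))
    hs_stop("invalid_trajectory", "frame times must be strictly increasing")
  if (!all(is.finite(frames)))
    hs_stop("invalid_trajectory", "non-finite coordinates present")
  if (is.null(topology$insertion_code)) topology$insertion_code <- ""
  if (is.null(topology$altloc)) topology$altloc <- ""
  if (is.null(topology$is_hetatm)) topology$is_hetatm <- FALSE
  rownames(topology) <- NULL
  dimnames(frames) <- NULL
  structure(list(topology = topology, frames = frames, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.4g .. %.4g ns\n",
              n_frames(x), nrow(x$topology), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$frames)[1]
}

#' Extract one frame of a trajectory as a structure_frame
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return a `structure_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj))
    hs_stop("invalid_input", "frame index %d out of range 1..%d", i, n_frames(traj))
  structure_frame(traj$topology, traj$frames[i, , , drop = TRUE])
}

#' Subset a trajectory by frame indices
#' @param traj a `trajectory`.
#' @param idx integer vector of frame indices, strictly increasing.
#' @return a `trajectory` with the selected frames and their times.
#' @export
subset_frames <- function(traj, idx) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- as.integer(idx)
  if (length(idx) < 1L)
    hs_stop("insufficient_frames", "frame subset is empty")
  trajectory(traj$topology, traj$frames[idx, , , drop = FALSE],
             times = traj$times[idx])
}
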