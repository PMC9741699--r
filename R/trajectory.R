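#' Trajectory container
#'
#' A trajectory is an ordered set of coordinate snapshots sharing one
#' topology. Coordinates are stored bio3d-style as an `n_frames x (3*n_atoms)`
#' matrix in Angstrom; the topology is a data frame with one row per atom
#' (`chain`, `resno`, `resid`, `elety`, `elem`). Exactly two protein chains,
#' addressed as "a" and "b", are kept.
#'
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns
#' @param atoms data.frame with columns chain, resno, resid, elety, elem
#' @param frame_spacing time between frames in ns
#' @param chain_map named character vector mapping the labels "a" and "b"
#'   to chain identifiers present in `atoms$chain`
#' @return an object of class `traj`
#' @export
new_trajectory <- function(xyz, atoms, frame_spacing = 1,
                           chain_map = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  stopifnot(is.matrix(xyz), ncol(xyz) == 3 * nrow(atoms))
  need <- c("chain", "resno", "resid", "elety", "elem")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  chains <- unique(atoms$chain)
  if (length(chains) != 2)
    stop("exactly two chains required, found: ",
         paste(chains, collapse = ", "))
  if (is.null(chain_map))
    chain_map <- stats::setNames(sort(chains), c("a", "b"))
  if (!all(chain_map %in% chains))
    stop("chain_map refers to chains not present")
  structure(list(xyz = xyz, atoms = atoms,
                 frame_spacing = frame_spacing, chain_map = chain_map),
            class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf("<traj> %d frames, %d atoms, chains %s=a %s=b, dt = %g ns\n",
              n_frames(x), nrow(x$atoms), x$chain_map["a"], x$chain_map["b"],
              x$frame_spacing))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `traj` object
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an n_atoms x 3 matrix
#' @param traj a `traj` object
#' @param i frame index (1-based)
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

# logical atom mask for the chain addressed by label "a"/"b" (or a raw id)
chain_mask <- function(traj, label) {
  id <- if (label %in% names(traj$chain_map)) traj$chain_map[[label]] else label
  if (!id %in% traj$atoms$chain)
    stop(sprintf("chain '%s' not found; available: %s", label,
                 paste(unique(traj$atoms$chain), collapse = ", ")))
  traj$atoms$chain == id
}

# heavy-atom (non-hydrogen) mask
heavy_mask <- function(traj) traj$atoms$elem != "H"

#' Subset a trajectory to a frame range
#' @param traj a `traj` object
#' @param frames integer vector of frame indices
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(all(frames >= 1), all(frames <= n_frames(traj)))
  out <- traj
  out$xyz <- traj$xyz[frames, , drop = FALSE]
  out
}

#' Load a two-chain trajectory from PDB (and optionally a DCD file)
#'
#' Accepts a multi-model PDB, or a single-model PDB used as topology for a
#' DCD trajectory. The two requested chains are retained and addressed as
#' "a" and "b" throughout the package.
#'
#' @param structure_path path to a PDB file
#' @param trajectory_path optional path to a DCD trajectory
#' @param chain_a,chain_b chain identifiers in the file
#' @param frame_spacing time between frames in ns
#' @return a [new_trajectory()] object
#' @export
load_trajectory <- function(structure_path, trajectory_path = NULL,
                            chain_a = "A", chain_b = "B",
                            frame_spacing = 1) {
  if (!file.exists(structure_path)) stop("file not found: ", structure_path)
  pdb <- bio3d::read.pdb(structure_path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  avail <- unique(at$chain)
  for (ch in c(chain_a, chain_b))
    if (!ch %in% avail)
      stop(sprintf("chain '%s' not in file; available chains: {%s}", ch,
                   paste(avail, collapse = ", ")))
  keep <- at$chain %in% c(chain_a, chain_b) & at$type %in% c("ATOM", "HETATM")
  idx <- which(keep)
  xyz_cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  xyz <- xyz[, xyz_cols, drop = FALSE]
  if (!is.null(trajectory_path)) {
    dcd <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    xyz <- dcd[, xyz_cols, drop = FALSE]
  }
  if (nrow(xyz) == 0) stop("zero frames in input")
  atoms <- data.frame(chain = at$chain[keep], resno = at$resno[keep],
                      resid = at$resid[keep], elety = at$elety[keep],
                      elem = element_from_name(at$elety[keep]),
                      stringsAsFactors = FALSE)
  new_trajectory(xyz, atoms, frame_spacing,
                 chain_map = c(a = chain_a, b = chain_b))
}

#' Write a trajectory as a multi-model PDB
#' @param traj a `traj` object
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$atoms
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain)
  invisible(path)
}
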