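# Core molecular containers: Topology, Trajectory, AtomSelection, HBondCriteria.
# Coordinates are Angstrom everywhere; atom and frame indices are 1-based;
# residue numbers follow the source file (PDB convention).

.masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
             P = 30.974, S = 32.06)

#' Guess the chemical element from a PDB atom name
#'
#' Strips digits, primes and blanks and takes the leading letter, which is
#' correct for the standard protein/nucleotide atom-name vocabulary
#' (`OE1 -> O`, `NZ -> N`, `H12 -> H`, `CA -> C`).
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols; unknown leading letters give
#'   `"X"`.
#' @export
guess_element <- function(name) {
  stripped <- gsub("[0-9' ]", "", name)
  first <- toupper(substr(stripped, 1, 1))
  ifelse(first %in% names(.masses), first, "X")
}

#' Construct a molecular topology
#'
#' A topology is the frame-independent description of a system: atoms (name,
#' element, residue, chain, mass) plus covalent bonds. Atoms of one residue
#' must be contiguous; atom indices are implicit 1-based row numbers.
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid` (integer
#'   residue number), `chain`; optional `element` (guessed from `name` when
#'   absent) and `mass` (filled from the element when absent).
#' @param bonds two-column integer matrix of bonded atom-index pairs, or
#'   `NULL` for no bonds.
#' @return an object of class `"topology"` with components `atoms`, `bonds`,
#'   `chains` and `n_atoms`.
#' @export
topology <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: topology must have >= 1 atom")
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$mass)) {
    atoms$mass <- unname(.masses[atoms$element])
    atoms$mass[is.na(atoms$mass)] <- 0
  }
  n <- nrow(atoms)
  atoms$index <- seq_len(n)
  rownames(atoms) <- NULL

  # residue contiguity: each (chain, resid) pair appears in one run
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  runs <- rle(key)
  if (anyDuplicated(runs$values) > 0)
    stop("atoms of one residue must be contiguous in the atom list")

  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 2)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) > 0) {
      if (any(bonds < 1L | bonds > n))
        stop("bond references an atom index outside 1..", n)
      if (any(bonds[, 1] == bonds[, 2]))
        stop("bond references the same atom twice")
    }
  }
  structure(
    list(atoms = atoms, bonds = bonds,
         chains = unique(atoms$chain), n_atoms = n),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = ", "), "],",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x a `topology` or `trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) return(x$topology$n_atoms)
  x$n_atoms
}

#' Infer covalent bonds from inter-atomic distances
#'
#' Distance heuristic used when the input file carries no CONECT records:
#' heavy-atom pairs closer than 1.9 Angstrom and heavy-hydrogen pairs closer
#' than 1.2 Angstrom are bonded. Needed only for hydrogen-bond donor
#' detection, so H-H pairs are never bonded.
#'
#' @param atoms atom table as in [topology()] (with `element`).
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return two-column integer matrix of bonded pairs.
#' @export
infer_bonds <- function(atoms, coords) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  is_h <- atoms$element == "H"
  d <- as.matrix(stats::dist(coords))
  cutoff <- matrix(1.9, n, n)
  cutoff[is_h, ] <- 1.2
  cutoff[, is_h] <- 1.2
  cutoff[is_h, is_h] <- 0      # no H-H bonds
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  matrix(as.integer(hit), ncol = 2, dimnames = NULL)
}

#' Construct a trajectory
#'
#' @param topology a [topology()].
#' @param coords either an `n_frames x n_atoms x 3` array or a single
#'   `n_atoms x 3` matrix (one frame), in Angstrom.
#' @param frame_times optional numeric vector of frame times (ps).
#' @return an object of class `"trajectory"` with components `topology`,
#'   `coords` (always a 3-d array), `n_frames`, `frame_times`.
#' @export
trajectory <- function(topology, coords, frame_times = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != topology$n_atoms)
    stop("topology mismatch: coords have ", dim(coords)[2],
         " atoms but topology has ", topology$n_atoms)
  if (dim(coords)[1] < 1) stop("trajectory must have >= 1 frame")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(frame_times)) {
    stopifnot(length(frame_times) == dim(coords)[1])
  }
  structure(
    list(topology = topology, coords = coords,
         n_frames = dim(coords)[1], frame_times = frame_times),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n_frames, "frames x", n_atoms(x), "atoms\n")
  invisible(x)
}

#' Extract one frame of a trajectory as an n x 3 matrix
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"), i >= 1, i <= traj$n_frames)
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the convention of standard MD trajectory H-bond analysis:
#' donor-heavy-atom to acceptor-heavy-atom distance of at most 3.0 Angstrom
#' and a donor-hydrogen-acceptor angle of at least 135 degrees. Boundaries
#' are closed (a pair exactly at a cutoff counts as bonded).
#'
#' @param max_da_distance maximum donor-acceptor heavy-atom distance
#'   (Angstrom, > 0).
#' @param min_dha_angle minimum D-H-A angle (degrees, in (0, 180]).
#' @return an object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_da_distance = 3.0, min_dha_angle = 135) {
  if (!is.numeric(max_da_distance) || max_da_distance <= 0)
    stop("max_da_distance must be > 0")
  if (!is.numeric(min_dha_angle) || min_dha_angle <= 0 || min_dha_angle > 180)
    stop("min_dha_angle must lie in (0, 180]")
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

#' @export
print.hbond_criteria <- function(x, ...) {
  cat(sprintf("hbond criteria: D-A <= %.2f A, D-H-A >= %.1f deg\n",
              x$max_da_distance, x$min_dha_angle))
  invisible(x)
}
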