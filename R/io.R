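# Structure and trajectory file I/O.
#
# PDB reading/writing and DCD reading are delegated to bio3d; a minimal
# CHARMM-format DCD writer is provided because bio3d has none. All
# coordinates are Angstrom.

# coords array (nf x na x 3)  <->  bio3d xyz matrix (nf x 3N, x1 y1 z1 x2 ...)
.as_xyz_matrix <- function(coords) {
  d <- dim(coords)
  matrix(aperm(coords, c(1, 3, 2)), d[1], 3 * d[2])
}

.from_xyz_matrix <- function(xyz, n_atoms) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  aperm(array(xyz, c(nrow(xyz), 3, n_atoms)), c(1, 3, 2))
}

.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records found")
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", i, ": shorter than 54 columns")
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("malformed ATOM record at line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

# Rename chain segments when the same chain id recurs in a non-contiguous
# block (TER-separated segments reusing an id). Segments get A, B, ... in
# order of appearance.
.resolve_chain_collisions <- function(chain) {
  runs <- rle(chain)
  if (anyDuplicated(runs$values) == 0) return(chain)
  if (length(runs$values) > length(LETTERS))
    stop("more than 26 chain segments; cannot auto-rename")
  warning("chain id reused across non-contiguous segments; segments renamed ",
          paste(LETTERS[seq_along(runs$values)], collapse = ", "))
  inverse.rle(list(values = LETTERS[seq_along(runs$values)],
                   lengths = runs$lengths))
}

#' Read a (possibly multi-model) PDB structure
#'
#' MODEL records become trajectory frames; atom order is preserved from the
#' file; elements are taken from the element column when present and guessed
#' from the atom name otherwise. Bonds absent from the file are inferred by
#' the distance heuristic of [infer_bonds()] on the first frame.
#'
#' @param path PDB file path.
#' @return list with components `topology` and `trajectory` (>= 1 frame).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n <- nrow(at)
  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[blank] <- guess_element(at$elety[blank])
  element <- trimws(toupper(element))
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  chain <- .resolve_chain_collisions(chain)
  atoms <- data.frame(name = at$elety, element = element,
                      resname = at$resid, resid = at$resno,
                      chain = chain, stringsAsFactors = FALSE)
  coords <- .from_xyz_matrix(pdb$xyz, n)
  frame1 <- matrix(coords[1, , ], ncol = 3)
  topo_nobonds <- topology(atoms)
  bonds <- infer_bonds(topo_nobonds$atoms, frame1)
  topo <- topology(atoms, bonds)
  list(topology = topo, trajectory = trajectory(topo, coords))
}

#' Read a coordinate trajectory against a known topology
#'
#' Supports DCD (binary, read through bio3d) and multi-model PDB. XTC is not
#' supported and raises an informative error.
#'
#' @param path trajectory file (`.dcd` or `.pdb`).
#' @param topology the [topology()] the frames belong to; the file's atom
#'   count must match.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology) {
  stopifnot(inherits(topology, "topology"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty trajectory file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc")
    stop("XTC reading is not supported; supply DCD or multi-model PDB")
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    na_file <- ncol(xyz) / 3
    if (na_file != topology$n_atoms)
      stop("topology mismatch: trajectory has ", na_file,
           " atoms, topology has ", topology$n_atoms)
    return(trajectory(topology, .from_xyz_matrix(xyz, topology$n_atoms)))
  }
  if (ext %in% c("pdb", "ent")) {
    tr <- read_structure(path)$trajectory
    if (n_atoms(tr) != topology$n_atoms)
      stop("topology mismatch: trajectory has ", n_atoms(tr),
           " atoms, topology has ", topology$n_atoms)
    return(trajectory(topology, tr$coords))
  }
  stop("unsupported trajectory format: .", ext)
}

#' Write a trajectory as CHARMM-format DCD
#'
#' Minimal single-precision DCD writer (no unit cell, native endianness),
#' round-trip compatible with `bio3d::read.dcd()`.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- traj$n_frames
  na <- n_atoms(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(nbytes, writer) {
    writeBin(as.integer(nbytes), con, size = 4)
    writer()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf           # frames
  icntrl[2] <- 1L           # first step
  icntrl[3] <- 1L           # step interval
  icntrl[4] <- nf           # total steps
  icntrl[20] <- 24L         # CHARMM version stamp
  rec(84, function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  })
  title <- formatC("written by mdiface::write_dcd", width = 80, flag = "-")
  rec(84, function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  })
  rec(4, function() writeBin(as.integer(na), con, size = 4))
  for (i in seq_len(nf)) {
    for (d in 1:3) {
      rec(4 * na, function() writeBin(as.numeric(traj$coords[i, , d]),
                                      con, size = 4))
    }
  }
  invisible(path)
}

#' Write a trajectory (or one frame) as PDB
#'
#' Multi-frame trajectories are written as multi-model PDB.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param b optional per-atom B-factor vector (defaults to 0).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path, b = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$topology$atoms
  if (is.null(b)) b <- rep(0, nrow(at))
  bio3d::write.pdb(file = path, xyz = .as_xyz_matrix(traj$coords),
                   resno = at$resid, resid = at$resname, chain = at$chain,
                   elety = at$name, elesy = at$element,
                   o = rep(1, nrow(at)), b = b)
  invisible(path)
}

#' Write per-residue values into the B-factor column of a PDB file
#'
#' The standard mechanism for colorimetric per-residue mapping: every atom of
#' a residue carries that residue's value in the B-factor field. Masked
#' residues (value `NA`, or residues absent from `per_residue_values`) are
#' written as 0.00 and listed in a leading REMARK record.
#'
#' @param topology a [topology()].
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param per_residue_values named numeric vector; names are residue numbers.
#'   `NA` marks a masked residue.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(topology, frame, per_residue_values, path) {
  stopifnot(inherits(topology, "topology"))
  vals <- per_residue_values
  finite <- vals[!is.na(vals)]
  if (any(finite < -999.99 | finite > 999.99))
    stop("B-factor value outside [-999.99, 999.99]")
  at <- topology$atoms
  key <- as.character(at$resid)
  b <- unname(vals[key])                 # NA for absent or masked residues
  masked_res <- sort(unique(at$resid[is.na(b)]))
  b[is.na(b)] <- 0
  tmp <- tempfile(fileext = ".pdb")
  write_pdb(trajectory(topology, frame), tmp, b = b)
  lines <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  remark <- if (length(masked_res) > 0) {
    sprintf("REMARK 999 MASKED RESIDUES (B-FACTOR SET TO 0.00): %s",
            paste(masked_res, collapse = " "))
  } else {
    "REMARK 999 NO MASKED RESIDUES"
  }
  writeLines(c(remark, lines), path)
  invisible(path)
}

# Deterministic TSV writer with '#'-prefixed header comment lines.
.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
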