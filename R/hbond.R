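# Geometric hydrogen-bond detection and occupancy time-averaging.
#
# A hydrogen bond is counted in a frame when the donor-heavy-atom to
# acceptor-heavy-atom distance is at most `max_da_distance` AND the
# donor-hydrogen-acceptor angle is at least `min_dha_angle` (closed
# boundaries). Occupancy is the percentage of frames bonded.

#' Construct a donor-hydrogen-acceptor triple
#'
#' @param donor index of the donor heavy atom (N or O).
#' @param hydrogen index of a hydrogen covalently bonded to the donor.
#' @param acceptor index of the acceptor heavy atom (N or O), distinct from
#'   the donor and not bonded to the hydrogen.
#' @param topology optional [topology()]; when supplied the bonding and
#'   element invariants are checked.
#' @return an object of class `"hbond_triple"`.
#' @export
hbond_triple <- function(donor, hydrogen, acceptor, topology = NULL) {
  donor <- as.integer(donor); hydrogen <- as.integer(hydrogen)
  acceptor <- as.integer(acceptor)
  if (donor == acceptor) stop("donor and acceptor must be distinct atoms")
  if (!is.null(topology)) {
    b <- topology$bonds
    bonded <- function(i, j)
      any((b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i))
    if (!bonded(donor, hydrogen))
      stop("hydrogen ", hydrogen, " is not bonded to donor ", donor)
    if (bonded(acceptor, hydrogen))
      stop("acceptor ", acceptor, " is bonded to the hydrogen")
    el <- topology$atoms$element
    if (!el[donor] %in% c("N", "O") || !el[acceptor] %in% c("N", "O"))
      stop("donor and acceptor must be N or O heavy atoms")
    if (el[hydrogen] != "H") stop("atom ", hydrogen, " is not a hydrogen")
  }
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor),
            class = "hbond_triple")
}

#' Report label for a triple
#'
#' Follows the acceptor-first convention used in trajectory H-bond reports:
#' `RES<num>:<acceptor atom>-RES<num>:<hydrogen atom>`.
#'
#' @param triple an [hbond_triple()].
#' @param topology the [topology()] the indices refer to.
#' @return a single string.
#' @export
triple_label <- function(triple, topology) {
  at <- topology$atoms
  tag <- function(i) paste0(at$resname[i], at$resid[i], ":", at$name[i])
  paste0(tag(triple$acceptor), "-", tag(triple$hydrogen))
}

#' Enumerate hydrogen-bond donors and acceptors in a selection
#'
#' Donors are N/O heavy atoms with at least one covalently bonded hydrogen
#' (one donor entry per hydrogen, so e.g. a lysine NZ with three hydrogens
#' yields three entries). Acceptors are all N/O heavy atoms in the selection.
#' Hydrogens follow their heavy atom: the heavy atom must be in the
#' selection, the hydrogen need not be listed separately.
#'
#' @param topology a [topology()] with bonds and explicit hydrogens.
#' @param selection an [select_atoms()] result, a selection expression, or
#'   `NULL` for all atoms.
#' @return list with `donors` (data.frame `heavy`, `hydrogen`) and
#'   `acceptors` (integer vector).
#' @export
find_donors_acceptors <- function(topology, selection = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (!any(topology$atoms$element == "H"))
    stop("topology has no explicit hydrogens; H-bond analysis requires ",
         "a protonated structure")
  idx <- if (is.null(selection)) seq_len(topology$n_atoms)
         else .as_selection(topology, selection)$indices
  el <- topology$atoms$element
  no_sel <- idx[el[idx] %in% c("N", "O")]
  if (length(no_sel) == 0) {
    warning("selection contains no N/O atoms")
    return(list(donors = data.frame(heavy = integer(0), hydrogen = integer(0)),
                acceptors = integer(0)))
  }
  b <- topology$bonds
  donors <- data.frame(heavy = integer(0), hydrogen = integer(0))
  if (nrow(b) > 0) {
    # bonds with one heavy N/O (selected) end and one hydrogen end
    h1 <- el[b[, 1]] == "H"
    h2 <- el[b[, 2]] == "H"
    heavy <- ifelse(h1, b[, 2], b[, 1])
    hyd <- ifelse(h1, b[, 1], b[, 2])
    keep <- xor(h1, h2) & heavy %in% no_sel
    donors <- data.frame(heavy = as.integer(heavy[keep]),
                         hydrogen = as.integer(hyd[keep]))
    donors <- donors[order(donors$heavy, donors$hydrogen), , drop = FALSE]
    rownames(donors) <- NULL
  }
  list(donors = donors, acceptors = no_sel)
}

# Vectorized per-frame bonded test for one triple: returns logical n_frames.
.bonded_frames <- function(traj, triple, criteria) {
  D <- matrix(traj$coords[, triple$donor, ], ncol = 3)
  H <- matrix(traj$coords[, triple$hydrogen, ], ncol = 3)
  A <- matrix(traj$coords[, triple$acceptor, ], ncol = 3)
  da <- sqrt(rowSums((D - A)^2))
  if (any(da == 0))
    stop("geometry error: coincident donor and acceptor coordinates")
  u <- D - H
  v <- A - H
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  da <= criteria$max_da_distance & ang >= criteria$min_dha_angle
}

#' Per-frame hydrogen-bond test
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param triple an [hbond_triple()].
#' @param criteria an [hbond_criteria()].
#' @return `TRUE` iff the donor-acceptor distance and D-H-A angle satisfy the
#'   criteria (closed boundaries).
#' @export
hbond_present <- function(frame, triple, criteria = hbond_criteria()) {
  traj1 <- structure(list(coords = array(frame, c(1L, dim(frame))),
                          n_frames = 1L), class = "trajectory")
  .bonded_frames(traj1, triple, criteria)[1]
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For each triple, the percentage of frames in which the bond satisfies the
#' geometric criteria: `occupancy = 100 * n_bonded / n_frames`. Occupancies
#' below 5% are reported but flagged (`low` column).
#'
#' @param traj a [trajectory()].
#' @param triples a list of [hbond_triple()] (a single triple is accepted).
#' @param criteria an [hbond_criteria()].
#' @return data.frame of class `"occupancy_table"` with columns `label`,
#'   `donor`, `hydrogen`, `acceptor` (atom indices), `occupancy_pct`,
#'   `n_bonded`, `n_frames`, `low`; criteria attached as attribute
#'   `"criteria"`.
#' @export
hbond_occupancy <- function(traj, triples, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "trajectory"))
  if (inherits(triples, "hbond_triple")) triples <- list(triples)
  nf <- traj$n_frames
  rows <- lapply(triples, function(tr) {
    nb <- sum(.bonded_frames(traj, tr, criteria))
    data.frame(label = triple_label(tr, traj$topology),
               donor = tr$donor, hydrogen = tr$hydrogen,
               acceptor = tr$acceptor,
               occupancy_pct = 100 * nb / nf,
               n_bonded = nb, n_frames = nf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(label = character(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      occupancy_pct = numeric(0), n_bonded = integer(0),
                      n_frames = integer(0))
  out$low <- out$occupancy_pct < 5
  attr(out, "criteria") <- criteria
  class(out) <- c("occupancy_table", class(out))
  out
}

#' Composite occupancy of a group of hydrogen bonds
#'
#' Two semantics for aggregating a group of equivalent bonds (e.g. the
#' oxygens of one phosphate group): `"sum"` adds the individual occupancies
#' (may exceed 100%); `"union"` is the percentage of frames in which at least
#' one bond of the group is present (at most 100%).
#'
#' @param traj a [trajectory()].
#' @param group non-empty list of [hbond_triple()].
#' @param criteria an [hbond_criteria()].
#' @param mode `"sum"` or `"union"`.
#' @return composite occupancy in percent.
#' @export
composite_occupancy <- function(traj, group, criteria = hbond_criteria(),
                                mode = c("sum", "union")) {
  mode <- match.arg(mode)
  if (inherits(group, "hbond_triple")) group <- list(group)
  if (length(group) == 0) stop("group must contain at least one triple")
  bonded <- vapply(group, function(tr) .bonded_frames(traj, tr, criteria),
                   logical(traj$n_frames))
  bonded <- matrix(bonded, nrow = traj$n_frames)
  if (mode == "sum") {
    sum(100 * colMeans(bonded))
  } else {
    100 * mean(rowSums(bonded) > 0)
  }
}

#' Write an occupancy table as TSV
#'
#' Criteria are echoed in `#` comment header lines.
#'
#' @param records an `occupancy_table` from [hbond_occupancy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(records, path) {
  crit <- attr(records, "criteria")
  comments <- c(
    sprintf("max_da_distance_A: %g", crit$max_da_distance),
    sprintf("min_dha_angle_deg: %g", crit$min_dha_angle)
  )
  .write_tsv(as.data.frame(records), path, comments)
}
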