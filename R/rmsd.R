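# Optimal rigid-body superposition (Kabsch, via SVD) and time-averaged RMSD.

#' Root-mean-square deviation of two coordinate sets (no fitting)
#' @param a,b `n x 3` coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

# Collinear (or pointlike) fit sets make the optimal rotation ill-defined;
# they show up as a rank-deficient cross-covariance (second singular value
# ~ 0 while coordinates have spread).
.check_fit_degenerate <- function(d, xc, yc) {
  spread <- max(sum(xc^2), sum(yc^2))
  if (spread > 0 && d[2] < 1e-10 * max(d[1], spread * 1e-6))
    stop("superposition error: degenerate (collinear) fit geometry")
  invisible(TRUE)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `mobile %*% R + t` to `reference` over the fitted atoms. The rotation is
#' computed from the SVD of the cross-covariance matrix with the usual
#' determinant sign correction, so it is always proper (det +1, no
#' reflection).
#'
#' @param mobile,reference `n x 3` coordinate matrices with matching rows.
#' @param fit_selection optional [select_atoms()] result or index vector
#'   giving the atoms used for the fit (default: all rows). The returned
#'   `rmsd_after_fit` is over these atoms.
#' @return object of class `"superposition"`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3, Angstrom) and `rmsd_after_fit` (Angstrom),
#'   with the convention `fitted = mobile %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, fit_selection = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            all(dim(mobile) == dim(reference)))
  idx <- if (is.null(fit_selection)) seq_len(nrow(mobile))
         else if (inherits(fit_selection, "atom_selection")) fit_selection$indices
         else as.integer(fit_selection)
  x <- mobile[idx, , drop = FALSE]
  y <- reference[idx, , drop = FALSE]
  if (nrow(x) < 3) stop("superposition error: need >= 3 atoms to fit")
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  h <- crossprod(xc, yc)                  # 3x3 cross-covariance
  s <- svd(h)
  .check_fit_degenerate(s$d, xc, yc)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- as.numeric(cy - cx %*% rot)
  fitted <- xc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  structure(list(rotation = rot, translation = trans, rmsd_after_fit = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: RMSD after fit %.4f A\n", x$rmsd_after_fit))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords `n x 3` matrix.
#' @param sp a `"superposition"` from [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(coords %*% sp$rotation, 2, sp$translation, "+")
}

#' Per-frame RMSD series after rigid superposition
#'
#' Each frame is superposed on the reference over `fit_selection`; the RMSD
#' is then measured over `measure_selection` (which may differ, e.g. fit on
#' the whole molecule, measure one subdomain).
#'
#' @param traj a [trajectory()].
#' @param reference `n_atoms x 3` reference coordinates (default: frame 1,
#'   the experimental starting structure convention).
#' @param fit_selection selection (expression, [select_atoms()] or indices)
#'   used for the fit; default all atoms.
#' @param measure_selection selection measured; default = `fit_selection`.
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, fit_selection = NULL,
                        measure_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  fit_idx <- if (is.null(fit_selection)) seq_len(topo$n_atoms)
             else .as_selection(topo, fit_selection)$indices
  meas_idx <- if (is.null(measure_selection)) fit_idx
              else .as_selection(topo, measure_selection)$indices
  if (length(meas_idx) == 0) stop("empty measure selection")
  ref_fit <- reference[fit_idx, , drop = FALSE]
  ref_meas <- reference[meas_idx, , drop = FALSE]
  vapply(seq_len(traj$n_frames), function(i) {
    fr <- frame_coords(traj, i)
    sp <- kabsch_superpose(fr[fit_idx, , drop = FALSE], ref_fit)
    coord_rmsd(apply_transform(fr[meas_idx, , drop = FALSE], sp), ref_meas)
  }, numeric(1))
}

#' Time-averaged RMSD of a selection
#'
#' Mean over frames of the per-frame RMSD from [rmsd_series()]. This is the
#' subdomain structural-disruption metric: fit each frame on
#' `fit_selection`, measure deviation over `measure_selection`, average over
#' the trajectory.
#'
#' @inheritParams rmsd_series
#' @return time-averaged RMSD in Angstrom.
#' @export
time_averaged_rmsd <- function(traj, reference = NULL, fit_selection = NULL,
                               measure_selection = NULL) {
  mean(rmsd_series(traj, reference, fit_selection, measure_selection))
}

#' Write a per-frame RMSD series as TSV
#'
#' @param series numeric vector from [rmsd_series()].
#' @param path output path.
#' @param fit,measure selection expressions echoed in the header.
#' @return `path`, invisibly.
#' @export
write_rmsd_tsv <- function(series, path, fit = "", measure = "") {
  comments <- c(sprintf("fit_selection: %s", fit),
                sprintf("measure_selection: %s", measure),
                sprintf("time_averaged_rmsd_A: %.6f", mean(series)))
  .write_tsv(data.frame(frame = seq_along(series), rmsd_A = series),
             path, comments)
}
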