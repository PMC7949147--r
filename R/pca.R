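# Cartesian-covariance principal component analysis of a trajectory.
#
# Rigid-body motion is removed by superposing every frame on the iterative
# mean structure; the covariance of the centered Cartesian coordinates is
# then diagonalized (via SVD of the centered frame matrix, which handles
# both the 3N x 3N and the frames x frames regime with identical spectra).
# Covariance is non-mass-weighted.

.default_pca_selection <- function(topology) {
  at <- topology$atoms
  ca <- which(at$name == "CA" & at$element == "C")
  idx <- if (length(ca) >= 3) ca else which(at$element != "H")
  structure(list(indices = idx,
                 expression = if (length(ca) >= 3) "name CA" else "not element H",
                 n = length(idx)),
            class = "atom_selection")
}

#' Iterative mean structure of a trajectory
#'
#' Fixed point of fit-to-mean: superpose every frame on the current mean,
#' re-average, repeat until the mean moves less than `tol` (RMSD), starting
#' from frame 1. This is the superposition target used for PCA, since
#' covariance about the mean requires a self-consistent alignment.
#'
#' @param traj a [trajectory()] with >= 2 frames (1 frame returns frame 1).
#' @param selection atoms to use (expression, [select_atoms()] or indices);
#'   default: CA atoms when present, else heavy atoms.
#' @param tol convergence tolerance in Angstrom.
#' @param max_iter iteration guard; exceeding it raises a convergence error
#'   reporting the last delta.
#' @return `n_selected x 3` mean coordinates with attributes `iterations`
#'   and `delta`.
#' @export
iterative_mean_structure <- function(traj, selection = NULL, tol = 1e-6,
                                     max_iter = 100) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- if (is.null(selection)) .default_pca_selection(traj$topology)
         else .as_selection(traj$topology, selection)
  idx <- sel$indices
  if (length(idx) < 3) stop("selection must contain >= 3 atoms")
  frames <- lapply(seq_len(traj$n_frames),
                   function(i) frame_coords(traj, i)[idx, , drop = FALSE])
  m <- frames[[1]]
  if (traj$n_frames == 1) {
    attr(m, "iterations") <- 0L
    attr(m, "delta") <- 0
    return(m)
  }
  delta <- Inf
  for (it in seq_len(max_iter)) {
    aligned <- lapply(frames, function(fr)
      apply_transform(fr, kabsch_superpose(fr, m)))
    m_new <- Reduce(`+`, aligned) / length(aligned)
    delta <- coord_rmsd(m_new, m)
    m <- m_new
    if (delta < tol) {
      attr(m, "iterations") <- it
      attr(m, "delta") <- delta
      return(m)
    }
  }
  stop(sprintf(
    "mean structure did not converge in %d iterations (last delta %.3g A)",
    max_iter, delta))
}

#' Principal component analysis of Cartesian trajectory coordinates
#'
#' Frames are superposed on the iterative mean structure over `selection`,
#' flattened to `(x1, y1, z1, x2, ...)` rows, column-centered, and
#' decomposed. Eigenvalues (Angstrom^2, descending) are the variances along
#' the principal modes; the sum of all eigenvalues equals the trace of the
#' covariance matrix. Eigenvector signs are fixed so each vector's
#' largest-magnitude element is positive, making results reproducible
#' run-to-run.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param selection atoms to analyze; default CA when present, else heavy
#'   atoms.
#' @param k number of eigenvectors/projection columns to keep
#'   (`1 <= k <= min(3N, n_frames - 1)`).
#' @param tol convergence tolerance for the mean structure (Angstrom).
#' @return object of class `"pca_result"`: `mean_structure` (`N x 3`),
#'   `eigenvalues` (all, descending), `eigenvectors` (`3N x k`, orthonormal),
#'   `projections` (`n_frames x k`, Angstrom, column means 0), `selection`,
#'   `trace_covariance`, `n_frames`, `n_coords`.
#' @export
trajectory_pca <- function(traj, selection = NULL, k = 3, tol = 1e-6) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$n_frames < 2) stop("PCA requires more than one frame")
  sel <- if (is.null(selection)) .default_pca_selection(traj$topology)
         else .as_selection(traj$topology, selection)
  idx <- sel$indices
  n3 <- 3L * length(idx)
  kmax <- min(n3, traj$n_frames - 1L)
  if (k < 1 || k > kmax)
    stop("k must lie in 1..", kmax, " (min of 3N and n_frames - 1)")
  m <- iterative_mean_structure(traj, sel, tol = tol)
  X <- t(vapply(seq_len(traj$n_frames), function(i) {
    fr <- frame_coords(traj, i)[idx, , drop = FALSE]
    as.numeric(t(apply_transform(fr, kabsch_superpose(fr, m))))
  }, numeric(n3)))
  X <- sweep(X, 2, colMeans(X))
  s <- svd(X, nu = k, nv = k)
  nf <- traj$n_frames
  eigenvalues <- s$d^2 / (nf - 1)
  vectors <- s$v
  projections <- X %*% vectors
  # sign convention: largest-|element| of each eigenvector positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vectors[, j]))
    if (vectors[i_max, j] < 0) {
      vectors[, j] <- -vectors[, j]
      projections[, j] <- -projections[, j]
    }
  }
  structure(
    list(mean_structure = m, eigenvalues = eigenvalues,
         eigenvectors = vectors, projections = projections,
         selection = sel$expression, trace_covariance = sum(X^2) / (nf - 1),
         n_frames = nf, n_coords = n3, k = k,
         convergence = list(iterations = attr(m, "iterations"),
                            delta = attr(m, "delta"))),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$eigenvalues[seq_len(min(3, length(x$eigenvalues)))]
  cat(sprintf("PCA: %d frames x %d coordinates ('%s'); top eigenvalues (A^2): %s\n",
              x$n_frames, x$n_coords, x$selection,
              paste(sprintf("%.3f", ev), collapse = ", ")))
  invisible(x)
}

.density_hist <- function(x, edges) {
  h <- graphics::hist(x, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(density = h$density, counts = h$counts)
}

#' Normalized histogram of a principal-component projection
#'
#' Density (area-1) normalized histogram over a range symmetric about zero
#' spanning the observed extremes, for shape comparison between systems.
#'
#' @param result a [trajectory_pca()] result.
#' @param component which projection column (<= `k`).
#' @param bins number of bins (>= 2).
#' @return object of class `"pc_histogram"`: `bin_edges` (Angstrom),
#'   `density` (per Angstrom; integrates to 1), `counts`, `eigenvalue`
#'   (the component's weight, Angstrom^2), `component`.
#' @export
pc_histogram <- function(result, component = 1, bins = 100) {
  stopifnot(inherits(result, "pca_result"))
  if (bins < 2) stop("bins must be >= 2")
  if (component < 1 || component > result$k)
    stop("component must lie in 1..", result$k)
  proj <- result$projections[, component]
  r <- max(abs(proj))
  if (r == 0) r <- 0.5     # degenerate all-zero projections: unit-width range
  edges <- seq(-r, r, length.out = bins + 1)
  h <- .density_hist(proj, edges)
  structure(list(bin_edges = edges, density = h$density, counts = h$counts,
                 eigenvalue = result$eigenvalues[component],
                 component = component),
            class = "pc_histogram")
}

#' Histogram-intersection divergence of two samples
#'
#' `1 - sum(min(density_a, density_b)) * bin_width` over a shared symmetric
#' binning: 0 for identical samples, 1 for disjoint support.
#'
#' @param x,y numeric samples.
#' @param bins number of shared bins.
#' @return divergence in `[0, 1]`.
#' @export
histogram_divergence <- function(x, y, bins = 100) {
  if (bins < 2) stop("bins must be >= 2")
  r <- max(abs(c(x, y)))
  if (r == 0) return(0)
  edges <- seq(-r, r, length.out = bins + 1)
  bw <- edges[2] - edges[1]
  dx <- .density_hist(x, edges)$density
  dy <- .density_hist(y, edges)$density
  min(1, max(0, 1 - sum(pmin(dx, dy)) * bw))
}

#' PC1 distribution divergence between two systems
#'
#' Operationalizes the visual "divergent PC1 shape" comparison as a
#' histogram-intersection score on the first projection columns over a
#' shared binning.
#'
#' @param a,b [trajectory_pca()] results computed on equivalent selections
#'   (same coordinate count).
#' @param bins shared bin count.
#' @return divergence score in `[0, 1]` (0 = identical distributions).
#' @export
compare_pc1 <- function(a, b, bins = 100) {
  stopifnot(inherits(a, "pca_result"), inherits(b, "pca_result"))
  if (a$n_coords != b$n_coords)
    stop("comparability error: PCA selections have different sizes (",
         a$n_coords, " vs ", b$n_coords, " coordinates)")
  histogram_divergence(a$projections[, 1], b$projections[, 1], bins)
}

#' Write a PC histogram as TSV
#' @param hist a [pc_histogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  nb <- length(hist$density)
  df <- data.frame(bin_left = hist$bin_edges[seq_len(nb)],
                   bin_right = hist$bin_edges[seq_len(nb) + 1],
                   density = hist$density)
  .write_tsv(df, path,
             c(sprintf("component: %d", hist$component),
               sprintf("eigenvalue_A2: %.8f", hist$eigenvalue)))
}

#' Write PCA eigen-summary as JSON and projections as TSV
#' @param result a [trajectory_pca()] result.
#' @param json_path path for the eigen-summary JSON.
#' @param proj_path optional path for the projection time-series TSV.
#' @return `json_path`, invisibly.
#' @export
write_pca_json <- function(result, json_path, proj_path = NULL) {
  jsonlite::write_json(
    list(selection = result$selection, n_frames = result$n_frames,
         n_coords = result$n_coords, k = result$k,
         eigenvalues = result$eigenvalues,
         trace_covariance = result$trace_covariance,
         convergence = result$convergence),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(proj_path)) {
    df <- as.data.frame(result$projections)
    names(df) <- paste0("PC", seq_len(ncol(df)))
    .write_tsv(cbind(frame = seq_len(nrow(df)), df), proj_path)
  }
  invisible(json_path)
}
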