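# Cartesian-covariance PCA, projection histograms, and PC1 comparison.

all_atom_sel <- function(traj) seq_len(n_atoms(traj))

test_that("iterative mean structure handles static and rigid trajectories", {
  toy <- gen_toy_complex(4)
  static <- trajectory(toy$topology,
                       array(rep(toy$base, each = 6),
                             c(6, nrow(toy$base), 3)))
  m <- iterative_mean_structure(static, all_atom_sel(static))
  expect_equal(unclass(m)[, ], toy$base, tolerance = 1e-10,
               ignore_attr = TRUE)

  gr <- gen_rigid_trajectory(n_res = 6, n_frames = 20, seed = 7)
  m2 <- iterative_mean_structure(gr$trajectory, all_atom_sel(gr$trajectory))
  # equal to the base up to a global rigid transform
  expect_lt(kabsch_superpose(m2, gr$base)$rmsd_after_fit, 1e-6)
})

test_that("two-cluster trajectory has the aligned midpoint as its mean", {
  toy <- gen_toy_complex(5)
  x <- toy$base
  set.seed(33)
  y <- x + matrix(stats::rnorm(length(x), sd = 0.3), ncol = 3)
  coords <- array(0, c(40, nrow(x), 3))
  for (i in 1:40) coords[i, , ] <- if (i %% 2 == 0) x else y
  m <- iterative_mean_structure(trajectory(toy$topology, coords),
                                seq_len(nrow(x)), tol = 1e-9)
  mid <- (x + apply_transform(y, kabsch_superpose(y, x))) / 2
  expect_lt(kabsch_superpose(unclass(m), mid)$rmsd_after_fit, 1e-3)
})

test_that("a static trajectory has all-zero eigenvalues", {
  toy <- gen_toy_complex(3)
  static <- trajectory(toy$topology,
                       array(rep(toy$base, each = 5),
                             c(5, nrow(toy$base), 3)))
  p <- trajectory_pca(static, all_atom_sel(static), k = 2)
  expect_lt(max(p$eigenvalues), 1e-16)
})

test_that("a planted collective mode is recovered as PC1", {
  gm <- gen_mode_trajectory(n_res = 10, n_frames = 2000,
                            amplitude_sd = 1, noise_sd = 0.05, seed = 15)
  p <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 3)
  cosang <- abs(sum(p$eigenvectors[, 1] * gm$mode))
  expect_gte(cosang, 0.95)
  expect_gte(p$eigenvalues[1] / p$eigenvalues[2], 10)
  # eigenvalue sum equals the covariance trace
  expect_lt(abs(sum(p$eigenvalues) - p$trace_covariance) /
              p$trace_covariance, 1e-8)
  # projection columns are centered and eigenvectors orthonormal
  expect_lt(max(abs(colMeans(p$projections))), 1e-8 * sd(p$projections[, 1]))
  gram <- crossprod(p$eigenvectors)
  expect_lt(max(abs(gram - diag(3))), 1e-8)
  # PC1 projections track the planted amplitudes up to sign and mean
  a <- gm$amplitudes - mean(gm$amplitudes)
  expect_gt(abs(stats::cor(p$projections[, 1], a)), 0.99)
})

test_that("pure isotropic noise has no dominant mode", {
  gm <- gen_mode_trajectory(n_res = 2, n_frames = 5000,
                            amplitude_sd = 0, noise_sd = 0.1, seed = 25)
  p <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 3)
  expect_lt(p$eigenvalues[1] / p$eigenvalues[2], 1.2)
})

test_that("eigenvalues and |projections| are rigid-transform invariant", {
  gm <- gen_mode_trajectory(n_res = 4, n_frames = 150, seed = 18)
  sel <- all_atom_sel(gm$trajectory)
  p1 <- trajectory_pca(gm$trajectory, sel, k = 3)
  set.seed(91)
  moved <- transform_trajectory(gm$trajectory, random_rotation(), c(4, -9, 1))
  p2 <- trajectory_pca(moved, sel, k = 3)
  expect_equal(p2$eigenvalues, p1$eigenvalues, tolerance = 1e-6)
  for (j in 1:3) {
    agree <- max(abs(p2$projections[, j] - p1$projections[, j]))
    flipped <- max(abs(p2$projections[, j] + p1$projections[, j]))
    expect_lt(min(agree, flipped), 1e-5 * max(1, sd(p1$projections[, j])))
  }
})

test_that("full back-projection reconstructs the centered coordinates", {
  gm <- gen_mode_trajectory(n_res = 1, n_frames = 100, noise_sd = 0.2,
                            seed = 44)      # 10 atoms, 30 coordinates
  sel <- all_atom_sel(gm$trajectory)
  k_full <- 30
  p <- trajectory_pca(gm$trajectory, sel, k = k_full)
  recon <- p$projections %*% t(p$eigenvectors)
  # rebuild the centered matrix the same way the implementation aligns it
  m <- p$mean_structure
  X <- t(vapply(seq_len(gm$trajectory$n_frames), function(i) {
    fr <- frame_coords(gm$trajectory, i)
    as.numeric(t(apply_transform(fr, kabsch_superpose(fr, unclass(m)))))
  }, numeric(30)))
  X <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(recon - X)), 1e-8)
})

test_that("eigenvector sign convention makes runs reproducible", {
  gm <- gen_mode_trajectory(n_res = 3, n_frames = 100, seed = 5)
  p1 <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 2)
  p2 <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 2)
  expect_identical(p1$eigenvectors, p2$eigenvectors)
  expect_identical(p1$projections, p2$projections)
  i_max <- apply(abs(p1$eigenvectors), 2, which.max)
  expect_true(all(p1$eigenvectors[cbind(i_max, 1:2)] > 0))
})

test_that("k outside 1..min(3N, frames-1) is rejected", {
  gm <- gen_mode_trajectory(n_res = 1, n_frames = 10, seed = 2)
  expect_error(trajectory_pca(gm$trajectory,
                              all_atom_sel(gm$trajectory), k = 10),
               "k must lie")
  expect_error(trajectory_pca(gm$trajectory,
                              all_atom_sel(gm$trajectory), k = 0),
               "k must lie")
})

test_that("histograms integrate to one and capture degenerate projections", {
  toy <- gen_toy_complex(3)
  static <- trajectory(toy$topology,
                       array(rep(toy$base, each = 5),
                             c(5, nrow(toy$base), 3)))
  p0 <- trajectory_pca(static, seq_len(nrow(toy$base)), k = 2)
  h0 <- pc_histogram(p0, 1, bins = 20)
  expect_equal(sum(h0$counts > 0), 1L)    # single occupied bin
  bw <- diff(h0$bin_edges)[1]
  expect_equal(sum(h0$density) * bw, 1, tolerance = 1e-9)

  gm <- gen_mode_trajectory(n_res = 3, n_frames = 400, seed = 10)
  p <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 2)
  h <- pc_histogram(p, 1, bins = 50)
  expect_true(all(h$density >= 0))
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)
  expect_equal(h$bin_edges[1], -h$bin_edges[51])   # symmetric about zero
  expect_equal(h$eigenvalue, p$eigenvalues[1])
  expect_error(pc_histogram(p, 1, bins = 1), "bins")
  expect_error(pc_histogram(p, 5, bins = 10), "component")
})

test_that("Gaussian-mode PC1 histogram is close to the fitted normal", {
  gm <- gen_mode_trajectory(n_res = 3, n_frames = 8000,
                            amplitude_sd = 1, noise_sd = 0.05, seed = 61)
  p <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 1)
  x <- p$projections[, 1]
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = 0, sd = stats::sd(x)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a bimodal planted amplitude yields a two-peaked PC1 histogram", {
  gm <- gen_mode_trajectory(n_res = 3, n_frames = 4000,
                            mixture_means = c(-15, 5),
                            mixture_weights = c(0.7, 0.3),
                            mixture_sd = 1.5, noise_sd = 0.05, seed = 71)
  p <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 1)
  h <- pc_histogram(p, 1, bins = 80)
  dens <- h$density
  centers <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  peaks <- peaks[dens[peaks] > 0.25 * max(dens)]
  expect_gte(length(peaks), 2)
  expect_gte(max(diff(sort(peaks))), 5)   # modes separated by >= 5 bins
  # dominant mode sits at the majority component (|-15 - mean| = 6 after
  # centering), the minor one across zero at ~14; sign of PC1 is arbitrary
  dom <- centers[peaks[which.max(dens[peaks])]]
  minor <- centers[peaks[which.min(dens[peaks])]]
  expect_lt(abs(abs(dom) - 6), 2.5)
  expect_lt(abs(abs(minor) - 14), 3.5)
  expect_lt(dom * minor, 0)
})

test_that("PC1 divergence is 0 for identical, 1 for disjoint distributions", {
  gm <- gen_mode_trajectory(n_res = 3, n_frames = 300, seed = 12)
  p <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 1)
  expect_equal(compare_pc1(p, p), 0)
  expect_equal(histogram_divergence(stats::runif(500, -10, -5),
                                    stats::runif(500, 5, 10), bins = 40), 1)
  small <- gen_mode_trajectory(n_res = 2, n_frames = 300, seed = 12)
  q <- trajectory_pca(small$trajectory, all_atom_sel(small$trajectory), k = 1)
  expect_error(compare_pc1(p, q), "comparability")
})

test_that("divergence of two shifted normals matches the analytic overlap", {
  set.seed(55)
  x <- stats::rnorm(20000)
  y <- stats::rnorm(20000, mean = 2)     # means 0 and 2*sigma
  score <- histogram_divergence(x, y, bins = 50)
  analytic <- 1 - 2 * stats::pnorm(-1)   # overlap of N(0,1), N(2,1)
  expect_lt(abs(score - analytic), 0.05)
})

test_that("mean-structure iteration reports non-convergence", {
  gm <- gen_mode_trajectory(n_res = 3, n_frames = 50, noise_sd = 0.5, seed = 9)
  expect_error(iterative_mean_structure(gm$trajectory,
                                        all_atom_sel(gm$trajectory),
                                        tol = 1e-16, max_iter = 2),
               "did not converge")
})

test_that("PCA JSON/TSV writers round-trip the eigen-summary", {
  gm <- gen_mode_trajectory(n_res = 2, n_frames = 60, seed = 8)
  p <- trajectory_pca(gm$trajectory, all_atom_sel(gm$trajectory), k = 2)
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_pca_json(p, jf, tf)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(meta$eigenvalues, p$eigenvalues)
  proj <- utils::read.delim(tf)
  expect_equal(proj$PC1, p$projections[, 1])
  hf <- withr::local_tempfile(fileext = ".tsv")
  write_histogram_tsv(pc_histogram(p, 1, 30), hf)
  hh <- utils::read.delim(hf, comment.char = "#")
  expect_equal(sum(hh$density * (hh$bin_right - hh$bin_left)), 1,
               tolerance = 1e-9)
})
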