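# Independent oracles used to cross-check the implementation.

# Rotation matrix from z-y-z Euler angles.
rot_zyz <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# Brute-force minimal RMSD over rotations: coarse Euler-angle grid search
# followed by Nelder-Mead refinement from the best grid points. Never uses
# the SVD solution.
brute_min_rmsd <- function(mobile, reference, grid_step = pi / 6) {
  xc <- sweep(mobile, 2, colMeans(mobile))
  yc <- sweep(reference, 2, colMeans(reference))
  f <- function(p) {
    r <- rot_zyz(p[1], p[2], p[3])
    sqrt(mean(rowSums((xc %*% r - yc)^2)))
  }
  angles <- seq(0, 2 * pi - 1e-9, by = grid_step)
  betas <- seq(0, pi, by = grid_step)
  grid <- expand.grid(a = angles, b = betas, c = angles)
  vals <- apply(grid, 1, f)
  starts <- grid[order(vals)[1:5], , drop = FALSE]
  best <- min(vals)
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(as.numeric(starts[i, ]), f, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  best
}

# Replicate every frame of a trajectory through one rigid transform.
transform_trajectory <- function(traj, rotation, translation) {
  coords <- traj$coords
  for (i in seq_len(traj$n_frames)) {
    coords[i, , ] <- sweep(matrix(coords[i, , ], ncol = 3) %*% rotation,
                           2, translation, "+")
  }
  trajectory(traj$topology, coords)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# Contact trajectory with fully specified hidden states (bypasses the Markov
# chain so tests control co-occurrence exactly).
planted_contact_traj <- function(states, donor_res, acceptor_res,
                                 n_res = max(donor_res)) {
  toy <- gen_toy_complex(n_res)
  mdiface:::.realize_contacts(toy, states, donor_res, acceptor_res)
}
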