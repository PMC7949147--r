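# Geometric hydrogen-bond detection and occupancy time-averaging.

test_that("donor/acceptor enumeration follows bonding and element rules", {
  toy <- gen_toy_complex(3)
  da <- find_donors_acceptors(toy$topology)
  at <- toy$topology$atoms
  # one donor entry per backbone amide N-H
  expect_equal(sort(da$donors$heavy), sort(which(at$name == "N")))
  expect_equal(sort(da$donors$hydrogen), sort(which(at$name == "H")))
  # acceptors = every N and O; carbonyl O never appears as a donor
  expect_equal(sort(da$acceptors), sort(which(at$element %in% c("N", "O"))))
  expect_false(any(da$donors$heavy %in% which(at$name == "O")))

  # a lysine-like NZ bearing three hydrogens yields three donor entries
  atoms <- data.frame(name = c("NZ", "HZ1", "HZ2", "HZ3"), resname = "LYS",
                      resid = 1, chain = "A")
  lys <- topology(atoms, bonds = rbind(c(1, 2), c(1, 3), c(1, 4)))
  da_lys <- find_donors_acceptors(lys)
  expect_equal(nrow(da_lys$donors), 3L)
  expect_equal(unique(da_lys$donors$heavy), 1L)

  # selections without N/O warn and return empty lists
  expect_warning(da0 <- find_donors_acceptors(toy$topology, "name CA"),
                 "no N/O")
  expect_equal(nrow(da0$donors), 0L)

  # structures without explicit hydrogens are rejected
  heavy <- data.frame(name = c("N", "CA", "C", "O"), resname = "ALA",
                      resid = 1, chain = "A")
  expect_error(find_donors_acceptors(topology(heavy)), "hydrogens")
})

test_that("per-frame bonded test honours closed distance/angle boundaries", {
  # D at origin, H one Angstrom along +y; acceptor placed by angle/radius
  place <- function(theta_deg, r) {
    th <- theta_deg * pi / 180
    c(r * sin(th), 1 - r * cos(th), 0)    # angle at H between D and A
  }
  frame <- function(A) rbind(c(0, 0, 0), c(0, 1, 0), A)
  atoms <- data.frame(name = c("N", "H", "O"), resname = "ALA", resid = 1,
                      chain = "A")
  topo <- topology(atoms, rbind(c(1, 2)))
  tr <- hbond_triple(1, 2, 3, topo)
  crit <- hbond_criteria(3.0, 135)

  expect_true(hbond_present(frame(c(0, 2.9, 0)), tr, crit))    # 2.9 A, 180 deg
  expect_false(hbond_present(frame(c(0, 3.01, 0)), tr, crit))  # distance fails
  expect_false(hbond_present(frame(place(134.9, 1.0)), tr, crit)) # angle fails
  expect_true(hbond_present(frame(place(135, 1.0)), tr, crit))  # closed bound
  expect_true(hbond_present(frame(c(0, 3.0, 0)), tr, crit))     # closed bound
  expect_error(hbond_present(frame(c(0, 0, 0)), tr, crit), "coincident")
})

test_that("triple construction validates bonding and elements", {
  topo <- gen_toy_complex(1)$topology
  at <- topo$atoms
  iN <- which(at$name == "N")[1]; iH <- which(at$name == "H")[1]
  iO <- which(at$name == "O")[1]; iCA <- which(at$name == "CA")[1]
  expect_s3_class(hbond_triple(iN, iH, iO, topo), "hbond_triple")
  expect_error(hbond_triple(iN, iH, iN, topo), "distinct")
  expect_error(hbond_triple(iO, iH, iN, topo), "not bonded")
  expect_error(hbond_triple(iCA, iH, iO, topo), "N or O|not bonded")
})

test_that("occupancy equals the per-frame bonded count exactly", {
  # always bonded / never bonded
  g1 <- gen_hbond_trajectory(
    pairs = data.frame(donor_res = 1, acceptor_res = 6, p_on = 1, p_off = 0),
    n_frames = 200, seed = 2)
  expect_equal(hbond_occupancy(g1$trajectory, g1$triples)$occupancy_pct, 100)
  g0 <- gen_hbond_trajectory(
    pairs = data.frame(donor_res = 1, acceptor_res = 6, p_on = 0, p_off = 1),
    n_frames = 200, seed = 2)
  expect_equal(hbond_occupancy(g0$trajectory, g0$triples)$occupancy_pct, 0)

  # two-state Markov bond: estimate equals the hidden-state mean exactly
  g <- gen_hbond_trajectory(n_frames = 5000, seed = 31)
  rec <- hbond_occupancy(g$trajectory, g$triples)
  expect_equal(rec$occupancy_pct, 100 * mean(g$states))
  expect_equal(rec$occupancy_pct, 100 * rec$n_bonded / rec$n_frames)
  expect_equal(rec$n_frames, 5000L)
  # report label follows the RES<num>:<atom> convention
  expect_match(rec$label, "^ALA6:O-ALA1:H$")
})

test_that("occupancy error shrinks with frame count (Markov convergence)", {
  err <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      g <- gen_hbond_trajectory(n_frames = n, seed = s)
      abs(100 * mean(g$states) - 70)
    }, numeric(1)))
  }
  seeds <- 101:120
  expect_lt(err(5000, seeds), err(500, seeds))
})

test_that("composite occupancy: sum and union semantics", {
  # two bonds, 30% each, never co-occurring
  states <- cbind(rep(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 10),
                  rep(c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), 10))
  states[, 1] <- rep(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 10)
  states[, 2] <- rep(c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 10)
  pl <- planted_contact_traj(states, donor_res = c(1, 2),
                             acceptor_res = c(4, 5), n_res = 3)
  expect_equal(composite_occupancy(pl$trajectory, pl$triples, mode = "sum"), 60)
  expect_equal(composite_occupancy(pl$trajectory, pl$triples, mode = "union"), 60)

  # two always-on bonds: sum 200, union 100
  on <- matrix(1L, 50, 2)
  pl2 <- planted_contact_traj(on, c(1, 2), c(4, 5), n_res = 3)
  expect_equal(composite_occupancy(pl2$trajectory, pl2$triples, mode = "sum"),
               200)
  expect_equal(composite_occupancy(pl2$trajectory, pl2$triples, mode = "union"),
               100)
  expect_error(composite_occupancy(pl2$trajectory, pl2$triples,
                                   mode = "bogus"))
  expect_error(composite_occupancy(pl2$trajectory, list()), "at least one")
})

test_that("independent duty cycles 0.4/0.2 give sum ~60 and union ~52", {
  # p_on = p, p_off = 1 - p makes the chain i.i.d. Bernoulli(p) per frame
  g <- gen_hbond_trajectory(
    pairs = data.frame(donor_res = c(1, 2), acceptor_res = c(6, 7),
                       p_on = c(0.4, 0.2), p_off = c(0.6, 0.8)),
    n_frames = 10000, seed = 8)
  s <- composite_occupancy(g$trajectory, g$triples, mode = "sum")
  u <- composite_occupancy(g$trajectory, g$triples, mode = "union")
  expect_lt(abs(s - 60), 2)
  expect_lt(abs(u - 52), 2)      # 1 - 0.6 * 0.8 = 0.52
  expect_lte(u, min(100, s))
  # oracle: direct frame count on the hidden states
  expect_equal(u, 100 * mean(rowSums(g$states) > 0))
  expect_equal(s, sum(100 * colMeans(g$states)))
})

test_that("union <= min(100, sum) for random planted groups", {
  set.seed(5)
  for (rep in 1:5) {
    p <- stats::runif(3, 0.05, 0.95)
    g <- gen_hbond_trajectory(
      pairs = data.frame(donor_res = 1:3, acceptor_res = 6:8,
                         p_on = p, p_off = 1 - p),
      n_frames = 500, seed = rep)
    s <- composite_occupancy(g$trajectory, g$triples, mode = "sum")
    u <- composite_occupancy(g$trajectory, g$triples, mode = "union")
    expect_lte(u, min(100, s) + 1e-12)
  }
})

test_that("occupancy is invariant under a global rigid transform", {
  g <- gen_hbond_trajectory(n_frames = 300, seed = 13)
  before <- hbond_occupancy(g$trajectory, g$triples)$occupancy_pct
  set.seed(77)
  moved <- transform_trajectory(g$trajectory, random_rotation(), c(12, -3, 40))
  after <- hbond_occupancy(moved, g$triples)$occupancy_pct
  expect_equal(after, before)
})

test_that("loosening criteria never decreases occupancy", {
  g <- gen_hbond_trajectory(n_frames = 400, seed = 21)
  base <- hbond_occupancy(g$trajectory, g$triples,
                          hbond_criteria(3.0, 135))$occupancy_pct
  wider_d <- hbond_occupancy(g$trajectory, g$triples,
                             hbond_criteria(3.5, 135))$occupancy_pct
  lower_a <- hbond_occupancy(g$trajectory, g$triples,
                             hbond_criteria(3.0, 120))$occupancy_pct
  expect_gte(wider_d, base)
  expect_gte(lower_a, base)
})

test_that("occupancy TSV report echoes criteria and flags low occupancies", {
  g <- gen_hbond_trajectory(
    pairs = data.frame(donor_res = c(1, 2), acceptor_res = c(6, 7),
                       p_on = c(0.02, 0.5), p_off = c(0.98, 0.5)),
    n_frames = 2000, seed = 6)
  rec <- hbond_occupancy(g$trajectory, g$triples)
  expect_true(rec$low[1])
  expect_false(rec$low[2])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_tsv(rec, path)
  lines <- readLines(path)
  expect_match(lines[1], "max_da_distance_A: 3")
  got <- utils::read.delim(path, comment.char = "#")
  expect_equal(got$occupancy_pct, rec$occupancy_pct)
})
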