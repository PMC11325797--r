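# Minimal three-atom donor/acceptor system at controllable geometry:
# N at origin, H at (1,0,0); acceptor O placed by distance from H and by the
# D-H...A angle.
hbond_probe <- function(h_to_a, angle_deg) {
  atoms <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                      element = c("N", "H", "O"),
                      resno = c(1L, 1L, 2L), resid = "XXX", chain = "A",
                      stringsAsFactors = FALSE)
  th <- (180 - angle_deg) * pi / 180  # 180 deg = collinear extension
  a_pos <- c(1, 0, 0) + h_to_a * c(cos(th), sin(th), 0)
  gaswitch:::new_structure(atoms, rbind(c(0, 0, 0), c(1, 0, 0), a_pos))
}

test_that("detection follows the distance and angle cut-offs", {
  crit <- hbond_criteria()   # < 2.4 A, > 120 deg
  cases <- list(list(2.0, 180, TRUE),   # canonical linear bond
                list(2.5, 180, FALSE),  # too long
                list(2.0, 110, FALSE),  # too bent
                list(2.39, 121, TRUE),  # just inside both cut-offs
                list(2.4, 180, FALSE))  # boundary: strict <
  for (cs in cases) {
    s <- hbond_probe(cs[[1]], cs[[2]])
    det <- detect_hbonds_frame(s, s$xyz, crit,
                               region_def("A", 1), region_def("B", 2))
    expect_equal(nrow(det) == 1, cs[[3]],
                 label = sprintf("d=%.2f angle=%g", cs[[1]], cs[[2]]))
  }
})

test_that("detection requires explicit hydrogens", {
  atoms <- data.frame(serial = 1:2, name = c("N", "O"),
                      element = c("N", "O"), resno = c(1L, 2L),
                      resid = "XXX", chain = "A", stringsAsFactors = FALSE)
  s <- gaswitch:::new_structure(atoms, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(
    detect_hbonds_frame(s, s$xyz, hbond_criteria(),
                        region_def("A", 1), region_def("B", 2)),
    "no hydrogens")
})

test_that("detection is invariant under global rotation and translation", {
  s <- hbond_probe(2.0, 150)
  crit <- hbond_criteria()
  rA <- region_def("A", 1); rB <- region_def("B", 2)
  base <- detect_hbonds_frame(s, s$xyz, crit, rA, rB)
  set.seed(21)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    xyz2 <- s$xyz %*% R + matrix(rep(runif(3, -30, 30), each = 3), ncol = 3)
    det <- detect_hbonds_frame(s, xyz2, crit, rA, rB)
    expect_equal(nrow(det), nrow(base))
    expect_equal(det$distance, base$distance, tolerance = 1e-9)
    expect_equal(det$angle, base$angle, tolerance = 1e-6)
  }
})

test_that("occupancy counts planted frames and matches the generator ledger", {
  spec <- trajectory_spec(n_frames = 100, seed = 31,
    hbond_plants = list(list(donor_resno = 205, acceptor_resno = 230,
                             occupancy = 0.8, corlen = 5)))
  g <- generate_trajectory(spec)
  regs <- default_switch_regions()
  mat <- hbond_occupancy(g$trajectory, regs$switch_I, regs$switch_II)
  expect_equal(nrow(mat), 1)
  expect_equal(mat$count, g$ledger$plants[[1]]$n_on)
  expect_equal(mat$occupancy, g$ledger$plants[[1]]$realized)
})

test_that("always-on bond has occupancy 1 and empty trajectories are rejected", {
  spec <- trajectory_spec(n_frames = 50, seed = 32,
    hbond_plants = list(list(donor_resno = 205, acceptor_resno = 230,
                             occupancy = 1.0, corlen = 5)))
  g <- generate_trajectory(spec)
  regs <- default_switch_regions()
  mat <- hbond_occupancy(g$trajectory, regs$switch_I, regs$switch_II)
  expect_equal(mat$occupancy, 1.0)
})

test_that("occupancy matches the brute-force oracle on random fixtures", {
  crit <- hbond_criteria()
  rA <- region_def("A", 1:2); rB <- region_def("B", 3:4)
  for (seed in 1:3) {
    tr <- random_hbond_fixture(n_frames = 60, seed = 100 + seed)
    mat <- hbond_occupancy(tr, rA, rB, crit)
    oracle <- naive_hbond_occupancy(tr, rA, rB, crit)
    expect_identical(mat$count, oracle$count)
    expect_identical(mat$donor_resno, oracle$donor_resno)
    expect_identical(mat$acceptor_resno, oracle$acceptor_resno)
    expect_identical(mat$donor_atom, oracle$donor_atom)
  }
})

test_that("occupancy of concatenated trajectories is the frame-weighted mean", {
  tr1 <- random_hbond_fixture(40, seed = 201)
  # second trajectory must share tr1's topology (donor assignment is a
  # property of the topology reference coordinates)
  tr2 <- gaswitch:::new_trajectory(tr1$topology,
                                   random_hbond_fixture(60, seed = 202)$coords)
  top <- tr1$topology
  stacked <- array(NA_real_, c(100, dim(tr1$coords)[2], 3))
  stacked[1:40, , ] <- tr1$coords
  stacked[41:100, , ] <- tr2$coords
  both <- gaswitch:::new_trajectory(top, stacked)
  rA <- region_def("A", 1:2); rB <- region_def("B", 3:4)
  crit <- hbond_criteria()
  m1 <- hbond_occupancy(tr1, rA, rB, crit)
  m2 <- hbond_occupancy(tr2, rA, rB, crit)
  mb <- hbond_occupancy(both, rA, rB, crit)
  key <- function(m) paste(m$donor_resno, m$donor_atom,
                           m$acceptor_resno, m$acceptor_atom)
  for (i in seq_len(nrow(mb))) {
    k <- key(mb)[i]
    c1 <- if (k %in% key(m1)) m1$count[key(m1) == k] else 0L
    c2 <- if (k %in% key(m2)) m2$count[key(m2) == k] else 0L
    expect_identical(mb$count[i], c1 + c2)
  }
})

test_that("persistence tiers count thresholds met, inclusively", {
  mat <- data.frame(donor_resno = 1:4, donor_atom = "N",
                    acceptor_resno = 11:14, acceptor_atom = "O",
                    count = c(60, 20, 50, 100),
                    occupancy = c(0.6, 0.2, 0.5, 1.0))
  tiers <- persistence_tiers(mat, c(0.25, 0.5, 0.75))
  expect_equal(nrow(tiers), 3)            # the 0.2 pair is excluded
  expect_equal(tiers$tier[tiers$occupancy == 0.6], 2)
  expect_equal(tiers$tier[tiers$occupancy == 0.5], 2)   # boundary: >=
  expect_equal(tiers$tier[tiers$occupancy == 1.0], 3)
  expect_error(persistence_tiers(mat, c(0.5, 0.25)), "config error")
})

test_that("network comparison classifies gained, lost and shared pairs", {
  mk <- function(occ227_259) {
    structure(data.frame(
      donor_resno = c(205L, 227L), donor_atom = "N",
      acceptor_resno = c(230L, 259L), acceptor_atom = "O",
      count = c(90L, round(100 * occ227_259)),
      occupancy = c(0.9, occ227_259)),
      class = c("hbond_matrix", "data.frame"),
      regions = c("switch_I", "switch_II"), criteria = hbond_criteria())
  }
  A <- mk(0.1); B <- mk(0.9)
  cmp <- compare_networks(A, B, threshold = 0.5)
  expect_equal(nrow(cmp$gained), 1)
  expect_equal(cmp$gained$donor_resno, 227)
  expect_equal(nrow(cmp$lost), 0)
  expect_equal(nrow(cmp$shared), 1)
  # identical matrices: nothing gained or lost
  cmp2 <- compare_networks(A, A, threshold = 0.5)
  expect_equal(nrow(cmp2$gained), 0)
  expect_equal(nrow(cmp2$lost), 0)
  # loss direction: strong in A, weak in B
  cmp3 <- compare_networks(B, A, threshold = 0.5)
  expect_equal(cmp3$lost$donor_resno, 227)
  # mismatched region labels refuse to compare
  C <- mk(0.9); attr(C, "regions") <- c("switch_II", "switch_III")
  expect_error(compare_networks(A, C), "comparison error")
})

test_that("residue-level aggregation connects a pair when any atom pair passes", {
  mat <- structure(data.frame(
    donor_resno = c(1L, 1L), donor_atom = c("N", "OG"),
    acceptor_resno = c(2L, 2L), acceptor_atom = c("O", "O"),
    count = c(30L, 80L), occupancy = c(0.3, 0.8)),
    class = c("hbond_matrix", "data.frame"))
  res <- hbond_residue_matrix(mat)
  expect_equal(nrow(res), 1)
  expect_equal(res$occupancy, 0.8)
})
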