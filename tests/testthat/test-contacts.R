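# place a chosen residue's HA at an exact distance from a ligand proton
planted_frame <- function(top, resno, proton_name, dist,
                          dir = c(1, 0, 0)) {
  xyz <- top$xyz
  at <- top$atoms
  p <- xyz[at$resid == "GDP" & at$name == proton_name, ]
  xyz[at$resno == resno & at$name == "HA", ] <- p + dist * dir
  xyz
}

test_that("frame-level contacts find in-radius residues and the closest one", {
  top <- toy_topology()
  lp <- default_ligand_protons()
  xyz <- planted_frame(top, 173, "H1'", 3.0)
  res <- proton_contacts_frame(top, xyz, lp, radius = 6.0)
  expect_equal(res[["b"]]$in_radius, 173)
  expect_equal(res[["b"]]$closest, 173)
  # no residue but the planted one is near any proton (the ligand protons sit
  # a few Angstrom apart, so 173 may graze several of them)
  for (lab in names(res))
    expect_true(all(res[[lab]]$in_radius %in% 173))
})

test_that("residues at exactly the radius and beyond are excluded", {
  top <- toy_topology()
  lp <- default_ligand_protons()
  # plant along +z, which points away from all ligand protons
  xyz <- planted_frame(top, 173, "H1'", 7.0, dir = c(0, 0, 1))
  res <- proton_contacts_frame(top, xyz, lp, radius = 6.0)
  expect_equal(length(res[["b"]]$in_radius), 0)
  expect_true(is.na(res[["b"]]$closest))
})

test_that("two in-radius residues are both listed and the nearer wins; ties go to the lower residue number", {
  top <- toy_topology()
  lp <- default_ligand_protons()
  xyz <- planted_frame(top, 173, "H1'", 3.0, dir = c(1, 0, 0))
  xyz <- planted_frame(gaswitch:::new_structure(top$atoms, xyz), 205, "H1'",
                       4.0, dir = c(0, 1, 0))
  res <- proton_contacts_frame(top, xyz, lp, radius = 6.0)
  expect_setequal(res[["b"]]$in_radius, c(173, 205))
  expect_equal(res[["b"]]$closest, 173)
  # exact tie at 3 A: lower residue number wins
  xyz2 <- planted_frame(top, 205, "H1'", 3.0, dir = c(1, 0, 0))
  xyz2 <- planted_frame(gaswitch:::new_structure(top$atoms, xyz2), 173, "H1'",
                        3.0, dir = c(0, 1, 0))
  res2 <- proton_contacts_frame(top, xyz2, lp, radius = 6.0)
  expect_equal(res2[["b"]]$closest, 173)
})

test_that("contact occupancy counts planted frames and matches the ledger", {
  spec <- trajectory_spec(n_frames = 400, seed = 51,
    contact_plants = list(list(resno = 173, proton = "b", occupancy = 0.75,
                               corlen = 10)))
  g <- generate_trajectory(spec)
  prof <- contact_occupancy(g$trajectory, default_ligand_protons(), 6.0)
  expect_equal(prof[["b"]]$resno, 173)
  expect_equal(prof[["b"]]$proximity_occupancy, g$ledger$plants[[1]]$realized)
  expect_equal(prof[["b"]]$closest_frequency, g$ledger$plants[[1]]$realized)
})

test_that("alternating closest residues split the closest frequency", {
  # two residues planted always-in-radius on the same proton at different
  # distances; swap which is nearer every other frame by hand
  top <- toy_topology()
  nf <- 40
  arr <- array(rep(top$xyz, each = nf), c(nf, nrow(top$xyz), 3))
  at <- top$atoms
  p <- top$xyz[at$resid == "GDP" & at$name == "H1'", ]
  i173 <- which(at$resno == 173 & at$name == "HA")
  i205 <- which(at$resno == 205 & at$name == "HA")
  for (f in seq_len(nf)) {
    d173 <- if (f %% 2 == 0) 3.0 else 4.5
    d205 <- if (f %% 2 == 0) 4.5 else 3.0
    arr[f, i173, ] <- p + d173 * c(1, 0, 0)
    arr[f, i205, ] <- p + d205 * c(0, 1, 0)
  }
  tr <- gaswitch:::new_trajectory(top, arr)
  prof <- contact_occupancy(tr, default_ligand_protons(), 6.0)
  b <- prof[["b"]]
  expect_equal(b$proximity_occupancy[b$resno %in% c(173, 205)], c(1, 1))
  expect_equal(b$closest_frequency[b$resno %in% c(173, 205)], c(0.5, 0.5))
})

test_that("profiles match the brute-force oracle on random fixtures", {
  set.seed(61)
  top <- toy_topology()
  nf <- 40
  # random positions for every HA within a 10 A shell of the ligand: dense
  # contact traffic across residues
  arr <- array(rep(top$xyz, each = nf), c(nf, nrow(top$xyz), 3))
  at <- top$atoms
  p0 <- top$xyz[at$resid == "GDP" & at$name == "H8", ]
  ha_idx <- which(at$name == "HA")
  for (f in seq_len(nf))
    for (i in ha_idx)
      arr[f, i, ] <- p0 + runif(3, -6, 6)
  tr <- gaswitch:::new_trajectory(top, arr)
  prof <- contact_occupancy(tr, default_ligand_protons(), 6.0)
  for (pn in c("H8", "H1'")) {
    lab <- c("H8" = "a", "H1'" = "b")[[pn]]
    oracle <- naive_contact_occupancy(tr, pn, "GDP", 6.0)
    got <- prof[[lab]]
    expect_equal(got$resno, oracle$resno)
    expect_equal(got$proximity_occupancy, oracle$proximity_occupancy)
    expect_equal(got$closest_frequency, oracle$closest_frequency)
  }
})

test_that("closest frequency never exceeds proximity occupancy; occupancy is monotone in radius", {
  spec <- trajectory_spec(n_frames = 200, seed = 52, fluctuation_sd = 0.2,
    contact_plants = list(
      list(resno = 173, proton = "b", occupancy = 0.6, corlen = 10,
           distance = 4.5),
      list(resno = 205, proton = "b", occupancy = 0.5, corlen = 10,
           distance = 5.5)))
  g <- generate_trajectory(spec)
  lp <- default_ligand_protons()
  prev <- NULL
  for (r in c(6, 5, 4)) {
    prof <- contact_occupancy(g$trajectory, lp, r)
    for (lab in names(prof)) {
      df <- prof[[lab]]
      expect_true(all(df$closest_frequency <= df$proximity_occupancy + 1e-12))
      expect_true(sum(df$closest_frequency) <= 1 + 1e-12)
    }
    occ_of <- function(p, lab, resno) {
      df <- p[[lab]]
      if (resno %in% df$resno) df$proximity_occupancy[df$resno == resno] else 0
    }
    if (!is.null(prev))
      for (resno in c(173, 205))
        expect_lte(occ_of(prof, "b", resno), occ_of(prev, "b", resno))
    prev <- prof
  }
})

test_that("equivalent protons average arithmetically", {
  prof <- structure(list(
    "a" = data.frame(resno = 52, proximity_occupancy = 1,
                     closest_frequency = 1),
    "d.1" = data.frame(resno = c(50, 201), proximity_occupancy = c(0.4, 1.0),
                       closest_frequency = c(0.4, 0.6)),
    "d.2" = data.frame(resno = c(50), proximity_occupancy = 0.6,
                       closest_frequency = 0.6)),
    class = "contact_profile", n_frames = 100, radius = 6)
  lp <- ligand_selection("GDP", list(a = "H8", d = c("H5'", "H5''")))
  merged <- average_equivalent_protons(prof, lp)
  d <- merged[["d"]]
  expect_equal(d$proximity_occupancy[d$resno == 50], 0.5)
  # residue absent from one proton counts as 0 there
  expect_equal(d$proximity_occupancy[d$resno == 201], 0.5)
  expect_equal(merged[["a"]]$proximity_occupancy, 1)
  bad <- ligand_selection("GDP", list(x = "H8"))
  expect_error(average_equivalent_protons(prof, bad), "usage error")
})

test_that("cross-system aggregation gives the closed-form mean and SEM", {
  mk <- function(occ) structure(list(
    "a" = data.frame(resno = 52, proximity_occupancy = occ,
                     closest_frequency = occ)),
    class = "contact_profile", n_frames = 10, radius = 6)
  agg <- aggregate_contacts(list(sys1 = mk(0.90), sys2 = mk(1.00)))
  expect_equal(agg$mean_pct, 95)
  expect_equal(agg$sem_pct, 5)   # SD of {90,100} = sqrt(50); /sqrt(2) = 5
  agg2 <- aggregate_contacts(list(s1 = mk(0.8), s2 = mk(0.8), s3 = mk(0.8)))
  expect_equal(agg2$sem_pct, 0)
  expect_error(aggregate_contacts(list(only = mk(0.5))), "SEM undefined")
})
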