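# build a small complete synthetic system on disk + in memory
make_system_inputs <- function(dir, label, tm, hbond_occ, b_pct, seed) {
  melt <- generate_curves(curve_spec("boltzmann",
                                     list(V50 = tm, Slope = 2,
                                          Top = -8, Bottom = -1),
                                     seed = seed, noise_sd = 0.05,
                                     replicates = 3))
  melt_csv <- file.path(dir, paste0(gsub(":", "_", label), "_melt.csv"))
  write.csv(data.frame(temperature = melt$curves$x,
                       ellipticity = melt$curves$y,
                       replicate = melt$curves$replicate),
            melt_csv, row.names = FALSE)
  plants <- if (hbond_occ > 0)
    list(list(donor_resno = 228, acceptor_resno = 259,
              occupancy = hbond_occ, corlen = 10)) else list()
  traj <- generate_trajectory(trajectory_spec(
    n_frames = 150, seed = seed + 1, fluctuation_sd = 0.1,
    hbond_plants = plants,
    contact_plants = list(list(resno = 52, proton = "a", occupancy = 0.9,
                               corlen = 10))))
  peaks <- data.frame(proton = c("a", "b", "c"),
                      window_lo_ppm = c(8.0, 5.8, 4.2),
                      window_hi_ppm = c(8.2, 6.0, 4.4),
                      I0 = 1000, Idiff = c(20, 20 * b_pct / 100, 24),
                      SNR = 30)
  list(label = label,
       melt_csv = melt_csv,
       stdaf = list(peaks = peaks, ligand_conc = 2000, protein_conc = 40,
                    reference_proton = "a"),
       trajectory = list(object = traj$trajectory))
}

# two-particle fixture for closed-form nonbonded-energy checks
two_particle_traj <- function(r, qpair = c(1, 1), sigma = c(0, 0),
                              epsilon = c(0, 0)) {
  atoms <- data.frame(serial = 1:2, name = c("Q1", "Q2"),
                      element = c("N", "N"), resno = c(1L, 2L),
                      resid = c("XXA", "XXB"), chain = "A",
                      stringsAsFactors = FALSE)
  top <- gaswitch:::new_structure(atoms, rbind(c(0, 0, 0), c(r, 0, 0)))
  tr <- gaswitch:::new_trajectory(top, array(rep(top$xyz, each = 1), c(1, 2, 3)))
  pars <- nonbonded_params(data.frame(
    resid = c("XXA", "XXB"), name = c("Q1", "Q2"),
    charge = qpair, sigma = sigma, epsilon = epsilon))
  list(tr = tr, pars = pars)
}
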