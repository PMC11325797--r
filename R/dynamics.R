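## Coulomb constant in kcal * Angstrom / (mol * e^2).
KE_COULOMB <- 332.0636

#' Per-residue backbone RMSF
#'
#' Root-mean-square fluctuation about the trajectory mean position: per atom,
#' `RMSF = sqrt(mean_t |x_t - mean(x)|^2)`; per residue, the unweighted mean
#' over its selected atoms. The trajectory should be superposed on the
#' analysis selection first (see [superpose()]), so fluctuations are measured
#' relative to the average position of the full trajectory.
#'
#' @param traj A `gas_trajectory` (superposed).
#' @param backbone_atoms Atom names averaged per residue (default N, CA, C, O).
#' @param chain Optional chain filter.
#' @return An `rmsf_profile`: data frame with `resno` and `rmsf` (Angstrom),
#'   with attributes `n_frames` and `atom_rmsf` (per-atom values).
#' @export
compute_rmsf <- function(traj, backbone_atoms = c("N", "CA", "C", "O"),
                         chain = NULL) {
  stopifnot(inherits(traj, "gas_trajectory"))
  at <- traj$topology$atoms
  sel <- at$name %in% backbone_atoms
  if (!is.null(chain)) sel <- sel & at$chain %in% chain
  sel <- which(sel)
  if (length(sel) == 0L) stop("empty selection: no atoms match backbone_atoms")
  nf <- n_frames(traj)
  if (nf == 1L) warning("single-frame trajectory: RMSF is identically zero")
  sub <- traj$coords[, sel, , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  # mean squared deviation per atom, summed over x/y/z
  msd <- rep(0, length(sel))
  for (k in 1:3) {
    dev <- sweep(sub[, , k, drop = FALSE], 2, mu[, k])
    msd <- msd + colMeans(matrix(dev, nrow = nf)^2)
  }
  atom_rmsf <- sqrt(msd)
  res <- tapply(atom_rmsf, at$resno[sel], mean)
  out <- data.frame(resno = as.integer(names(res)), rmsf = as.numeric(res))
  out <- out[order(out$resno), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rmsf_profile", "data.frame"),
            n_frames = nf,
            atom_rmsf = data.frame(atom_idx = sel, rmsf = atom_rmsf))
}

#' Read a nonbonded parameter table
#'
#' CSV with columns `resid`, `name`, `charge` (e), `sigma` (Angstrom) and
#' `epsilon` (kcal/mol). The table bundled with the package covers the toy
#' synthetic systems only and is explicitly non-authoritative: production use
#' requires a force-field-derived table.
#'
#' @param path CSV path (default: bundled minimal table).
#' @param combining Lennard-Jones combining rule: `"geometric"` (OPLS
#'   convention, default) or `"lorentz-berthelot"`.
#' @return A `nonbonded_params` object.
#' @export
read_nonbonded_params <- function(path = system.file("extdata",
                                                     "nonbonded_params.csv",
                                                     package = "gaswitch"),
                                  combining = c("geometric", "lorentz-berthelot")) {
  combining <- match.arg(combining)
  nonbonded_params(utils::read.csv(path, stringsAsFactors = FALSE), combining)
}

#' Construct a nonbonded parameter set from a data frame
#'
#' @param table Data frame with columns `resid`, `name`, `charge`, `sigma`,
#'   `epsilon`.
#' @param combining Combining rule, `"geometric"` or `"lorentz-berthelot"`.
#' @return A `nonbonded_params` object.
#' @export
nonbonded_params <- function(table, combining = c("geometric", "lorentz-berthelot")) {
  combining <- match.arg(combining)
  need <- c("resid", "name", "charge", "sigma", "epsilon")
  if (!all(need %in% names(table)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(table$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(table$epsilon > 0 & table$sigma <= 0))
    stop("sigma must be > 0 for LJ-active atoms")
  structure(list(table = table, combining = combining),
            class = "nonbonded_params")
}

## Per-atom parameter lookup for a set of atom indices; errors listing any
## atom without parameters.
lookup_params <- function(topology, idx, params) {
  at <- topology$atoms[idx, , drop = FALSE]
  key <- paste(at$resid, at$name)
  tkey <- paste(params$table$resid, params$table$name)
  m <- match(key, tkey)
  if (anyNA(m)) {
    miss <- unique(key[is.na(m)])
    stop("parameterization error: no nonbonded parameters for atom(s): ",
         paste(miss, collapse = ", "))
  }
  params$table[m, c("charge", "sigma", "epsilon")]
}

#' Mean nonbonded interaction energy between two residue groups
#'
#' Per frame, the sum over inter-group atom pairs of the Coulomb term
#' `k_e q_i q_j / r` (k_e = 332.0636 kcal A / (mol e^2)) plus Lennard-Jones
#' `4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)` with the declared combining rule;
#' the frame mean is returned. All pairs are summed exactly (no cut-off);
#' group sizes here are tens of atoms, so exact summation is cheap.
#'
#' @param traj A `gas_trajectory`.
#' @param groupA,groupB `region_def` objects (disjoint residue sets).
#' @param params A [read_nonbonded_params()] object.
#' @return List with `mean_energy` (kcal/mol), per-frame `energies`, and the
#'   region names.
#' @export
nonbonded_energy <- function(traj, groupA, groupB, params) {
  stopifnot(inherits(traj, "gas_trajectory"),
            inherits(params, "nonbonded_params"))
  if (length(intersect(groupA$residue_numbers, groupB$residue_numbers)) > 0L)
    stop("groups must be disjoint")
  ia <- region_atom_idx(traj$topology, groupA)
  ib <- region_atom_idx(traj$topology, groupB)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty group selection")
  pa <- lookup_params(traj$topology, ia, params)
  pb <- lookup_params(traj$topology, ib, params)
  qq <- KE_COULOMB * outer(pa$charge, pb$charge)
  if (params$combining == "geometric") {
    sig <- sqrt(outer(pa$sigma, pb$sigma))
    # atoms with epsilon 0 contribute no LJ regardless of sigma
    sig[outer(pa$epsilon, pb$epsilon) == 0] <- 0
  } else {
    sig <- outer(pa$sigma, pb$sigma, `+`) / 2
  }
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  nf <- n_frames(traj)
  energies <- vapply(seq_len(nf), function(i) {
    fc <- frame_coords(traj, i)
    A <- fc[ia, , drop = FALSE]; B <- fc[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
          outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
    r <- sqrt(pmax(d2, 1e-12))
    ecoul <- qq / r
    s6 <- (sig / r)^6
    elj <- 4 * eps * (s6^2 - s6)
    sum(ecoul) + sum(elj)
  }, numeric(1))
  list(mean_energy = mean(energies), energies = energies,
       regions = c(groupA$name, groupB$name))
}

#' Normalize an interaction-energy table to a reference system
#'
#' Divides each system's mean energy by the reference system's energy for the
#' same region pair; the reference row maps to exactly 1.
#'
#' @param table Data frame with columns `system`, `region_pair`, `energy`.
#' @param reference Reference system label (e.g. `"WT:GTP"`).
#' @param tol Reference energies with `|E| < tol` refuse to normalize.
#' @return The table with a `normalized` column appended.
#' @export
normalize_energies <- function(table, reference, tol = 1e-9) {
  stopifnot(all(c("system", "region_pair", "energy") %in% names(table)))
  if (!reference %in% table$system)
    stop("reference system '", reference, "' not present in table")
  ref <- table[table$system == reference, , drop = FALSE]
  m <- match(table$region_pair, ref$region_pair)
  if (anyNA(m))
    stop("reference system lacks region pair(s): ",
         paste(unique(table$region_pair[is.na(m)]), collapse = ", "))
  refE <- ref$energy[m]
  if (any(abs(refE) < tol))
    stop("normalization error: reference energy is ~0 for pair(s): ",
         paste(unique(table$region_pair[abs(refE) < tol]), collapse = ", "))
  table$normalized <- table$energy / refE
  table
}
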