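## Synthetic-data generators. Every generator takes a mandatory seed and
## returns, alongside the artifact, a ground-truth ledger of what was planted
## (realized counts, not nominal targets). The generators exist to test the
## estimators: they emulate the *statistics* of trajectories, spectra and
## melt/kinetics curves, with no physical realism.

#' Toy two-chain topology for synthetic trajectories
#'
#' A synthetic mini-system: chain A carries one minimal residue (N, H, CA,
#' HA, C, O) per requested residue number, laid out on a wide grid so that no
#' inter-residue contact satisfies any geometric criterion by default; chain B
#' is a nucleotide-like ligand (residue `GDP`) carrying the monitored protons
#' H8, H1', H2', H5' and H5''. Small enough for brute-force O(N^2) oracle
#' checks in milliseconds. Entirely synthetic: residue numbers follow the
#' switch-region and binding-pocket numbering conventions but the geometry is
#' a test fixture, not a model of the protein.
#'
#' @param residues Residue numbers to place on chain A.
#' @param spacing Grid spacing (Angstrom, default 14).
#' @return A `gas_structure`.
#' @export
toy_topology <- function(residues = c(50, 52, 173, 197, 201, 205, 226, 227,
                                      228, 230, 258, 259, 265, 268, 293),
                         spacing = 14) {
  res_template <- rbind(
    N  = c(0.00,  0.00, 0.00),
    H  = c(-1.00, 0.00, 0.00),
    CA = c(1.45,  0.00, 0.00),
    HA = c(1.45, -1.09, 0.00),
    C  = c(2.21,  1.25, 0.00),
    O  = c(2.21,  1.25, 1.23))
  elements <- c("N", "H", "C", "H", "C", "O")
  nres <- length(residues)
  ncol_grid <- ceiling(sqrt(nres))
  atoms <- list(); xyz <- list()
  for (i in seq_len(nres)) {
    gx <- ((i - 1) %% ncol_grid) * spacing
    gy <- ((i - 1) %/% ncol_grid) * spacing
    xyz[[i]] <- sweep(res_template, 2, c(gx, gy, 0), `+`)
    atoms[[i]] <- data.frame(name = rownames(res_template),
                             element = elements,
                             resno = residues[i], resid = "SER", chain = "A",
                             stringsAsFactors = FALSE)
  }
  lig_xyz <- rbind(
    "C8"   = c(0.0, 0.0, 0.0),
    "H8"   = c(0.0, 0.0, 1.08),
    "N9"   = c(1.37, 0.0, -0.20),
    "C1'"  = c(2.30, 1.00, 0.00),
    "H1'"  = c(2.30, 1.00, 1.09),
    "C2'"  = c(3.60, 0.50, -0.40),
    "H2'"  = c(3.60, -0.30, 0.34),
    "O2'"  = c(4.80, 1.10, -0.20),
    "C5'"  = c(1.50, 3.00, 0.50),
    "H5'"  = c(0.90, 3.40, 1.30),
    "H5''" = c(2.10, 3.40, 1.30),
    "O5'"  = c(1.50, 2.00, -0.50))
  lig_elem <- c("C", "H", "N", "C", "H", "C", "H", "O", "C", "H", "H", "O")
  lig_off <- c(10, 10, 30)
  xyz[[nres + 1]] <- sweep(lig_xyz, 2, lig_off, `+`)
  atoms[[nres + 1]] <- data.frame(name = rownames(lig_xyz),
                                  element = lig_elem,
                                  resno = 901L, resid = "GDP", chain = "B",
                                  stringsAsFactors = FALSE)
  at <- do.call(rbind, atoms)
  at <- cbind(serial = seq_len(nrow(at)), at)
  rownames(at) <- NULL
  new_structure(at, do.call(rbind, xyz))
}

## Two-state telegraph process: stationary occupancy p, correlation length
## corlen frames (per-frame autocorrelation exp(-1/corlen)).
telegraph_states <- function(n, p, corlen) {
  lambda <- exp(-1 / corlen)
  q_on <- p * (1 - lambda)        # off -> on
  q_off <- (1 - p) * (1 - lambda) # on -> off
  s <- integer(n)
  s[1] <- stats::rbinom(1, 1, p)
  u <- stats::runif(n - 1)
  for (i in 2:n) {
    s[i] <- if (s[i - 1] == 1L) as.integer(u[i - 1] >= q_off)
            else as.integer(u[i - 1] < q_on)
  }
  s
}

## 99% interval for the realized mean of a telegraph process around target p:
## binomial variance inflated by the AR(1)-like autocorrelation factor.
telegraph_ci99 <- function(p, n, corlen) {
  lambda <- exp(-1 / corlen)
  infl <- (1 + lambda) / (1 - lambda)
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) * infl / n)
  c(max(0, p - half), min(1, p + half))
}

#' Specification for a synthetic trajectory
#'
#' @param n_frames Number of frames (>= 10).
#' @param seed Random seed (mandatory).
#' @param topology A `gas_structure` (default [toy_topology()]).
#' @param fluctuation_sd Per-coordinate Gaussian displacement SD (Angstrom);
#'   a scalar, or a named vector keyed by residue number.
#' @param hbond_plants List of plants, each
#'   `list(donor_resno=, acceptor_resno=, occupancy=, corlen=)`: a two-state
#'   telegraph process moves the acceptor residue's backbone O into (H...O =
#'   2.0 A, angle 180 deg) or out of (6.0 A) criteria geometry relative to the
#'   donor residue's backbone H.
#' @param contact_plants List of plants, each
#'   `list(resno=, proton=, occupancy=, corlen=, distance=)`: the residue's HA
#'   proton is moved to `distance` (default 3 A) of the named ligand proton
#'   when on, and 12 A when off.
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(n_frames, seed, topology = toy_topology(),
                            fluctuation_sd = 0.1,
                            hbond_plants = list(), contact_plants = list()) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_frames < 10L) stop("n_frames must be >= 10")
  occs <- c(vapply(hbond_plants, `[[`, numeric(1), "occupancy"),
            vapply(contact_plants, `[[`, numeric(1), "occupancy"))
  if (length(occs) && (any(occs < 0) || any(occs > 1)))
    stop("planted occupancies must lie in [0, 1]")
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 topology = topology, fluctuation_sd = fluctuation_sd,
                 hbond_plants = hbond_plants, contact_plants = contact_plants),
            class = "trajectory_spec")
}

#' Generate a synthetic trajectory with planted ground truth
#'
#' Frames are the reference coordinates plus iid Gaussian displacements of
#' the stated SD; planted hydrogen bonds and ligand contacts are realized by
#' two-state telegraph processes whose stationary occupancy equals the
#' target. Atoms involved in a plant are positioned deterministically (no
#' jitter), so the analysis modules recover the ledger counts exactly. The
#' ledger records realized (counted) occupancies and their 99% target
#' intervals under the autocorrelation-inflated binomial.
#'
#' @param spec A [trajectory_spec()].
#' @return List with `trajectory` (a `gas_trajectory`) and `ledger`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  top <- spec$topology
  at <- top$atoms
  nf <- spec$n_frames
  na <- nrow(at)
  atom_idx <- function(resno, name, what) {
    i <- which(at$resno == resno & at$name == name)
    if (length(i) != 1L)
      stop("spec error: cannot resolve ", what, " atom ", name,
           " of residue ", resno)
    i
  }
  claimed <- integer(0)
  claim <- function(idx, what) {
    if (any(idx %in% claimed))
      stop("spec error: conflicting plants claim atom(s) ",
           paste(intersect(idx, claimed), collapse = ", "), " (", what, ")")
    claimed <<- c(claimed, idx)
  }

  # resolve plants up front (also claims atoms and freezes them from jitter)
  hplants <- lapply(spec$hbond_plants, function(p) {
    d_n <- atom_idx(p$donor_resno, "N", "donor")
    d_h <- atom_idx(p$donor_resno, "H", "donor")
    a_o <- atom_idx(p$acceptor_resno, "O", "acceptor")
    claim(c(d_n, d_h, a_o), paste0("hbond ", p$donor_resno, "->", p$acceptor_resno))
    u <- top$xyz[d_h, ] - top$xyz[d_n, ]
    u <- u / sqrt(sum(u^2))
    list(p = p, d_n = d_n, d_h = d_h, a_o = a_o, u = u,
         corlen = p$corlen %||% 20)
  })
  lig <- at$resid == "GDP" | at$chain == "B"
  cplants <- lapply(seq_along(spec$contact_plants), function(k) {
    p <- spec$contact_plants[[k]]
    ha <- atom_idx(p$resno, "HA", "contact")
    claim(ha, paste0("contact ", p$resno, "->", p$proton))
    pr_names <- if (p$proton %in% names(default_ligand_protons()$protons))
      default_ligand_protons()$protons[[p$proton]] else p$proton
    pj <- which(lig & at$name == pr_names[1])
    if (length(pj) != 1L)
      stop("spec error: ligand proton '", p$proton, "' not resolvable")
    dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
                  c(0.707, 0.707, 0), c(-0.707, 0.707, 0))
    list(p = p, ha = ha, proton_idx = pj,
         v = dirs[((k - 1) %% nrow(dirs)) + 1, ],
         dist_on = p$distance %||% 3.0, corlen = p$corlen %||% 20)
  })

  # fluctuation SDs per atom (0 for planted atoms)
  sd_atom <- if (length(spec$fluctuation_sd) == 1L && is.null(names(spec$fluctuation_sd))) {
    rep(spec$fluctuation_sd, na)
  } else {
    s <- spec$fluctuation_sd[as.character(at$resno)]
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  sd_atom[claimed] <- 0

  coords <- array(rep(top$xyz, each = nf), c(nf, na, 3))
  jit <- which(sd_atom > 0)
  for (k in 1:3) {
    noise <- matrix(stats::rnorm(nf * length(jit)), nf, length(jit))
    coords[, jit, k] <- coords[, jit, k] + sweep(noise, 2, sd_atom[jit], `*`)
  }

  ledger <- list(seed = spec$seed, n_frames = nf, plants = list())
  for (hp in hplants) {
    s <- telegraph_states(nf, hp$p$occupancy, hp$corlen)
    pos_on <- top$xyz[hp$d_h, ] + 2.0 * hp$u
    pos_off <- top$xyz[hp$d_h, ] + 6.0 * hp$u
    for (k in 1:3)
      coords[, hp$a_o, k] <- ifelse(s == 1L, pos_on[k], pos_off[k])
    ledger$plants[[length(ledger$plants) + 1L]] <- list(
      type = "hbond", donor_resno = hp$p$donor_resno,
      acceptor_resno = hp$p$acceptor_resno,
      target = hp$p$occupancy, corlen = hp$corlen,
      n_on = sum(s), realized = sum(s) / nf,
      ci99 = telegraph_ci99(hp$p$occupancy, nf, hp$corlen))
  }
  for (cp in cplants) {
    s <- telegraph_states(nf, cp$p$occupancy, cp$corlen)
    base <- top$xyz[cp$proton_idx, ]
    pos_on <- base + cp$dist_on * cp$v
    pos_off <- base + 12.0 * cp$v
    for (k in 1:3)
      coords[, cp$ha, k] <- ifelse(s == 1L, pos_on[k], pos_off[k])
    ledger$plants[[length(ledger$plants) + 1L]] <- list(
      type = "contact", resno = cp$p$resno, proton = cp$p$proton,
      target = cp$p$occupancy, corlen = cp$corlen,
      n_on = sum(s), realized = sum(s) / nf,
      ci99 = telegraph_ci99(cp$p$occupancy, nf, cp$corlen))
  }
  list(trajectory = new_trajectory(top, coords), ledger = ledger)
}

#' Specification for synthetic STD spectra
#'
#' @param protons Data frame with columns `label`, `shift_ppm`, `I0` (peak
#'   area) and `alpha` (saturation attenuation in `[0, 1)`); optional
#'   `fwhm_hz` (default 6).
#' @param seed Random seed (mandatory).
#' @param noise_sd Additive Gaussian noise SD per point (default 0).
#' @param n_points,sw_ppm Axis: `n_points` over `sw_ppm` ppm ending at 0
#'   (defaults 16384 points over 12 ppm).
#' @param frequency_mhz Spectrometer frequency (default 800).
#' @param background Add a broad protein-background hump present identically
#'   in on- and off-resonance spectra (default FALSE).
#' @param window_halfwidth_ppm Integration half-window recorded in the ledger
#'   (default 0.1 ppm, matched to the default 6 Hz linewidth and digital
#'   resolution so that the sino-convention sigma approximates a 95% error
#'   bar; see the methods vignette).
#' @return A `spectra_spec` list.
#' @export
spectra_spec <- function(protons, seed, noise_sd = 0, n_points = 16384,
                         sw_ppm = 12, frequency_mhz = 800,
                         background = FALSE, window_halfwidth_ppm = 0.1) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(c("label", "shift_ppm", "I0", "alpha") %in% names(protons)))
  if (any(duplicated(protons$shift_ppm))) stop("chemical shifts must be distinct")
  if (any(protons$alpha < 0 | protons$alpha >= 1)) stop("alpha must be in [0, 1)")
  if (is.null(protons$fwhm_hz)) protons$fwhm_hz <- 6
  structure(list(protons = protons, seed = as.integer(seed),
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 sw_ppm = sw_ppm, frequency_mhz = frequency_mhz,
                 background = background,
                 window_halfwidth_ppm = window_halfwidth_ppm),
            class = "spectra_spec")
}

#' Default synthetic nucleotide proton set
#'
#' Four protons at GDP-like shifts with unit-order areas and per-proton
#' attenuations; a convenience starting point for [spectra_spec()].
#'
#' @param alpha Attenuations, recycled to 4 (default 0.02).
#' @return Data frame for `spectra_spec(protons = ...)`.
#' @export
default_spectra_protons <- function(alpha = 0.02) {
  data.frame(label = c("a", "b", "c", "d"),
             shift_ppm = c(8.10, 5.90, 4.30, 4.05),
             I0 = c(1000, 1000, 1000, 2000),
             alpha = rep(alpha, length.out = 4))
}

lorentzian <- function(x, x0, gamma, area) {
  (area / pi) * gamma / ((x - x0)^2 + gamma^2)
}

#' Generate paired on/off-resonance STD spectra with planted attenuations
#'
#' Off-resonance peaks carry the stated areas; on-resonance peak areas are
#' `(1 - alpha)` times the off areas, so the difference spectrum holds
#' exactly `alpha` times each reference peak. Gaussian noise is drawn
#' independently for the two spectra; the optional broad background hump is
#' present identically in both (it cancels in the difference; the returned
#' `background` spectrum holds the hump alone for reference-spectrum
#' correction).
#'
#' @param spec A [spectra_spec()].
#' @return List with `off`, `on`, `background` (`spectrum1d`s) and `ledger`
#'   (true alpha, integration and noise windows, seed).
#' @export
generate_std_spectra <- function(spec) {
  stopifnot(inherits(spec, "spectra_spec"))
  set.seed(spec$seed)
  ppm <- seq(spec$sw_ppm, 0, length.out = spec$n_points)
  gamma_ppm <- (spec$protons$fwhm_hz / 2) / spec$frequency_mhz
  clean_off <- rep(0, spec$n_points)
  clean_on <- rep(0, spec$n_points)
  for (i in seq_len(nrow(spec$protons))) {
    pk <- lorentzian(ppm, spec$protons$shift_ppm[i], gamma_ppm[i],
                     spec$protons$I0[i])
    clean_off <- clean_off + pk
    clean_on <- clean_on + (1 - spec$protons$alpha[i]) * pk
  }
  bg <- if (spec$background)
    30 * mean(spec$protons$I0) / 100 * exp(-(ppm - 1.5)^2 / (2 * 0.8^2))
  else rep(0, spec$n_points)
  noise <- function() if (spec$noise_sd > 0)
    stats::rnorm(spec$n_points, sd = spec$noise_sd) else 0
  meta <- list(frequency_mhz = spec$frequency_mhz,
               on_resonance_ppm = 0.79, off_resonance_ppm = -40.0,
               saturation_time_s = 2.0)
  off <- spectrum1d(ppm, clean_off + bg + noise(), meta)
  on <- spectrum1d(ppm, clean_on + bg + noise(), meta)
  background <- spectrum1d(ppm, bg, meta)
  w <- spec$window_halfwidth_ppm
  windows <- lapply(seq_len(nrow(spec$protons)), function(i)
    spec$protons$shift_ppm[i] + c(-w, w))
  names(windows) <- spec$protons$label
  merged <- overlapping_windows(windows)
  ledger <- list(seed = spec$seed,
                 alpha = stats::setNames(spec$protons$alpha,
                                         spec$protons$label),
                 windows = windows,
                 noise_window = c(spec$sw_ppm * 0.85, spec$sw_ppm * 0.95),
                 overlap_warning = merged)
  list(off = off, on = on, background = background, ledger = ledger)
}

## labels of integration windows that overlap (peaks would merge)
overlapping_windows <- function(windows) {
  labs <- names(windows)
  out <- character(0)
  if (length(windows) < 2) return(out)
  for (i in seq_along(windows)) for (j in seq_along(windows)) {
    if (i >= j) next
    if (min(max(windows[[i]]), max(windows[[j]])) >
        max(min(windows[[i]]), min(windows[[j]])))
      out <- c(out, paste(labs[i], labs[j], sep = "/"))
  }
  out
}

#' Specification for synthetic melt or kinetics curves
#'
#' @param model `"boltzmann"` or `"one_phase"`.
#' @param params Named list of true parameters: `V50`, `Slope` (and
#'   optionally `Top`, `Bottom`) for `boltzmann`; `Y0`, `Plateau`, `k` for
#'   `one_phase`.
#' @param seed Random seed (mandatory).
#' @param schedule Sampling axis. Defaults follow the acquisition protocols
#'   the fitters target: 65 temperatures over 25-89 degrees C for melts (1
#'   degree/min, one reading per degree), and 1000 time points every 12 s
#'   (0.2 min) out to 200 min for kinetics.
#' @param noise_sd Gaussian noise SD (additive, or fractional when
#'   `noise_type = "proportional"`).
#' @param noise_type `"additive"` or `"proportional"`.
#' @param replicates Number of replicate curves (>= 1).
#' @return A `curve_spec` list.
#' @export
curve_spec <- function(model = c("boltzmann", "one_phase"), params, seed,
                       schedule = NULL, noise_sd = 0,
                       noise_type = c("additive", "proportional"),
                       replicates = 1L) {
  model <- match.arg(model)
  noise_type <- match.arg(noise_type)
  if (missing(seed)) stop("seed is mandatory")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (is.null(schedule)) {
    schedule <- if (model == "boltzmann") seq(25, 89, length.out = 65)
                else seq(0.2, 200, by = 0.2)
  }
  if (model == "boltzmann" && any(schedule < -273.15))
    stop("spec error: temperatures below absolute zero")
  if (model == "one_phase" && any(schedule < 0))
    stop("spec error: negative times")
  structure(list(model = model, params = params, seed = as.integer(seed),
                 schedule = schedule, noise_sd = noise_sd,
                 noise_type = noise_type, replicates = as.integer(replicates)),
            class = "curve_spec")
}

#' Generate synthetic curves with known parameters
#'
#' Exact model evaluation plus Gaussian noise, replicate-wise independent
#' given the seed stream.
#'
#' @param spec A [curve_spec()].
#' @return List with `curves` (data frame `x`, `y`, `replicate`) and `ledger`
#'   (true parameters, noise, seed).
#' @export
generate_curves <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  set.seed(spec$seed)
  p <- spec$params
  clean <- if (spec$model == "boltzmann") {
    folded_fraction_y(spec$schedule, p$V50, p$Slope) *
      ((p$Top %||% 1) - (p$Bottom %||% 0)) + (p$Bottom %||% 0)
  } else {
    p$Y0 + (p$Plateau - p$Y0) * (1 - exp(-p$k * spec$schedule))
  }
  out <- lapply(seq_len(spec$replicates), function(r) {
    eps <- stats::rnorm(length(clean), sd = spec$noise_sd)
    y <- if (spec$noise_type == "additive") clean + eps
         else clean * (1 + eps)
    data.frame(x = spec$schedule, y = y, replicate = r)
  })
  list(curves = do.call(rbind, out),
       ledger = list(model = spec$model, params = p, seed = spec$seed,
                     noise_sd = spec$noise_sd, noise_type = spec$noise_type,
                     replicates = spec$replicates))
}
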