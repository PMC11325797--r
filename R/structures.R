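#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that returns the package's
#' `gas_structure` container. Author (PDB) residue numbering is preserved and
#' HETATM records (e.g. the GDP/GTP ligand) are retained so that ligand atoms
#' remain selectable by residue name.
#'
#' @param path Path to a PDB file.
#' @return An object of class `gas_structure`: a list with `atoms` (data frame
#'   with columns `serial`, `name`, `element`, `resno`, `resid`, `chain`) and
#'   `xyz` (numeric matrix, n_atoms x 3, Angstrom).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("empty input: no ATOM/HETATM records in ", path)
  as_structure(pdb)
}

## Build a gas_structure from a bio3d pdb object (first model only).
as_structure <- function(pdb) {
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- ifelse(is.na(elem) | !nzchar(trimws(elem)),
                 element_from_name(at$elety), trimws(elem))
  atoms <- data.frame(
    serial  = at$eleno,
    name    = at$elety,
    element = elem,
    resno   = at$resno,
    resid   = at$resid,
    chain   = ifelse(is.na(at$chain), "", at$chain),
    stringsAsFactors = FALSE
  )
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  new_structure(atoms, xyz)
}

new_structure <- function(atoms, xyz) {
  stopifnot(nrow(atoms) == nrow(xyz))
  if (nrow(atoms) == 0L) stop("empty input: structure has zero atoms")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure")
  if (any(is.na(atoms$resno))) stop("every atom must carry a residue number")
  structure(list(atoms = atoms, xyz = xyz), class = "gas_structure")
}

## PDB atom names lead with the element symbol once digits are stripped;
## two-letter biological elements in this domain are rare (no metals in the
## toy systems), so the first alphabetic character suffices.
element_from_name <- function(name) {
  stripped <- sub("^[0-9']*", "", trimws(name))
  toupper(substr(stripped, 1, 1))
}

#' @export
print.gas_structure <- function(x, ...) {
  cat("gas_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  invisible(x)
}

n_atoms <- function(x) nrow(x$atoms)

#' Read an MD trajectory bound to a topology
#'
#' Reads one or more coordinate files (CHARMM/NAMD-style DCD, or multi-model
#' PDB) and concatenates their frames in file order. Every file must carry the
#' same number of atoms as the topology.
#'
#' @param topology A `gas_structure` (see [read_structure()]).
#' @param paths Character vector of trajectory file paths (`.dcd` or `.pdb`).
#' @param frame_interval_ps Optional frame spacing metadata (picoseconds).
#' @return A `gas_trajectory`: list with `topology`, `coords`
#'   (n_frames x n_atoms x 3 array, Angstrom) and `frame_interval_ps`.
#' @export
read_trajectory <- function(topology, paths, frame_interval_ps = NULL) {
  stopifnot(inherits(topology, "gas_structure"))
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    ext <- tolower(tools::file_ext(p))
    xyz <- switch(ext,
      dcd = bio3d::read.dcd(p, verbose = FALSE),
      pdb = bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz,
      stop("unsupported trajectory format '.", ext,
           "' (supported: .dcd, .pdb multi-model)")
    )
    xyz <- as.matrix(xyz)
    if (ncol(xyz) != 3L * n_atoms(topology))
      stop("topology error: ", p, " has ", ncol(xyz) / 3,
           " atoms but topology has ", n_atoms(topology))
    xyz
  })
  xyz <- do.call(rbind, frames)
  new_trajectory(topology, xyz_to_array(xyz), frame_interval_ps)
}

xyz_to_array <- function(xyz_mat) {
  nf <- nrow(xyz_mat); na <- ncol(xyz_mat) / 3L
  arr <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) arr[, , k] <- xyz_mat[, seq(k, by = 3L, length.out = na), drop = FALSE]
  arr
}

array_to_xyz <- function(arr) {
  nf <- dim(arr)[1]; na <- dim(arr)[2]
  out <- matrix(NA_real_, nf, 3L * na)
  for (k in 1:3) out[, seq(k, by = 3L, length.out = na)] <- arr[, , k]
  out
}

new_trajectory <- function(topology, coords, frame_interval_ps = NULL) {
  stopifnot(inherits(topology, "gas_structure"), length(dim(coords)) == 3L)
  if (dim(coords)[1] < 1L) stop("empty input: trajectory has zero frames")
  if (dim(coords)[2] != n_atoms(topology))
    stop("topology error: coordinate atom count does not match topology")
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  structure(list(topology = topology, coords = coords,
                 frame_interval_ps = frame_interval_ps),
            class = "gas_trajectory")
}

#' @export
print.gas_trajectory <- function(x, ...) {
  cat("gas_trajectory:", dim(x$coords)[1], "frames x",
      dim(x$coords)[2], "atoms\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

## Extract frame i as an n_atoms x 3 matrix.
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (CHARMM header, no unit cell),
#' readable by [bio3d::read.dcd()] and standard MD toolchains. Provided
#' because no installed package writes DCD; used mainly to materialise
#' synthetic trajectories.
#'
#' @param traj A `gas_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "gas_trajectory"))
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); na <- dim(traj$coords)[2]
  rec <- function(writer) {
    # Fortran unformatted record: payload framed by its byte count.
    raw_payload <- writer
    writeBin(length(raw_payload), con, size = 4L)
    writeBin(raw_payload, con)
    writeBin(length(raw_payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf       # NSET
  icntrl[2] <- 1L       # ISTART
  icntrl[3] <- 1L       # NSAVC
  icntrl[20] <- 24L     # CHARMM version tag
  hdr <- c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4L))
  # DELTA occupies word 10 as a float in CHARMM files; leave 0 (no metadata).
  rec(hdr)
  title <- formatC("synthetic trajectory written by gaswitch", width = 80, flag = "-")
  rec(c(writeBin(1L, raw(), size = 4L), charToRaw(title)))
  rec(writeBin(na, raw(), size = 4L))
  for (i in seq_len(nf)) {
    fc <- frame_coords(traj, i)
    for (k in 1:3) rec(writeBin(as.numeric(fc[, k]), raw(), size = 4L))
  }
  invisible(path)
}

#' Write a structure (or single frame) to a PDB file
#'
#' @param struct A `gas_structure`.
#' @param path Output file path.
#' @param xyz Optional replacement coordinates (n_atoms x 3).
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path, xyz = NULL) {
  stopifnot(inherits(struct, "gas_structure"))
  if (is.null(xyz)) xyz <- struct$xyz
  at <- struct$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid,
                   eleno = at$serial, elety = at$name,
                   chain = ifelse(nzchar(at$chain), at$chain, " "),
                   elesy = at$element)
  invisible(path)
}

# ---- regions and selections -------------------------------------------------

#' Define a named residue region
#'
#' @param name Region name (e.g. `"switch_I"`).
#' @param residue_numbers Integer vector of author residue numbers.
#' @return A `region_def` object.
#' @export
region_def <- function(name, residue_numbers) {
  residue_numbers <- sort(unique(as.integer(residue_numbers)))
  if (length(residue_numbers) == 0L) stop("region '", name, "' is empty")
  structure(list(name = name, residue_numbers = residue_numbers),
            class = "region_def")
}

#' Load region definitions from a YAML config
#'
#' The file holds `regions: {switch_I: [197, 207], ...}` where each value is an
#' inclusive `[first, last]` residue range (or an explicit list of residues
#' when longer than 2 or not ordered).
#'
#' @param path YAML file path. Defaults to the switch-region definitions
#'   shipped with the package.
#' @return Named list of `region_def` objects.
#' @export
load_regions <- function(path = system.file("extdata", "regions.yaml",
                                            package = "gaswitch")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions)) stop("config error: no 'regions' key in ", path)
  regions_from_list(cfg$regions)
}

regions_from_list <- function(lst) {
  out <- lapply(names(lst), function(nm) {
    v <- as.integer(unlist(lst[[nm]]))
    if (length(v) == 2L && v[1] <= v[2]) v <- v[1]:v[2]
    region_def(nm, v)
  })
  names(out) <- names(lst)
  out
}

#' Default switch-region definitions for Galpha-S
#'
#' Inclusive author-numbering ranges: switch I 197-207, switch II 219-236,
#' switch III 254-270. These are configuration data (shipped as YAML), chosen
#' so that every switch residue discussed in the package documentation
#' (R201, S205, G226, Q227, R228, E230, R258, E259, R265, E268) falls inside
#' its named region.
#'
#' @return Named list of `region_def` objects.
#' @export
default_switch_regions <- function() {
  load_regions()
}

## Atom indices (into topology) whose residue number is in the region.
region_atom_idx <- function(topology, region, chain = NULL) {
  at <- topology$atoms
  sel <- at$resno %in% region$residue_numbers
  if (!is.null(chain)) sel <- sel & at$chain %in% chain
  which(sel)
}

assert_region_in_topology <- function(topology, region) {
  missing <- setdiff(region$residue_numbers, unique(topology$atoms$resno))
  if (length(missing) == length(region$residue_numbers))
    stop("region '", region$name, "' matches no residue in topology")
  invisible(TRUE)
}

#' Define a ligand and its monitored protons
#'
#' @param resname Ligand residue name in the topology (e.g. `"GDP"`).
#' @param protons Named list mapping proton labels (`"a"`..`"d"`) to one or
#'   more ligand hydrogen atom names; labels with more than one atom are
#'   treated as equivalent protons (a single overlapped NMR signal).
#' @return A `ligand_selection` object.
#' @export
ligand_selection <- function(resname, protons) {
  stopifnot(is.list(protons), length(protons) > 0, !is.null(names(protons)))
  structure(list(resname = resname, protons = protons),
            class = "ligand_selection")
}

#' Default nucleotide proton map
#'
#' Labels `a`-`d` mapped to GDP/GTP proton names in PDB ligand nomenclature:
#' a = H8 (guanine base), b = H1' (ribose anomeric), c = H2', d = the two
#' equivalent H5' protons. A best-reading default; override via
#' [ligand_selection()] or the YAML config.
#'
#' @param resname Ligand residue name (default `"GDP"`).
#' @return A `ligand_selection`.
#' @export
default_ligand_protons <- function(resname = "GDP") {
  ligand_selection(resname, list(a = "H8", b = "H1'", c = "H2'",
                                 d = c("H5'", "H5''")))
}

# ---- superposition ----------------------------------------------------------

## Kabsch: optimal rotation R and translation mapping moving -> target
## (both n x 3). Returns list(R, t); apply as sweep(x,2,cm) %*% R + ct.
kabsch <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  A <- sweep(moving, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(R = R, cm = cm, ct = ct)
}

apply_kabsch <- function(x, fit) {
  sweep(sweep(x, 2, fit$cm) %*% fit$R, 2, fit$ct, `+`)
}

#' Superpose trajectory frames onto their iterated mean structure
#'
#' Each frame is least-squares superposed (optimal rotation + translation,
#' Kabsch) on the selection, onto an iteratively refined mean structure: fit
#' all frames to the current mean of the selection, recompute the mean, and
#' repeat until the mean moves less than `tol` (max `max_iter` iterations).
#' The transform fitted on the selection is applied to all atoms.
#'
#' @param traj A `gas_trajectory`.
#' @param selection Integer atom indices used for fitting (>= 3 non-collinear).
#' @param max_iter,tol Iteration controls (defaults 5 and 1e-6 Angstrom).
#' @return A new, superposed `gas_trajectory`.
#' @export
superpose <- function(traj, selection, max_iter = 5L, tol = 1e-6) {
  stopifnot(inherits(traj, "gas_trajectory"))
  selection <- as.integer(selection)
  if (length(selection) < 3L)
    stop("degenerate superposition: need >= 3 selected atoms")
  ref0 <- frame_coords(traj, 1)[selection, , drop = FALSE]
  sv <- svd(sweep(ref0, 2, colMeans(ref0)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate superposition: selected atoms are collinear")
  nf <- n_frames(traj)
  coords <- traj$coords
  mean_sel <- ref0
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(nf)) {
      fc <- matrix(coords[i, , ], ncol = 3)
      fit <- kabsch(fc[selection, , drop = FALSE], mean_sel)
      coords[i, , ] <- apply_kabsch(fc, fit)
    }
    new_mean <- apply(coords[, selection, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(max(rowSums((new_mean - mean_sel)^2)))
    mean_sel <- new_mean
    if (shift < tol) break
  }
  new_trajectory(traj$topology, coords, traj$frame_interval_ps)
}
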