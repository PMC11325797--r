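## Proton-contact machinery: for each monitored nucleotide proton, which
## protein residues keep a hydrogen within a cut-off radius, and which residue
## is closest. Distances are ligand-proton to protein-proton (H-H), because
## saturation transfer is proton-mediated.

## Precompute ligand proton atom indices and protein hydrogen indices.
contact_cache <- function(topology, ligand_protons) {
  stopifnot(inherits(ligand_protons, "ligand_selection"))
  at <- topology$atoms
  lig <- at$resid == ligand_protons$resname
  if (!any(lig)) stop("ligand residue '", ligand_protons$resname,
                      "' not found in topology")
  proton_idx <- lapply(ligand_protons$protons, function(atom_names) {
    idx <- which(lig & at$name %in% atom_names)
    if (length(idx) == 0L)
      stop("ligand proton atom(s) ", paste(atom_names, collapse = "/"),
           " not found in ligand ", ligand_protons$resname)
    idx
  })
  prot_h <- which(!lig & at$element == "H")
  if (length(prot_h) == 0L)
    stop("no protein hydrogens in topology: contact analysis requires ",
         "explicit hydrogens")
  list(proton_idx = proton_idx, prot_h = prot_h,
       prot_h_resno = at$resno[prot_h])
}

## Expand a proton label map into one entry per physical proton atom: labels
## with several atoms (equivalent protons) become "d.1", "d.2", ...
expand_proton_atoms <- function(cache) {
  out <- list()
  for (lab in names(cache$proton_idx)) {
    idx <- cache$proton_idx[[lab]]
    if (length(idx) == 1L) out[[lab]] <- idx
    else for (k in seq_along(idx)) out[[paste0(lab, ".", k)]] <- idx[k]
  }
  out
}

#' Per-frame proton contacts
#'
#' For one frame, lists for each monitored ligand proton the protein residues
#' whose nearest hydrogen lies within `radius` of the proton, and the identity
#' of the closest residue (ties broken by the lower residue number).
#'
#' @param topology A `gas_structure`.
#' @param coords Frame coordinates (n_atoms x 3).
#' @param ligand_protons A [ligand_selection()].
#' @param radius Cut-off radius (Angstrom, > 0; default 6).
#' @return Named list (one element per physical proton; equivalent protons
#'   appear as `label.1`, `label.2`) with `in_radius` (integer residue
#'   numbers), `closest` (residue number or NA) and `distances` (named vector,
#'   per-residue nearest H-H distance).
#' @export
proton_contacts_frame <- function(topology, coords, ligand_protons,
                                  radius = 6.0) {
  stopifnot(radius > 0)
  cache <- contact_cache(topology, ligand_protons)
  lapply(expand_proton_atoms(cache), function(pi)
    proton_contact_one(cache, coords, pi, radius))
}

proton_contact_one <- function(cache, coords, proton_atom, radius) {
  p <- coords[proton_atom, ]
  d <- sqrt(rowSums(sweep(coords[cache$prot_h, , drop = FALSE], 2, p)^2))
  # nearest protein hydrogen per residue, in numeric residue order
  res_min <- tapply(d, cache$prot_h_resno, min)
  resnos <- as.integer(names(res_min))
  ord <- order(resnos)
  resnos <- resnos[ord]
  res_min <- as.numeric(res_min)[ord]
  inr <- resnos[res_min < radius]
  closest <- if (length(inr) == 0L) NA_integer_ else {
    cand <- which(res_min == min(res_min))
    # ties broken by lower residue number (resnos sorted by tapply)
    resnos[cand[1]]
  }
  list(in_radius = inr, closest = closest,
       distances = stats::setNames(res_min, resnos))
}

#' Proton-contact occupancy profile over a trajectory
#'
#' For each monitored proton and protein residue: `proximity_occupancy` = the
#' fraction of frames with a residue hydrogen inside `radius` of the proton,
#' and `closest_frequency` = the fraction of frames in which the residue is
#' the closest one (frames with no residue in radius count toward neither, so
#' closest frequencies may sum below 1). Equivalent protons declared in the
#' ligand selection (e.g. the two H5' protons of label "d") are reported
#' separately here and merged by [average_equivalent_protons()].
#'
#' @param traj A `gas_trajectory`.
#' @param ligand_protons A [ligand_selection()].
#' @param radius Cut-off radius (Angstrom; default 6).
#' @return A `contact_profile`: named list per physical proton of data frames
#'   (`resno`, `proximity_occupancy`, `closest_frequency`), with attributes
#'   `n_frames`, `radius` and `union_occupancy` (per residue, fraction of
#'   frames within radius of one or more monitored protons).
#' @export
contact_occupancy <- function(traj, ligand_protons, radius = 6.0) {
  stopifnot(inherits(traj, "gas_trajectory"))
  nf <- n_frames(traj)
  cache <- contact_cache(traj$topology, ligand_protons)
  protons <- expand_proton_atoms(cache)
  resnos <- sort(unique(cache$prot_h_resno))
  nres <- length(resnos)
  prox <- matrix(0L, nres, length(protons),
                 dimnames = list(resnos, names(protons)))
  clos <- prox
  union_count <- stats::setNames(integer(nres), resnos)
  for (i in seq_len(nf)) {
    fc <- frame_coords(traj, i)
    seen <- character(0)
    for (j in seq_along(protons)) {
      r <- proton_contact_one(cache, fc, protons[[j]], radius)
      key <- as.character(r$in_radius)
      prox[key, j] <- prox[key, j] + 1L
      if (!is.na(r$closest))
        clos[as.character(r$closest), j] <- clos[as.character(r$closest), j] + 1L
      seen <- union(seen, key)
    }
    union_count[seen] <- union_count[seen] + 1L
  }
  out <- lapply(seq_along(protons), function(j) {
    keep <- prox[, j] > 0L
    data.frame(resno = resnos[keep],
               proximity_occupancy = prox[keep, j] / nf,
               closest_frequency = clos[keep, j] / nf,
               row.names = NULL)
  })
  names(out) <- names(protons)
  structure(out, class = "contact_profile", n_frames = nf, radius = radius,
            union_occupancy = data.frame(
              resno = resnos[union_count > 0L],
              occupancy = union_count[union_count > 0L] / nf,
              row.names = NULL))
}

#' Merge equivalent protons by arithmetic averaging
#'
#' Protons declared equivalent in the ligand selection (one overlapped NMR
#' signal, e.g. the two H5' protons) are measured independently and merged by
#' the arithmetic mean of their per-residue metrics.
#'
#' @param profile A `contact_profile` from [contact_occupancy()].
#' @param ligand_protons The [ligand_selection()] used to compute it.
#' @return A `contact_profile` with one entry per proton *label*.
#' @export
average_equivalent_protons <- function(profile, ligand_protons) {
  stopifnot(inherits(profile, "contact_profile"),
            inherits(ligand_protons, "ligand_selection"))
  out <- list()
  for (lab in names(ligand_protons$protons)) {
    n_eq <- length(ligand_protons$protons[[lab]])
    members <- if (n_eq == 1L) lab else paste0(lab, ".", seq_len(n_eq))
    if (!all(members %in% names(profile)))
      stop("usage error: profile lacks entries for proton label '", lab, "'")
    sub <- profile[members]
    resnos <- sort(unique(unlist(lapply(sub, `[[`, "resno"))))
    avg <- function(col) rowMeans(matrix(vapply(sub, function(df) {
      v <- stats::setNames(rep(0, length(resnos)), resnos)
      v[as.character(df$resno)] <- df[[col]]
      v
    }, numeric(length(resnos))), nrow = length(resnos)))
    out[[lab]] <- data.frame(resno = resnos,
                             proximity_occupancy = avg("proximity_occupancy"),
                             closest_frequency = avg("closest_frequency"),
                             row.names = NULL)
  }
  structure(out, class = "contact_profile",
            n_frames = attr(profile, "n_frames"),
            radius = attr(profile, "radius"),
            union_occupancy = attr(profile, "union_occupancy"))
}

#' Aggregate contact profiles across systems
#'
#' Mean and SEM (in percent) of per-system proximity occupancies for each
#' (proton, residue); residues absent from a system's profile count as 0
#' there. Requires at least two systems (SEM is undefined for one).
#'
#' @param profiles Named list of `contact_profile`s, one per system; all must
#'   carry identical proton labels.
#' @return Data frame with `proton`, `resno`, `mean_pct`, `sem_pct`, `n`, with
#'   attribute `systems`.
#' @export
aggregate_contacts <- function(profiles) {
  if (length(profiles) < 2L)
    stop("SEM undefined: need >= 2 systems to aggregate")
  labs <- names(profiles[[1]])
  for (p in profiles)
    if (!identical(names(p), labs))
      stop("profiles carry different proton labels")
  n <- length(profiles)
  rows <- list()
  for (lab in labs) {
    resnos <- sort(unique(unlist(lapply(profiles, function(p) p[[lab]]$resno))))
    occ <- vapply(profiles, function(p) {
      v <- stats::setNames(rep(0, length(resnos)), resnos)
      df <- p[[lab]]
      v[as.character(df$resno)] <- df$proximity_occupancy
      v
    }, numeric(length(resnos)))
    occ <- matrix(occ, nrow = length(resnos))
    m <- rowMeans(occ)
    sem <- apply(occ, 1, stats::sd) / sqrt(n)
    rows[[lab]] <- data.frame(proton = lab, resno = resnos,
                              mean_pct = 100 * m, sem_pct = 100 * sem, n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, systems = names(profiles))
}
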