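#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond D-H...A is counted when the H-to-acceptor distance is below
#' `max_distance` and the donor-H-acceptor angle exceeds `min_angle`. Defaults
#' are the conventional 2.4 Angstrom / 120 degree cut-offs used for
#' switch-region network analysis.
#'
#' @param max_distance Maximum H...A distance (Angstrom, > 0).
#' @param min_angle Minimum D-H...A angle (degrees, in (0, 180]).
#' @return An `hbond_criteria` object.
#' @export
hbond_criteria <- function(max_distance = 2.4, min_angle = 120) {
  stopifnot(max_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

## Polar hydrogens: H atoms whose nearest heavy atom (from the topology
## reference coordinates, within 1.25 A) is N or O. Covalent connectivity is
## frame-independent, so assignment from the topology is done once.
## Returns data.frame(h_idx, d_idx).
polar_hydrogens <- function(topology) {
  at <- topology$atoms
  h_idx <- which(at$element == "H")
  if (length(h_idx) == 0L)
    stop("no hydrogens in topology: H-bond detection requires explicit ",
         "polar hydrogens (add them before analysis)")
  heavy_idx <- which(at$element != "H")
  xyz <- topology$xyz
  d_of_h <- vapply(h_idx, function(h) {
    d2 <- rowSums(sweep(xyz[heavy_idx, , drop = FALSE], 2, xyz[h, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > 1.25) return(NA_integer_)
    heavy_idx[j]
  }, integer(1))
  keep <- !is.na(d_of_h) & at$element[d_of_h] %in% c("N", "O")
  data.frame(h_idx = h_idx[keep], d_idx = d_of_h[keep])
}

## Acceptor atoms: all N and O, backbone and sidechain.
acceptor_atoms <- function(topology) {
  which(topology$atoms$element %in% c("N", "O"))
}

#' Detect hydrogen bonds in a single frame
#'
#' Evaluates all donor/acceptor combinations in both directions (donors in
#' `regionA` against acceptors in `regionB`, and vice versa) and reports every
#' D-H...A triplet satisfying the criteria.
#'
#' @param topology A `gas_structure` with explicit polar hydrogens.
#' @param coords Frame coordinates (n_atoms x 3 matrix).
#' @param criteria An [hbond_criteria()].
#' @param regionA,regionB `region_def` objects.
#' @return Data frame with one row per detected bond: donor/acceptor residue
#'   numbers and atom names, hydrogen atom name, distance (Angstrom) and angle
#'   (degrees).
#' @export
detect_hbonds_frame <- function(topology, coords, criteria, regionA, regionB) {
  cache <- hbond_cache(topology, regionA, regionB)
  detect_hbonds_cached(cache, coords, criteria)
}

## Precompute donor/acceptor index tables for a region pair.
hbond_cache <- function(topology, regionA, regionB) {
  assert_region_in_topology(topology, regionA)
  assert_region_in_topology(topology, regionB)
  ph <- polar_hydrogens(topology)
  at <- topology$atoms
  in_region <- function(idx, region) at$resno[idx] %in% region$residue_numbers
  acc <- acceptor_atoms(topology)
  pairs_dir <- function(don_region, acc_region) {
    dsel <- ph[in_region(ph$d_idx, don_region), , drop = FALSE]
    asel <- acc[in_region(acc, acc_region)]
    list(donors = dsel, acceptors = asel)
  }
  list(topology = topology,
       dirs = list(pairs_dir(regionA, regionB), pairs_dir(regionB, regionA)))
}

detect_hbonds_cached <- function(cache, coords, criteria) {
  at <- cache$topology$atoms
  out <- list()
  for (dir in cache$dirs) {
    dn <- dir$donors; acc <- dir$acceptors
    if (nrow(dn) == 0L || length(acc) == 0L) next
    H <- coords[dn$h_idx, , drop = FALSE]
    D <- coords[dn$d_idx, , drop = FALSE]
    A <- coords[acc, , drop = FALSE]
    # H...A distances: nH x nA
    d2 <- outer(rowSums(H^2), rep(1, nrow(A))) +
          outer(rep(1, nrow(H)), rowSums(A^2)) - 2 * tcrossprod(H, A)
    d2[d2 < 0] <- 0
    dist <- sqrt(d2)
    hit <- which(dist < criteria$max_distance, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    hi <- hit[, 1]; ai <- hit[, 2]
    # exclude the donor heavy atom itself as acceptor
    keep <- dn$d_idx[hi] != acc[ai]
    hi <- hi[keep]; ai <- ai[keep]
    if (length(hi) == 0L) next
    v1 <- D[hi, , drop = FALSE] - H[hi, , drop = FALSE]
    v2 <- A[ai, , drop = FALSE] - H[hi, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    ang <- acos(cosang) * 180 / pi
    keep <- ang > criteria$min_angle
    if (!any(keep)) next
    hi <- hi[keep]; ai <- ai[keep]
    out[[length(out) + 1L]] <- data.frame(
      donor_resno = at$resno[dn$d_idx[hi]],
      donor_atom  = at$name[dn$d_idx[hi]],
      h_atom      = at$name[dn$h_idx[hi]],
      acceptor_resno = at$resno[acc[ai]],
      acceptor_atom  = at$name[acc[ai]],
      distance = dist[cbind(hi, ai)],
      angle    = ang[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L)
    return(data.frame(donor_resno = integer(), donor_atom = character(),
                      h_atom = character(), acceptor_resno = integer(),
                      acceptor_atom = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy matrix between two regions
#'
#' Fraction of trajectory frames in which each atom-level donor-acceptor pair
#' satisfies the geometric criteria. Pairs never detected are omitted.
#'
#' @param traj A `gas_trajectory`.
#' @param regionA,regionB `region_def` objects.
#' @param criteria An [hbond_criteria()].
#' @return An `hbond_matrix`: data frame with donor/acceptor residue and atom
#'   columns, `count` and `occupancy`, plus attributes `n_frames`, `regions`
#'   and `criteria`.
#' @export
hbond_occupancy <- function(traj, regionA, regionB,
                            criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "gas_trajectory"))
  nf <- n_frames(traj)
  cache <- hbond_cache(traj$topology, regionA, regionB)
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    det <- detect_hbonds_cached(cache, frame_coords(traj, i), criteria)
    if (nrow(det) == 0L) next
    keys <- unique(paste(det$donor_resno, det$donor_atom,
                         det$acceptor_resno, det$acceptor_atom, sep = "\r"))
    for (k in keys) assign(k, (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L,
                           envir = counts)
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    tab <- data.frame(donor_resno = integer(), donor_atom = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      count = integer(), occupancy = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    tab <- data.frame(donor_resno = as.integer(parts[, 1]),
                      donor_atom = parts[, 2],
                      acceptor_resno = as.integer(parts[, 3]),
                      acceptor_atom = parts[, 4],
                      count = vapply(keys, function(k) counts[[k]], integer(1)),
                      stringsAsFactors = FALSE)
    tab$occupancy <- tab$count / nf
    tab <- tab[order(tab$donor_resno, tab$donor_atom,
                     tab$acceptor_resno, tab$acceptor_atom), ]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("hbond_matrix", "data.frame"),
            n_frames = nf,
            regions = c(regionA$name, regionB$name),
            criteria = criteria)
}

#' Aggregate an atom-level occupancy matrix to residue pairs
#'
#' A residue pair is connected in any frame in which at least one of its
#' atom-level pairs is; the residue-level occupancy reported here is the
#' maximum over atom-level occupancies of the pair (an exact lower bound on,
#' and in practice close to, the per-frame union occupancy).
#'
#' @param mat An `hbond_matrix`.
#' @return Data frame with `donor_resno`, `acceptor_resno`, `occupancy`.
#' @export
hbond_residue_matrix <- function(mat) {
  if (nrow(mat) == 0L)
    return(data.frame(donor_resno = integer(), acceptor_resno = integer(),
                      occupancy = numeric()))
  key <- paste(mat$donor_resno, mat$acceptor_resno)
  agg <- tapply(mat$occupancy, key, max)
  parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  out <- data.frame(donor_resno = as.integer(parts[, 1]),
                    acceptor_resno = as.integer(parts[, 2]),
                    occupancy = as.numeric(agg))
  out[order(out$donor_resno, out$acceptor_resno), , drop = FALSE]
}

#' Classify occupancy into persistence tiers
#'
#' The tier of a pair is the number of thresholds its occupancy meets
#' (comparison is inclusive, `>=`); pairs below the lowest threshold are
#' excluded. With the default tiers (0.25, 0.50, 0.75) an occupancy of 0.6
#' sits in tier 2.
#'
#' @param mat An `hbond_matrix` (or the residue-level aggregate).
#' @param thresholds Strictly increasing occupancy thresholds in (0, 1].
#' @return The input rows at or above the lowest threshold, with a `tier`
#'   column appended.
#' @export
persistence_tiers <- function(mat, thresholds = c(0.25, 0.50, 0.75)) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds > 1))
    stop("config error: thresholds must be strictly increasing in (0, 1]")
  tier <- vapply(mat$occupancy, function(o) sum(o >= thresholds), integer(1))
  out <- mat[tier > 0L, , drop = FALSE]
  out$tier <- tier[tier > 0L]
  rownames(out) <- NULL
  out
}

#' Compare two hydrogen-bond networks
#'
#' Classifies pairs by presence at `>= threshold` occupancy in each matrix:
#' pairs present in A but not B are "lost in B", the converse "gained in B",
#' pairs present in both "shared".
#'
#' @param matA,matB `hbond_matrix` objects computed with identical criteria.
#' @param threshold Presence threshold (occupancy fraction).
#' @param by `"atom"` (default) or `"residue"` granularity.
#' @return List with data frames `lost`, `gained`, `shared`.
#' @export
compare_networks <- function(matA, matB, threshold = 0.5, by = c("atom", "residue")) {
  by <- match.arg(by)
  ca <- attr(matA, "criteria"); cb <- attr(matB, "criteria")
  if (!is.null(ca) && !is.null(cb) && !identical(unclass(ca), unclass(cb)))
    stop("comparison error: matrices computed with different criteria")
  ra <- attr(matA, "regions"); rb <- attr(matB, "regions")
  if (!is.null(ra) && !is.null(rb) && !identical(sort(ra), sort(rb)))
    stop("comparison error: mismatched region labels (",
         paste(ra, collapse = "/"), " vs ", paste(rb, collapse = "/"), ")")
  keyfun <- if (by == "atom") {
    function(m) paste(m$donor_resno, m$donor_atom,
                      m$acceptor_resno, m$acceptor_atom, sep = "|")
  } else {
    function(m) paste(m$donor_resno, m$acceptor_resno, sep = "|")
  }
  if (by == "residue") { matA <- hbond_residue_matrix(matA); matB <- hbond_residue_matrix(matB) }
  pa <- matA[matA$occupancy >= threshold, , drop = FALSE]
  pb <- matB[matB$occupancy >= threshold, , drop = FALSE]
  ka <- keyfun(pa); kb <- keyfun(pb)
  list(lost   = pa[!(ka %in% kb), , drop = FALSE],
       gained = pb[!(kb %in% ka), , drop = FALSE],
       shared = pa[ka %in% kb, , drop = FALSE])
}

#' Write an occupancy matrix to CSV
#'
#' @param mat An `hbond_matrix` (optionally tiered).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hbond_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  invisible(path)
}
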