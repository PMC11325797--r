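# Independent brute-force oracles: deliberately naive O(N^2) per-frame loops,
# sharing no code with the package implementation. Used to validate the
# vectorised H-bond and contact machinery on random-geometry fixtures.

dist3 <- function(a, b) sqrt(sum((a - b)^2))

angle_deg <- function(p_center, p1, p2) {
  v1 <- p1 - p_center; v2 <- p2 - p_center
  ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(min(1, max(-1, ct))) * 180 / pi
}

# naive donor table: every H whose nearest heavy atom (topology coords,
# < 1.25 A) is N or O
naive_donors <- function(top) {
  at <- top$atoms
  out <- NULL
  for (h in which(at$element == "H")) {
    best <- NA; bestd <- Inf
    for (j in seq_len(nrow(at))) {
      if (at$element[j] == "H") next
      d <- dist3(top$xyz[h, ], top$xyz[j, ])
      if (d < bestd) { bestd <- d; best <- j }
    }
    if (bestd < 1.25 && at$element[best] %in% c("N", "O"))
      out <- rbind(out, c(h, best))
  }
  out
}

# occupancy counts for every donor/acceptor pair across regions, both
# directions; returns data.frame keyed like hbond_occupancy()
naive_hbond_occupancy <- function(traj, regionA, regionB, criteria) {
  top <- traj$topology; at <- top$atoms
  don <- naive_donors(top)
  acc <- which(at$element %in% c("N", "O"))
  nf <- dim(traj$coords)[1]
  counts <- list()
  for (f in seq_len(nf)) {
    fc <- matrix(traj$coords[f, , ], ncol = 3)
    # occupancy is a per-frame indicator: a pair detected through several
    # hydrogens in the same frame still counts once
    frame_keys <- character(0)
    for (r in seq_len(nrow(don))) {
      h <- don[r, 1]; d <- don[r, 2]
      for (a in acc) {
        if (a == d) next
        dir_ok <-
          (at$resno[d] %in% regionA$residue_numbers &&
           at$resno[a] %in% regionB$residue_numbers) ||
          (at$resno[d] %in% regionB$residue_numbers &&
           at$resno[a] %in% regionA$residue_numbers)
        if (!dir_ok) next
        if (dist3(fc[h, ], fc[a, ]) >= criteria$max_distance) next
        if (angle_deg(fc[h, ], fc[d, ], fc[a, ]) <= criteria$min_angle) next
        key <- paste(at$resno[d], at$name[d], at$resno[a], at$name[a],
                     sep = "|")
        if (!(key %in% frame_keys)) frame_keys <- c(frame_keys, key)
      }
    }
    for (key in frame_keys) counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  if (length(counts) == 0L)
    return(data.frame(donor_resno = integer(), donor_atom = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      count = integer()))
  parts <- do.call(rbind, strsplit(names(counts), "|", fixed = TRUE))
  out <- data.frame(donor_resno = as.integer(parts[, 1]),
                    donor_atom = parts[, 2],
                    acceptor_resno = as.integer(parts[, 3]),
                    acceptor_atom = parts[, 4],
                    count = unlist(counts), stringsAsFactors = FALSE)
  out <- out[order(out$donor_resno, out$donor_atom,
                   out$acceptor_resno, out$acceptor_atom), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive contact profile for one physical proton atom name
naive_contact_occupancy <- function(traj, proton_atom_name, lig_resname,
                                    radius) {
  top <- traj$topology; at <- top$atoms
  p_idx <- which(at$resid == lig_resname & at$name == proton_atom_name)
  prot_h <- which(at$resid != lig_resname & at$element == "H")
  nf <- dim(traj$coords)[1]
  prox <- list(); clos <- list()
  for (f in seq_len(nf)) {
    fc <- matrix(traj$coords[f, , ], ncol = 3)
    res_best <- list()
    for (h in prot_h) {
      d <- dist3(fc[p_idx, ], fc[h, ])
      key <- as.character(at$resno[h])
      if (is.null(res_best[[key]]) || d < res_best[[key]])
        res_best[[key]] <- d
    }
    inr <- names(res_best)[unlist(res_best) < radius]
    for (key in inr) prox[[key]] <- (prox[[key]] %||% 0L) + 1L
    if (length(inr) > 0) {
      dmin <- min(unlist(res_best))
      cand <- as.integer(names(res_best)[unlist(res_best) == dmin])
      key <- as.character(min(cand))
      clos[[key]] <- (clos[[key]] %||% 0L) + 1L
    }
  }
  resnos <- sort(as.integer(names(prox)))
  data.frame(resno = resnos,
             proximity_occupancy = vapply(as.character(resnos), function(k)
               prox[[k]] / nf, numeric(1)),
             closest_frequency = vapply(as.character(resnos), function(k)
               (clos[[k]] %||% 0L) / nf, numeric(1)),
             row.names = NULL)
}

# small random-geometry fixture: a handful of residues with polar hydrogens
# and acceptors scattered in a box so criteria hits are frequent but not
# universal; coordinates are redrawn independently every frame
random_hbond_fixture <- function(n_frames, seed, box = 6) {
  set.seed(seed)
  # topology: 4 residues x (N, H, O); H placed 1.0 A from its N
  atoms <- do.call(rbind, lapply(1:4, function(r)
    data.frame(name = c("N", "H", "O"), element = c("N", "H", "O"),
               resno = r, resid = "XXX", chain = "A",
               stringsAsFactors = FALSE)))
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  ref <- matrix(runif(nrow(atoms) * 3, 0, box), ncol = 3)
  for (r in 1:4) {
    iN <- (r - 1) * 3 + 1
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    ref[iN + 1, ] <- ref[iN, ] + u   # H bonded to N
  }
  top <- gaswitch:::new_structure(atoms, ref)
  coords <- array(NA_real_, c(n_frames, nrow(atoms), 3))
  for (f in seq_len(n_frames)) {
    fc <- matrix(runif(nrow(atoms) * 3, 0, box), ncol = 3)
    for (r in 1:4) {
      iN <- (r - 1) * 3 + 1
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      fc[iN + 1, ] <- fc[iN, ] + u
    }
    coords[f, , ] <- fc
  }
  gaswitch:::new_trajectory(top, coords)
}
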