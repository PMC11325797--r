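## Pipeline orchestration: run every requested analysis stage per system
## (variant x nucleotide), record skips and failures explicitly, and compare
## systems against a reference. Interpretation (gain- vs loss-of-function
## narrative) is deliberately left to the user: the report juxtaposes the
## quantitative evidence only.

#' Run the integrative analysis pipeline
#'
#' Executes, per configured system, whichever stages its inputs support:
#' melt-curve fitting (Tm), exchange kinetics, STD amplification factors,
#' and trajectory-derived metrics (H-bond occupancy matrices between switch
#' regions, per-residue RMSF, inter-region nonbonded energies, and
#' nucleotide-proton contact profiles). Missing inputs yield explicit skip
#' records; a failing stage is recorded and the run continues for independent
#' stages. Deterministic given inputs.
#'
#' @param config A YAML file path or an equivalent nested list. Top-level
#'   keys: `systems` (list; each with `label` and any of `melt_csv`,
#'   `kinetics_csv`, `stdaf` (`peaks_csv`/`peaks`, `ligand_conc`,
#'   `protein_conc`, `reference_proton`), `trajectory` (`topology` + `files`,
#'   or an in-memory `object`)); optional `regions`, `hbond`
#'   (`max_distance`, `min_angle`, `thresholds`, `presence_threshold`),
#'   `contacts` (`radius`, `ligand`, `protons`), `energy` (`params_csv`),
#'   `reference`.
#' @return A `run_report` list: `systems` (per-label stage results), `config`
#'   echoes, and provenance.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  regions <- cfg$regions
  report <- list(systems = list(),
                 reference = cfg$reference,
                 provenance = list(package_version =
                                     as.character(utils::packageVersion("gaswitch")),
                                   n_systems = length(cfg$systems)))
  for (sys in cfg$systems) {
    report$systems[[sys$label]] <- run_system(sys, cfg, regions)
  }
  class(report) <- "run_report"
  report
}

load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config error: file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config error: config must be a path or a list")
  if (is.null(cfg$systems) || length(cfg$systems) == 0L)
    stop("config error: no 'systems' defined")
  for (sys in cfg$systems) {
    if (is.null(sys$label)) stop("config error: every system needs a 'label'")
    for (f in c(sys$melt_csv, sys$kinetics_csv, sys$stdaf$peaks_csv,
                sys$trajectory$topology, unlist(sys$trajectory$files)))
      if (is.character(f) && !file.exists(f))
        stop("config error: input not found for system '", sys$label, "': ", f)
  }
  cfg$regions <- if (is.null(cfg$regions)) default_switch_regions()
                 else regions_from_list(cfg$regions)
  cfg$hbond <- utils::modifyList(
    list(max_distance = 2.4, min_angle = 120,
         thresholds = c(0.25, 0.5, 0.75), presence_threshold = 0.5),
    cfg$hbond %||% list())
  cfg$contacts <- utils::modifyList(list(radius = 6.0, ligand = "GDP"),
                                    cfg$contacts %||% list())
  cfg
}

skip_record <- function(reason) list(skipped = TRUE, reason = reason)

run_stage <- function(expr) {
  tryCatch(expr, error = function(e)
    list(failed = TRUE, error = conditionMessage(e)))
}

run_system <- function(sys, cfg, regions) {
  out <- list(label = sys$label)

  out$melt <- if (is.null(sys$melt_csv)) skip_record("no melt data configured")
  else run_stage({
    res <- fit_melt_replicates(read_melt_csv(sys$melt_csv))
    list(tm = res$aggregate$mean_tm, sd = res$aggregate$sd_tm,
         n = res$aggregate$n,
         replicates = lapply(res$fits, function(f)
           list(V50 = f$V50, Slope = f$Slope, se_V50 = unname(f$se["V50"]),
                converged = f$converged)))
  })

  out$kinetics <- if (is.null(sys$kinetics_csv))
    skip_record("no kinetics data configured")
  else run_stage({
    tab <- utils::read.csv(sys$kinetics_csv)
    if (!all(c("time", "intensity") %in% names(tab)))
      stop("kinetics CSV must have columns time, intensity")
    f <- fit_one_phase(tab$time, tab$intensity)
    list(k = f$k, Y0 = f$Y0, Plateau = f$Plateau, se = as.list(f$se),
         window_warning = f$window_warning, converged = f$converged)
  })

  out$stdaf <- if (is.null(sys$stdaf)) skip_record("no STD-NMR data configured")
  else run_stage({
    peaks <- if (!is.null(sys$stdaf$peaks)) sys$stdaf$peaks
             else read_peak_table(sys$stdaf$peaks_csv)
    res <- std_af_from_peaks(peaks,
                             L = sys$stdaf$ligand_conc,
                             P = sys$stdaf$protein_conc,
                             reference = sys$stdaf$reference_proton %||% "a")
    as.data.frame(res)
  })

  traj <- NULL
  if (!is.null(sys$trajectory)) {
    traj <- run_stage({
      if (!is.null(sys$trajectory$object)) sys$trajectory$object
      else read_trajectory(read_structure(sys$trajectory$topology),
                           unlist(sys$trajectory$files))
    })
    if (is.list(traj) && isTRUE(traj$failed)) {
      out$hbond <- out$rmsf <- out$energy <- out$contacts <- traj
      traj <- NULL
    }
  } else {
    msg <- skip_record("no trajectory configured")
    out$hbond <- out$rmsf <- out$energy <- out$contacts <- msg
  }

  if (!is.null(traj)) {
    crit <- hbond_criteria(cfg$hbond$max_distance, cfg$hbond$min_angle)
    pairs <- region_pairs(regions)
    out$hbond <- run_stage({
      lapply(pairs, function(rp) {
        mat <- hbond_occupancy(traj, regions[[rp[1]]], regions[[rp[2]]], crit)
        list(matrix = as.data.frame(mat),
             tiers = as.data.frame(persistence_tiers(mat, cfg$hbond$thresholds)),
             n_frames = attr(mat, "n_frames"))
      })
    })
    out$rmsf <- run_stage({
      sel <- which(traj$topology$atoms$name %in% c("N", "CA", "C", "O") &
                   traj$topology$atoms$chain == "A")
      as.data.frame(compute_rmsf(superpose(traj, sel)))
    })
    out$energy <- if (is.null(cfg$energy$params_csv))
      skip_record("no nonbonded parameter table configured")
    else run_stage({
      params <- read_nonbonded_params(cfg$energy$params_csv)
      do.call(rbind, lapply(pairs, function(rp) {
        e <- nonbonded_energy(traj, regions[[rp[1]]], regions[[rp[2]]], params)
        data.frame(system = sys$label,
                   region_pair = paste(rp, collapse = "-"),
                   energy = e$mean_energy)
      }))
    })
    out$contacts <- run_stage({
      lp <- if (!is.null(cfg$contacts$protons))
        ligand_selection(cfg$contacts$ligand, cfg$contacts$protons)
      else default_ligand_protons(cfg$contacts$ligand)
      prof <- contact_occupancy(traj, lp, radius = cfg$contacts$radius)
      merged <- average_equivalent_protons(prof, lp)
      list(per_proton = lapply(merged, as.data.frame),
           union = attr(prof, "union_occupancy"),
           radius = cfg$contacts$radius)
    })
  }
  out
}

## consecutive region pairs: switch_I-switch_II, switch_II-switch_III, ...
region_pairs <- function(regions) {
  nms <- names(regions)
  if (length(nms) < 2L) stop("need at least two regions")
  out <- list()
  for (i in 1:(length(nms) - 1))
    out[[paste(nms[i], nms[i + 1], sep = "-")]] <- c(nms[i], nms[i + 1])
  out
}

stage_ok <- function(x) !is.null(x) && !isTRUE(x$skipped) && !isTRUE(x$failed)

#' Compare systems in a run report against a reference
#'
#' Produces, per non-reference system: the Tm difference (with SDs combined
#' in quadrature), hydrogen-bond pairs gained and lost relative to the
#' reference at the configured presence threshold, nonbonded-energy ratios
#' normalized to the reference, and STD-AF interaction-bin shifts per proton.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param reference Reference system label (defaults to the one configured).
#' @param presence_threshold Occupancy threshold for H-bond presence
#'   (default 0.5).
#' @return A `comparison` list keyed by system label.
#' @export
compare_systems <- function(report, reference = report$reference,
                            presence_threshold = 0.5) {
  stopifnot(inherits(report, "run_report"))
  if (is.null(reference) || !reference %in% names(report$systems))
    stop("comparison error: reference system '", reference %||% "<none>",
         "' missing from report")
  ref <- report$systems[[reference]]
  others <- setdiff(names(report$systems), reference)
  out <- list()
  for (lab in others) {
    sys <- report$systems[[lab]]
    cmp <- list(system = lab, reference = reference)

    cmp$delta_tm <- if (stage_ok(sys$melt) && stage_ok(ref$melt)) {
      list(delta_tm = sys$melt$tm - ref$melt$tm,
           sd = sqrt((sys$melt$sd %||% 0)^2 + (ref$melt$sd %||% 0)^2))
    } else skip_record("melt data unavailable in one of the systems")

    cmp$hbond <- if (stage_ok(sys$hbond) && stage_ok(ref$hbond)) {
      common <- intersect(names(sys$hbond), names(ref$hbond))
      lapply(stats::setNames(common, common), function(rp) {
        diff_pairs(ref$hbond[[rp]]$matrix, sys$hbond[[rp]]$matrix,
                   presence_threshold)
      })
    } else skip_record("trajectory data unavailable in one of the systems")

    cmp$energy <- if (stage_ok(sys$energy) && stage_ok(ref$energy)) {
      tab <- rbind(ref$energy, sys$energy)
      normalize_energies(tab, reference)[tab$system == lab, ]
    } else skip_record("energy data unavailable in one of the systems")

    cmp$stdaf_bins <- if (stage_ok(sys$stdaf) && stage_ok(ref$stdaf)) {
      m <- merge(ref$stdaf[, c("proton", "normalized_pct", "bin")],
                 sys$stdaf[, c("proton", "normalized_pct", "bin")],
                 by = "proton", suffixes = c("_ref", "_sys"))
      m$shifted <- m$bin_ref != m$bin_sys
      m
    } else skip_record("STD-AF data unavailable in one of the systems")

    out[[lab]] <- cmp
  }
  structure(out, class = "comparison")
}

## atom-level presence comparison on plain data frames
diff_pairs <- function(matA, matB, threshold) {
  key <- function(m) if (nrow(m) == 0L) character(0) else
    paste(m$donor_resno, m$donor_atom, m$acceptor_resno, m$acceptor_atom,
          sep = "|")
  pa <- matA[matA$occupancy >= threshold, , drop = FALSE]
  pb <- matB[matB$occupancy >= threshold, , drop = FALSE]
  list(lost = pa[!(key(pa) %in% key(pb)), , drop = FALSE],
       gained = pb[!(key(pb) %in% key(pa)), , drop = FALSE],
       shared = pa[key(pa) %in% key(pb), , drop = FALSE])
}

#' Write a run report (or comparison) as JSON
#'
#' @param x A `run_report` or `comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}
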