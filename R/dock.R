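# Docking driver: digitize -> rotate -> FFT scan -> per-rotation rescoring
# and retention -> restraint filter -> energy ranking -> clustering ->
# model output.

#' Docking configuration
#'
#' Defaults are the standard global-docking parameter set: 15 degree
#' angular interval, 1.2 A grid spacing, top 10 translations rescored per
#' rotation, 5 A ligand-RMSD cluster cutoff, 10 A interface cutoff, 5.0 A
#' IRMSD hit threshold, 100 output models.
#'
#' @param angle_interval rotational sampling interval, degrees.
#' @param spacing grid spacing, Angstrom.
#' @param top_translations translations rescored per rotation.
#' @param n_models maximum number of emitted models.
#' @param cluster_cutoff ligand RMSD clustering cutoff, Angstrom.
#' @param interface_cutoff interface distance cutoff, Angstrom.
#' @param hit_threshold IRMSD hit threshold, Angstrom.
#' @param kernel receptor surface kernel, `"gaussian"` or
#'   `"paper_literal"`.
#' @param kernel_cutoff kernel reach in grid spacings.
#' @param core_penalty receptor core cell value.
#' @param r_occ receptor occupancy radius, Angstrom (heavy-atom van der
#'   Waals scale; the receptor envelope is dilated by it).
#' @param lig_r_occ ligand occupancy radius, Angstrom.  Kept near the cell
#'   inradius so ligand cells mark atom centers: dilating both molecules
#'   would make touching envelopes overlap and penalize true contact.
#' @param restraint_mode `"filter"` or `"penalty"`.
#' @param seed seed for any stochastic subroutine (the pipeline itself is
#'   deterministic).
#' @param auto_swap use the larger molecule as receptor (with a notice).
#' @return object of class `dock_config`.
#' @export
dock_config <- function(angle_interval = 15, spacing = 1.2,
                        top_translations = 10, n_models = 100,
                        cluster_cutoff = 5, interface_cutoff = 10,
                        hit_threshold = 5.0,
                        kernel = c("gaussian", "paper_literal"),
                        kernel_cutoff = 2, core_penalty = -15, r_occ = 1.8,
                        lig_r_occ = 1.05,
                        restraint_mode = c("filter", "penalty"), seed = 1,
                        auto_swap = TRUE) {
  kernel <- match.arg(kernel)
  restraint_mode <- match.arg(restraint_mode)
  cfg <- list(angle_interval = angle_interval, spacing = spacing,
              top_translations = top_translations, n_models = n_models,
              cluster_cutoff = cluster_cutoff,
              interface_cutoff = interface_cutoff,
              hit_threshold = hit_threshold, kernel = kernel,
              kernel_cutoff = kernel_cutoff, core_penalty = core_penalty,
              r_occ = r_occ, lig_r_occ = lig_r_occ,
              restraint_mode = restraint_mode, seed = seed,
              auto_swap = auto_swap)
  stopifnot(angle_interval > 0, spacing > 0, top_translations >= 1,
            n_models >= 1, cluster_cutoff > 0, interface_cutoff > 0,
            hit_threshold > 0)
  structure(cfg, class = "dock_config")
}

#' Global rigid-body docking of two nucleic-acid structures
#'
#' For every rotation of the deterministic rotation set, the ligand is
#' rotated about its heavy-atom centroid, scanned over all translations on
#' the receptor grid by FFT correlation, and the `top_translations` best
#' shape-complementarity offsets are rescored with the pair potential; the
#' lowest-energy one is retained, giving exactly one binding mode per
#' rotation.  The pooled modes are restraint-filtered, ranked by energy,
#' clustered greedily by ligand C4' RMSD, and (optionally) written out as
#' ranked PDB models.
#'
#' @param receptor,ligand `na_structure`s.  With `auto_swap` (default) the
#'   larger molecule by heavy-atom count becomes the receptor.
#' @param config a [dock_config()].
#' @param restraints a [restraint_set()] (default: empty).
#' @param potential a [potential_table()]; default is the table derived
#'   from synthetic duplexes ([default_potential()]).
#' @param out_dir optional output directory for model PDBs and
#'   `scores.tsv`.
#' @param verbose log per-stage progress to stderr.
#' @return list with `modes` (all retained modes, ranked), `clusters`,
#'   `receptor`, `ligand` (as docked, post swap), `config`, `score_table`
#'   (data.frame for the emitted models, or of all clusters when no
#'   `out_dir`), and `swapped`.
#' @export
dock <- function(receptor, ligand, config = dock_config(),
                 restraints = restraint_set(), potential = NULL,
                 out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(receptor, "na_structure"), inherits(ligand, "na_structure"))
  swapped <- FALSE
  if (isTRUE(config$auto_swap) && nrow(ligand$atoms) > nrow(receptor$atoms)) {
    tmp <- receptor; receptor <- ligand; ligand <- tmp
    swapped <- TRUE
    say("note: molecules swapped; the larger one is docked as receptor")
  }
  if (is.null(potential)) potential <- default_potential()
  resolve_restraints(restraints, receptor, ligand)

  t0 <- proc.time()[3]
  rgrid <- digitize(receptor, spacing = config$spacing, role = "receptor",
                    r_occ = config$r_occ, core_penalty = config$core_penalty,
                    kernel = config$kernel, kernel_cutoff = config$kernel_cutoff)
  say("receptor grid: %d x %d x %d cells (%.1f s)", rgrid$dims[1],
      rgrid$dims[2], rgrid$dims[3], proc.time()[3] - t0)

  rs <- generate_rotations(config$angle_interval)
  rotm <- .rotations_matrix(rs)
  say("rotations: %d at %g degrees", nrow(rotm), config$angle_interval)

  rec_typed <- suppressWarnings(assign_atom_types(receptor))
  lig_typed <- suppressWarnings(assign_atom_types(ligand))
  lig_xyz <- coords(ligand)
  centroid <- colMeans(lig_xyz)

  t1 <- proc.time()[3]
  scan <- cpp_dock_scan(as.numeric(rgrid$values), as.integer(rgrid$dims),
                        rgrid$origin, config$spacing,
                        lig_xyz, centroid, config$lig_r_occ, rotm,
                        as.integer(config$top_translations),
                        rec_typed$xyz, rec_typed$type - 1L,
                        lig_typed$type - 1L,
                        as.numeric(potential$energies),
                        length(potential$types),
                        dim(potential$energies)[3],
                        potential$bin_width, potential$r_max,
                        potential$clash_dist, potential$clash_energy)
  say("FFT scan + rescoring: %d modes retained (%.1f s)", nrow(scan),
      proc.time()[3] - t1)

  tab <- data.frame(rotation_index = as.integer(scan[, 1]),
                    tx = as.integer(scan[, 2]), ty = as.integer(scan[, 3]),
                    tz = as.integer(scan[, 4]),
                    shape_score = scan[, 5], energy = scan[, 6])

  # cached ligand C4' coordinates per mode, in the receptor frame
  c4sel <- select_atoms(ligand, "C4'")
  c4rel <- sweep(c4sel$coords, 2, centroid)
  nmode <- nrow(tab)
  c4 <- matrix(0, nmode, nrow(c4rel) * 3)
  for (i in seq_len(nmode)) {
    R <- matrix(rotm[tab$rotation_index[i], ], 3, 3, byrow = TRUE)
    pos <- c4rel %*% t(R)
    pos <- sweep(pos, 2, centroid + c(tab$tx[i], tab$ty[i], tab$tz[i]) * config$spacing, "+")
    c4[i, ] <- as.numeric(t(pos))
  }

  ctx <- list(receptor = receptor, ligand = ligand, rotations = rotm,
              centroid = centroid, spacing = config$spacing)
  modes <- binding_modes(tab, c4, ctx)
  modes_all <- modes

  if (n_restraints(restraints) > 0) {
    restraints$mode <- config$restraint_mode
    modes <- apply_restraint_filter(modes, restraints,
                                    interface_cutoff = config$interface_cutoff)
    say("restraints: %d of %d modes kept", n_modes(modes), nmode)
  }

  modes <- rank_modes(modes)
  t2 <- proc.time()[3]
  clusters <- cluster_modes(modes, cutoff = config$cluster_cutoff)
  say("clustering: %d clusters (%.1f s)", length(clusters), proc.time()[3] - t2)

  score_table <- NULL
  if (!is.null(out_dir)) {
    score_table <- emit_top_models(clusters, modes, out_dir, n = config$n_models)
  } else {
    take <- head(clusters, config$n_models)
    score_table <- do.call(rbind, lapply(take, function(cl) {
      row <- modes$table[cl$representative, ]
      data.frame(rank = cl$rank, energy = row$energy,
                 shape_score = row$shape_score,
                 rotation_index = row$rotation_index,
                 offset = sprintf("%d,%d,%d", row$tx, row$ty, row$tz))
    }))
  }
  say("total: %.1f s", proc.time()[3] - t0)
  list(modes = modes, modes_unfiltered = modes_all, clusters = clusters,
       receptor = receptor, ligand = ligand, config = config,
       score_table = score_table, swapped = swapped)
}

#' Realize the representative pose of an emitted model rank
#'
#' @param result a [dock()] result.
#' @param rank cluster rank (1-based).
#' @return list with `receptor` and `ligand` (`na_structure`s), the
#'   predicted complex.
#' @export
model_complex <- function(result, rank) {
  cl <- result$clusters[[rank]]
  list(receptor = result$receptor,
       ligand = realize_mode(result$modes, cl$representative))
}

#' Run a docking benchmark and tabulate success rates
#'
#' @param cases list of cases, each a list with `receptor`, `ligand` and
#'   `native` (a list with `receptor` and `ligand`).
#' @param config a [dock_config()].
#' @param top_ns vector of top-N values for the success curve.
#' @param potential optional [potential_table()].
#' @return list with `first_hit_ranks`, `per_case` (list of
#'   [evaluate_models()] results) and `success` (data.frame top_n /
#'   success_rate).
#' @export
run_benchmark <- function(cases, config = dock_config(),
                          top_ns = c(1, 5, 10, 20, 50, 100),
                          potential = NULL) {
  stopifnot(length(cases) >= 1)
  per_case <- vector("list", length(cases))
  ranks <- integer(length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    res <- dock(cs$receptor, cs$ligand, config, potential = potential)
    nmod <- min(length(res$clusters), config$n_models)
    models <- lapply(seq_len(nmod), function(r) model_complex(res, r))
    ev <- evaluate_models(models, cs$native,
                          interface_cutoff = config$interface_cutoff,
                          hit_threshold = config$hit_threshold)
    per_case[[i]] <- ev
    ranks[i] <- ev$first_hit_rank
  }
  success <- data.frame(top_n = top_ns,
                        success_rate = vapply(top_ns, function(n)
                          success_rate(ranks, n), numeric(1)))
  list(first_hit_ranks = ranks, per_case = per_case, success = success)
}
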