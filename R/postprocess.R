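# Post-processing of sampled binding modes: ranking, ligand-RMSD
# clustering and model output.
#
# A `binding_modes` object holds one row per retained mode
# (rotation_index, lattice offset, shape score, energy) plus the cached
# ligand C4' coordinates of every mode, flattened one row per mode.  The
# cache lets clustering run without re-realizing poses; RMSDs are taken in
# the common receptor frame without superposition, so distinct placements
# stay distinct.

#' Construct a binding-modes object
#'
#' @param table data.frame with columns `rotation_index`, `tx`, `ty`, `tz`
#'   (lattice offset), `shape_score`, `energy`.
#' @param c4 numeric matrix, one row per mode: the mode's ligand C4'
#'   coordinates flattened as (x1, y1, z1, x2, ...).
#' @param context list with `receptor`, `ligand` (`na_structure`s),
#'   `rotations` (n x 9 row-major matrix), `centroid` and `spacing`,
#'   sufficient to realize any mode as a posed structure.
#' @return object of class `binding_modes`.
#' @export
binding_modes <- function(table, c4, context) {
  stopifnot(nrow(table) == nrow(c4))
  structure(list(table = table, c4 = c4), context = context,
            class = "binding_modes")
}

#' @export
print.binding_modes <- function(x, ...) {
  cat(sprintf("binding_modes: %d modes, energies [%.3f, %.3f]\n",
              nrow(x$table), suppressWarnings(min(x$table$energy)),
              suppressWarnings(max(x$table$energy))))
  invisible(x)
}

#' Number of modes
#' @param x a `binding_modes` object.
#' @export
n_modes <- function(x) nrow(x$table)

#' Realize one binding mode as a posed ligand structure
#'
#' @param modes a `binding_modes` object.
#' @param i mode row index.
#' @return the posed ligand `na_structure`.
#' @export
realize_mode <- function(modes, i) {
  ctx <- attr(modes, "context")
  row <- modes$table[i, ]
  R <- matrix(as.numeric(ctx$rotations[row$rotation_index, ]), 3, 3, byrow = TRUE)
  shift <- c(row$tx, row$ty, row$tz) * ctx$spacing
  lig <- ctx$ligand
  xyz <- coords(lig)
  xyz <- sweep(xyz, 2, ctx$centroid) %*% t(R)
  xyz <- sweep(xyz, 2, ctx$centroid + shift, "+")
  coords(lig) <- xyz
  lig
}

#' Rank binding modes by energy
#'
#' Ascending energy; ties broken by rotation index, then lexicographic
#' (z, y, x) offset.
#'
#' @param modes a `binding_modes` object.
#' @return the reordered `binding_modes` object.
#' @export
rank_modes <- function(modes) {
  df <- modes$table
  ord <- order(df$energy, df$rotation_index, df$tz, df$ty, df$tx)
  modes$table <- df[ord, , drop = FALSE]
  rownames(modes$table) <- NULL
  modes$c4 <- modes$c4[ord, , drop = FALSE]
  modes
}

#' Ligand RMSD between two binding modes
#'
#' RMSD over paired ligand C4' atoms in the common receptor frame, with no
#' superposition.
#'
#' @param a,b either two rows of cached C4' coordinates (numeric vectors)
#'   or two coordinate matrices with matching rows.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd_between <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("C4' atom count mismatch")
  sqrt(sum((a - b)^2) / (length(a) / 3))
}

# RMSD of one cached row against a block of cached rows
.rmsd_to_block <- function(row, block) {
  n <- length(row) / 3
  sqrt(rowSums(sweep(block, 2, row)^2) / n)
}

#' Greedy ligand-RMSD clustering of ranked binding modes
#'
#' Exactly the greedy procedure used after docking: the first cluster
#' contains every mode within the RMSD cutoff of the lowest-energy mode;
#' the second cluster repeats this on what remains; and so on until no
#' mode is left (or `max_clusters` is reached).  The seed (lowest-energy
#' member) is each cluster's representative.
#'
#' @param modes a `binding_modes` object sorted ascending by energy (see
#'   [rank_modes()]).
#' @param cutoff ligand RMSD cutoff in Angstrom (default 5).
#' @param max_clusters stop after this many clusters (default: exhaust).
#' @return list of clusters, each a list with `representative` (mode row
#'   index into `modes$table`), `members` (row indices) and `rank`.
#' @export
cluster_modes <- function(modes, cutoff = 5, max_clusters = Inf) {
  df <- modes$table
  if (is.unsorted(df$energy)) stop("modes must be sorted ascending by energy")
  remaining <- seq_len(nrow(df))
  clusters <- list()
  while (length(remaining) > 0 && length(clusters) < max_clusters) {
    seed <- remaining[1]                  # lowest energy remaining
    rms <- .rmsd_to_block(modes$c4[seed, ], modes$c4[remaining, , drop = FALSE])
    members <- remaining[rms <= cutoff]
    clusters[[length(clusters) + 1L]] <- list(representative = seed,
                                              members = members,
                                              rank = length(clusters) + 1L)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

#' Write the top cluster representatives as PDB models plus a score table
#'
#' One PDB file per cluster representative (`model_<rank>.pdb`), up to
#' `n`, and a tab-separated `scores.tsv` with rank, energy, shape score,
#' rotation index and lattice offset.
#'
#' @param clusters cluster list from [cluster_modes()].
#' @param modes the `binding_modes` object the clusters refer to.
#' @param out_dir output directory (created if needed).
#' @param n maximum number of models (default 100).
#' @return invisibly, a data.frame of the score table.
#' @export
emit_top_models <- function(clusters, modes, out_dir, n = 100) {
  if (length(clusters) == 0L) stop("no clusters to emit")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctx <- attr(modes, "context")
  take <- head(clusters, n)
  tab <- data.frame(rank = integer(0), energy = numeric(0),
                    shape_score = numeric(0), rotation_index = integer(0),
                    offset = character(0), stringsAsFactors = FALSE)
  for (cl in take) {
    i <- cl$representative
    row <- modes$table[i, ]
    pose <- realize_mode(modes, i)
    write_model(ctx$receptor, pose, cl$rank,
                list(shape = row$shape_score, energy = row$energy),
                file = file.path(out_dir, sprintf("model_%d.pdb", cl$rank)))
    tab <- rbind(tab, data.frame(
      rank = cl$rank, energy = row$energy, shape_score = row$shape_score,
      rotation_index = row$rotation_index,
      offset = sprintf("%d,%d,%d", row$tx, row$ty, row$tz),
      stringsAsFactors = FALSE))
  }
  utils::write.table(tab, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tab)
}
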