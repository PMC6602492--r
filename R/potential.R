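# Distance-dependent knowledge-based atom-pair potential.
#
# Heavy atoms are mapped to a compact type alphabet (backbone atoms by name,
# base atoms by purine/pyrimidine ring context), pair distances are binned,
# and pose energies are sums of tabulated pair terms plus a short-range
# clash guard.  Tables are derived from training complexes by an
# inverse-Boltzmann start (distance-uniform-density reference state) with
# optional discriminative refinement iterations against caller-supplied
# decoys.

.BACKBONE_TYPES <- c(
  "P" = "P", "OP1" = "OP", "OP2" = "OP", "O1P" = "OP", "O2P" = "OP",
  "O3P" = "OP", "O5'" = "O5'", "C5'" = "C5'", "C4'" = "C4'", "O4'" = "O4'",
  "C3'" = "C3'", "O3'" = "O3'", "C2'" = "C2'", "O2'" = "O2'", "C1'" = "C1'"
)

.PURINE_BASES <- c("A", "G", "DA", "DG")

.PUR_TYPES <- c(
  "N9" = "pur.Nr", "N7" = "pur.Nr", "N1" = "pur.Nr", "N3" = "pur.Nr",
  "C8" = "pur.Cr", "C5" = "pur.Cr", "C6" = "pur.Cr", "C2" = "pur.Cr",
  "C4" = "pur.Cr", "N6" = "pur.Nam", "N2" = "pur.Nam", "O6" = "pur.Oc"
)

.PYR_TYPES <- c(
  "N1" = "pyr.Nr", "N3" = "pyr.Nr",
  "C2" = "pyr.Cr", "C4" = "pyr.Cr", "C5" = "pyr.Cr", "C6" = "pyr.Cr",
  "N4" = "pyr.Nam", "O2" = "pyr.Oc", "O4" = "pyr.Oc",
  "C7" = "pyr.Cme", "C5M" = "pyr.Cme"
)

#' Atom type scheme for nucleic-acid heavy atoms
#'
#' Backbone atoms keep their own types (phosphate oxygens merged); base
#' atoms collapse to purine/pyrimidine ring nitrogen/carbon, amino
#' nitrogen, carbonyl oxygen and the thymine methyl carbon.  DNA residues
#' reuse the RNA classes (T falls in U's pyrimidine class, its methyl
#' carbon gets its own type).  Everything else lands in a catch-all type.
#'
#' @return object of class `atom_type_scheme` with `types` (type names) and
#'   a vectorized mapper `type_of(resname, elety)` returning 1-based ids.
#' @export
atom_type_scheme <- function() {
  types <- c(unique(unname(.BACKBONE_TYPES)), unique(unname(.PUR_TYPES)),
             unique(unname(.PYR_TYPES)), "X")
  type_of <- function(resname, elety) {
    out <- rep(NA_character_, length(elety))
    bb <- elety %in% names(.BACKBONE_TYPES)
    out[bb] <- .BACKBONE_TYPES[elety[bb]]
    pur <- is.na(out) & resname %in% .PURINE_BASES
    hit <- pur & elety %in% names(.PUR_TYPES)
    out[hit] <- .PUR_TYPES[elety[hit]]
    pyr <- is.na(out) & !(resname %in% .PURINE_BASES)
    hit <- pyr & elety %in% names(.PYR_TYPES)
    out[hit] <- .PYR_TYPES[elety[hit]]
    out[is.na(out)] <- "X"
    match(out, types)
  }
  structure(list(types = types, type_of = type_of), class = "atom_type_scheme")
}

#' Assign atom types to every heavy atom of a structure
#'
#' @param s an `na_structure`.
#' @param scheme an [atom_type_scheme()].
#' @return list with `xyz` (coordinate matrix), `type` (integer ids) and
#'   `n_catchall` (atoms that fell to the catch-all type).
#' @export
assign_atom_types <- function(s, scheme = atom_type_scheme()) {
  a <- s$atoms
  if (nrow(a) == 0L)
    return(list(xyz = matrix(0, 0, 3), type = integer(0), n_catchall = 0L))
  ty <- scheme$type_of(a$resname, a$elety)
  catchall <- sum(ty == length(scheme$types))
  if (catchall > 0L)
    warning(sprintf("%d atom(s) mapped to the catch-all type", catchall))
  list(xyz = coords(s), type = ty, n_catchall = catchall)
}

#' Construct a potential table
#'
#' @param energies `ntypes x ntypes x nbins` array, symmetric in the first
#'   two dimensions.
#' @param bin_width bin width in Angstrom.
#' @param r_max maximum interaction distance (energy 0 beyond it).
#' @param types character vector of type names.
#' @param clash_dist,clash_energy pairs closer than `clash_dist` get the
#'   fixed repulsive `clash_energy` instead of a table lookup.
#' @param metadata free-form provenance list.
#' @return object of class `potential_table`.
#' @export
potential_table <- function(energies, bin_width, r_max, types,
                            clash_dist = 2.0, clash_energy = 10.0,
                            metadata = list()) {
  stopifnot(length(dim(energies)) == 3,
            dim(energies)[1] == dim(energies)[2],
            dim(energies)[1] == length(types),
            dim(energies)[3] == round(r_max / bin_width),
            all(is.finite(energies)))
  if (max(abs(energies - aperm(energies, c(2, 1, 3)))) > 1e-12)
    stop("potential table must be symmetric in the type pair")
  structure(list(energies = energies, bin_width = bin_width, r_max = r_max,
                 types = types, clash_dist = clash_dist,
                 clash_energy = clash_energy, metadata = metadata),
            class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("potential_table: %d types, %d bins of %g A (r_max %g A)\n",
              length(x$types), dim(x$energies)[3], x$bin_width, x$r_max))
  invisible(x)
}

#' Score a ligand pose against a receptor with a pair potential
#'
#' Sum of tabulated energies over inter-molecular heavy-atom pairs closer
#' than `r_max`, with a fixed repulsive term for pairs closer than the
#' clash distance.  Lower is better; the value ranks poses and carries no
#' physical affinity units.
#'
#' @param receptor,ligand typed atom lists from [assign_atom_types()], or
#'   `na_structure` objects (typed with the default scheme).
#' @param table a `potential_table`.
#' @param transform optional `rigid_transform` applied to the ligand (with
#'   optional `center`).
#' @param center rotation center for `transform`.
#' @return numeric energy score.
#' @export
score_pose <- function(receptor, ligand, table, transform = NULL,
                       center = c(0, 0, 0)) {
  if (inherits(receptor, "na_structure")) receptor <- assign_atom_types(receptor)
  if (inherits(ligand, "na_structure")) ligand <- assign_atom_types(ligand)
  lxyz <- ligand$xyz
  if (!is.null(transform)) {
    lxyz <- sweep(lxyz, 2, center) %*% t(transform$R)
    lxyz <- sweep(lxyz, 2, center + transform$t, "+")
  }
  cpp_pair_energy(receptor$xyz, receptor$type - 1L, lxyz, ligand$type - 1L,
                  as.numeric(table$energies), length(table$types),
                  dim(table$energies)[3], table$bin_width, table$r_max,
                  table$clash_dist, table$clash_energy)
}

# inter-molecular pair counts of one complex, as a (ntypes, ntypes, nbins)
# array (each pair counted once into [i,j] and [j,i])
.pair_counts <- function(rec, lig, ntypes, nbins, bin_width, r_max) {
  cnt <- array(0, c(ntypes, ntypes, nbins))
  if (nrow(rec$xyz) == 0L || nrow(lig$xyz) == 0L) return(cnt)
  d <- sqrt(pmax(outer(rowSums(rec$xyz^2), rowSums(lig$xyz^2), "+") -
                   2 * rec$xyz %*% t(lig$xyz), 0))
  sel <- which(d < r_max, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(cnt)
  b <- pmin(floor(d[sel] / bin_width) + 1L, nbins)
  ti <- rec$type[sel[, 1]]; tj <- lig$type[sel[, 2]]
  for (k in seq_along(b)) {
    cnt[ti[k], tj[k], b[k]] <- cnt[ti[k], tj[k], b[k]] + 1
    cnt[tj[k], ti[k], b[k]] <- cnt[tj[k], ti[k], b[k]] + 1
  }
  cnt
}

#' Derive a pair potential from training complexes
#'
#' Iteration 0 is an inverse-Boltzmann potential,
#' `E(i,j,b) = -log((N_obs + eps) / (N_ref + eps))`, against a
#' distance-uniform-density reference state: for each type pair the
#' observed total count is spread over bins proportionally to shell volume
#' `(r_hi^3 - r_lo^3)`.  Optional further iterations sharpen discrimination
#' of natives from caller-supplied decoys by a damped count-difference
#' update whenever a decoy outscores its native.
#'
#' @param training list of complexes, each a list with `receptor` and
#'   `ligand` (`na_structure`s).
#' @param scheme an [atom_type_scheme()].
#' @param bin_width,r_max binning parameters (Angstrom).
#' @param eps pseudo-count.
#' @param iterations number of refinement passes after the
#'   inverse-Boltzmann start (0 = none).
#' @param decoys optional list parallel to `training`, each element a list
#'   of decoy ligand `na_structure`s; required when `iterations > 0`.
#' @param learning_rate damping factor for refinement updates.
#' @return a `potential_table`.
#' @export
derive_potential <- function(training, scheme = atom_type_scheme(),
                             bin_width = 0.5, r_max = 10, eps = 0.5,
                             iterations = 0, decoys = NULL,
                             learning_rate = 0.1) {
  if (length(training) == 0L) stop("empty training set")
  ntypes <- length(scheme$types)
  nbins <- round(r_max / bin_width)
  typed <- lapply(training, function(cx)
    list(rec = suppressWarnings(assign_atom_types(cx$receptor, scheme)),
         lig = suppressWarnings(assign_atom_types(cx$ligand, scheme))))
  nobs <- array(0, c(ntypes, ntypes, nbins))
  for (tc in typed)
    nobs <- nobs + .pair_counts(tc$rec, tc$lig, ntypes, nbins, bin_width, r_max)

  # distance-uniform-density reference: spread each pair's total over bins
  # by shell volume
  edges <- seq(0, r_max, by = bin_width)
  shell <- diff(edges^3)
  shell <- shell / sum(shell)
  tot <- apply(nobs, c(1, 2), sum)
  nref <- outer(tot, shell)
  energies <- -log((nobs + eps) / (nref + eps))

  table <- potential_table(energies, bin_width, r_max, scheme$types,
                           metadata = list(derivation = "inverse-Boltzmann",
                                           eps = eps,
                                           n_complexes = length(training)))
  if (iterations > 0) {
    if (is.null(decoys)) stop("refinement iterations require decoys")
    for (it in seq_len(iterations)) {
      upd <- array(0, dim(energies))
      for (ci in seq_along(typed)) {
        tc <- typed[[ci]]
        cnat <- .pair_counts(tc$rec, tc$lig, ntypes, nbins, bin_width, r_max)
        enat <- score_pose(tc$rec, tc$lig, table)
        for (dec in decoys[[ci]]) {
          td <- suppressWarnings(assign_atom_types(dec, scheme))
          if (score_pose(tc$rec, td, table) <= enat) {
            cdec <- .pair_counts(tc$rec, td, ntypes, nbins, bin_width, r_max)
            upd <- upd + (cnat - cdec)
          }
        }
      }
      mx <- max(abs(upd))
      if (mx > 0) {
        energies <- energies - learning_rate * upd / mx
        energies <- (energies + aperm(energies, c(2, 1, 3))) / 2
        table <- potential_table(energies, bin_width, r_max, scheme$types,
                                 metadata = c(table$metadata,
                                              list(refined_iterations = it)))
      }
    }
  }
  table
}

#' Write a potential table as plain text
#'
#' Format: header lines (`types`, `bins`), then one
#' `type_i type_j bin_lo bin_hi energy` row per upper-triangle pair and
#' bin.  Energies are printed with 17 significant digits so the round-trip
#' is bit-exact.
#'
#' @param table a `potential_table`.
#' @param file output path (or `NULL` to return lines).
#' @return invisibly, the text lines.
#' @export
write_potential <- function(table, file = NULL) {
  n <- length(table$types)
  nb <- dim(table$energies)[3]
  lines <- c("# nadock potential table v1",
             paste("types", paste(table$types, collapse = " ")),
             sprintf("bins %d %.17g %.17g", nb, table$bin_width, table$r_max),
             sprintf("clash %.17g %.17g", table$clash_dist, table$clash_energy))
  for (i in seq_len(n)) for (j in i:n) for (b in seq_len(nb)) {
    e <- table$energies[i, j, b]
    if (e != 0)
      lines <- c(lines, sprintf("%s %s %.17g %.17g %.17g", table$types[i],
                                table$types[j], (b - 1) * table$bin_width,
                                b * table$bin_width, e))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a potential table written by [write_potential()]
#' @param file path or character vector of lines.
#' @return a `potential_table`.
#' @export
read_potential <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[!grepl("^#", lines)]
  types <- strsplit(sub("^types ", "", lines[grepl("^types ", lines)]), " ")[[1]]
  bins <- as.numeric(strsplit(sub("^bins ", "", lines[grepl("^bins ", lines)]), " ")[[1]])
  clash <- as.numeric(strsplit(sub("^clash ", "", lines[grepl("^clash ", lines)]), " ")[[1]])
  nb <- as.integer(bins[1]); bw <- bins[2]; rmax <- bins[3]
  energies <- array(0, c(length(types), length(types), nb))
  rows <- lines[!grepl("^(types|bins|clash) ", lines)]
  rows <- rows[nzchar(rows)]
  for (ln in rows) {
    p <- strsplit(ln, " +")[[1]]
    i <- match(p[1], types); j <- match(p[2], types)
    b <- as.integer(round(as.numeric(p[3]) / bw)) + 1L
    e <- as.numeric(p[5])
    energies[i, j, b] <- e
    energies[j, i, b] <- e
  }
  potential_table(energies, bw, rmax, types, clash[1], clash[2],
                  metadata = list(derivation = "read from file"))
}

#' Default pair potential derived from synthetic duplexes
#'
#' A small table derived (inverse-Boltzmann) from a fixed set of ideal
#' A-form duplex fixtures, so the docking pipeline runs out of the box.  It
#' is cached for the session and fully deterministic.  It is a stand-in
#' trained on synthetic geometry, not a published parameter set.
#'
#' @return a `potential_table`.
#' @export
default_potential <- function() {
  if (!is.null(.nadock_env$default_potential)) return(.nadock_env$default_potential)
  seqs <- c("GGGGCCCC", "AUCGAUCG", "GCGCGCGC", "AAUUGGCC", "CAGUCAGUCA",
            "GGAUACCGUU", "ACGUACG", "UUUAAACG")
  training <- lapply(seqs, function(sq) {
    dup <- build_aform_duplex(sq)
    split_chains(dup)
  })
  tab <- derive_potential(training)
  tab$metadata$source <- "synthetic A-form duplex fixtures"
  .nadock_env$default_potential <- tab
  tab
}
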