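# Binding-site and distance restraints.
#
# Grammar (one restraint per line):
#   site <R|L> chain:seqid[,chain:seqid...]   residue(s) required at the
#                                             interface of that partner
#   dist chain:seqid chain:seqid <Angstrom>   receptor residue, ligand
#                                             residue, maximum distance
# "At the interface" means: minimum heavy-atom distance to the partner
# molecule <= the interface cutoff (default 10 A).  Distance restraints use
# the minimum inter-heavy-atom distance between the two residues, which is
# robust to missing named atoms; inter-RNA base-pair predictions can be
# encoded as 6-8 A constraints between the paired residues.

#' Construct a restraint set
#'
#' @param site_residues data.frame with columns `partner` ("R" or "L"),
#'   `chain`, `resno`.
#' @param distance_pairs data.frame with columns `rec_chain`, `rec_resno`,
#'   `lig_chain`, `lig_resno`, `max_dist`.
#' @param mode `"filter"` (violating modes removed) or `"penalty"` (modes
#'   reordered by energy + lambda * violations).
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(site_residues = NULL, distance_pairs = NULL,
                          mode = c("filter", "penalty")) {
  mode <- match.arg(mode)
  if (is.null(site_residues))
    site_residues <- data.frame(partner = character(0), chain = character(0),
                                resno = integer(0), stringsAsFactors = FALSE)
  if (is.null(distance_pairs))
    distance_pairs <- data.frame(rec_chain = character(0), rec_resno = integer(0),
                                 lig_chain = character(0), lig_resno = integer(0),
                                 max_dist = numeric(0), stringsAsFactors = FALSE)
  if (nrow(distance_pairs) > 0 && any(distance_pairs$max_dist <= 0))
    stop("restraint distances must be positive")
  structure(list(site_residues = site_residues, distance_pairs = distance_pairs,
                 mode = mode), class = "restraint_set")
}

#' Number of restraints in a set
#' @param r a `restraint_set`.
#' @return integer count.
#' @export
n_restraints <- function(r) nrow(r$site_residues) + nrow(r$distance_pairs)

.parse_res_key <- function(tok) {
  p <- strsplit(tok, ":", fixed = TRUE)[[1]]
  if (length(p) != 2 || !grepl("^-?[0-9]+$", p[2]))
    stop("malformed residue key '", tok, "' (expected chain:seqid)")
  list(chain = p[1], resno = as.integer(p[2]))
}

#' Parse a restraint specification
#'
#' @param text restraint lines (single string with newlines, or a character
#'   vector).  Empty text gives an empty set, satisfied by every pose.
#' @param mode filtering mode, see [restraint_set()].
#' @param receptor,ligand optional `na_structure`s; when given, every
#'   residue key is checked to resolve and unresolvable keys raise an
#'   error naming them.
#' @return a `restraint_set`.
#' @export
parse_restraints <- function(text, mode = c("filter", "penalty"),
                             receptor = NULL, ligand = NULL) {
  mode <- match.arg(mode)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- trimws(text)
  text <- text[nzchar(text) & !grepl("^#", text)]
  sites <- list(); dists <- list()
  for (ln in text) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "site") {
      if (length(tok) < 3 || !(tok[2] %in% c("R", "L")))
        stop("malformed site restraint: '", ln, "'")
      for (key in strsplit(paste(tok[-(1:2)], collapse = ","), ",")[[1]]) {
        k <- .parse_res_key(key)
        sites[[length(sites) + 1L]] <- data.frame(
          partner = tok[2], chain = k$chain, resno = k$resno,
          stringsAsFactors = FALSE)
      }
    } else if (tok[1] == "dist") {
      if (length(tok) != 4) stop("malformed distance restraint: '", ln, "'")
      d <- suppressWarnings(as.numeric(tok[4]))
      if (!is.finite(d) || d <= 0)
        stop("malformed distance '", tok[4], "' in: '", ln, "'")
      kr <- .parse_res_key(tok[2]); kl <- .parse_res_key(tok[3])
      dists[[length(dists) + 1L]] <- data.frame(
        rec_chain = kr$chain, rec_resno = kr$resno,
        lig_chain = kl$chain, lig_resno = kl$resno, max_dist = d,
        stringsAsFactors = FALSE)
    } else stop("unknown restraint keyword '", tok[1], "'")
  }
  rs <- restraint_set(if (length(sites)) do.call(rbind, sites),
                      if (length(dists)) do.call(rbind, dists), mode)
  if (!is.null(receptor) && !is.null(ligand))
    resolve_restraints(rs, receptor, ligand)
  rs
}

#' Check that all restraint residue keys resolve against the structures
#' @param r a `restraint_set`.
#' @param receptor,ligand `na_structure`s.
#' @return invisibly `TRUE`; errors naming any unresolvable key.
#' @export
resolve_restraints <- function(r, receptor, ligand) {
  have <- function(s, chain, resno)
    any(s$atoms$chain == chain & s$atoms$resno == resno)
  bad <- character(0)
  if (nrow(r$site_residues) > 0)
    for (i in seq_len(nrow(r$site_residues))) {
      row <- r$site_residues[i, ]
      s <- if (row$partner == "R") receptor else ligand
      if (!have(s, row$chain, row$resno))
        bad <- c(bad, sprintf("site %s %s:%d", row$partner, row$chain, row$resno))
    }
  if (nrow(r$distance_pairs) > 0)
    for (i in seq_len(nrow(r$distance_pairs))) {
      row <- r$distance_pairs[i, ]
      if (!have(receptor, row$rec_chain, row$rec_resno))
        bad <- c(bad, sprintf("dist receptor %s:%d", row$rec_chain, row$rec_resno))
      if (!have(ligand, row$lig_chain, row$lig_resno))
        bad <- c(bad, sprintf("dist ligand %s:%d", row$lig_chain, row$lig_resno))
    }
  if (length(bad) > 0)
    stop("unresolvable restraint residue key(s): ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

# minimum distance between two coordinate matrices
.min_cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Evaluate restraints against a ligand pose
#'
#' A site residue is satisfied when its minimum heavy-atom distance to the
#' partner molecule is at most `interface_cutoff`; a distance pair when
#' the minimum heavy-atom distance between the two residues is at most its
#' maximum distance.
#'
#' @param receptor an `na_structure` (fixed partner).
#' @param ligand_pose an `na_structure` (posed ligand).
#' @param r a `restraint_set`.
#' @param interface_cutoff interface distance cutoff, Angstrom.
#' @return list with `satisfied` (logical) and `violation_count`.
#' @export
evaluate_restraints <- function(receptor, ligand_pose, r, interface_cutoff = 10) {
  viol <- 0L
  rxyz <- coords(receptor); lxyz <- coords(ligand_pose)
  rkey_r <- paste(receptor$atoms$chain, receptor$atoms$resno)
  rkey_l <- paste(ligand_pose$atoms$chain, ligand_pose$atoms$resno)
  if (nrow(r$site_residues) > 0)
    for (i in seq_len(nrow(r$site_residues))) {
      row <- r$site_residues[i, ]
      if (row$partner == "R") {
        res <- rxyz[rkey_r == paste(row$chain, row$resno), , drop = FALSE]
        d <- .min_cross_dist(res, lxyz)
      } else {
        res <- lxyz[rkey_l == paste(row$chain, row$resno), , drop = FALSE]
        d <- .min_cross_dist(res, rxyz)
      }
      if (!(d <= interface_cutoff)) viol <- viol + 1L
    }
  if (nrow(r$distance_pairs) > 0)
    for (i in seq_len(nrow(r$distance_pairs))) {
      row <- r$distance_pairs[i, ]
      a <- rxyz[rkey_r == paste(row$rec_chain, row$rec_resno), , drop = FALSE]
      b <- lxyz[rkey_l == paste(row$lig_chain, row$lig_resno), , drop = FALSE]
      if (!(.min_cross_dist(a, b) <= row$max_dist)) viol <- viol + 1L
    }
  list(satisfied = viol == 0L, violation_count = viol)
}

#' Filter or reorder ranked binding modes by restraints
#'
#' In `filter` mode violating modes are removed (keeping rank order); if
#' every mode violates, the full list is returned reordered by
#' (violation count, energy) with a warning.  In `penalty` mode the list
#' is reordered by `energy + lambda * violation_count`.
#'
#' @param modes a `binding_modes` object from [dock()]'s sampling stage.
#' @param r a `restraint_set`.
#' @param interface_cutoff interface cutoff for site restraints, Angstrom.
#' @param lambda penalty weight per violation in penalty mode.
#' @return the filtered/reordered `binding_modes` object, with a
#'   `violations` column added.
#' @export
apply_restraint_filter <- function(modes, r, interface_cutoff = 10, lambda = 100) {
  if (n_restraints(r) == 0L) return(modes)
  ctx <- attr(modes, "context")
  df <- modes$table
  viol <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    pose <- realize_mode(modes, i)
    viol[i] <- evaluate_restraints(ctx$receptor, pose, r, interface_cutoff)$violation_count
  }
  df$violations <- viol
  if (r$mode == "penalty") {
    ord <- order(df$energy + lambda * viol, df$rotation_index)
  } else if (all(viol > 0L)) {
    warning("all binding modes violate the restraints; falling back to ",
            "(violations, energy) ordering")
    ord <- order(viol, df$energy, df$rotation_index)
  } else {
    ord <- which(viol == 0L)
  }
  out <- modes
  out$table <- df[ord, , drop = FALSE]
  rownames(out$table) <- NULL
  out$c4 <- modes$c4[ord, , drop = FALSE]
  out
}
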