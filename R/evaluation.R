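# Evaluation of predicted complexes against a native complex.
#
# The interface is the set of residues with any heavy atom within the
# interface cutoff (default 10 A) of the partner molecule.  Model quality
# is the interface RMSD (IRMSD): C4' atoms of the native interface
# residues of both partners are superposed jointly (least-squares, proper
# rotation) and the residual RMSD is reported.  A model is a hit when
# IRMSD < 5.0 A; the success rate over a benchmark is the fraction of
# cases with at least one hit within the top N predictions.

#' Interface residues of a bound complex
#'
#' @param native_receptor,native_ligand `na_structure`s of the bound
#'   partners.
#' @param cutoff interface distance cutoff, Angstrom (default 10).
#' @return list with `receptor` and `ligand`: character vectors of residue
#'   keys (`chain|resno|ins`).  Warns when the interface is empty.
#' @export
interface_residues <- function(native_receptor, native_ligand, cutoff = 10) {
  ra <- native_receptor$atoms; la <- native_ligand$atoms
  if (nrow(ra) == 0L || nrow(la) == 0L) stop("empty structure")
  rxyz <- coords(native_receptor); lxyz <- coords(native_ligand)
  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") - 2 * rxyz %*% t(lxyz)
  close_pair <- d2 <= cutoff^2
  rkeys <- .res_key(ra); lkeys <- .res_key(la)
  rsel <- unique(rkeys[rowSums(close_pair) > 0])
  lsel <- unique(lkeys[colSums(close_pair) > 0])
  rsel <- rsel[order(match(rsel, unique(rkeys)))]
  lsel <- lsel[order(match(lsel, unique(lkeys)))]
  if (length(rsel) == 0L && length(lsel) == 0L)
    warning("empty interface at cutoff ", cutoff, " A")
  list(receptor = rsel, ligand = lsel)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `target` with a proper
#' rotation (no reflection).
#'
#' @param mobile,target coordinate matrices with equal row counts (>= 3
#'   non-collinear points).
#' @return list with `transform` (a `rigid_transform` mapping mobile onto
#'   target: `x -> R (x - center) + center + t` with `center = 0`) and
#'   `rmsd` (residual RMSD, Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("point count mismatch")
  if (nrow(mobile) < 3) stop("need at least 3 points to superpose")
  mc <- colMeans(mobile); tc <- colMeans(target)
  P <- sweep(mobile, 2, mc); Q <- sweep(target, 2, tc)
  dP <- svd(P)$d                 # planar sets are fine; collinear are not
  if (dP[2] < 1e-9 * max(dP[1], 1))
    stop("degenerate (collinear) geometry")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  tr <- rigid_transform(R, tc - as.numeric(R %*% mc))
  list(transform = tr, rmsd = rmsd)
}

# C4' coordinates of the residues named by `keys`, matched by residue key;
# errors if any key lacks a C4' atom in `s`
.c4_of_residues <- function(s, keys) {
  sel <- select_atoms(s, "C4'")
  m <- match(keys, sel$keys)
  if (any(is.na(m)))
    stop("residue(s) without C4' atom: ", paste(keys[is.na(m)], collapse = ", "))
  sel$coords[m, , drop = FALSE]
}

#' Interface RMSD of a predicted complex against the native complex
#'
#' Interface residues are taken from the native complex; the predicted
#' C4' atoms of those residues (both partners jointly, matched by chain
#' and residue number) are superposed onto their native counterparts and
#' the residual RMSD is the IRMSD.  Setting `superpose_set = "all"` uses
#' every C4' atom for the superposition instead while still measuring the
#' residual over the interface atoms.
#'
#' @param predicted,native lists with `receptor` and `ligand`
#'   (`na_structure`s).
#' @param interface_cutoff interface cutoff, Angstrom.
#' @param superpose_set `"interface"` (default) or `"all"`.
#' @return IRMSD in Angstrom.
#' @export
irmsd <- function(predicted, native, interface_cutoff = 10,
                  superpose_set = c("interface", "all")) {
  superpose_set <- match.arg(superpose_set)
  iface <- interface_residues(native$receptor, native$ligand, interface_cutoff)
  nat_i <- rbind(.c4_of_residues(native$receptor, iface$receptor),
                 .c4_of_residues(native$ligand, iface$ligand))
  # match in the combined predicted complex so receptor/ligand swaps and
  # renamed roles do not matter as long as chain ids and numbering agree
  pred_all <- .bind_structures(predicted$receptor, predicted$ligand)
  pred_i <- .c4_of_residues(pred_all, c(iface$receptor, iface$ligand))
  if (nrow(nat_i) < 3) stop("fewer than 3 interface C4' atoms")
  if (superpose_set == "interface") {
    sp <- superpose(pred_i, nat_i)
    return(sp$rmsd)
  }
  nat_all <- .bind_structures(native$receptor, native$ligand)
  all_keys <- select_atoms(nat_all, "C4'")$keys
  all_nat <- .c4_of_residues(nat_all, all_keys)
  all_pred <- .c4_of_residues(pred_all, all_keys)
  sp <- superpose(all_pred, all_nat)
  moved <- sweep(pred_i %*% t(sp$transform$R), 2, sp$transform$t, "+")
  sqrt(mean(rowSums((moved - nat_i)^2)))
}

#' Hit classification of an IRMSD value
#' @param irmsd_value IRMSD in Angstrom.
#' @param threshold hit threshold (default 5.0; a hit is strictly below).
#' @return logical.
#' @export
is_hit <- function(irmsd_value, threshold = 5.0) irmsd_value < threshold

#' Success rate over benchmark cases
#'
#' Fraction of cases whose first hit rank is within the top `top_n`.
#'
#' @param first_hit_ranks integer vector of 1-based first-hit ranks, `NA`
#'   for cases with no hit.
#' @param top_n number of top predictions considered.
#' @return fraction in \[0, 1\].
#' @export
success_rate <- function(first_hit_ranks, top_n) {
  if (length(first_hit_ranks) == 0L) stop("empty case list")
  mean(!is.na(first_hit_ranks) & first_hit_ranks <= top_n)
}

#' Evaluate a set of ranked models against a native complex
#'
#' @param models list of predicted complexes (each a list with `receptor`
#'   and `ligand`), in rank order.
#' @param native the native complex (list with `receptor`, `ligand`).
#' @param interface_cutoff interface cutoff, Angstrom.
#' @param hit_threshold IRMSD hit threshold, Angstrom.
#' @return list with `per_model_irmsd`, `first_hit_rank` (or `NA`),
#'   `hit_threshold`, `interface_cutoff`.
#' @export
evaluate_models <- function(models, native, interface_cutoff = 10,
                            hit_threshold = 5.0) {
  vals <- vapply(models, irmsd, numeric(1), native = native,
                 interface_cutoff = interface_cutoff)
  hits <- which(is_hit(vals, hit_threshold))
  list(per_model_irmsd = vals,
       first_hit_rank = if (length(hits)) hits[1] else NA_integer_,
       hit_threshold = hit_threshold, interface_cutoff = interface_cutoff)
}
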