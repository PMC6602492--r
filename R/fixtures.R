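# Synthetic data: ideal A-form duplexes, perturbed decoy poses and toy
# grids.  These are coarse but geometrically faithful stand-ins for small
# RNA-RNA (or DNA) complexes so every docking stage is testable without
# external structures.
#
# Helix constants default to textbook A-form values: 32.7 degrees twist and
# 2.81 A rise per base pair, C4' ring radius 9.4 A.  Each residue carries a
# coarse heavy-atom set (P and phosphate oxygens absent on the 5' terminus):
# the full sugar-phosphate backbone plus a reduced base skeleton (the
# glycosidic nitrogen N9/N1 and ring atoms N3, C6, C2, C4), placed on
# per-atom cylinders so intra-chain and cross-strand geometry are helically
# regular.  The placements are tuned so that, at the default 1.2 A grid
# spacing and 1.8 A occupancy radius, the duplex (and even a single strand)
# has buried "core" grid cells, and the closest cross-strand heavy-atom
# contact (about 2.3 A) stays above the scoring clash guard -- both
# properties of real nucleic-acid complexes that a sparser atom set cannot
# reproduce on a 1.2 A lattice.

.COMPLEMENT_RNA <- c(A = "U", U = "A", G = "C", C = "G")
.COMPLEMENT_DNA <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")

# per-atom cylindrical placement: radius (A), phase (deg), axial shift (A)
.COARSE_ATOMS <- list(
  "P"    = list(r = 9.7,  phase = -16.3, dz = -1.40, element = "P"),
  "OP1"  = list(r = 10.9, phase = -23.0, dz = -2.10, element = "O"),
  "OP2"  = list(r = 10.5, phase = -8.0,  dz = -0.60, element = "O"),
  "O5'"  = list(r = 9.3,  phase = -12.0, dz = -0.70, element = "O"),
  "C5'"  = list(r = 8.9,  phase = -6.0,  dz = 0.10,  element = "C"),
  "C4'"  = list(r = 9.4,  phase = 0.0,   dz = 0.00,  element = "C"),
  "O4'"  = list(r = 7.9,  phase = 4.0,   dz = -0.70, element = "O"),
  "C3'"  = list(r = 9.0,  phase = 7.0,   dz = 1.30,  element = "C"),
  "O3'"  = list(r = 9.4,  phase = 12.0,  dz = 2.20,  element = "O"),
  "C2'"  = list(r = 8.2,  phase = 14.0,  dz = 0.90,  element = "C"),
  "O2'"  = list(r = 8.4,  phase = 21.0,  dz = 1.40,  element = "O"),
  "C1'"  = list(r = 6.9,  phase = 13.0,  dz = -0.50, element = "C"),
  "Ngly" = list(r = 5.0,  phase = 21.0,  dz = -0.70, element = "N"),
  "N3"   = list(r = 5.8,  phase = 34.0,  dz = -0.30, element = "N"),
  "C6"   = list(r = 4.2,  phase = 38.0,  dz = -0.60, element = "C"),
  "C2"   = list(r = 3.1,  phase = 52.0,  dz = -0.20, element = "C"),
  "C4"   = list(r = 2.2,  phase = 45.0,  dz = -0.20, element = "C"),
  "C5"   = list(r = 3.6,  phase = 33.0,  dz = -0.45, element = "C")
)

# base atoms present only on one base class (Watson-Crick pairs are always
# purine + pyrimidine, which keeps these from clashing across the helix)
.PURINE_EXTRA <- list(
  "N7" = list(r = 4.0, phase = 52.0, dz = -0.30, element = "N"),
  "C8" = list(r = 5.0, phase = 47.0, dz = -0.55, element = "C")
)
.PYRIMIDINE_EXTRA <- list(
  "O2" = list(r = 2.6, phase = 58.0, dz = -0.20, element = "O")
)

# 5'-terminal residues lack the phosphate group entirely
.PHOSPHATE_ATOMS <- c("P", "OP1", "OP2")

.is_purine <- function(resname) resname %in% c("A", "G", "DA", "DG")

#' Build an ideal A-form duplex
#'
#' Chain A carries the given 5'->3' sequence on an ideal helix; chain B is
#' its reverse complement, antiparallel, phase-shifted around the helix
#' axis so that paired residues face each other.  Deterministic: identical
#' specs give bit-identical coordinates.
#'
#' @param sequence 5'->3' string over ACGU (RNA) or ACGT (DNA when
#'   `dna = TRUE`), length >= 2.
#' @param rise axial rise per base pair, Angstrom.
#' @param twist helical twist per base pair, degrees.
#' @param radius C4' radius, Angstrom.
#' @param pair_phase angular offset of the partner strand, degrees.
#' @param dna treat the sequence as DNA (T allowed, residues DA/DC/DG/DT).
#' @param label structure label.
#' @return an `na_structure` with chains A and B.
#' @export
build_aform_duplex <- function(sequence, rise = 2.81, twist = 32.7,
                               radius = 9.4, pair_phase = 151,
                               dna = FALSE, label = sequence) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  n <- length(bases)
  if (n < 2) stop("duplex sequence must have length >= 2")
  alphabet <- if (dna) c("A", "C", "G", "T") else c("A", "C", "G", "U")
  if (!all(bases %in% alphabet))
    stop("invalid base(s) in sequence: ",
         paste(unique(setdiff(bases, alphabet)), collapse = ", "))
  resA <- if (dna) paste0("D", bases) else bases
  comp <- if (dna) .COMPLEMENT_DNA else .COMPLEMENT_RNA
  resB <- rev(unname(comp[resA]))              # 5'->3' of chain B

  rscale <- radius / 9.4                       # scale all radii with the spec
  place <- function(theta_deg, z, sign_phase, sign_dz, resname) {
    # returns one residue's coarse atoms at helical angle theta (degrees)
    atoms <- c(.COARSE_ATOMS,
               if (.is_purine(resname)) .PURINE_EXTRA else .PYRIMIDINE_EXTRA)
    out <- lapply(names(atoms), function(nm) {
      a <- atoms[[nm]]
      th <- (theta_deg + sign_phase * a$phase) * pi / 180
      c(a$r * rscale * cos(th), a$r * rscale * sin(th), z + sign_dz * a$dz)
    })
    names(out) <- names(atoms)
    out
  }

  rows <- list()
  add_atom <- function(chain, resno, resname, elety, element, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, ins = "", resname = resname,
      elety = elety, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], serial = length(rows) + 1L,
      stringsAsFactors = FALSE)
  }
  elem_of <- c(lapply(.COARSE_ATOMS, `[[`, "element"),
               lapply(.PURINE_EXTRA, `[[`, "element"),
               lapply(.PYRIMIDINE_EXTRA, `[[`, "element"))
  emit_residue <- function(chain, resno, resname, atoms, with_p) {
    for (nm in names(atoms)) {
      if (nm %in% .PHOSPHATE_ATOMS && !with_p) next
      if (nm == "O2'" && startsWith(resname, "D")) next   # deoxyribose
      elety <- if (nm == "Ngly") (if (.is_purine(resname)) "N9" else "N1") else nm
      add_atom(chain, resno, resname, elety, elem_of[[nm]], atoms[[nm]])
    }
  }

  for (i in seq_len(n)) {                       # chain A, 5'->3'
    theta <- (i - 1) * twist
    z <- (i - 1) * rise
    emit_residue("A", i, resA[i], place(theta, z, +1, +1, resA[i]), with_p = i > 1)
  }
  for (j in seq_len(n)) {                       # chain B, 5'->3', antiparallel
    i_pair <- n - j + 1                          # pairs chain A residue i_pair
    theta <- (i_pair - 1) * twist + pair_phase
    z <- (i_pair - 1) * rise
    emit_residue("B", j, resB[j], place(theta, z, -1, -1, resB[j]), with_p = j > 1)
  }
  .new_structure(do.call(rbind, rows), label = label)
}

#' Split a structure into receptor and ligand halves by chain
#'
#' @param s an `na_structure` with at least two chains.
#' @param receptor_chains chains forming the receptor (default: first
#'   chain).
#' @return list with `receptor` and `ligand` (`na_structure`s).
#' @export
split_chains <- function(s, receptor_chains = NULL) {
  ch <- unique(s$atoms$chain)
  if (length(ch) < 2) stop("need at least two chains to split")
  if (is.null(receptor_chains)) receptor_chains <- ch[1]
  rec <- s$atoms[s$atoms$chain %in% receptor_chains, , drop = FALSE]
  lig <- s$atoms[!(s$atoms$chain %in% receptor_chains), , drop = FALSE]
  list(receptor = .new_structure(rec, paste0(s$label, ":receptor")),
       ligand = .new_structure(lig, paste0(s$label, ":ligand")))
}

# random unit vector from the session RNG
.runif_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# rotation by `ang` radians about unit axis (Rodrigues)
.axis_angle_matrix <- function(axis, ang) {
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(ang) * vx + (1 - cos(ang)) * (vx %*% vx)
}

#' Generate perturbed decoy poses of a ligand
#'
#' Each decoy is the ligand under a random rigid transform about its
#' centroid: rotation by exactly `rot_deg` degrees about a random axis,
#' then translation by exactly `trans` Angstrom in a random direction.
#' Each decoy is tagged with its exact C4' RMSD from the native ligand.
#'
#' @param native list with `receptor` and `ligand` (`na_structure`s), e.g.
#'   from [split_chains()].
#' @param n number of decoys.
#' @param trans translation magnitude, Angstrom.
#' @param rot_deg rotation magnitude, degrees.
#' @param seed integer seed; identical seeds give identical decoy sets.
#' @return list of lists, each with `pose` (`na_structure`), `rmsd`
#'   (exact ligand C4' RMSD from native) and `transform`.
#' @export
make_decoys <- function(native, n, trans = 5, rot_deg = 0, seed = 1) {
  stopifnot(n >= 1)
  lig <- native$ligand
  ctr <- colMeans(coords(lig))
  c4 <- select_atoms(lig, "C4'")$coords
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    R <- if (rot_deg > 0) .axis_angle_matrix(.runif_unit(), rot_deg * pi / 180) else diag(3)
    t <- if (trans > 0) .runif_unit() * trans else c(0, 0, 0)
    tr <- rigid_transform(R, t)
    # zero-magnitude decoys are bit-identical to the native ligand
    pose <- if (rot_deg > 0 || trans > 0) apply_transform(lig, tr, center = ctr) else lig
    pc4 <- select_atoms(pose, "C4'")$coords
    list(pose = pose, rmsd = sqrt(mean(rowSums((pc4 - c4)^2))), transform = tr)
  })
}

#' Analytically known toy grids for FFT oracle tests
#'
#' * `point`: a single occupied cell at the box center (ligand role).
#' * `slab`: an axis-aligned slab of occupied cells.
#' * `pocket_plug`: a receptor block with a rectangular cavity plus a
#'   ligand plug that fits it exactly; the best correlation offset is the
#'   one stored in the `best_offset` attribute.
#'
#' @param pattern one of `"point"`, `"slab"`, `"pocket_plug"`.
#' @param dims integer dimensions of the grid (default `c(12, 12, 12)`).
#' @param spacing lattice spacing.
#' @return a `grid_map` (for `pocket_plug`, a list of `receptor` and
#'   `ligand` grid maps with attribute `best_offset`).
#' @export
toy_grid <- function(pattern = c("point", "slab", "pocket_plug"),
                     dims = c(12, 12, 12), spacing = 1.2) {
  pattern <- match.arg(pattern)
  dims <- as.integer(dims)
  if (pattern == "point") {
    v <- array(0, dims)
    v[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- 1
    return(grid_map(v, c(0, 0, 0), spacing, "ligand"))
  }
  if (pattern == "slab") {
    v <- array(0, dims)
    v[, , seq_len(max(1L, dims[3] %/% 3))] <- 1
    return(grid_map(v, c(0, 0, 0), spacing, "ligand"))
  }
  # pocket_plug: receptor slab (core penalty) for z in [1, zs] with a
  # cavity whose empty cells carry the smeared surface reward +1; a 3x3x2
  # plug of ones fits the cavity exactly, so the unique correlation
  # maximum (score 18) is at the cavity corner offset
  v <- array(0, dims)
  zs <- max(3L, dims[3] %/% 2)
  v[, , 1:zs] <- -15
  cx <- 4:(4 + 2); cy <- 4:(4 + 2); cz <- (zs - 1):zs
  v[cx, cy, cz] <- 1                     # cavity: rewarded open space
  plug <- array(1, c(3L, 3L, 2L))
  rec <- grid_map(v, c(0, 0, 0), spacing, "receptor")
  lig <- grid_map(plug, c(0, 0, 0), spacing, "ligand")
  out <- list(receptor = rec, ligand = lig)
  # plug cell [1,1,1] must land on cavity cell (cx[1], cy[1], cz[1]):
  # offset t satisfies L[g - t]: t = cavity_corner - 1 (0-based lag)
  attr(out, "best_offset") <- c(cx[1] - 1L, cy[1] - 1L, cz[1] - 1L)
  out
}
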