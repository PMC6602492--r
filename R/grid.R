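# Shape-complementarity grids and the FFT translation scan.
#
# Both molecules are digitized on a regular lattice (default spacing 1.2 A).
# A cell is occupied when any heavy-atom center lies within r_occ of the
# cell center.  Receptor grids distinguish buried "core" cells (all 26
# neighbors occupied), which carry a negative penalty so that poses pushing
# the ligand into the receptor interior are rejected, from surface cells,
# which are smeared with a short-range decaying kernel so that near-contact
# poses score smoothly.  Ligand grids are binary.

#' Construct a grid map object
#' @param values 3D numeric array (x fastest).
#' @param origin coordinates of the center of cell \[1,1,1\] (Angstrom).
#' @param spacing lattice spacing (Angstrom).
#' @param role `"receptor"` or `"ligand"`.
#' @return object of class `grid_map`.
#' @export
grid_map <- function(values, origin, spacing, role = c("receptor", "ligand")) {
  role <- match.arg(role)
  stopifnot(length(dim(values)) == 3, spacing > 0, length(origin) == 3)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, dims = dim(values), role = role),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("grid_map (%s): %d x %d x %d cells, spacing %g A, origin (%.2f, %.2f, %.2f)\n",
              x$role, x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# occupancy array: TRUE where a cell center is within r_occ of any atom
.occupancy <- function(xyz, origin, spacing, dims, r_occ) {
  occ <- array(FALSE, dims)
  reach <- ceiling(r_occ / spacing)
  off <- as.matrix(expand.grid(x = -reach:reach, y = -reach:reach, z = -reach:reach))
  for (i in seq_len(nrow(xyz))) {
    ctr <- round((xyz[i, ] - origin) / spacing)
    cand <- sweep(off, 2, ctr, "+")
    inside <- cand[, 1] >= 0 & cand[, 1] < dims[1] &
              cand[, 2] >= 0 & cand[, 2] < dims[2] &
              cand[, 3] >= 0 & cand[, 3] < dims[3]
    cand <- cand[inside, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cc <- sweep(cand * spacing, 2, origin, "+")
    d2 <- rowSums((cc - matrix(xyz[i, ], nrow(cc), 3, byrow = TRUE))^2)
    hit <- cand[d2 <= r_occ^2, , drop = FALSE] + 1L
    occ[hit] <- TRUE
  }
  occ
}

# shift a 3D logical/numeric array by an integer offset, zero/FALSE filled
.shift3 <- function(a, s, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (s[k] >= 0) { dst[[k]] <- seq(1 + s[k], d[k]); src[[k]] <- seq(1, d[k] - s[k]) }
    else           { dst[[k]] <- seq(1, d[k] + s[k]); src[[k]] <- seq(1 - s[k], d[k]) }
    if (length(dst[[k]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Digitize a structure onto a 3D grid
#'
#' @param s an `na_structure`.
#' @param spacing lattice spacing in Angstrom (default 1.2, the docking
#'   default).
#' @param padding extra margin added around the bounding box, Angstrom.
#' @param role `"receptor"` (soft surface + core penalty) or `"ligand"`
#'   (binary occupancy).
#' @param r_occ occupancy radius in Angstrom.
#' @param core_penalty value assigned to buried receptor cells (negative).
#' @param kernel `"gaussian"` for `exp(-(r/r0)^2)` with `r0` = one spacing,
#'   or `"paper_literal"` for the printed `exp(-1/r^2)` form (r in grid
#'   units, capped at the cutoff).
#' @param kernel_cutoff kernel reach in multiples of the spacing.
#' @param max_cells error out above this many cells (suggests a larger
#'   spacing).
#' @param align_to optional reference point: the grid origin is placed on
#'   the lattice through this point, so that two grids digitized with the
#'   same `align_to` and spacing share one lattice (as the docking scan
#'   does internally).
#' @return a `grid_map`.
#' @export
digitize <- function(s, spacing = 1.2, padding = 0, role = c("receptor", "ligand"),
                     r_occ = 1.8, core_penalty = -15,
                     kernel = c("gaussian", "paper_literal"),
                     kernel_cutoff = 2, max_cells = 256^3, align_to = NULL) {
  role <- match.arg(role)
  kernel <- match.arg(kernel)
  stopifnot(spacing > 0)
  if (nrow(s$atoms) == 0L) stop("cannot digitize an empty structure")
  xyz <- coords(s)
  margin <- r_occ + padding
  origin <- apply(xyz, 2, min) - margin
  if (!is.null(align_to))
    origin <- align_to + floor((origin - align_to) / spacing) * spacing
  upper <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((upper - origin) / spacing)) + 1L
  if (prod(as.numeric(dims)) > max_cells)
    stop(sprintf("grid of %d x %d x %d cells exceeds the limit; use a larger spacing",
                 dims[1], dims[2], dims[3]))
  occ <- .occupancy(xyz, origin, spacing, dims, r_occ)

  if (role == "ligand")
    return(grid_map(array(as.numeric(occ), dims), origin, spacing, "ligand"))

  # core cells: occupied with all 26 neighbors occupied.  Buried cells:
  # occupied with all 6 face neighbors occupied.  Both carry the core
  # penalty: on a thin nucleic-acid strand at 1.2 A spacing, 26-neighbor
  # erosion alone leaves almost no interior, and without a penalized
  # interior the correlation score rewards interpenetration over contact.
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  face <- nb[rowSums(abs(nb)) == 1, ]
  all_nb <- array(TRUE, dims)
  for (i in seq_len(nrow(nb))) all_nb <- all_nb & .shift3(occ, nb[i, ], FALSE)
  core <- occ & all_nb
  all_face <- array(TRUE, dims)
  for (i in seq_len(nrow(face))) all_face <- all_face & .shift3(occ, face[i, ], FALSE)
  buried <- occ & all_face
  surface <- occ & !buried

  # soft surface field: sum of kernel weights from surface cells within the
  # cutoff, capped at 1
  reach <- as.integer(ceiling(kernel_cutoff))
  off <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
  rr <- sqrt(rowSums(off^2))               # distance in grid units
  off <- off[rr <= kernel_cutoff + 1e-9, , drop = FALSE]
  rr <- rr[rr <= kernel_cutoff + 1e-9]
  w <- if (kernel == "gaussian") exp(-rr^2) else ifelse(rr > 0, exp(-1 / rr^2), 0)
  field <- array(0, dims)
  surf_num <- array(as.numeric(surface), dims)
  for (i in seq_len(nrow(off))) field <- field + w[i] * .shift3(surf_num, off[i, ], 0)
  vals <- pmin(field, 1)
  vals[buried] <- core_penalty
  g <- grid_map(array(vals, dims), origin, spacing, "receptor")
  g$core <- core
  g
}

#' FFT translation scan of a ligand grid against a receptor grid
#'
#' Computes `score(t) = sum_g R[g] * L[g - t]` for every integer offset `t`
#' at which the two grid boxes overlap, via zero-padded forward/inverse
#' discrete Fourier transforms (no wrap-around), matching the
#' direct-summation definition to within 1e-6 relative error.
#'
#' @param receptor_grid,ligand_grid `grid_map` objects with equal spacing.
#' @return object of class `score_field`: list with `values` (3D array),
#'   `offset0` (integer lag of element \[1,1,1\] along each axis) and
#'   `spacing`.
#' @export
fft_translation_scan <- function(receptor_grid, ligand_grid) {
  if (abs(receptor_grid$spacing - ligand_grid$spacing) > 1e-12)
    stop("receptor and ligand grids must share the same spacing")
  rd <- receptor_grid$dims; ld <- ligand_grid$dims
  vals <- cpp_correlate(as.numeric(receptor_grid$values), as.integer(rd),
                        as.numeric(ligand_grid$values), as.integer(ld))
  structure(list(values = vals, offset0 = -(as.integer(ld) - 1L),
                 spacing = receptor_grid$spacing),
            class = "score_field")
}

#' Top-scoring translations of a score field
#'
#' @param score_field a `score_field` from [fft_translation_scan()].
#' @param k number of translations to return (default 10).
#' @return data.frame with integer offsets `tx, ty, tz` and `shape_score`,
#'   descending by score; ties broken by lexicographic (z, y, x) offset
#'   order.
#' @export
top_translations <- function(score_field, k = 10) {
  stopifnot(k >= 1)
  v <- score_field$values
  d <- dim(v)
  o <- score_field$offset0
  idx <- arrayInd(seq_along(v), d)
  tx <- idx[, 1] - 1L + o[1]; ty <- idx[, 2] - 1L + o[2]; tz <- idx[, 3] - 1L + o[3]
  ord <- order(-as.numeric(v), tz, ty, tx)
  take <- head(ord, k)
  data.frame(tx = tx[take], ty = ty[take], tz = tz[take],
             shape_score = as.numeric(v)[take])
}
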