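# Deterministic, evenly distributed rotation sampling.
#
# Orientation space is covered as (axis orientation) x (in-plane spin):
# N_sphere = floor(4*pi / delta_rad^2) unit vectors are placed by a
# deterministic generalized-spiral lattice on the sphere (first point at the
# +z pole), each combined with round(360/delta) uniform spin angles starting
# at 0.  At delta = 15 degrees this gives 183 x 24 = 4392 rotations, and the
# first rotation is always the identity.

# rotation about z by `ang` radians
.rot_z <- function(ang) {
  c_ <- cos(ang); s_ <- sin(ang)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# minimal proper rotation mapping +z onto unit vector p
.rot_z_to <- function(p) {
  z <- c(0, 0, 1)
  cth <- sum(z * p)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12)                      # antipodal: flip about x
    return(matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3))
  v <- c(z[2] * p[3] - z[3] * p[2],
         z[3] * p[1] - z[1] * p[3],
         z[1] * p[2] - z[2] * p[1])
  s <- sqrt(sum(v^2))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# generalized spiral (Saff-Kuijlaars) on the unit sphere, pole first
.sphere_lattice <- function(n) {
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  h <- 1 - 2 * (seq_len(n) - 1) / (n - 1)      # z from +1 down to -1
  phi <- numeric(n)
  for (k in 2:n) {
    if (abs(h[k]) >= 1 - 1e-12) phi[k] <- 0
    else phi[k] <- (phi[k - 1] + 3.6 / sqrt(n * (1 - h[k]^2))) %% (2 * pi)
  }
  r <- sqrt(pmax(0, 1 - h^2))
  cbind(r * cos(phi), r * sin(phi), h)
}

#' Generate an evenly distributed set of rotations
#'
#' Produces the deterministic rotation set searched by global docking at a
#' given angular interval.  The count obeys
#' `floor(4*pi/delta_rad^2) * round(360/delta)`; at the default docking
#' interval of 15 degrees this is 4392.
#'
#' @param delta_deg angular interval in degrees, in (0, 120].
#' @return An object of class `rotation_set`: list with `delta` and
#'   `rotations` (list of 3x3 proper orthonormal matrices, identity first).
#' @export
generate_rotations <- function(delta_deg = 15) {
  if (!is.numeric(delta_deg) || length(delta_deg) != 1L ||
      delta_deg <= 0 || delta_deg > 120)
    stop("delta_deg must be a single value in (0, 120]")
  delta_rad <- delta_deg * pi / 180
  n_sphere <- floor(4 * pi / delta_rad^2)
  n_spin <- round(360 / delta_deg)
  pts <- .sphere_lattice(n_sphere)
  spins <- 2 * pi * (seq_len(n_spin) - 1) / n_spin
  rots <- vector("list", n_sphere * n_spin)
  idx <- 0L
  for (i in seq_len(n_sphere)) {
    A <- .rot_z_to(pts[i, ])
    for (j in seq_len(n_spin)) {
      idx <- idx + 1L
      rots[[idx]] <- A %*% .rot_z(spins[j])
    }
  }
  structure(list(delta = delta_deg, rotations = rots), class = "rotation_set")
}

#' @export
print.rotation_set <- function(x, ...) {
  cat(sprintf("rotation_set: %d rotations at %g degree interval\n",
              length(x$rotations), x$delta))
  invisible(x)
}

#' @export
length.rotation_set <- function(x) length(x$rotations)

#' Rotation angle between two rotation matrices
#'
#' Geodesic distance on SO(3): `acos((trace(a' b) - 1) / 2)`.
#'
#' @param a,b 3x3 proper orthonormal matrices.
#' @return angle in degrees, in \[0, 180\].
#' @export
rotation_angle_between <- function(a, b) {
  tr <- sum(a * b)                       # trace(t(a) %*% b)
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# rotation set as an n x 9 matrix (row-major rows), the C++ scan layout
.rotations_matrix <- function(rs) {
  t(vapply(rs$rotations, function(m) as.numeric(t(m)), numeric(9)))
}

#' Export rotations as plain text
#'
#' One rotation per line: nine whitespace-separated matrix entries,
#' row-major.
#'
#' @param rs a `rotation_set`.
#' @param file optional output path.
#' @return invisibly, the text lines.
#' @export
export_rotations <- function(rs, file = NULL) {
  m <- .rotations_matrix(rs)
  lines <- apply(m, 1, function(r) paste(sprintf("%.12f", r), collapse = " "))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
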