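# Interface extraction, superposition, IRMSD, success rates.

test_that("interface extraction follows the 10 A heavy-atom rule", {
  h <- fix_halves()
  iface <- interface_residues(h$receptor, h$ligand, cutoff = 10)
  expect_length(iface$receptor, 8L)       # the whole 8-bp duplex interface
  expect_length(iface$ligand, 8L)
  far <- apply_transform(h$ligand, rigid_transform(diag(3), c(100, 0, 0)))
  expect_warning(e2 <- interface_residues(h$receptor, far), "empty")
  expect_length(e2$receptor, 0L)
  expect_warning(e0 <- interface_residues(h$receptor, far, cutoff = 0))
  expect_length(e0$ligand, 0L)
})

test_that("superpose recovers exact transforms and rejects reflections", {
  set.seed(41)
  pts <- matrix(rnorm(30), ncol = 3)
  sp0 <- superpose(pts, pts)
  expect_equal(sp0$transform$R, diag(3), tolerance = 1e-9)
  expect_lt(sp0$rmsd, 1e-12)
  # parameter recovery
  R <- random_rotation(); tvec <- c(3, -2, 7)
  target <- sweep(pts %*% t(R), 2, tvec, "+")
  sp <- superpose(pts, target)
  expect_lt(max(abs(sp$transform$R - R)), 1e-6)
  expect_lt(sp$rmsd, 1e-9)
  # a mirrored point set cannot be superposed with a proper rotation
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mirrored <- tetra %*% diag(c(-1, 1, 1))
  expect_gt(superpose(tetra, mirrored)$rmsd, 0.1)
  expect_error(superpose(pts[1:2, ], pts[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose residual equals the closed-form on a 3-point case", {
  # equilateral triangle vs itself rotated in-plane by 60 degrees about its
  # centroid: optimal superposition is exact, residual 0; against a scaled
  # copy the residual is computable by hand
  tri <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  rot60 <- nadock:::.rot_z(pi / 3)
  expect_lt(superpose(tri, tri %*% t(rot60))$rmsd, 1e-9)
  # uniform 2x scaling: best rigid fit keeps the rotation, residual is the
  # per-point distance |2r - r| = 1 for unit-radius points
  expect_equal(superpose(tri, 2 * tri)$rmsd, 1, tolerance = 1e-9)
})

test_that("irmsd is zero on self, invariant under rigid motion, and oracle-checked", {
  h <- fix_halves()
  expect_lt(irmsd(h, h), 1e-9)
  set.seed(9)
  tr <- rigid_transform(random_rotation(), rnorm(3, sd = 20))
  moved <- list(receptor = apply_transform(h$receptor, tr),
                ligand = apply_transform(h$ligand, tr))
  expect_lt(irmsd(moved, h), 1e-6)
  # perturbed ligand: compare against a direct numerical-minimization oracle
  iface <- interface_residues(h$receptor, h$ligand)
  ctr <- colMeans(rbind(nadock:::.c4_of_residues(h$receptor, iface$receptor),
                        nadock:::.c4_of_residues(h$ligand, iface$ligand)))
  pert <- list(receptor = h$receptor,
               ligand = apply_transform(h$ligand,
                                        rigid_transform(nadock:::.rot_z(10 * pi / 180),
                                                        c(0, 0, 0)), center = ctr))
  val <- irmsd(pert, h)
  nat <- rbind(nadock:::.c4_of_residues(h$receptor, iface$receptor),
               nadock:::.c4_of_residues(h$ligand, iface$ligand))
  prd <- rbind(nadock:::.c4_of_residues(pert$receptor, iface$receptor),
               nadock:::.c4_of_residues(pert$ligand, iface$ligand))
  obj <- function(p) {
    R <- nadock:::.axis_angle_matrix(c(sin(p[1]) * cos(p[2]),
                                       sin(p[1]) * sin(p[2]), cos(p[1])), p[3])
    sqrt(mean(rowSums((sweep(prd %*% t(R), 2, p[4:6], "+") - nat)^2)))
  }
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    o <- optim(c(runif(3), rnorm(3)), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_gte(best, val - 1e-6)            # Kabsch is the true minimum
  expect_lt(abs(best - val), 1e-3)
  expect_gt(val, 0.1)
})

test_that("hit threshold is a strict 5.0 A boundary", {
  expect_true(is_hit(4.9))
  expect_false(is_hit(5.1))
  expect_false(is_hit(5.0))               # strictly below 5.0
})

test_that("success_rate counts cases with a hit within top N", {
  expect_equal(success_rate(c(1, 1, 1), 1), 1.0)
  expect_equal(success_rate(c(1, 4, NA, 12), 10), 0.5)
  expect_error(success_rate(integer(0), 10), "empty")
  # monotone in top_n
  set.seed(77)
  for (i in 1:20) {
    ranks <- sample(c(1:50, NA), 12, replace = TRUE)
    sr <- vapply(1:50, function(n) success_rate(ranks, n), numeric(1))
    expect_true(all(diff(sr) >= 0))
  }
})

test_that("irmsd grows with coordinate noise on average", {
  h <- fix_halves()
  set.seed(55)
  mean_irmsd <- vapply(c(0.2, 1.0, 3.0), function(sig) {
    mean(vapply(1:5, function(i) {
      lig <- h$ligand
      lig$atoms$x <- lig$atoms$x + rnorm(nrow(lig$atoms), sd = sig)
      lig$atoms$y <- lig$atoms$y + rnorm(nrow(lig$atoms), sd = sig)
      lig$atoms$z <- lig$atoms$z + rnorm(nrow(lig$atoms), sd = sig)
      irmsd(list(receptor = h$receptor, ligand = lig), h)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_irmsd) > 0))
})

test_that("evaluate_models reports per-model IRMSD and the first hit rank", {
  h <- fix_halves()
  shift <- function(d) list(receptor = h$receptor,
                            ligand = apply_transform(h$ligand,
                                                     rigid_transform(diag(3), c(d, 0, 0))))
  ev <- evaluate_models(list(shift(30), shift(0.5), shift(0)), h)
  expect_length(ev$per_model_irmsd, 3L)
  expect_equal(ev$first_hit_rank, 2L)
  ev2 <- evaluate_models(list(shift(30)), h)
  expect_true(is.na(ev2$first_hit_rank))
})
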