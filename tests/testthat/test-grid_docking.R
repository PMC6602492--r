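# Grid digitization and the FFT translation scan.

test_that("ligand digitization occupies exactly the cells within r_occ", {
  ln <- pdb_atom_line(1, "C4'", "A", "A", 1, 0, 0, 0, "C")
  s <- read_structure(text = ln)
  g <- digitize(s, spacing = 1.2, role = "ligand", r_occ = 1.8)
  idx <- which(g$values > 0, arr.ind = TRUE)
  centers <- sweep((idx - 1) * g$spacing, 2, g$origin, "+")
  expect_true(all(sqrt(rowSums(centers^2)) <= 1.8 + 1e-12))
  # and no cell within r_occ was missed
  allidx <- which(array(TRUE, g$dims), arr.ind = TRUE)
  allcenters <- sweep((allidx - 1) * g$spacing, 2, g$origin, "+")
  inside <- sqrt(rowSums(allcenters^2)) <= 1.8
  expect_equal(sum(g$values > 0), sum(inside))
})

test_that("digitize rejects empty structures and oversized grids", {
  s <- fix_halves()$receptor
  empty <- s
  empty$atoms <- empty$atoms[0, ]
  expect_error(digitize(empty), "empty")
  expect_error(digitize(s, max_cells = 10), "spacing")
})

test_that("duplex receptor grid has core cells with fully occupied neighborhoods", {
  g <- digitize(fix_duplex(), role = "receptor")
  expect_gt(sum(g$core), 0)
  # exhaustive audit: every core cell's 26 neighbors are occupied
  # (occupied = any positive/penalized value; recompute occupancy directly)
  occ <- nadock:::.occupancy(coords(fix_duplex()), g$origin, g$spacing,
                             g$dims, 1.8)
  core_idx <- which(g$core, arr.ind = TRUE)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (k in seq_len(nrow(core_idx))) {
    nbr <- sweep(nb, 2, core_idx[k, ], "+")
    expect_true(all(occ[nbr]))
  }
  # core cells carry the penalty
  expect_true(all(g$values[g$core] == -15))
})

test_that("the FFT scan matches trivial closed forms", {
  z <- grid_map(array(0, c(4, 4, 4)), c(0, 0, 0), 1.2, "ligand")
  r <- grid_map(array(rnorm(64), c(4, 4, 4)), c(0, 0, 0), 1.2, "receptor")
  sf <- fft_translation_scan(r, z)
  expect_lt(max(abs(sf$values)), 1e-9)
  # delta correlation: single occupied cell against itself
  one <- array(0, c(3, 3, 3)); one[2, 2, 2] <- 1
  gr <- grid_map(one, c(0, 0, 0), 1.2, "receptor")
  gl <- grid_map(one, c(0, 0, 0), 1.2, "ligand")
  sf2 <- fft_translation_scan(gr, gl)
  expect_equal(max(sf2$values), 1, tolerance = 1e-9)
  hit <- which(sf2$values > 0.5, arr.ind = TRUE)
  expect_equal(nrow(hit), 1L)
  expect_equal(as.integer(hit[1, ] - 1L) + sf2$offset0, c(0L, 0L, 0L))
  expect_error(fft_translation_scan(gr, grid_map(one, c(0, 0, 0), 1.0, "ligand")),
               "spacing")
})

test_that("FFT scan equals the direct-summation oracle on random grids", {
  set.seed(31)
  for (i in 1:20) {
    rd <- sample(5:12, 3, replace = TRUE)
    ld <- sample(3:8, 3, replace = TRUE)
    rv <- array(rnorm(prod(rd)), rd)
    lv <- array(0, ld)
    lv[sample(prod(ld), max(2, prod(ld) %/% 4))] <- runif(max(2, prod(ld) %/% 4))
    sf <- fft_translation_scan(grid_map(rv, c(0, 0, 0), 1.2, "receptor"),
                               grid_map(lv, c(0, 0, 0), 1.2, "ligand"))
    oracle <- direct_correlate(rv, lv)
    denom <- max(abs(oracle), 1)
    expect_lt(max(abs(sf$values - oracle)) / denom, 1e-6)
  }
})

test_that("translation invariance: common lattice shifts move the argmax", {
  set.seed(7)
  rv <- array(runif(6^3), c(6, 6, 6))
  lv <- array(0, c(3, 3, 3)); lv[sample(27, 5)] <- 1
  base <- fft_translation_scan(grid_map(rv, c(0, 0, 0), 1, "receptor"),
                               grid_map(lv, c(0, 0, 0), 1, "ligand"))
  # embed both in larger boxes shifted by (1, 2, 1): argmax offset unchanged
  shift <- c(1L, 2L, 1L)
  rv2 <- array(0, dim(rv) + 3L)
  rv2[shift[1] + 1:6, shift[2] + 1:6, shift[3] + 1:6] <- rv
  lv2 <- array(0, dim(lv) + 3L)
  lv2[shift[1] + 1:3, shift[2] + 1:3, shift[3] + 1:3] <- lv
  moved <- fft_translation_scan(grid_map(rv2, c(0, 0, 0), 1, "receptor"),
                                grid_map(lv2, c(0, 0, 0), 1, "ligand"))
  t1 <- top_translations(base, 1)
  t2 <- top_translations(moved, 1)
  expect_equal(t1$shape_score, t2$shape_score, tolerance = 1e-6)
  expect_equal(c(t1$tx, t1$ty, t1$tz), c(t2$tx, t2$ty, t2$tz))
})

test_that("top_translations ranks and tie-breaks deterministically", {
  v <- array(0, c(3, 3, 3))
  v[2, 2, 2] <- 5
  sf <- structure(list(values = v, offset0 = c(0L, 0L, 0L), spacing = 1),
                  class = "score_field")
  tt <- top_translations(sf, 10)
  expect_equal(nrow(tt), 10L)
  expect_equal(c(tt$tx[1], tt$ty[1], tt$tz[1]), c(1, 1, 1))
  # remaining zero scores come in lexicographic (z, y, x) order
  expect_equal(c(tt$tx[2], tt$ty[2], tt$tz[2]), c(0, 0, 0))
  expect_equal(c(tt$tx[3], tt$ty[3], tt$tz[3]), c(1, 0, 0))
  # two equal maxima: lexicographically smaller (z, y, x) first
  v2 <- array(0, c(3, 3, 3)); v2[3, 1, 2] <- 7; v2[1, 2, 2] <- 7
  sf2 <- structure(list(values = v2, offset0 = c(0L, 0L, 0L), spacing = 1),
                   class = "score_field")
  t2 <- top_translations(sf2, 2)
  expect_equal(c(t2$tx[1], t2$ty[1], t2$tz[1]), c(2, 0, 1))
  expect_equal(c(t2$tx[2], t2$ty[2], t2$tz[2]), c(0, 1, 1))
  # against a full-sort oracle on a random field
  set.seed(13)
  v3 <- array(rnorm(5^3), c(5, 5, 5))
  sf3 <- structure(list(values = v3, offset0 = c(-2L, -2L, -2L), spacing = 1),
                   class = "score_field")
  tt3 <- top_translations(sf3, 10)
  idx <- arrayInd(order(-v3), dim(v3))[1:10, ]
  expect_equal(tt3$shape_score, v3[idx])
})

test_that("fixture redock has a near-native offset among the identity top-10", {
  h <- fix_halves()
  rg <- digitize(h$receptor, role = "receptor")
  lg <- digitize(h$ligand, role = "ligand", r_occ = 1.05, align_to = rg$origin)
  sf <- fft_translation_scan(rg, lg)
  tt <- top_translations(sf, 10)
  # the native placement corresponds to the (real-valued) origin difference
  nat <- (lg$origin - rg$origin) / rg$spacing
  d <- sqrt((tt$tx - nat[1])^2 + (tt$ty - nat[2])^2 + (tt$tz - nat[3])^2)
  expect_lte(min(d), sqrt(3))
})
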