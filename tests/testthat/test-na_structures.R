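# Structure container, PDB I/O and rigid transforms.

test_that("a minimal single ATOM record parses", {
  ln <- pdb_atom_line(1, "C4'", "A", "A", 1, 1.5, -2.25, 3.125, "C")
  s <- read_structure(text = ln)
  expect_equal(length(unique(s$atoms$chain)), 1L)
  expect_equal(n_residues(s), 1L)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(unname(coords(s)[1, ]), c(1.5, -2.25, 3.125))
  expect_equal(s$atoms$elety, "C4'")
})

test_that("parse errors are specific", {
  expect_error(read_structure(text = "REMARK nothing here"), "no ATOM")
  ln <- pdb_atom_line(1, "C1'", "XYZ", "A", 1, 0, 0, 0, "C")
  expect_error(read_structure(text = ln), "XYZ")
  dup_lines <- write_structure(fix_duplex())
  expect_error(read_structure(text = dup_lines, chains = "Q"), "Q")
})

test_that("parsing filters hydrogens, waters, altlocs and extra MODELs", {
  lines <- c("MODEL        1",
             pdb_atom_line(1, "C4'", "G", "A", 1, 0, 0, 0, "C"),
             pdb_atom_line(2, "H1'", "G", "A", 1, 1, 0, 0, "H"),
             sub("^ATOM  (.{10}).", "ATOM  \\1B",   # altloc B copy
                 pdb_atom_line(3, "C1'", "G", "A", 1, 2, 0, 0, "C")),
             "HETATM    4  O   HOH A   2       0.0     0.0     0.0",
             "ENDMDL",
             "MODEL        2",
             pdb_atom_line(5, "C4'", "G", "A", 9, 9, 9, 9, "C"),
             "ENDMDL")
  s <- read_structure(text = lines)
  expect_equal(nrow(s$atoms), 1L)        # only the first model's heavy C4'
  expect_equal(s$atoms$resno, 1L)
})

test_that("write/read round-trip preserves counts and coordinates", {
  dup <- fix_duplex()
  s2 <- read_structure(text = write_structure(dup))
  expect_equal(nrow(s2$atoms), nrow(dup$atoms))
  expect_equal(n_residues(s2), n_residues(dup))
  expect_lt(max(abs(coords(s2) - coords(dup))), 1e-3)
  # idempotence: read(write(read(x))) == read(write(x))
  s3 <- read_structure(text = write_structure(s2))
  expect_equal(s3$atoms, s2$atoms)
})

test_that("chain filtering returns the requested half", {
  dup_lines <- write_structure(fix_duplex())
  full <- read_structure(text = dup_lines)
  a <- read_structure(text = dup_lines, chains = "A")
  expect_equal(unique(a$atoms$chain), "A")
  expect_equal(n_residues(a), n_residues(full) / 2)
})

test_that("select_atoms picks one atom per residue in order", {
  h <- fix_halves()
  c4 <- select_atoms(h$receptor, "C4'")
  expect_equal(nrow(c4$coords), 8L)
  expect_equal(c4$skipped, 0L)
  none <- select_atoms(h$receptor, "XX9")
  expect_equal(nrow(none$coords), 0L)
  expect_equal(none$skipped, 8L)
  p <- select_atoms(h$receptor, "P")       # 5' terminus has no phosphate
  expect_equal(nrow(p$coords), 7L)
  expect_equal(p$skipped, 1L)
})

test_that("apply_transform is rigid and invertible", {
  s <- fix_halves()$ligand
  expect_equal(coords(apply_transform(s, rigid_transform())), coords(s))
  set.seed(11)
  for (i in 1:5) {
    tr <- rigid_transform(random_rotation(), rnorm(3, sd = 5))
    ctr <- rnorm(3)
    s2 <- apply_transform(s, tr, center = ctr)
    # rigidity: intra-structure distances preserved
    expect_lt(max(abs(dist(coords(s2)) - dist(coords(s)))), 1e-9)
    # group inverse
    s3 <- apply_transform(s2, invert_transform(tr), center = ctr)
    expect_lt(max(abs(coords(s3) - coords(s))), 1e-9)
    # composition equals sequential application
    tr2 <- rigid_transform(random_rotation(), rnorm(3))
    seq2 <- apply_transform(s2, tr2, center = ctr)
    once <- apply_transform(s, compose_transforms(tr2, tr), center = ctr)
    expect_lt(max(abs(coords(seq2) - coords(once))), 1e-9)
  }
  expect_error(rigid_transform(matrix(rnorm(9), 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "proper")
})

test_that("write_model round-trips scores and renames colliding chains", {
  h <- fix_halves()
  lines <- write_model(h$receptor, h$ligand, rank = 3,
                       scores = list(shape = 12.5, energy = -87.25))
  back <- read_structure(text = lines)
  expect_equal(nrow(back$atoms), nrow(h$receptor$atoms) + nrow(h$ligand$atoms))
  sc <- read_model_scores(lines)
  expect_equal(sc$rank, 3L)
  expect_equal(sc$shape, 12.5)
  expect_equal(sc$energy, -87.25)
  # same ligand in two poses: atom records identical except coordinates
  pose2 <- apply_transform(h$ligand, rigid_transform(diag(3), c(5, 0, 0)))
  l2 <- write_model(h$receptor, pose2, 4, list(shape = 0, energy = 0))
  a1 <- read_structure(text = lines)$atoms
  a2 <- read_structure(text = l2)$atoms
  expect_equal(a1[, c("chain", "resno", "resname", "elety")],
               a2[, c("chain", "resno", "resname", "elety")])
  # collision: ligand chain A against receptor chain A gets renamed
  ligA <- h$ligand
  ligA$atoms$chain <- "A"
  lines3 <- write_model(h$receptor, ligA, 1, list(shape = 0, energy = 0))
  back3 <- read_structure(text = lines3)
  expect_equal(length(unique(back3$atoms$chain)), 2L)
  expect_error(write_model(h$receptor, h$ligand, 0, list(shape = 0, energy = 0)))
})
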