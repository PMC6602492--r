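# Atom typing, pose scoring and potential derivation.

# tiny custom table: every pair energy = bin index / 100, easy closed forms
tiny_table <- function(bin_width = 0.5, r_max = 10) {
  sch <- atom_type_scheme()
  nb <- round(r_max / bin_width)
  e <- array(rep(seq_len(nb) / 100, each = length(sch$types)^2),
             c(length(sch$types), length(sch$types), nb))
  potential_table(e, bin_width, r_max, sch$types)
}

test_that("the type scheme covers standard nucleotides without a catch-all", {
  h <- fix_halves()
  typed <- assign_atom_types(h$receptor)      # G and C residues
  sch <- atom_type_scheme()
  expect_equal(typed$n_catchall, 0L)
  expect_equal(length(typed$type), nrow(h$receptor$atoms))
  expect_true(all(typed$type >= 1 & typed$type <= length(sch$types)))
  # DT: same backbone typing as U, methyl carbon gets its own type
  dna <- build_aform_duplex("GATC", dna = TRUE)
  t7 <- sch$type_of("DT", "C7")
  expect_equal(sch$types[t7], "pyr.Cme")
  expect_equal(sch$type_of("DT", "C4'"), sch$type_of("U", "C4'"))
  # empty structure
  empty <- h$receptor; empty$atoms <- empty$atoms[0, ]
  expect_length(assign_atom_types(empty)$type, 0L)
})

test_that("score_pose obeys one-pair closed forms", {
  tab <- tiny_table()
  mk1 <- function(x) read_structure(text = pdb_atom_line(1, "C4'", "A", "A", 1,
                                                         x, 0, 0, "C"))
  a <- mk1(0)
  # beyond r_max: zero
  expect_equal(score_pose(a, mk1(15), tab), 0)
  # one pair at d = 3.3: bin floor(3.3/0.5)+1 = 7 -> 0.07
  expect_equal(score_pose(a, mk1(3.3), tab), 0.07)
  # clash guard below 2 A
  expect_equal(score_pose(a, mk1(1.0), tab), tab$clash_energy)
})

test_that("score_pose is symmetric, additive, and rigid-motion invariant", {
  h <- fix_halves()
  tab <- fix_potential()
  e0 <- score_pose(h$receptor, h$ligand, tab)
  expect_identical(e0, score_pose(h$ligand, h$receptor, tab))
  # joint rigid motion leaves the score unchanged
  set.seed(3)
  tr <- rigid_transform(random_rotation(), rnorm(3, sd = 10))
  r2 <- apply_transform(h$receptor, tr)
  l2 <- apply_transform(h$ligand, tr)
  expect_equal(score_pose(r2, l2, tab), e0, tolerance = 1e-9)
  # additivity over non-interacting ligand copies
  far <- apply_transform(h$ligand, rigid_transform(diag(3), c(200, 0, 0)))
  both <- h$ligand
  both$atoms <- rbind(both$atoms, within(far$atoms, chain <- "C"))
  e_far <- score_pose(h$receptor, far, tab)
  expect_equal(score_pose(h$receptor, both, tab), e0 + e_far, tolerance = 1e-9)
})

test_that("locality: a sub-bin perturbation only changes that atom's terms", {
  h <- fix_halves()
  tab <- fix_potential()
  lig <- h$ligand
  one_atom <- function(l, i) { l$atoms <- l$atoms[i, , drop = FALSE]; l }
  rest <- function(l, i) { l$atoms <- l$atoms[-i, , drop = FALSE]; l }
  i <- 5L
  lig2 <- lig
  lig2$atoms$x[i] <- lig2$atoms$x[i] + 0.05
  e_rest <- score_pose(h$receptor, rest(lig, i), tab)
  expect_equal(score_pose(h$receptor, lig2, tab) -
                 score_pose(h$receptor, one_atom(lig2, i), tab),
               e_rest, tolerance = 1e-9)
})

test_that("inverse-Boltzmann derivation matches an independent recomputation", {
  seqs <- c("GGGGCCCC", "AUCGAUCG")
  training <- lapply(seqs, function(sq) split_chains(build_aform_duplex(sq)))
  tab <- derive_potential(training, bin_width = 0.5, r_max = 10, eps = 0.5)
  sch <- atom_type_scheme()
  nt <- length(sch$types); nb <- 20
  # oracle: direct double loop over atom pairs
  nobs <- array(0, c(nt, nt, nb))
  for (cx in training) {
    tr <- assign_atom_types(cx$receptor, sch)
    tl <- assign_atom_types(cx$ligand, sch)
    for (i in seq_len(nrow(tr$xyz))) for (j in seq_len(nrow(tl$xyz))) {
      d <- sqrt(sum((tr$xyz[i, ] - tl$xyz[j, ])^2))
      if (d < 10) {
        b <- floor(d / 0.5) + 1
        nobs[tr$type[i], tl$type[j], b] <- nobs[tr$type[i], tl$type[j], b] + 1
        nobs[tl$type[j], tr$type[i], b] <- nobs[tl$type[j], tr$type[i], b] + 1
      }
    }
  }
  edges <- seq(0, 10, by = 0.5)
  shell <- diff(edges^3); shell <- shell / sum(shell)
  nref <- outer(apply(nobs, c(1, 2), sum), shell)
  expected <- -log((nobs + 0.5) / (nref + 0.5))
  expect_equal(tab$energies, expected, tolerance = 1e-12)
  # pairs never observed anywhere have zero energy (log(eps/eps))
  never <- apply(nobs, c(1, 2), sum) == 0
  expect_true(all(abs(tab$energies[cbind(which(never, arr.ind = TRUE), 1)]) < 1e-12))
  # enrichment closed form: observed > reference in a bin => negative energy
  enriched <- which(nobs > 2 * nref & nobs > 5, arr.ind = TRUE)
  expect_gt(nrow(enriched), 0)
  expect_true(all(tab$energies[enriched] < 0))
  expect_error(derive_potential(list()), "empty")
})

test_that("the derived table separates natives from 5 A decoys in >= 90% of cases", {
  tab <- fix_potential()
  seqs <- c("GGGGCCCC", "AUCGAUCG", "GCGCGCGC", "AAUUGGCC", "CAGUCAGU",
            "GGAUACCG", "ACGUACGU", "UUUAAACG", "GGCCGGCC", "AUAUAUAU",
            "CCCGGGAA", "UGCAUGCA", "GAGAGAGA", "CUCUCUCU", "GGUUCCAA",
            "ACCGGUUA", "UGGACCAA", "CGAUCGAU", "AAGGCCUU", "GCCAAUGG")
  wins <- 0L
  for (k in seq_along(seqs)) {
    h <- split_chains(build_aform_duplex(seqs[k]))
    e_nat <- score_pose(h$receptor, h$ligand, tab)
    dec <- make_decoys(h, 1, trans = 5, rot_deg = 0, seed = k)[[1]]
    if (e_nat < score_pose(h$receptor, dec$pose, tab)) wins <- wins + 1L
  }
  expect_gte(wins / length(seqs), 0.9)
})

test_that("refinement iterations are deterministic and keep the table valid", {
  training <- list(fix_halves())
  decoys <- list(lapply(make_decoys(fix_halves(), 3, trans = 6, seed = 2),
                        `[[`, "pose"))
  t1 <- derive_potential(training, iterations = 2, decoys = decoys)
  t2 <- derive_potential(training, iterations = 2, decoys = decoys)
  expect_identical(t1$energies, t2$energies)
  expect_lt(max(abs(t1$energies - aperm(t1$energies, c(2, 1, 3)))), 1e-12)
  expect_error(derive_potential(training, iterations = 1), "decoys")
})

test_that("potential text serialization round-trips bit-exactly", {
  tab <- fix_potential()
  tab2 <- read_potential(write_potential(tab))
  expect_identical(tab2$energies, tab$energies)
  expect_identical(tab2$bin_width, tab$bin_width)
  expect_identical(tab2$r_max, tab$r_max)
  expect_identical(tab2$types, tab$types)
  # and through a file on disk
  f <- tempfile(fileext = ".tsv")
  write_potential(tab, f)
  expect_identical(read_potential(f)$energies, tab$energies)
  unlink(f)
})
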