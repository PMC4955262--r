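test_that("toy structures round-trip through PDB and chain roles are detected", {
  toy <- genToyStructure(c(2, 6), structureId = "toy26")
  pdb <- tempfile(fileext = ".pdb")
  writeStructurePDB(toy, pdb)
  got <- suppressMessages(parseStructure(pdb))
  expect_s4_class(got, "ComplexStructure")
  expect_equal(got@peptideChain, "P")
  expect_equal(got@hlaChains, "H")    # larger non-peptide chain
  expect_equal(got@partnerChains, "T")
  expect_equal(unname(which(contactPattern(got))), c(2L, 6L))

  # explicit roles respected; wrong peptide chain rejected
  got2 <- parseStructure(pdb, peptideChain = "P", hlaChains = "H",
                         partnerChains = "T")
  expect_equal(unname(which(contactPattern(got2))), c(2L, 6L))
  expect_error(parseStructure(pdb, peptideChain = "H"), "not 9")

  # two 9-residue chains without a manifest is ambiguous
  amb <- toy@atoms
  extra <- amb[amb$chain == "P", ]
  extra$chain <- "Q"
  extra$x <- extra$x + 100
  writeStructurePDB(ComplexStructure(rbind(amb, extra), "amb", "P", "H", "T"),
                    pdb)
  expect_error(parseStructure(pdb), "ambiguous")
})

test_that("hydrophobic contacts respect the vdW gap window and side-chain restriction", {
  mkToy <- function(partnerAtoms) {
    base <- genToyStructure(rep(FALSE, 9))@atoms
    base <- base[base$chain != "T", ]
    ComplexStructure(rbind(base, partnerAtoms), "probe", "P", "H", "T")
  }
  atomRow <- function(x, y, z, element = "C")
    data.frame(chain = "T", resno = 1L, resid = "LIG", atom = "C1",
               element = element, x = x, y = y, z = z)

  # gap 0.2 from the CB of position 3 (CB at (27, 1.5, 0), radii 1.7 + 1.7)
  expect_equal(hydrophobicContactPositions(mkToy(atomRow(27, 1.5, 3.6))), 3L)
  # boundary: gap exactly 0.4 in, 0.41 out, small negative gap out
  expect_equal(hydrophobicContactPositions(mkToy(atomRow(27, 1.5, 3.8))), 3L)
  expect_equal(length(hydrophobicContactPositions(mkToy(atomRow(27, 1.5, 3.81)))), 0L)
  expect_equal(length(hydrophobicContactPositions(mkToy(atomRow(27, 1.5, 3.35)))), 0L)
  # all partner atoms far away
  expect_equal(length(hydrophobicContactPositions(mkToy(atomRow(27, 1.5, 40)))), 0L)
  # contact only to a backbone atom (CA of residue 3 at (27, 0, 0)) is ignored
  expect_equal(length(hydrophobicContactPositions(mkToy(atomRow(27, 0, -3.6)))), 0L)
  # HLA-chain proximity never counts: a partner-distance probe on chain H
  hla <- genToyStructure(rep(FALSE, 9))@atoms
  hla <- rbind(hla[hla$chain != "T", ],
               atomRow(200, 1.5, 3.6)[, ])
  hla$chain[nrow(hla)] <- "T"  # partner present but far
  hh <- data.frame(chain = "H", resno = 13L, resid = "GLY", atom = "CA",
                   element = "C", x = 27, y = 1.5, z = 3.6)
  s <- ComplexStructure(rbind(hla, hh), "hla-probe", "P", "H", "T")
  expect_equal(length(hydrophobicContactPositions(s)), 0L)
  # unknown element is a configuration error
  s2 <- mkToy(atomRow(27, 1.5, 3.6, element = "ZZ"))
  expect_error(hydrophobicContactPositions(s2), "radius")
})

test_that("hydrogen bonds follow the donor-acceptor distance and linearity criteria", {
  expect_equal(hydrogenBondPositions(genHbondToy(3.0)), 5L)
  expect_equal(length(hydrogenBondPositions(genHbondToy(4.5))), 0L)
  expect_equal(length(hydrogenBondPositions(genHbondToy(4.0))), 0L)  # strict <
  expect_equal(hydrogenBondPositions(genHbondToy(3.9)), 5L)
  # explicit hydrogens: near-linear geometry accepted, bent rejected
  expect_equal(hydrogenBondPositions(genHbondToy(3.0, "linear")), 5L)
  expect_equal(length(hydrogenBondPositions(genHbondToy(3.0, "bent"))), 0L)
})

test_that("contact patterns are the union of both criteria and invariant to atom order and rigid motion", {
  toy <- genToyStructure(c(3, 7))
  hb <- genHbondToy(3.0)
  expect_equal(unname(which(contactPattern(toy))), c(3L, 7L))
  expect_equal(unname(which(contactPattern(hb))), 5L)

  shuffled <- toy@atoms[sample(nrow(toy@atoms)), ]
  toy2 <- ComplexStructure(shuffled, "shuffled", "P", "H", "T")
  expect_equal(as.vector(contactPattern(toy2)), as.vector(contactPattern(toy)))

  for (seed in c(2, 77)) {
    moved <- genToyStructure(c(3, 7), seed = seed)
    expect_false(isTRUE(all.equal(moved@atoms$x, toy@atoms$x)))
    expect_equal(as.vector(contactPattern(moved)), as.vector(contactPattern(toy)))
    expect_equal(detectClashes(moved), detectClashes(toy))
  }
})

test_that("clash detection uses strict overlap beyond the configured tolerance", {
  mk <- function(d) {
    # probe approaches the CA of residue 1 from -y, clear of all other atoms
    atoms <- rbind(
      genToyStructure(rep(FALSE, 9))@atoms,
      data.frame(chain = "T", resno = 2L, resid = "LIG", atom = "C2",
                 element = "C", x = 9, y = -d, z = 0))
    ComplexStructure(atoms, "clash-probe", "P", "H", "T")
  }
  # residue 1 CA at (9, 0, 0); radii 1.7 + 1.7 = 3.4
  expect_true(detectClashes(mk(1.0)))     # overlap 2.4 > 0.6
  expect_false(detectClashes(mk(2.8)))    # overlap exactly 0.6: no clash
  expect_true(detectClashes(mk(2.79)))    # overlap 0.61
  expect_false(detectClashes(genToyStructure(c(1, 5, 9))))
})

test_that("pattern deduplication and importance voting behave as a threshold vote", {
  p1 <- c(TRUE, rep(FALSE, 8)); p2 <- p1; p3 <- c(rep(FALSE, 8), TRUE)
  pats <- list(p1, p2, p3)
  u <- uniquePatterns(pats)
  expect_equal(nrow(u), 2L)
  expect_equal(nrow(uniquePatterns(list(p1, p3))), 2L)
  expect_error(uniquePatterns(list()), "length")

  m <- patternMatrix(list(c(TRUE, TRUE, rep(FALSE, 7)),
                          c(TRUE, rep(FALSE, 8)),
                          c(TRUE, FALSE, TRUE, rep(FALSE, 6))))
  expect_equal(importantPositions(voteImportance(m, 0)), 1:9)
  expect_equal(length(importantPositions(voteImportance(m, 10))), 0L)
  expect_equal(importantPositions(voteImportance(m, 2)), 1L)
  expect_equal(importantPositions(voteImportance(m, 1)), 1:3)
  # monotone in the threshold
  for (t in 0:3) {
    hi <- importantPositions(voteImportance(m, t + 1L))
    lo <- importantPositions(voteImportance(m, t))
    expect_true(all(hi %in% lo))
  }

  tsv <- tempfile(fileext = ".tsv")
  writePatterns(m, tsv)
  expect_equal(unname(readPatterns(tsv)), unname(m))
})
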