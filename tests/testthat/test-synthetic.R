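# The generators' planted guarantees are contracts: each one is re-derived
# here with the corresponding analysis operation.

test_that("the synthetic proteome embeds every planted peptide exactly once, reproducibly", {
  spec <- fixtureSpec(seed = 7)
  ps <- genProteome(spec)
  idx <- extract9mers(ps)
  occ <- as.data.frame(occurrences(idx))
  planted <- rbind(spec$targets[, c("peptide", "gene")],
                   spec$offtargets[, c("peptide", "gene")],
                   spec$negatives[, c("peptide", "gene")])
  for (i in seq_len(nrow(planted))) {
    hit <- occ[occ$peptide == planted$peptide[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$gene_symbol, planted$gene[i])
  }
  # planted off-targets realize their designed DoS
  for (i in seq_len(nrow(spec$offtargets)))
    expect_gte(dos(spec$offtargets$target[i], spec$offtargets$peptide[i]), 5L)

  # bit-reproducible for a fixed seed
  ps2 <- genProteome(fixtureSpec(seed = 7))
  expect_identical(as.character(ps2@sequences), as.character(ps@sequences))
  ps3 <- genProteome(fixtureSpec(seed = 8))
  expect_false(identical(as.character(ps3@sequences),
                         as.character(ps@sequences)))
})

test_that("the synthetic expression matrix satisfies its planted threshold guarantees", {
  spec <- fixtureSpec(seed = 7)
  se <- genExpression(spec)
  s <- summarizeExpression(se)
  for (i in seq_len(nrow(spec$targets))) {
    expect_true(isCancerSpecific(spec$targets$gene[i],
                                 spec$targets$cancer_type[i], s))
    # the planted tumor p75 is hit exactly
    expect_equal(
      s$p75[s$gene == spec$targets$gene[i] &
              s$group == spec$targets$cancer_type[i]],
      spec$targets$tumor_p75[i], tolerance = 1e-9)
  }
  for (g in unique(spec$offtargets$gene)) {
    expect_true(offtargetExpressed(g, s))
    for (ct in spec$cancerGroups)
      expect_false(isCancerSpecific(g, ct, s))
  }
  for (g in spec$negatives$gene)
    expect_false(offtargetExpressed(g, s))
  # designated tissue is the top expressing tissue of each off-target gene
  for (i in seq_len(nrow(spec$offtargets))) {
    tiss <- expressingTissues(spec$offtargets$gene[i], s)
    expect_equal(as.character(tiss$tissue[1]), spec$offtargets$tissue[i])
  }
})

test_that("the synthetic affinity table plants binders and forces ambient similars out", {
  spec <- fixtureSpec(seed = 7)
  idx <- extract9mers(genProteome(spec))
  aff <- genAffinity(spec, idx)
  for (i in seq_len(nrow(spec$targets)))
    expect_equal(affinityFor(aff, spec$targets$peptide[i]),
                 spec$targets$ic50[i])
  for (i in seq_len(nrow(spec$offtargets)))
    expect_equal(affinityFor(aff, spec$offtargets$peptide[i]),
                 spec$offtargets$ic50[i])
  # every non-planted peptide within DoS >= 5 of a target is a non-binder
  planted <- c(spec$targets$peptide, spec$offtargets$peptide,
               spec$negatives$peptide)
  peps <- peptides(idx)
  for (t in spec$targets$peptide) {
    near <- peps[dos(t, peps) >= 5L & !(peps %in% planted)]
    if (length(near))
      expect_true(all(affinityFor(aff, near) >= 500))
  }
})

test_that("toy structures are verified inverses of contact-pattern analysis", {
  set.seed(71)
  pats <- c(list(rep(FALSE, 9), rep(TRUE, 9)),
            lapply(1:25, function(i) runif(9) < 0.5))
  for (p in pats) {
    toy <- genToyStructure(p)
    expect_equal(as.vector(contactPattern(toy)), as.logical(p))
    expect_false(detectClashes(toy))
  }
  # position-list form and the documented realistic profiles
  for (p in list(c(1, 5, 7), c(1, 4, 5), c(4, 5, 8)))
    expect_equal(unname(which(contactPattern(genToyStructure(p)))), as.integer(p))
})

test_that("the on-disk fixture round-trips through the package readers", {
  spec <- fixtureSpec(seed = 12)
  fx <- genPipelineFixture(spec)
  dir <- tempfile()
  writeFixture(fx, dir)
  ps <- readProteome(file.path(dir, "proteome.fasta"),
                     manifest = file.path(dir, "manifest.tsv"))
  expect_equal(length(ps), length(fx$proteins))
  expect_equal(sort(geneSymbols(ps)), sort(geneSymbols(fx$proteins)))
  idx <- extract9mers(ps)
  expect_equal(peptides(idx), peptides(fx$index))
  aff <- readAffinityTable(file.path(dir, "affinity.tsv"))
  expect_equal(affinityAllele(aff), spec$allele)
  expect_equal(affinityFor(aff, peptides(idx)),
               affinityFor(fx$affinity, peptides(idx)), tolerance = 1e-6)
  se <- readExpressionMatrix(file.path(dir, "expression.tsv"),
                             file.path(dir, "samples.tsv"))
  s1 <- summarizeExpression(se)
  expect_equal(s1$p75, fx$summaries$p75, tolerance = 1e-6)
})
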