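test_that("FASTA parsing preserves records, uppercases, and flags lincRNA products", {
  fa <- tempfile(fileext = ".fa")
  writeFasta(c("sp|P001|PROT1 Some protein GN=GENE1", "P002", "P003 GN=GENE3"),
             c("MKVAELVHFLW", "acdefghikl", "MSLLMWITQCW"), fa)
  ps <- readProteome(fa)
  expect_s4_class(ps, "ProteinSet")
  expect_equal(length(ps), 3L)
  expect_equal(accessions(ps), c("P001", "P002", "P003"))
  expect_equal(geneSymbols(ps), c("GENE1", "P002", "GENE3"))
  expect_equal(as.character(ps@sequences[["P002"]]), "ACDEFGHIKL")

  mf <- data.frame(accession = "P003", gene_symbol = "LINC1",
                   is_hla_variant = FALSE, allele_name = "",
                   is_lincRNA = TRUE, stringsAsFactors = FALSE)
  ps2 <- readProteome(fa, manifest = mf)
  expect_equal(length(ps2), 2L)
  expect_false("P003" %in% accessions(ps2))
  ps3 <- readProteome(fa, manifest = mf, excludeLincRNA = FALSE)
  expect_equal(length(ps3), 3L)

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(readProteome(empty), "empty")
})

test_that("HLA-variant filtering keeps only the configured alleles", {
  fa <- tempfile(fileext = ".fa")
  writeFasta(paste0("H", 1:6),
             c(replicate(5, paste(sample(standardAminoAcids(), 30, TRUE),
                                  collapse = "")),
               "MKVAELVHFLW"), fa)
  mf <- data.frame(
    accession = paste0("H", 1:5), gene_symbol = "HLA-A",
    is_hla_variant = TRUE,
    allele_name = c("HLA-A*02:01", "HLA-A*01:01", "HLA-A*03:01",
                    "HLA-A*11:01", "HLA-A*24:02"),
    is_lincRNA = FALSE, stringsAsFactors = FALSE)
  ps <- readProteome(fa, manifest = mf)
  kept <- filterHlaVariants(ps, keepAlleles = "HLA-A*02")
  expect_equal(length(kept), 2L)  # one allele product + the non-HLA record
  expect_true(all(c("H1", "H6") %in% accessions(kept)))

  # default keep list warns about manifest gaps but keeps non-HLA untouched
  expect_warning(filterHlaVariants(ps), "HLA-B\\*07")

  # no HLA-flagged records: identity
  noHla <- readProteome(fa)
  expect_equal(accessions(filterHlaVariants(noHla)), accessions(noHla))
})

test_that("9-mer extraction enumerates L-8 windows, drops non-standard, merges duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeFasta(c("A1", "A2", "A3", "A4"),
             c("ACDEFGHIKLMN",           # L = 12 -> 4 windows
               "ACDEFGHIKXACDEFGHIK",    # windows overlapping X dropped
               "SHORT",                  # < 9 residues -> nothing
               "MKVAELVHFLW"), fa)
  idx <- extract9mers(readProteome(fa))
  occ <- as.data.frame(occurrences(idx))

  expect_equal(sum(occ$accession == "A1"), 4L)
  expect_equal(sum(occ$accession == "A3"), 0L)

  # only starts 1 and 11 of A2 avoid the X; both give the same peptide
  a2 <- occ[occ$accession == "A2", ]
  expect_equal(sort(a2$start), c(1L, 11L))
  expect_equal(unique(a2$peptide), "ACDEFGHIK")
  expect_equal(sum(peptides(idx) == "ACDEFGHIK"), 1L)

  # every occurrence locates the peptide verbatim in its protein
  seqs <- as.character(readProteome(fa)@sequences)
  for (i in seq_len(nrow(occ))) {
    expect_equal(substr(seqs[[occ$accession[i]]], occ$start[i],
                        occ$start[i] + 8L), occ$peptide[i])
  }
})

test_that("window-count conservation holds for clean random proteins", {
  set.seed(11)
  for (L in c(9L, 10L, 37L, 100L)) {
    fa <- tempfile(fileext = ".fa")
    writeFasta("R1", paste(sample(standardAminoAcids(), L, TRUE),
                           collapse = ""), fa)
    idx <- extract9mers(readProteome(fa))
    expect_equal(nrow(occurrences(idx)), L - 8L)
  }
})

test_that("peptide index round-trips through its TSV form", {
  fa <- tempfile(fileext = ".fa")
  writeFasta(c("B1 GN=G1", "B2 GN=G2"),
             c("MKVAELVHFLW", "AKVAELVHFLW"), fa)
  idx <- extract9mers(readProteome(fa))
  tsv <- tempfile(fileext = ".tsv")
  writePeptideIndex(idx, tsv)
  idx2 <- readPeptideIndex(tsv)
  expect_equal(peptides(idx2), peptides(idx))
  expect_equal(idx2@nProteins, idx@nProteins)
  o1 <- as.data.frame(occurrences(idx))
  o2 <- as.data.frame(occurrences(idx2))
  o1 <- o1[order(o1$peptide, o1$accession, o1$start), ]
  o2 <- o2[order(o2$peptide, o2$accession, o2$start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
  # the shared 9-mers of B1/B2 carry both genes
  shared <- intersect(o1$peptide[o1$accession == "B1"],
                      o1$peptide[o1$accession == "B2"])
  expect_true(length(shared) > 0)
  expect_equal(peptideGenes(idx2, shared[1]), c("G1", "G2"))
})
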