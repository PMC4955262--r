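test_that("DoS counts identical positions, is symmetric, and equals 9 minus Hamming", {
  expect_equal(dos("KVAELVHFL", "KMAELVHFL"), 8L)
  expect_equal(dos("EVDPIGHLY", "ESDPIVAQY"), 5L)
  expect_equal(dos("AAAAAAAAA", "AAAAAAAAA"), 9L)
  expect_equal(dosPositions("EVDPIGHLY", "ESDPIVAQY"), c(1L, 3L, 4L, 5L, 9L))
  expect_error(dos("KVAELVHF", "KMAELVHFL"), "9-mer")
  expect_error(dos("KVAELVHFX", "KMAELVHFL"), "9-mer")

  set.seed(41)
  a <- randomPeptides(50)
  b <- randomPeptides(50)
  for (i in seq_along(a)) {
    expect_equal(dos(a[i], b[i]), dos(b[i], a[i]))
    expect_equal(dos(a[i], b[i]), oracleDos(a[i], b[i]))
    ham <- sum(strsplit(a[i], "")[[1]] != strsplit(b[i], "")[[1]])
    expect_equal(dos(a[i], b[i]), 9L - ham)
    expect_equal(length(dosPositions(a[i], b[i])), dos(a[i], b[i]))
  }
})

test_that("findSimilar returns exactly the DoS-qualified peptides, sorted deterministically", {
  idx <- peptideIndex(c("KMAELVHFL", "AAAAAAAAA"))
  h <- findSimilar("KVAELVHFL", idx, minDos = 5)
  expect_equal(nrow(h), 1L)
  expect_equal(h$peptide, "KMAELVHFL")
  expect_equal(h$dos, 8L)
  expect_equal(h$identical_positions[[1]], setdiff(1:9, 2L))

  expect_equal(nrow(findSimilar("WWWWWWWWW", idx, minDos = 9)), 0L)
  expect_error(findSimilar("KVAELVHFL", idx, minDos = 4), "between 5 and 9")

  # ordering: descending DoS then lexicographic
  idx2 <- peptideIndex(c("KVAELVHIL", "KMAELVHFL", "SAADLVHFL", "KVAELVQFL"))
  h2 <- findSimilar("KVAELVHFL", idx2, minDos = 5)
  expect_equal(h2$peptide, c("KMAELVHFL", "KVAELVHIL", "KVAELVQFL",
                             "SAADLVHFL"))
  expect_equal(h2$dos, c(8L, 8L, 8L, 6L))
})

test_that("a DoS-9 hit is an off-target only when it occurs outside the query's own genes", {
  idx <- peptideIndex(c("KVAELVHFL", "KMAELVHFL"), genes = c("MAGEA3", "MAGEA12"))
  h <- findSimilar("KVAELVHFL", idx, minDos = 5)
  expect_false("KVAELVHFL" %in% h$peptide)  # only its own gene

  idx2 <- peptideIndex(c("KVAELVHFL", "KVAELVHFL", "KMAELVHFL"),
                       genes = c("MAGEA3", "ELSEWHERE", "MAGEA12"))
  h2 <- findSimilar("KVAELVHFL", idx2, minDos = 5,
                    queryGenes = "MAGEA3")
  self <- h2[h2$peptide == "KVAELVHFL", ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$dos, 9L)
  expect_equal(self$genes[[1]], "ELSEWHERE")
})

test_that("the pigeonhole index equals a brute-force scan on random indexes", {
  set.seed(51)
  for (rep in 1:10) {
    peps <- unique(randomPeptides(3000))
    idx <- peptideIndex(peps)
    expect_false(is.null(idx@blocks))  # exercises the block path
    q <- if (rep %% 2) randomPeptides(1) else
      paste0(substr(sample(peps, 1), 1, 7),
             paste(sample(standardAminoAcids(), 2, TRUE), collapse = ""))
    md <- sample(5:9, 1)
    got <- findSimilar(q, idx, minDos = md, queryGenes = "query-gene")
    want <- oracleSimilar(q, peps, md)
    expect_setequal(got$peptide, want$peptide)
    expect_equal(got$dos[order(got$peptide)],
                 want$dos[order(want$peptide)])
  }
})

test_that("important-position overlap counts the intersection used by the masking gate", {
  p <- dosPositions("SLSVMSSNV", "MLAVMSYNT")
  expect_equal(p, c(2L, 4L, 5L, 6L, 8L))
  expect_equal(importantOverlap(p, c(4L, 5L, 8L)), 3L)
  expect_equal(importantOverlap(p, integer(0)), 0L)
  expect_equal(importantOverlap(p, 1:9), dos("SLSVMSSNV", "MLAVMSYNT"))
  # vectorized over hit lists
  expect_equal(importantOverlap(list(p, integer(0)), c(4L, 5L, 8L)),
               c(3L, 0L))
})
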