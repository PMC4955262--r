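test_that("percentile uses linear interpolation and matches the brute-force oracle", {
  expect_equal(expressionPercentile(c(1, 2, 3, 4), 75), 3.25)
  expect_equal(expressionPercentile(rep(7, 5), 33), 7)
  expect_equal(expressionPercentile(c(0, 10), 50), 5)
  expect_equal(expressionPercentile(c(3, 1, 2), 0), 1)
  expect_equal(expressionPercentile(c(3, 1, 2), 100), 3)
  expect_error(expressionPercentile(numeric(0), 50), "empty")
  expect_error(expressionPercentile(c(1, NA), 50), "finite")
  expect_error(expressionPercentile(1:3, 101), "\\[0, 100\\]")

  set.seed(21)
  for (i in 1:1000) {
    v <- runif(sample(1:40, 1), 0, 100)
    q <- runif(1, 0, 100)
    expect_equal(expressionPercentile(v, q), oraclePercentile(v, q),
                 tolerance = 1e-9)
  }
})

test_that("summaries cover every (gene, group), are order-invariant, and aggregate duplicate genes by max", {
  groups <- data.frame(group = c("SKCM", "brain"), is_cancer = c(TRUE, FALSE),
                       is_essential = c(NA, TRUE), n = c(4, 4))
  se <- makeTinySE(list(G1 = list(SKCM = c(1, 2, 3, 4), brain = 7),
                        G2 = list(SKCM = 0, brain = c(0, 1, 2, 10))),
                   groups)
  s <- summarizeExpression(se)
  expect_equal(nrow(s), 4L)
  expect_equal(s$p75[s$gene == "G1" & s$group == "SKCM"], 3.25)
  expect_equal(s$p75[s$gene == "G1" & s$group == "brain"], 7)
  expect_equal(s$p95[s$gene == "G1" & s$group == "brain"], 7)

  # permuting samples leaves every summary unchanged
  se2 <- se[, sample(ncol(se))]
  s2 <- summarizeExpression(se2)
  key <- function(x) x[order(x$gene, x$group), c("p75", "p95", "n_samples")]
  expect_equal(key(as.data.frame(s2)), key(as.data.frame(s)),
               ignore_attr = TRUE)

  # duplicate gene rows collapse by element-wise max before percentiles
  m <- SummarizedExperiment::assay(se, "rpkm")
  m2 <- rbind(m, G1 = m["G2", ])
  rownames(m2) <- c("G1", "G2", "G1")
  se3 <- makeExpressionSE(m2, as.data.frame(SummarizedExperiment::colData(se)))
  s3 <- summarizeExpression(se3)
  # element-wise max of the duplicate rows, then the percentile
  agg <- pmax(m["G1", 5:8], m["G2", 5:8])
  expect_equal(s3$p95[s3$gene == "G1" & s3$group == "brain"],
               oraclePercentile(agg, 95))
})

test_that("multi-gene peptides aggregate by max and missing genes degrade gracefully", {
  groups <- data.frame(group = c("SKCM", "brain"), is_cancer = c(TRUE, FALSE),
                       is_essential = c(NA, TRUE), n = c(3, 3))
  se <- makeTinySE(list(G1 = list(SKCM = 2, brain = 0.1),
                        G2 = list(SKCM = 8, brain = 0.2)), groups)
  s <- summarizeExpression(se)
  v1 <- geneGroupStat("G1", s, "p75")
  expect_equal(v1$value[v1$group == "SKCM"], 2)
  v <- geneGroupStat(c("G1", "G2"), s, "p75")
  expect_equal(v$value[v$group == "SKCM"], 8)
  expect_warning(v2 <- geneGroupStat(c("G1", "GHOST"), s, "p75"), "GHOST")
  expect_equal(v2$value[v2$group == "SKCM"], 2)
  expect_error(geneGroupStat("GHOST", s, "p75", context = "KVAELVHFL"),
               "KVAELVHFL")
})

test_that("cancer-specificity and off-target rules apply strict thresholds and the essential-tissue partition", {
  groups <- data.frame(
    group = c("DLBC", "brain", "liver", "testis"),
    is_cancer = c(TRUE, FALSE, FALSE, FALSE),
    is_essential = c(NA, TRUE, TRUE, FALSE), n = rep(3, 4))
  se <- makeTinySE(list(
    SPEC  = list(DLBC = 6.57, brain = 0.1, liver = 0.1, testis = 40),
    EDGE1 = list(DLBC = 5.0, brain = 0.1, liver = 0.1, testis = 0),
    EDGE2 = list(DLBC = 9, brain = 0.5, liver = 0.1, testis = 0),
    OFFT  = list(DLBC = 0.1, brain = 0.6, liver = 0, testis = 0),
    QUIET = list(DLBC = 0.1, brain = 0, liver = 0, testis = 50)), groups)
  s <- summarizeExpression(se)

  expect_true(isCancerSpecific("SPEC", "DLBC", s))     # testis high is fine
  expect_false(isCancerSpecific("EDGE1", "DLBC", s))   # tumor p75 == 5.0
  expect_false(isCancerSpecific("EDGE2", "DLBC", s))   # normal p75 == 0.5
  expect_error(isCancerSpecific("SPEC", "GBM", s), "GBM")

  expect_false(offtargetExpressed("QUIET", s))  # testis-only, non-essential
  expect_true(offtargetExpressed("OFFT", s))    # brain p95 = 0.6 > 0.5
  expect_false(offtargetExpressed("EDGE1", s))  # all essential at/below cut

  tiss <- expressingTissues("OFFT", s)
  expect_equal(as.character(tiss$tissue), "brain")
})

test_that("planted-gene recovery and threshold monotonicity hold on random matrices", {
  set.seed(31)
  groups <- data.frame(
    group = c("SKCM", "LAML", "brain", "liver"),
    is_cancer = c(TRUE, TRUE, FALSE, FALSE),
    is_essential = c(NA, NA, TRUE, TRUE), n = rep(8, 4))
  vals <- list()
  planted <- paste0("P", 1:5)
  for (g in planted)
    vals[[g]] <- list(SKCM = 6 + runif(8, 0, 4), LAML = runif(8, 0, 0.2),
                      brain = runif(8, 0, 0.2), liver = runif(8, 0, 0.2))
  for (g in paste0("N", 1:10))
    vals[[g]] <- list(SKCM = runif(8, 0, 3), LAML = runif(8, 0, 3),
                      brain = runif(8, 0.5, 3), liver = runif(8, 0.5, 3))
  s <- summarizeExpression(makeTinySE(vals, groups))
  hits <- names(vals)[vapply(names(vals), isCancerSpecific, logical(1),
                             cancerType = "SKCM", summaries = s)]
  expect_setequal(hits, planted)

  # raising tumorCut only removes; raising normalCut only adds
  for (g in names(vals)) {
    base <- isCancerSpecific(g, "SKCM", s)
    expect_true(!isCancerSpecific(g, "SKCM", s, tumorCut = 8) | base)
    expect_true(base | !isCancerSpecific(g, "SKCM", s, normalCut = 0.1))
  }
})
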