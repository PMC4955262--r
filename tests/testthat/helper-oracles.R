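# Independent oracles and small generators used across the suite. These are
# deliberately naive implementations, kept separate from the package's own
# code paths.

# position-by-position DoS, one pair at a time
oracleDos <- function(a, b) {
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# brute-force neighbor scan over a plain peptide vector
oracleSimilar <- function(query, peps, minDos) {
  d <- vapply(peps, oracleDos, integer(1), a = query)
  keep <- d >= minDos
  data.frame(peptide = unname(peps[keep]), dos = unname(d[keep]),
             stringsAsFactors = FALSE)
}

# sort-and-interpolate percentile at rank (n-1)q/100
oraclePercentile <- function(values, q) {
  v <- sort(unname(values))
  n <- length(v)
  if (n == 1) return(v)
  h <- (n - 1) * q / 100
  lo <- floor(h)
  v[lo + 1] + (h - lo) * (v[min(lo + 2, n)] - v[lo + 1])
}

# tie-corrected Mann-Whitney AUC for "higher score => more positive"
oracleRankAuc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(rank(scores)[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

randomPeptides <- function(n) {
  m <- matrix(sample(standardAminoAcids(), 9 * n, replace = TRUE), ncol = 9)
  apply(m, 1, paste, collapse = "")
}

# minimal FASTA writer for fixtures
writeFasta <- function(headers, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

writeManifest <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

makeAffinity <- function(peptide, ic50, allele = "HLA-A*02:01") {
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(peptide = peptide, ic50 = ic50), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  readAffinityTable(tsv, allele = allele)
}

# tiny expression experiment: genes x (groups x n) with explicit values
makeTinySE <- function(geneValues, groups) {
  # geneValues: named list gene -> named list group -> numeric vector
  meta <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    n <- groups$n[i]
    data.frame(sample_id = sprintf("%s_%02d", gsub("\\s", "", groups$group[i]),
                                   seq_len(n)),
               source = "synthetic", group = groups$group[i],
               is_cancer = groups$is_cancer[i],
               is_essential = groups$is_essential[i],
               stringsAsFactors = FALSE)
  }))
  m <- do.call(rbind, lapply(names(geneValues), function(g) {
    unlist(lapply(seq_len(nrow(groups)), function(i)
      rep_len(geneValues[[g]][[groups$group[i]]], groups$n[i])))
  }))
  rownames(m) <- names(geneValues)
  colnames(m) <- meta$sample_id
  makeExpressionSE(m, meta)
}
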