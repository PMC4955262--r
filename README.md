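# pepHLAtarget

Discovery and cross-reactivity prioritization of cancer-specific
peptide–HLA class I targets, for immunoinformaticians designing engineered
T-cell or TCR-like-antibody therapies.

Therapies against a peptide–HLA complex can be cross-reactive: a peptide
elsewhere in the proteome that matches the target at as few as 5 of 9
positions, binds the same allele, and is presented in essential normal
tissue can be recognized too — with clinically documented fatal outcomes
(the MAGEA3 peptide KVAELVHFL vs the MAGEA12 peptide KMAELVHFL; the
MAGEA3/Titin pair EVDPIGHLY vs ESDPIVAQY). `pepHLAtarget` finds candidate
targets in a proteome and ranks them by their predicted off-target burden
instead of assuming any target is clean.

## The method

For a 9-mer peptide *p* with source gene(s) *g* and allele *a*:

* **Binder:** predicted IC50(*p*, *a*) < 500 nM (strong if < 50 nM), strict
  inequalities.
* **Cancer-specific to type *c*:** p75 RPKM(*g*, *c*) > 5.0 and
  max over essential normal tissues *t* of p75 RPKM(*g*, *t*) < 0.5
  (reproductive tissues are non-essential and ignored — this is what lets
  cancer-testis antigens qualify).
* **Degree of similarity:** DoS(*p*, *q*) = #{i : p_i = q_i} = 9 − Hamming.
  Neighbor search is exact via a 5-block pigeonhole index (≤ 4 mismatches
  ⇒ one block matches verbatim).
* **Off-target of *p*:** any *q* with DoS ≥ 5 that binds *a* and whose gene
  has p95 RPKM > 0.5 in some essential normal tissue.
* **Prioritization:** ascending #off-targets at DoS ≥ 6, then at DoS ≥ 5,
  then descending tumor p75.
* **Importance masking (optional):** from peptide–HLA–TCR/antibody
  structures, position *i* is important if a side-chain atom has a van der
  Waals gap in [0.0, 0.4] Å to a partner atom or forms a hydrogen bond
  (D–A < 4 Å, D–H–A within 30° of linear when hydrogens exist). Unique
  contact patterns vote; positions with < 2 votes are non-important, and
  similar peptides sharing < 3 important positions with the target are
  discarded. The vote predictor is validated by structure-level
  leave-one-out ROC.

## Worked example

The package ships generators for a fully synthetic study with known
planted truth (no downloads needed):

```r
library(pepHLAtarget)

fx  <- genPipelineFixture(fixtureSpec(seed = 1))
res <- runTargetDiscovery(fx$index, fx$affinity, fx$summaries)
#> peptides indexed: 4852
#> binders (IC50 < 500 nM) in affinity table: 56
#> cancer-specific targets: 5 (5 unique peptides)
#> total off-targets attached: 12

as.data.frame(res$targets)[, c("rank","cancer_type","peptide","ic50_nM",
                               "tumor_p75","n_dos5","n_dos6")]
#>   rank cancer_type   peptide ic50_nM tumor_p75 n_dos5 n_dos6
#> 1    1        DLBC HLSPIDCEV   42.48      6.57      0      0
#> 2    2        LAML LTSMWSPAV  279.13      6.47      1      0
#> 3    3        SKCM SLSVMSSNV  265.87     19.91      3      0
#> 4    4        LIHC TQIGIEWNL  229.74     19.13      2      2
#> 5    5        SKCM KVAELVHFL  150.00     10.00      6      6
```

The rank-1 target is a lymphoma-specific peptide with *no* similar
expressed binder anywhere in the (synthetic) proteome; the clinically
problematic melanoma peptide KVAELVHFL lands last with 6 off-targets at
DoS ≥ 6, among them the documented MAGEA12 culprit:

```r
ot <- res$offtargets[["KVAELVHFL.SKCM"]]
data.frame(off.target = ot$peptide, DoS = ot$dos, IC50 = ot$ic50_nM,
           gene = sapply(as.list(ot$genes), paste, collapse = ";"),
           tissue = sapply(as.list(ot$tissues), function(x) x[1]))
#>   off.target DoS   IC50    gene         tissue
#> 1  KMAELVHFL   8   2.66 MAGEA12          brain
#> 2  KVAELVHIL   8 103.72   DDX28         muscle
#> 3  KVAELVQFL   8  46.07  MAGEC3          brain
#> 4  KLEELVHFL   7  11.98   MRVI1          blood
#> 5  SAAELVHFL   7 187.05  EPS8L2      esophagus
#> 6  SAADLVHFL   6 211.83    EPS8 adipose tissue
```

Each column reads: the similar peptide, its degree of similarity to the
target, its predicted binding affinity (nM), its source gene, and the top
essential normal tissue expressing that gene — i.e. where cross-reactive
toxicity would strike. `writeReports(res, "out/")` writes the target table,
per-target off-target tables and a JSON run summary; real studies feed
`readProteome()` / `readAffinityTable()` / `readExpressionMatrix()` with a
FASTA proteome, a NetMHC-style IC50 table and RPKM matrices (see
`inst/scripts/discover-targets.R` for a command-line front end, and the
vignette for the structural importance predictor).

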