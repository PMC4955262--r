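---
title: "Discovering cancer-specific peptide-HLA targets and ranking their off-target risk"
author: "pepHLAtarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cancer-specific peptide-HLA targets and ranking their off-target risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepHLAtarget)
```

## The problem

Engineered T-cells and TCR-like antibodies recognize a short peptide bound
in the groove of an HLA class I molecule. A peptide derived from a gene
that is highly expressed in tumors and silent in essential normal tissue is
an attractive therapeutic target — but clinical trials have shown that a
*different* peptide, similar to the target at as few as 5 of 9 positions
and presented by the same allele in healthy tissue, can be cross-recognized
with fatal consequences. `pepHLAtarget` implements the full discovery loop:
it finds candidate targets in a proteome and then ranks them by how many
such cross-reactive "off-targets" they carry, rather than pretending any
target is free of them.

## The procedure

Four stages, each with explicit, configurable thresholds
(`targetConfig()`):

1. **Peptide enumeration.** All overlapping 9-mers are extracted from the
   canonical protein set (`readProteome()`, `extract9mers()`). Windows
   containing any character outside the 20-letter standard alphabet are
   dropped; identical 9-mers merge into one index entry whose gene set is
   the union of its source genes. Only the most frequent HLA allele
   products are kept as proteome representatives
   (`filterHlaVariants()`), and lincRNA-derived entries are excluded.
   We restrict to 9-mers because they dominate class I epitopes for the
   allele of interest.

2. **Binding.** Predicted IC50 values (nanomolar) come from an external
   predictor's table (`readAffinityTable()`); the package deliberately
   does not re-implement a neural-network predictor, and ships a
   deterministic hash-based mock (`mockAffinity()`) for simulation. A
   peptide is a strong binder below 50 nM and a weak binder below
   500 nM, with strict inequalities at both cutoffs; any peptide under
   500 nM counts as a putative complex. The same 500 nM gate is applied
   to off-target candidates — every reported off-target is itself a
   predicted binder — and is configurable because it is an inference from
   the reported off-target lists rather than an explicitly stated rule.

3. **Cancer specificity.** Expression is summarized per gene and group as
   75th and 95th RPKM percentiles (`summarizeExpression()`). A peptide is
   specific to a cancer type when its gene's p75 exceeds 5.0 RPKM there
   while the *maximum* p75 over all **essential** normal tissues stays
   below 0.5 RPKM (`isCancerSpecific()`, both strict). The 5.0/0.5 pair
   brackets the RPKM range corresponding to roughly one transcript copy
   per cell. Reproductive tissues (breast, cervix, fallopian tube,
   testis, uterus, vagina) are classed non-essential and ignored, which
   is precisely what admits cancer-testis antigens. Normal samples from
   both compendium sources are pooled into a joint maximum; the source
   label is kept in the metadata so a per-source rule remains possible.

4. **Off-target search and prioritization.** The degree of similarity
   (DoS) between two 9-mers is the number of identical residues at
   identical positions, i.e. 9 minus the Hamming distance (`dos()`).
   `findSimilar()` returns every proteome peptide with DoS ≥ 5 — the
   similarity level at which clinical cross-reactivity has been observed —
   and an off-target is a similar peptide that also binds the allele and
   whose gene's p95 exceeds 0.5 RPKM in some essential normal tissue
   (`offtargetExpressed()`). Targets are ranked by ascending off-target
   count at DoS ≥ 6, then at DoS ≥ 5, then by descending tumor p75, with
   lexicographic tie-breaks so re-runs are byte-identical
   (`prioritizeTargets()`).

## The structural importance predictor

Counting every DoS ≥ 5 peptide overestimates risk: only positions engaged
by the TCR/antibody matter for cross-recognition. From each
peptide–HLA–TCR/antibody complex we derive a 9-position **contact
pattern** (`contactPattern()`): position *i* is important when

* a side-chain atom of residue *i* sits at a van der Waals surface gap
  $d - r_1 - r_2 \in [0.0, 0.4]$ Å of any partner-chain atom (backbone N,
  CA, C, O excluded; HLA chains never count as partners), or
* residue *i* forms a hydrogen bond with the partner: donor–acceptor
  distance < 4 Å between N/O atoms, and — when explicit hydrogens are
  present — a D–H–A geometry within 30° of linearity.

A literal donor–hydrogen–acceptor angle *below* 30° is geometrically
impossible for a hydrogen bond, so the angle criterion is implemented as
deviation-from-linearity (D–H–A ≥ 150°); this interpretation is logged
here prominently as a deliberate reading. Crystal structures usually lack
hydrogens, in which case the distance criterion alone decides — the
package never invents hydrogen placement. When hydrogens are present,
only atoms with an attached hydrogen may donate. Van der Waals radii
default to a Bondi-style element table (`bondiRadii()`), shipped as data
and overridable, because contact calls are sensitive to the radius set.

Duplicate patterns are collapsed (`uniquePatterns()`) and a position of a
query peptide is voted **non-important** when fewer than `voteThreshold`
unique patterns mark it important (`voteImportance()`). The default
threshold of 2 is the operating point where the predictor's false-positive
rate reaches zero: the positions it calls non-important are reliably so,
even though it cannot find all of them — the cautious direction for a
safety screen. With a profile in hand, a similar peptide is discarded
when it matches the target at fewer than 3 important positions
(`importantOverlap()`), since at least three peptide positions are
generally engaged by a TCR. Masking is optional per run: without usable
structures (e.g. for alleles with few crystal structures) the pipeline
runs in pure-DoS mode, and when a profile is supplied the reports carry
both masked and unmasked counts.

Validation is leave-one-out at the structure level (`looRoc()`): each
complex is held out, unique patterns are recomputed from the remainder
(or from pre-modeled structures of the held-out peptide for the
modeling-based variant, after discarding structures with residual steric
clashes), and every held-out position is scored by its vote count.
Truly non-important positions are the positive class; sweeping the vote
threshold yields a pooled ROC whose AUC is the trapezoidal area with
(0,0) and (1,1) appended. Because the sweep visits every distinct vote
count, the AUC coincides with the tie-corrected Mann–Whitney statistic of
the scores — a property the test suite checks against an independent
rank-statistic oracle to 1e-9. Externally modeled (mutated and
energy-minimized) structures are accepted as *input* for the
modeling-based predictor; the package does not perform side-chain
mutation or minimization itself.

## Numerical choices

* **Percentiles** use linear interpolation between order statistics at
  rank $(n-1)q/100$ (`stats::quantile` type 7, the common default of
  mainstream numerics libraries). The choice is documented and the
  functions are exported because genes sitting exactly at a threshold can
  flip under a different convention; all threshold comparisons are strict,
  so a gene *at* 5.0/0.5 RPKM never qualifies.
* **Geometry comparisons** carry a 1e-9 guard so an atom pair engineered
  to sit exactly on a configured bound (gap 0.4 Å, overlap 0.6 Å,
  distance 4.0 Å) is classified by the stated rule, not by floating-point
  representation.
* **Neighbor search** uses a pigeonhole block index: the 9 positions are
  split into 5 blocks (sizes 2,2,2,2,1), candidates are the union of
  exact-block matches, and every candidate is verified position by
  position. With DoS ≥ 5 there are at most 4 mismatches, so at least one
  block is shared verbatim — the index can have no false negatives, and
  the suite asserts set-equality against a naive scan on randomized
  indexes. Indexes below 2,000 peptides skip the block tables and scan
  linearly.
* **Self-hits:** a DoS = 9 match is excluded only when its occurrences
  are confined to the target's own gene(s); an identical peptide encoded
  elsewhere in the proteome is a legitimate off-target candidate.
  Expression of the target's own gene is already handled by the
  specificity filter.
* **Duplicate inputs:** duplicate peptides in an affinity table resolve to
  the minimum IC50 (with a warning), and duplicate gene rows in an
  expression matrix aggregate by element-wise maximum — both conservative
  toward off-target detection, as is the max-over-genes rule for peptides
  with several source genes.
* **Missing affinity records** are counted and treated as non-binders
  rather than errors, so upstream-filtered tables degrade gracefully.

## What the synthetic fixtures emulate — and what they do not

`fixtureSpec()` defines a miniature study whose defaults echo documented
biology: five planted targets (including a cancer-testis-antigen peptide
whose gene is high in testis and a clinically studied melanoma target),
twelve planted off-targets at DoS 5–8 from genes expressed in designated
essential tissues, and one planted *negative* — a similar binder whose
gene stays below 0.5 RPKM in every essential tissue and must therefore
never be reported. Generators verify their own guarantees after sampling
(`genProteome()` re-extracts the index and demands each planted peptide
occur exactly once in its own gene; `genExpression()` re-runs the
specificity and expression rules; `genToyStructure()` is an exact inverse
of `contactPattern()`) and redraw on violation, so tests assert planted
truth with zero tolerance. Ambient random peptides that happen to fall
within DoS ≥ 5 of a planted target are deterministically assigned
non-binder affinities so the planted structure is the exact answer.

These fixtures establish *correctness of the machinery*, not biological
performance: real proteomes have compositional bias and homologous gene
families (far more high-DoS neighbors than uniform random sequence), real
RPKM distributions are heavier-tailed than the log-normal blocks used
here, mock affinities carry no binding physics, and toy structures have
idealized geometry with single-atom side chains. Passing tests therefore
demonstrate that the filters, search and geometry kernels compute what
they claim — they say nothing about how many targets a real proteome
would yield.

Default problem sizes — 40-60 background proteins (≈5,000 indexed
9-mers), 12 samples per expression group, 10k-peptide random indexes for
the search-equivalence checks, 32-200 structures for the ROC checks —
were chosen as the smallest sizes at which every code path (block index,
percentile interpolation, vote sweep) is genuinely exercised.

## Limitations

Inherited from the strategy itself: only 9-mers and one allele at a time;
binding is as good as the external predictor's table; proteasomal
cleavage and TAP transport are not modeled; isoform and variant peptides
are outside the canonical proteome. The importance predictor is built
from the small set of available crystal structures and deliberately
overestimates importance (it only ever *discards* similar peptides that
are demonstrably mismatched at engaged positions). The package
accordingly never filters targets on predicted cross-reactivity — it only
prioritizes them.
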