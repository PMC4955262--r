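# Synthetic-fixture generators with verified planted truth: proteomes with
# embedded target/off-target peptides, expression matrices meeting the
# percentile thresholds by construction, deterministic affinity tables, and
# toy 3-chain structures realizing prescribed contact patterns. Every
# generator re-derives its guarantees with the corresponding analysis
# operation and redraws (bounded) on violation, so probabilistic
# construction yields deterministic contracts.

.defaultPlantedTargets <- function() {
  data.frame(
    peptide = c("HLSPIDCEV", "LTSMWSPAV", "SLSVMSSNV", "KVAELVHFL",
                "TQIGIEWNL"),
    gene = c("NLRP4", "UMODL1", "MAGEC2", "MAGEA3", "COX7B2"),
    cancer_type = c("DLBC", "LAML", "SKCM", "SKCM", "LIHC"),
    tumor_p75 = c(6.57, 6.47, 19.91, 10.0, 19.13),
    ic50 = c(42.48, 279.13, 265.87, 150.0, 229.74),
    stringsAsFactors = FALSE)
}

.defaultPlantedOfftargets <- function() {
  data.frame(
    target = c("LTSMWSPAV",
               "SLSVMSSNV", "SLSVMSSNV", "SLSVMSSNV",
               "KVAELVHFL", "KVAELVHFL", "KVAELVHFL", "KVAELVHFL",
               "KVAELVHFL", "KVAELVHFL",
               "TQIGIEWNL", "TQIGIEWNL"),
    peptide = c("LLKMWFPEV",
                "MLAVMSYNT", "MLYVMWKNV", "VLFVMWKNV",
                "KVAELVHIL", "KVAELVQFL", "KMAELVHFL", "SAAELVHFL",
                "KLEELVHFL", "SAADLVHFL",
                "SQIGIEWNL", "TQIGLEWNV"),
    gene = c("DNAH7", "SLC31A2", "OTOP2", "OTOP3", "DDX28", "MAGEC3",
             "MAGEA12", "EPS8L2", "MRVI1", "EPS8", "DNAH3", "ABCD1"),
    tissue = c("brain", "blood", "colon", "esophagus", "muscle", "brain",
               "brain", "esophagus", "blood", "adipose tissue", "lung",
               "liver"),
    ic50 = c(21.60, 206.18, 137.41, 276.13, 103.72, 46.07, 2.66, 187.05,
             11.98, 211.83, 60.0, 90.0),
    stringsAsFactors = FALSE)
}

# A similar binder whose gene stays below the essential-tissue expression
# cutoff: similar + binding, but never reported (expression gate).
.defaultPlantedNegatives <- function() {
  data.frame(target = "KVAELVHFL", peptide = "KVVSLVHFL", gene = "MAGEB18",
             ic50 = 100.0, stringsAsFactors = FALSE)
}

#' Specification of a synthetic study fixture
#'
#' Bundles everything the generators need: the planted cancer-specific
#' targets (peptide, source gene, cancer type, tumor p75, IC50), the
#' planted off-targets (peptide at a known DoS from its target, source
#' gene, the essential tissue expressing it, IC50), planted negatives
#' (similar binders whose genes are silent in essential tissue), the tissue
#' panel and per-group sample counts. Defaults emulate the study design:
#' lymphoma/leukemia/melanoma/liver cancer groups, a broad essential-tissue
#' panel from two pseudo-sources, reproductive tissues non-essential, and
#' planted peptides echoing clinically documented target/off-target pairs
#' (including a cancer-testis-antigen target whose gene is high in testis).
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param nBackgroundProteins Number of random background proteins.
#' @param proteinLengthRange Min/max background protein length.
#' @param targets,offtargets,negatives Planted-truth data.frames (see
#'   defaults for the schemas).
#' @param cancerGroups,essentialTissues,nonEssentialTissues Group panel.
#' @param samplesPerGroup Samples per expression group.
#' @param allele HLA allele name.
#' @return A list of class \code{fixtureSpec}.
#' @export
fixtureSpec <- function(seed = 1L, nBackgroundProteins = 40L,
                        proteinLengthRange = c(60L, 120L),
                        targets = .defaultPlantedTargets(),
                        offtargets = .defaultPlantedOfftargets(),
                        negatives = .defaultPlantedNegatives(),
                        cancerGroups = c("DLBC", "LAML", "SKCM", "LIHC",
                                         "BLCA"),
                        essentialTissues = c("brain", "muscle", "esophagus",
                                             "blood", "adipose tissue",
                                             "colon", "lung", "liver",
                                             "heart", "kidney"),
                        nonEssentialTissues = c("testis", "breast"),
                        samplesPerGroup = 12L, allele = "HLA-A*02:01") {
  .assertPeptide9(targets$peptide)
  .assertPeptide9(offtargets$peptide)
  if (nrow(negatives)) .assertPeptide9(negatives$peptide)
  stopifnot(all(offtargets$target %in% targets$peptide),
            all(offtargets$tissue %in% essentialTissues),
            all(targets$cancer_type %in% cancerGroups),
            samplesPerGroup >= 2L)
  d <- mapply(function(t, p) dos(t, p), offtargets$target, offtargets$peptide)
  if (any(d < 5L))
    stop("planted off-targets must have DoS >= 5 to their target",
         call. = FALSE)
  structure(list(seed = as.integer(seed),
                 nBackgroundProteins = as.integer(nBackgroundProteins),
                 proteinLengthRange = as.integer(proteinLengthRange),
                 targets = targets, offtargets = offtargets,
                 negatives = negatives, cancerGroups = cancerGroups,
                 essentialTissues = essentialTissues,
                 nonEssentialTissues = nonEssentialTissues,
                 samplesPerGroup = as.integer(samplesPerGroup),
                 allele = allele),
            class = "fixtureSpec")
}

.randomProtein <- function(len) {
  paste(sample(standardAminoAcids(), len, replace = TRUE), collapse = "")
}

.plantPeptide <- function(peptide, len) {
  flank <- len - 9L
  left <- sample.int(flank + 1L, 1L) - 1L
  paste0(.randomProtein(left), peptide, .randomProtein(flank - left))
}

#' Generate a synthetic proteome with embedded planted peptides
#'
#' Each planted target, off-target and negative peptide is embedded
#' verbatim in its own protein (named by its source gene), surrounded by
#' random standard-alphabet flanks; background proteins are fully random.
#' After generation the 9-mer index is rebuilt and checked: every planted
#' peptide must occur exactly once, in its own gene, and nowhere else;
#' violations trigger a logged redraw (bounded).
#'
#' @param spec A [fixtureSpec()].
#' @param maxTries Redraw bound.
#' @return A \linkS4class{ProteinSet}.
#' @export
genProteome <- function(spec, maxTries = 20L) {
  stopifnot(inherits(spec, "fixtureSpec"))
  planted <- rbind(
    data.frame(peptide = spec$targets$peptide, gene = spec$targets$gene),
    data.frame(peptide = spec$offtargets$peptide, gene = spec$offtargets$gene),
    if (nrow(spec$negatives))
      data.frame(peptide = spec$negatives$peptide, gene = spec$negatives$gene))
  if (anyDuplicated(planted$peptide))
    stop("planted peptides must be distinct", call. = FALSE)
  for (try in seq_len(maxTries)) {
    set.seed(spec$seed + (try - 1L) * 7919L)
    lens <- sample(seq(spec$proteinLengthRange[1], spec$proteinLengthRange[2]),
                   nrow(planted) + spec$nBackgroundProteins, replace = TRUE)
    seqs <- character(0)
    accs <- genes <- character(0)
    for (i in seq_len(nrow(planted))) {
      seqs <- c(seqs, .plantPeptide(planted$peptide[i], lens[i]))
      accs <- c(accs, paste0("SP_", planted$gene[i]))
      genes <- c(genes, planted$gene[i])
    }
    for (j in seq_len(spec$nBackgroundProteins)) {
      seqs <- c(seqs, .randomProtein(lens[nrow(planted) + j]))
      accs <- c(accs, sprintf("BGP%03d", j))
      genes <- c(genes, sprintf("BG%03d", j))
    }
    ps <- new("ProteinSet",
              sequences = Biostrings::AAStringSet(stats::setNames(seqs, accs)),
              meta = DataFrame(accession = accs, gene_symbol = genes,
                               is_hla_variant = FALSE,
                               allele_name = NA_character_,
                               is_lincRNA = FALSE))
    idx <- extract9mers(ps)
    occ <- occurrences(idx)
    ok <- all(vapply(seq_len(nrow(planted)), function(i) {
      hit <- occ[occ$peptide == planted$peptide[i], , drop = FALSE]
      nrow(hit) == 1L && hit$gene_symbol == planted$gene[i]
    }, logical(1)))
    if (ok) return(ps)
    message("planted-peptide collision in synthetic proteome; redrawing")
  }
  stop("could not generate a collision-free synthetic proteome", call. = FALSE)
}

# lognormal block scaled so a chosen percentile hits an exact value
.scaledBlock <- function(n, q, value, sdlog = 0.35) {
  v <- stats::rlnorm(n, 0, sdlog)
  v * value / stats::quantile(v, q / 100, type = 7, names = FALSE)
}

.lowBlock <- function(n) stats::rlnorm(n, log(0.05), 0.3)

#' Generate a synthetic expression matrix with planted truth
#'
#' Builds an RPKM matrix over the spec's cancer and normal groups:
#' background genes float around 1 RPKM everywhere; each planted target
#' gene is scaled so its 75th percentile in its cancer type equals the
#' planted value exactly while all essential normal tissues stay near 0.05
#' RPKM (and testis is high, the cancer-testis profile); each planted
#' off-target gene is scaled so its designated essential tissue's 95th
#' percentile is 20 RPKM while everything else stays low; planted negative
#' genes stay low in every essential tissue. All guarantees are re-checked
#' with [isCancerSpecific()] / [offtargetExpressed()] and violating genes
#' are redrawn (bounded).
#'
#' @param spec A [fixtureSpec()].
#' @param nBackgroundGenes Background genes to include beyond the planted
#'   ones (gene symbols \code{BG001}...), matching the proteome generator.
#' @param maxTries Redraw bound per verification round.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
genExpression <- function(spec, nBackgroundGenes = spec$nBackgroundProteins,
                          maxTries = 20L) {
  stopifnot(inherits(spec, "fixtureSpec"))
  set.seed(spec$seed + 104729L)
  groups <- data.frame(
    group = c(spec$cancerGroups, spec$essentialTissues,
              spec$nonEssentialTissues),
    is_cancer = c(rep(TRUE, length(spec$cancerGroups)),
                  rep(FALSE, length(spec$essentialTissues) +
                        length(spec$nonEssentialTissues))),
    is_essential = c(rep(NA, length(spec$cancerGroups)),
                     rep(TRUE, length(spec$essentialTissues)),
                     rep(FALSE, length(spec$nonEssentialTissues))),
    stringsAsFactors = FALSE)
  n <- spec$samplesPerGroup
  meta <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    data.frame(
      sample_id = sprintf("%s_S%02d", gsub("\\s", "", groups$group[g]),
                          seq_len(n)),
      source = ifelse(groups$is_cancer[g], "TCGA",
                      rep(c("GTEx", "TCGA"), length.out = n)),
      group = groups$group[g], is_cancer = groups$is_cancer[g],
      is_essential = groups$is_essential[g], stringsAsFactors = FALSE)
  }))
  genes <- c(spec$targets$gene, spec$offtargets$gene,
             if (nrow(spec$negatives)) spec$negatives$gene,
             sprintf("BG%03d", seq_len(nBackgroundGenes)))
  genes <- unique(genes)

  drawGene <- function(g) {
    v <- numeric(0)
    ti <- match(g, spec$targets$gene)
    oi <- which(spec$offtargets$gene == g)[1]
    for (k in seq_len(nrow(groups))) {
      grp <- groups$group[k]
      block <- if (!is.na(ti)) {
        if (grp == spec$targets$cancer_type[ti])
          .scaledBlock(n, 75, spec$targets$tumor_p75[ti])
        else if (grp == "testis") .scaledBlock(n, 75, 30)
        else .lowBlock(n)
      } else if (!is.na(oi)) {
        if (grp == spec$offtargets$tissue[oi]) .scaledBlock(n, 95, 20)
        else .lowBlock(n)
      } else if (g %in% spec$negatives$gene) {
        if (grp == "testis") .scaledBlock(n, 75, 30) else .lowBlock(n)
      } else {
        stats::rlnorm(n, 0, 0.5)  # background: ~1 RPKM everywhere
      }
      v <- c(v, block)
    }
    v
  }

  m <- t(vapply(genes, drawGene, numeric(nrow(meta))))
  dimnames(m) <- list(genes, meta$sample_id)
  se <- makeExpressionSE(m, meta)

  for (round in seq_len(maxTries)) {
    summ <- summarizeExpression(se)
    bad <- character(0)
    for (i in seq_len(nrow(spec$targets))) {
      g <- spec$targets$gene[i]
      if (!isCancerSpecific(g, spec$targets$cancer_type[i], summ)) bad <- c(bad, g)
    }
    nonTarget <- setdiff(genes, spec$targets$gene)
    for (g in nonTarget) {
      spec_any <- any(vapply(spec$cancerGroups, function(ct)
        isCancerSpecific(g, ct, summ), logical(1)))
      if (spec_any) bad <- c(bad, g)
    }
    for (g in unique(spec$offtargets$gene))
      if (!offtargetExpressed(g, summ)) bad <- c(bad, g)
    for (g in spec$negatives$gene)
      if (offtargetExpressed(g, summ)) bad <- c(bad, g)
    if (length(bad) == 0L) return(se)
    message("redrawing ", length(bad), " gene(s) violating planted guarantees")
    for (g in unique(bad)) m[g, ] <- drawGene(g)
    se <- makeExpressionSE(m, meta)
  }
  stop("could not realize planted expression guarantees", call. = FALSE)
}

#' Generate a deterministic affinity table honoring the planted truth
#'
#' Planted targets, off-targets and negatives receive their planted IC50
#' values; every other indexed peptide receives the deterministic
#' [mockAffinity()] value - except that a non-planted peptide which (a)
#' shares a source gene with a planted target or (b) lies within DoS >= 5
#' of any planted target is forced into the non-binder range (>= 500 nM,
#' still deterministic), so the planted structure is exactly what the
#' pipeline recovers.
#'
#' @param spec A [fixtureSpec()].
#' @param index The \linkS4class{ProteomeIndex} built from [genProteome()].
#' @return An \linkS4class{AffinityTable}.
#' @export
genAffinity <- function(spec, index) {
  stopifnot(inherits(spec, "fixtureSpec"), is(index, "ProteomeIndex"))
  peps <- peptides(index)
  ic50 <- mockAffinity(peps, spec$allele, spec$seed)
  planted <- c(stats::setNames(spec$targets$ic50, spec$targets$peptide),
               stats::setNames(spec$offtargets$ic50, spec$offtargets$peptide),
               if (nrow(spec$negatives))
                 stats::setNames(spec$negatives$ic50, spec$negatives$peptide))
  isPlanted <- peps %in% names(planted)
  ic50[isPlanted] <- planted[peps[isPlanted]]

  similarAny <- rep(FALSE, length(peps))
  for (t in spec$targets$peptide)
    similarAny <- similarAny | dos(t, peps) >= 5L
  targetGenes <- spec$targets$gene
  occ <- occurrences(index)
  pepsWithTargetGene <- unique(occ$peptide[occ$gene_symbol %in% targetGenes])
  force_non <- !isPlanted & (similarAny | peps %in% pepsWithTargetGene)
  if (any(force_non)) {
    h <- .hashString(paste0("nonbinder|", peps[force_non], "|", spec$seed))
    ic50[force_non] <- 500 + (h %% 49000) + 1
  }
  .makeAffinityTable(peps, ic50, spec$allele)
}

#' Build a toy complex structure realizing a prescribed contact pattern
#'
#' Constructs a 3-chain structure: a 9-residue peptide chain (backbone N,
#' CA, C, O plus one CB side-chain pseudo-atom per residue, residues 9
#' Angstrom apart), an inert 12-residue HLA chain far away, and a partner
#' chain with one carbon atom per important position placed at a van der
#' Waals gap of 0.2 Angstrom from that position's CB and more than 8
#' Angstrom from every other side-chain atom. By construction
#' [contactPattern()] with default geometry recovers the pattern exactly;
#' the seed applies a rigid rotation/translation, which leaves all contact
#' and clash calls unchanged.
#'
#' @param pattern Logical vector of length 9 (or integer positions) marking
#'   important positions.
#' @param structureId Identifier for the structure.
#' @param seed Optional integer; rigid-motion placement.
#' @return A \linkS4class{ComplexStructure}.
#' @export
#' @examples
#' toy <- genToyStructure(c(1, 5, 7))
#' which(contactPattern(toy))
genToyStructure <- function(pattern, structureId = "toy", seed = NULL) {
  if (is.numeric(pattern)) pattern <- seq_len(9L) %in% as.integer(pattern)
  stopifnot(is.logical(pattern), length(pattern) == 9L)
  rows <- list()
  addAtom <- function(chain, resno, resid, atom, element, x, y, z)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, atom = atom,
      element = element, x = x, y = y, z = z, stringsAsFactors = FALSE)
  for (i in 1:9) {
    x0 <- 9 * i
    addAtom("P", i, "ALA", "N", "N", x0 - 1.2, 0.9, 0)
    addAtom("P", i, "ALA", "CA", "C", x0, 0, 0)
    addAtom("P", i, "ALA", "C", "C", x0 + 1.2, 0.9, 0)
    addAtom("P", i, "ALA", "O", "O", x0 + 1.2, 2.1, 0)
    addAtom("P", i, "ALA", "CB", "C", x0, 1.5, 0)
  }
  imp <- which(pattern)
  if (length(imp)) {
    for (k in seq_along(imp)) {
      i <- imp[k]
      # gap 0.2: distance = rC + rC + 0.2 = 3.6 from the CB of position i
      addAtom("T", k, "LIG", "C1", "C", 9 * i, 1.5, 3.6)
    }
  } else {
    addAtom("T", 1L, "LIG", "C1", "C", 0, 1.5, 60)
  }
  for (j in 1:12) addAtom("H", j, "GLY", "CA", "C", 9 * j, -30, 0)
  atoms <- do.call(rbind, rows)
  if (!is.null(seed)) {
    h <- .hashString(paste0("rigid|", seed))
    ang <- (h %% 3600) / 3600 * 2 * pi
    ax <- ((h %/% 3600) %% 3) + 1L
    R <- diag(3)
    idx <- setdiff(1:3, ax)
    R[idx, idx] <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
    shift <- c((h %% 97) - 48, (h %% 89) - 44, (h %% 83) - 41) / 10
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, shift, "+")
    atoms[, c("x", "y", "z")] <- xyz
  }
  ComplexStructure(atoms, structureId, "P", "H", "T")
}

#' Toy structure exercising the hydrogen-bond criterion
#'
#' A 9-residue peptide chain plus a partner chain holding a single oxygen
#' acceptor at a chosen donor-acceptor distance from the backbone nitrogen
#' of residue 5, positioned away from all side chains so no hydrophobic
#' contact arises. \code{hydrogen} controls explicit-hydrogen handling:
#' \code{"none"} (distance-only), \code{"linear"} (H on the donor-acceptor
#' line: deviation 0), or \code{"bent"} (H perpendicular to it: deviation
#' far above any sensible cutoff).
#'
#' @param daDist Donor-acceptor distance in Angstrom.
#' @param hydrogen One of \code{"none"}, \code{"linear"}, \code{"bent"}.
#' @param structureId Identifier.
#' @return A \linkS4class{ComplexStructure}.
#' @export
genHbondToy <- function(daDist, hydrogen = c("none", "linear", "bent"),
                        structureId = "hbond-toy") {
  hydrogen <- match.arg(hydrogen)
  rows <- list()
  addAtom <- function(chain, resno, resid, atom, element, x, y, z)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, atom = atom,
      element = element, x = x, y = y, z = z, stringsAsFactors = FALSE)
  for (i in 1:9) {
    x0 <- 9 * i
    addAtom("P", i, "ALA", "N", "N", x0 - 1.2, 0.9, 0)
    addAtom("P", i, "ALA", "CA", "C", x0, 0, 0)
    addAtom("P", i, "ALA", "C", "C", x0 + 1.2, 0.9, 0)
    addAtom("P", i, "ALA", "O", "O", x0 + 1.2, 2.1, 0)
    addAtom("P", i, "ALA", "CB", "C", x0, 1.5, 0)
  }
  D <- c(9 * 5 - 1.2, 0.9, 0)  # backbone N of residue 5
  A <- c(D[1], D[2] - daDist, D[3])
  addAtom("T", 1L, "LIG", "O1", "O", A[1], A[2], A[3])
  if (hydrogen == "linear")
    addAtom("P", 5L, "ALA", "H", "H", D[1], D[2] - 1.0, D[3])
  else if (hydrogen == "bent")
    addAtom("P", 5L, "ALA", "H", "H", D[1], D[2], D[3] + 1.0)
  for (j in 1:12) addAtom("H", j, "GLY", "CA", "C", 9 * j, -30, 0)
  ComplexStructure(do.call(rbind, rows), structureId, "P", "H", "T")
}

#' Generate the full synthetic study fixture
#'
#' One call producing every pipeline input with consistent planted truth:
#' proteome, 9-mer index, affinity table, expression experiment and its
#' summaries.
#'
#' @param spec A [fixtureSpec()].
#' @return List with \code{proteins}, \code{index}, \code{affinity},
#'   \code{se}, \code{summaries}, and \code{spec}.
#' @export
genPipelineFixture <- function(spec = fixtureSpec()) {
  proteins <- genProteome(spec)
  index <- extract9mers(proteins)
  affinity <- genAffinity(spec, index)
  se <- genExpression(spec)
  summaries <- summarizeExpression(se)
  list(proteins = proteins, index = index, affinity = affinity, se = se,
       summaries = summaries, spec = spec)
}

#' Write the synthetic fixture to disk
#'
#' Emits FASTA, protein manifest, affinity TSV, expression matrix +
#' metadata TSVs and a truth JSON into a directory.
#'
#' @param fixture Output of [genPipelineFixture()].
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- fixture$proteins
  Biostrings::writeXStringSet(ps@sequences, file.path(dir, "proteome.fasta"))
  utils::write.table(as.data.frame(ps@meta), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- affinityRecords(fixture$affinity)
  utils::write.table(
    data.frame(peptide = rec$peptide, allele = affinityAllele(fixture$affinity),
               ic50 = rec$ic50_nM),
    file.path(dir, "affinity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  m <- SummarizedExperiment::assay(fixture$se, "rpkm")
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(fixture$se)),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(targets = fixture$spec$targets,
         offtargets = fixture$spec$offtargets,
         negatives = fixture$spec$negatives, seed = fixture$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
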