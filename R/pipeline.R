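# End-to-end orchestration: call cancer-specific targets, attach predicted
# off-targets, prioritize and write reports.

#' Pipeline configuration
#'
#' All thresholds of the target-discovery strategy in one place. Defaults
#' are the study's operating point: binder cutoffs 50/500 nM, tumor p75
#' threshold 5.0 RPKM, normal p75 threshold 0.5 RPKM, off-target p95
#' threshold 0.5 RPKM, minimum DoS 5, minimum important-position overlap 3,
#' vote threshold 2, and the reproductive-organ list as non-essential
#' tissues. The binder cutoff applies to both targets and off-target
#' candidates.
#'
#' @param allele HLA allele under study.
#' @param strongCut,weakCut IC50 cutoffs in nM ([classifyBinder()]).
#' @param tumorCut,normalCut RPKM p75 cutoffs ([isCancerSpecific()]).
#' @param offtargetCut RPKM p95 cutoff ([offtargetExpressed()]).
#' @param minDos Minimum degree of similarity for off-target candidates.
#' @param minImportantOverlap Minimum identical important positions for an
#'   off-target to be retained when an importance profile is used.
#' @param voteThreshold Vote cutoff for [voteImportance()].
#' @param nonEssentialTissues Normal tissues that may be sacrificed during
#'   therapy.
#' @return A list of class \code{targetConfig}.
#' @export
targetConfig <- function(allele = "HLA-A*02:01", strongCut = 50,
                         weakCut = 500, tumorCut = 5.0, normalCut = 0.5,
                         offtargetCut = 0.5, minDos = 5L,
                         minImportantOverlap = 3L, voteThreshold = 2L,
                         nonEssentialTissues = c("breast", "cervix",
                                                 "fallopian tube", "testis",
                                                 "uterus", "vagina")) {
  structure(list(allele = allele, strongCut = strongCut, weakCut = weakCut,
                 tumorCut = tumorCut, normalCut = normalCut,
                 offtargetCut = offtargetCut, minDos = as.integer(minDos),
                 minImportantOverlap = as.integer(minImportantOverlap),
                 voteThreshold = as.integer(voteThreshold),
                 nonEssentialTissues = nonEssentialTissues),
            class = "targetConfig")
}

#' Discover cancer-specific binder peptides
#'
#' A (peptide, cancer type) pair is a target candidate when the peptide
#' binds the allele (IC50 < \code{weakCut}) and its source genes pass the
#' cancer-specificity rule for that cancer type. Indexed peptides without
#' an affinity record are treated as non-binders (counted in a single
#' message, not an error). One candidate row is emitted per (peptide,
#' cancer type); the same peptide may be specific to several cancer types.
#'
#' @param index A \linkS4class{ProteomeIndex}.
#' @param affinity An \linkS4class{AffinityTable}.
#' @param summaries Output of [summarizeExpression()].
#' @param config A [targetConfig()].
#' @return \code{DataFrame}: \code{peptide}, \code{cancer_type},
#'   \code{allele}, \code{ic50_nM}, \code{tumor_p75}, \code{genes}
#'   (CharacterList).
#' @export
discoverTargets <- function(index, affinity, summaries,
                            config = targetConfig()) {
  peps <- peptides(index)
  ic50 <- affinityFor(affinity, peps)
  nMissing <- sum(is.na(ic50))
  if (nMissing > 0)
    message(sprintf("%d indexed peptide(s) lack affinity records; treated as non-binders",
                    nMissing))
  binders <- peps[!is.na(ic50) & ic50 < config$weakCut]
  cancerTypes <- unique(summaries$group[summaries$is_cancer])
  rows <- list()
  # gene-set level cache: specificity depends only on the gene set
  cache <- new.env(hash = TRUE)
  for (p in binders) {
    genes <- peptideGenes(index, p)
    key <- paste(genes, collapse = ";")
    spec <- get0(key, envir = cache)
    if (is.null(spec)) {
      v <- geneGroupStat(genes, summaries, "p75", context = p)
      ess <- which(!v$is_cancer & v$is_essential %in% TRUE)
      normalMax <- if (length(ess)) max(v$value[ess]) else Inf
      spec <- lapply(cancerTypes, function(ct) {
        i <- which(v$group == ct)
        ok <- length(i) == 1L && v$value[i] > config$tumorCut &&
          normalMax < config$normalCut
        list(ok = ok, p75 = if (length(i)) v$value[i] else NA_real_)
      })
      names(spec) <- cancerTypes
      assign(key, spec, envir = cache)
    }
    for (ct in cancerTypes) {
      if (spec[[ct]]$ok)
        rows[[length(rows) + 1L]] <- list(peptide = p, cancer_type = ct,
                                          p75 = spec[[ct]]$p75, genes = genes)
    }
  }
  if (length(rows) == 0L)
    return(DataFrame(peptide = character(0), cancer_type = character(0),
                     allele = character(0), ic50_nM = numeric(0),
                     tumor_p75 = numeric(0),
                     genes = IRanges::CharacterList()))
  DataFrame(
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    cancer_type = vapply(rows, `[[`, character(1), "cancer_type"),
    allele = affinityAllele(affinity),
    ic50_nM = affinityFor(affinity, vapply(rows, `[[`, character(1), "peptide")),
    tumor_p75 = vapply(rows, `[[`, numeric(1), "p75"),
    genes = IRanges::CharacterList(lapply(rows, `[[`, "genes")))
}

#' Attach predicted off-targets to a target peptide
#'
#' Off-targets pass four gates: similarity (DoS >= \code{minDos} to the
#' target), binding (IC50 < \code{weakCut}; missing records are
#' non-binders), expression (p95 > \code{offtargetCut} in some essential
#' normal tissue), and - when an importance profile is supplied - overlap
#' (at least \code{minImportantOverlap} identical positions among the
#' important ones). Each retained off-target carries its expressing
#' essential tissues sorted by decreasing p95.
#'
#' @param targetPeptide The target 9-mer.
#' @param targetGenes Source genes of the target (self-hit exclusion).
#' @param index,affinity,summaries,config As in [discoverTargets()].
#' @param profile Optional \code{importanceProfile} (or integer positions)
#'   for the overlap gate; \code{NULL} runs pure DoS mode.
#' @return \code{DataFrame}: \code{peptide}, \code{dos}, \code{ic50_nM},
#'   \code{genes}, \code{important_overlap} (NA without profile),
#'   \code{tissues}, \code{tissue_p95}.
#' @export
attachOfftargets <- function(targetPeptide, targetGenes, index, affinity,
                             summaries, profile = NULL,
                             config = targetConfig()) {
  hits <- findSimilar(targetPeptide, index, minDos = config$minDos,
                      queryGenes = targetGenes)
  empty <- DataFrame(peptide = character(0), dos = integer(0),
                     ic50_nM = numeric(0), genes = IRanges::CharacterList(),
                     important_overlap = integer(0),
                     tissues = IRanges::CharacterList(),
                     tissue_p95 = IRanges::NumericList())
  if (nrow(hits) == 0L) return(empty)
  ic50 <- affinityFor(affinity, hits$peptide)
  keep <- !is.na(ic50) & ic50 < config$weakCut
  hits <- hits[keep, , drop = FALSE]
  ic50 <- ic50[keep]
  if (nrow(hits) == 0L) return(empty)

  expr <- vapply(seq_len(nrow(hits)), function(i)
    offtargetExpressed(hits$genes[[i]], summaries, config$offtargetCut),
    logical(1))
  hits <- hits[expr, , drop = FALSE]
  ic50 <- ic50[expr]
  if (nrow(hits) == 0L) return(empty)

  overlap <- rep(NA_integer_, nrow(hits))
  if (!is.null(profile)) {
    impPos <- importantPositions(profile)
    overlap <- importantOverlap(hits$identical_positions, impPos)
    keep <- overlap >= config$minImportantOverlap
    hits <- hits[keep, , drop = FALSE]
    ic50 <- ic50[keep]
    overlap <- overlap[keep]
    if (nrow(hits) == 0L) return(empty)
  }
  tiss <- lapply(seq_len(nrow(hits)), function(i)
    expressingTissues(hits$genes[[i]], summaries, config$offtargetCut))
  DataFrame(peptide = hits$peptide, dos = hits$dos, ic50_nM = ic50,
            genes = hits$genes, important_overlap = overlap,
            tissues = IRanges::CharacterList(lapply(tiss, function(t) t$tissue)),
            tissue_p95 = IRanges::NumericList(lapply(tiss, function(t) t$p95)))
}

#' Prioritize targets by predicted cross-reactivity
#'
#' Stable sort by increasing number of off-targets at DoS >= 6, then at
#' DoS >= 5, then by decreasing tumor p75, with remaining ties broken
#' lexicographically by peptide; ranks 1..N are assigned in that order, so
#' the input order never affects the result.
#'
#' @param targets Target \code{DataFrame} (from [discoverTargets()])
#'   augmented with columns \code{n_dos5} and \code{n_dos6}.
#' @return The same \code{DataFrame} sorted, with a leading \code{rank}
#'   column.
#' @export
prioritizeTargets <- function(targets) {
  stopifnot(all(c("n_dos5", "n_dos6") %in% colnames(targets)))
  o <- order(targets$n_dos6, targets$n_dos5, -targets$tumor_p75,
             targets$peptide, targets$cancer_type)
  out <- targets[o, , drop = FALSE]
  res <- DataFrame(rank = seq_len(nrow(out)))
  cbind(res, out)
}

#' Run the full target-discovery pipeline
#'
#' Orchestrates discovery, off-target attachment, prioritization. When an
#' importance profile is supplied, off-target counts are reported both
#' masked (overlap gate applied) and unmasked; ranking uses the masked
#' counts since masking is the operative prediction.
#'
#' @inheritParams discoverTargets
#' @param profile Optional \code{importanceProfile}.
#' @param verbose Emit per-stage counts via \code{message}.
#' @return List with \code{targets} (prioritized \code{DataFrame} including
#'   \code{n_dos5}/\code{n_dos6} and, with a profile,
#'   \code{n_dos5_unmasked}/\code{n_dos6_unmasked}), \code{offtargets}
#'   (list keyed \code{peptide.cancer_type}), \code{counts} (stage counts),
#'   and \code{config}.
#' @export
runTargetDiscovery <- function(index, affinity, summaries, profile = NULL,
                               config = targetConfig(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("peptides indexed: %d", nPeptides(index))
  nBinders <- sum(affinityRecords(affinity)$ic50_nM < config$weakCut)
  say("binders (IC50 < %g nM) in affinity table: %d", config$weakCut, nBinders)
  targets <- discoverTargets(index, affinity, summaries, config)
  say("cancer-specific targets: %d (%d unique peptides)", nrow(targets),
      length(unique(targets$peptide)))
  offt <- list()
  n5 <- n6 <- n5u <- n6u <- integer(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    ot <- attachOfftargets(targets$peptide[i], targets$genes[[i]], index,
                           affinity, summaries, profile, config)
    key <- paste(targets$peptide[i], targets$cancer_type[i], sep = ".")
    offt[[key]] <- ot
    n5[i] <- nrow(ot)
    n6[i] <- sum(ot$dos >= 6L)
    if (!is.null(profile)) {
      otu <- attachOfftargets(targets$peptide[i], targets$genes[[i]], index,
                              affinity, summaries, NULL, config)
      n5u[i] <- nrow(otu)
      n6u[i] <- sum(otu$dos >= 6L)
    }
  }
  targets$n_dos5 <- n5
  targets$n_dos6 <- n6
  if (!is.null(profile)) {
    targets$n_dos5_unmasked <- n5u
    targets$n_dos6_unmasked <- n6u
  }
  say("total off-targets attached: %d", sum(n5))
  prioritized <- prioritizeTargets(targets)
  list(targets = prioritized, offtargets = offt,
       counts = list(n_peptides = nPeptides(index), n_binders = nBinders,
                     n_targets = nrow(targets),
                     n_unique_target_peptides = length(unique(targets$peptide)),
                     n_offtargets = sum(n5)),
       config = config)
}

#' Write pipeline reports
#'
#' Emits \code{targets.tsv} (rank, tumor, peptide, gene, IC50, RPKM.tumor,
#' Sim.5, Sim.6), one off-target TSV per target under \code{offtargets/}
#' (off.target, DoS, IC50, gene, top expressing tissues), and a JSON run
#' summary with the stage counts and configuration. Output is byte-stable
#' for fixed inputs and configuration.
#'
#' @param result Output of [runTargetDiscovery()].
#' @param dir Output directory (created if needed).
#' @param topTissues How many expressing tissues to print per off-target.
#' @return \code{dir}, invisibly.
#' @export
writeReports <- function(result, dir, topTissues = 4L) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  t <- result$targets
  df <- data.frame(
    rank = t$rank, tumor = t$cancer_type, peptide = t$peptide,
    gene = vapply(as.list(t$genes), paste, character(1), collapse = ";"),
    IC50 = t$ic50_nM, RPKM.tumor = t$tumor_p75,
    Sim.5 = t$n_dos5, Sim.6 = t$n_dos6, stringsAsFactors = FALSE)
  if ("n_dos5_unmasked" %in% colnames(t)) {
    df$Sim.5.unmasked <- t$n_dos5_unmasked
    df$Sim.6.unmasked <- t$n_dos6_unmasked
  }
  utils::write.table(df, file.path(dir, "targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  otdir <- file.path(dir, "offtargets")
  dir.create(otdir, showWarnings = FALSE)
  for (i in seq_len(nrow(t))) {
    key <- paste(t$peptide[i], t$cancer_type[i], sep = ".")
    ot <- result$offtargets[[key]]
    odf <- data.frame(
      off.target = ot$peptide, DoS = ot$dos, IC50 = ot$ic50_nM,
      gene = vapply(as.list(ot$genes), paste, character(1), collapse = ";"),
      important.overlap = ot$important_overlap,
      normal.tissues = vapply(as.list(ot$tissues), function(x)
        paste(utils::head(x, topTissues), collapse = ", "), character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(odf, file.path(otdir, paste0(key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(counts = result$counts,
                  config = result$config[setdiff(names(result$config), "")])
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
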