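#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' ProteinSet: canonical protein sequences with provenance flags
#'
#' Wraps an \link[Biostrings]{AAStringSet} together with a per-protein
#' metadata table (accession, gene symbol, HLA-variant and lincRNA-product
#' flags). The metadata flags come from a side manifest, not from header
#' heuristics, because FASTA header conventions vary by release.
#'
#' @slot sequences An \code{AAStringSet}, one entry per protein, named by
#'   accession.
#' @slot meta A \code{DataFrame} with columns \code{accession},
#'   \code{gene_symbol}, \code{is_hla_variant}, \code{allele_name},
#'   \code{is_lincRNA}.
#'
#' @seealso [readProteome()], [filterHlaVariants()], [extract9mers()]
#' @export
setClass("ProteinSet",
  representation(sequences = "AAStringSet", meta = "DataFrame"))

setValidity("ProteinSet", function(object) {
  msg <- character(0)
  need <- c("accession", "gene_symbol", "is_hla_variant", "allele_name",
            "is_lincRNA")
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, paste("meta must have columns:", paste(need, collapse = ", ")))
  else {
    if (length(object@sequences) != nrow(object@meta))
      msg <- c(msg, "sequences and meta must have the same length")
    if (anyDuplicated(object@meta$accession))
      msg <- c(msg, "accessions must be unique")
    if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
      msg <- c(msg, "sequences must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' ProteomeIndex: deduplicated 9-mer peptide index over a proteome
#'
#' Maps every distinct standard-alphabet 9-mer to its occurrences
#' (accession, gene symbol, 1-based start). Identical peptides from
#' different proteins are merged globally; a peptide's gene set is the union
#' of its source genes. The index carries a 5-block pigeonhole table used
#' for exact similarity search (any 9-mer pair with at most 4 mismatches
#' must agree on at least one of 5 position blocks).
#'
#' @slot peptides Character vector of distinct 9-mers, sorted.
#' @slot occurrences \code{DataFrame} with columns \code{peptide},
#'   \code{accession}, \code{gene_symbol}, \code{start}.
#' @slot nProteins Number of proteins indexed.
#' @slot blocks Internal pigeonhole lookup tables (may be empty for tiny
#'   indexes, where a linear scan is used instead).
#'
#' @seealso [extract9mers()], [findSimilar()], [peptideIndex()]
#' @export
setClass("ProteomeIndex",
  representation(peptides = "character", occurrences = "DataFrame",
                 nProteins = "integer", blocks = "listOrNULL"))

setValidity("ProteomeIndex", function(object) {
  msg <- character(0)
  need <- c("peptide", "accession", "gene_symbol", "start")
  if (!all(need %in% colnames(object@occurrences)))
    msg <- c(msg, paste("occurrences must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@peptides))
      msg <- c(msg, "peptides must be distinct")
    if (length(object@peptides) && !all(isValidPeptide9(object@peptides)))
      msg <- c(msg, "all peptides must be standard-alphabet 9-mers")
    if (!all(object@occurrences$peptide %in% object@peptides))
      msg <- c(msg, "every occurrence must reference an indexed peptide")
    if (!all(object@peptides %in% object@occurrences$peptide))
      msg <- c(msg, "every peptide must have at least one occurrence")
    if (nrow(object@occurrences) && any(object@occurrences$start < 1L))
      msg <- c(msg, "occurrence starts must be >= 1 (1-based)")
  }
  if (length(msg)) msg else TRUE
})

#' ComplexStructure: a peptide-HLA-TCR/antibody complex
#'
#' Atom table of a 3-role complex: a 9-residue peptide chain, the HLA
#' chain(s) (never counted as contact partners), and the TCR/antibody
#' partner chain(s). Coordinates are in Angstrom.
#'
#' @slot structureId Identifier (e.g. a PDB ID or fixture name).
#' @slot atoms \code{data.frame} with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{atom}, \code{element}, \code{x}, \code{y}, \code{z}.
#' @slot peptideChain Single chain id of the 9-mer peptide.
#' @slot hlaChains Chain ids of the HLA molecule (possibly empty).
#' @slot partnerChains Chain ids of the TCR/antibody (non-empty).
#'
#' @seealso [parseStructure()], [contactPattern()], [genToyStructure()]
#' @export
setClass("ComplexStructure",
  representation(structureId = "character", atoms = "data.frame",
                 peptideChain = "character", hlaChains = "character",
                 partnerChains = "character"))

setValidity("ComplexStructure", function(object) {
  msg <- character(0)
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z")
  if (!all(need %in% colnames(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      msg <- c(msg, "all coordinates must be finite")
    if (length(object@peptideChain) != 1L)
      msg <- c(msg, "exactly one peptide chain required")
    else {
      pep <- object@atoms[object@atoms$chain == object@peptideChain, ]
      if (length(unique(pep$resno)) != 9L)
        msg <- c(msg, sprintf("peptide chain '%s' must have exactly 9 residues (has %d)",
                              object@peptideChain, length(unique(pep$resno))))
    }
    if (length(object@partnerChains) < 1L)
      msg <- c(msg, "at least one partner (TCR/antibody) chain required")
    roles <- c(object@peptideChain, object@hlaChains, object@partnerChains)
    if (anyDuplicated(roles))
      msg <- c(msg, "chain roles must be disjoint")
    if (!all(roles %in% object@atoms$chain))
      msg <- c(msg, "every role chain must be present in the atom table")
  }
  if (length(msg)) msg else TRUE
})

#' AffinityTable: peptide-HLA binding-affinity predictions for one allele
#'
#' Holds predicted IC50 values (nanomolar) for 9-mer peptides against a
#' single HLA allele, with each peptide classified as a strong
#' (IC50 < 50 nM), weak (IC50 < 500 nM) or non-binder.
#'
#' @slot allele HLA allele name, e.g. \code{"HLA-A*02:01"}.
#' @slot records \code{DataFrame} with columns \code{peptide},
#'   \code{ic50_nM}, \code{binder_class}; one row per peptide.
#'
#' @seealso [readAffinityTable()], [classifyBinder()], [mockAffinity()]
#' @export
setClass("AffinityTable",
  representation(allele = "character", records = "DataFrame"))

setValidity("AffinityTable", function(object) {
  msg <- character(0)
  need <- c("peptide", "ic50_nM", "binder_class")
  if (length(object@allele) != 1L)
    msg <- c(msg, "exactly one allele per table")
  if (!all(need %in% colnames(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@records$peptide))
      msg <- c(msg, "duplicate peptides are not allowed")
    if (nrow(object@records) &&
        (any(!is.finite(object@records$ic50_nM)) || any(object@records$ic50_nM <= 0)))
      msg <- c(msg, "all IC50 values must be finite and > 0")
    if (!all(object@records$binder_class %in% c("strong", "weak", "non")))
      msg <- c(msg, "binder_class must be one of strong/weak/non")
  }
  if (length(msg)) msg else TRUE
})
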