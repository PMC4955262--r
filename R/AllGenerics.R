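#' @include AllClasses.R
NULL

#' Accessors for pepHLAtarget classes
#'
#' Small accessor generics: \code{accessions} and \code{geneSymbols} for a
#' \linkS4class{ProteinSet}; \code{peptides}, \code{nPeptides},
#' \code{occurrences} and \code{peptideGenes} for a
#' \linkS4class{ProteomeIndex}; \code{affinityAllele} and
#' \code{affinityRecords} for an \linkS4class{AffinityTable}.
#'
#' @param x An object of the relevant class.
#' @param peptide For \code{peptideGenes}, one 9-mer sequence.
#' @return Vectors or \code{DataFrame}s as described per accessor.
#' @name accessors
#' @aliases accessions geneSymbols peptides nPeptides occurrences
#'   peptideGenes affinityAllele affinityRecords
NULL

#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname accessors
#' @export
setGeneric("nPeptides", function(x) standardGeneric("nPeptides"))

#' @rdname accessors
#' @export
setGeneric("occurrences", function(x) standardGeneric("occurrences"))

#' @rdname accessors
#' @export
setGeneric("peptideGenes", function(x, peptide) standardGeneric("peptideGenes"))

#' @rdname accessors
#' @export
setGeneric("affinityAllele", function(x) standardGeneric("affinityAllele"))

#' @rdname accessors
#' @export
setGeneric("affinityRecords", function(x) standardGeneric("affinityRecords"))

#' @rdname accessors
setMethod("accessions", "ProteinSet", function(x) x@meta$accession)

#' @rdname accessors
setMethod("geneSymbols", "ProteinSet", function(x) x@meta$gene_symbol)

#' @rdname accessors
setMethod("peptides", "ProteomeIndex", function(x) x@peptides)

#' @rdname accessors
setMethod("nPeptides", "ProteomeIndex", function(x) length(x@peptides))

#' @rdname accessors
setMethod("occurrences", "ProteomeIndex", function(x) x@occurrences)

#' @rdname accessors
setMethod("peptideGenes", "ProteomeIndex", function(x, peptide) {
  stopifnot(length(peptide) == 1L)
  sort(unique(x@occurrences$gene_symbol[x@occurrences$peptide == peptide]))
})

#' @rdname accessors
setMethod("affinityAllele", "AffinityTable", function(x) x@allele)

#' @rdname accessors
setMethod("affinityRecords", "AffinityTable", function(x) x@records)

#' @describeIn ProteinSet Number of proteins.
#' @param x A \code{ProteinSet}.
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet with %d proteins (%d flagged HLA variants, %d lincRNA products)\n",
              length(object), sum(object@meta$is_hla_variant),
              sum(object@meta$is_lincRNA)))
})

setMethod("show", "ProteomeIndex", function(object) {
  cat(sprintf("ProteomeIndex: %d distinct 9-mers from %d proteins (%d occurrences)\n",
              length(object@peptides), object@nProteins,
              nrow(object@occurrences)))
})

setMethod("show", "ComplexStructure", function(object) {
  cat(sprintf(
    "ComplexStructure '%s': %d atoms | peptide chain %s | HLA %s | partner %s\n",
    object@structureId, nrow(object@atoms), object@peptideChain,
    if (length(object@hlaChains)) paste(object@hlaChains, collapse = ",") else "-",
    paste(object@partnerChains, collapse = ",")))
})

setMethod("show", "AffinityTable", function(object) {
  cls <- table(factor(object@records$binder_class,
                      levels = c("strong", "weak", "non")))
  cat(sprintf("AffinityTable for %s: %d peptides (%d strong, %d weak, %d non-binders)\n",
              object@allele, nrow(object@records), cls[["strong"]],
              cls[["weak"]], cls[["non"]]))
})
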