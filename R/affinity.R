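# Peptide-HLA binding-affinity tables and binder classification.
# Prediction itself is external (NetMHC-style output is consumed as a TSV);
# a deterministic mock stands in for tests and simulation.

#' Classify binding strength from predicted IC50
#'
#' Strong binder if IC50 < \code{strongCut} nM, weak binder if
#' \code{strongCut} <= IC50 < \code{weakCut} nM, non-binder otherwise.
#' Both comparisons are strict ("smaller than"), so 50 nM exactly is weak
#' and 500 nM exactly is a non-binder. The three classes partition
#' (0, Inf): every positive IC50 maps to exactly one class.
#'
#' @param ic50 Numeric vector of predicted IC50 values in nanomolar (> 0).
#' @param strongCut Strong-binder cutoff in nM. Default 50.
#' @param weakCut Weak-binder cutoff in nM. Default 500.
#' @return Character vector in \code{c("strong", "weak", "non")}.
#' @export
#' @examples
#' classifyBinder(c(42.48, 279.13, 500))
classifyBinder <- function(ic50, strongCut = 50, weakCut = 500) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 values must be finite and > 0", call. = FALSE)
  stopifnot(strongCut > 0, weakCut >= strongCut)
  ifelse(ic50 < strongCut, "strong", ifelse(ic50 < weakCut, "weak", "non"))
}

.makeAffinityTable <- function(peptide, ic50, allele, strongCut = 50,
                               weakCut = 500) {
  .assertPeptide9(peptide)
  rec <- DataFrame(peptide = peptide, ic50_nM = as.numeric(ic50),
                   binder_class = classifyBinder(ic50, strongCut, weakCut))
  rec <- rec[order(rec$peptide), , drop = FALSE]
  rownames(rec) <- NULL
  new("AffinityTable", allele = allele, records = rec)
}

#' Read a peptide-affinity TSV into an AffinityTable
#'
#' Expects a tab-separated file with a header row and at least columns
#' \code{peptide} and \code{ic50}; \code{allele} may be a column or supplied
#' as an argument. Duplicate peptides are resolved by keeping the minimum
#' IC50 (with a warning); rows with non-numeric IC50 abort with their line
#' numbers.
#'
#' @param path Path to the TSV.
#' @param allele HLA allele name; required if the file has no \code{allele}
#'   column. If the file has one, all rows must agree with it.
#' @param strongCut,weakCut Binder cutoffs passed to [classifyBinder()].
#' @return An \linkS4class{AffinityTable}.
#' @export
readAffinityTable <- function(path, allele = NULL, strongCut = 50,
                              weakCut = 500) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("peptide", "ic50")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("affinity table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("allele" %in% colnames(df)) {
    al <- unique(df$allele)
    if (length(al) != 1L)
      stop("affinity table mixes alleles: ", paste(al, collapse = ", "),
           call. = FALSE)
    if (!is.null(allele) && allele != al)
      stop(sprintf("requested allele '%s' but table is for '%s'", allele, al),
           call. = FALSE)
    allele <- al
  }
  if (is.null(allele))
    stop("allele must be supplied when the table has no allele column",
         call. = FALSE)
  ic50 <- suppressWarnings(as.numeric(df$ic50))
  bad <- which(!is.finite(ic50))
  if (length(bad))
    stop("non-numeric ic50 at line(s): ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  if (anyDuplicated(df$peptide)) {
    dup <- unique(df$peptide[duplicated(df$peptide)])
    warning(sprintf("%d duplicate peptide(s) resolved by minimum IC50: %s",
                    length(dup),
                    paste(utils::head(dup, 5L), collapse = ", ")),
            call. = FALSE)
    o <- order(df$peptide, ic50)
    keep <- o[!duplicated(df$peptide[o])]
    df <- df[keep, , drop = FALSE]
    ic50 <- ic50[keep]
  }
  .makeAffinityTable(df$peptide, ic50, allele, strongCut, weakCut)
}

#' Deterministic mock binding-affinity predictor
#'
#' A platform-stable stand-in for an external peptide-HLA affinity
#' predictor: IC50 values in (0, 50000] nM are derived from a polynomial
#' hash of (peptide, allele, seed), so the mapping is identical across
#' machines and RNG states, changes completely when the seed changes, and
#' generically differs between peptides.
#'
#' @param peptide Character vector of 9-mers.
#' @param allele HLA allele name. Default \code{"HLA-A*02:01"}.
#' @param seed Integer seed selecting the mapping.
#' @return Numeric vector of IC50 values in nanomolar.
#' @export
#' @examples
#' mockAffinity(c("KVAELVHFL", "SLLMWITQC"), seed = 7)
mockAffinity <- function(peptide, allele = "HLA-A*02:01", seed = 1L) {
  .assertPeptide9(peptide)
  h <- .hashString(paste(peptide, allele, as.integer(seed), sep = "|"))
  ((h + 1) / 2147483648) * 50000
}

#' Look up IC50 values for peptides
#'
#' @param table An \linkS4class{AffinityTable}.
#' @param peptide Character vector of peptides.
#' @return Numeric vector of IC50 values, \code{NA} where a peptide has no
#'   record.
#' @export
affinityFor <- function(table, peptide) {
  stopifnot(is(table, "AffinityTable"))
  table@records$ic50_nM[match(peptide, table@records$peptide)]
}
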