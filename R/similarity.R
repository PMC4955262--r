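# Degree of similarity (DoS) between 9-mers and exact neighbor search.
# DoS counts identical residues at identical positions, i.e. 9 minus the
# Hamming distance; two peptides are "similar" at DoS >= 5 (<= 4
# mismatches), the regime in which clinical cross-reactivity has been
# observed.

#' Degree of similarity between 9-mers
#'
#' \code{dos(a, b)} counts positions at which \code{a} and \code{b} carry
#' the same residue (symmetric, 0..9; 9 iff identical).
#' \code{dosPositions(a, b)} additionally returns the identical-position
#' set.
#'
#' @param a A single 9-mer.
#' @param b A character vector of 9-mers (\code{dosPositions} takes one).
#' @return \code{dos}: integer vector of DoS values. \code{dosPositions}:
#'   sorted integer vector of matching positions (1-based).
#' @export
#' @examples
#' dos("KVAELVHFL", c("KMAELVHFL", "SAADLVHFL")) # 8, 6
#' dosPositions("EVDPIGHLY", "ESDPIVAQY")
dos <- function(a, b) {
  .assertPeptide9(a, "query")
  .assertPeptide9(b, "candidate")
  stopifnot(length(a) == 1L)
  if (length(b) == 0L) return(integer(0))
  qc <- strsplit(a, "", fixed = TRUE)[[1]]
  m <- .charMatrix9(b)
  as.integer(rowSums(m == matrix(qc, nrow = nrow(m), ncol = 9L, byrow = TRUE)))
}

#' @rdname dos
#' @export
dosPositions <- function(a, b) {
  .assertPeptide9(a, "query")
  .assertPeptide9(b, "candidate")
  stopifnot(length(a) == 1L, length(b) == 1L)
  which(strsplit(a, "", fixed = TRUE)[[1]] == strsplit(b, "", fixed = TRUE)[[1]])
}

# Exact candidate generation via the pigeonhole block tables; with DoS >= 5
# every true hit shares at least one of the 5 blocks verbatim with the
# query, so the union of block matches has zero false negatives.
.blockCandidates <- function(query, index) {
  idx <- integer(0)
  for (k in seq_along(.BLOCK_BOUNDS)) {
    b <- .BLOCK_BOUNDS[[k]]
    key <- substr(query, b[1], b[2])
    hit <- index@blocks[[k]][[key]]
    if (!is.null(hit)) idx <- c(idx, hit)
  }
  unique(idx)
}

#' Find all proteome peptides similar to a query
#'
#' Returns exactly the indexed peptides with DoS >= \code{minDos} to the
#' query, each with its DoS, identical-position set and source genes.
#' Candidates are generated with the pigeonhole block index (exact for
#' \code{minDos} >= 5) and verified position by position; small indexes use
#' a plain linear scan. A DoS = 9 self-hit is excluded when its only
#' occurrences are the query's own source gene(s) and included otherwise
#' (an identical peptide elsewhere in the proteome is a legitimate
#' off-target candidate). Results are sorted by decreasing DoS, ties broken
#' lexicographically.
#'
#' @param query A single 9-mer.
#' @param index A \linkS4class{ProteomeIndex}.
#' @param minDos Minimum DoS, between 5 and 9. Default 5.
#' @param queryGenes Source genes of the query used for the self-hit rule;
#'   defaults to the query's own genes in the index (empty if absent).
#' @return \code{DataFrame} with columns \code{query}, \code{peptide},
#'   \code{dos}, \code{identical_positions} (an \code{IntegerList}) and
#'   \code{genes} (a \code{CharacterList}).
#' @export
#' @examples
#' idx <- peptideIndex(c("KMAELVHFL", "AAAAAAAAA"))
#' findSimilar("KVAELVHFL", idx, minDos = 5)
findSimilar <- function(query, index, minDos = 5L, queryGenes = NULL) {
  stopifnot(is(index, "ProteomeIndex"))
  .assertPeptide9(query, "query")
  if (minDos < 5L || minDos > 9L)
    stop("minDos must be between 5 and 9 (the pigeonhole index assumes <= 4 mismatches)",
         call. = FALSE)
  if (is.null(queryGenes))
    queryGenes <- if (query %in% index@peptides)
      peptideGenes(index, query) else character(0)

  peps <- index@peptides
  cand <- if (!is.null(index@blocks)) peps[.blockCandidates(query, index)]
          else peps
  if (length(cand) == 0L)
    return(.emptySimilarHits(query))
  d <- dos(query, cand)
  keep <- d >= minDos
  cand <- cand[keep]
  d <- d[keep]
  if (length(cand) == 0L)
    return(.emptySimilarHits(query))

  genes <- lapply(cand, function(p) peptideGenes(index, p))
  if (query %in% cand) {
    i <- which(cand == query)
    extra <- setdiff(genes[[i]], queryGenes)
    if (length(extra) == 0L) {
      cand <- cand[-i]; d <- d[-i]; genes <- genes[-i]
    } else {
      genes[[i]] <- extra
    }
  }
  if (length(cand) == 0L)
    return(.emptySimilarHits(query))
  o <- order(-d, cand)
  cand <- cand[o]; d <- d[o]; genes <- genes[o]
  DataFrame(query = query, peptide = cand, dos = d,
            identical_positions = IRanges::IntegerList(
              lapply(cand, function(p) dosPositions(query, p))),
            genes = IRanges::CharacterList(genes))
}

.emptySimilarHits <- function(query) {
  DataFrame(query = character(0), peptide = character(0), dos = integer(0),
            identical_positions = IRanges::IntegerList(),
            genes = IRanges::CharacterList())
}

#' Overlap between identical positions and important positions
#'
#' Counts how many of a similarity hit's identical positions fall on
#' positions classified as important for TCR/antibody binding. Downstream,
#' hits sharing fewer than 3 important positions with the target are
#' discarded (at least 3 peptide positions are generally engaged by a TCR).
#'
#' @param identicalPositions Integer vector, or list of integer vectors, of
#'   matching positions (subset of 1..9).
#' @param importantPositions Integer vector of important positions.
#' @return Integer count(s).
#' @export
#' @examples
#' importantOverlap(c(2, 4, 5, 6, 8), c(4, 5, 8)) # 3
importantOverlap <- function(identicalPositions, importantPositions) {
  if (is.list(identicalPositions) || is(identicalPositions, "List"))
    return(vapply(as.list(identicalPositions), function(p)
      length(intersect(p, importantPositions)), integer(1)))
  length(intersect(identicalPositions, importantPositions))
}

#' Write similarity hits as TSV
#'
#' Columns: query, peptide, dos, identical_positions (comma-joined), genes
#' (semicolon-joined).
#'
#' @param hits Output of [findSimilar()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSimilarHits <- function(hits, path) {
  df <- data.frame(
    query = hits$query, peptide = hits$peptide, dos = hits$dos,
    identical_positions = vapply(as.list(hits$identical_positions),
                                 paste, character(1), collapse = ","),
    genes = vapply(as.list(hits$genes), paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
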