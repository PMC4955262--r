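# Proteome ingestion and 9-mer enumeration.

#' Read a protein manifest
#'
#' The manifest is a TSV marking which FASTA records are HLA allele products
#' or lincRNA-derived entries. Columns: \code{accession}, \code{gene_symbol},
#' \code{is_hla_variant}, \code{allele_name}, \code{is_lincRNA}.
#'
#' @param path Path to the manifest TSV.
#' @return \code{data.frame} with the five manifest columns.
#' @export
readProteinManifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("accession", "gene_symbol", "is_hla_variant", "allele_name",
            "is_lincRNA")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m$is_hla_variant <- toupper(m$is_hla_variant) %in% c("TRUE", "T", "1", "YES")
  m$is_lincRNA <- toupper(m$is_lincRNA) %in% c("TRUE", "T", "1", "YES")
  m[, need]
}

.parseFastaHeaders <- function(headers) {
  first <- sub("\\s.*$", "", headers)
  acc <- ifelse(grepl("^(sp|tr)\\|", first),
                vapply(strsplit(first, "|", fixed = TRUE),
                       function(p) if (length(p) >= 2) p[2] else p[1],
                       character(1)),
                first)
  gn <- rep(NA_character_, length(headers))
  hit <- regexpr("GN=([^ ]+)", headers)
  has <- hit > 0
  gn[has] <- sub("^GN=", "", regmatches(headers, hit)[seq_len(sum(has))])
  list(accession = acc, gene = gn)
}

#' Read a proteome FASTA into a ProteinSet
#'
#' Parses canonical protein sequences (UniProtKB-style headers supported:
#' \code{sp|ACC|NAME ... GN=SYMBOL}). Sequences are uppercased; content is
#' otherwise preserved losslessly. HLA-variant and lincRNA-product flags are
#' taken from the side manifest; records flagged as lincRNA products are
#' excluded when \code{excludeLincRNA} is \code{TRUE}, since lincRNAs are
#' not known to be translated.
#'
#' @param fasta Path to a FASTA file (multi-line sequences allowed).
#' @param manifest Optional manifest \code{data.frame} (see
#'   [readProteinManifest()]) or path to one.
#' @param excludeLincRNA Drop records flagged \code{is_lincRNA}.
#'   Default \code{TRUE}.
#' @return A \linkS4class{ProteinSet}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 GN=GENE1", "MKVAELVHFLW", ">P2", "acdefghik"), fa)
#' readProteome(fa)
readProteome <- function(fasta, manifest = NULL, excludeLincRNA = TRUE) {
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta),
                   error = function(e) stop(sprintf(
                     "malformed FASTA '%s': %s", fasta, conditionMessage(e)),
                     call. = FALSE))
  if (length(seqs) == 0)
    stop(sprintf("empty FASTA input: '%s'", fasta), call. = FALSE)
  hdr <- .parseFastaHeaders(names(seqs))
  if (anyDuplicated(hdr$accession))
    stop("duplicate accessions in FASTA: ",
         paste(unique(hdr$accession[duplicated(hdr$accession)]), collapse = ", "),
         call. = FALSE)
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(seqs) <- hdr$accession

  if (is.character(manifest)) manifest <- readProteinManifest(manifest)
  meta <- DataFrame(
    accession = hdr$accession,
    gene_symbol = ifelse(is.na(hdr$gene), hdr$accession, hdr$gene),
    is_hla_variant = FALSE,
    allele_name = NA_character_,
    is_lincRNA = FALSE)
  if (!is.null(manifest)) {
    i <- match(meta$accession, manifest$accession)
    hit <- !is.na(i)
    meta$gene_symbol[hit] <- ifelse(nzchar(manifest$gene_symbol[i[hit]]),
                                    manifest$gene_symbol[i[hit]],
                                    meta$gene_symbol[hit])
    meta$is_hla_variant[hit] <- manifest$is_hla_variant[i[hit]]
    meta$allele_name[hit] <- ifelse(nzchar(manifest$allele_name[i[hit]]),
                                    manifest$allele_name[i[hit]], NA_character_)
    meta$is_lincRNA[hit] <- manifest$is_lincRNA[i[hit]]
  }
  if (excludeLincRNA && any(meta$is_lincRNA)) {
    keep <- !meta$is_lincRNA
    seqs <- seqs[keep]
    meta <- meta[keep, , drop = FALSE]
  }
  new("ProteinSet", sequences = seqs, meta = meta)
}

#' Keep only the most frequent HLA allele products
#'
#' The reviewed proteome contains one entry per HLA allele; only the alleles
#' with the highest population frequency are kept as representative
#' (defaults: HLA-A*02, HLA-B*07, HLA-C*07, HLA-DRB1*15). Non-HLA records
#' are untouched. An allele name in \code{keepAlleles} matches a manifest
#' allele either exactly or as a group prefix (\code{"HLA-A*02"} keeps
#' \code{"HLA-A*02:01"}).
#'
#' @param proteins A \linkS4class{ProteinSet}.
#' @param keepAlleles Character vector of allele names to retain.
#' @return A filtered \linkS4class{ProteinSet}.
#' @export
filterHlaVariants <- function(proteins,
                              keepAlleles = c("HLA-A*02", "HLA-B*07",
                                              "HLA-C*07", "HLA-DRB1*15")) {
  stopifnot(is(proteins, "ProteinSet"))
  meta <- proteins@meta
  if (!any(meta$is_hla_variant)) return(proteins)
  alleles <- meta$allele_name
  matched <- rep(FALSE, nrow(meta))
  for (k in keepAlleles) {
    matched <- matched |
      (!is.na(alleles) & (alleles == k | startsWith(alleles, paste0(k, ":"))))
  }
  present <- unique(alleles[meta$is_hla_variant & !is.na(alleles)])
  absent <- keepAlleles[!vapply(keepAlleles, function(k) {
    any(present == k | startsWith(present, paste0(k, ":")))
  }, logical(1))]
  if (length(absent))
    warning("keep list references alleles absent from the manifest: ",
            paste(absent, collapse = ", "), call. = FALSE)
  keep <- !meta$is_hla_variant | matched
  new("ProteinSet", sequences = proteins@sequences[keep],
      meta = meta[keep, , drop = FALSE])
}

.BLOCK_BOUNDS <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L), c(9L, 9L))

# Pigeonhole tables: for each of 5 position blocks, an environment mapping
# the block substring to the indices of peptides carrying it. With <= 4
# mismatches (DoS >= 5) at least one block is shared exactly, so the union
# of block matches is a superset of all true hits.
.buildBlocks <- function(peps) {
  lapply(.BLOCK_BOUNDS, function(b) {
    key <- substr(peps, b[1], b[2])
    list2env(split(seq_along(peps), key), hash = TRUE,
             size = max(29L, length(peps)))
  })
}

# Threshold below which findSimilar() uses a plain linear scan.
.BLOCK_MIN_N <- 2000L

.newProteomeIndex <- function(occ, nProteins) {
  peps <- sort(unique(occ$peptide))
  blocks <- if (length(peps) >= .BLOCK_MIN_N) .buildBlocks(peps) else NULL
  new("ProteomeIndex", peptides = peps, occurrences = occ,
      nProteins = as.integer(nProteins), blocks = blocks)
}

#' Enumerate all candidate 9-mers of a proteome
#'
#' Slides a 9-residue window over every protein; windows containing any
#' non-standard character are dropped; identical 9-mers from different
#' proteins (or positions) merge into a single index entry with multiple
#' occurrences. Proteins shorter than 9 residues contribute nothing.
#' Positions are 1-based.
#'
#' @param proteins A \linkS4class{ProteinSet}.
#' @return A \linkS4class{ProteomeIndex}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1", "ACDEFGHIKL"), fa)
#' extract9mers(readProteome(fa))
extract9mers <- function(proteins) {
  stopifnot(is(proteins, "ProteinSet"))
  seqs <- as.character(proteins@sequences)
  meta <- proteins@meta
  parts <- vector("list", length(seqs))
  for (j in seq_along(seqs)) {
    s <- seqs[[j]]
    L <- nchar(s)
    if (L < 9L) next
    starts <- seq_len(L - 8L)
    w <- substring(s, starts, starts + 8L)
    ok <- isValidPeptide9(w)
    if (!any(ok)) next
    parts[[j]] <- data.frame(peptide = w[ok],
                             accession = meta$accession[j],
                             gene_symbol = meta$gene_symbol[j],
                             start = starts[ok],
                             stringsAsFactors = FALSE)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  occ <- if (length(parts)) do.call(rbind, parts) else
    data.frame(peptide = character(0), accession = character(0),
               gene_symbol = character(0), start = integer(0))
  occ <- DataFrame(occ)
  .newProteomeIndex(occ, length(proteins))
}

#' Build a ProteomeIndex directly from a peptide vector
#'
#' Convenience constructor for benchmarking and simulation: each peptide is
#' given a synthetic single occurrence (or the supplied gene labels).
#'
#' @param peps Character vector of 9-mers (duplicates collapse).
#' @param genes Optional gene symbol per peptide; defaults to one synthetic
#'   gene per distinct peptide.
#' @return A \linkS4class{ProteomeIndex}.
#' @export
peptideIndex <- function(peps, genes = NULL) {
  .assertPeptide9(peps)
  if (is.null(genes))
    genes <- paste0("GENE", match(peps, unique(peps)))
  stopifnot(length(genes) == length(peps))
  occ <- DataFrame(peptide = peps, accession = paste0("SYN", seq_along(peps)),
                   gene_symbol = genes, start = 1L)
  .newProteomeIndex(occ, length(unique(occ$accession)))
}

#' Write / read a peptide index as TSV
#'
#' The on-disk form has one row per peptide with semicolon-joined gene
#' symbols and an occurrence list \code{accession|gene|start;...}; the
#' round trip reproduces the index exactly.
#'
#' @param index A \linkS4class{ProteomeIndex}.
#' @param path Output (input) TSV path.
#' @return \code{writePeptideIndex} returns \code{path} invisibly;
#'   \code{readPeptideIndex} returns a \linkS4class{ProteomeIndex}.
#' @export
writePeptideIndex <- function(index, path) {
  stopifnot(is(index, "ProteomeIndex"))
  occ <- as.data.frame(index@occurrences)
  occ <- occ[order(occ$peptide, occ$accession, occ$start), ]
  sp <- split(occ, occ$peptide)
  df <- data.frame(
    peptide = names(sp),
    gene_symbols = vapply(sp, function(d)
      paste(sort(unique(d$gene_symbol)), collapse = ";"), character(1)),
    occurrences = vapply(sp, function(d)
      paste(sprintf("%s|%s|%d", d$accession, d$gene_symbol, d$start),
            collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  hdr <- sprintf("# n_proteins=%d n_peptides=%d", index@nProteins,
                 length(index@peptides))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePeptideIndex
#' @export
readPeptideIndex <- function(path) {
  hdr <- readLines(path, n = 1L)
  nProt <- as.integer(sub(".*n_proteins=(\\d+).*", "\\1", hdr))
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    occ <- strsplit(df$occurrences[i], ";", fixed = TRUE)[[1]]
    f <- .charFields <- strsplit(occ, "|", fixed = TRUE)
    data.frame(peptide = df$peptide[i],
               accession = vapply(f, `[`, character(1), 1L),
               gene_symbol = vapply(f, `[`, character(1), 2L),
               start = as.integer(vapply(f, `[`, character(1), 3L)),
               stringsAsFactors = FALSE)
  })
  occ <- DataFrame(do.call(rbind, rows))
  .newProteomeIndex(occ, nProt)
}
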