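# RPKM expression summaries and the cancer-specificity / off-target rules.
# Expression matrices live in a SummarizedExperiment with sample metadata in
# colData; summaries are per (gene, group) 75th/95th percentiles.

#' Inclusive linear-interpolation percentile
#'
#' Percentile by linear interpolation between order statistics at rank
#' (n - 1) * q / 100 (the common default of mainstream numerics libraries;
#' \code{stats::quantile} type 7). q = 0 gives the minimum, q = 100 the
#' maximum.
#'
#' @param values Non-empty numeric vector, all finite and >= 0.
#' @param q Percentile in [0, 100].
#' @return A single numeric value.
#' @export
#' @examples
#' expressionPercentile(c(1, 2, 3, 4), 75) # 3.25
expressionPercentile <- function(values, q) {
  if (length(values) == 0)
    stop("percentile of an empty vector is undefined", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  if (length(q) != 1L || !is.finite(q) || q < 0 || q > 100)
    stop("q must be a single value in [0, 100]", call. = FALSE)
  stats::quantile(values, q / 100, type = 7, names = FALSE)
}

.checkSampleMeta <- function(meta) {
  need <- c("sample_id", "source", "group", "is_cancer", "is_essential")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("sample metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(meta$group)) || any(is.na(meta$group)))
    stop("every sample must have a non-empty group", call. = FALSE)
  meta
}

#' Assemble an expression SummarizedExperiment
#'
#' @param values Gene x sample matrix of non-negative RPKM values with
#'   rownames (gene symbols) and colnames (sample ids).
#' @param meta \code{data.frame} of sample metadata: \code{sample_id},
#'   \code{source} (TCGA / GTEx / synthetic), \code{group} (cancer-type code
#'   or normal-tissue name), \code{is_cancer}, \code{is_essential} (normal
#'   tissues only; ignored for cancer samples).
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{rpkm}.
#' @export
makeExpressionSE <- function(values, meta) {
  meta <- .checkSampleMeta(meta)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("RPKM values must be finite and >= 0", call. = FALSE)
  i <- match(colnames(values), meta$sample_id)
  if (any(is.na(i)))
    stop("samples absent from metadata: ",
         paste(utils::head(colnames(values)[is.na(i)], 5L), collapse = ", "),
         call. = FALSE)
  meta <- meta[i, , drop = FALSE]
  rownames(meta) <- meta$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = values), colData = S4Vectors::DataFrame(meta))
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix TSV has gene symbols in the first column and one column per
#' sample; the metadata TSV has columns \code{sample_id}, \code{source},
#' \code{group}, \code{is_cancer}, \code{is_essential}.
#'
#' @param matrixPath Path to the expression TSV.
#' @param metaPath Path to the metadata TSV.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
readExpressionMatrix <- function(matrixPath, metaPath) {
  df <- utils::read.delim(matrixPath, stringsAsFactors = FALSE,
                          check.names = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  meta$is_cancer <- as.logical(meta$is_cancer)
  meta$is_essential <- as.logical(meta$is_essential)
  makeExpressionSE(m, meta)
}

#' Summarize expression per gene and group
#'
#' Computes the 75th- and 95th-percentile RPKM of every gene in every
#' sample group (cancer types and normal tissues are summarized
#' identically). Duplicate gene rows are aggregated by element-wise maximum
#' before summarizing (conservative toward off-target detection). Results
#' are invariant to sample order.
#'
#' @param se A \link[SummarizedExperiment]{SummarizedExperiment} from
#'   [makeExpressionSE()].
#' @return A \code{DataFrame} with columns \code{gene}, \code{group},
#'   \code{is_cancer}, \code{is_essential}, \code{p75}, \code{p95},
#'   \code{n_samples}.
#' @export
summarizeExpression <- function(se) {
  m <- SummarizedExperiment::assay(se, "rpkm")
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  if (anyDuplicated(rownames(m))) {
    g <- rownames(m)
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), g), function(i)
      apply(m[i, , drop = FALSE], 2, max)))
  }
  groups <- unique(meta$group)
  out <- lapply(groups, function(grp) {
    cols <- which(meta$group == grp)
    if (length(cols) == 0L) {
      warning(sprintf("group '%s' has no samples; omitted", grp),
              call. = FALSE)
      return(NULL)
    }
    isC <- unique(meta$is_cancer[cols])
    if (length(isC) != 1L)
      stop(sprintf("group '%s' mixes cancer and normal samples", grp),
           call. = FALSE)
    isE <- if (isC) NA else all(meta$is_essential[cols])
    sub <- m[, cols, drop = FALSE]
    qs <- t(apply(sub, 1, stats::quantile, probs = c(0.75, 0.95),
                  type = 7, names = FALSE))
    DataFrame(gene = rownames(m), group = grp, is_cancer = isC,
              is_essential = isE, p75 = unname(qs[, 1]),
              p95 = unname(qs[, 2]), n_samples = length(cols))
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Per-group expression of a (possibly multi-gene) peptide
#'
#' For a peptide mapping to several source genes, the value in each group is
#' the maximum over those genes of the group's summary statistic (p75 for
#' specificity tests, p95 for off-target tests) - the cautious aggregation.
#'
#' @param genes Character vector of source gene symbols.
#' @param summaries Output of [summarizeExpression()].
#' @param stat \code{"p75"} or \code{"p95"}.
#' @param context Label used in error messages (e.g. the peptide).
#' @return \code{DataFrame} with one row per group: \code{group},
#'   \code{is_cancer}, \code{is_essential}, \code{value}.
#' @export
geneGroupStat <- function(genes, summaries, stat = c("p75", "p95"),
                          context = NULL) {
  stat <- match.arg(stat)
  present <- genes %in% summaries$gene
  if (!any(present))
    stop(sprintf("no expression summary for gene(s) %s%s",
                 paste(genes, collapse = ", "),
                 if (is.null(context)) "" else paste0(" (", context, ")")),
         call. = FALSE)
  if (!all(present))
    warning("gene(s) absent from expression summaries: ",
            paste(genes[!present], collapse = ", "), call. = FALSE)
  sub <- summaries[summaries$gene %in% genes[present], , drop = FALSE]
  sp <- split(sub[[stat]], sub$group)
  first <- sub[!duplicated(sub$group), , drop = FALSE]
  val <- vapply(sp, max, numeric(1))[first$group]
  DataFrame(group = first$group, is_cancer = first$is_cancer,
            is_essential = first$is_essential, value = unname(val))
}

#' Cancer-specificity rule
#'
#' A peptide (via its source genes) is specific to a cancer type when its
#' 75th-percentile RPKM in that cancer type exceeds \code{tumorCut} and the
#' maximum 75th-percentile RPKM over all essential normal tissues is below
#' \code{normalCut}. Both inequalities are strict, so values exactly at a
#' cutoff fail. Non-essential tissues (reproductive organs by default) are
#' ignored, which is what lets cancer-testis antigens qualify.
#'
#' @param genes Source gene symbols of the peptide.
#' @param cancerType Cancer group code (must be present in the summaries).
#' @param summaries Output of [summarizeExpression()].
#' @param tumorCut Tumor p75 threshold in RPKM. Default 5.0 (roughly one
#'   transcript copy per cell).
#' @param normalCut Normal p75 threshold in RPKM. Default 0.5.
#' @return Single logical.
#' @export
isCancerSpecific <- function(genes, cancerType, summaries, tumorCut = 5.0,
                             normalCut = 0.5) {
  v <- geneGroupStat(genes, summaries, "p75")
  i <- which(v$group == cancerType)
  if (length(i) != 1L)
    stop(sprintf("cancer type '%s' not found in summaries", cancerType),
         call. = FALSE)
  ess <- which(!v$is_cancer & v$is_essential %in% TRUE)
  if (length(ess) == 0L)
    stop("summaries contain no essential normal tissue group", call. = FALSE)
  v$value[i] > tumorCut && max(v$value[ess]) < normalCut
}

#' Off-target expression rule
#'
#' A similar peptide is considered expressed (hence a potential toxicity
#' risk) when any essential normal tissue shows a 95th-percentile RPKM
#' strictly above \code{cut}. Non-essential tissues are ignored.
#'
#' @inheritParams isCancerSpecific
#' @param cut p95 threshold in RPKM. Default 0.5.
#' @return Single logical.
#' @export
offtargetExpressed <- function(genes, summaries, cut = 0.5) {
  v <- geneGroupStat(genes, summaries, "p95")
  ess <- which(!v$is_cancer & v$is_essential %in% TRUE)
  length(ess) > 0L && any(v$value[ess] > cut)
}

#' Essential normal tissues expressing a gene set
#'
#' @inheritParams offtargetExpressed
#' @return \code{DataFrame} of essential normal tissues with p95 > cut,
#'   sorted by decreasing p95; columns \code{tissue}, \code{p95}.
#' @export
expressingTissues <- function(genes, summaries, cut = 0.5) {
  v <- geneGroupStat(genes, summaries, "p95")
  v <- v[!v$is_cancer & v$is_essential %in% TRUE & v$value > cut, ,
         drop = FALSE]
  v <- v[order(-v$value, v$group), , drop = FALSE]
  DataFrame(tissue = v$group, p95 = v$value)
}
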