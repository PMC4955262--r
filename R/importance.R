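# Positional-importance prediction from contact patterns, and its
# leave-one-out ROC validation. A position of a query peptide is voted
# non-important when fewer than a threshold number of (unique) contact
# patterns mark it important.

#' Stack contact patterns into a matrix
#'
#' @param patterns A list of length-9 logical vectors (as returned by
#'   [contactPattern()]), or an already-formed logical matrix with 9
#'   columns.
#' @return Logical matrix, one row per structure, rownames = structure ids
#'   when available.
#' @export
patternMatrix <- function(patterns) {
  if (is.matrix(patterns)) {
    stopifnot(ncol(patterns) == 9L, is.logical(patterns))
    colnames(patterns) <- paste0("P", 1:9)
    return(patterns)
  }
  stopifnot(is.list(patterns), length(patterns) >= 1L)
  m <- do.call(rbind, lapply(patterns, as.logical))
  stopifnot(ncol(m) == 9L)
  ids <- vapply(seq_along(patterns), function(i) {
    id <- attr(patterns[[i]], "structureId")
    if (is.null(id)) paste0("structure", i) else id
  }, character(1))
  rownames(m) <- make.unique(ids)
  colnames(m) <- paste0("P", 1:9)
  m
}

#' Deduplicate contact patterns
#'
#' Collapses identical 9-position boolean vectors; the provenance
#' (contributing structure ids) of each unique pattern is retained in the
#' \code{provenance} attribute.
#'
#' @inheritParams patternMatrix
#' @return Logical matrix of unique patterns with attribute
#'   \code{provenance} (list of character vectors).
#' @export
uniquePatterns <- function(patterns) {
  m <- patternMatrix(patterns)
  if (nrow(m) == 0L)
    stop("no contact patterns supplied", call. = FALSE)
  key <- apply(m, 1, function(r) paste(as.integer(r), collapse = ""))
  keep <- !duplicated(key)
  u <- m[keep, , drop = FALSE]
  prov <- lapply(key[keep], function(k) rownames(m)[key == k])
  names(prov) <- rownames(u)
  attr(u, "provenance") <- prov
  u
}

#' Vote positional importance from a pattern set
#'
#' Position i is classified non-important when fewer than
#' \code{voteThreshold} of the (unique) patterns mark it important, and
#' important otherwise. Raising the threshold can only demote positions
#' (monotone). The default threshold of 2 is the operating point at which
#' the structure-based predictor attains a zero false-positive rate.
#'
#' @inheritParams patternMatrix
#' @param voteThreshold Non-negative integer vote cutoff. Default 2.
#' @param dedupe Deduplicate patterns before voting. Default \code{TRUE}.
#' @param method Label recorded in the profile (\code{"simple"} or
#'   \code{"modeling"}).
#' @return An \code{importanceProfile}: list with \code{important}
#'   (logical 9), \code{votes} (integer 9), \code{threshold},
#'   \code{nPatterns}, \code{method}.
#' @export
voteImportance <- function(patterns, voteThreshold = 2L, dedupe = TRUE,
                           method = c("simple", "modeling")) {
  method <- match.arg(method)
  stopifnot(voteThreshold >= 0)
  m <- if (dedupe) uniquePatterns(patterns) else patternMatrix(patterns)
  votes <- colSums(m)
  structure(list(important = votes >= voteThreshold,
                 votes = as.integer(votes),
                 threshold = as.integer(voteThreshold),
                 nPatterns = nrow(m), method = method),
            class = "importanceProfile")
}

#' @export
print.importanceProfile <- function(x, ...) {
  cat(sprintf("importanceProfile (%s, %d unique patterns, threshold %d)\n",
              x$method, x$nPatterns, x$threshold))
  cat("  important positions:",
      paste(importantPositions(x), collapse = ", "), "\n")
  invisible(x)
}

#' Important positions of an importance profile
#'
#' @param profile An \code{importanceProfile} from [voteImportance()], or a
#'   plain integer vector of positions (returned unchanged).
#' @return Integer vector, subset of 1..9.
#' @export
importantPositions <- function(profile) {
  if (is.numeric(profile)) return(sort(unique(as.integer(profile))))
  stopifnot(inherits(profile, "importanceProfile"))
  unname(which(profile$important))
}

#' Pooled ROC over position scores
#'
#' The ROC engine shared by the leave-one-out validation: positions carry a
#' vote score and a truth label; the positive class is "non-important" and
#' a position is predicted non-important when its score falls strictly
#' below the swept threshold. Counts are pooled over all positions; the
#' curve gets (0,0) and (1,1) appended and the AUC is the trapezoidal area.
#'
#' @param scores Numeric vector of vote counts (one per position).
#' @param isImportant Logical truth per position (\code{FALSE} =
#'   non-important = positive class).
#' @param thresholds Thresholds to sweep; default covers every distinct
#'   score plus both extremes.
#' @return List with \code{roc} (data.frame: threshold, TP, FP, TN, FN,
#'   TPR, FPR) and \code{auc}.
#' @export
positionRoc <- function(scores, isImportant, thresholds = NULL) {
  stopifnot(length(scores) == length(isImportant))
  pos <- !isImportant   # positive class: truly non-important
  if (!any(pos) || all(pos))
    stop("ROC undefined: need both important and non-important positions",
         call. = FALSE)
  if (is.null(thresholds))
    thresholds <- sort(unique(c(min(scores), unique(scores) + 1)))
  rows <- lapply(thresholds, function(t) {
    pred <- scores < t
    data.frame(threshold = t,
               TP = sum(pred & pos), FP = sum(pred & !pos),
               TN = sum(!pred & !pos), FN = sum(!pred & pos))
  })
  roc <- do.call(rbind, rows)
  roc$TPR <- roc$TP / (roc$TP + roc$FN)
  roc$FPR <- roc$FP / (roc$FP + roc$TN)
  fpr <- c(0, sort(roc$FPR), 1)
  tpr <- c(0, roc$TPR[order(roc$FPR, roc$TPR)], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Leave-one-out ROC of the importance predictors
#'
#' Each structure is held out in turn and every peptide position of the
#' held-out structure is scored by the number of unique patterns - from the
#' remaining structures (\code{predictor = "simple"}) or from pre-modeled
#' structures of the held-out peptide (\code{predictor = "modeling"}) -
#' that mark the position important. Sweeping the vote threshold yields the
#' pooled ROC; a position is predicted non-important when its vote count is
#' below the threshold, and truly non-important positions are the positive
#' class.
#'
#' For the modeling predictor, \code{modeled} maps each held-out structure
#' id to a list of \linkS4class{ComplexStructure} objects (externally
#' modeled and energy-minimized elsewhere); structures with residual
#' clashes are discarded before pattern extraction.
#'
#' @param patterns Contact patterns of the known complexes (list or
#'   matrix; see [patternMatrix()]), at least 2.
#' @param predictor \code{"simple"} or \code{"modeling"}.
#' @param modeled Named list of pre-modeled structure lists, required for
#'   the modeling predictor.
#' @param thresholds Vote thresholds to sweep; default 0..(max patterns + 1).
#' @param cfg [geometryConfig()] used when deriving patterns from modeled
#'   structures.
#' @return List with \code{roc} (pooled counts per threshold), \code{auc},
#'   \code{scores} and \code{truth} (per held-out position).
#' @export
looRoc <- function(patterns, predictor = c("simple", "modeling"),
                   modeled = NULL, thresholds = NULL,
                   cfg = geometryConfig()) {
  predictor <- match.arg(predictor)
  m <- patternMatrix(if (is.list(patterns)) patterns else patterns)
  if (nrow(m) < 2L)
    stop("leave-one-out needs at least 2 complexes", call. = FALSE)
  if (predictor == "modeling" && is.null(modeled))
    stop("the modeling predictor needs pre-modeled structures per held-out complex",
         call. = FALSE)
  scores <- numeric(0)
  truth <- logical(0)
  for (i in seq_len(nrow(m))) {
    votes <- if (predictor == "simple") {
      colSums(uniquePatterns(m[-i, , drop = FALSE]))
    } else {
      id <- rownames(m)[i]
      structs <- modeled[[id]]
      if (is.null(structs))
        stop(sprintf("no modeled structures supplied for '%s'", id),
             call. = FALSE)
      structs <- structs[!vapply(structs, detectClashes, logical(1),
                                 cfg = cfg)]
      if (length(structs) == 0L) {
        rep(0L, 9L)  # nothing survives clash filtering: no votes
      } else {
        colSums(uniquePatterns(lapply(structs, contactPattern, cfg = cfg)))
      }
    }
    scores <- c(scores, votes)
    truth <- c(truth, m[i, ])
  }
  if (is.null(thresholds))
    thresholds <- 0:(max(scores) + 1L)
  res <- positionRoc(scores, truth, thresholds)
  res$scores <- scores
  res$truth <- truth
  res
}

#' Write / read a pattern matrix as TSV
#'
#' Columns: \code{structure_id} then \code{P1}..\code{P9} as 0/1.
#'
#' @param patterns List or matrix of patterns.
#' @param path TSV path.
#' @return \code{writePatterns} returns \code{path} invisibly;
#'   \code{readPatterns} returns a logical matrix.
#' @export
writePatterns <- function(patterns, path) {
  m <- patternMatrix(patterns)
  df <- data.frame(structure_id = rownames(m),
                   `colnames<-`(1L * m, paste0("P", 1:9)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePatterns
#' @export
readPatterns <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, paste0("P", 1:9)]) == 1
  rownames(m) <- df$structure_id
  m
}
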