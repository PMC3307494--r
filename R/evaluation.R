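#' Confusion counts at a score threshold
#'
#' Positive class is set A: TP are truth-A abstracts scoring strictly above
#' the threshold, FP truth-B abstracts above it, FN truth-A at or below,
#' TN truth-B at or below.
#'
#' @param results data frame with columns \code{pmid} and \code{score}
#'   (e.g. from [classify_and_rank()]).
#' @param truth named character vector mapping PMID to \code{"A"} or
#'   \code{"B"}; every result PMID must be present.
#' @param threshold score threshold (strict inequality for A).
#' @return Object of class \code{"confusion_counts"} with integer fields
#'   \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusion <- function(results, truth, threshold = 0.5) {
  missing <- setdiff(results$pmid, names(truth))
  if (length(missing)) {
    lr_stop("no truth label for PMID(s): %s",
            paste(utils::head(missing, 10), collapse = ", "))
  }
  lab <- truth[results$pmid]
  pos <- results$score > threshold
  confusion_counts(TP = sum(pos & lab == "A"),
                   FP = sum(pos & lab == "B"),
                   TN = sum(!pos & lab == "B"),
                   FN = sum(!pos & lab == "A"))
}

#' Construct confusion counts directly
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return Object of class \code{"confusion_counts"}.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  stopifnot(all(counts >= 0), all(counts == as.integer(counts)))
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (positive = set A): TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Precision, recall and false-positive rate
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN), fpr = FP/(FP+TN).  A ratio
#' with a zero denominator is undefined and reported as \code{NA}, never
#' coerced to 0, so extreme-threshold curve points are not distorted.
#'
#' @param c a [confusion_counts()] object.
#' @return Named list with \code{precision}, \code{recall}, \code{fpr}.
#' @export
precision_recall_fpr <- function(c) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(precision = ratio(c$TP, c$TP + c$FP),
       recall = ratio(c$TP, c$TP + c$FN),
       fpr = ratio(c$FP, c$FP + c$TN))
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), a balanced
#' two-class quality measure in [-1, 1]: +1 a perfect, 0 an average random,
#' -1 an inverse prediction.  Any zero factor in the denominator gives the
#' conventional value 0.
#'
#' @param c a [confusion_counts()] object.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$TP); fp <- as.numeric(c$FP)
  tn <- as.numeric(c$TN); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Metric sweep over score thresholds
#'
#' Recomputes confusion counts at each threshold and tabulates precision,
#' recall, false-positive rate and MCC multiplied by 100 (the scale the ROC
#' comparison uses).  Recall and FPR are non-increasing as the threshold
#' rises.  Default thresholds are the sorted distinct scores plus 0 and 1.
#'
#' @inheritParams confusion
#' @param thresholds ascending numeric thresholds, or \code{NULL} for the
#'   default.
#' @return Data frame of class \code{"metric_curve"} with columns
#'   \code{threshold}, \code{precision}, \code{recall}, \code{fpr},
#'   \code{mcc_x100}.
#' @export
sweep_thresholds <- function(results, truth, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, results$score, 1)))
  }
  if (is.unsorted(thresholds)) lr_stop("thresholds must be ascending")
  rows <- lapply(thresholds, function(th) {
    cc <- confusion(results, truth, th)
    m <- precision_recall_fpr(cc)
    data.frame(threshold = th, precision = m$precision, recall = m$recall,
               fpr = m$fpr, mcc_x100 = 100 * mcc(cc))
  })
  structure(do.call(rbind, rows),
            class = c("metric_curve", "data.frame"))
}

#' Majority-vote curation of truth labels
#'
#' The correct classification of each abstract is the label assigned by the
#' majority of an odd number of independent curators; any disagreement among
#' curators flags the abstract as ambiguous.
#'
#' @param annotations data frame whose first column is \code{pmid} and whose
#'   remaining k columns (k odd) hold one curator's \code{"A"}/\code{"B"}
#'   label each.
#' @return Data frame with columns \code{pmid}, \code{label},
#'   \code{ambiguous}.
#' @export
majority_vote <- function(annotations) {
  k <- ncol(annotations) - 1L
  if (k < 1 || k %% 2 == 0) {
    lr_stop("majority vote needs an odd number of curators, got %d", k)
  }
  labs <- as.matrix(annotations[, -1, drop = FALSE])
  if (!all(labs %in% c("A", "B"))) lr_stop("curator labels must be A or B")
  n_a <- rowSums(labs == "A")
  data.frame(pmid = as.character(annotations[[1]]),
             label = ifelse(n_a > k / 2, "A", "B"),
             ambiguous = n_a != 0 & n_a != k,
             stringsAsFactors = FALSE)
}

#' Read a truth table
#'
#' @param path TSV \code{pmid<TAB>label}, or \code{pmid} plus one column per
#'   curator for curation mode (resolved by [majority_vote()]).
#' @return Named character vector PMID -> \code{"A"}/\code{"B"}.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) == 2) {
    stats::setNames(df[[2]], df[[1]])
  } else {
    mv <- majority_vote(df)
    stats::setNames(mv$label, mv$pmid)
  }
}
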