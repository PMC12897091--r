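## Cutoff calibration (ROC / Youden) and diagnostic concordance.

.as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    up <- toupper(labels)
    if (!all(up %in% c("MSI", "MSS"))) {
      stop("labels must be logical or 'MSI'/'MSS'", call. = FALSE)
    }
    return(up == "MSI")
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  stop("labels must be logical, 0/1, or 'MSI'/'MSS'", call. = FALSE)
}

#' ROC curve over per-sample instability scores
#'
#' Candidate thresholds are the distinct observed scores (classification
#' rule: positive iff `score >= t`), optionally midpoints between adjacent
#' distinct scores. The AUC is computed by trapezoidal integration over the
#' (FPR, TPR) points; it equals the fraction of positive–negative score
#' pairs correctly ordered, with ties counted one half.
#'
#' @param scores Numeric vector of sample scores.
#' @param labels Reference calls: logical (`TRUE` = MSI), 0/1, or
#'   `"MSI"`/`"MSS"` strings. Both classes must be present.
#' @param candidates `"observed"` (default) or `"midpoint"`.
#' @return A list of class `msq_roc`: `points` (data.frame with
#'   `threshold`, `sensitivity`, `specificity`, `fpr`), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels, candidates = c("observed", "midpoint")) {
  candidates <- match.arg(candidates)
  labels <- .as_binary_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires at least one positive and one negative label",
         call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  if (candidates == "midpoint" && length(thr) > 1L) {
    thr <- c(thr[1] + 1, (thr[-1] + thr[-length(thr)]) / 2,
             thr[length(thr)] - 1)
  }
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n_neg, 0)
  pts <- data.frame(threshold = thr, sensitivity = sens,
                    specificity = spec, fpr = 1 - spec)
  ## trapezoid over the full curve including the (0,0) and (1,1) anchors
  fpr <- c(0, pts$fpr, 1)
  tpr <- c(0, pts$sensitivity, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 candidates = candidates), class = "msq_roc")
}

#' @export
print.msq_roc <- function(x, ...) {
  cat(sprintf("ROC: %d positives, %d negatives, AUC = %.4f (%s thresholds)\n",
              x$n_pos, x$n_neg, x$auc, x$candidates))
  invisible(x)
}

#' Optimal cutoff by the maximum Youden index
#'
#' The Youden index is J = sensitivity + specificity - 1. Among thresholds
#' maximizing J, ties are broken toward higher specificity (avoiding false
#' MSI calls), then toward the lower cutoff value.
#'
#' @param roc An `msq_roc` from [roc_curve()].
#' @return List with `cutoff`, `youden_j`, `sensitivity`, `specificity` at
#'   the chosen cutoff.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "msq_roc"))
  p <- roc$points
  j <- p$sensitivity + p$specificity - 1
  cand <- which(j == max(j))
  cand <- cand[p$specificity[cand] == max(p$specificity[cand])]
  best <- cand[which.min(p$threshold[cand])]
  list(cutoff = p$threshold[best], youden_j = j[best],
       sensitivity = p$sensitivity[best], specificity = p$specificity[best])
}

#' Dichotomize a sample score against a cutoff
#'
#' A sample at or above the cutoff is called MSI; below, MSS. The boundary
#' (score equal to the cutoff) maps to MSI so that a calibrated cutoff —
#' itself an observed score — keeps its own sample positive.
#'
#' @param score Numeric score (may be a vector).
#' @param cutoff Finite numeric cutoff.
#' @param metric Metric name carried into the result, e.g.
#'   `"pct_mutated_reads"`.
#' @param sample_id Optional sample identifier(s).
#' @return Data.frame with `sample_id`, `metric`, `score`, `cutoff`,
#'   `call` (`"MSI"`/`"MSS"`).
#' @export
classify_msi <- function(score, cutoff, metric = "score",
                         sample_id = NULL) {
  stopifnot(is.finite(cutoff))
  if (is.null(sample_id)) sample_id <- as.character(seq_along(score))
  data.frame(sample_id = sample_id, metric = metric, score = score,
             cutoff = cutoff,
             call = ifelse(score >= cutoff, "MSI", "MSS"),
             stringsAsFactors = FALSE)
}

#' PCR marker-panel classification rule
#'
#' MSI-high is called when the fraction of unstable markers reaches the
#' threshold (default 30%, i.e. at least two unstable markers in a
#' five-marker panel). Anything below — including MSI-low — is grouped
#' with MSS.
#'
#' @param marker_results Logical vector (`TRUE` = unstable) or character
#'   vector of `"stable"`/`"unstable"`, optionally named by marker.
#' @param threshold Fraction of unstable markers required, default 0.30.
#' @return List of class `msq_pcr_call`: `n_markers`, `n_unstable`,
#'   `fraction_unstable`, `threshold`, `call` (`"MSI-H"` or `"MSS"`).
#' @examples
#' pcr_call(c(BAT25 = TRUE, BAT26 = TRUE, D2S123 = FALSE,
#'            D5S346 = FALSE, D17S250 = FALSE))$call  # "MSI-H"
#' @export
pcr_call <- function(marker_results, threshold = 0.30) {
  if (is.character(marker_results)) {
    low <- tolower(marker_results)
    if (!all(low %in% c("stable", "unstable"))) {
      stop("marker results must be 'stable'/'unstable' or logical",
           call. = FALSE)
    }
    marker_results <- low == "unstable"
  }
  stopifnot(is.logical(marker_results), !anyNA(marker_results))
  if (length(marker_results) == 0L) {
    stop("empty marker list", call. = FALSE)
  }
  frac <- mean(marker_results)
  structure(list(n_markers = length(marker_results),
                 n_unstable = sum(marker_results),
                 fraction_unstable = frac, threshold = threshold,
                 call = if (frac >= threshold) "MSI-H" else "MSS"),
            class = "msq_pcr_call")
}

#' Build a 2x2 contingency table from counts or paired calls
#'
#' @param tp,fp,fn,tn Cell counts (test vs reference positives/negatives),
#'   or leave missing and supply `test`/`reference` call vectors.
#' @param test,reference Character vectors of `"MSI"`/`"MSS"` calls
#'   (positive = MSI).
#' @return List of class `msq_contingency` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
contingency_table <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                              test = NULL, reference = NULL) {
  if (!is.null(test) || !is.null(reference)) {
    stopifnot(length(test) == length(reference), length(test) > 0L)
    tpos <- .as_binary_labels(test)
    rpos <- .as_binary_labels(reference)
    tp <- sum(tpos & rpos); fp <- sum(tpos & !rpos)
    fn <- sum(!tpos & rpos); tn <- sum(!tpos & !rpos)
  }
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(length(cells) == 4L, all(cells >= 0))
  structure(as.list(cells), class = "msq_contingency")
}

#' Sensitivity, specificity and concordance from a 2x2 table
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), concordance =
#' (TP+TN)/total, each as a percentage. A zero denominator yields `NA`
#' (undefined) for that metric.
#'
#' @param table An `msq_contingency` from [contingency_table()].
#' @return List with `sensitivity`, `specificity`, `concordance`
#'   (percentages) and the input counts.
#' @examples
#' concordance_stats(contingency_table(tp = 14, fp = 3, fn = 0, tn = 14))
#' @export
concordance_stats <- function(table) {
  stopifnot(inherits(table, "msq_contingency"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  total <- tp + fp + fn + tn
  conc <- if (total > 0) 100 * (tp + tn) / total else NA_real_
  list(sensitivity = sens, specificity = spec, concordance = conc,
       tp = tp, fp = fp, fn = fn, tn = tn, n = total)
}
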