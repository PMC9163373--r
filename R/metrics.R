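# coerce a list of label records or a plain matrix to an n x 5 0/1
# matrix with note ids as rownames
label_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 5L)
    colnames(x) <- FH_CODES
    return(x)
  }
  m <- do.call(rbind, lapply(x, function(l) unclass(as_fh_label(l$label))))
  rownames(m) <- vapply(x, `[[`, "", "note_id")
  m
}

#' Per-label confusion counts
#'
#' @param pred,gold label-record lists or 0/1 matrices (rows = notes,
#'   columns = the quintet).  When rownames/ids are present the two
#'   inputs must cover the same note ids; gold is aligned to pred's
#'   order.
#' @return data.frame with one row per label: `label`, `TP`, `FP`, `FN`,
#'   `TN` (integers; `TP+FP+FN+TN` = number of scored notes).
#' @export
confusion <- function(pred, gold) {
  p <- label_matrix(pred); g <- label_matrix(gold)
  if (!is.null(rownames(p)) && !is.null(rownames(g))) {
    extra <- setdiff(rownames(p), rownames(g))
    miss <- setdiff(rownames(g), rownames(p))
    if (length(extra) || length(miss))
      stop("note id mismatch between pred and gold; offenders: ",
           paste(c(extra, miss), collapse = ", "))
    g <- g[rownames(p), , drop = FALSE]
  }
  if (nrow(p) != nrow(g))
    stop("pred and gold must score the same notes")
  data.frame(label = FH_CODES,
             TP = as.integer(colSums(p == 1L & g == 1L)),
             FP = as.integer(colSums(p == 1L & g == 0L)),
             FN = as.integer(colSums(p == 0L & g == 1L)),
             TN = as.integer(colSums(p == 0L & g == 0L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

prf <- function(tp, fp, fn) {
  prec <- if ((tp + fp) == 0) {
    fh_log("precision undefined (no positive predictions); using 0")
    0
  } else tp / (tp + fp)
  rec <- if ((tp + fn) == 0) {
    fh_log("recall undefined (no gold positives); using 0")
    0
  } else tp / (tp + fn)
  f1 <- if ((prec + rec) == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

#' Micro- or macro-averaged precision, recall and F1
#'
#' Micro pools the confusion counts over the five labels before
#' computing the metrics (so class frequencies act as weights); macro
#' computes the metrics per label and takes their unweighted mean.  The
#' two diverge under label imbalance.  Zero-denominator metrics are 0
#' (logged via `options(famhx.verbose = TRUE)`).
#'
#' @param counts data.frame from [confusion()].
#' @param mode `"micro"` or `"macro"`.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
aggregate_metrics <- function(counts, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (mode == "micro") {
    prf(sum(counts$TP), sum(counts$FP), sum(counts$FN))
  } else {
    per <- mapply(prf, counts$TP, counts$FP, counts$FN)
    rowMeans(per)
  }
}

#' Multi-label accuracy
#'
#' `"per_decision"` (the default) counts correct (note, label) decisions
#' over all `n_notes x 5` of them; `"subset"` counts notes whose whole
#' quintet is exactly right.  Per-decision accuracy dominates subset
#' accuracy on every input, and under rare positives it can be high even
#' when precision is modest.
#'
#' @inheritParams confusion
#' @param mode `"per_decision"` or `"subset"`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(pred, gold, mode = c("per_decision", "subset")) {
  mode <- match.arg(mode)
  p <- label_matrix(pred); g <- label_matrix(gold)
  if (!is.null(rownames(p)) && !is.null(rownames(g)))
    g <- g[rownames(p), , drop = FALSE]
  if (mode == "per_decision") mean(p == g) else mean(rowSums(p == g) == 5L)
}

#' ROC curve and AUC for one label
#'
#' Points are (FPR, TPR) at every distinct score threshold (plus the
#' (0,0) and (1,1) endpoints); AUC is the trapezoid area, which equals
#' the pairwise concordance probability of positive-over-negative score
#' ranks (ties counted half).
#'
#' @param scores numeric scores (higher = more positive).
#' @param gold 0/1 gold indicators for the label.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`),
#'   `auc`, and `degenerate` (TRUE with `auc = NA` when the label has no
#'   positives or no negatives).
#' @export
roc <- function(scores, gold) {
  stopifnot(length(scores) == length(gold))
  n_pos <- sum(gold == 1L); n_neg <- sum(gold == 0L)
  if (n_pos == 0L || n_neg == 0L)
    return(list(points = NULL, auc = NA_real_, degenerate = TRUE))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- gold[ord]
  # indices of the last element of each tied-score block
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1L)[last]; fp <- cumsum(y == 0L)[last]
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) +
                                utils::tail(pts$tpr, -1L)) / 2)
  list(points = pts, auc = auc, degenerate = FALSE)
}

#' Full evaluation report for one run
#'
#' Per-label and aggregate precision/recall/F1, per-decision and subset
#' accuracy, and (when probability scores are given) per-label ROC/AUC.
#'
#' @inheritParams confusion
#' @param scores optional n x 5 matrix of probabilities for ROC/AUC.
#' @return List of class `fh_metric_report`.
#' @export
metric_report <- function(pred, gold, scores = NULL) {
  counts <- confusion(pred, gold)
  g <- label_matrix(gold)
  per_label <- cbind(counts,
                     t(mapply(prf, counts$TP, counts$FP, counts$FN)))
  per_label$accuracy <- with(counts, (TP + TN) / (TP + FP + FN + TN))
  rep <- list(per_label = per_label,
              micro = aggregate_metrics(counts, "micro"),
              macro = aggregate_metrics(counts, "macro"),
              accuracy = accuracy(pred, gold, "per_decision"),
              subset_accuracy = accuracy(pred, gold, "subset"))
  if (!is.null(scores)) {
    if (!is.null(rownames(scores)) && !is.null(rownames(g)))
      g <- g[rownames(scores), , drop = FALSE]
    rep$auc <- vapply(seq_len(5L), function(j)
      roc(scores[, j], g[, j])$auc, 0)
    names(rep$auc) <- FH_CODES
  }
  class(rep) <- "fh_metric_report"
  rep
}

# flatten the scalar metrics of a report to a named vector
report_vector <- function(rep) {
  c(micro_precision = unname(rep$micro["precision"]),
    micro_recall = unname(rep$micro["recall"]),
    micro_f1 = unname(rep$micro["f1"]),
    macro_precision = unname(rep$macro["precision"]),
    macro_recall = unname(rep$macro["recall"]),
    macro_f1 = unname(rep$macro["f1"]),
    accuracy = rep$accuracy,
    subset_accuracy = rep$subset_accuracy)
}

#' Mean and standard deviation over repeated runs
#'
#' Each reported metric is summarised as the sample mean and sample
#' standard deviation (n - 1 denominator) over independent runs.
#'
#' @param reports list of `fh_metric_report` objects (>= 2) or a numeric
#'   matrix/data.frame with one row per run.
#' @return data.frame with columns `metric`, `mean`, `sd`, `n_runs`.
#' @export
aggregate_runs <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports) &&
      inherits(reports[[1L]], "fh_metric_report"))
    reports <- do.call(rbind, lapply(reports, report_vector))
  reports <- as.matrix(reports)
  if (nrow(reports) < 2L)
    stop("aggregate_runs() needs at least 2 runs")
  if (is.null(colnames(reports)))
    colnames(reports) <- paste0("metric_", seq_len(ncol(reports)))
  data.frame(metric = colnames(reports),
             mean = colMeans(reports),
             sd = apply(reports, 2L, stats::sd),
             n_runs = nrow(reports), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test between run-level metric samples
#'
#' Compares the run-level values of a metric (conventionally micro-F1)
#' between two configurations.  Unequal-variance (Welch) statistic with
#' Welch-Satterthwaite degrees of freedom.  When both samples have zero
#' variance: p = 1 if the means are equal, p = 0 otherwise.
#'
#' @param a,b numeric vectors of run-level metric values (>= 2 each).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
compare_configs <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("compare_configs() needs >= 2 samples per configuration")
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p_value = if (eq) 1 else 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}
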