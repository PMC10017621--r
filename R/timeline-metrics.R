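#' Elementary segmentation of two totalized tracks
#'
#' Sweeps over the merged interval boundaries of both tracks and returns the
#' piecewise-constant joint labelling: for each elementary segment the ground
#' truth (`gt`) and predicted (`pred`) labels. Exact integer-millisecond
#' interval algebra; equivalent to dense 1 ms sampling at any video length.
#'
#' @param gt,pred Totalized [annotation_track()]s at the same level with the
#'   same duration.
#' @return `data.frame` with columns `start_ms`, `end_ms`, `gt`, `pred`.
#' @keywords internal
segment_grid <- function(gt, pred) {
  check_comparable(gt, pred)
  breaks <- sort(unique(c(gt$start_ms, gt$end_ms, pred$start_ms, pred$end_ms)))
  s <- breaks[-length(breaks)]
  data.frame(
    start_ms = s,
    end_ms = breaks[-1L],
    gt = gt$label[findInterval(s, gt$start_ms)],
    pred = pred$label[findInterval(s, pred$start_ms)],
    stringsAsFactors = FALSE
  )
}

check_comparable <- function(gt, pred) {
  stopifnot(inherits(gt, "annotation_track"), inherits(pred, "annotation_track"))
  if (track_level(gt) != track_level(pred)) {
    stop("tracks are at different levels (", track_level(gt), " vs ",
         track_level(pred), ")", call. = FALSE)
  }
  if (track_duration(gt) != track_duration(pred)) {
    stop("tracks have different durations; totalize onto a common timeline first",
         call. = FALSE)
  }
  for (tr in list(gt, pred)) {
    if (nrow(tr) == 0L || tr$start_ms[1L] != 0L ||
        tr$end_ms[nrow(tr)] != track_duration(tr) ||
        (nrow(tr) > 1L && any(tr$start_ms[-1L] != tr$end_ms[-nrow(tr)]))) {
      stop("tracks must be totalized (gap-free over [0, duration))", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Time-weighted confusion matrix between two tracks
#'
#' Cell `(a, b)` holds the total number of milliseconds during which the
#' ground-truth track carries label `a` while the prediction carries `b`.
#' Computed exactly by an interval sweep (see [segment_grid()]); the cell
#' total always equals the common duration.
#'
#' @inheritParams segment_grid
#' @param labels Optional label ordering for the matrix axes; defaults to the
#'   union of labels present in either track, in order of first definition
#'   within each track. Labels absent from both tracks yield all-zero
#'   rows/columns (used for the "macro over all classes" averaging scheme).
#' @return Square numeric matrix of millisecond durations with identical row
#'   and column `dimnames`.
#' @export
#' @examples
#' a <- totalize(annotation_track(
#'   data.frame(label = c("A", "B"), start_ms = c(0, 60), end_ms = c(60, 100)),
#'   "v", "phase"))
#' b <- totalize(annotation_track(
#'   data.frame(label = c("A", "B"), start_ms = c(0, 50), end_ms = c(50, 100)),
#'   "v", "phase"))
#' time_weighted_confusion(a, b)
time_weighted_confusion <- function(gt, pred, labels = NULL) {
  g <- segment_grid(gt, pred)
  labels <- labels %||% unique(c(gt$label, pred$label))
  cm <- matrix(0, nrow = length(labels), ncol = length(labels),
               dimnames = list(gt = labels, pred = labels))
  len <- g$end_ms - g$start_ms
  idx <- cbind(match(g$gt, labels), match(g$pred, labels))
  if (anyNA(idx)) stop("track labels missing from 'labels'", call. = FALSE)
  for (k in seq_along(len)) cm[idx[k, 1L], idx[k, 2L]] <- cm[idx[k, 1L], idx[k, 2L]] + len[k]
  cm
}

#' Overall accuracy from a time-weighted confusion matrix
#'
#' Proportion of correctly labelled time: matrix trace over matrix total.
#'
#' @param cm Confusion matrix from [time_weighted_confusion()].
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot <= 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / tot
}

#' Per-class and macro precision, recall and F1
#'
#' Per class `c`: precision = `cm[c,c] / colsum(c)` (proportion of time
#' predicted as `c` that truly is `c`), recall = `cm[c,c] / rowsum(c)`
#' (proportion of true `c` time recovered), F1 = harmonic mean. Classes with
#' a zero denominator score 0 by convention, which penalizes hallucinated or
#' omitted classes deterministically.
#'
#' Macro averages are unweighted means over classes; which classes enter the
#' mean is governed by `average`:
#' \describe{
#'   \item{`macro_present`}{classes occurring in either track (row or column
#'     support > 0); the default, keeping per-video values comparable across
#'     videos that contain different facultative phases.}
#'   \item{`macro_all`}{every class of the matrix, absent ones scoring 0.}
#'   \item{`micro`}{duration-weighted pooling; equals accuracy for
#'     single-label-per-instant tracks.}
#' }
#'
#' @inheritParams accuracy
#' @param average Macro-averaging scheme (see Details).
#' @return List with `per_class` (`data.frame`: label, precision, recall, f1,
#'   support_ms) and macro `precision`, `recall`, `f1`.
#' @export
per_class_prf <- function(cm, average = c("macro_present", "macro_all", "micro")) {
  average <- match.arg(average)
  if (sum(cm) <= 0) stop("empty confusion matrix", call. = FALSE)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  d <- diag(cm)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe_div(d, cs)
  rec <- safe_div(d, rs)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  per_class <- data.frame(label = rownames(cm), precision = prec, recall = rec,
                          f1 = f1, support_ms = rs, row.names = NULL,
                          stringsAsFactors = FALSE)
  sel <- switch(average,
    macro_present = rs > 0 | cs > 0,
    macro_all = rep(TRUE, length(rs)),
    micro = NULL
  )
  if (average == "micro") {
    p <- sum(d) / sum(cs)
    macro <- list(precision = p, recall = sum(d) / sum(rs),
                  f1 = p)  # micro-P = micro-R = micro-F1 = accuracy here
  } else {
    macro <- list(precision = mean(prec[sel]), recall = mean(rec[sel]),
                  f1 = mean(f1[sel]))
  }
  c(list(per_class = per_class), macro)
}

#' Cohen's kappa on time-weighted labels
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and chance agreement
#' `p_e = sum_c rowsum(c) * colsum(c) / total^2`. When both raters used a
#' single identical label for the whole timeline, `p_e = 1` and kappa is
#' undefined; `NA` is returned and aggregation counts the skip.
#'
#' @inheritParams accuracy
#' @return Fraction in `[-1, 1]`, or `NA` in the degenerate single-label case.
#' @export
cohens_kappa <- function(cm) {
  tot <- sum(cm)
  if (tot <= 0) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cm)) / tot
  p_e <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (1 - p_e < .Machine$double.eps) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Full classical metric set for one ordered (gt, pred) comparison
#'
#' @inheritParams time_weighted_confusion
#' @inheritParams per_class_prf
#' @return A `metric_set`: list with `accuracy`, `precision`, `recall`, `f1`
#'   (macro), `kappa` (or `NA`) and `per_class`.
#' @export
metric_set <- function(gt, pred, labels = NULL, average = "macro_present") {
  cm <- time_weighted_confusion(gt, pred, labels = labels)
  metric_set_from_confusion(cm, average = average)
}

metric_set_from_confusion <- function(cm, average = "macro_present") {
  prf <- per_class_prf(cm, average = average)
  structure(
    list(accuracy = accuracy(cm), precision = prf$precision,
         recall = prf$recall, f1 = prf$f1, kappa = cohens_kappa(cm),
         per_class = prf$per_class),
    class = "metric_set"
  )
}

#' Symmetric (ground-truth-swap averaged) comparison of two tracks
#'
#' Two human annotations have no privileged ground truth, so each track is
#' treated once as ground truth and the two metric sets are averaged
#' element-wise. Because the confusion matrix transposes under the swap,
#' swap-averaged macro precision equals swap-averaged macro recall exactly —
#' the reason reliability tables report identical precision and recall
#' columns. Kappa is symmetric by construction, so both directions agree.
#'
#' @param a,b Comparable totalized [annotation_track()]s.
#' @inheritParams time_weighted_confusion
#' @inheritParams per_class_prf
#' @return A `metric_set` of swap-averaged values; per-class values are
#'   averaged label-wise.
#' @export
symmetric_compare <- function(a, b, labels = NULL, average = "macro_present") {
  labels <- labels %||% unique(c(a$label, b$label))
  m_ab <- metric_set(a, b, labels = labels, average = average)
  m_ba <- metric_set(b, a, labels = labels, average = average)
  average_metric_sets(list(m_ab, m_ba))
}

average_metric_sets <- function(ms_list) {
  avg <- function(xs) {
    xs <- xs[!is.na(xs)]
    if (length(xs) == 0L) NA_real_ else mean(xs)
  }
  pc <- ms_list[[1L]]$per_class
  for (col in c("precision", "recall", "f1", "support_ms")) {
    pc[[col]] <- rowMeans(vapply(ms_list, function(m) m$per_class[[col]],
                                 numeric(nrow(pc))))
  }
  structure(
    list(
      accuracy = avg(vapply(ms_list, `[[`, numeric(1), "accuracy")),
      precision = avg(vapply(ms_list, `[[`, numeric(1), "precision")),
      recall = avg(vapply(ms_list, `[[`, numeric(1), "recall")),
      f1 = avg(vapply(ms_list, `[[`, numeric(1), "f1")),
      kappa = avg(vapply(ms_list, `[[`, numeric(1), "kappa")),
      per_class = pc
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> accuracy %.3f | precision %.3f | recall %.3f | f1 %.3f | kappa %s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              if (is.na(x$kappa)) "undefined" else sprintf("%.3f", x$kappa)))
  invisible(x)
}
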