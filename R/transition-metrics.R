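#' Configuration for application-dependent (AD) metrics
#'
#' @param delta_ms Transitional-delay relaxation threshold in milliseconds
#'   (default 5000, i.e. 5 s): label disagreement within `delta_ms` of a
#'   ground-truth transition is forgiven by the relaxed metrics, provided the
#'   predicted label matches one of the labels adjacent to that transition.
#' @param delay_mode How average transitional delay is reported: `"signed"`
#'   (annotated minus real; early annotations are negative) or `"absolute"`.
#' @param relax_mode Which adjacent ground-truth label(s) a prediction may
#'   match inside the relaxation window: `"both"` (default), `"pre"` (label
#'   before the transition only) or `"post"`.
#' @return An `ad_config` list.
#' @export
ad_config <- function(delta_ms = 5000, delay_mode = c("signed", "absolute"),
                      relax_mode = c("both", "pre", "post")) {
  delta_ms <- as.integer(delta_ms)
  stopifnot(delta_ms >= 0L)
  structure(list(delta_ms = delta_ms, delay_mode = match.arg(delay_mode),
                 relax_mode = match.arg(relax_mode)),
            class = "ad_config")
}

#' Extract transitional moments from a totalized track
#'
#' A transitional moment is any time point where the label changes, including
#' changes into or out of the idle label (idle participates like any label on
#' the totalized timeline).
#'
#' @param track A totalized [annotation_track()].
#' @return `data.frame` with columns `time_ms`, `from_label`, `to_label`,
#'   sorted by time; zero rows for a single-label track.
#' @export
extract_transitions <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  n <- nrow(track)
  if (n <= 1L) {
    return(data.frame(time_ms = integer(), from_label = character(),
                      to_label = character(), stringsAsFactors = FALSE))
  }
  chg <- which(track$label[-1L] != track$label[-n])
  data.frame(time_ms = track$end_ms[chg], from_label = track$label[chg],
             to_label = track$label[chg + 1L], stringsAsFactors = FALSE)
}

#' Match annotated transitions to real transitions
#'
#' One-to-one matching in two greedy passes: first, pairs sharing the same
#' `(from_label, to_label)` signature are matched in order of smallest
#' absolute delay; then the remaining events are matched by smallest absolute
#' delay regardless of signature. No time window is imposed at the matching
#' stage — the relaxation threshold applies only to the relaxed agreement
#' metrics, since average transitional delays may well exceed it. Ties on
#' |delay| are broken by real-event time, then annotated-event time, so the
#' matching is deterministic.
#'
#' @param real,annotated Transition tables from [extract_transitions()].
#' @return List with `matches` (`data.frame`: real_time_ms, annotated_time_ms,
#'   from_label, to_label of the real event, delay_ms = annotated - real),
#'   `unmatched_real` and `unmatched_annotated` (the leftover event tables).
#' @export
match_transitions <- function(real, annotated) {
  nr <- nrow(real)
  na <- nrow(annotated)
  used_r <- rep(FALSE, nr)
  used_a <- rep(FALSE, na)
  out_r <- integer()
  out_a <- integer()

  greedy_pass <- function(pairs) {
    # pairs: data.frame(i = real idx, j = annotated idx, adel = |delay|)
    pairs <- pairs[order(pairs$adel, real$time_ms[pairs$i],
                         annotated$time_ms[pairs$j]), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!used_r[i] && !used_a[j]) {
        used_r[i] <<- TRUE; used_a[j] <<- TRUE
        out_r[[length(out_r) + 1L]] <<- i
        out_a[[length(out_a) + 1L]] <<- j
      }
    }
  }

  if (nr > 0L && na > 0L) {
    all_pairs <- expand.grid(i = seq_len(nr), j = seq_len(na))
    all_pairs$adel <- abs(annotated$time_ms[all_pairs$j] - real$time_ms[all_pairs$i])
    same_sig <- real$from_label[all_pairs$i] == annotated$from_label[all_pairs$j] &
      real$to_label[all_pairs$i] == annotated$to_label[all_pairs$j]
    greedy_pass(all_pairs[same_sig, , drop = FALSE])
    remaining <- all_pairs[!used_r[all_pairs$i] & !used_a[all_pairs$j], , drop = FALSE]
    greedy_pass(remaining)
  }
  matches <- data.frame(
    real_time_ms = real$time_ms[out_r],
    annotated_time_ms = annotated$time_ms[out_a],
    from_label = real$from_label[out_r],
    to_label = real$to_label[out_r],
    delay_ms = annotated$time_ms[out_a] - real$time_ms[out_r],
    stringsAsFactors = FALSE
  )
  matches <- matches[order(matches$real_time_ms), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_real = real[!used_r, , drop = FALSE],
       unmatched_annotated = annotated[!used_a, , drop = FALSE])
}

#' Average transitional delay (ATD), in seconds
#'
#' Mean delay between matched annotated and real transitional moments. In
#' `"signed"` mode a systematically late rater yields a positive ATD and an
#' early one a negative ATD; `"absolute"` mode averages magnitudes.
#'
#' @param matches The `matches` table from [match_transitions()] (or a full
#'   [match_transitions()] result).
#' @param cfg An [ad_config()].
#' @return Mean delay in seconds, or `NA` when there are no matches.
#' @export
average_transitional_delay <- function(matches, cfg = ad_config()) {
  if (is.list(matches) && !is.data.frame(matches)) matches <- matches$matches
  if (nrow(matches) == 0L) return(NA_real_)
  d <- matches$delay_ms
  if (cfg$delay_mode == "absolute") d <- abs(d)
  mean(d) / 1000
}

#' Coefficient of transitional moments (C_TM), percent
#'
#' Ratio of the number of annotated to real transitional moments, as a
#' percentage. 100 means equal counts; spurious insertions push it above 100.
#'
#' @param real,annotated Transition tables from [extract_transitions()].
#' @return Percent, or `NA` when the real track has no transitions.
#' @export
coefficient_of_transitional_moments <- function(real, annotated) {
  if (nrow(real) == 0L) return(NA_real_)
  100 * nrow(annotated) / nrow(real)
}

#' Noise level (NL), percent
#'
#' Proportion of annotated segments that are not part of any real segment:
#' an annotated (non-idle) segment counts as noise iff it has zero temporal
#' overlap with a real segment bearing the same label. Segments are maximal
#' same-label runs on the totalized timeline; idle segments are excluded from
#' both numerator and denominator.
#'
#' @param real,annotated Comparable totalized [annotation_track()]s.
#' @param idle_label Label excluded from the segment counts.
#' @return Percent of annotated segments that are noise, or `NA` when the
#'   annotated track has no non-idle segments.
#' @export
noise_level <- function(real, annotated, idle_label = "idle") {
  check_comparable(real, annotated)
  r <- merge_runs(real)
  a <- merge_runs(annotated)
  a <- a[a$label != idle_label, , drop = FALSE]
  if (nrow(a) == 0L) return(NA_real_)
  is_noise <- vapply(seq_len(nrow(a)), function(i) {
    same <- r[r$label == a$label[i], , drop = FALSE]
    if (nrow(same) == 0L) return(TRUE)
    ov <- pmin(same$end_ms, a$end_ms[i]) - pmax(same$start_ms, a$start_ms[i])
    all(ov <= 0L)
  }, logical(1))
  100 * sum(is_noise) / nrow(a)
}

#' Delta-relaxed (application-dependent) confusion matrix
#'
#' Identical to [time_weighted_confusion()] except that any millisecond lying
#' within `cfg$delta_ms` of a ground-truth transition — i.e. in the window
#' `[t - delta, t + delta)` around a boundary at `t` — whose predicted label
#' equals an adjacent ground-truth label of that transition (per
#' `cfg$relax_mode`) is credited to the diagonal cell of the ground-truth
#' label. All other mass is unchanged and the matrix total is conserved, so a
#' prediction that is merely a few seconds late or early around a boundary is
#' not penalized.
#'
#' @inheritParams time_weighted_confusion
#' @param cfg An [ad_config()].
#' @return Square numeric matrix of millisecond durations.
#' @export
relaxed_confusion <- function(gt, pred, cfg = ad_config(), labels = NULL) {
  cm <- time_weighted_confusion(gt, pred, labels = labels)
  if (cfg$delta_ms == 0L) return(cm)
  g <- segment_grid(gt, pred)
  trans <- extract_transitions(gt)
  if (nrow(trans) == 0L) return(cm)
  win_start <- trans$time_ms - cfg$delta_ms
  win_end <- trans$time_ms + cfg$delta_ms
  for (k in which(g$gt != g$pred)) {
    ok <- switch(cfg$relax_mode,
      both = g$pred[k] == trans$from_label | g$pred[k] == trans$to_label,
      pre = g$pred[k] == trans$from_label,
      post = g$pred[k] == trans$to_label
    )
    s <- pmax(win_start[ok], g$start_ms[k])
    e <- pmin(win_end[ok], g$end_ms[k])
    credited <- interval_union_length(s[e > s], e[e > s])
    if (credited > 0L) {
      cm[g$gt[k], g$pred[k]] <- cm[g$gt[k], g$pred[k]] - credited
      cm[g$gt[k], g$gt[k]] <- cm[g$gt[k], g$gt[k]] + credited
    }
  }
  cm
}

# total length of the union of possibly-overlapping intervals [s_i, e_i)
interval_union_length <- function(s, e) {
  if (length(s) == 0L) return(0L)
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0L
  cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else {
      cur_e <- max(cur_e, e[i])
    }
  }
  tot + (cur_e - cur_s)
}

#' Symmetric delta-relaxed metric set
#'
#' [symmetric_compare()] built on [relaxed_confusion()]: each track is
#' treated once as ground truth, the relaxed metric sets are averaged. At
#' `delta_ms = 0` this equals the classical symmetric metric set exactly;
#' relaxed metrics are monotone non-decreasing in `delta_ms` and never fall
#' below their classical counterparts.
#'
#' @inheritParams symmetric_compare
#' @param cfg An [ad_config()].
#' @export
ad_metric_set <- function(a, b, cfg = ad_config(), labels = NULL,
                          average = "macro_present") {
  labels <- labels %||% unique(c(a$label, b$label))
  m_ab <- metric_set_from_confusion(relaxed_confusion(a, b, cfg, labels = labels),
                                    average = average)
  m_ba <- metric_set_from_confusion(relaxed_confusion(b, a, cfg, labels = labels),
                                    average = average)
  average_metric_sets(list(m_ab, m_ba))
}
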