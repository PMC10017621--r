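# Independent brute-force oracles. They all work on a dense 1 ms expansion of
# the tracks (one label per millisecond) or on exhaustive enumeration, never
# on the package's interval-sweep code paths.

dense_labels <- function(track) {
  rep(track$label, track$end_ms - track$start_ms)
}

oracle_confusion <- function(gt, pred, labels) {
  lg <- factor(dense_labels(gt), levels = labels)
  lp <- factor(dense_labels(pred), levels = labels)
  m <- table(gt = lg, pred = lp)
  matrix(as.numeric(m), nrow = length(labels), dimnames = list(gt = labels, pred = labels))
}

# boundary scan on the dense expansion
oracle_transitions <- function(track) {
  lv <- dense_labels(track)
  n <- length(lv)
  chg <- which(lv[-1L] != lv[-n])
  data.frame(time_ms = chg, from_label = lv[chg], to_label = lv[chg + 1L],
             stringsAsFactors = FALSE)
}

# dense relaxation: a millisecond m (covering [m, m+1)) is credited when some
# ground-truth transition t satisfies t - delta <= m < t + delta and the
# predicted label equals the gt label just before or just after t
oracle_relaxed_confusion <- function(gt, pred, delta_ms, labels) {
  lg <- dense_labels(gt)
  lp <- dense_labels(pred)
  n <- length(lg)
  trans <- oracle_transitions(gt)
  credited <- rep(FALSE, n)
  for (k in seq_len(nrow(trans))) {
    t <- trans$time_ms[k]
    lo <- max(0L, t - delta_ms)
    hi <- min(n - 1L, t + delta_ms - 1L)
    if (hi < lo) next
    w <- lo:hi
    ok <- lp[w + 1L] %in% c(trans$from_label[k], trans$to_label[k])
    credited[w + 1L] <- credited[w + 1L] | ok
  }
  eff_pred <- ifelse(credited & lg != lp, lg, lp)
  m <- table(gt = factor(lg, levels = labels), pred = factor(eff_pred, levels = labels))
  matrix(as.numeric(m), nrow = length(labels), dimnames = list(gt = labels, pred = labels))
}

# segment-wise overlap scan on the dense expansion
oracle_noise_level <- function(real, annotated, idle = "idle") {
  lr <- dense_labels(real)
  la <- dense_labels(annotated)
  runs <- rle(la)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != idle
  if (!any(keep)) return(NA_real_)
  noise <- mapply(function(s, e, lab) !any(lr[s:e] == lab),
                  starts[keep], ends[keep], runs$values[keep])
  100 * sum(noise) / sum(keep)
}

# exhaustive one-to-one assignment minimizing total |delay| (small inputs)
oracle_min_delay_matching <- function(real, annotated) {
  nr <- nrow(real)
  na <- nrow(annotated)
  k <- min(nr, na)
  if (k == 0L) return(list(total_abs_delay = 0))
  best <- Inf
  r_sets <- utils::combn(nr, k, simplify = FALSE)
  a_perms <- perms(na, k)
  for (rs in r_sets) {
    for (ap in a_perms) {
      tot <- sum(abs(annotated$time_ms[ap] - real$time_ms[rs]))
      if (tot < best) best <- tot
    }
  }
  list(total_abs_delay = best)
}

perms <- function(n, k) {
  if (k == 0L) return(list(integer()))
  out <- list()
  rec <- function(chosen, left) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return()
    }
    for (x in left) rec(c(chosen, x), setdiff(left, x))
  }
  rec(integer(), seq_len(n))
  out
}

# per-ms hierarchy violation scan: milliseconds where a step lies under a
# phase that is not its parent
oracle_hierarchy_violation_ms <- function(va, o) {
  dur <- max(track_duration(va$phase_track), track_duration(va$step_track))
  ph <- totalize(va$phase_track, idle_label = o$idle_label, duration_ms = dur)
  st <- totalize(va$step_track, idle_label = o$idle_label, duration_ms = dur)
  lp <- dense_labels(ph)
  ls <- dense_labels(st)
  parent <- setNames(o$phases$name[match(o$steps$parent_phase_id, o$phases$id)],
                     o$steps$name)
  active <- ls != o$idle_label
  sum(active & lp != parent[ls])
}
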