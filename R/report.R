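#' Evaluate one pair of annotations of the same video
#'
#' Runs the full reliability protocol at both levels (phase and step) for two
#' annotations of one video: both tracks are totalized onto a common timeline
#' (the longer of the two durations, trailing time filled with idle), then
#' classical swap-averaged metrics, delta-relaxed metrics, and the transition
#' metrics (ATD, C_TM, NL) are computed. The directional transition metrics
#' are evaluated in both ground-truth directions and averaged, mirroring the
#' symmetric protocol; per-direction values are retained under `$directions`.
#' Note that a symmetric *signed* ATD is 0 by construction (delays negate
#' when ground truth and annotation swap roles), so inspect the per-direction
#' signed values, or use `delay_mode = "absolute"`, to see delay magnitudes.
#'
#' @param a,b [video_annotation()]s sharing a `video_id`.
#' @param cfg An [ad_config()].
#' @param idle_label Idle label used when totalizing.
#' @param average Macro-averaging scheme, see [per_class_prf()].
#' @return List with elements `phase` and `step`, each a
#'   `video_metric_report`: list with `video_id`, `level`, `classical` and
#'   `ad` ([metric_set()]s), `atd_s`, `ctm_pct`, `nl_pct`, and `directions`.
#' @export
evaluate_video_pair <- function(a, b, cfg = ad_config(), idle_label = "idle",
                                average = "macro_present") {
  stopifnot(inherits(a, "video_annotation"), inherits(b, "video_annotation"))
  if (a$video_id != b$video_id) {
    stop("annotations are for different videos ('", a$video_id, "' vs '",
         b$video_id, "')", call. = FALSE)
  }
  out <- lapply(c(phase = "phase", step = "step"), function(lv) {
    ta <- if (lv == "phase") a$phase_track else a$step_track
    tb <- if (lv == "phase") b$phase_track else b$step_track
    dur <- max(track_duration(ta), track_duration(tb))
    ta <- totalize(ta, idle_label = idle_label, duration_ms = dur)
    tb <- totalize(tb, idle_label = idle_label, duration_ms = dur)
    labels <- unique(c(ta$label, tb$label))

    classical <- symmetric_compare(ta, tb, labels = labels, average = average)
    ad <- ad_metric_set(ta, tb, cfg = cfg, labels = labels, average = average)

    ev_a <- extract_transitions(ta)
    ev_b <- extract_transitions(tb)
    dir_metrics <- function(real_tr, annot_tr, real_ev, annot_ev) {
      m <- match_transitions(real_ev, annot_ev)
      list(atd_s = average_transitional_delay(m, cfg),
           ctm_pct = coefficient_of_transitional_moments(real_ev, annot_ev),
           nl_pct = noise_level(real_tr, annot_tr, idle_label = idle_label),
           n_matched = nrow(m$matches),
           n_unmatched_real = nrow(m$unmatched_real),
           n_unmatched_annotated = nrow(m$unmatched_annotated))
    }
    d_ab <- dir_metrics(ta, tb, ev_a, ev_b)  # a as ground truth
    d_ba <- dir_metrics(tb, ta, ev_b, ev_a)
    avg2 <- function(x, y) {
      v <- c(x, y); v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else mean(v)
    }
    structure(
      list(video_id = a$video_id, level = lv,
           classical = classical, ad = ad,
           atd_s = avg2(d_ab$atd_s, d_ba$atd_s),
           ctm_pct = avg2(d_ab$ctm_pct, d_ba$ctm_pct),
           nl_pct = avg2(d_ab$nl_pct, d_ba$nl_pct),
           directions = list(a_as_gt = d_ab, b_as_gt = d_ba)),
      class = "video_metric_report"
    )
  })
  out
}

#' @export
print.video_metric_report <- function(x, ...) {
  cat(sprintf("<video_metric_report> video '%s', level %s\n", x$video_id, x$level))
  cat(sprintf("  classical: acc %.3f  kappa %s | AD: acc %.3f\n",
              x$classical$accuracy,
              if (is.na(x$classical$kappa)) "undef" else sprintf("%.3f", x$classical$kappa),
              x$ad$accuracy))
  cat(sprintf("  ATD %.2f s | C_TM %.1f%% | NL %.1f%%\n",
              x$atd_s, x$ctm_pct, x$nl_pct))
  invisible(x)
}

# the scalar metrics reported per video, in reliability-table column order
report_metric_names <- function() {
  c("kappa", "accuracy", "precision", "recall", "f1",
    "atd_s", "ctm_pct", "nl_pct",
    "ad_accuracy", "ad_precision", "ad_recall", "ad_f1")
}

report_metric_row <- function(r) {
  data.frame(
    video_id = r$video_id, level = r$level,
    kappa = r$classical$kappa, accuracy = r$classical$accuracy,
    precision = r$classical$precision, recall = r$classical$recall,
    f1 = r$classical$f1,
    atd_s = r$atd_s, ctm_pct = r$ctm_pct, nl_pct = r$nl_pct,
    ad_accuracy = r$ad$accuracy, ad_precision = r$ad$precision,
    ad_recall = r$ad$recall, ad_f1 = r$ad$f1,
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-video reports into a dataset summary
#'
#' Unweighted mean and sample (n-1) standard deviation of each metric across
#' videos, per level. Undefined (NA) per-video values are skipped and the
#' number of defined values is recorded per metric (`n_defined`); a
#' single-video dataset reports SD 0 with `n_defined = 1` as the flagged
#' degenerate convention.
#'
#' @param reports A list of `video_metric_report`s (flat, or the
#'   phase/step pairs returned by [evaluate_video_pair()]).
#' @param dataset_id Label for the cohort.
#' @return A `dataset_report`: list with `dataset_id`, `per_video`
#'   (`data.frame`, one row per video x level) and `summary` (`data.frame`
#'   with level, metric, mean, sd, n_defined).
#' @export
aggregate_dataset <- function(reports, dataset_id = "dataset") {
  if (length(reports) > 0L && !inherits(reports[[1L]], "video_metric_report")) {
    reports <- unlist(reports, recursive = FALSE)
  }
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "video_metric_report")))
  per_video <- do.call(rbind, lapply(reports, report_metric_row))
  rows <- list()
  for (lv in unique(per_video$level)) {
    sub <- per_video[per_video$level == lv, , drop = FALSE]
    for (m in report_metric_names()) {
      v <- sub[[m]][!is.na(sub[[m]])]
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, metric = m,
        mean = if (length(v) > 0L) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        n_defined = length(v), stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(dataset_id = dataset_id, per_video = per_video,
         summary = do.call(rbind, rows)),
    class = "dataset_report"
  )
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(sprintf("<dataset_report> '%s': %d video-level reports\n",
              x$dataset_id, nrow(x$per_video)))
  cat(render_table(x, format = "text"), sep = "\n")
  invisible(x)
}

# column layout shared by both render formats: heading, per-video column,
# and a scale applied before printing (fractions are shown as percent)
report_columns <- function() {
  data.frame(
    heading = c("Cohen's kappa", "Accuracy", "Precision", "Recall", "F1-score",
                "ATD (seconds)", "C_TM", "NL", "AD-accuracy", "AD-precision",
                "AD-recall", "AD-F1-score"),
    metric = c("kappa", "accuracy", "precision", "recall", "f1",
               "atd_s", "ctm_pct", "nl_pct",
               "ad_accuracy", "ad_precision", "ad_recall", "ad_f1"),
    scale = c(100, 100, 100, 100, 100, 1, 1, 1, 100, 100, 100, 100),
    stringsAsFactors = FALSE
  )
}

#' Render a dataset report as a reliability table
#'
#' One row per annotation level, columns in the conventional reliability
#' ordering (kappa, accuracy, precision, recall, F1, ATD in seconds, C_TM,
#' NL, then the AD variants), each cell `mean ± sd` to one decimal, with
#' fractions scaled to percent. `"tsv"` emits two numeric columns per metric
#' (`<metric>_mean`, `<metric>_sd`) so the table re-parses losslessly at the
#' printed precision; `"text"` emits an aligned human-readable table.
#'
#' @param dr A [aggregate_dataset()] result.
#' @param format `"tsv"` or `"text"`.
#' @return Character vector of table lines.
#' @export
render_table <- function(dr, format = c("tsv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(dr, "dataset_report"))
  cols <- report_columns()
  levels_present <- intersect(c("phase", "step"), unique(dr$summary$level))
  cell <- function(lv, i, part) {
    s <- dr$summary[dr$summary$level == lv & dr$summary$metric == cols$metric[i], ]
    val <- if (part == "mean") s$mean else s$sd
    if (is.na(val)) NA_real_ else round(val * cols$scale[i], 1)
  }
  if (format == "tsv") {
    heads <- c("level", as.vector(rbind(paste0(cols$metric, "_mean"),
                                        paste0(cols$metric, "_sd"))))
    lines <- paste(heads, collapse = "\t")
    for (lv in levels_present) {
      vals <- as.vector(rbind(
        vapply(seq_len(nrow(cols)), cell, numeric(1), lv = lv, part = "mean"),
        vapply(seq_len(nrow(cols)), cell, numeric(1), lv = lv, part = "sd")
      ))
      lines <- c(lines, paste(c(lv, formatC(vals, format = "f", digits = 1)),
                              collapse = "\t"))
    }
    return(lines)
  }
  # aligned text: "mean ± sd" cells
  body <- lapply(levels_present, function(lv) {
    vapply(seq_len(nrow(cols)), function(i) {
      m <- cell(lv, i, "mean"); s <- cell(lv, i, "sd")
      if (is.na(m)) "--" else sprintf("%.1f ± %.1f", m, s)
    }, character(1))
  })
  tab <- rbind(cols$heading, do.call(rbind, body))
  tab <- cbind(c(dr$dataset_id, levels_present), tab)
  widths <- apply(nchar(tab, type = "width"), 2, max)
  apply(tab, 1, function(row) {
    paste(mapply(formatC, row, width = widths, flag = "-"), collapse = "  ")
  })
}

#' Parse a TSV reliability table back into summary numbers
#'
#' Inverse of `render_table(dr, "tsv")` at the printed precision; used for
#' report round-tripping.
#'
#' @param lines Character vector of TSV lines.
#' @return `data.frame` with level, metric, mean, sd.
#' @export
parse_table_tsv <- function(lines) {
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  cols <- report_columns()
  out <- list()
  for (r in seq_len(nrow(df))) {
    for (i in seq_len(nrow(cols))) {
      out[[length(out) + 1L]] <- data.frame(
        level = df$level[r], metric = cols$metric[i],
        mean = df[[paste0(cols$metric[i], "_mean")]][r],
        sd = df[[paste0(cols$metric[i], "_sd")]][r],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Bar chart of mean per-label durations across cohorts
#'
#' One bar per ontology label (in canonical ontology order) per cohort,
#' height = mean duration in minutes over the cohort's videos; labels absent
#' from a cohort get zero-height bars.
#'
#' @param cohorts Named list of cohorts; each cohort is a list of
#'   [video_annotation()]s.
#' @param ontology The [ontology()] fixing label order.
#' @param level `"phase"` or `"step"`.
#' @param path Output image path (format from extension, e.g. `.png`, `.pdf`).
#' @return `path`, invisibly. The plotted data is attached as attribute
#'   `"data"` for programmatic checking.
#' @export
plot_duration_bars <- function(cohorts, ontology, level = c("phase", "step"),
                               path) {
  level <- match.arg(level)
  stopifnot(length(cohorts) >= 1L, !is.null(names(cohorts)))
  labs <- labels_at_level(ontology, level)
  df <- do.call(rbind, lapply(names(cohorts), function(cid) {
    per_video <- lapply(cohorts[[cid]], function(va) {
      tr <- if (level == "phase") va$phase_track else va$step_track
      durs <- tapply(tr$end_ms - tr$start_ms, factor(tr$label, levels = labs),
                     sum, default = 0)
      durs / 60000
    })
    mat <- do.call(rbind, per_video)
    data.frame(cohort = cid, label = factor(labs, levels = labs),
               mean_min = colMeans(mat), stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean_min,
                                        fill = .data$cohort)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "Mean duration (min)", fill = NULL,
                  title = sprintf("Average %s durations", level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  ggplot2::ggsave(path, p, width = 9, height = 4.5, dpi = 150)
  out <- invisible(path)
  attr(out, "data") <- df
  out
}

#' Ribbon comparison plot of two annotation tracks
#'
#' Two horizontal ribbons on a shared time axis, one per rater; each coloured
#' segment's width is proportional to its duration, with a consistent
#' label-to-colour mapping taken from ontology order (so the same label has
#' the same colour in both ribbons, and every label present in either track
#' appears in the legend).
#'
#' @param a,b Comparable [annotation_track()]s.
#' @param ontology The [ontology()] fixing the colour order.
#' @param path Output image path.
#' @param names_ab Length-2 character, ribbon labels.
#' @return `path`, invisibly, with the plotted segment table attached as
#'   attribute `"data"`.
#' @export
plot_timeline_ribbon <- function(a, b, ontology, path,
                                 names_ab = c("rater A", "rater B")) {
  lv <- track_level(a)
  labs <- c(labels_at_level(ontology, lv), ontology$idle_label)
  dur <- max(track_duration(a), track_duration(b))
  ta <- totalize(a, idle_label = ontology$idle_label, duration_ms = dur)
  tb <- totalize(b, idle_label = ontology$idle_label, duration_ms = dur)
  seg <- rbind(
    data.frame(who = names_ab[1L], as.data.frame(ta), stringsAsFactors = FALSE),
    data.frame(who = names_ab[2L], as.data.frame(tb), stringsAsFactors = FALSE)
  )
  seg$label <- factor(seg$label, levels = labs)
  seg$who <- factor(seg$who, levels = rev(names_ab))
  pal <- stats::setNames(grDevices::hcl.colors(length(labs), "Spectral"), labs)
  pal[ontology$idle_label] <- "grey85"
  present <- labs[labs %in% unique(as.character(seg$label))]
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_ms / 60000, xmax = .data$end_ms / 60000,
      ymin = as.integer(.data$who) - 0.4, ymax = as.integer(.data$who) + 0.4,
      fill = .data$label)) +
    ggplot2::scale_fill_manual(values = pal, breaks = present, drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(seg$who)),
                                labels = levels(seg$who)) +
    ggplot2::labs(x = "Time (min)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 9, height = 2.6, dpi = 150)
  out <- invisible(path)
  attr(out, "data") <- seg
  out
}
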