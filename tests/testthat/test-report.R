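# small hand-built video pairs with known metric values
va_identity <- function(vid = "v1") {
  video_annotation(vid, "r",
                   tr(c("A", "B"), c(0, 60000, 100000), video_id = vid),
                   tr(c("s1", "s2"), c(0, 50000, 100000), video_id = vid,
                      level = "step"))
}

# phase accuracy 0.9 in both directions (the worked A/B example, in seconds)
va_shifted <- function(vid = "v2", rater = "r2") {
  video_annotation(vid, rater,
                   tr(c("A", "B"), c(0, 50000, 100000), video_id = vid),
                   tr(c("s1", "s2"), c(0, 45000, 100000), video_id = vid,
                      level = "step"))
}

test_that("self-comparison yields perfect agreement on every metric", {
  rep <- evaluate_video_pair(va_identity(), va_identity())
  for (lv in c("phase", "step")) {
    r <- rep[[lv]]
    expect_equal(r$classical$accuracy, 1)
    expect_equal(r$classical$kappa, 1)
    expect_equal(r$classical$f1, 1)
    expect_equal(r$ad$accuracy, 1)
    expect_equal(r$atd_s, 0)
    expect_equal(r$nl_pct, 0)
    expect_equal(r$ctm_pct, 100)
  }
  expect_error(evaluate_video_pair(va_identity("x"), va_identity("y")),
               "different videos")
})

test_that("jitter-only pairs keep C_TM at 100 and NL at 0 while accuracy drops", {
  a <- va_identity()
  b <- video_annotation("v1", "r2",
                        tr(c("A", "B"), c(0, 63000, 100000), video_id = "v1"),
                        tr(c("s1", "s2"), c(0, 52000, 100000), video_id = "v1",
                           level = "step"))
  rep <- evaluate_video_pair(a, b)
  for (lv in c("phase", "step")) {
    expect_equal(rep[[lv]]$ctm_pct, 100)
    expect_equal(rep[[lv]]$nl_pct, 0)
    expect_lt(rep[[lv]]$classical$accuracy, 1)
  }
  # signed symmetric ATD cancels; the per-direction values carry the sign
  expect_equal(rep$phase$atd_s, 0)
  expect_equal(rep$phase$directions$a_as_gt$atd_s, 3)
  expect_equal(rep$phase$directions$b_as_gt$atd_s, -3)
})

test_that("insertion-only pairs push C_TM above 100 in the annotated direction", {
  a <- va_identity()
  b <- video_annotation("v1", "r2",
                        tr(c("A", "C", "A", "B"),
                           c(0, 20000, 30000, 60000, 100000), video_id = "v1"),
                        va_identity()$step_track)
  rep <- evaluate_video_pair(a, b)
  expect_equal(rep$phase$directions$a_as_gt$ctm_pct, 300)  # 3 annotated vs 1 real
  expect_equal(rep$phase$directions$b_as_gt$ctm_pct, 100 / 3)
  expect_gt(rep$phase$nl_pct, 0)
})

test_that("aggregation computes unweighted mean and sample SD, skipping undefined values", {
  reports <- list(evaluate_video_pair(va_identity("v1"), va_identity("v1")),
                  evaluate_video_pair(va_identity("v2"),
                                      va_shifted("v2")))
  dr <- aggregate_dataset(reports, "toy")
  s <- dr$summary
  acc <- s[s$level == "phase" & s$metric == "accuracy", ]
  expect_equal(acc$mean, 0.95)
  expect_equal(acc$sd, stats::sd(c(0.9, 1)))  # ~0.0707
  expect_identical(acc$n_defined, 2L)

  # ten identical reports: SD 0
  same <- replicate(10, evaluate_video_pair(va_shifted(), va_shifted()),
                    simplify = FALSE)
  dr10 <- aggregate_dataset(same)
  expect_true(all(dr10$summary$sd == 0))

  # single video: SD reported as 0 with n_defined = 1
  dr1 <- aggregate_dataset(list(evaluate_video_pair(va_identity(), va_identity())))
  expect_true(all(dr1$summary$sd == 0))
  expect_true(all(dr1$summary$n_defined <= 1))

  # permutation invariance over videos
  dr_rev <- aggregate_dataset(rev(reports), "toy")
  expect_equal(dr_rev$summary[order(dr_rev$summary$level, dr_rev$summary$metric), ],
               s[order(s$level, s$metric), ], ignore_attr = TRUE)

  # AD summary dominates the classical summary metric-wise
  for (m in c("accuracy", "precision", "recall", "f1")) {
    for (lv in c("phase", "step")) {
      expect_gte(s[s$level == lv & s$metric == paste0("ad_", m), "mean"],
                 s[s$level == lv & s$metric == m, "mean"] - 1e-12)
    }
  }
})

test_that("rendered tables follow the reliability-table column order and round-trip", {
  reports <- list(evaluate_video_pair(va_identity("v1"), va_identity("v1")),
                  evaluate_video_pair(va_identity("v2"), va_shifted("v2")))
  dr <- aggregate_dataset(reports, "toy")

  txt <- render_table(dr, "text")
  expect_match(txt[1], paste0("Cohen's kappa.*Accuracy.*Precision.*Recall.*",
                              "F1-score.*ATD \\(seconds\\).*C_TM.*NL.*",
                              "AD-accuracy.*AD-precision.*AD-recall.*AD-F1-score"))
  expect_length(txt, 3)  # header + phase + step

  # identity-only cohort renders 100.0 ± 0.0 across agreement columns
  ident <- aggregate_dataset(list(evaluate_video_pair(va_identity(), va_identity())))
  itxt <- render_table(ident, "text")
  expect_match(itxt[2], "100.0 ± 0.0", fixed = TRUE)

  tsv <- render_table(dr, "tsv")
  parsed <- parse_table_tsv(tsv)
  for (r in seq_len(nrow(parsed))) {
    s <- dr$summary[dr$summary$level == parsed$level[r] &
                      dr$summary$metric == parsed$metric[r], ]
    scale <- ifelse(parsed$metric[r] %in% c("atd_s", "ctm_pct", "nl_pct"), 1, 100)
    expect_equal(parsed$mean[r], round(s$mean * scale, 1))
    expect_equal(parsed$sd[r], round(s$sd * scale, 1))
  }
})

test_that("duration bar data matches hand-computed means and zero-height absentees", {
  o <- toy_ontology()
  v1 <- video_annotation("v1", "r",
                         tr(c("P1", "P2"), c(0, 60000, 100000), video_id = "v1"),
                         tr("s1", c(0, 100000), video_id = "v1", level = "step"))
  v2 <- video_annotation("v2", "r",
                         tr("P1", c(0, 40000), video_id = "v2"),
                         tr("s1", c(0, 40000), video_id = "v2", level = "step"))
  path <- withr::local_tempfile(fileext = ".png")
  res <- plot_duration_bars(list(c1 = list(v1, v2)), o, "phase", path)
  expect_true(file.exists(path))
  d <- attr(res, "data")
  # P1: mean(60, 40) s = 50 s; P2 present only in v1: mean(40, 0) s = 20 s
  expect_equal(d$mean_min[d$label == "P1"], 50 / 60)
  expect_equal(d$mean_min[d$label == "P2"], 20 / 60)

  # a label absent from the whole cohort has zero height
  res0 <- plot_duration_bars(list(c1 = list(v2)), o, "phase",
                             withr::local_tempfile(fileext = ".png"))
  expect_equal(attr(res0, "data")$mean_min[attr(res0, "data")$label == "P2"], 0)
})

test_that("ribbon plots share the time axis and keep widths proportional to durations", {
  o <- toy_ontology()
  a <- tr(c("P1", "P2"), c(0, 60000, 100000))
  b <- tr("P1", c(0, 100000))
  path <- withr::local_tempfile(fileext = ".png")
  res <- plot_timeline_ribbon(a, b, o, path)
  expect_true(file.exists(path))
  seg <- attr(res, "data")
  wa <- seg[seg$who == "rater A", ]
  expect_equal(wa$end_ms - wa$start_ms, c(60000L, 40000L))
  # identical tracks render identical ribbons
  res2 <- plot_timeline_ribbon(a, a, o, withr::local_tempfile(fileext = ".png"))
  seg2 <- attr(res2, "data")
  expect_identical(seg2$start_ms[seg2$who == "rater A"],
                   seg2$start_ms[seg2$who == "rater B"])
  # a label present in only one track still appears in the fill levels
  expect_true("P2" %in% levels(seg$label))
})
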