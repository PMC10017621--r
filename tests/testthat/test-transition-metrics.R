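test_that("transition extraction finds every label change, idle included", {
  expect_identical(
    extract_transitions(tr(c("A", "B"), c(0, 50, 100))),
    data.frame(time_ms = 50L, from_label = "A", to_label = "B",
               stringsAsFactors = FALSE))
  expect_identical(nrow(extract_transitions(tr("A", c(0, 100)))), 0L)
  ev <- extract_transitions(tr(c("A", "idle", "B"), c(0, 40, 60, 100)))
  expect_identical(ev$time_ms, c(40L, 60L))
  expect_identical(ev$from_label, c("A", "idle"))
  # adjacent same-label intervals do not create a transition
  expect_identical(nrow(extract_transitions(tr(c("A", "A"), c(0, 50, 100)))), 0L)
})

test_that("transition extraction agrees with the dense boundary-scan oracle on random tracks", {
  set.seed(303)
  for (i in 1:40) {
    x <- random_totalized_track(sample(2000:30000, 1), n_labels = 4)
    got <- extract_transitions(x)
    want <- oracle_transitions(x)
    expect_identical(got$time_ms, as.integer(want$time_ms))
    expect_identical(got$from_label, want$from_label)
    expect_identical(got$to_label, want$to_label)
  }
})

test_that("matching pairs events one-to-one, signature first, then by |delay|", {
  ev <- function(t, from, to) data.frame(time_ms = as.integer(t),
                                         from_label = from, to_label = to,
                                         stringsAsFactors = FALSE)
  # identical lists: all matched at delay 0
  e <- ev(c(50, 200), c("A", "B"), c("B", "C"))
  m <- match_transitions(e, e)
  expect_identical(nrow(m$matches), 2L)
  expect_true(all(m$matches$delay_ms == 0))

  # one shifted pair
  m2 <- match_transitions(ev(50, "A", "B"), ev(58, "A", "B"))
  expect_identical(m2$matches$delay_ms, 8L)

  # spurious annotated event stays unmatched; the exhaustive minimum-total-
  # |delay| assignment agrees on this instance
  real <- ev(50, "A", "B")
  annot <- ev(c(48, 300), c("A", "C"), c("B", "A"))
  m3 <- match_transitions(real, annot)
  expect_identical(m3$matches$delay_ms, -2L)
  expect_identical(nrow(m3$unmatched_annotated), 1L)
  expect_identical(m3$unmatched_annotated$time_ms, 300L)
  expect_equal(sum(abs(m3$matches$delay_ms)),
               oracle_min_delay_matching(real, annot)$total_abs_delay)

  # signature match wins over a nearer event with the wrong signature
  real2 <- ev(100, "A", "B")
  annot2 <- ev(c(95, 130), c("C", "A"), c("D", "B"))
  m4 <- match_transitions(real2, annot2)
  expect_identical(m4$matches$annotated_time_ms, 130L)
  expect_identical(m4$matches$delay_ms, 30L)
})

test_that("matching is symmetric: swapping roles negates every delay (signature-unique case)", {
  set.seed(404)
  for (i in 1:25) {
    x <- random_totalized_track(sample(10000:40000, 1), n_labels = 5)
    pc <- perturbation_config(jitter_sd_ms = 400)
    y <- perturb_as_rater(
      video_annotation("v", "t", x, tr("s1", c(0, track_duration(x)), level = "step")),
      pc, toy_big_ontology(), seed = i)$phase_track
    ex <- extract_transitions(totalize(x))
    ey <- extract_transitions(totalize(y, duration_ms = track_duration(x)))
    m_xy <- match_transitions(ex, ey)
    m_yx <- match_transitions(ey, ex)
    expect_identical(sort(m_xy$matches$delay_ms), sort(-m_yx$matches$delay_ms))
  }
})

test_that("ATD arithmetic and modes", {
  mk <- function(delays) data.frame(real_time_ms = rep(0L, length(delays)),
                                    annotated_time_ms = as.integer(delays),
                                    from_label = rep("A", length(delays)),
                                    to_label = rep("B", length(delays)),
                                    delay_ms = as.integer(delays))
  expect_equal(average_transitional_delay(mk(c(0, 0))), 0)
  expect_equal(average_transitional_delay(mk(c(8000, -2000))), 3)
  expect_equal(average_transitional_delay(mk(c(8000, -2000)),
                                          ad_config(delay_mode = "absolute")), 5)
  expect_equal(average_transitional_delay(mk(5000)), 5)
  expect_true(is.na(average_transitional_delay(mk(integer(0)))))
})

test_that("C_TM is the annotated/real transition-count ratio in percent", {
  ev_n <- function(n) data.frame(time_ms = seq_len(n) * 10L,
                                 from_label = rep("A", n),
                                 to_label = rep("B", n),
                                 stringsAsFactors = FALSE)
  expect_equal(coefficient_of_transitional_moments(ev_n(30), ev_n(30)), 100)
  expect_equal(coefficient_of_transitional_moments(ev_n(30), ev_n(33)), 110)
  expect_equal(coefficient_of_transitional_moments(ev_n(5), ev_n(0)), 0)
  expect_true(is.na(coefficient_of_transitional_moments(ev_n(0), ev_n(5))))
})

test_that("noise level counts annotated segments with zero same-label overlap", {
  x <- tr(c("A", "B", "C"), c(0, 40000, 70000, 100000))
  expect_equal(noise_level(x, x), 0)
  # insert a 10 s segment of label D where the real track never has D:
  # annotated non-idle segments = 5 (A, B-left, D, B-right, C), 1 is noise
  y <- tr(c("A", "B", "D", "B", "C"),
          c(0, 40000, 50000, 60000, 70000, 100000))
  expect_equal(noise_level(x, y), 100 / 5)
  expect_equal(noise_level(x, y), oracle_noise_level(x, y))
  # every annotated segment mislabeled
  z <- tr(c("B", "C", "A"), c(0, 40000, 70000, 100000))
  expect_equal(noise_level(x, z), 100)
  # idle annotated segments are excluded from both counts
  w <- tr(c("A", "idle", "C"), c(0, 40000, 70000, 100000))
  expect_equal(noise_level(x, w), 0)
  expect_true(is.na(noise_level(x, tr("idle", c(0, 100000)))))
})

test_that("noise level agrees with the dense segment-overlap oracle on random tracks", {
  set.seed(505)
  for (i in 1:40) {
    dur <- sample(5000:40000, 1)
    a <- random_totalized_track(dur, n_labels = 4)
    b <- random_totalized_track(dur, n_labels = 4)
    expect_equal(noise_level(a, b), oracle_noise_level(a, b))
  }
})

test_that("relaxed confusion forgives near-boundary disagreement within delta only", {
  gt <- tr(c("A", "B"), c(0, 50000, 100000))
  late3 <- tr(c("A", "B"), c(0, 53000, 100000))
  cfg5 <- ad_config(delta_ms = 5000)
  # 3 s late inside delta: fully credited
  expect_equal(accuracy(relaxed_confusion(gt, late3, cfg5)), 1)
  expect_lt(accuracy(time_weighted_confusion(gt, late3)), 1)
  # 8 s late: 3 s of error remains
  late8 <- tr(c("A", "B"), c(0, 58000, 100000))
  cm8 <- relaxed_confusion(gt, late8, cfg5)
  expect_equal(cm8["B", "A"], 3000)
  expect_equal(accuracy(cm8), 0.97)
  # delta 0 reduces to the classical confusion
  expect_identical(relaxed_confusion(gt, late3, ad_config(delta_ms = 0)),
                   time_weighted_confusion(gt, late3))
  # totals conserved
  expect_equal(sum(cm8), 100000)
})

test_that("relaxed confusion equals the dense-sampling relaxation oracle on random tracks", {
  set.seed(606)
  for (i in 1:40) {
    dur <- sample(5000:40000, 1)
    a <- random_totalized_track(dur, n_labels = 4)
    b <- random_totalized_track(dur, n_labels = 4)
    delta <- sample(c(0L, 200L, 1000L, 5000L), 1)
    labels <- unique(c(a$label, b$label))
    expect_identical(relaxed_confusion(a, b, ad_config(delta_ms = delta),
                                       labels = labels) + 0,
                     oracle_relaxed_confusion(a, b, delta, labels))
  }
})

test_that("AD metric set dominates the classical set and is monotone in delta", {
  set.seed(707)
  for (i in 1:15) {
    dur <- sample(20000:60000, 1)
    a <- random_totalized_track(dur, n_labels = 4)
    b <- random_totalized_track(dur, n_labels = 4)
    cl <- symmetric_compare(a, b)
    prev <- NULL
    for (delta in c(0, 1000, 3000, 8000)) {
      ad <- ad_metric_set(a, b, ad_config(delta_ms = delta))
      if (delta == 0) {
        expect_equal(ad[c("accuracy", "precision", "recall", "f1", "kappa")],
                     cl[c("accuracy", "precision", "recall", "f1", "kappa")])
      }
      for (m in c("accuracy", "precision", "recall", "f1")) {
        expect_gte(ad[[m]], cl[[m]] - 1e-12)
        if (!is.null(prev)) expect_gte(ad[[m]], prev[[m]] - 1e-12)
      }
      prev <- ad
    }
  }
  x <- tr(c("A", "B"), c(0, 50, 100))
  adx <- ad_metric_set(x, x, ad_config())
  expect_equal(adx$accuracy, 1)
  expect_equal(adx$f1, 1)
})
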