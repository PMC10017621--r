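#' Cohort profile: the statistical shape of a simulated video collection
#'
#' A `cohort_profile` specifies, per phase: a log-normal duration
#' distribution (given as mean and SD in minutes) and an inclusion
#' probability (1 for obligatory phases; facultative phases are included by
#' an independent Bernoulli draw per video). Steps tile their parent phase
#' using fixed relative duration weights, with their own inclusion
#' probability for facultative steps. An idle lead-in and tail model
#' un-annotated time before the first and after the last phase.
#'
#' Two named profiles ship with the package, emulating the center-specific
#' technique differences reported for two bariatric-surgery cohorts: a
#' `"strasbourg"`-like profile (longer videos, ~108 min, routine omentum
#' division / Petersen space closure / mesenteric defect closure: inclusion
#' 0.95 / 0.98 / 1.00, gastric pouch ~26 min, jejunojejunal anastomosis ~24
#' min, on average 10 phases and 33 steps per video) and a `"bern"`-like
#' profile (~75 min, inclusion 0.36 / 0.16 / 0.21 for the same three phases,
#' pouch ~15 min, jejunojejunostomy ~18 min, on average 8 phases and 27
#' steps). Inclusion probabilities not tied to a specific phase were
#' calibrated once so the expected phase/step counts match those averages.
#'
#' @param name `"strasbourg"` or `"bern"`.
#' @param ontology The ontology the profile refers to; defaults to the
#'   packaged LRYGB instance.
#' @return A `cohort_profile`: list with `name`, `phase_mean_min`,
#'   `phase_sd_min`, `phase_inclusion` (all named by phase label),
#'   `step_inclusion`, `step_weight` (named by step label),
#'   `idle_lead_mean_min`, `idle_tail_mean_min`.
#' @export
cohort_profile <- function(name = c("strasbourg", "bern"),
                           ontology = load_ontology(lrygb_ontology_path())) {
  name <- match.arg(name)
  ph <- labels_at_level(ontology, "phase")
  st <- labels_at_level(ontology, "step")
  stopifnot(length(ph) == 12L)

  mean_min <- c(5, 26, 6, 18, 3, 8, 6, 24, 6, 4, 2, 5)
  if (name == "bern") mean_min[c(2, 8)] <- c(15, 18)
  inclusion <- rep(1, 12)
  if (name == "strasbourg") {
    inclusion[c(1, 3, 5, 7, 9, 10, 12)] <- c(0.60, 0.95, 0.80, 0.98, 1.00, 0.52, 0.15)
    step_fac_p <- 0.45
  } else {
    inclusion[c(1, 3, 5, 7, 9, 10, 12)] <- c(0.60, 0.36, 0.80, 0.16, 0.21, 0.72, 0.15)
    step_fac_p <- 0.27
  }
  step_inclusion <- ifelse(ontology$steps$facultative, step_fac_p, 1)
  # relative within-phase duration weights; uneven on purpose so that step
  # boundaries are not equally spaced
  step_weight <- rep(c(1, 1.6, 0.7, 1.2), length.out = length(st))

  structure(
    list(name = name,
         phase_mean_min = stats::setNames(mean_min, ph),
         phase_sd_min = stats::setNames(0.35 * mean_min, ph),
         phase_inclusion = stats::setNames(inclusion, ph),
         step_inclusion = stats::setNames(step_inclusion, st),
         step_weight = stats::setNames(step_weight, st),
         idle_lead_mean_min = 2, idle_tail_mean_min = 1),
    class = "cohort_profile"
  )
}

# lognormal draw parameterized by arithmetic mean m and sd s (both > 0)
rlnorm_ms <- function(n, mean_min, sd_min) {
  sdlog2 <- log(1 + (sd_min / mean_min)^2)
  meanlog <- log(mean_min) - sdlog2 / 2
  round(stats::rlnorm(n, meanlog, sqrt(sdlog2)) * 60000)
}

#' Sample one ground-truth video annotation from a cohort profile
#'
#' Phases are laid out sequentially in canonical ontology order (facultative
#' phases included by Bernoulli draw), each with a log-normal duration; the
#' included steps of each phase tile it exactly according to the profile's
#' relative weights. An idle lead-in precedes the first phase and an idle
#' tail follows the last, so the tracks do not cover the full video span
#' until totalized. Deterministic under `seed`.
#'
#' @param ontology An [ontology()].
#' @param profile A [cohort_profile()].
#' @param seed Integer seed (local to this call; the caller's RNG state is
#'   untouched).
#' @param video_id,rater_id Identifiers for the result.
#' @return A [video_annotation()].
#' @export
sample_ground_truth <- function(ontology, profile, seed,
                                video_id = "video", rater_id = "truth") {
  stopifnot(inherits(ontology, "ontology"), inherits(profile, "cohort_profile"))
  with_local_seed(seed, {
    ph_labels <- labels_at_level(ontology, "phase")
    incl <- stats::runif(length(ph_labels)) < profile$phase_inclusion
    lead <- max(10000, rlnorm_ms(1, profile$idle_lead_mean_min, profile$idle_lead_mean_min / 2))
    tail_ms <- max(5000, rlnorm_ms(1, profile$idle_tail_mean_min, profile$idle_tail_mean_min / 2))

    t <- lead
    phase_rows <- list()
    step_rows <- list()
    for (i in seq_along(ph_labels)) {
      if (!incl[i]) next
      lab <- ph_labels[i]
      dur <- max(60000, rlnorm_ms(1, profile$phase_mean_min[lab], profile$phase_sd_min[lab]))
      phase_rows[[length(phase_rows) + 1L]] <-
        data.frame(label = lab, start_ms = t, end_ms = t + dur)
      # steps of this phase
      sdef <- ontology$steps[ontology$steps$parent_phase_id == ontology$phases$id[i], ]
      s_incl <- stats::runif(nrow(sdef)) < profile$step_inclusion[sdef$name]
      if (any(s_incl)) {
        sdef <- sdef[s_incl, , drop = FALSE]
        w <- profile$step_weight[sdef$name]
        cuts <- round(t + dur * cumsum(c(0, w)) / sum(w))
        keep <- cuts[-1L] > cuts[-length(cuts)]
        step_rows[[length(step_rows) + 1L]] <-
          data.frame(label = sdef$name[keep], start_ms = cuts[-length(cuts)][keep],
                     end_ms = cuts[-1L][keep])
      }
      t <- t + dur
    }
    duration <- t + tail_ms
    phase_track <- annotation_track(do.call(rbind, phase_rows), video_id,
                                    "phase", duration_ms = duration,
                                    ontology = ontology)
    step_track <- annotation_track(do.call(rbind, step_rows), video_id,
                                   "step", duration_ms = duration,
                                   ontology = ontology)
    video_annotation(video_id, rater_id, phase_track, step_track)
  })
}

#' Rater noise model
#'
#' Four noise channels stand in for human rater variability: Gaussian
#' boundary jitter (shifting each transition by `N(jitter_mean_ms,
#' jitter_sd_ms)`, optionally clamped to `jitter_max_abs_ms`), label
#' substitution (a segment's label is swapped for a confusable same-level
#' label), spurious insertion (a short extra segment spliced strictly inside
#' an existing one, adding exactly two transitions), and omission (a
#' facultative segment is relabelled idle, as if the rater had not annotated
#' that span).
#'
#' @param jitter_mean_ms,jitter_sd_ms Boundary jitter distribution (ms).
#' @param jitter_max_abs_ms Clamp on |jitter| per boundary (ms, `Inf` = none).
#' @param substitution_rate Per-segment probability of a label swap.
#' @param substitution_mode `"adjacent"` (swap with the neighbouring label in
#'   ontology order, a plausible rater confusion) or `"uniform"`.
#' @param insertion_rate Expected number of spurious segments per track
#'   (Poisson).
#' @param insertion_mean_ms,insertion_sd_ms Spurious-segment duration
#'   distribution (log-normal, ms).
#' @param deletion_rate Per-segment probability that a facultative segment is
#'   omitted.
#' @return A `perturbation_config`.
#' @export
perturbation_config <- function(jitter_mean_ms = 0, jitter_sd_ms = 0,
                                jitter_max_abs_ms = Inf,
                                substitution_rate = 0,
                                substitution_mode = c("adjacent", "uniform"),
                                insertion_rate = 0,
                                insertion_mean_ms = 20000,
                                insertion_sd_ms = 10000,
                                deletion_rate = 0) {
  stopifnot(jitter_sd_ms >= 0, jitter_max_abs_ms >= 0,
            substitution_rate >= 0, substitution_rate <= 1,
            insertion_rate >= 0, deletion_rate >= 0, deletion_rate <= 1)
  structure(
    list(jitter_mean_ms = jitter_mean_ms, jitter_sd_ms = jitter_sd_ms,
         jitter_max_abs_ms = jitter_max_abs_ms,
         substitution_rate = substitution_rate,
         substitution_mode = match.arg(substitution_mode),
         insertion_rate = insertion_rate,
         insertion_mean_ms = insertion_mean_ms,
         insertion_sd_ms = insertion_sd_ms,
         deletion_rate = deletion_rate),
    class = "perturbation_config"
  )
}

# jitter the internal boundaries of a totalized label sequence.
# boundaries that would invert an interval are clipped to keep every
# interval >= 1 ms (this slightly biases recovery under extreme jitter).
jitter_boundaries <- function(bounds, duration, pc) {
  if (length(bounds) == 0L) return(bounds)
  shift <- stats::rnorm(length(bounds), pc$jitter_mean_ms, pc$jitter_sd_ms)
  if (is.finite(pc$jitter_max_abs_ms)) {
    shift <- pmax(-pc$jitter_max_abs_ms, pmin(pc$jitter_max_abs_ms, shift))
  }
  b <- round(bounds + shift)
  b <- pmin(pmax(b, 1), duration - 1)
  for (i in seq_along(b)[-1L]) if (b[i] <= b[i - 1L]) b[i] <- b[i - 1L] + 1
  k <- length(b)
  if (b[k] > duration - 1) {  # clipped pile-up at the right edge
    b[k] <- duration - 1
    for (i in rev(seq_len(k - 1L))) if (b[i] >= b[i + 1L]) b[i] <- b[i + 1L] - 1
  }
  as.integer(b)
}

perturb_track <- function(track, pc, ontology, idle_label) {
  lv <- track_level(track)
  dur <- track_duration(track)
  tt <- merge_runs(totalize(track, idle_label = idle_label))
  labs <- tt$label
  bounds <- tt$end_ms[-nrow(tt)]

  # 1. boundary jitter
  if (length(bounds) > 0L && (pc$jitter_sd_ms > 0 || pc$jitter_mean_ms != 0)) {
    bounds <- jitter_boundaries(bounds, dur, pc)
  }
  seg <- data.frame(label = labs, start_ms = c(0L, bounds),
                    end_ms = c(bounds, dur), stringsAsFactors = FALSE)

  # 2. substitutions
  vocab <- labels_at_level(ontology, lv)
  if (pc$substitution_rate > 0) {
    hit <- which(seg$label != idle_label &
                   stats::runif(nrow(seg)) < pc$substitution_rate)
    for (i in hit) {
      pos <- match(seg$label[i], vocab)
      seg$label[i] <- if (pc$substitution_mode == "adjacent") {
        vocab[if (pos == length(vocab)) pos - 1L else pos + 1L]
      } else {
        sample(vocab[-pos], 1L)
      }
    }
  }

  # 3. spurious insertions, strictly interior to a non-idle segment so each
  #    adds exactly two transitions and splits its host into two pieces;
  #    inserted segments never host further insertions, keeping the
  #    noise-segment count equal to the insertion count by construction
  n_ins <- stats::rpois(1L, pc$insertion_rate)
  inserted <- rep(FALSE, nrow(seg))
  for (k in seq_len(n_ins)) {
    host_ok <- which(!inserted & seg$label != idle_label &
                       (seg$end_ms - seg$start_ms) >= 3000L)
    if (length(host_ok) == 0L) break
    w <- seg$end_ms[host_ok] - seg$start_ms[host_ok]
    i <- host_ok[sample.int(length(host_ok), 1L, prob = w)]
    span <- seg$end_ms[i] - seg$start_ms[i]
    d <- max(500L, min(round(span / 3),
                       rlnorm_ms(1, pc$insertion_mean_ms / 60000,
                                 pc$insertion_sd_ms / 60000)))
    s0 <- seg$start_ms[i] + sample.int(span - d - 1L, 1L)
    new_lab <- sample(setdiff(vocab, seg$label[i]), 1L)
    pieces <- data.frame(
      label = c(seg$label[i], new_lab, seg$label[i]),
      start_ms = c(seg$start_ms[i], s0, s0 + d),
      end_ms = c(s0, s0 + d, seg$end_ms[i]), stringsAsFactors = FALSE)
    keep_lo <- seq_len(i - 1L)
    keep_hi <- seq_len(nrow(seg)) > i
    seg <- rbind(seg[keep_lo, ], pieces, seg[keep_hi, ])
    inserted <- c(inserted[keep_lo], c(FALSE, TRUE, FALSE), inserted[keep_hi])
  }

  # 4. omissions of facultative segments
  if (pc$deletion_rate > 0) {
    fac <- if (lv == "phase") {
      ontology$phases$name[ontology$phases$facultative]
    } else {
      ontology$steps$name[ontology$steps$facultative]
    }
    hit <- seg$label %in% fac & stats::runif(nrow(seg)) < pc$deletion_rate
    seg$label[hit] <- idle_label
  }

  out <- annotation_track(seg[seg$label != idle_label, , drop = FALSE],
                          video_id = track_video_id(track), level = lv,
                          duration_ms = dur, ontology = ontology)
  out
}

#' Perturb a ground-truth annotation as a simulated rater
#'
#' Applies the [perturbation_config()] noise channels independently to the
#' phase and the step track. With all-zero noise the output equals the input
#' (up to merging of adjacent same-label intervals). Deterministic under
#' `seed`.
#'
#' @param truth A [video_annotation()].
#' @param pc A [perturbation_config()].
#' @param ontology The [ontology()] (for label vocabularies and facultative
#'   flags).
#' @param rater_id Identifier of the simulated rater.
#' @param seed Integer seed.
#' @param idle_label Idle label used during totalization.
#' @return A valid [video_annotation()].
#' @export
perturb_as_rater <- function(truth, pc, ontology, rater_id = "rater",
                             seed = 1L, idle_label = ontology$idle_label) {
  stopifnot(inherits(truth, "video_annotation"),
            inherits(pc, "perturbation_config"))
  with_local_seed(seed, {
    video_annotation(
      truth$video_id, rater_id,
      perturb_track(truth$phase_track, pc, ontology, idle_label),
      perturb_track(truth$step_track, pc, ontology, idle_label)
    )
  })
}

#' Generate a paired two-rater cohort
#'
#' Draws `n` ground-truth videos from `profile` and perturbs each
#' independently with two rater noise configurations. One global integer
#' seed fans out deterministically to per-video streams (`seed * 1000 + 3 *
#' video_index + channel`), so cohorts are byte-identical on re-run and
#' extensible in `n` without reusing random streams.
#'
#' @param ontology An [ontology()].
#' @param profile A [cohort_profile()].
#' @param pc_a,pc_b [perturbation_config()]s for the two raters.
#' @param n Number of videos.
#' @param seed Global integer seed.
#' @param id_prefix Prefix for generated video ids.
#' @return List with `truth`, `rater_a`, `rater_b`: parallel lists of
#'   [video_annotation()]s.
#' @export
generate_cohort <- function(ontology, profile, pc_a, pc_b, n, seed,
                            id_prefix = "video") {
  stopifnot(n >= 1L)
  truth <- vector("list", n)
  ra <- vector("list", n)
  rb <- vector("list", n)
  for (i in seq_len(n)) {
    vid <- sprintf("%s%03d", id_prefix, i)
    base <- seed * 1000 + 3 * i
    truth[[i]] <- sample_ground_truth(ontology, profile, seed = base, video_id = vid)
    ra[[i]] <- perturb_as_rater(truth[[i]], pc_a, ontology, "raterA", seed = base + 1)
    rb[[i]] <- perturb_as_rater(truth[[i]], pc_b, ontology, "raterB", seed = base + 2)
  }
  list(truth = truth, rater_a = ra, rater_b = rb)
}

# run code under a temporary RNG state; restores the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
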