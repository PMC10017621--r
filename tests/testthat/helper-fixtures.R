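# Compact fixture builders used across the suite.

# track from a label sequence and its boundary vector (length = labels + 1)
tr <- function(labels, bounds, video_id = "v", level = "phase",
               duration_ms = NULL) {
  annotation_track(
    data.frame(label = labels, start_ms = bounds[-length(bounds)],
               end_ms = bounds[-1L]),
    video_id = video_id, level = level, duration_ms = duration_ms
  )
}

# a random gap-free (totalized) track: k segments over [0, duration)
random_totalized_track <- function(duration_ms, n_labels = 4,
                                   max_segments = 12, video_id = "v",
                                   level = "phase", idle = TRUE) {
  k <- sample(2:max_segments, 1)
  cuts <- sort(sample(seq_len(duration_ms - 1L), k - 1L))
  vocab <- c(LETTERS[seq_len(n_labels)], if (idle) "idle")
  labs <- sample(vocab, k, replace = TRUE)
  tr(labs, c(0L, cuts, duration_ms), video_id = video_id, level = level)
}

toy_ontology <- function() {
  ontology(
    name = "toy",
    phases = data.frame(id = 1:2, name = c("P1", "P2"), facultative = c(FALSE, TRUE)),
    steps = data.frame(id = 1:3, name = c("s1", "s2", "s3"),
                       facultative = c(FALSE, FALSE, TRUE),
                       parent_phase_id = c(1L, 1L, 2L))
  )
}

# a wide flat ontology whose phase labels cover the random-track vocabulary
toy_big_ontology <- function() {
  ontology(
    name = "toy-wide",
    phases = data.frame(id = 1:6, name = LETTERS[1:6], facultative = FALSE),
    steps = data.frame(id = 1:2, name = c("s1", "s2"), facultative = FALSE,
                       parent_phase_id = c(1L, 2L))
  )
}

lrygb <- local({
  o <- NULL
  function() {
    if (is.null(o)) o <<- load_ontology(lrygb_ontology_path())
    o
  }
})
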