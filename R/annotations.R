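#' One rater's labelled intervals for one video at one level
#'
#' An `annotation_track` holds ordered, non-overlapping, half-open intervals
#' `[start_ms, end_ms)` in integer milliseconds, at either the phase or the
#' step level. Half-open intervals guarantee that no millisecond is counted
#' twice at a boundary. Gaps (un-annotated time) are permitted; [totalize()]
#' fills them with an explicit idle label when a total labelling of the
#' timeline is required.
#'
#' @param intervals `data.frame` with columns `label` (character), `start_ms`
#'   and `end_ms` (non-negative integers, `end_ms > start_ms`).
#' @param video_id Video identifier.
#' @param level `"phase"` or `"step"`.
#' @param duration_ms Total video length in ms; defaults to the largest
#'   `end_ms`.
#' @param ontology Optional [ontology()]; when given, every label must belong
#'   to the ontology at `level` or equal its idle label.
#'
#' @return An `annotation_track` (a `data.frame` with attributes `video_id`,
#'   `level`, `duration_ms`).
#' @export
#' @examples
#' tr <- annotation_track(
#'   data.frame(label = c("A", "B"), start_ms = c(0, 60000), end_ms = c(60000, 100000)),
#'   video_id = "v1", level = "phase"
#' )
#' track_duration(tr)
annotation_track <- function(intervals, video_id, level = c("phase", "step"),
                             duration_ms = NULL, ontology = NULL) {
  level <- match.arg(level)
  iv <- as.data.frame(intervals, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start_ms", "end_ms") %in% names(iv)))
  iv <- iv[c("label", "start_ms", "end_ms")]
  iv$label <- as.character(iv$label)
  iv$start_ms <- as.integer(round(iv$start_ms))
  iv$end_ms <- as.integer(round(iv$end_ms))
  iv <- iv[order(iv$start_ms), , drop = FALSE]
  rownames(iv) <- NULL

  if (nrow(iv) > 0L) {
    if (any(iv$start_ms < 0L)) stop("negative start_ms", call. = FALSE)
    bad <- which(iv$end_ms <= iv$start_ms)
    if (length(bad) > 0L) {
      stop("empty/inverted interval(s) at row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    ov <- which(iv$start_ms[-1L] < iv$end_ms[-nrow(iv)])
    if (length(ov) > 0L) {
      stop(sprintf("overlapping intervals: rows %d ('%s' [%d,%d)) and %d ('%s' [%d,%d))",
                   ov[1L], iv$label[ov[1L]], iv$start_ms[ov[1L]], iv$end_ms[ov[1L]],
                   ov[1L] + 1L, iv$label[ov[1L] + 1L], iv$start_ms[ov[1L] + 1L],
                   iv$end_ms[ov[1L] + 1L]),
           call. = FALSE)
    }
  }
  duration_ms <- as.integer(duration_ms %||% if (nrow(iv) > 0L) max(iv$end_ms) else 0L)
  if (nrow(iv) > 0L && max(iv$end_ms) > duration_ms) {
    stop("intervals extend beyond duration_ms", call. = FALSE)
  }
  if (!is.null(ontology)) {
    allowed <- c(labels_at_level(ontology, level), ontology$idle_label)
    unknown <- setdiff(iv$label, allowed)
    if (length(unknown) > 0L) {
      stop(sprintf("label(s) not in ontology at level '%s': %s", level,
                   paste(unique(unknown), collapse = ", ")), call. = FALSE)
    }
  }
  structure(iv, video_id = as.character(video_id), level = level,
            duration_ms = duration_ms,
            class = c("annotation_track", "data.frame"))
}

#' @rdname annotation_track
#' @param track An `annotation_track`.
#' @export
track_duration <- function(track) attr(track, "duration_ms")

#' @rdname annotation_track
#' @export
track_level <- function(track) attr(track, "level")

#' @rdname annotation_track
#' @export
track_video_id <- function(track) attr(track, "video_id")

#' Fill gaps of a track with explicit idle intervals
#'
#' Returns a track whose intervals tile `[0, duration_ms)` exactly: every gap
#' between annotated intervals and the un-annotated head/tail of the video is
#' filled with `idle_label`. Idempotent; total interval length afterwards
#' equals the duration exactly.
#'
#' @param track An `annotation_track`.
#' @param idle_label Label used for un-annotated time.
#' @param duration_ms Optionally extend the timeline to this duration (used
#'   when two raters trimmed the same video differently and must be compared
#'   on a common timeline).
#' @return A totalized `annotation_track`.
#' @export
totalize <- function(track, idle_label = "idle", duration_ms = NULL) {
  stopifnot(inherits(track, "annotation_track"))
  dur <- as.integer(max(attr(track, "duration_ms"), duration_ms %||% 0L))
  if (dur <= 0L) stop("cannot totalize a zero-duration track", call. = FALSE)
  starts <- track$start_ms
  ends <- track$end_ms
  # gap boundaries: before first, between consecutive, after last
  gap_start <- c(0L, ends)
  gap_end <- c(starts, dur)
  keep <- gap_end > gap_start
  gaps <- data.frame(label = rep(idle_label, sum(keep)),
                     start_ms = gap_start[keep],
                     end_ms = gap_end[keep], stringsAsFactors = FALSE)
  iv <- rbind(as.data.frame(track)[c("label", "start_ms", "end_ms")], gaps)
  annotation_track(iv, video_id = attr(track, "video_id"),
                   level = attr(track, "level"), duration_ms = dur)
}

#' Merge adjacent same-label intervals into maximal segments
#'
#' A *segment* is a maximal run of identical labels. Segment counts (not raw
#' interval counts) are what the noise-level metric is defined on.
#'
#' @param track An `annotation_track` that tiles its timeline (see
#'   [totalize()]); gap-free input is required so runs are well defined.
#' @return An `annotation_track` with adjacent equal labels merged.
#' @export
merge_runs <- function(track) {
  stopifnot(inherits(track, "annotation_track"))
  n <- nrow(track)
  if (n <= 1L) return(track)
  contiguous <- track$start_ms[-1L] == track$end_ms[-n]
  new_run <- c(TRUE, !(contiguous & track$label[-1L] == track$label[-n]))
  first <- which(new_run)
  last <- c(first[-1L] - 1L, n)
  iv <- data.frame(
    label = track$label[first],
    start_ms = track$start_ms[first],
    end_ms = track$end_ms[last],
    stringsAsFactors = FALSE
  )
  annotation_track(iv, video_id = attr(track, "video_id"),
                   level = attr(track, "level"),
                   duration_ms = attr(track, "duration_ms"))
}

#' Both tracks of one rater's annotation of one video
#'
#' @param video_id,rater_id Identifiers.
#' @param phase_track,step_track [annotation_track()]s at the respective
#'   level; they share `video_id` and, after construction, `duration_ms`
#'   (the maximum of the two is adopted for both).
#' @return A `video_annotation`.
#' @export
video_annotation <- function(video_id, rater_id, phase_track, step_track) {
  stopifnot(inherits(phase_track, "annotation_track"),
            inherits(step_track, "annotation_track"),
            track_level(phase_track) == "phase",
            track_level(step_track) == "step")
  if (track_video_id(phase_track) != video_id || track_video_id(step_track) != video_id) {
    stop("tracks do not share video_id '", video_id, "'", call. = FALSE)
  }
  dur <- max(track_duration(phase_track), track_duration(step_track))
  attr(phase_track, "duration_ms") <- dur
  attr(step_track, "duration_ms") <- dur
  structure(
    list(video_id = as.character(video_id), rater_id = as.character(rater_id),
         phase_track = phase_track, step_track = step_track),
    class = "video_annotation"
  )
}

#' @export
print.video_annotation <- function(x, ...) {
  cat(sprintf("<video_annotation> video '%s', rater '%s', %.1f min\n",
              x$video_id, x$rater_id, track_duration(x$phase_track) / 60000))
  cat(sprintf("  phase track: %d intervals; step track: %d intervals\n",
              nrow(x$phase_track), nrow(x$step_track)))
  invisible(x)
}

#' Read one video/rater annotation from CSV
#'
#' The file format is a plain UTF-8 CSV with header columns
#' `video_id,rater_id,level,label,start_ms,end_ms` and an optional
#' `#duration_ms=<int>` comment line; rows with `level == "phase"` populate
#' the phase track, `level == "step"` the step track.
#'
#' @param path CSV file path.
#' @param ontology An [ontology()]; labels are validated against it.
#' @return A [video_annotation()].
#' @export
read_annotation_file <- function(path, ontology) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 5L)
  dur <- NULL
  m <- grep("^#duration_ms=", header, value = TRUE)
  if (length(m) > 0L) dur <- as.integer(sub("^#duration_ms=", "", m[1L]))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("video_id", "rater_id", "level", "label", "start_ms", "end_ms")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("annotation file '", path, "' missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("annotation file '", path, "' has no rows", call. = FALSE)
  if (length(unique(df$video_id)) != 1L || length(unique(df$rater_id)) != 1L) {
    stop("annotation file '", path, "' must hold exactly one video/rater",
         call. = FALSE)
  }
  bad_level <- which(!df$level %in% c("phase", "step"))
  if (length(bad_level) > 0L) {
    stop("annotation file '", path, "': unknown level '", df$level[bad_level[1L]],
         "' at data row ", bad_level[1L], call. = FALSE)
  }
  vid <- df$video_id[1L]
  dur <- as.integer(dur %||% max(df$end_ms))
  mk <- function(lv) {
    rows <- df[df$level == lv, , drop = FALSE]
    tryCatch(
      annotation_track(rows[c("label", "start_ms", "end_ms")], video_id = vid,
                       level = lv, duration_ms = dur, ontology = ontology),
      error = function(e) {
        stop("annotation file '", path, "', level '", lv, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  video_annotation(vid, df$rater_id[1L], mk("phase"), mk("step"))
}

#' Write one video/rater annotation to CSV
#'
#' Inverse of [read_annotation_file()]; `read(write(x))` is the identity on
#' valid annotations.
#'
#' @param va A [video_annotation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_file <- function(va, path) {
  stopifnot(inherits(va, "video_annotation"))
  rows <- rbind(
    data.frame(video_id = va$video_id, rater_id = va$rater_id, level = "phase",
               as.data.frame(va$phase_track), stringsAsFactors = FALSE),
    data.frame(video_id = va$video_id, rater_id = va$rater_id, level = "step",
               as.data.frame(va$step_track), stringsAsFactors = FALSE)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#duration_ms=%d", track_duration(va$phase_track)), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = 4L)
  invisible(path)
}

#' Check that step intervals nest inside their parent phase
#'
#' The agreement metrics treat the phase and step tracks independently, so a
#' step lying outside its parent phase is reported as a warning, never an
#' error. One warning is produced per maximal millisecond span where a step
#' interval overlaps phase time (including idle) that is not its parent.
#'
#' @param va A [video_annotation()].
#' @param ontology The [ontology()] defining step parentage.
#' @return Character vector of warnings; empty when all steps nest correctly.
#' @export
validate_hierarchy <- function(va, ontology) {
  stopifnot(inherits(va, "video_annotation"), inherits(ontology, "ontology"))
  idle <- ontology$idle_label
  phase_of_step <- stats::setNames(
    ontology$phases$name[match(ontology$steps$parent_phase_id, ontology$phases$id)],
    ontology$steps$name
  )
  ph <- totalize(va$phase_track, idle_label = idle,
                 duration_ms = track_duration(va$step_track))
  out <- character()
  for (i in seq_len(nrow(va$step_track))) {
    s <- va$step_track[i, ]
    if (s$label == idle) next
    parent <- phase_of_step[[s$label]]
    hit <- ph[ph$end_ms > s$start_ms & ph$start_ms < s$end_ms, , drop = FALSE]
    off <- hit[hit$label != parent, , drop = FALSE]
    for (j in seq_len(nrow(off))) {
      a <- max(s$start_ms, off$start_ms[j])
      b <- min(s$end_ms, off$end_ms[j])
      out[[length(out) + 1L]] <- sprintf(
        "step '%s' [%d,%d) overlaps phase '%s' (expected parent '%s') over [%d,%d)",
        s$label, s$start_ms, s$end_ms, off$label[j], parent, a, b)
    }
  }
  out
}
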