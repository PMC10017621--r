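#' Hierarchical phase/step annotation ontology
#'
#' An `ontology` is the label vocabulary used to annotate a surgical video at
#' two hierarchical levels: *phases* (first-level temporal components executed
#' sequentially) and *steps* (finer-grained actions accomplished within a
#' phase). Elements flagged `facultative` may legitimately be absent from an
#' individual procedure. A reserved `idle_label` denotes un-annotated time
#' (before the first trocar, between phases) so that a video timeline can be
#' labelled totally.
#'
#' @param name Ontology name.
#' @param phases `data.frame` with columns `id` (positive integer, contiguous
#'   from 1 in canonical order), `name` (unique non-empty character) and
#'   `facultative` (logical).
#' @param steps `data.frame` with columns `id`, `name`, `facultative` and
#'   `parent_phase_id` (must resolve to a phase `id`).
#' @param idle_label Reserved label for un-annotated time; must not collide
#'   with any phase or step name.
#' @param version Free-form schema version string.
#'
#' @return An object of class `ontology`.
#' @seealso [load_ontology()], [validate_ontology()], [labels_at_level()]
#' @export
#' @examples
#' o <- ontology(
#'   name = "toy",
#'   phases = data.frame(id = 1:2, name = c("A", "B"), facultative = FALSE),
#'   steps = data.frame(id = 1:3, name = c("a1", "a2", "b1"),
#'                      facultative = FALSE, parent_phase_id = c(1L, 1L, 2L))
#' )
#' labels_at_level(o, "phase")
ontology <- function(name, phases, steps, idle_label = "idle", version = "1.0") {
  o <- structure(
    list(
      name = as.character(name),
      version = as.character(version),
      idle_label = as.character(idle_label),
      phases = as.data.frame(phases, stringsAsFactors = FALSE),
      steps = as.data.frame(steps, stringsAsFactors = FALSE)
    ),
    class = "ontology"
  )
  v <- validate_ontology(o)
  if (length(v) > 0L) {
    stop("invalid ontology:\n", paste("-", v, collapse = "\n"), call. = FALSE)
  }
  o
}

#' Validate an ontology, reporting all violations
#'
#' Checks every structural invariant: column presence and types, unique and
#' contiguous phase ids, unique names, resolvable step parentage, and
#' non-collision of the idle label. Reports violations rather than raising, so
#' callers can list every problem at once.
#'
#' @param o An object as produced by [ontology()] or [load_ontology()] (not
#'   necessarily valid).
#' @return Character vector of human-readable violation descriptions; empty
#'   when the ontology is valid.
#' @export
validate_ontology <- function(o) {
  bad <- character()
  say <- function(...) bad[[length(bad) + 1L]] <<- sprintf(...)

  if (!is.list(o)) return("ontology must be a list")
  for (fld in c("name", "idle_label", "phases", "steps")) {
    if (is.null(o[[fld]])) say("missing field '%s'", fld)
  }
  if (length(bad) > 0L) return(bad)
  if (!nzchar(o$name)) say("ontology name must be non-empty")

  ph <- o$phases
  st <- o$steps
  for (col in c("id", "name", "facultative")) {
    if (!col %in% names(ph)) say("phases: missing column '%s'", col)
  }
  for (col in c("id", "name", "facultative", "parent_phase_id")) {
    if (!col %in% names(st)) say("steps: missing column '%s'", col)
  }
  if (length(bad) > 0L) return(bad)

  check_defs <- function(df, what) {
    if (anyNA(df$id) || any(df$id != as.integer(df$id)) || any(df$id < 1)) {
      say("%s: ids must be positive integers", what)
    }
    if (anyDuplicated(df$id)) {
      say("%s: duplicate id(s): %s", what,
          paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    }
    if (any(!nzchar(df$name) | is.na(df$name))) {
      say("%s: empty name for id(s): %s", what,
          paste(df$id[!nzchar(df$name) | is.na(df$name)], collapse = ", "))
    }
    if (anyDuplicated(df$name)) {
      say("%s: duplicate name(s): %s", what,
          paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
    }
    if (!is.logical(df$facultative) || anyNA(df$facultative)) {
      say("%s: facultative must be TRUE/FALSE", what)
    }
  }
  check_defs(ph, "phases")
  check_defs(st, "steps")

  if (!anyNA(ph$id) && !identical(sort(as.integer(ph$id)), seq_len(nrow(ph)))) {
    say("phases: ids must be contiguous 1..%d", nrow(ph))
  }
  dangling <- setdiff(st$parent_phase_id, ph$id)
  if (length(dangling) > 0L) {
    for (pid in dangling) {
      say("steps: parent_phase_id %s (step id(s) %s) resolves to no phase",
          pid, paste(st$id[st$parent_phase_id == pid], collapse = ", "))
    }
  }
  if (!nzchar(o$idle_label)) say("idle_label must be non-empty")
  if (o$idle_label %in% ph$name) say("idle_label '%s' collides with a phase name", o$idle_label)
  if (o$idle_label %in% st$name) say("idle_label '%s' collides with a step name", o$idle_label)
  bad
}

#' Load an ontology from a structured-text (YAML) file
#'
#' The on-disk schema has top-level keys `name`, `idle_label`, `phases` (list
#' of `{id, name, facultative}`) and `steps` (list of
#' `{id, name, facultative, parent_phase_id}`), plus an optional `version`.
#' The packaged LRYGB instance lives at
#' `system.file("extdata", "lrygb_ontology.yaml", package = "annotRR")`.
#'
#' @param path Path to an ontology YAML file.
#' @return A validated `ontology`.
#' @export
#' @examples
#' o <- load_ontology(lrygb_ontology_path())
#' nrow(o$phases)  # 12
#' nrow(o$steps)   # 46
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("ontology schema error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (key in c("name", "idle_label", "phases", "steps")) {
    if (is.null(raw[[key]])) {
      stop("ontology schema error in '", path, "': missing top-level key '",
           key, "'", call. = FALSE)
    }
  }
  bind_defs <- function(lst, cols) {
    rows <- lapply(lst, function(el) {
      miss <- setdiff(cols, names(el))
      if (length(miss) > 0L) {
        stop("ontology schema error in '", path, "': entry ",
             deparse(el, nlines = 1L), " missing key(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      el[cols]
    })
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    df$id <- as.integer(df$id)
    if ("parent_phase_id" %in% cols) df$parent_phase_id <- as.integer(df$parent_phase_id)
    df
  }
  o <- structure(
    list(
      name = as.character(raw$name),
      version = as.character(raw$version %||% "1.0"),
      idle_label = as.character(raw$idle_label),
      phases = bind_defs(raw$phases, c("id", "name", "facultative")),
      steps = bind_defs(raw$steps, c("id", "name", "facultative", "parent_phase_id"))
    ),
    class = "ontology"
  )
  v <- validate_ontology(o)
  if (length(v) > 0L) {
    stop("ontology validation failed for '", path, "':\n",
         paste("-", v, collapse = "\n"), call. = FALSE)
  }
  o
}

#' Write an ontology to its canonical YAML serialization
#'
#' Serialization is canonical (fixed key order, definition order preserved) so
#' that `save_ontology(load_ontology(p))` round-trips.
#'
#' @param o A validated `ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ontology <- function(o, path) {
  stopifnot(inherits(o, "ontology"))
  phase_list <- lapply(seq_len(nrow(o$phases)), function(i) {
    list(id = o$phases$id[i], name = o$phases$name[i],
         facultative = o$phases$facultative[i])
  })
  step_list <- lapply(seq_len(nrow(o$steps)), function(i) {
    list(id = o$steps$id[i], name = o$steps$name[i],
         facultative = o$steps$facultative[i],
         parent_phase_id = o$steps$parent_phase_id[i])
  })
  yaml::write_yaml(
    list(name = o$name, version = o$version, idle_label = o$idle_label,
         phases = phase_list, steps = step_list),
    path
  )
  invisible(path)
}

#' Canonical label list at one annotation level
#'
#' @param o An `ontology`.
#' @param level `"phase"` or `"step"`.
#' @return Character vector of labels in definition (canonical) order; the
#'   idle label is never included.
#' @export
labels_at_level <- function(o, level = c("phase", "step")) {
  stopifnot(inherits(o, "ontology"))
  level <- match.arg(level)
  if (level == "phase") o$phases$name else o$steps$name
}

#' Path to the packaged LRYGB ontology fixture
#'
#' @return File path of the versioned 12-phase / 46-step LRYGB ontology
#'   shipped with the package.
#' @export
lrygb_ontology_path <- function() {
  system.file("extdata", "lrygb_ontology.yaml", package = "annotRR", mustWork = TRUE)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %s (v%s): %d phases, %d steps, idle label '%s'\n",
              x$name, x$version, nrow(x$phases), nrow(x$steps), x$idle_label))
  n_fac <- sum(x$phases$facultative)
  cat(sprintf("  facultative: %d phases, %d steps\n", n_fac, sum(x$steps$facultative)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
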