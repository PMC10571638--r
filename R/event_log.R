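## Event-log domain model: typed containers for IntelliCage-style event data,
## CSV readers/writers, validation, canonical sort and phase slicing.

#' Construct an event log
#'
#' Bundles a table of time-stamped corner events with the animal registry and
#' the phase schedule, canonically sorts the events and (optionally) validates
#' the whole object.
#'
#' Events are sorted by `(animal_id, timestamp_s, kind)` where kinds at equal
#' timestamps order as `visit_start < nosepoke < lick < visit_end`, so that a
#' visit always opens before, and closes after, the responses it contains.
#'
#' @param events data.frame with columns `animal_id` (character),
#'   `timestamp_s` (numeric seconds since experiment start, >= 0), `corner`
#'   (`"reward"`, `"water"` or `"inactive"`), `side` (`"left"`, `"right"`,
#'   `"none"`), `kind` (`"visit_start"`, `"visit_end"`, `"nosepoke"`,
#'   `"lick"`) and `visit_seq` (integer per-animal visit counter).
#' @param registry data.frame with columns `animal_id`, `body_weight_g` (> 0)
#'   and `cohort`.
#' @param schedule data.frame with columns `phase`, `occurrence`, `start_s`,
#'   `end_s`, `alcohol_fraction` and `reward_corner`; windows are half-open
#'   `[start_s, end_s)`, non-overlapping and ordered.
#' @param validate logical; run [validate_event_log()] on the result.
#' @return An object of class `"eventlog"`: a list with elements `events`,
#'   `registry` and `schedule`.
#' @seealso [read_event_log()], [slice_phase()], [simulate_cohort()]
#' @export
event_log <- function(events, registry, schedule, validate = TRUE) {
  events <- as.data.frame(events)
  registry <- as.data.frame(registry)
  schedule <- as.data.frame(schedule)

  needed <- c("animal_id", "timestamp_s", "corner", "side", "kind", "visit_seq")
  miss <- setdiff(needed, names(events))
  if (length(miss) > 0) {
    stop_audcage(paste0("events table lacks column(s): ",
                        paste(miss, collapse = ", ")), "audcage_parse_error")
  }
  events <- events[needed]
  events$animal_id <- as.character(events$animal_id)
  events$timestamp_s <- as.numeric(events$timestamp_s)
  events$visit_seq <- as.integer(events$visit_seq)

  events <- canonical_sort(events)
  log <- structure(
    list(events = events, registry = registry, schedule = schedule),
    class = "eventlog"
  )
  if (validate) validate_event_log(log)
  log
}

#' @export
print.eventlog <- function(x, ...) {
  n_an <- length(unique(x$events$animal_id))
  cat(sprintf(
    "<eventlog> %d events, %d animal(s) observed (%d registered), %d phase window(s)\n",
    nrow(x$events), n_an, nrow(x$registry), nrow(x$schedule)
  ))
  if (nrow(x$events) > 0) {
    cat(sprintf("  time span: %.1f - %.1f s (%.1f days)\n",
                min(x$events$timestamp_s), max(x$events$timestamp_s),
                diff(range(x$events$timestamp_s)) / .SECONDS_PER_DAY))
  }
  invisible(x)
}

#' Canonically sort an event table
#'
#' Stable sort by animal, then timestamp, then the fixed kind order
#' `visit_start < nosepoke < lick < visit_end`. Idempotent.
#'
#' @param events event data.frame (see [event_log()]).
#' @return The sorted data.frame, row names dropped.
#' @export
canonical_sort <- function(events) {
  kind_rank <- match(events$kind, .kinds)
  o <- order(events$animal_id, events$timestamp_s, kind_rank, method = "radix")
  out <- events[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate an event log
#'
#' Checks the structural invariants of the event model and raises a classed
#' condition (`audcage_validation_error`) describing every violation class
#' found:
#' * unknown columns/enum levels, negative or missing timestamps;
#' * `animal_id`s absent from the registry;
#' * visit bookkeeping: each `(animal_id, visit_seq)` has exactly one
#'   `visit_start` and one `visit_end`, with `end >= start`, and visits of one
#'   animal do not overlap;
#' * orphan responses: every `nosepoke`/`lick` must fall inside the open visit
#'   carrying its `visit_seq`, at the same corner.
#'
#' @param log an `"eventlog"`.
#' @return `log`, invisibly, if valid.
#' @export
validate_event_log <- function(log) {
  ev <- log$events
  reg <- log$registry
  problems <- character(0)

  if (nrow(reg) > 0 && anyDuplicated(reg$animal_id)) {
    problems <- c(problems, "duplicated animal_id in registry")
  }
  if (nrow(reg) > 0 && any(!is.finite(reg$body_weight_g) | reg$body_weight_g <= 0)) {
    problems <- c(problems, "registry body_weight_g must be > 0")
  }

  if (nrow(ev) > 0) {
    if (anyNA(ev$timestamp_s) || any(ev$timestamp_s < 0)) {
      problems <- c(problems, "timestamps must be finite and >= 0")
    }
    bad_enum <- !(ev$corner %in% .corners) | !(ev$side %in% .sides) |
      !(ev$kind %in% .kinds)
    if (any(bad_enum)) {
      problems <- c(problems, sprintf(
        "invalid corner/side/kind in %d event row(s), e.g. row %d",
        sum(bad_enum), which(bad_enum)[1]
      ))
    }
    unknown <- !(ev$animal_id %in% reg$animal_id)
    if (any(unknown)) {
      problems <- c(problems, sprintf(
        "%d event(s) reference animal_id(s) absent from the registry: %s",
        sum(unknown),
        paste(utils::head(unique(ev$animal_id[unknown]), 5), collapse = ", ")
      ))
    }

    if (!any(bad_enum) && !anyNA(ev$timestamp_s)) {
      problems <- c(problems, .check_visit_structure(ev))
    }
  }

  if (length(problems) > 0) {
    stop_audcage(
      paste0("event log failed validation:\n  - ",
             paste(problems, collapse = "\n  - ")),
      "audcage_validation_error"
    )
  }
  invisible(log)
}

## visit nesting / orphan-response checks; assumes enums and timestamps clean
.check_visit_structure <- function(ev) {
  problems <- character(0)
  an_idx <- match(ev$animal_id, unique(ev$animal_id))
  key <- visit_key(an_idx, ev$visit_seq)

  is_start <- ev$kind == "visit_start"
  is_end <- ev$kind == "visit_end"
  skey <- key[is_start]
  ekey <- key[is_end]
  if (anyDuplicated(skey) || anyDuplicated(ekey)) {
    problems <- c(problems, "duplicated visit_start/visit_end for a visit_seq")
  }
  only_start <- setdiff(skey, ekey)
  only_end <- setdiff(ekey, skey)
  if (length(only_start) || length(only_end)) {
    problems <- c(problems, sprintf(
      "%d visit(s) lack a matching visit_start/visit_end pair",
      length(only_start) + length(only_end)
    ))
    return(problems)
  }
  if (anyDuplicated(skey)) return(problems)

  vstart <- ev$timestamp_s[is_start][order(skey)]
  vend <- ev$timestamp_s[is_end][order(ekey)]
  vcorner <- ev$corner[is_start][order(skey)]
  vkey <- sort(skey)
  if (any(vend < vstart)) {
    problems <- c(problems, "visit_end precedes visit_start for some visit(s)")
  }

  ## per-animal non-overlap: visits sorted by start; next start >= this end
  van <- floor(vkey / 1e7)
  o <- order(van, vstart, method = "radix")
  same_animal <- diff(van[o]) == 0
  overlap <- same_animal & (vstart[o][-1] < vend[o][-length(o)])
  if (any(overlap)) {
    problems <- c(problems, sprintf("%d overlapping visit pair(s) within an animal",
                                    sum(overlap)))
  }

  ## responses must sit inside their declared visit, same corner
  is_resp <- ev$kind %in% c("nosepoke", "lick")
  if (any(is_resp)) {
    m <- match(key[is_resp], vkey)
    orphan <- is.na(m)
    ok <- !orphan
    idx <- m[ok]
    inside <- ev$timestamp_s[is_resp][ok] >= vstart[idx] &
      ev$timestamp_s[is_resp][ok] <= vend[idx] &
      ev$corner[is_resp][ok] == vcorner[idx]
    n_bad <- sum(orphan) + sum(!inside)
    if (n_bad > 0) {
      bad_rows <- which(is_resp)[c(which(orphan), which(ok)[!inside])]
      problems <- c(problems, sprintf(
        "%d orphan nosepoke/lick event(s) outside an enclosing visit (event row(s) %s%s)",
        n_bad,
        paste(utils::head(sort(bad_rows), 5), collapse = ", "),
        if (n_bad > 5) ", ..." else ""
      ))
    }
  }
  problems
}

#' Read an event log from CSV files
#'
#' Reads the package's documented CSV dialect (UTF-8, comma separator, dot
#' decimal): `events.csv` with columns `animal_id, timestamp_s, corner, side,
#' kind, visit_seq`; `registry.csv` with `animal_id, body_weight_g, cohort`;
#' `schedule.csv` with `phase, occurrence, start_s, end_s, alcohol_fraction,
#' reward_corner`.
#'
#' Malformed rows (non-numeric timestamps, unknown enum levels) raise a parse
#' error naming the offending line number(s); structural problems (orphan
#' responses, unknown animals) raise a validation error via
#' [validate_event_log()].
#'
#' @param path path to the events CSV.
#' @param schedule_path path to the schedule CSV.
#' @param registry_path path to the registry CSV.
#' @return A validated `"eventlog"`.
#' @export
read_event_log <- function(path, schedule_path, registry_path) {
  for (p in c(path, schedule_path, registry_path)) {
    if (!file.exists(p)) stop_audcage(paste0("file not found: ", p),
                                      "audcage_parse_error")
  }
  ev <- data.table::fread(path, colClasses = list(character = c(
    "animal_id", "corner", "side", "kind"
  )), data.table = FALSE, showProgress = FALSE)
  .check_header(ev, c("animal_id", "timestamp_s", "corner", "side", "kind",
                      "visit_seq"), path)
  if (nrow(ev) > 0) {
    ev$timestamp_s <- suppressWarnings(as.numeric(ev$timestamp_s))
    ev$visit_seq <- suppressWarnings(as.integer(ev$visit_seq))
    bad <- is.na(ev$timestamp_s) | is.na(ev$visit_seq) |
      !(ev$corner %in% .corners) | !(ev$side %in% .sides) |
      !(ev$kind %in% .kinds)
    if (any(bad)) {
      # +1 for the header line
      lines <- utils::head(which(bad) + 1L, 10)
      stop_audcage(sprintf(
        "malformed event row(s) in %s at line(s): %s%s", path,
        paste(lines, collapse = ", "), if (sum(bad) > 10) ", ..." else ""
      ), "audcage_parse_error")
    }
  }

  reg <- data.table::fread(registry_path,
                           colClasses = list(character = c("animal_id", "cohort")),
                           data.table = FALSE, showProgress = FALSE)
  .check_header(reg, c("animal_id", "body_weight_g", "cohort"), registry_path)

  sch <- data.table::fread(schedule_path,
                           colClasses = list(character = c("phase", "reward_corner")),
                           data.table = FALSE, showProgress = FALSE)
  .check_header(sch, c("phase", "occurrence", "start_s", "end_s",
                       "alcohol_fraction", "reward_corner"), schedule_path)
  validate_schedule(sch)

  event_log(ev, reg, sch, validate = TRUE)
}

.check_header <- function(df, expected, path) {
  miss <- setdiff(expected, names(df))
  if (length(miss) > 0) {
    stop_audcage(sprintf("%s lacks required column(s): %s", path,
                         paste(miss, collapse = ", ")), "audcage_parse_error")
  }
}

#' Write an event log to CSV files
#'
#' Inverse of [read_event_log()]; writes `events.csv`, `registry.csv` and
#' `schedule.csv` into `dir`. Timestamps survive the round trip exactly
#' provided they carry at most millisecond resolution (the simulator's
#' convention).
#'
#' @param log an `"eventlog"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_event_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    registry = file.path(dir, "registry.csv"),
    schedule = file.path(dir, "schedule.csv")
  )
  data.table::fwrite(log$events, paths[["events"]])
  data.table::fwrite(log$registry, paths[["registry"]])
  data.table::fwrite(log$schedule, paths[["schedule"]])
  invisible(paths)
}

#' Validate a phase schedule
#'
#' Windows must be well-formed (`end_s > start_s`), non-overlapping, sorted by
#' start time, with known phase labels and `alcohol_fraction` in `[0, 1]`.
#' Occurrence numbers must count repeats of the same phase in order.
#'
#' @param schedule schedule data.frame (see [read_event_log()]).
#' @return `schedule`, invisibly.
#' @export
validate_schedule <- function(schedule) {
  if (nrow(schedule) == 0) return(invisible(schedule))
  if (any(!(schedule$phase %in% .phases))) {
    stop_audcage(paste0("unknown phase label(s): ",
                        paste(setdiff(schedule$phase, .phases), collapse = ", ")),
                 "audcage_validation_error")
  }
  if (any(schedule$end_s <= schedule$start_s)) {
    stop_audcage("schedule windows must satisfy end_s > start_s",
                 "audcage_validation_error")
  }
  if (is.unsorted(schedule$start_s)) {
    stop_audcage("schedule windows must be ordered by start_s",
                 "audcage_validation_error")
  }
  if (nrow(schedule) > 1 &&
      any(schedule$start_s[-1] < schedule$end_s[-nrow(schedule)])) {
    stop_audcage("schedule windows overlap", "audcage_validation_error")
  }
  if (any(schedule$alcohol_fraction < 0 | schedule$alcohol_fraction > 1)) {
    stop_audcage("alcohol_fraction must lie in [0, 1]",
                 "audcage_validation_error")
  }
  for (ph in unique(schedule$phase)) {
    occ <- schedule$occurrence[schedule$phase == ph]
    if (!identical(as.integer(occ), seq_along(occ))) {
      stop_audcage(sprintf("occurrence numbers of phase '%s' must be 1, 2, ...", ph),
                   "audcage_validation_error")
    }
  }
  invisible(schedule)
}

#' Look up a phase window
#'
#' @param schedule schedule data.frame.
#' @param phase phase label.
#' @param occurrence which repeat of the phase (1-based).
#' @return One-row data.frame (the window).
#' @export
phase_window <- function(schedule, phase, occurrence = 1L) {
  hit <- schedule$phase == phase & schedule$occurrence == occurrence
  if (sum(hit) != 1) {
    stop_audcage(sprintf("phase '%s' occurrence %d not found in schedule",
                         phase, occurrence), "audcage_lookup_error")
  }
  schedule[hit, , drop = FALSE]
}

#' Slice an event log to one phase window
#'
#' Returns the events whose timestamps fall inside the half-open window
#' `[start_s, end_s)` of the requested phase occurrence; the returned log's
#' schedule is restricted to that window. Boundary events belong to the later
#' window. Slices over all windows partition the events (no event appears in
#' two slices).
#'
#' @param log an `"eventlog"`.
#' @param phase phase label, e.g. `"extinction"`.
#' @param occurrence which repeat of the phase (default first).
#' @return An `"eventlog"` restricted to the window (not re-validated: visits
#'   that straddle the boundary keep their responses on either side).
#' @export
slice_phase <- function(log, phase, occurrence = 1L) {
  win <- phase_window(log$schedule, phase, occurrence)
  keep <- log$events$timestamp_s >= win$start_s & log$events$timestamp_s < win$end_s
  structure(
    list(events = log$events[keep, , drop = FALSE],
         registry = log$registry,
         schedule = win),
    class = "eventlog"
  )
}

#' Slice an event log to an arbitrary half-open time window
#'
#' Like [slice_phase()] but for an explicit `[from_s, to_s)` window, e.g. one
#' daily bin (24-h bins are anchored at the day-0 dark-phase onset,
#' `t = 0`). The resulting schedule is the windows of the original schedule
#' clipped to the slice, so downstream index functions can check spans.
#'
#' @param log an `"eventlog"`.
#' @param from_s,to_s window bounds in seconds, `to_s > from_s`.
#' @return An `"eventlog"` restricted to the window.
#' @export
slice_window <- function(log, from_s, to_s) {
  if (to_s <= from_s) {
    stop_audcage("slice_window needs to_s > from_s", "audcage_config_error")
  }
  keep <- log$events$timestamp_s >= from_s & log$events$timestamp_s < to_s
  sch <- log$schedule
  overl <- sch$end_s > from_s & sch$start_s < to_s
  sch <- sch[overl, , drop = FALSE]
  sch$start_s <- pmax(sch$start_s, from_s)
  sch$end_s <- pmin(sch$end_s, to_s)
  structure(
    list(events = log$events[keep, , drop = FALSE],
         registry = log$registry,
         schedule = sch),
    class = "eventlog"
  )
}

## events in [from, to) for one animal/kind/corner; internal workhorse
count_responses <- function(events, animal_id, kind, corner, from = -Inf, to = Inf) {
  sum(events$animal_id == animal_id & events$kind == kind &
        events$corner == corner &
        events$timestamp_s >= from & events$timestamp_s < to)
}

#' Default experimental schedule
#'
#' The package's reference timeline for a long-term home-cage AUD training
#' protocol (~89 days, seconds since the day-0 dark-phase onset): 4 d
#' adaptation; alcohol initiation at 4/8/12 % (3/3/6 d); 32 d free access to
#' 10 % alcohol; 3 d motivation (progressive-ratio) test; 3 d persistence test
#' (alternating 6-h active/non-active periods); 3 d free access (baseline);
#' 7 d extinction; 24 h cue relapse; 2 d alcohol relapse; 12 d free access;
#' and a second 7-d extinction test ending around day 89.
#'
#' @param day0_offset_s shift applied to all windows (seconds), default 0.
#' @return A schedule data.frame (see [read_event_log()] for columns).
#' @export
default_schedule <- function(day0_offset_s = 0) {
  d <- .SECONDS_PER_DAY
  plan <- list(
    list("adaptation",      4, 0.00),
    list("initiation_4",    3, 0.04),
    list("initiation_8",    3, 0.08),
    list("initiation_12",   6, 0.12),
    list("free_access",    32, 0.10),
    list("motivation",      3, 0.10),
    list("persistence",     3, 0.10),
    list("free_access",     3, 0.10),
    list("extinction",      7, 0.00),
    list("cue_relapse",     1, 0.00),
    list("alcohol_relapse", 2, 0.10),
    list("free_access",    12, 0.10),
    list("extinction",      7, 0.00)
  )
  phase <- vapply(plan, `[[`, "", 1)
  len <- vapply(plan, `[[`, 0, 2)
  frac <- vapply(plan, `[[`, 0, 3)
  end <- cumsum(len) * d
  start <- c(0, end[-length(end)])
  occurrence <- stats::ave(seq_along(phase), phase, FUN = seq_along)
  data.frame(
    phase = phase,
    occurrence = as.integer(occurrence),
    start_s = start + day0_offset_s,
    end_s = end + day0_offset_s,
    alcohol_fraction = frac,
    reward_corner = "reward",
    stringsAsFactors = FALSE
  )
}
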