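## Five per-animal behavioral indices computed from phase-sliced event logs:
## motivation breakpoint (M), extinction responding (E), cue-relapse
## responding (CR), first-day relapse intake (AR, g/kg/day) and persistence
## of non-rewarded seeking (P).

#' Progressive-ratio ladder
#'
#' Parameters of the progressive-ratio (motivation) test: the sequence of
#' nosepoke requirements, how many completed sets advance the requirement,
#' the maximum inter-poke gap within a burst, and the reward-access duration.
#'
#' @param requirements strictly increasing positive integers; the default
#'   ladder is 2, 4, 8, 12, 16, 20, 24, 28, 32, 36.
#' @param sets_to_advance completed sets of the current requirement needed to
#'   advance to the next (default 10).
#' @param max_intra_burst_gap_s pokes closer than this (seconds) within one
#'   visit belong to the same burst (default 1.0).
#' @param reward_access_s bottle-access duration after a completed set
#'   (default 5.0; informational, not used in scoring).
#' @return An object of class `"ratio_ladder"`.
#' @export
ratio_ladder <- function(requirements = c(2L, 4L, 8L, 12L, 16L, 20L, 24L, 28L, 32L, 36L),
                         sets_to_advance = 10L,
                         max_intra_burst_gap_s = 1.0,
                         reward_access_s = 5.0) {
  requirements <- as.integer(requirements)
  if (length(requirements) == 0) {
    stop_audcage("ladder must contain at least one requirement", "audcage_config_error")
  }
  if (any(requirements <= 0) || is.unsorted(requirements, strictly = TRUE)) {
    stop_audcage("ladder requirements must be strictly increasing positive integers",
                 "audcage_config_error")
  }
  if (sets_to_advance < 1) {
    stop_audcage("sets_to_advance must be >= 1", "audcage_config_error")
  }
  structure(list(requirements = requirements,
                 sets_to_advance = as.integer(sets_to_advance),
                 max_intra_burst_gap_s = max_intra_burst_gap_s,
                 reward_access_s = reward_access_s),
            class = "ratio_ladder")
}

#' Motivation breakpoint from a progressive-ratio phase slice
#'
#' Replays the animal's reward-corner nosepokes in time order. Within one
#' visit, consecutive pokes separated by less than
#' `ladder$max_intra_burst_gap_s` form a burst; when a burst reaches the
#' current requirement one set is completed and the burst counter resets
#' (door-open period). After `sets_to_advance` sets at a requirement, the
#' requirement advances to the next ladder value. A gap of at least the
#' threshold, or a visit boundary, resets a partial burst.
#'
#' @param log an `"eventlog"` sliced to one motivation phase (see
#'   [slice_phase()]).
#' @param animal_id which animal to score; must be present in the registry.
#' @param ladder a [ratio_ladder()].
#' @param rule `"current"` (default) returns the requirement in effect at the
#'   end of the slice (the level advanced *to*); `"last_completed"` returns
#'   the highest requirement at which at least one full set was completed.
#'   An animal that never completes a set returns the first ladder value
#'   under either rule.
#' @return Integer FR level.
#' @export
compute_breakpoint <- function(log, animal_id, ladder = ratio_ladder(),
                               rule = c("current", "last_completed")) {
  rule <- match.arg(rule)
  if (!animal_id %in% log$registry$animal_id) {
    stop_audcage(paste0("animal not in registry: ", animal_id), "audcage_lookup_error")
  }
  ev <- log$events
  sel <- ev$animal_id == animal_id & ev$kind == "nosepoke" & ev$corner == "reward"
  .breakpoint_replay(ev$timestamp_s[sel], ev$visit_seq[sel], ladder, rule)
}

## event-by-event ladder replay shared by compute_breakpoint() and
## build_behavior_matrix(); t and vs are one animal's reward-corner poke
## times and visit counters in canonical order
.breakpoint_replay <- function(t, vs, ladder, rule) {
  reqs <- ladder$requirements
  li <- 1L
  sets <- 0L
  run <- 0L
  best_completed <- 0L
  n <- length(t)
  if (n > 0) {
    for (j in seq_len(n)) {
      new_burst <- j == 1L || vs[j] != vs[j - 1L] ||
        (t[j] - t[j - 1L]) >= ladder$max_intra_burst_gap_s
      run <- if (new_burst) 1L else run + 1L
      if (run == reqs[li]) {
        sets <- sets + 1L
        run <- 0L
        if (best_completed < li) best_completed <- li
        if (sets == ladder$sets_to_advance) {
          sets <- 0L
          if (li < length(reqs)) li <- li + 1L
        }
      }
    }
  }
  if (rule == "current") reqs[li] else reqs[max(1L, best_completed)]
}

## reward-corner nosepoke count per animal in [from, to); returns named
## integer over `ids`
.np_counts <- function(events, ids, from, to, kind = "nosepoke") {
  sel <- events$kind == kind & events$corner == "reward" &
    events$timestamp_s >= from & events$timestamp_s < to
  tab <- table(factor(events$animal_id[sel], levels = ids))
  as.integer(tab)
}

.window_span_days <- function(win) (win$end_s - win$start_s) / .SECONDS_PER_DAY

#' Extinction index: average daily and baseline-relative nosepoke rates
#'
#' @param log an `"eventlog"` sliced to one 7-day extinction window.
#' @param baseline_log an `"eventlog"` sliced to the last whole day before
#'   the extinction test (one daily bin).
#' @param animal_id which animal to score.
#' @return Named numeric: `avg_daily_np` (total reward-corner nosepokes / 7)
#'   and `delta_np` (`avg_daily_np` minus the baseline-day count).
#' @export
compute_extinction_index <- function(log, baseline_log, animal_id) {
  win <- log$schedule
  if (nrow(win) != 1 || abs(.window_span_days(win) - 7) > 1e-9) {
    stop_audcage("extinction slice must span exactly 7 daily bins",
                 "audcage_schedule_error")
  }
  bwin <- baseline_log$schedule
  if (nrow(bwin) != 1 || abs(.window_span_days(bwin) - 1) > 1e-9) {
    stop_audcage("baseline slice must span exactly 1 daily bin",
                 "audcage_schedule_error")
  }
  total <- .np_counts(log$events, animal_id, win$start_s, win$end_s)
  base <- .np_counts(baseline_log$events, animal_id, bwin$start_s, bwin$end_s)
  avg <- total / 7
  c(avg_daily_np = avg, delta_np = avg - base)
}

#' Cue-relapse index: 24-h nosepoke count and change from last extinction day
#'
#' @param log an `"eventlog"` sliced to the 24-h cue-relapse window.
#' @param last_ext_day_log an `"eventlog"` sliced to the last extinction day
#'   (one daily bin).
#' @param animal_id which animal to score.
#' @return Named numeric: `daily_np` (reward-corner nosepokes during the 24-h
#'   cue test) and `delta_np` (`daily_np` minus the last-extinction-day
#'   count).
#' @export
compute_cue_relapse_index <- function(log, last_ext_day_log, animal_id) {
  win <- log$schedule
  if (nrow(win) != 1 || abs(.window_span_days(win) - 1) > 1e-9) {
    stop_audcage("cue-relapse slice must span exactly 1 daily bin",
                 "audcage_schedule_error")
  }
  bwin <- last_ext_day_log$schedule
  if (nrow(bwin) != 1 || abs(.window_span_days(bwin) - 1) > 1e-9) {
    stop_audcage("last-extinction-day slice must span exactly 1 daily bin",
                 "audcage_schedule_error")
  }
  daily <- .np_counts(log$events, animal_id, win$start_s, win$end_s)
  base <- .np_counts(last_ext_day_log$events, animal_id, bwin$start_s, bwin$end_s)
  c(daily_np = daily, delta_np = daily - base)
}

#' Calibrate the volume of a single lick
#'
#' Average lick volume = total volume consumed / number of licks, measured
#' cohort-wide over a multi-day water-consumption calibration. When no
#' calibration data are available, downstream functions use the package
#' default [DEFAULT_LICK_VOLUME_UL] (1.94 microlitres).
#'
#' @param total_volume_ul total volume consumed (microlitres, >= 0).
#' @param n_licks number of licks recorded over the same span (> 0).
#' @return Microlitres per lick.
#' @export
calibrate_lick_volume <- function(total_volume_ul, n_licks) {
  if (n_licks == 0) {
    stop_audcage("cannot calibrate lick volume: number of licks is zero (division by zero)",
                 "audcage_domain_error")
  }
  if (total_volume_ul < 0 || n_licks < 0) {
    stop_audcage("volumes and lick counts must be >= 0", "audcage_domain_error")
  }
  total_volume_ul / n_licks
}

#' Daily alcohol consumption in g/kg/day
#'
#' `n_licks * lick_volume_ul[ml] * alcohol_fraction * 1 g/ml / body_weight[kg]`.
#' The 1 g/ml density convention is applied to the alcohol fraction of the
#' consumed volume.
#'
#' @param n_licks licks of the alcohol solution per day (>= 0).
#' @param lick_volume_ul microlitres per lick (>= 0).
#' @param alcohol_fraction volume fraction of alcohol in `[0, 1]` (e.g. 0.12).
#' @param body_weight_g animal body weight in grams (> 0).
#' @return Grams of alcohol per kilogram body weight per day.
#' @export
compute_daily_consumption <- function(n_licks, lick_volume_ul, alcohol_fraction,
                                      body_weight_g) {
  if (any(body_weight_g <= 0)) {
    stop_audcage("body_weight_g must be > 0", "audcage_domain_error")
  }
  if (any(c(n_licks, lick_volume_ul, alcohol_fraction) < 0)) {
    stop_audcage("licks, lick volume and alcohol fraction must be >= 0",
                 "audcage_domain_error")
  }
  n_licks * (lick_volume_ul * 1e-3) * alcohol_fraction * 1 / (body_weight_g * 1e-3)
}

#' Persistence index: non-active-period responding
#'
#' The 3-day persistence test alternates six 6-hour "active" (A, FR1 reward
#' available, cue light on) and six 6-hour "non-active" (nA, no programmed
#' consequences) periods, starting with an active period at the window start
#' (the test begins at dark-phase onset).
#'
#' @param log an `"eventlog"` sliced to one 3-day persistence window.
#' @param animal_id which animal to score.
#' @param active_first logical; whether the first 6-h period is active
#'   (default `TRUE`).
#' @return Named numeric: `na_np` (reward-corner nosepokes summed over nA
#'   periods) and `delta_na_a` (`na_np` minus the A-period sum).
#' @export
compute_persistence_index <- function(log, animal_id, active_first = TRUE) {
  win <- log$schedule
  if (nrow(win) != 1 || abs(.window_span_days(win) - 3) > 1e-9) {
    stop_audcage("persistence slice must span 3 days of six 6-h active and six 6-h non-active periods",
                 "audcage_schedule_error")
  }
  period <- 6 * 3600
  bounds <- seq(win$start_s, win$end_s, by = period)
  active <- ((seq_len(12) %% 2) == 1) == active_first
  na_np <- 0L
  a_np <- 0L
  for (p in seq_len(12)) {
    cnt <- .np_counts(log$events, animal_id, bounds[p], bounds[p + 1])
    if (active[p]) a_np <- a_np + cnt else na_np <- na_np + cnt
  }
  c(na_np = na_np, delta_na_a = na_np - a_np)
}

#' Build the animals-by-behaviors matrix
#'
#' Computes all five behavioral indices (and their alternate variants) for
#' every registered animal: `M` (breakpoint), `E` / `E_delta` (extinction),
#' `CR` / `CR_delta` (cue relapse), `AR` (first relapse-day intake,
#' g/kg/day), `P` / `P_delta` (persistence). All five scored columns are
#' oriented so that larger values are more AUD-like.
#'
#' Animals with no events in one or more scored phases are excluded, with a
#' warning listing them (available afterwards as `attr(x, "excluded")`).
#'
#' @param log a full-experiment `"eventlog"` containing at least one
#'   occurrence of each of the five test phases.
#' @param lick_volume_ul microlitres per lick for the consumption formula;
#'   default the package calibration constant [DEFAULT_LICK_VOLUME_UL].
#' @param occurrence named list selecting which occurrence of each recurring
#'   phase to score (default: the first of each).
#' @param ladder a [ratio_ladder()] for the breakpoint.
#' @param breakpoint_rule passed to [compute_breakpoint()].
#' @return A data.frame of class `"behavior_matrix"`: `animal_id`, `M`, `E`,
#'   `E_delta`, `CR`, `CR_delta`, `AR`, `P`, `P_delta`; attributes
#'   `behaviors` (the five scored columns), `direction` (all `+1`) and
#'   `excluded`.
#' @export
build_behavior_matrix <- function(log,
                                  lick_volume_ul = DEFAULT_LICK_VOLUME_UL,
                                  occurrence = list(motivation = 1L, extinction = 1L,
                                                    cue_relapse = 1L,
                                                    alcohol_relapse = 1L,
                                                    persistence = 1L),
                                  ladder = ratio_ladder(),
                                  breakpoint_rule = "current") {
  sch <- log$schedule
  ev <- log$events
  ids <- log$registry$animal_id
  phases <- c("motivation", "extinction", "cue_relapse", "alcohol_relapse",
              "persistence")
  wins <- lapply(phases, function(ph) {
    phase_window(sch, ph, occurrence[[ph]] %||% 1L)
  })
  names(wins) <- phases

  ## completeness: an animal must appear in every scored phase window
  present <- vapply(wins, function(w) {
    sel <- ev$timestamp_s >= w$start_s & ev$timestamp_s < w$end_s
    ids %in% unique(ev$animal_id[sel])
  }, logical(length(ids)))
  if (length(ids) == 1) present <- matrix(present, nrow = 1)
  complete <- rowSums(present) == length(phases)
  excluded <- ids[!complete]
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d animal(s) missing from one or more scored phases: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  ids <- ids[complete]

  ## breakpoint: split motivation reward pokes by animal once, then replay
  mw <- wins[["motivation"]]
  msel <- ev$kind == "nosepoke" & ev$corner == "reward" &
    ev$timestamp_s >= mw$start_s & ev$timestamp_s < mw$end_s
  mfac <- factor(ev$animal_id[msel], levels = ids)
  mt <- split(ev$timestamp_s[msel], mfac)
  mv <- split(ev$visit_seq[msel], mfac)
  M <- vapply(ids, function(a) {
    as.numeric(.breakpoint_replay(mt[[a]], mv[[a]], ladder, breakpoint_rule))
  }, 0)

  ew <- wins[["extinction"]]
  E_total <- .np_counts(ev, ids, ew$start_s, ew$end_s)
  E_base <- .np_counts(ev, ids, ew$start_s - .SECONDS_PER_DAY, ew$start_s)
  E <- E_total / 7
  E_delta <- E - E_base

  cw <- wins[["cue_relapse"]]
  CR <- .np_counts(ev, ids, cw$start_s, cw$end_s)
  CR_base <- .np_counts(ev, ids, cw$start_s - .SECONDS_PER_DAY, cw$start_s)
  CR_delta <- CR - CR_base

  rw <- wins[["alcohol_relapse"]]
  licks <- .np_counts(ev, ids, rw$start_s, rw$start_s + .SECONDS_PER_DAY,
                      kind = "lick")
  bw <- log$registry$body_weight_g[match(ids, log$registry$animal_id)]
  AR <- compute_daily_consumption(licks, lick_volume_ul, rw$alcohol_fraction, bw)

  ## persistence: vectorized A/nA split over 6-h periods, active first
  pw <- wins[["persistence"]]
  psel <- ev$kind == "nosepoke" & ev$corner == "reward" &
    ev$timestamp_s >= pw$start_s & ev$timestamp_s < pw$end_s
  period_idx <- floor((ev$timestamp_s[psel] - pw$start_s) / 21600)
  in_active <- (period_idx %% 2) == 0
  pfac <- factor(ev$animal_id[psel], levels = ids)
  P <- as.integer(table(pfac[!in_active]))
  P_a <- as.integer(table(pfac[in_active]))
  P_delta <- P - P_a

  out <- data.frame(
    animal_id = ids,
    M = unname(M), E = E, E_delta = E_delta,
    CR = as.numeric(CR), CR_delta = as.numeric(CR_delta),
    AR = AR, P = as.numeric(P), P_delta = as.numeric(P_delta),
    stringsAsFactors = FALSE
  )
  structure(out,
            behaviors = .behaviors,
            direction = stats::setNames(rep(1, 5), .behaviors),
            excluded = excluded,
            class = c("behavior_matrix", "data.frame"))
}
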