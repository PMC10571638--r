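test_that("breakpoint follows the 10-sets advancement rule", {
  # zero nosepokes: no advancement from the first requirement
  expect_equal(compute_breakpoint(motivation_log(numeric(0), integer(0)), "A1"), 2L)

  # exactly 10 bursts of 2 pokes (gaps 0.5 s, one burst per visit): the
  # requirement advances once, to 4
  t <- c(); v <- c()
  for (i in 1:10) {
    t <- c(t, i * 1000 + c(0, 0.5)); v <- c(v, i, i)
  }
  expect_equal(compute_breakpoint(motivation_log(t, v), "A1"), 4L)

  # 9 bursts do not advance
  expect_equal(compute_breakpoint(motivation_log(t[1:18], v[1:18]), "A1"), 2L)

  # a gap >= 1 s inside a visit splits the burst
  t2 <- c(0, 0.5, 2.0, 2.5)  # two bursts of 2 within one visit
  expect_equal(compute_breakpoint(motivation_log(t2, rep(1, 4)), "A1"), 2L)

  # last_completed rule: after advancing to 4 with no further sets, the
  # highest completed requirement is still 2
  expect_equal(compute_breakpoint(motivation_log(t, v), "A1",
                                  rule = "last_completed"), 2L)

  expect_error(compute_breakpoint(motivation_log(t, v), "NOPE"),
               class = "audcage_lookup_error")
})

test_that("breakpoint equals the independent burst-decomposition oracle", {
  set.seed(42)
  for (i in 1:500) {
    st <- random_poke_stream(n_visits = sample(5:40, 1))
    log <- motivation_log(st$t, st$vseq)
    expect_equal(
      compute_breakpoint(log, "A1"),
      oracle_breakpoint(st$t, st$vseq),
      info = sprintf("random stream %d", i)
    )
  }
})

test_that("appending completed sets never decreases the breakpoint", {
  set.seed(9)
  for (i in 1:25) {
    st <- random_poke_stream(n_visits = sample(5:25, 1))
    bp0 <- compute_breakpoint(motivation_log(st$t, st$vseq), "A1")
    # append 10 full sets at bp0's requirement, each in its own later visit
    t_extra <- c(); v_extra <- c()
    t_base <- max(c(st$t, 0)) + 1000
    for (j in 1:10) {
      t_extra <- c(t_extra, t_base + j * 100 + 0.5 * (seq_len(bp0) - 1))
      v_extra <- c(v_extra, rep(1000 + j, bp0))
    }
    bp1 <- compute_breakpoint(
      motivation_log(c(st$t, t_extra), c(st$vseq, v_extra)), "A1")
    expect_gte(bp1, bp0)
  }
})

test_that("extinction index averages 7 daily bins against a baseline day", {
  day <- 86400
  ext <- daily_count_log(c(14, 10, 7, 7, 7, 7, 7), "extinction", t0 = day)
  base <- daily_count_log(20, "free_access", t0 = 0)
  out <- compute_extinction_index(ext, base, "A1")
  expect_equal(unname(round(out["avg_daily_np"], 2)), 8.43)
  expect_equal(unname(round(out["delta_np"], 2)), -11.57)

  # zero nosepokes in both
  ext0 <- daily_count_log(rep(0, 7), "extinction")
  base0 <- daily_count_log(0, "free_access", t0 = 7 * day)
  expect_equal(unname(compute_extinction_index(ext0, base0, "A1")), c(0, 0))

  # avg_daily_np is invariant to permuting the daily counts
  perm <- daily_count_log(c(7, 7, 14, 7, 10, 7, 7), "extinction", t0 = day)
  expect_equal(compute_extinction_index(perm, base, "A1")[["avg_daily_np"]],
               out[["avg_daily_np"]])

  # a 6-day slice is rejected
  ext6 <- daily_count_log(rep(1, 6), "extinction")
  expect_error(compute_extinction_index(ext6, base, "A1"),
               class = "audcage_schedule_error")
})

test_that("cue-relapse index is the 24-h count and its change from extinction", {
  cue <- daily_count_log(120, "cue_relapse")
  last_ext <- daily_count_log(30, "extinction", t0 = 5 * 86400)
  out <- compute_cue_relapse_index(cue, last_ext, "A1")
  expect_equal(unname(out), c(120, 90))

  # zero pokes on the cue day
  cue0 <- daily_count_log(0, "cue_relapse")
  expect_equal(unname(compute_cue_relapse_index(cue0, last_ext, "A1")),
               c(0, -30))

  # algebraic identity delta + last_day == daily
  expect_equal(out[["delta_np"]] + 30, out[["daily_np"]])

  expect_error(compute_cue_relapse_index(daily_count_log(c(1, 1), "cue_relapse"),
                                         last_ext, "A1"),
               class = "audcage_schedule_error")
})

test_that("lick-volume calibration divides volume by licks", {
  expect_equal(calibrate_lick_volume(9700, 5000), 1.94)
  expect_equal(calibrate_lick_volume(0, 100), 0)
  expect_error(calibrate_lick_volume(100, 0), "zero",
               class = "audcage_domain_error")
  # package default when uncalibrated
  expect_equal(DEFAULT_LICK_VOLUME_UL, 1.94)
})

test_that("daily consumption follows the licks x volume x fraction / weight formula", {
  expect_equal(compute_daily_consumption(1000, 1.94, 0.12, 20), 11.64)
  expect_equal(compute_daily_consumption(0, 1.94, 0.12, 20), 0)
  # joint linearity and inverse weight proportionality
  base <- compute_daily_consumption(500, 2, 0.1, 25)
  expect_equal(compute_daily_consumption(1000, 2, 0.1, 25), 2 * base)
  expect_equal(compute_daily_consumption(500, 4, 0.1, 25), 2 * base)
  expect_equal(compute_daily_consumption(500, 2, 0.2, 25), 2 * base)
  expect_equal(compute_daily_consumption(500, 2, 0.1, 50), base / 2)
  expect_error(compute_daily_consumption(1, 1, 0.1, 0),
               class = "audcage_domain_error")
})

test_that("persistence index sums non-active periods and their A-contrast", {
  ## 3 days = 12 six-hour periods, active first; put 10 pokes in each active
  ## and 5 in each non-active period
  period <- 6 * 3600
  ev <- NULL
  vs <- 0
  for (p in 0:11) {
    n <- if (p %% 2 == 0) 10 else 5
    vs <- vs + 1
    ev <- rbind(ev, visit_rows("A1", "reward", p * period + 100,
                               2 * seq_len(n), visit_seq = vs))
  }
  log <- event_log(ev, tiny_registry("A1"),
                   one_window_schedule("persistence", 0, 3 * 86400),
                   validate = FALSE)
  out <- compute_persistence_index(log, "A1")
  expect_equal(unname(out), c(30, -30))

  # swapping the A / nA labels negates the difference
  swapped <- compute_persistence_index(log, "A1", active_first = FALSE)
  expect_equal(swapped[["delta_na_a"]], 30)
  expect_equal(swapped[["na_np"]], 60)

  # zero pokes
  empty <- event_log(visit_rows("A1", "water", 5, numeric(0), visit_seq = 1),
                     tiny_registry("A1"),
                     one_window_schedule("persistence", 0, 3 * 86400),
                     validate = FALSE)
  expect_equal(unname(compute_persistence_index(empty, "A1")), c(0, 0))

  expect_error(
    compute_persistence_index(
      event_log(ev, tiny_registry("A1"),
                one_window_schedule("persistence", 0, 2 * 86400),
                validate = FALSE), "A1"),
    class = "audcage_schedule_error")
})

test_that("build_behavior_matrix assembles all indices for a cohort", {
  co <- small_cohort()
  bm <- build_behavior_matrix(co$log)
  expect_s3_class(bm, "behavior_matrix")
  expect_equal(nrow(bm), 10)
  expect_false(anyNA(bm[attr(bm, "behaviors")]))
  expect_equal(attr(bm, "behaviors"), c("M", "E", "CR", "AR", "P"))
  expect_equal(unname(attr(bm, "direction")), rep(1, 5))

  # column M equals the per-animal breakpoint computation
  mot <- slice_phase(co$log, "motivation", 1)
  M_each <- vapply(bm$animal_id, function(a) {
    as.numeric(compute_breakpoint(mot, a))
  }, 0)
  expect_equal(bm$M, unname(M_each))

  # column P equals the per-animal persistence computation
  per <- slice_phase(co$log, "persistence", 1)
  P_each <- vapply(bm$animal_id, function(a) {
    compute_persistence_index(per, a)[["na_np"]]
  }, 0)
  expect_equal(bm$P, unname(P_each))
})

test_that("a single-animal cohort yields a one-row matrix", {
  co1 <- simulate_cohort(sim_config(n_animals = 1, seed = 3))
  bm1 <- build_behavior_matrix(co1$log)
  expect_equal(nrow(bm1), 1)
  expect_false(anyNA(bm1[c("M", "E", "CR", "AR", "P")]))
})

test_that("counting indices ignore events at other corners", {
  day <- 86400
  ext <- daily_count_log(rep(3, 7), "extinction", t0 = day)
  base <- daily_count_log(5, "free_access", t0 = 0)
  ref <- compute_extinction_index(ext, base, "A1")

  # inject water-corner visits with pokes into the extinction window
  extra <- rbind(
    visit_rows("A1", "water", day + 50, c(1, 2, 3), visit_seq = 500),
    visit_rows("A1", "inactive", day + 7000, c(1, 2), visit_seq = 501)
  )
  ext2 <- event_log(rbind(ext$events, extra), ext$registry, ext$schedule,
                    validate = FALSE)
  expect_equal(compute_extinction_index(ext2, base, "A1"), ref)
})

test_that("animals absent from a scored phase are excluded with a warning", {
  co <- small_cohort()
  ev <- co$log$events
  drop_id <- co$log$registry$animal_id[1]
  mot <- phase_window(co$log$schedule, "motivation", 1)
  keep <- !(ev$animal_id == drop_id & ev$timestamp_s >= mot$start_s &
              ev$timestamp_s < mot$end_s)
  log2 <- event_log(ev[keep, ], co$log$registry, co$log$schedule,
                    validate = FALSE)
  expect_warning(bm <- build_behavior_matrix(log2), "excluding")
  expect_false(drop_id %in% bm$animal_id)
  expect_equal(attr(bm, "excluded"), drop_id)
  expect_equal(nrow(bm), 9)
})
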