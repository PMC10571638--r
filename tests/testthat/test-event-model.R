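test_that("a minimal well-formed CSV triple reads into a one-visit log", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "animal_id,timestamp_s,corner,side,kind,visit_seq",
    "A1,10,reward,none,visit_start,1",
    "A1,11,reward,left,nosepoke,1",
    "A1,15,reward,none,visit_end,1"
  ), file.path(dir, "events.csv"))
  writeLines(c("animal_id,body_weight_g,cohort", "A1,20,c1"),
             file.path(dir, "registry.csv"))
  writeLines(c("phase,occurrence,start_s,end_s,alcohol_fraction,reward_corner",
               "free_access,1,0,86400,0.1,reward"),
             file.path(dir, "schedule.csv"))
  log <- read_event_log(file.path(dir, "events.csv"),
                        file.path(dir, "schedule.csv"),
                        file.path(dir, "registry.csv"))
  expect_s3_class(log, "eventlog")
  expect_equal(nrow(log$events), 3)
  expect_equal(sum(log$events$kind == "visit_start"), 1)
})

test_that("an empty events file with valid headers yields an empty log", {
  dir <- withr::local_tempdir()
  writeLines("animal_id,timestamp_s,corner,side,kind,visit_seq",
             file.path(dir, "events.csv"))
  writeLines(c("animal_id,body_weight_g,cohort", "A1,20,c1"),
             file.path(dir, "registry.csv"))
  writeLines(c("phase,occurrence,start_s,end_s,alcohol_fraction,reward_corner",
               "free_access,1,0,86400,0.1,reward"),
             file.path(dir, "schedule.csv"))
  log <- read_event_log(file.path(dir, "events.csv"),
                        file.path(dir, "schedule.csv"),
                        file.path(dir, "registry.csv"))
  expect_equal(nrow(log$events), 0)
})

test_that("malformed rows raise a parse error naming the line number", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "animal_id,timestamp_s,corner,side,kind,visit_seq",
    "A1,10,reward,none,visit_start,1",
    "A1,oops,reward,left,nosepoke,1",
    "A1,15,reward,none,visit_end,1"
  ), file.path(dir, "events.csv"))
  writeLines(c("animal_id,body_weight_g,cohort", "A1,20,c1"),
             file.path(dir, "registry.csv"))
  writeLines(c("phase,occurrence,start_s,end_s,alcohol_fraction,reward_corner",
               "free_access,1,0,86400,0.1,reward"),
             file.path(dir, "schedule.csv"))
  expect_error(
    read_event_log(file.path(dir, "events.csv"), file.path(dir, "schedule.csv"),
                   file.path(dir, "registry.csv")),
    "line\\(s\\): 3", class = "audcage_parse_error"
  )
})

test_that("write_event_log / read_event_log round-trips the simulator output", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  paths <- write_event_log(co$log, dir)
  back <- read_event_log(paths[["events"]], paths[["schedule"]],
                         paths[["registry"]])
  expect_equal(back$events, co$log$events)
  expect_equal(back$registry, co$log$registry)
  expect_equal(back$schedule, co$log$schedule, ignore_attr = TRUE)
})

test_that("validation rejects the documented malformation classes", {
  reg <- tiny_registry("A1")
  sch <- one_window_schedule("free_access", 0, 86400)

  # orphan nosepoke: visit_seq without an enclosing visit
  ev <- visit_rows("A1", "reward", 10, c(1, 2), visit_seq = 1)
  orphan <- ev[ev$kind == "nosepoke", ][1, ]
  orphan$visit_seq <- 99L
  expect_error(event_log(rbind(ev, orphan), reg, sch),
               "orphan", class = "audcage_validation_error")

  # response outside its visit's time span
  late <- ev
  late$timestamp_s[late$kind == "nosepoke"][2] <- 500
  expect_error(event_log(late, reg, sch),
               "orphan", class = "audcage_validation_error")

  # unknown animal
  ev2 <- visit_rows("GHOST", "reward", 10, 1, visit_seq = 1)
  expect_error(event_log(rbind(ev, ev2), reg, sch),
               "absent from the registry", class = "audcage_validation_error")

  # overlapping visits of one animal
  v1 <- visit_rows("A1", "reward", 10, numeric(0), visit_seq = 1, duration = 50)
  v2 <- visit_rows("A1", "water", 30, numeric(0), visit_seq = 2, duration = 50)
  expect_error(event_log(rbind(v1, v2), reg, sch),
               "overlapping", class = "audcage_validation_error")

  # negative timestamp
  neg <- visit_rows("A1", "reward", -5, numeric(0), visit_seq = 1)
  expect_error(event_log(neg, reg, sch),
               "timestamps", class = "audcage_validation_error")
})

test_that("canonical sort is idempotent and orders kinds within a timestamp", {
  ev <- visit_rows("A1", "reward", 10, c(0, 0), visit_seq = 1)
  shuffled <- ev[sample(nrow(ev)), ]
  s1 <- canonical_sort(shuffled)
  expect_identical(canonical_sort(s1), s1)
  same_t <- s1[s1$timestamp_s == 10, ]
  expect_equal(same_t$kind[1], "visit_start")
})

test_that("slice_phase picks the requested occurrence and slices half-open", {
  sch <- rbind(
    one_window_schedule("extinction", 0, 7 * 86400, 0),
    data.frame(phase = "extinction", occurrence = 2L, start_s = 10 * 86400,
               end_s = 17 * 86400, alcohol_fraction = 0,
               reward_corner = "reward", stringsAsFactors = FALSE)
  )
  ev <- rbind(
    visit_rows("A1", "reward", 100, 1, visit_seq = 1),
    visit_rows("A1", "reward", 10 * 86400, 1, visit_seq = 2),   # boundary
    visit_rows("A1", "reward", 12 * 86400, 1, visit_seq = 3)
  )
  log <- event_log(ev, tiny_registry("A1"), sch)

  s2 <- slice_phase(log, "extinction", 2)
  expect_equal(sort(unique(s2$events$visit_seq)), c(2L, 3L))
  expect_equal(nrow(s2$schedule), 1)

  # boundary event belongs to the later window
  expect_true(any(s2$events$timestamp_s == 10 * 86400))
  s1 <- slice_phase(log, "extinction", 1)
  expect_false(any(s1$events$timestamp_s >= 7 * 86400))

  expect_error(slice_phase(log, "extinction", 3), class = "audcage_lookup_error")

  # empty slice is fine
  sch3 <- rbind(sch, data.frame(phase = "cue_relapse", occurrence = 1L,
                                start_s = 20 * 86400, end_s = 21 * 86400,
                                alcohol_fraction = 0, reward_corner = "reward",
                                stringsAsFactors = FALSE))
  log3 <- event_log(ev, tiny_registry("A1"), sch3)
  expect_equal(nrow(slice_phase(log3, "cue_relapse", 1)$events), 0)
})

test_that("phase slices partition the events", {
  co <- small_cohort()
  log <- co$log
  sch <- log$schedule
  n_in_slices <- 0
  seen <- rep(FALSE, nrow(log$events))
  for (i in seq_len(nrow(sch))) {
    s <- slice_phase(log, sch$phase[i], sch$occurrence[i])
    n_in_slices <- n_in_slices + nrow(s$events)
    hit <- log$events$timestamp_s >= sch$start_s[i] &
      log$events$timestamp_s < sch$end_s[i]
    expect_false(any(seen & hit))   # no event in two slices
    seen <- seen | hit
  }
  off_window <- sum(!seen)
  expect_equal(n_in_slices + off_window, nrow(log$events))
})

test_that("simulator output validates across many seeds", {
  for (s in 1:100) {
    co <- simulate_cohort(sim_config(n_animals = 2, seed = s))
    expect_no_error(validate_event_log(co$log))
  }
})
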