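## Independent oracles and small fixture builders used across the suite.
## These are deliberately written along different lines than the package
## implementations they check.

## ---- progressive-ratio breakpoint oracle ------------------------------
## Burst-decomposition simulator: first split the poke stream into maximal
## bursts (visit change, or inter-poke gap >= max_gap, breaks a burst), then
## consume each burst greedily against the ladder, advancing after
## `sets_to_advance` completed sets of the current requirement. Partial
## bursts are lost. Returns the requirement in effect at the end.
oracle_breakpoint <- function(t, vseq, reqs = c(2, 4, 8, 12, 16, 20, 24, 28, 32, 36),
                              sets_to_advance = 10, max_gap = 1) {
  if (length(t) == 0) return(reqs[1])
  o <- order(t)
  t <- t[o]
  vseq <- vseq[o]
  new_burst <- c(TRUE, diff(t) >= max_gap | diff(vseq) != 0)
  burst_id <- cumsum(new_burst)
  burst_len <- as.vector(table(burst_id))

  li <- 1
  sets <- 0
  for (L in burst_len) {
    while (L >= reqs[li]) {
      L <- L - reqs[li]
      sets <- sets + 1
      if (sets == sets_to_advance) {
        sets <- 0
        if (li < length(reqs)) li <- li + 1
      }
    }
  }
  reqs[li]
}

## random motivation-phase poke stream: visits at random times, each holding
## a burst whose pokes have random sub- and supra-threshold gaps
random_poke_stream <- function(n_visits = 30, max_pokes = 12) {
  starts <- sort(runif(n_visits, 0, 3 * 86400))
  n_pokes <- sample(0:max_pokes, n_visits, replace = TRUE)
  t <- numeric(0)
  v <- integer(0)
  for (i in seq_len(n_visits)) {
    if (n_pokes[i] == 0) next
    gaps <- sample(c(0.2, 0.5, 0.9, 1.1, 2.5), n_pokes[i], replace = TRUE,
                   prob = c(0.35, 0.3, 0.15, 0.1, 0.1))
    t <- c(t, starts[i] + cumsum(gaps))
    v <- c(v, rep.int(i, n_pokes[i]))
  }
  list(t = t, vseq = v)
}

## ---- Spearman oracle --------------------------------------------------
## average ranks from first principles (no rank()/cor()), then the explicit
## product-moment formula on the ranks
oracle_avg_rank <- function(v) {
  vapply(v, function(a) (sum(v < a) + 1 + sum(v <= a)) / 2, 0)
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

## ---- tiny hand-built event logs ---------------------------------------
## rows for one visit containing pokes at the given offsets (and optional
## licks 0.3 s after each poke)
visit_rows <- function(animal, corner, start, poke_offsets = numeric(0),
                       visit_seq, licks_per_poke = 0, duration = NULL) {
  dur <- duration %||% (max(c(1, poke_offsets, 0)) + 2)
  rows <- data.frame(
    animal_id = animal, timestamp_s = start, corner = corner, side = "none",
    kind = "visit_start", visit_seq = visit_seq, stringsAsFactors = FALSE
  )
  for (off in poke_offsets) {
    rows <- rbind(rows, data.frame(
      animal_id = animal, timestamp_s = start + off, corner = corner,
      side = "left", kind = "nosepoke", visit_seq = visit_seq,
      stringsAsFactors = FALSE
    ))
    if (licks_per_poke > 0) {
      rows <- rbind(rows, data.frame(
        animal_id = animal,
        timestamp_s = start + off + 0.3 + 0.1 * seq_len(licks_per_poke),
        corner = corner, side = "left", kind = "lick", visit_seq = visit_seq,
        stringsAsFactors = FALSE
      ))
      dur <- max(dur, off + 0.3 + 0.1 * licks_per_poke + 1)
    }
  }
  rbind(rows, data.frame(
    animal_id = animal, timestamp_s = start + dur, corner = corner,
    side = "none", kind = "visit_end", visit_seq = visit_seq,
    stringsAsFactors = FALSE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## registry for hand-built logs
tiny_registry <- function(ids, bw = 20) {
  data.frame(animal_id = ids, body_weight_g = bw, cohort = "test",
             stringsAsFactors = FALSE)
}

## one-window schedule helper
one_window_schedule <- function(phase, start_s, end_s, alcohol_fraction = 0.1) {
  data.frame(phase = phase, occurrence = 1L, start_s = start_s, end_s = end_s,
             alcohol_fraction = alcohol_fraction, reward_corner = "reward",
             stringsAsFactors = FALSE)
}

## event log holding daily reward-corner nosepoke counts for one animal:
## day d (0-based) gets counts[d+1] pokes, one visit per day at day start +
## 1 h, pokes 2 s apart
daily_count_log <- function(counts, phase, t0 = 0, animal = "A1",
                            alcohol_fraction = 0) {
  n_days <- length(counts)
  ev <- NULL
  for (d in seq_len(n_days)) {
    if (counts[d] == 0) next
    ev <- rbind(ev, visit_rows(animal, "reward", t0 + (d - 1) * 86400 + 3600,
                               poke_offsets = 2 * seq_len(counts[d]),
                               visit_seq = d))
  }
  if (is.null(ev)) {
    ev <- data.frame(animal_id = character(0), timestamp_s = numeric(0),
                     corner = character(0), side = character(0),
                     kind = character(0), visit_seq = integer(0),
                     stringsAsFactors = FALSE)
  }
  event_log(ev, tiny_registry(animal),
            one_window_schedule(phase, t0, t0 + n_days * 86400,
                                alcohol_fraction),
            validate = FALSE)
}

## small simulated cohort shared by several tests (cheap, deterministic)
small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- simulate_cohort(sim_config(n_animals = 10, seed = 7))
    memo
  }
})

## wrap a poke stream (times + visit seqs) into a motivation-phase slice
motivation_log <- function(t, vseq, animal = "A1", span_days = 3) {
  sch <- one_window_schedule("motivation", 0, span_days * 86400, 0.1)
  if (length(t) == 0) {
    ev <- visit_rows(animal, "reward", 10, numeric(0), visit_seq = 1)
  } else {
    ev <- NULL
    for (v in unique(vseq)) {
      tv <- t[vseq == v]
      start <- min(tv) - 1
      ev <- rbind(ev, visit_rows(animal, "reward", start, tv - start,
                                 visit_seq = v))
    }
  }
  event_log(ev, tiny_registry(animal), sch, validate = FALSE)
}
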