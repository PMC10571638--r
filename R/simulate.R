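## Agent-based synthetic-cohort simulator.
##
## A cohort contains a latent AUD-prone subpopulation (Bernoulli(pi)) whose
## five behavioral propensities (M, E, CR, AR, P) are drawn from an
## equicorrelated multivariate normal (rho_prone), and a resistant
## subpopulation with uncorrelated propensities (rho_resistant = 0 by
## default). Propensities are mapped to non-negative event rates through a
## softplus-type link; events (visits, nosepokes, licks) are emitted phase by
## phase under the experimental schedule.

#' Simulator configuration
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults encode
#' the package's reference study conditions: 58 animals, 38 % latent
#' AUD-prone, prone trait propensities shifted upward on every behavior,
#' within-class equicorrelation 0.7 (prone) versus 0 (resistant),
#' and home-cage event rates realistic for group-housed C57BL/6J females
#' (~29 corner visits/day with a 3:1 dark:light activity ratio, ~1.3
#' nosepokes/visit, ~15 licks per rewarded nosepoke, giving roughly
#' 2-3 g alcohol/kg/day at 10 % v/v).
#'
#' @param n_animals number of animals (>= 0).
#' @param seed root seed; one per-animal substream is derived per animal
#'   (substream seed of animal i is `(seed + 1000003 * i) mod (2^31 - 1)`).
#' @param prone_fraction probability an animal is latently AUD-prone.
#' @param trait_mean_prone,trait_mean_resistant length-5 numeric propensity
#'   means (order M, E, CR, AR, P; unit = latent SD).
#' @param trait_sd length-5 positive propensity SDs.
#' @param rho_prone,rho_resistant within-class equicorrelation of the five
#'   propensities; must lie in (-0.25, 1) for positive definiteness.
#' @param visits_per_day expected total corner visits per animal per day.
#' @param dark_light_ratio visit-rate ratio dark:light (12 h/12 h cycle,
#'   experiment starts at dark onset).
#' @param corner_probs length-3 probabilities (reward, water, inactive
#'   corner) for baseline visits.
#' @param nosepokes_per_visit Poisson mean nosepokes per baseline visit.
#' @param licks_per_reward_poke,licks_per_water_poke Poisson mean licks per
#'   rewarded nosepoke at the alcohol and water corner.
#' @param extinction_base_level baseline-propensity expected reward-corner
#'   nosepokes on extinction day 1 (decays exponentially over days).
#' @param extinction_decay_per_day baseline daily decay rate of extinction
#'   responding; prone-shifted propensities slow the decay.
#' @param cue_base_np baseline-propensity expected reward nosepokes during
#'   the 24-h cue-relapse test.
#' @param persistence_base_na_np baseline-propensity expected reward
#'   nosepokes summed over the six non-active 6-h periods.
#' @param breakpoint_base_capacity baseline-propensity progressive-ratio
#'   capacity (largest requirement the animal will complete sets at).
#' @param body_weight_mean_g,body_weight_sd_g registry body-weight
#'   distribution (grams).
#' @param lick_volume_ul microlitres per lick used by downstream consumption
#'   computations.
#' @param schedule phase schedule; defaults to [default_schedule()].
#' @param ladder progressive-ratio ladder; defaults to [ratio_ladder()].
#' @return An object of class `"sim_config"` (a named list).
#' @export
sim_config <- function(n_animals = 58,
                       seed = 1,
                       prone_fraction = 0.38,
                       trait_mean_prone = rep(1.5, 5),
                       trait_mean_resistant = rep(0, 5),
                       trait_sd = rep(0.8, 5),
                       rho_prone = 0.7,
                       rho_resistant = 0,
                       visits_per_day = 29,
                       dark_light_ratio = 3,
                       corner_probs = c(reward = 0.45, water = 0.35, inactive = 0.20),
                       nosepokes_per_visit = 1.3,
                       licks_per_reward_poke = 15,
                       licks_per_water_poke = 10,
                       extinction_base_level = 45,
                       extinction_decay_per_day = 0.35,
                       cue_base_np = 60,
                       persistence_base_na_np = 60,
                       breakpoint_base_capacity = 8,
                       body_weight_mean_g = 22,
                       body_weight_sd_g = 1.5,
                       lick_volume_ul = DEFAULT_LICK_VOLUME_UL,
                       schedule = default_schedule(),
                       ladder = ratio_ladder()) {
  cfg <- list(
    n_animals = as.integer(n_animals), seed = as.integer(seed),
    prone_fraction = prone_fraction,
    trait_mean_prone = trait_mean_prone,
    trait_mean_resistant = trait_mean_resistant,
    trait_sd = trait_sd,
    rho_prone = rho_prone, rho_resistant = rho_resistant,
    visits_per_day = visits_per_day,
    dark_light_ratio = dark_light_ratio,
    corner_probs = corner_probs,
    nosepokes_per_visit = nosepokes_per_visit,
    licks_per_reward_poke = licks_per_reward_poke,
    licks_per_water_poke = licks_per_water_poke,
    extinction_base_level = extinction_base_level,
    extinction_decay_per_day = extinction_decay_per_day,
    cue_base_np = cue_base_np,
    persistence_base_na_np = persistence_base_na_np,
    breakpoint_base_capacity = breakpoint_base_capacity,
    body_weight_mean_g = body_weight_mean_g,
    body_weight_sd_g = body_weight_sd_g,
    lick_volume_ul = lick_volume_ul,
    schedule = schedule,
    ladder = ladder
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n = %d, seed = %d, prone fraction = %.2f, rho = %.2f (prone) / %.2f (resistant)\n",
    x$n_animals, x$seed, x$prone_fraction, x$rho_prone, x$rho_resistant
  ))
  invisible(x)
}

#' @rdname sim_config
#' @param config a `"sim_config"` to validate.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (n_animals < 0) stop_audcage("n_animals must be >= 0", "audcage_config_error")
    if (prone_fraction < 0 || prone_fraction > 1) {
      stop_audcage("prone_fraction must lie in [0, 1]", "audcage_config_error")
    }
    for (rho in c(rho_prone, rho_resistant)) {
      # equicorrelation of 5 variables is positive definite iff rho in (-1/4, 1)
      if (rho <= -0.25 || rho >= 1) {
        stop_audcage("equicorrelation rho must lie in (-0.25, 1) for a positive-definite 5x5 matrix",
                     "audcage_config_error")
      }
    }
    if (length(trait_mean_prone) != 5 || length(trait_mean_resistant) != 5 ||
        length(trait_sd) != 5) {
      stop_audcage("trait means and SDs must be length-5 vectors", "audcage_config_error")
    }
    if (any(trait_sd <= 0)) stop_audcage("trait_sd must be > 0", "audcage_config_error")
    rates <- c(visits_per_day, nosepokes_per_visit, licks_per_reward_poke,
               licks_per_water_poke, extinction_base_level,
               extinction_decay_per_day, cue_base_np, persistence_base_na_np,
               breakpoint_base_capacity)
    if (any(rates < 0)) stop_audcage("event-rate parameters must be >= 0",
                                     "audcage_config_error")
  })
  validate_schedule(config$schedule)
  invisible(config)
}

## softplus-type link from latent propensity to a positive rate multiplier,
## normalized so a propensity of 0 maps to 1
.rate_mult <- function(theta) softplus(theta + 1) / softplus(1)

## sample n event times in [t0, t1) with dark-phase density `ratio` times the
## light-phase density (dark = first 12 h of each 24-h day, day 0 at t = 0);
## exact inverse-CDF on the piecewise-constant intensity
.sample_times_warped <- function(n, t0, t1, ratio) {
  if (n == 0) return(numeric(0))
  half <- .SECONDS_PER_DAY / 2
  breaks <- seq(floor(t0 / half) * half, ceiling(t1 / half) * half, by = half)
  breaks[1] <- t0
  breaks[length(breaks)] <- t1
  breaks <- unique(pmin(pmax(breaks, t0), t1))
  if (length(breaks) < 2) return(rep(t0, n))
  seg_dark <- (floor(breaks[-length(breaks)] / half) %% 2) == 0
  w <- diff(breaks) * ifelse(seg_dark, ratio, 1)
  cw <- c(0, cumsum(w))
  u <- stats::runif(n, 0, cw[length(cw)])
  i <- findInterval(u, cw, rightmost.closed = TRUE)
  i[i >= length(breaks)] <- length(breaks) - 1
  breaks[i] + (u - cw[i]) / ifelse(seg_dark[i], ratio, 1)
}

## Emit the event matrix for a set of visits of one animal.
## visits: list with numeric vectors start, corner (code), n_pokes,
##         lick_mean (per poke), spacing (inter-poke seconds).
## Returns a numeric matrix with columns t, corner, side, kind, vid where
## vid is a local visit identifier (offset by `vid0`).
.emit_visits <- function(visits, vid0 = 0L) {
  nv <- length(visits$start)
  if (nv == 0) {
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, c("t", "corner", "side", "kind", "vid"))))
  }
  np <- visits$n_pokes
  total_p <- sum(np)
  vid <- seq_len(nv) + vid0

  ## nosepokes
  if (total_p > 0) {
    pv <- rep.int(seq_len(nv), np)                    # visit index per poke
    off <- 1 + rep.int(visits$spacing, np) * (sequence(np) - 1)
    pt <- visits$start[pv] + off
    pside <- sample(c(1, 2), total_p, replace = TRUE)
    nl <- stats::rpois(total_p, rep.int(visits$lick_mean, np))
    total_l <- sum(nl)
  } else {
    pv <- integer(0); off <- pt <- numeric(0); pside <- numeric(0)
    nl <- integer(0); total_l <- 0
  }

  ## licks: burst at ~7.7 Hz starting 0.25 s after the rewarded poke
  if (total_l > 0) {
    lp <- rep.int(seq_len(total_p), nl)               # poke index per lick
    lt <- pt[lp] + 0.25 + 0.13 * (sequence(nl) - 1)
    lv <- pv[lp]
    lside <- pside[lp]
  } else {
    lp <- integer(0); lt <- numeric(0); lv <- integer(0); lside <- numeric(0)
  }

  ## visit duration covers all content, grouped max via sort trick
  dur <- rep(4, nv)
  if (total_p > 0) {
    content_end <- off + ifelse(nl > 0, 0.25 + 0.13 * nl, 0)
    o <- order(pv, content_end)
    last <- c(pv[o][-1] != pv[o][-total_p], TRUE)
    g <- pv[o][last]
    dur[g] <- pmax(dur[g], content_end[o][last] + 1)
  }

  rbind(
    cbind(t = visits$start, corner = visits$corner, side = 3, kind = 1, vid = vid),
    if (total_p > 0)
      cbind(t = pt, corner = visits$corner[pv], side = pside, kind = 2, vid = vid[pv]),
    if (total_l > 0)
      cbind(t = lt, corner = visits$corner[lv], side = lside, kind = 3, vid = vid[lv]),
    cbind(t = visits$start + dur, corner = visits$corner, side = 3, kind = 4, vid = vid)
  )
}

## baseline FR1 visits at one corner over [t0, t1)
.baseline_visits <- function(cfg, t0, t1, corner_code, rate_per_day,
                             lick_mean) {
  days <- (t1 - t0) / .SECONDS_PER_DAY
  n <- stats::rpois(1, rate_per_day * days)
  if (n == 0) return(NULL)
  start <- sort(.sample_times_warped(n, t0, t1, cfg$dark_light_ratio))
  list(start = start,
       corner = rep(corner_code, n),
       n_pokes = stats::rpois(n, cfg$nosepokes_per_visit),
       lick_mean = rep(lick_mean, n),
       spacing = rep(4, n))
}

## count-driven visits: distribute `total` nosepokes at `corner_code` over
## visits inside [t0, t1); no licks (used for extinction / cue / persistence
## non-active responding, where responses are unrewarded)
.count_visits <- function(cfg, t0, t1, corner_code, total) {
  if (total <= 0) return(NULL)
  nv <- max(1L, stats::rpois(1, total / 3))
  split <- as.vector(stats::rmultinom(1, total, rep(1, nv)))
  start <- sort(.sample_times_warped(nv, t0, t1, cfg$dark_light_ratio))
  list(start = start,
       corner = rep(corner_code, nv),
       n_pokes = split,
       lick_mean = rep(0, nv),
       spacing = rep(2, nv))
}

## progressive-ratio visits for the motivation window: the agent completes
## `sets_to_advance` sets (one burst per visit, inter-poke gaps 0.5 s) at each
## ladder requirement it is willing to meet (requirement <= capacity), then
## emits a few sub-threshold bursts at the next requirement and stops
.motivation_visits <- function(cfg, t0, t1, capacity) {
  ladder <- cfg$ladder$requirements
  sets <- cfg$ladder$sets_to_advance
  done <- ladder[ladder <= capacity]
  n_done <- length(done)
  next_req <- if (n_done < length(ladder)) ladder[n_done + 1] else NA
  pokes <- rep.int(done, rep.int(sets, n_done))
  lick_mean <- rep(2, length(pokes))
  if (!is.na(next_req)) {
    n_fail <- 3L
    pokes <- c(pokes, rep.int(max(1L, floor(next_req / 2)), n_fail))
    lick_mean <- c(lick_mean, rep(0, n_fail))
  }
  nv <- length(pokes)
  if (nv == 0) return(NULL)
  start <- sort(.sample_times_warped(nv, t0, t1, cfg$dark_light_ratio))
  list(start = start, corner = rep(1, nv), n_pokes = pokes,
       lick_mean = lick_mean, spacing = rep(0.5, nv))
}

## all events of one animal; traits: named numeric (M, E, CR, AR, P)
.sim_animal <- function(cfg, traits) {
  sch <- cfg$schedule
  mult <- .rate_mult(traits)
  rate_reward <- cfg$visits_per_day * cfg$corner_probs[[1]]
  rate_water <- cfg$visits_per_day * cfg$corner_probs[[2]]
  rate_inactive <- cfg$visits_per_day * cfg$corner_probs[[3]]

  pieces <- vector("list", nrow(sch) * 4L)
  k <- 0L
  add <- function(v) if (!is.null(v)) {
    k <<- k + 1L
    pieces[[k]] <<- v
  }

  for (i in seq_len(nrow(sch))) {
    ph <- sch$phase[i]
    t0 <- sch$start_s[i]
    t1 <- sch$end_s[i]

    ## water / inactive corner background in every phase
    add(.baseline_visits(cfg, t0, t1, 2, rate_water, cfg$licks_per_water_poke))
    add(.baseline_visits(cfg, t0, t1, 3, rate_inactive, 0))

    if (ph %in% c("adaptation", "initiation_4", "initiation_8",
                  "initiation_12", "free_access")) {
      lick_mean <- if (ph == "adaptation") cfg$licks_per_water_poke else cfg$licks_per_reward_poke
      add(.baseline_visits(cfg, t0, t1, 1, rate_reward, lick_mean))
    } else if (ph == "motivation") {
      capacity <- cfg$breakpoint_base_capacity * mult[["M"]]
      add(.motivation_visits(cfg, t0, t1, capacity))
    } else if (ph == "extinction") {
      level <- cfg$extinction_base_level * mult[["E"]]
      decay <- cfg$extinction_decay_per_day / sqrt(mult[["E"]])
      n_days <- round((t1 - t0) / .SECONDS_PER_DAY)
      daily <- stats::rpois(n_days, level * exp(-decay * (seq_len(n_days) - 1)))
      for (d in seq_len(n_days)) {
        d0 <- t0 + (d - 1) * .SECONDS_PER_DAY
        add(.count_visits(cfg, d0, d0 + .SECONDS_PER_DAY, 1, daily[d]))
      }
    } else if (ph == "cue_relapse") {
      total <- stats::rpois(1, cfg$cue_base_np * mult[["CR"]])
      add(.count_visits(cfg, t0, t1, 1, total))
    } else if (ph == "alcohol_relapse") {
      ## relapse intake scales lick output per rewarded poke
      add(.baseline_visits(cfg, t0, t1, 1, rate_reward,
                           cfg$licks_per_reward_poke * mult[["AR"]]))
    } else if (ph == "persistence") {
      ## 12 alternating 6-h periods, active first (test starts at dark onset)
      period <- 6 * 3600
      bounds <- seq(t0, t1, by = period)
      active <- (seq_len(length(bounds) - 1) %% 2) == 1
      na_total <- stats::rpois(1, cfg$persistence_base_na_np * mult[["P"]])
      na_split <- as.vector(stats::rmultinom(1, na_total, rep(1, sum(!active))))
      j <- 0L
      for (p in seq_len(length(bounds) - 1)) {
        if (active[p]) {
          add(.baseline_visits(cfg, bounds[p], bounds[p + 1], 1,
                               rate_reward, cfg$licks_per_reward_poke))
        } else {
          j <- j + 1L
          add(.count_visits(cfg, bounds[p], bounds[p + 1], 1, na_split[j]))
        }
      }
    }
  }

  pieces <- pieces[seq_len(k)]
  if (k == 0) {
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, c("t", "corner", "side", "kind", "vid"))))
  }

  ## assign disjoint local visit-id ranges, emit, then de-overlap whole visits
  nvs <- vapply(pieces, function(p) length(p$start), 0L)
  vid0 <- cumsum(c(0L, nvs[-length(nvs)]))
  mats <- mapply(.emit_visits, pieces, vid0, SIMPLIFY = FALSE)
  ev <- do.call(rbind, mats)

  ## visit starts/ends in vid order (pieces emit visits in vid order)
  vstart <- unlist(lapply(pieces, `[[`, "start"), use.names = FALSE)
  vend <- ev[ev[, "kind"] == 4, "t"]
  dur <- vend - vstart

  ## serialize visits: start'_i = max(start_i, start'_{i-1} + dur_{i-1} + 0.5)
  o <- order(vstart, method = "radix")
  s <- vstart[o]
  d <- dur[o]
  S <- cumsum(c(0, d[-length(d)] + 0.5))
  s_adj <- cummax(s - S) + S
  delta <- numeric(length(vstart))
  delta[o] <- s_adj - s
  seq_new <- integer(length(vstart))
  seq_new[o] <- seq_along(o)                        # chronological visit_seq

  ev[, "t"] <- round(ev[, "t"] + delta[ev[, "vid"]], 3)
  ev[, "vid"] <- seq_new[ev[, "vid"]]
  ev
}

#' Simulate a synthetic cohort with latent ground truth
#'
#' Generates a full event log (visits, nosepokes, licks at three corners over
#' the whole schedule) for `config$n_animals` animals, together with each
#' animal's latent class and propensity vector. Output is fully determined by
#' `config` (including its seed); animals are simulated on independent seed
#' substreams so that changing `n_animals` does not perturb earlier animals.
#'
#' Phase-specific behavior is driven by the latent propensities: the
#' progressive-ratio agent completes sets up to a propensity-determined
#' capacity; extinction responding has propensity-scaled level and slowed
#' decay; cue-relapse responding, first-day relapse licking and non-active
#' persistence responding are propensity-scaled Poisson counts.
#'
#' @param config a [sim_config()].
#' @return A list with elements `log` (a validated-by-construction
#'   `"eventlog"`) and `truth` (data.frame: `animal_id`, `class`
#'   (`"prone"`/`"resistant"`), `trait_M` ... `trait_P`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_animals = 4, seed = 42))
#' cohort$log
#' table(cohort$truth$class)
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_animals
  ids <- sprintf("M%03d", seq_len(n))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  set.seed(config$seed)
  cls <- if (n > 0) {
    ifelse(stats::runif(n) < config$prone_fraction, "prone", "resistant")
  } else character(0)

  ## equicorrelated MVN propensities per class
  draw_traits <- function(mean, rho, m) {
    if (m == 0) return(matrix(numeric(0), ncol = 5))
    C <- matrix(rho, 5, 5); diag(C) <- 1
    L <- chol(C)
    z <- matrix(stats::rnorm(m * 5), m, 5) %*% L
    sweep(sweep(z, 2, config$trait_sd, "*"), 2, mean, "+")
  }
  traits <- matrix(NA_real_, n, 5,
                   dimnames = list(ids, paste0("trait_", .behaviors)))
  traits[cls == "prone", ] <- draw_traits(config$trait_mean_prone,
                                          config$rho_prone, sum(cls == "prone"))
  traits[cls == "resistant", ] <- draw_traits(config$trait_mean_resistant,
                                              config$rho_resistant,
                                              sum(cls == "resistant"))
  bw <- round(pmax(12, stats::rnorm(n, config$body_weight_mean_g,
                                    config$body_weight_sd_g)), 1)

  mats <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((config$seed + 1000003 * i) %% 2147483647)
    th <- traits[i, ]
    names(th) <- .behaviors
    mats[[i]] <- .sim_animal(config, th)
  }

  if (n > 0) {
    nrows <- vapply(mats, nrow, 0L)
    big <- do.call(rbind, mats)
    events <- data.frame(
      animal_id = rep.int(ids, nrows),
      timestamp_s = big[, "t"],
      corner = .corners[big[, "corner"]],
      side = .sides[big[, "side"]],
      kind = .kinds[big[, "kind"]],
      visit_seq = as.integer(big[, "vid"]),
      stringsAsFactors = FALSE
    )
  } else {
    events <- data.frame(
      animal_id = character(0), timestamp_s = numeric(0),
      corner = character(0), side = character(0), kind = character(0),
      visit_seq = integer(0), stringsAsFactors = FALSE
    )
  }
  registry <- data.frame(animal_id = ids,
                         body_weight_g = if (n > 0) bw else numeric(0),
                         cohort = rep("sim", n),
                         stringsAsFactors = FALSE)
  truth <- data.frame(animal_id = ids, class = cls,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(traits, row.names = seq_len(n)))

  log <- event_log(events, registry, config$schedule, validate = FALSE)
  list(log = log, truth = truth)
}
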