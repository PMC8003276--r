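# Agent-based generator of facility localization traces.
#
# The simulated facility mirrors a village-style assisted-care home: 64
# residents in apartments of 8 private rooms, each apartment with a shared
# common area, plus a set of public places (piazza, gym, cafeteria, ...).
# Days follow a fixed routine — night in the private room, shared meals in
# the apartment common area, two scheduled public activities, and free
# half-hour blocks in which residents either stay in their room or dwell in
# the common area. A fraction of residents wander: they drift between
# places in short hops, producing the brief fortuitous co-locations the
# continuity filter is designed to discard. Attendance decisions are
# Bernoulli draws with known probabilities (friendship clusters share the
# activity draw), so the expected co-location fraction of every pair is
# available in closed form and shipped as ground truth.

#' Configuration of the synthetic village
#'
#' @param n_residents Number of residents (8 per apartment).
#' @param residents_per_apartment Private rooms per apartment.
#' @param n_public_places Number of public places.
#' @param cluster_size Size of cross-apartment friendship clusters; clusters
#'   are disjoint and cover roughly half of the residents.
#' @param wandering_fraction Fraction of residents with the wandering
#'   phenotype.
#' @param activity_propensity Mean probability of attending a scheduled
#'   public activity.
#' @param common_propensity Probability, per free half-hour block, of
#'   dwelling in the apartment common area.
#' @param common_dwell_slots Length of a common-area dwell in 10-second
#'   slots (at most 180, the block length); this is the pairwise-contact
#'   duration knob.
#' @param sociability Global multiplier on all attendance probabilities;
#'   0 keeps every resident in their room outside meals.
#' @param shared_meals Whether apartments share lunch and dinner in the
#'   common area (default) or residents eat in their rooms.
#' @param bracelet_loss_prob Per resident-day probability of losing the
#'   bracelet for a contiguous 1-6 h stretch (those slots become missing).
#' @param noise_sd Gaussian noise added by [simulate_ri_records()].
#' @param ri_coeffs Covariate response coefficients of the known smooth
#'   community-sociability function (see [ri_response()]).
#' @param scenario One of `"baseline"`, `"lockdown"`,
#'   `"isolated_resident"`.
#' @param lockdown_start,lockdown_phase2_start Dates delimiting the
#'   lockdown scenario: public places close at `lockdown_start` (short,
#'   solitary common-area visits); from `lockdown_phase2_start` residents
#'   settle into apartment cohabitation (longer, likelier common dwells).
#' @param lockdown_dwell_slots Dwell length during the first lockdown phase.
#' @param lockdown_phase2_boost Multiplier on `common_propensity` in the
#'   second phase.
#' @param seed Mandatory integer seed.
#' @return A list of class `village_config`.
#' @export
village_config <- function(n_residents = 64L, residents_per_apartment = 8L,
                           n_public_places = 8L, cluster_size = 4L,
                           wandering_fraction = 0.1,
                           activity_propensity = 0.5,
                           common_propensity = 0.5,
                           common_dwell_slots = 180L,
                           sociability = 1,
                           shared_meals = TRUE,
                           bracelet_loss_prob = 0.03,
                           noise_sd = 0.02,
                           ri_coeffs = NULL,
                           scenario = c("baseline", "lockdown",
                                        "isolated_resident"),
                           lockdown_start = NULL,
                           lockdown_phase2_start = NULL,
                           lockdown_dwell_slots = 30L,
                           lockdown_phase2_boost = 1.2,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory")
  scenario <- match.arg(scenario)
  probs <- c(wandering_fraction, activity_propensity, common_propensity,
             bracelet_loss_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_residents %% residents_per_apartment != 0L) {
    stop("n_residents must be a multiple of residents_per_apartment")
  }
  if (common_dwell_slots < 6L || common_dwell_slots > 180L) {
    stop("common_dwell_slots must be in [6, 180]")
  }
  if (is.null(ri_coeffs)) {
    ri_coeffs <- list(intercept = -1, workday = -0.5, temperature = 2,
                      walk = 0.5, noon = 0.9, afternoon = 0.5,
                      season = c(spring = 0.3, summer = 0.6, autumn = 0,
                                 winter = -0.3), scale = 0.5)
  }
  if (scenario == "lockdown" && is.null(lockdown_start)) {
    lockdown_start <- as.Date("2020-03-10")
    lockdown_phase2_start <- as.Date("2020-04-10")
  }
  structure(list(
    n_residents = as.integer(n_residents),
    residents_per_apartment = as.integer(residents_per_apartment),
    n_public_places = as.integer(n_public_places),
    cluster_size = as.integer(cluster_size),
    wandering_fraction = wandering_fraction,
    activity_propensity = activity_propensity,
    common_propensity = common_propensity,
    common_dwell_slots = as.integer(common_dwell_slots),
    sociability = sociability,
    shared_meals = shared_meals,
    bracelet_loss_prob = bracelet_loss_prob,
    noise_sd = noise_sd, ri_coeffs = ri_coeffs,
    scenario = scenario,
    lockdown_start = lockdown_start,
    lockdown_phase2_start = lockdown_phase2_start,
    lockdown_dwell_slots = as.integer(lockdown_dwell_slots),
    lockdown_phase2_boost = lockdown_phase2_boost,
    seed = as.integer(seed)
  ), class = "village_config")
}

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483647)
}

#' Resident attributes of the synthetic village
#'
#' Drawn once, deterministically from the configuration seed: activity
#' propensities, wandering phenotype, friendship clusters, and the
#' apartment layout.
#'
#' @param config A [village_config()].
#' @return A tibble with one row per resident.
#' @export
village_agents <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_residents
  apt <- rep(seq_len(n %/% config$residents_per_apartment),
             each = config$residents_per_apartment)
  p_act <- pmin(pmax(config$activity_propensity + runif(n, -0.2, 0.2),
                     0.05), 0.95)
  n_wander <- round(config$wandering_fraction * n)
  wander <- rep(FALSE, n)
  if (n_wander > 0) wander[sample.int(n, n_wander)] <- TRUE
  # disjoint cross-apartment friendship clusters over ~half the residents
  cluster <- seq_len(n)  # singletons by default
  eligible <- which(!wander)
  n_clusters <- floor(length(eligible) / 2 / config$cluster_size)
  if (n_clusters > 0) {
    chosen <- sample(eligible, n_clusters * config$cluster_size)
    cluster[chosen] <- n + rep(seq_len(n_clusters),
                               each = config$cluster_size)
  }
  common_mult <- rep(1, n)
  if (config$scenario == "isolated_resident") {
    iso <- which(!wander)[1]
    p_act[iso] <- 0.01
    common_mult[iso] <- 0.02
  }
  tibble::tibble(
    resident_id = sprintf("res%02d", seq_len(n)),
    apartment = apt,
    room = sprintf("R%02d", seq_len(n)),
    common = sprintf("C%d", apt),
    p_act = p_act, common_mult = common_mult,
    wander = wander, cluster = cluster
  )
}

#' Place map of the synthetic village
#'
#' @param config A [village_config()].
#' @return A [place_map()] covering every room, common area and public
#'   place the generator can emit.
#' @export
village_place_map <- function(config) {
  n <- config$n_residents
  n_apt <- n %/% config$residents_per_apartment
  public_labels <- c("piazza", "gym", "theatre", "cafeteria", "minimarket",
                     "chapel", "garden", "lab")
  np <- config$n_public_places
  labels <- if (np <= length(public_labels)) public_labels[seq_len(np)] else
    c(public_labels, sprintf("public%d", seq_len(np - length(public_labels))))
  place_map(
    place_id = c(sprintf("R%02d", seq_len(n)), sprintf("C%d", seq_len(n_apt)),
                 sprintf("P%d", seq_len(np))),
    label = c(sprintf("room %d", seq_len(n)),
              sprintf("apartment %d common", seq_len(n_apt)), labels),
    category = c(rep("apartment_private", n), rep("apartment_common", n_apt),
                 rep("public", np))
  )
}

# Daily routine windows in slot coordinates (1-based, 10 s slots).
day_schedule <- function(lockdown = FALSE) {
  block_starts <- c(2161L + 180L * (0:7),   # 06-10
                    3961L, 4141L,           # 11-12
                    4681L + 180L * (0:5),   # 13-16
                    6121L, 6301L,           # 17-18
                    6841L + 180L * (0:3))   # 19-21
  activities <- c(3601L, 5761L)             # 10-11 and 16-17
  # under lockdown public activities are cancelled and residents stay in
  # their room during those windows (the free-block routine is unchanged)
  if (lockdown) activities <- integer(0)
  list(blocks = block_starts, block_len = 180L,
       activities = activities, activity_len = 360L,
       meals = c(4321L, 6481L), meal_len = 360L,
       night = c(1L, 7561L), night_len = c(2160L, 1080L))
}

lockdown_phase <- function(config, date) {
  if (config$scenario != "lockdown" || is.null(config$lockdown_start) ||
      date < config$lockdown_start) {
    return("normal")
  }
  if (!is.null(config$lockdown_phase2_start) &&
      date >= config$lockdown_phase2_start) "lockdown2" else "lockdown1"
}

season_label <- function(date) {
  memb <- encode_season(date)
  colnames(memb)[max.col(memb, ties.method = "first")]
}

#' Synthetic covariates for a simulation period
#'
#' One record per day and day slot: workday flag, season and within-season
#' fraction, a seasonal temperature (sinusoid peaking in late July plus
#' noise), weather drawn with season-dependent probabilities, and a
#' standardized walk-predisposition proxy (higher on warm, sunny days and
#' in the morning/afternoon slots).
#'
#' @param config A [village_config()].
#' @param start First date.
#' @param n_days Number of days.
#' @return A tibble with `3 * n_days` rows.
#' @export
simulate_covariates <- function(config, start, n_days) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 2L))
  dates <- as.Date(start) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  temp <- 12 + 10 * cos(2 * pi * (doy - 205) / 365.25) + rnorm(n_days, 0, 2.5)
  season <- season_label(dates)
  wprob <- list(
    summer = c(0.6, 0.3, 0.1), winter = c(0.3, 0.4, 0.3),
    spring = c(0.45, 0.35, 0.2), autumn = c(0.45, 0.35, 0.2)
  )
  weather <- vapply(seq_len(n_days), function(d) {
    sample(WEATHER_KINDS, 1L, prob = wprob[[season[d]]])
  }, "")
  workday <- !(format(dates, "%u") %in% c("6", "7"))
  # within-season fraction: elapsed share of the current season
  memb <- encode_season(dates)
  season_fraction <- 1 - memb[cbind(seq_len(n_days),
                                    match(season, colnames(memb)))]
  slots <- day_slots()$slot
  out <- tibble::tibble(
    date = rep(dates, each = 3L),
    slot = rep(slots, n_days),
    workday = rep(workday, each = 3L),
    season = rep(season, each = 3L),
    season_fraction = rep(season_fraction, each = 3L),
    temperature_c = rep(pmin(pmax(temp, -15), 45), each = 3L),
    weather = rep(weather, each = 3L)
  )
  slot_eff <- c(morning = 0.2, noon = -0.1, afternoon = 0.3)
  latent <- 0.05 * (out$temperature_c - 10) +
    0.3 * (out$weather == "sunny") + slot_eff[out$slot] +
    rnorm(nrow(out), 0, 0.3)
  out$walk_predisposition <- as.numeric(scale(latent))
  out
}

# Day-level sociability multiplier driven by the covariates.
day_sociability <- function(config, cov_day) {
  config$sociability *
    (0.5 + plogis(0.08 * (cov_day$temperature_c[1] - 10) +
                    0.5 * (cov_day$weather[1] == "sunny") -
                    0.3 * cov_day$workday[1]))
}

# Per-resident attendance probabilities for one day.
day_probabilities <- function(config, agents, s_d, phase) {
  q_common <- config$common_propensity * agents$common_mult * s_d
  if (phase == "lockdown2") q_common <- q_common * config$lockdown_phase2_boost
  dwell <- switch(phase, lockdown1 = config$lockdown_dwell_slots,
                  config$common_dwell_slots)
  list(q_common = pmin(q_common, 1),
       r_act = pmin(agents$p_act * s_d, 1),
       dwell = as.integer(dwell))
}

#' Simulate one day of village life
#'
#' Produces a [day_traces()] for every resident, the day's covariate
#' records, and the analytic ground truth (expected raw co-location
#' fraction for every pair, plus a plug-in expected Community RI).
#'
#' @param config A [village_config()].
#' @param date The simulated date.
#' @param covariates Optional pre-generated covariate rows for this date
#'   (from [simulate_covariates()]); generated on the fly when `NULL`.
#' @param agents Optional pre-computed [village_agents()].
#' @return A list: `traces`, `covariates`, `ground_truth`.
#' @export
simulate_day <- function(config, date, covariates = NULL, agents = NULL) {
  date <- as.Date(date)
  if (is.null(agents)) agents <- village_agents(config)
  if (is.null(covariates)) {
    covariates <- simulate_covariates(config, date, 1L)
  }
  cov_day <- covariates[covariates$date == date, ]
  if (nrow(cov_day) == 0L) stop("no covariates for ", format(date))
  phase <- lockdown_phase(config, date)
  sched <- day_schedule(lockdown = phase != "normal")
  s_d <- day_sociability(config, cov_day)
  pp <- day_probabilities(config, agents, s_d, phase)
  n <- config$n_residents
  grid <- time_grid()
  Tn <- grid$slots_per_day

  map <- village_place_map(config)
  places <- map$place_id
  room_code <- match(agents$room, places)
  common_code <- match(agents$common, places)
  public_code <- match(sprintf("P%d", seq_len(config$n_public_places)), places)

  day_index <- as.integer(date)
  act_places <- if (length(sched$activities)) {
    public_code[(day_index + seq_along(sched$activities) - 1L) %%
                  config$n_public_places + 1L]
  } else integer(0)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, day_index))
  nb <- length(sched$blocks)
  u_common <- matrix(runif(n * nb), n, nb)
  clusters <- sort(unique(agents$cluster))
  u_act <- if (length(sched$activities)) {
    matrix(runif(length(clusters) * length(sched$activities)),
           length(clusters), length(sched$activities))
  } else matrix(0, 0, 0)
  u_loss <- matrix(runif(n * 3L), n, 3L)

  codes <- matrix(room_code, n, Tn)
  # meals: the whole apartment gathers in the common area
  if (config$shared_meals) {
    for (m in sched$meals) {
      codes[, m:(m + sched$meal_len - 1L)] <-
        matrix(common_code, n, sched$meal_len)
    }
  }
  cl_idx <- match(agents$cluster, clusters)
  normal <- which(!agents$wander)
  for (i in normal) {
    for (b in seq_len(nb)) {
      if (u_common[i, b] < pp$q_common[i]) {
        st <- sched$blocks[b]
        codes[i, st:(st + pp$dwell - 1L)] <- common_code[i]
      }
    }
    for (a in seq_along(sched$activities)) {
      if (u_act[cl_idx[i], a] < pp$r_act[i]) {
        st <- sched$activities[a]
        codes[i, st:(st + sched$activity_len - 1L)] <- act_places[a]
      }
    }
  }
  # wanderers drift through short stays during free and activity windows
  # confined wanderers pace the apartment common area
  wander_set <- lapply(seq_len(n), function(i) {
    if (phase == "normal") c(public_code, common_code[i]) else common_code[i]
  })
  wander_windows <- cbind(
    start = c(sched$blocks, sched$activities),
    len = c(rep(sched$block_len, nb),
            rep(sched$activity_len, length(sched$activities)))
  )
  for (i in which(agents$wander)) {
    sw <- wander_set[[i]]
    for (w in seq_len(nrow(wander_windows))) {
      st <- wander_windows[w, "start"]
      len <- wander_windows[w, "len"]
      t <- 0L
      while (t < len) {
        hop <- sample.int(3L, 1L)
        hop <- min(hop, len - t)
        codes[i, (st + t):(st + t + hop - 1L)] <- sw[sample.int(length(sw), 1L)]
        t <- t + hop
      }
    }
  }
  # bracelet loss: a contiguous stretch of missing positions
  for (i in seq_len(n)) {
    if (u_loss[i, 1] < config$bracelet_loss_prob) {
      len <- as.integer(360L * (1L + floor(u_loss[i, 2] * 6)))  # 1-6 h
      st <- 1L + as.integer(floor(u_loss[i, 3] * (Tn - len)))
      codes[i, st:(st + len - 1L)] <- NA_integer_
    }
  }

  traces <- day_traces(date, agents$resident_id, codes, places, grid)
  gt <- ground_truth_day(config, agents, pp, sched, phase)
  list(traces = traces, covariates = cov_day,
       ground_truth = c(gt, list(date = date, phase = phase, s_d = s_d)))
}

# Closed-form expected raw co-location fractions for one day, and a
# plug-in expected Community RI derived from them. Exact when bracelet
# loss is disabled; decisions are Bernoulli with the probabilities below,
# and common-area dwells all start at the block start, so overlaps are
# deterministic given the decisions.
ground_truth_day <- function(config, agents, pp, sched, phase) {
  n <- config$n_residents
  nb <- length(sched$blocks)
  n_act <- length(sched$activities)
  npub <- config$n_public_places
  Tn <- 8640
  wander_slots <- nb * sched$block_len + n_act * sched$activity_len
  size_w <- if (phase == "normal") npub + 1L else 1L
  E <- matrix(0, n, n)
  meal_slots <- if (config$shared_meals) {
    length(sched$meals) * sched$meal_len
  } else 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_apt <- agents$apartment[i] == agents$apartment[j]
      e <- 0
      wi <- agents$wander[i]; wj <- agents$wander[j]
      if (same_apt) e <- e + meal_slots
      if (!wi && !wj) {
        if (same_apt) {
          e <- e + nb * pp$q_common[i] * pp$q_common[j] * pp$dwell
        }
        if (n_act > 0) {
          p_both <- if (agents$cluster[i] == agents$cluster[j]) {
            pmin(pp$r_act[i], pp$r_act[j])
          } else pp$r_act[i] * pp$r_act[j]
          e <- e + n_act * p_both * sched$activity_len
        }
      } else if (xor(wi, wj)) {
        w <- if (wi) i else j
        s <- if (wi) j else i
        if (same_apt) {
          e <- e + nb * pp$q_common[s] * pp$dwell / size_w
        }
        if (n_act > 0 && phase == "normal") {
          e <- e + n_act * pp$r_act[s] * sched$activity_len / size_w
        }
      } else {
        shared <- if (phase == "normal") {
          if (same_apt) npub + 1L else npub
        } else {
          if (same_apt) 1L else 0L
        }
        e <- e + wander_slots * shared / (size_w^2)
      }
      E[i, j] <- E[j, i] <- e / Tn
    }
  }
  dimnames(E) <- list(agents$resident_id, agents$resident_id)
  indiv <- vapply(seq_len(n), function(i) mean(E[i, -i]^2), 0)
  list(expected_colocation = E, expected_community_ri_plugin = mean(indiv))
}

#' Simulate a period and assemble predictor-ready datasets
#'
#' Runs [simulate_day()] over consecutive days and collects: per-day-slot
#' Community Time-Specific Adjusted RI records aligned with covariates
#' (`ri_records`), per-place-hour popularity records (`pi_records`, target
#' `pi` is the hourly distinct-visitor count over the active-set size),
#' the daily Popularity Index per place (`pi_daily`), the daily index
#' summary (`ri_daily`), and the serialized ground truth.
#'
#' @param config A [village_config()].
#' @param start First date.
#' @param n_days Number of days (>= 1).
#' @param keep_traces Keep the raw [day_traces()] objects (memory-heavy).
#' @param coverage_threshold Active-set rule.
#' @return A list with elements `ri_records`, `pi_records`, `pi_daily`,
#'   `ri_daily`, `covariates`, `ground_truth`, `place_map`, `config`, and
#'   optionally `traces`.
#' @export
simulate_period <- function(config, start, n_days, keep_traces = FALSE,
                            coverage_threshold = 0.8) {
  stopifnot(n_days >= 1L)
  agents <- village_agents(config)
  covs <- simulate_covariates(config, start, n_days)
  dates <- as.Date(start) + seq_len(n_days) - 1L
  map <- village_place_map(config)
  ri_daily <- vector("list", n_days)
  pi_daily <- vector("list", n_days)
  pi_records <- vector("list", n_days)
  gt <- vector("list", n_days)
  traces <- if (keep_traces) vector("list", n_days) else NULL
  for (d in seq_len(n_days)) {
    sim <- simulate_day(config, dates[d], covs, agents)
    x <- sim$traces
    act <- active_set(x, coverage_threshold)
    ri_daily[[d]] <- day_indexes(x, coverage_threshold)
    pi_daily[[d]] <- popularity_index(x, act)
    att <- hourly_attendance(x, act)
    cd <- sim$covariates[1, ]
    pi_records[[d]] <- tibble::tibble(
      date = dates[d], place_id = att$place_id, hour = att$hour,
      weather = cd$weather, temperature_c = cd$temperature_c,
      pi = att$n / length(act)
    )
    gt[[d]] <- sim$ground_truth
    if (keep_traces) traces[[d]] <- x
  }
  ri_daily <- do.call(rbind, ri_daily)
  slots <- day_slots()$slot
  ri_records <- covs
  # covs rows are ordered date-major with slots in day_slots() order, so the
  # per-day slot values flatten row-major straight onto them
  slot_vals <- as.matrix(ri_daily[, paste0("ri_", slots)])
  ri_records$ri <- as.numeric(t(slot_vals))
  out <- list(
    ri_records = ri_records,
    pi_records = do.call(rbind, pi_records),
    pi_daily = do.call(rbind, pi_daily),
    ri_daily = ri_daily,
    covariates = covs,
    ground_truth = gt,
    place_map = map,
    config = config,
    agents = agents
  )
  if (keep_traces) out$traces <- traces
  out
}

#' Known smooth community-sociability response
#'
#' The deterministic function linking the covariates of a day slot to the
#' expected Community Time-Specific Adjusted RI in the record-level
#' generator: a scaled logistic in the workday flag, encoded temperature,
#' walk predisposition, day slot, and fuzzy season memberships.
#'
#' @param records Covariate rows (as produced by [simulate_covariates()]).
#' @param coeffs Coefficient list (see [village_config()]).
#' @return Numeric vector of expected RI values in `(0, scale)`.
#' @export
ri_response <- function(records, coeffs) {
  season <- encode_season(records$date)
  lin <- coeffs$intercept +
    coeffs$workday * records$workday +
    coeffs$temperature * encode_temperature(
      pmin(pmax(records$temperature_c, 0), 40)) +
    coeffs$walk * records$walk_predisposition +
    coeffs$noon * (records$slot == "noon") +
    coeffs$afternoon * (records$slot == "afternoon") +
    as.numeric(season %*% coeffs$season[colnames(season)])
  coeffs$scale * plogis(lin)
}

#' Record-level generator with a known covariate response
#'
#' Generates day-slot sociability records directly from the known smooth
#' response [ri_response()] plus Gaussian noise, bypassing the agent
#' simulation. This is the parameter-recovery benchmark for the community
#' sociability predictor: the attainable test error is governed by
#' `config$noise_sd`.
#'
#' @param config A [village_config()].
#' @param start First date.
#' @param n_days Number of days (3 records per day; 365 days gives the
#'   ~1000-record scale of a year of observation).
#' @return A list: `records` (covariates + `ri` target) and `ground_truth`
#'   (the noiseless response and the coefficients).
#' @export
simulate_ri_records <- function(config, start = as.Date("2020-01-01"),
                                n_days = 365L) {
  covs <- simulate_covariates(config, start, n_days)
  g <- ri_response(covs, config$ri_coeffs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 3L))
  covs$ri <- pmin(pmax(g + rnorm(nrow(covs), 0, config$noise_sd), 0), 1)
  list(records = covs,
       ground_truth = list(response = g, coeffs = config$ri_coeffs,
                           noise_sd = config$noise_sd))
}

#' Serialize ground truth to JSON
#'
#' @param ground_truth The `ground_truth` element of a simulation result.
#' @param path Output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
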