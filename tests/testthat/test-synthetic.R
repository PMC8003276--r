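test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_village(seed = 101L)
  d1 <- simulate_day(cfg, as.Date("2020-05-04"))
  d2 <- simulate_day(cfg, as.Date("2020-05-04"))
  expect_identical(d1$traces$codes, d2$traces$codes)
  expect_identical(d1$ground_truth$expected_colocation,
                   d2$ground_truth$expected_colocation)
  # different seed, different day
  d3 <- simulate_day(tiny_village(seed = 102L), as.Date("2020-05-04"))
  expect_false(identical(d1$traces$codes, d3$traces$codes))
  expect_error(village_config(), "seed")
})

test_that("zero sociability with private meals produces zero co-location", {
  cfg <- tiny_village(seed = 11L, sociability = 0, shared_meals = FALSE,
                      wandering_fraction = 0, bracelet_loss_prob = 0)
  sim <- simulate_day(cfg, as.Date("2020-05-04"))
  core <- proxisoc:::day_ri_core(sim$traces)
  expect_true(all(core$raw_pairs == 0))
  expect_true(all(sim$ground_truth$expected_colocation == 0))
})

test_that("wandering produces fortuitous contacts the filter discards", {
  # meals off so pair contact is dominated by the wandering behaviour
  cfg <- tiny_village(seed = 21L, wandering_fraction = 0.25,
                      shared_meals = FALSE, bracelet_loss_prob = 0)
  ag <- village_agents(cfg)
  sim <- simulate_day(cfg, as.Date("2020-05-06"))
  core <- proxisoc:::day_ri_core(sim$traces)
  n <- length(core$active)
  wpos <- which(ag$wander[match(core$active, ag$resident_id)])
  pair_rows <- which(core$pairs[, 1] %in% wpos | core$pairs[, 2] %in% wpos)
  raw <- sum(core$raw_pairs[pair_rows])
  filt <- sum(core$filtered_pairs[pair_rows])
  expect_gt(raw, 0)
  expect_lt(filt, 0.5 * raw)  # most wander contact time is fortuitous
})

test_that("empirical co-location converges to the analytic expectation", {
  cfg <- tiny_village(seed = 31L, bracelet_loss_prob = 0)
  n_days <- 30L
  n <- cfg$n_residents
  emp <- array(0, c(n, n, n_days))
  expd <- array(0, c(n, n, n_days))
  for (d in seq_len(n_days)) {
    sim <- simulate_day(cfg, as.Date("2020-06-01") + d - 1L)
    core <- proxisoc:::day_ri_core(sim$traces)
    m <- matrix(0, n, n)
    m[core$pairs] <- core$raw_pairs
    emp[, , d] <- m + t(m)
    expd[, , d] <- sim$ground_truth$expected_colocation
  }
  me <- apply(emp, 1:2, mean)
  se <- apply(emp, 1:2, sd) / sqrt(n_days)
  mx <- apply(expd, 1:2, mean)
  z <- (me - mx) / pmax(se, 1e-9)
  zu <- abs(z[upper.tri(z)])
  # at 3 SE a ~0.3% chance excess is expected; require 98% within
  expect_gte(mean(zu <= 3), 0.98)
  expect_lt(mean(me[upper.tri(me)]) - mean(mx[upper.tri(mx)]),
            3 * mean(se[upper.tri(se)]))
})

test_that("community sociability responds monotonically to the dials", {
  day <- as.Date("2020-06-10")
  comm_at <- function(...) {
    cfg <- tiny_village(seed = 3L, bracelet_loss_prob = 0, ...)
    day_indexes(simulate_day(cfg, day)$traces)$community_ri
  }
  soc <- vapply(c(0.5, 1, 1.5), function(s) comm_at(sociability = s), 0)
  expect_false(is.unsorted(soc))
  dwell <- vapply(c(30L, 90L, 180L),
                  function(d) comm_at(common_dwell_slots = d), 0)
  expect_false(is.unsorted(dwell))
})

test_that("bracelet loss creates missing stretches handled by the active set", {
  cfg <- tiny_village(seed = 41L, bracelet_loss_prob = 1)
  sim <- simulate_day(cfg, as.Date("2020-05-04"))
  cov <- rowMeans(!is.na(sim$traces$codes))
  expect_true(all(cov < 1))
  expect_true(length(active_set(sim$traces, 0.999)) == 0L)
})

test_that("period simulation yields the documented record volumes", {
  cfg <- tiny_village(seed = 51L)
  per1 <- simulate_period(cfg, as.Date("2020-07-01"), 1L)
  expect_equal(nrow(per1$ri_records), 3L)
  per <- simulate_period(cfg, as.Date("2020-07-01"), 5L)
  expect_equal(nrow(per$ri_records), 15L)  # 3 day-slot records per day
  expect_true(all(per$ri_records$ri >= 0 & per$ri_records$ri <= 1))
  n_places <- nrow(per$place_map)
  expect_equal(nrow(per$pi_records), 5L * n_places * 18L)
  expect_true(all(per$pi_records$pi >= 0 & per$pi_records$pi <= 1))
  expect_equal(nrow(per$ri_daily), 5L)
  # covariates align one-to-one with the sociability records
  expect_identical(per$ri_records[, c("date", "slot")],
                   per$covariates[, c("date", "slot")])
})

test_that("covariates are plausible and complete", {
  cfg <- tiny_village(seed = 61L)
  covs <- simulate_covariates(cfg, as.Date("2020-01-01"), 366L)
  expect_equal(nrow(covs), 3L * 366L)
  expect_true(all(covs$temperature_c > -20 & covs$temperature_c < 50))
  expect_true(all(covs$season_fraction >= 0 & covs$season_fraction < 1))
  expect_true(all(covs$weather %in% c("sunny", "cloudy", "rainy")))
  # summers are warmer than winters
  expect_gt(mean(covs$temperature_c[covs$season == "summer"]),
            mean(covs$temperature_c[covs$season == "winter"]) + 5)
  # walk predisposition is standardized
  expect_lt(abs(mean(covs$walk_predisposition)), 1e-8)
  expect_equal(sd(covs$walk_predisposition), 1, tolerance = 1e-8)
})

test_that("the record-level generator carries its known response", {
  cfg <- tiny_village(seed = 71L, noise_sd = 0.01)
  rr <- simulate_ri_records(cfg, n_days = 120L)
  expect_equal(nrow(rr$records), 360L)
  resid <- rr$records$ri - rr$ground_truth$response
  expect_lt(abs(mean(resid)), 0.005)
  expect_equal(sd(resid), 0.01, tolerance = 0.25)
  # response recomputes deterministically from the covariates
  expect_equal(ri_response(rr$records, cfg$ri_coeffs),
               rr$ground_truth$response)
})
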