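fit_tiny_models <- function() {
  cfg <- tiny_village(seed = 91L)
  rr <- simulate_ri_records(cfg, n_days = 60L)
  # winter covariates dip below 0 degrees C; the encoder clips with a warning
  ri_fit <- suppressWarnings(
    train_ri_predictor(rr$records, epochs = 15, seed = 1)
  )
  per <- simulate_period(cfg, as.Date("2020-05-01"), 4L)
  pub <- per$place_map$place_id[per$place_map$category == "public"]
  rec <- per$pi_records[per$pi_records$place_id %in% pub, ]
  pi_fit <- train_pi_predictor(rec, place_ids = pub, epochs = 15, seed = 1)
  list(ri = ri_fit, pi = pi_fit, map = per$place_map, cfg = cfg)
}

make_forecast <- function(dates = as.Date("2020-06-01") + 0:6) {
  tibble::tibble(
    date = rep(dates, each = 3),
    slot = rep(c("morning", "noon", "afternoon"), length(dates)),
    workday = rep(!(format(dates, "%u") %in% c("6", "7")), each = 3),
    temperature_c = rep(seq(15, 24, length.out = length(dates)), each = 3),
    walk_predisposition = rep(0.2, 3 * length(dates)),
    weather = rep(c("sunny", "cloudy", "sunny"), length(dates))
  )
}

models <- fit_tiny_models()

test_that("the prediction table covers the week with ranked place lists", {
  fc <- make_forecast()
  tab <- build_cbpt(fc, models$ri, models$pi, models$map)
  expect_s3_class(tab, "cbpt")
  expect_equal(nrow(tab$ri), 21L)
  expect_true(all(tab$ri$ri_pred >= 0 & tab$ri$ri_pred <= 1))
  n_places <- length(models$pi$place_ids)
  expect_equal(nrow(tab$pi), 21L * n_places)
  expect_true(all(tab$pi$pi_pred >= 0 & tab$pi$pi_pred <= 1))
  for (cell in split(tab$pi, paste(tab$pi$date, tab$pi$slot))) {
    expect_setequal(cell$place_id, models$pi$place_ids)
    expect_false(is.unsorted(rev(cell$pi_pred)))
    expect_equal(cell$rank, seq_len(n_places))
  }
  expect_output(print(tab), "Community Behaviour Prediction Table")
})

test_that("table generation is a pure function of its inputs", {
  fc <- make_forecast()
  t1 <- build_cbpt(fc, models$ri, models$pi, models$map)
  t2 <- build_cbpt(fc, models$ri, models$pi, models$map)
  expect_identical(t1$ri, t2$ri)
  expect_identical(t1$pi, t2$pi)
  # constant forecast: rows vary across days only through the slow fuzzy
  # season drift (the date is the one forecast field that cannot be held
  # fixed), so per-slot predictions stay nearly identical over the week
  fc_const <- fc
  fc_const$temperature_c <- 20
  fc_const$workday <- TRUE
  fc_const$weather <- "sunny"
  tc <- build_cbpt(fc_const, models$ri, models$pi, models$map)
  by_day <- split(tc$ri$ri_pred, tc$ri$slot)
  for (v in by_day) expect_lt(diff(range(v)), 0.05)
})

test_that("incomplete forecasts fail with informative errors", {
  fc <- make_forecast()
  expect_error(build_cbpt(fc[fc$date != as.Date("2020-06-03"), ],
                          models$ri, models$pi, models$map),
               "2020-06-03")
  fc_nofield <- fc[, setdiff(names(fc), "temperature_c")]
  expect_error(build_cbpt(fc_nofield, models$ri, models$pi, models$map),
               "temperature_c")
  fc_gap <- fc[-2, ]  # drop one day-slot cell
  expect_error(build_cbpt(fc_gap, models$ri, models$pi, models$map),
               "noon")
})

test_that("anonymized tables use stable place codes", {
  fc <- make_forecast()
  tab <- build_cbpt(fc, models$ri, models$pi, models$map, anonymize = TRUE)
  expect_true(all(grepl("^place-\\d+$", tab$pi$label)))
})

test_that("trend reports aggregate by place group over the range", {
  cfg <- models$cfg
  per <- simulate_period(cfg, as.Date("2020-04-01"), 10L)
  rep_ <- trend_report(per$ri_daily, per$pi_daily, per$place_map)
  expect_s3_class(rep_, "trend_report")
  expect_equal(nrow(rep_$ri), 10L)
  expect_setequal(unique(rep_$pi_groups$group), c("public", "apartment"))
  expect_true(all(rep_$pi_groups$pi_smooth >= 0))
  expect_output(print(rep_), "community RI")

  one <- trend_report(per$ri_daily, per$pi_daily, per$place_map,
                      range = rep(as.Date("2020-04-03"), 2))
  expect_equal(nrow(one$ri), 1L)
  expect_error(trend_report(per$ri_daily, per$pi_daily, per$place_map,
                            range = as.Date(c("2019-01-01", "2019-01-05"))),
               "empty date range")
  bad_map <- place_map("zzz", category = "public")
  expect_error(trend_report(per$ri_daily, per$pi_daily, bad_map),
               "no place resolves")

  dir <- withr::local_tempdir()
  write_trend_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "community_ri.csv")))
  expect_true(file.exists(file.path(dir, "pi_groups.csv")))
})
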