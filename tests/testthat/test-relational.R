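test_that("raw pairwise RI is the co-location fraction of the day", {
  v <- c(rep(1L, 2160), rep(0L, 6480))
  expect_equal(raw_pair_ri(v), 0.25)   # a quarter of the day together
  expect_equal(raw_pair_ri(rep(0L, 8640)), 0)
  set.seed(1)
  idx <- sample.int(8640, 100)
  v2 <- integer(8640); v2[idx] <- 1L
  expect_equal(raw_pair_ri(v2), 100 / 8640)
})

test_that("moving median reproduces the printed filter example rows", {
  v <- table1_vector(30)
  expect_identical(moving_median(v, 5)[1:20],
                   as.integer(c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1,
                                1, 1, 1, 1, 1)))
  expect_identical(moving_median(v, 11)[1:20],
                   as.integer(c(1, 1, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1,
                                1, 1, 1, 1, 1)))
  expect_identical(moving_median(rep(1L, 50), 7), rep(1L, 50))
  expect_error(moving_median(v, 4), "odd")
})

test_that("moving median boundaries copy the original values at both ends", {
  set.seed(42)
  for (k in c(3L, 5L, 11L)) {
    v <- as.integer(runif(200) < 0.5)
    m <- moving_median(v, k)
    h <- k %/% 2
    expect_identical(m[1:h], v[1:h])
    expect_identical(m[(200 - h + 1):200], v[(200 - h + 1):200])
  }
})

test_that("duration filter drops runs strictly shorter than the minimum", {
  pad <- function(run) c(rep(0L, 20), run, rep(0L, 20))
  expect_equal(sum(duration_filter(pad(rep(1L, 5)), 60)), 0)   # 50 s: removed
  expect_equal(sum(duration_filter(pad(rep(1L, 6)), 60)), 6)   # 60 s: kept
  expect_identical(duration_filter(rep(0L, 100), 60), rep(0L, 100))
  expect_error(duration_filter(pad(rep(1L, 6)), 65), "multiple")
})

test_that("filtered RI matches the independent oracle and kills isolated contacts", {
  # isolated single contacts spread across the day vanish entirely
  v <- integer(8640); v[seq(10, 8600, by = 50)] <- 1L
  expect_equal(filtered_pair_ri(v), 0)
  expect_equal(filtered_pair_ri(rep(1L, 8640)), 1)

  set.seed(7)
  for (r in 1:50) {
    # dense noise plus a few long genuine interactions
    v <- as.integer(runif(8640) < 0.4)
    for (st in sample.int(8400, 5)) {
      v[st:(st + sample(3:120, 1))] <- 1L
    }
    expect_equal(filtered_pair_ri(v), oracle_filtered_ri(v))
  }
})

test_that("individual RI is the mean of squares and rewards strong ties", {
  # one six-hour companion vs twelve half-hour encounters, 12 peers each
  one_strong <- c(0.25, rep(0, 11))
  many_weak <- rep(0.25 / 12, 12)
  expect_equal(sum(one_strong), sum(many_weak))  # same total time: 0.25
  expect_equal(individual_ri(one_strong) / individual_ri(many_weak), 12)
  expect_equal(individual_ri(rep(0, 5)), 0)
  expect_equal(individual_ri(0.3), 0.09)
  expect_error(individual_ri(numeric(0)), "peers")
})

test_that("community RI is the mean of individual values", {
  expect_equal(community_ri(c(0.2, 0.4)), 0.3)
  expect_equal(community_ri(rep(0, 10)), 0)
  expect_error(community_ri(numeric(0)), "empty")
})

test_that("time-specific RI restricts to the day slot", {
  expect_equal(time_specific_pair_ri(rep(1L, 8640), "morning"), 1)
  v <- integer(8640)
  v[hour_window_slots(12, 15)] <- 1L
  expect_equal(time_specific_pair_ri(v, "morning"), 0)
  morning <- hour_window_slots(8, 12)
  v2 <- integer(8640); v2[morning[1:(length(morning) / 2)]] <- 1L
  expect_equal(time_specific_pair_ri(v2, "morning"), 0.5)
  expect_error(time_specific_pair_ri(v2, "brunch"), "unknown day slot")
})

test_that("adjusted RI rewards and penalizes as in the worked examples", {
  expect_equal(adjusted_pair_ri(0.3, 0.2), 0.37)
  expect_equal(adjusted_pair_ri(0.05, 0.2), 0.0425)
  expect_equal(adjusted_pair_ri(0.4, 0.4), 0.4)  # delta = 0 fixed point
  expect_error(adjusted_pair_ri(1.2, 0.2), "\\[0, 1\\]")

  set.seed(3)
  rs <- runif(500); ri <- runif(500)
  adj <- adjusted_pair_ri(rs, ri)
  expect_true(all(adj >= 0 & adj <= 1))
  up <- rs >= ri
  expect_true(all(adj[up] >= rs[up]))
  expect_true(all(adj[!up] <= rs[!up]))
})

test_that("time-specific aggregate means behave as plain averages", {
  expect_equal(individual_ts_adjusted_ri(rep(0.37, 7)), 0.37)
  expect_equal(individual_ts_adjusted_ri(c(0.2, 0.4)), 0.3)
  expect_equal(community_ts_adjusted_ri(rep(0.2, 4)), 0.2)
  expect_error(individual_ts_adjusted_ri(numeric(0)), "fewer than 2")
})

test_that("every index stays in [0, 1] over random communities", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(2:16, 1)
    pair_mat <- matrix(runif(n * n), n, n)
    pair_mat <- (pair_mat + t(pair_mat)) / 2
    indiv <- vapply(1:n, function(i) individual_ri(pair_mat[i, -i]), 0)
    expect_true(all(indiv >= 0 & indiv <= 1))
    expect_true(community_ri(indiv) >= 0 && community_ri(indiv) <= 1)
    v <- as.integer(runif(8640) < runif(1))
    expect_gte(filtered_pair_ri(v), 0)
    expect_lte(filtered_pair_ri(v), 1)
  }
})

test_that("the day-level index table is internally consistent", {
  set.seed(21)
  fallback <- c("roomA", "roomB", "roomC", "roomD")
  seqs <- lapply(1:4, function(i) {
    s <- rep(fallback[i], 8640)
    # everyone shares the kitchen for a couple of stretches
    s[4321:4680] <- "kitchen"
    if (i <= 2) s[3601:3960] <- "gym"
    s
  })
  names(seqs) <- paste0("r", 1:4)
  x <- traces_from_sequences(seqs)
  tab <- ri_table(x)
  comm <- tab$value[tab$variant == "community"]
  indiv <- tab$value[tab$variant == "individual"]
  expect_equal(comm, mean(indiv))
  expect_true(all(tab$value >= 0 & tab$value <= 1))

  # pairwise filtered values agree with direct recomputation
  pw <- tab[tab$variant == "filtered", ]
  for (r in seq_len(nrow(pw))) {
    v <- colocation_vector(x, pw$i[r], pw$j[r])
    expect_equal(pw$value[r], filtered_pair_ri(v))
  }

  # community time-specific adjusted value per slot equals the mean of the
  # individual means of the adjusted pairwise values
  for (sl in c("morning", "noon", "afternoon")) {
    ind_adj <- tab$value[tab$variant == "individual_ts_adjusted" &
                           tab$slot == sl]
    comm_adj <- tab$value[tab$variant == "community_ts_adjusted" &
                            tab$slot == sl]
    expect_equal(comm_adj, mean(ind_adj))
  }

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_index_csv(tab, tmp)
  expect_identical(names(read.csv(tmp)),
                   c("date", "slot", "i", "j", "variant", "value"))
})
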