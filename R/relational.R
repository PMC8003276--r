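#' Raw pairwise Relational Index
#'
#' Fraction of the day's 10-second slots two residents spend in the same
#' place: `sum(V) / |T|` with `|T| = 8640`. Missing slots never co-locate
#' and the denominator stays the full grid.
#'
#' @param v Binary co-location vector (see [colocation_vector()]).
#' @return Value in `[0, 1]`.
#' @examples
#' v <- c(rep(1, 2160), rep(0, 6480))
#' raw_pair_ri(v) # 0.25: the pair spent 25% of the day together
#' @export
raw_pair_ri <- function(v) {
  check_binary(v)
  sum(v) / length(v)
}

#' Centred moving median of a binary vector
#'
#' Smooths a co-location vector so that very short contacts (and very short
#' gaps) are treated as noise. With the default window `k = 5` (50 s),
#' interactions lasting less than 20 s vanish. The first and last
#' `floor(k / 2)` values cannot centre a window and are copied unchanged.
#'
#' @param v Binary vector.
#' @param k Odd window size, at least 3.
#' @return Binary vector of the same length.
#' @export
moving_median <- function(v, k = 5L) {
  check_binary(v)
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("k must be odd and >= 3")
  cpp_moving_median_binary(as.integer(v), k)
}

#' Remove co-location runs shorter than a minimum duration
#'
#' Separate pass after the moving median: every maximal run of ones lasting
#' less than `min_seconds` is zeroed; runs of exactly `min_seconds` are kept
#' ("shorter than" is strict).
#'
#' @param m Binary vector (typically the output of [moving_median()]).
#' @param min_seconds Minimum duration in seconds; must be a multiple of the
#'   slot length.
#' @param grid A [time_grid()].
#' @return Binary vector of the same length.
#' @export
duration_filter <- function(m, min_seconds = 60, grid = time_grid()) {
  check_binary(m)
  if (min_seconds %% grid$slot_seconds != 0) {
    stop("min_seconds must be a multiple of the slot length")
  }
  cpp_duration_filter(as.integer(m), as.integer(min_seconds %/% grid$slot_seconds))
}

#' Continuity-filtered pairwise Relational Index
#'
#' The raw co-location vector is passed through the centred moving median
#' (window `k`) and the minimum-duration filter, so that fortuitous contacts
#' — typically produced by wandering — do not count towards sociability.
#'
#' @inheritParams raw_pair_ri
#' @param k Moving-median window (odd).
#' @param min_seconds Minimum interaction duration in seconds.
#' @param grid A [time_grid()].
#' @return Value in `[0, 1]`.
#' @export
filtered_pair_ri <- function(v, k = 5L, min_seconds = 60, grid = time_grid()) {
  f <- duration_filter(moving_median(v, k), min_seconds, grid)
  sum(f) / length(f)
}

#' Individual Relational Index
#'
#' Mean of the squared pairwise RIs of resident `i` with every other active
#' resident. The square rewards few strong ties over many weak ones: six
#' hours with one companion counts far more than the same total time spread
#' over twelve people.
#'
#' @param pair_values Pairwise RI values of `i` with each active peer
#'   (length `|A_d \ {i}|`).
#' @return Value in `[0, 1]`.
#' @export
individual_ri <- function(pair_values) {
  if (length(pair_values) == 0L) {
    stop("individual RI undefined: no active peers")
  }
  check_unit(pair_values)
  mean(pair_values^2)
}

#' Community Relational Index
#'
#' Arithmetic mean of the Individual RIs over the day's active residents.
#'
#' @param individual_values Individual RI values over the active set.
#' @return Value in `[0, 1]`.
#' @export
community_ri <- function(individual_values) {
  if (length(individual_values) == 0L) {
    stop("community RI undefined: empty active set")
  }
  check_unit(individual_values)
  mean(individual_values)
}

#' Time-specific pairwise Relational Index
#'
#' The pairwise RI restricted to a window of the day (`morning`, `noon`,
#' `afternoon`): ones of the co-location vector within the window divided by
#' the window length. Uses the raw co-location vector by default.
#'
#' @inheritParams raw_pair_ri
#' @param slot One row of [day_slots()] (or a name matching one).
#' @param slots The slot table, see [day_slots()].
#' @param grid A [time_grid()].
#' @return Value in `[0, 1]`.
#' @export
time_specific_pair_ri <- function(v, slot, slots = day_slots(),
                                  grid = time_grid()) {
  check_binary(v)
  idx <- slot_index_window(slot, slots, grid)
  sum(v[idx]) / length(idx)
}

slot_index_window <- function(slot, slots = day_slots(), grid = time_grid()) {
  if (is.character(slot)) {
    row <- slots[slots$slot == slot, ]
    if (nrow(row) != 1L) stop("unknown day slot: ", slot)
  } else {
    row <- slot
  }
  hour_window_slots(row$start_hour, row$end_hour, grid)
}

#' Time-specific adjusted pairwise Relational Index
#'
#' Shifts the slot-restricted pairwise RI towards 1 (reward) or 0 (penalty)
#' according to whether the relationship contributed positively to the
#' individual's overall daily sociability:
#' `delta = ri_slot - ri_individual`; `gamma = 1 - ri_slot` when
#' `delta >= 0`, else `gamma = ri_slot`; the result is
#' `ri_slot + gamma * delta`, always in `[0, 1]`.
#'
#' @param ri_slot Time-specific pairwise RI, in `[0, 1]`.
#' @param ri_individual Daily Individual RI of resident `i`, in `[0, 1]`.
#' @return Adjusted value in `[0, 1]`. Vectorized over both arguments.
#' @examples
#' adjusted_pair_ri(0.3, 0.2)   # rewarded: 0.37
#' adjusted_pair_ri(0.05, 0.2)  # penalized: 0.0425
#' @export
adjusted_pair_ri <- function(ri_slot, ri_individual) {
  check_unit(ri_slot)
  check_unit(ri_individual)
  delta <- ri_slot - ri_individual
  gamma <- ifelse(delta >= 0, 1 - ri_slot, ri_slot)
  ri_slot + gamma * delta
}

#' Individual and community time-specific adjusted RI
#'
#' Plain arithmetic means (not means of squares): the individual form
#' averages a resident's adjusted pairwise values over the `|A_d| - 1`
#' other active residents; the community form averages the individual
#' values over the active set.
#'
#' @param values Adjusted pairwise (individual form) or individual
#'   (community form) values.
#' @return Value in `[0, 1]`.
#' @export
individual_ts_adjusted_ri <- function(values) {
  if (length(values) == 0L) stop("undefined: community has fewer than 2 members")
  check_unit(values)
  mean(values)
}

#' @rdname individual_ts_adjusted_ri
#' @export
community_ts_adjusted_ri <- function(values) {
  if (length(values) == 0L) stop("undefined: empty active set")
  check_unit(values)
  mean(values)
}

check_binary <- function(v) {
  if (length(v) == 0L || !all(v %in% c(0L, 1L))) {
    stop("expected a non-empty binary (0/1) vector")
  }
  invisible(v)
}

check_unit <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("values must lie in [0, 1]")
  }
  invisible(x)
}

#' All Relational Index values for one day
#'
#' Computes, for the active residents of a day, the filtered pairwise RIs,
#' the Individual and Community RI, and — for each day slot — the
#' time-specific adjusted pairwise, individual, and community values.
#' Pairs with an inactive member are excluded from every aggregate.
#'
#' @param x A [day_traces()].
#' @param coverage_threshold Passed to [active_set()].
#' @param k,min_seconds Continuity-filter parameters.
#' @param slots A [day_slots()] table.
#' @param use_filtered_for_slots Use the filtered co-location vector for the
#'   time-specific indexes instead of the raw one (default off).
#' @return A long tibble with columns `date`, `slot` (`"day"` or a slot
#'   name), `i`, `j` (`NA` for individual rows, `"community"` sentinel rows
#'   use `i = "community"`), `variant`, `value`.
#' @export
ri_table <- function(x, coverage_threshold = 0.8, k = 5L, min_seconds = 60,
                     slots = day_slots(), use_filtered_for_slots = FALSE) {
  core <- day_ri_core(x, coverage_threshold, k, min_seconds, slots,
                      use_filtered_for_slots)
  act <- core$active
  n <- length(act)
  pr <- core$pairs
  win <- core$windows
  indiv <- core$individual
  comm <- core$community

  rows <- list(
    tibble::tibble(date = x$date, slot = "day", i = act[pr[, 1]],
                   j = act[pr[, 2]], variant = "filtered",
                   value = core$filtered_pairs),
    tibble::tibble(date = x$date, slot = "day", i = act[pr[, 1]],
                   j = act[pr[, 2]], variant = "raw",
                   value = core$raw_pairs),
    tibble::tibble(date = x$date, slot = "day", i = act, j = NA_character_,
                   variant = "individual", value = indiv),
    tibble::tibble(date = x$date, slot = "day", i = "community",
                   j = NA_character_, variant = "community", value = comm)
  )

  for (w in seq_along(win)) {
    adj <- core$ts[[w]]$adjusted
    sl <- slots$slot[w]
    keep <- rep(act, each = n) != rep(act, n)
    rows <- c(rows, list(
      tibble::tibble(date = x$date, slot = sl, i = rep(act, each = n),
                     j = rep(act, n), variant = "time_specific_adjusted",
                     value = as.vector(t(adj)))[keep, ],
      tibble::tibble(date = x$date, slot = sl, i = act, j = NA_character_,
                     variant = "individual_ts_adjusted",
                     value = core$ts[[w]]$individual),
      tibble::tibble(date = x$date, slot = sl, i = "community",
                     j = NA_character_, variant = "community_ts_adjusted",
                     value = core$ts[[w]]$community)
    ))
  }
  do.call(rbind, rows)
}

# Shared per-day computation behind ri_table() and day_indexes().
day_ri_core <- function(x, coverage_threshold = 0.8, k = 5L,
                        min_seconds = 60, slots = day_slots(),
                        use_filtered_for_slots = FALSE) {
  act <- active_set(x, coverage_threshold)
  n <- length(act)
  if (n < 2L) stop("need at least 2 active residents")
  idx <- match(act, x$residents)
  codes <- x$codes[idx, , drop = FALSE]
  grid <- x$grid
  win <- lapply(seq_len(nrow(slots)), function(r)
    slot_index_window(slots[r, ], slots, grid))
  starts <- vapply(win, min, 1L)
  ends <- vapply(win, max, 1L)
  min_run <- as.integer(min_seconds %/% grid$slot_seconds)
  cnt <- cpp_pair_counts(codes, as.integer(k), min_run,
                         as.integer(starts), as.integer(ends))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- pr[order(pr[, "row"], pr[, "col"]), , drop = FALSE]
  Tn <- grid$slots_per_day

  filt <- matrix(0, n, n)
  filt[pr] <- cnt[, 2] / Tn
  filt <- filt + t(filt)
  if (use_filtered_for_slots) {
    # recompute windowed counts on filtered vectors pair by pair
    act_traces <- day_traces(x$date, act, codes, x$places, grid)
    slot_counts <- matrix(0, nrow(cnt), length(win))
    for (r in seq_len(nrow(pr))) {
      v <- colocation_vector(act_traces, act[pr[r, 1]], act[pr[r, 2]])
      f <- duration_filter(moving_median(v, k), min_seconds, grid)
      slot_counts[r, ] <- vapply(win, function(w) sum(f[w]), 0)
    }
  } else {
    slot_counts <- cnt[, -(1:2), drop = FALSE]
  }

  indiv <- vapply(seq_len(n), function(i) individual_ri(filt[i, -i]), 0)
  comm <- community_ri(indiv)

  ts <- lapply(seq_along(win), function(w) {
    ts_mat <- matrix(0, n, n)
    ts_mat[pr] <- slot_counts[, w] / length(win[[w]])
    ts_mat <- ts_mat + t(ts_mat)
    # element [i, j] is adjusted with the Individual RI of resident i
    adj <- adjusted_pair_ri(ts_mat, matrix(indiv, n, n))
    diag(adj) <- 0
    indiv_adj <- rowSums(adj) / (n - 1)
    list(adjusted = adj, individual = indiv_adj,
         community = community_ts_adjusted_ri(indiv_adj))
  })

  list(active = act, pairs = pr, windows = win,
       raw_pairs = cnt[, 1] / Tn, filtered_pairs = cnt[, 2] / Tn,
       individual = indiv, community = comm, ts = ts)
}

#' Compact daily index summary
#'
#' Community-level view of one day: the daily Community RI (filtered) and
#' the Community Time-Specific Adjusted RI per day slot.
#'
#' @inheritParams ri_table
#' @return A one-row tibble: `date`, `n_active`, `community_ri`, one
#'   `ri_<slot>` column per day slot.
#' @export
day_indexes <- function(x, coverage_threshold = 0.8, k = 5L,
                        min_seconds = 60, slots = day_slots(),
                        use_filtered_for_slots = FALSE) {
  core <- day_ri_core(x, coverage_threshold, k, min_seconds, slots,
                      use_filtered_for_slots)
  out <- tibble::tibble(date = x$date, n_active = length(core$active),
                        community_ri = core$community)
  for (w in seq_along(core$ts)) {
    out[[paste0("ri_", slots$slot[w])]] <- core$ts[[w]]$community
  }
  out
}

#' Write an index table to CSV
#'
#' Long format with stable column order (`date`, `slot`, `i`, `j`,
#' `variant`, `value`) so exports diff cleanly.
#'
#' @param tab A tibble from [ri_table()].
#' @param path Output path.
#' @export
write_index_csv <- function(tab, path) {
  write.csv(tab[, c("date", "slot", "i", "j", "variant", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
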