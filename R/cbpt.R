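#' Community Behaviour Prediction Table
#'
#' For each day of an upcoming week and each day slot (morning, noon,
#' afternoon), predicts the Community Time-Specific Adjusted RI and the
#' Popularity Index of every predictable place, ranked descending — the
#' table caregivers consult when scheduling activities: pick activities
#' compatible with the predicted sociability, then a place from the
#' popularity ranking. PI predictions use the midpoint hour of each slot.
#' Generation is a pure function of the forecast, the fitted models, and
#' the place map.
#'
#' @param forecast A tibble covering 7 consecutive days x 3 slots with the
#'   columns of [encode_ri_features()] plus `weather`; i.e., `date`,
#'   `slot`, `workday`, `temperature_c`, `walk_predisposition`, `weather`.
#' @param ri_predictor A fitted [train_ri_predictor()] object.
#' @param pi_predictor A fitted [train_pi_predictor()] object.
#' @param map A [place_map()]; only places known to the PI predictor are
#'   ranked.
#' @param slots A [day_slots()] table.
#' @param anonymize Replace place labels by stable codes in the output.
#' @return An object of class `cbpt`: list with tibbles `ri` (date, slot,
#'   `ri_pred`) and `pi` (date, slot, place_id, label, `pi_pred`, `rank`),
#'   plus a `provenance` record (model seeds and metrics).
#' @export
build_cbpt <- function(forecast, ri_predictor, pi_predictor, map,
                       slots = day_slots(), anonymize = FALSE) {
  need <- c("date", "slot", "workday", "temperature_c",
            "walk_predisposition", "weather")
  miss <- setdiff(need, names(forecast))
  if (length(miss)) {
    stop("forecast is missing fields: ", paste(miss, collapse = ", "))
  }
  dates <- sort(unique(as.Date(forecast$date)))
  if (length(dates) != 7L) {
    expected <- min(dates) + 0:6
    gap <- setdiff(format(expected), format(dates))
    stop("forecast must cover 7 days; missing: ",
         paste(gap, collapse = ", "))
  }
  cells <- merge(data.frame(date = dates),
                 data.frame(slot = slots$slot), by = NULL)
  have <- paste(forecast$date, forecast$slot)
  gap <- setdiff(paste(cells$date, cells$slot), have)
  if (length(gap)) {
    stop("forecast is missing day-slot cells: ", paste(gap, collapse = "; "))
  }
  fc <- forecast[match(paste(cells$date, cells$slot), have), ]

  ri_pred <- pmin(pmax(predict(ri_predictor, fc), 0), 1)
  ri_tab <- tibble::tibble(date = as.Date(cells$date), slot = cells$slot,
                           ri_pred = ri_pred)

  mid_hour <- round((slots$start_hour + slots$end_hour) / 2)
  names(mid_hour) <- slots$slot
  place_ids <- pi_predictor$place_ids
  pi_rows <- fc[rep(seq_len(nrow(fc)), each = length(place_ids)), ]
  pi_rows$place_id <- rep(place_ids, nrow(fc))
  pi_rows$hour <- mid_hour[pi_rows$slot]
  pi_pred <- pmin(pmax(predict(pi_predictor, pi_rows), 0), 1)
  labels <- map$label[match(pi_rows$place_id, map$place_id)]
  if (anonymize) {
    labels <- sprintf("place-%02d", match(pi_rows$place_id, place_ids))
  }
  pi_tab <- tibble::tibble(date = as.Date(pi_rows$date), slot = pi_rows$slot,
                           place_id = pi_rows$place_id, label = labels,
                           pi_pred = pi_pred)
  ord <- order(pi_tab$date, match(pi_tab$slot, slots$slot), -pi_tab$pi_pred)
  pi_tab <- pi_tab[ord, ]
  pi_tab$rank <- stats::ave(pi_tab$pi_pred,
                            paste(pi_tab$date, pi_tab$slot),
                            FUN = function(v) seq_along(v))
  structure(list(ri = ri_tab, pi = pi_tab,
                 provenance = list(
                   ri_seed = ri_predictor$seed, pi_seed = pi_predictor$seed,
                   ri_metrics = ri_predictor$metrics,
                   pi_metrics = pi_predictor$metrics)),
            class = "cbpt")
}

#' @export
print.cbpt <- function(x, ...) {
  cat("Community Behaviour Prediction Table\n")
  cat(sprintf("week of %s\n\n", format(min(x$ri$date))))
  for (d in unique(format(x$ri$date))) {
    rid <- x$ri[format(x$ri$date) == d, ]
    cat(d, "\n")
    for (r in seq_len(nrow(rid))) {
      top <- x$pi[format(x$pi$date) == d & x$pi$slot == rid$slot[r], ]
      top <- top[top$rank <= 3, ]
      cat(sprintf("  %-9s community RI %.3f | top places: %s\n",
                  rid$slot[r], rid$ri_pred[r],
                  paste(sprintf("%s (%.3f)", top$label, top$pi_pred),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Period trend report
#'
#' Daily Community RI series alongside the mean Popularity Index of places
#' grouped by category (public vs apartment areas), raw and smoothed —
#' the view used to read period-level patterns such as the collapse of
#' public-place attendance when public areas close while apartment
#' attendance holds steady.
#'
#' @param ri_daily Tibble from [simulate_period()]'s `ri_daily` (or built
#'   with [day_indexes()] per day): columns `date`, `community_ri`.
#' @param pi_daily Tibble with columns `date`, `place_id`, `pi`.
#' @param map A [place_map()] resolving every place to a category.
#' @param range Optional length-2 date vector restricting the report.
#' @param lambda Optional smoothing parameter for [smooth_series()].
#' @param anonymize Replace place ids by stable codes in the per-place
#'   table.
#' @return An object of class `trend_report`: `ri` (date, community_ri,
#'   smoothed), `pi_groups` (date, group, pi_raw, pi_smooth).
#' @export
trend_report <- function(ri_daily, pi_daily, map, range = NULL,
                         lambda = NULL, anonymize = TRUE) {
  if (!is.null(range)) {
    range <- as.Date(range)
    ri_daily <- ri_daily[ri_daily$date >= range[1] & ri_daily$date <= range[2], ]
    pi_daily <- pi_daily[pi_daily$date >= range[1] & pi_daily$date <= range[2], ]
  }
  if (nrow(ri_daily) == 0L || nrow(pi_daily) == 0L) {
    stop("empty date range")
  }
  cat_of <- place_categories(map, pi_daily$place_id)
  group <- ifelse(cat_of == "public", "public", "apartment")
  if (all(cat_of == "unknown")) stop("no place resolves to a category")
  agg <- stats::aggregate(pi ~ date + grp,
                          data = data.frame(date = pi_daily$date, grp = group,
                                            pi = pi_daily$pi),
                          FUN = mean)
  agg <- agg[order(agg$grp, agg$date), ]
  pi_groups <- do.call(rbind, lapply(split(agg, agg$grp), function(g) {
    sm <- if (nrow(g) >= 8L) smooth_series(g$pi, lambda) else g$pi
    tibble::tibble(date = g$date, group = g$grp, pi_raw = g$pi,
                   pi_smooth = sm)
  }))
  ri <- ri_daily[order(ri_daily$date), c("date", "community_ri")]
  ri$smoothed <- if (nrow(ri) >= 8L) smooth_series(ri$community_ri, lambda) else
    ri$community_ri
  structure(list(ri = tibble::as_tibble(ri),
                 pi_groups = tibble::as_tibble(pi_groups)),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  rng <- range(x$ri$date)
  cat(sprintf("<trend_report> %s to %s (%d days)\n", rng[1], rng[2],
              nrow(x$ri)))
  cat(sprintf("  community RI: mean %.4f [%.4f, %.4f]\n",
              mean(x$ri$community_ri), min(x$ri$community_ri),
              max(x$ri$community_ri)))
  for (g in unique(x$pi_groups$group)) {
    v <- x$pi_groups$pi_raw[x$pi_groups$group == g]
    cat(sprintf("  mean PI (%s places): %.4f\n", g, mean(v)))
  }
  invisible(x)
}

#' Write a trend report to CSV files
#'
#' @param report A [trend_report()].
#' @param dir Output directory (created if needed); writes
#'   `community_ri.csv` and `pi_groups.csv`.
#' @export
write_trend_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$ri, file.path(dir, "community_ri.csv"), row.names = FALSE)
  write.csv(report$pi_groups, file.path(dir, "pi_groups.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Plot a trend report
#'
#' Requires ggplot2. Two panels: the daily Community RI and the per-group
#' mean PI, raw points with smoothed lines.
#'
#' @param report A [trend_report()].
#' @return A ggplot object.
#' @export
plot_trend_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ri <- report$ri
  pg <- report$pi_groups
  df <- rbind(
    data.frame(date = ri$date, value = ri$community_ri,
               smooth = ri$smoothed, series = "community RI"),
    data.frame(date = pg$date, value = pg$pi_raw, smooth = pg$pi_smooth,
               series = paste("PI:", pg$group))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = date)) +
    ggplot2::geom_point(ggplot2::aes(y = value), alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = smooth), colour = "firebrick") +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
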