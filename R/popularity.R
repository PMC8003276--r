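#' Hourly attendance of places
#'
#' For each place and awake hour, the number of *distinct* active residents
#' detected in the place for at least one 10-second slot during
#' `[h, h + 1)`. The hourly granularity is deliberate: someone crossing a
#' piazza for a minute still attends it that hour, but cannot inflate the
#' count by re-entering.
#'
#' @param x A [day_traces()].
#' @param active Character vector of active resident ids (see
#'   [active_set()]); defaults to all residents of `x`.
#' @param hours Integer hours of the day to count, default the 18 awake
#'   hours 6..23.
#' @return A tibble with columns `date`, `place_id`, `hour`, `n`.
#' @export
hourly_attendance <- function(x, active = x$residents, hours = 6:23) {
  stopifnot(all(hours %in% 0:23))
  idx <- match(active, x$residents)
  if (anyNA(idx)) stop("active ids not in traces")
  per_hour <- 3600L %/% x$grid$slot_seconds
  np <- length(x$places)
  counts <- matrix(0L, np, length(hours),
                   dimnames = list(x$places, as.character(hours)))
  for (h in seq_along(hours)) {
    cols <- (hours[h] * per_hour + 1L):((hours[h] + 1L) * per_hour)
    sl <- x$codes[idx, cols, drop = FALSE]
    for (r in seq_along(idx)) {
      pl <- unique(sl[r, ])
      pl <- pl[!is.na(pl)]
      counts[pl, h] <- counts[pl, h] + 1L
    }
  }
  tibble::tibble(
    date = x$date,
    place_id = rep(x$places, times = length(hours)),
    hour = rep(hours, each = np),
    n = as.integer(counts)
  )
}

#' Popularity Index of places for one day
#'
#' Average hourly attendance over the awake hours, normalized by the number
#' of active residents: `PI = sum_h n_p(h) / (|A_d| |D|)`, a value in
#' `[0, 1]` interpretable as the expected fraction of the community found in
#' the place during an awake hour.
#'
#' @inheritParams hourly_attendance
#' @return A tibble with columns `date`, `place_id`, `pi`.
#' @export
popularity_index <- function(x, active = x$residents, hours = 6:23) {
  if (length(active) == 0L) stop("PI undefined: empty active set")
  att <- hourly_attendance(x, active, hours)
  agg <- tapply(att$n, att$place_id, sum)
  tibble::tibble(
    date = x$date,
    place_id = names(agg),
    pi = as.numeric(agg) / (length(active) * length(hours))
  )
}

#' Daily Popularity Index series over several days
#'
#' @param traces A list of [day_traces()].
#' @param coverage_threshold Passed to [active_set()].
#' @param hours Awake hours.
#' @return A tibble `date`, `place_id`, `pi` over all days and places.
#' @export
pi_series <- function(traces, coverage_threshold = 0.8, hours = 6:23) {
  out <- lapply(traces, function(x)
    popularity_index(x, active_set(x, coverage_threshold), hours))
  do.call(rbind, out)
}

#' Smooth a daily Popularity Index series
#'
#' Fits a penalized regression spline (cubic B-spline basis with a
#' first-order difference penalty, so large penalties shrink the fit
#' towards a constant) to a daily series, treating the observed points as a
#' noisy discretisation of a smooth popularity trend. The penalty weight
#' `lambda` is chosen by generalized cross-validation when not supplied.
#' Tiny negative fitted values are clipped to zero.
#'
#' @param values Numeric series (one value per day, in day order).
#' @param lambda Optional smoothing parameter; `NULL` selects it by GCV.
#' @param basis_dim Basis dimension; defaults to one function per observed
#'   day, capped for long series.
#' @return Numeric vector of smoothed values, same length as `values`.
#' @export
smooth_series <- function(values, lambda = NULL, basis_dim = NULL) {
  n <- length(values)
  if (n < 8L) stop("need at least 8 days of data to smooth")
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be > 0")
  df <- data.frame(day = seq_len(n), y = as.numeric(values))
  if (is.null(basis_dim)) basis_dim <- min(n - 1L, 120L)
  fit <- mgcv::gam(y ~ s(day, bs = "ps", k = basis_dim, m = c(2, 1)),
                   data = df, sp = lambda, method = "GCV.Cp")
  out <- as.numeric(predict(fit, newdata = df))
  out[out < 0] <- 0
  out
}

#' Drop low-activity popularity records
#'
#' Records with PI below 0.01 are taken to mean no event is ongoing in the
#' place at that time and are removed before model fitting; the comparison
#' is strict, so a PI of exactly 0.01 is kept.
#'
#' @param records A data frame with a `pi` column.
#' @param threshold Minimum PI kept.
#' @return The filtered records.
#' @export
low_activity_filter <- function(records, threshold = 0.01) {
  records[records$pi >= threshold, , drop = FALSE]
}
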