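#' The daily time grid
#'
#' Localization data are sampled every 10 seconds, so one day is discretised
#' into 8640 slots indexed `t = 1, ..., 8640`. Slot `t` covers the half-open
#' interval `[(t - 1) * 10 s, t * 10 s)` from midnight; the midnight boundary
#' belongs to the next day.
#'
#' @param slots_per_day Number of slots in one day.
#' @param slot_seconds Duration of one slot in seconds.
#' @return A list with elements `slots_per_day` and `slot_seconds`.
#' @examples
#' time_grid()
#' @export
time_grid <- function(slots_per_day = 8640L, slot_seconds = 10L) {
  slots_per_day <- as.integer(slots_per_day)
  slot_seconds <- as.integer(slot_seconds)
  if (slots_per_day * slot_seconds != 86400L) {
    stop("slots_per_day * slot_seconds must equal 86,400 s (one day)")
  }
  list(slots_per_day = slots_per_day, slot_seconds = slot_seconds)
}

#' Day slots for time-specific indexes
#'
#' The day is partitioned into three non-overlapping windows used for the
#' time-specific Relational Index and the prediction table: morning 8-12,
#' noon 12-15, afternoon 15-20 (hours of the day, half-open on the right).
#'
#' @param morning,noon,afternoon Length-2 numeric vectors `c(start, end)`
#'   in hours.
#' @return A tibble with columns `slot`, `start_hour`, `end_hour`.
#' @examples
#' day_slots()
#' @export
day_slots <- function(morning = c(8, 12), noon = c(12, 15),
                      afternoon = c(15, 20)) {
  out <- tibble::tibble(
    slot = c("morning", "noon", "afternoon"),
    start_hour = c(morning[1], noon[1], afternoon[1]),
    end_hour = c(morning[2], noon[2], afternoon[2])
  )
  if (any(out$end_hour <= out$start_hour)) stop("empty day slot")
  # non-overlap check on the hour line
  iv <- out[order(out$start_hour), ]
  if (any(iv$start_hour[-1] < iv$end_hour[-nrow(iv)])) {
    stop("day slots must not overlap")
  }
  out
}

#' Slot indices covered by a window of hours
#'
#' @param start_hour,end_hour Window bounds in hours (half-open on the right).
#' @param grid A [time_grid()].
#' @return Integer vector of 1-based slot indices.
#' @export
hour_window_slots <- function(start_hour, end_hour, grid = time_grid()) {
  per_hour <- 3600L %/% grid$slot_seconds
  lo <- as.integer(round(start_hour * per_hour)) + 1L
  hi <- as.integer(round(end_hour * per_hour))
  if (hi < lo || lo < 1L || hi > grid$slots_per_day) stop("invalid hour window")
  lo:hi
}
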