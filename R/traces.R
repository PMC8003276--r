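#' One day of localization traces
#'
#' Container for the positions of a set of residents over one day on the
#' 10-second grid. Positions are stored as an integer matrix of place codes
#' (`n_residents x 8640`), with `NA` marking slots where a resident could not
#' be localized (e.g., a lost bracelet). Codes index into the `places`
#' attribute; gaps are kept as missing, never interpolated.
#'
#' @param date A `Date` (length 1).
#' @param residents Character vector of resident ids.
#' @param codes Integer matrix `length(residents) x slots_per_day`; entries
#'   are indices into `places` or `NA`.
#' @param places Character vector of place ids referenced by `codes`.
#' @param grid A [time_grid()].
#' @return An object of class `day_traces`.
#' @export
day_traces <- function(date, residents, codes, places, grid = time_grid()) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L, is.matrix(codes),
            nrow(codes) == length(residents),
            ncol(codes) == grid$slots_per_day)
  storage.mode(codes) <- "integer"
  if (any(codes < 1L | codes > length(places), na.rm = TRUE)) {
    stop("place codes out of range")
  }
  structure(
    list(date = date, residents = as.character(residents), codes = codes,
         places = as.character(places), grid = grid),
    class = "day_traces"
  )
}

#' @export
print.day_traces <- function(x, ...) {
  cov <- rowMeans(!is.na(x$codes))
  cat(sprintf("<day_traces> %s: %d residents, %d slots, %d places\n",
              format(x$date), length(x$residents), ncol(x$codes),
              length(x$places)))
  cat(sprintf("  coverage: min %.2f, median %.2f, max %.2f\n",
              min(cov), median(cov), max(cov)))
  invisible(x)
}

#' Extract one resident's place sequence
#'
#' @param x A [day_traces()].
#' @param resident Resident id.
#' @return Character vector of length `slots_per_day` (place ids, `NA` where
#'   unknown).
#' @export
resident_places <- function(x, resident) {
  i <- match(resident, x$residents)
  if (is.na(i)) stop("unknown resident: ", resident)
  x$places[x$codes[i, ]]
}

#' Read localization traces from a CSV file
#'
#' Expects a header row and columns `resident_id`, `timestamp` (ISO-8601,
#' facility-local time), `place_id`. Each record is assigned to the 10-second
#' slot containing its timestamp; when several records fall into the same
#' slot for one resident (multi-tagging), the last one in file order wins.
#' Slots without any record remain missing. Place ids absent from the place
#' map are kept and flagged with a warning.
#'
#' @param path CSV file path.
#' @param map Optional [place_map()] used to flag unknown place ids.
#' @param grid A [time_grid()].
#' @return A named list of [day_traces()], one per date (names are the
#'   dates).
#' @export
read_traces <- function(path, map = NULL, grid = time_grid()) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) return(list())
  need <- c("resident_id", "timestamp", "place_id")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  }
  ts <- strptime(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  alt <- is.na(ts)
  ts[alt] <- strptime(df$timestamp[alt], format = "%Y-%m-%d %H:%M:%OS",
                      tz = "UTC")
  ts <- as.POSIXct(ts)
  bad <- which(is.na(ts) | df$resident_id == "" | df$place_id == "")
  if (length(bad)) {
    stop("malformed trace rows at lines: ",
         paste(head(bad + 1L, 10L), collapse = ", "))
  }
  if (!is.null(map)) {
    unk <- setdiff(unique(df$place_id), map$place_id)
    if (length(unk)) {
      warning("place ids not in place map (kept as unknown): ",
              paste(unk, collapse = ", "))
    }
  }
  dates <- as.Date(ts, tz = "UTC")
  secs <- as.numeric(ts) - as.numeric(as.POSIXct(paste(dates, "00:00:00"),
                                                 tz = "UTC"))
  slot <- pmin(floor(secs / grid$slot_seconds) + 1L, grid$slots_per_day)
  out <- list()
  for (d in split(seq_len(nrow(df)), dates)) {
    date <- dates[d[1]]
    residents <- sort(unique(df$resident_id[d]))
    places <- sort(unique(df$place_id[d]))
    codes <- matrix(NA_integer_, length(residents), grid$slots_per_day)
    ri <- match(df$resident_id[d], residents)
    pi_ <- match(df$place_id[d], places)
    # assignment in file order: the last record in a slot wins
    codes[cbind(ri, slot[d])] <- pi_
    out[[format(date)]] <- day_traces(date, residents, codes, places, grid)
  }
  out
}

#' Write traces back to the CSV dialect read by [read_traces()]
#'
#' One row per observed (non-missing) slot, timestamped at the slot start.
#'
#' @param traces A named list of [day_traces()] or a single object.
#' @param path Output CSV path.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "day_traces")) traces <- list(traces)
  rows <- lapply(traces, function(x) {
    obs <- which(!is.na(x$codes), arr.ind = TRUE)
    secs <- (obs[, 2] - 1L) * x$grid$slot_seconds
    data.frame(
      resident_id = x$residents[obs[, 1]],
      timestamp = format(as.POSIXct(paste(x$date, "00:00:00"), tz = "UTC") +
                           secs, "%Y-%m-%dT%H:%M:%S"),
      place_id = x$places[x$codes[obs]],
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$resident_id, df$timestamp), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Co-location vector of two residents
#'
#' Binary vector over the day grid: slot `t` is 1 iff both residents'
#' positions are known at `t` and equal. A missing position never
#' co-locates.
#'
#' @param x A [day_traces()] object, or a `day_traces` holding resident `i`
#'   when `j` is itself a `day_traces` (two-object form).
#' @param i,j Resident ids (or, in the two-object form, `i` is the second
#'   `day_traces` and `j` the two resident ids are taken from each object).
#' @return Integer 0/1 vector of length `slots_per_day`.
#' @export
colocation_vector <- function(x, i, j = NULL) {
  if (inherits(i, "day_traces")) {
    if (x$date != i$date) stop("traces are for different dates")
    if (length(x$residents) != 1L || length(i$residents) != 1L) {
      stop("two-object form requires single-resident traces")
    }
    pi_ <- x$places[x$codes[1, ]]
    pj <- i$places[i$codes[1, ]]
  } else {
    pi_ <- resident_places(x, i)
    pj <- resident_places(x, j)
  }
  as.integer(!is.na(pi_) & !is.na(pj) & pi_ == pj)
}

#' Active residents of a day
#'
#' A resident is active on day `d` when their position can be tracked
#' throughout the day; operationally, when the fraction of non-missing slots
#' reaches `coverage_threshold`.
#'
#' @param x A [day_traces()].
#' @param coverage_threshold Required fraction of non-missing slots, in
#'   `(0, 1]`.
#' @return Character vector of active resident ids.
#' @export
active_set <- function(x, coverage_threshold = 0.8) {
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1)
  cov <- rowMeans(!is.na(x$codes))
  x$residents[cov >= coverage_threshold]
}
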