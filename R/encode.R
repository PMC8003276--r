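WEATHER_KINDS <- c("sunny", "cloudy", "rainy")

#' Encode the hour of the day
#'
#' Linear map of the awake window (6 A.M. to midnight) onto `[0, 1]`:
#' `(t - 21600) / 64800` for `t` seconds since midnight. 6 A.M. encodes to
#' 0, midnight to 1, 5 P.M. to 0.6111....
#'
#' @param t_seconds Seconds since midnight, within `[21600, 86400]`.
#' @return Value(s) in `[0, 1]`.
#' @examples
#' encode_hour(17 * 3600) # 5 P.M. -> 0.6111...
#' @export
encode_hour <- function(t_seconds) {
  if (any(t_seconds < 21600 | t_seconds > 86400)) {
    stop("timestamp outside the awake window (6 A.M. - midnight)")
  }
  (t_seconds - 21600) / 64800
}

season_anchors <- function(year) {
  # spring equinox, summer solstice, autumn equinox, winter solstice
  as.Date(sprintf(c("%d-03-20", "%d-06-21", "%d-09-22", "%d-12-21"), year))
}

#' Triangular fuzzy season encoding
#'
#' Encodes a date as memberships in (spring, summer, autumn, winter),
#' peaking at the equinox/solstice anchoring each season and decaying
#' linearly to the neighbouring anchors, so components always sum to 1 and
#' at most two are nonzero. The winter solstice encodes to `[0, 0, 0, 1]`;
#' the midpoint of spring (equidistant from the spring equinox and the
#' summer solstice) to `[1/2, 1/2, 0, 0]`. Unlike a linear day-of-year
#' mapping, the encoding is continuous across New Year.
#'
#' @param date `Date` vector.
#' @return Numeric matrix `length(date) x 4` with columns `spring`,
#'   `summer`, `autumn`, `winter`.
#' @examples
#' encode_season(as.Date("2020-12-21")) # winter solstice
#' @export
encode_season <- function(date) {
  date <- as.Date(date)
  out <- matrix(0, length(date), 4,
                dimnames = list(NULL, c("spring", "summer", "autumn", "winter")))
  for (r in seq_along(date)) {
    d <- date[r]
    y <- as.integer(format(d, "%Y"))
    anchors <- c(season_anchors(y - 1L), season_anchors(y), season_anchors(y + 1L))
    season_of <- rep(1:4, times = 3)
    prev <- max(which(anchors <= d))
    nxt <- prev + 1L
    span <- as.numeric(anchors[nxt] - anchors[prev])
    w_next <- as.numeric(d - anchors[prev]) / span
    out[r, season_of[prev]] <- out[r, season_of[prev]] + (1 - w_next)
    out[r, season_of[nxt]] <- out[r, season_of[nxt]] + w_next
  }
  out
}

#' Encode temperature
#'
#' Linear map of `[0, 40]` degrees Celsius onto `[0, 1]`; values outside the
#' range are clipped with a warning.
#'
#' @param celsius Numeric temperature(s) in degrees Celsius.
#' @return Value(s) in `[0, 1]`.
#' @export
encode_temperature <- function(celsius) {
  if (any(celsius < 0 | celsius > 40)) {
    warning("temperature outside [0, 40] degrees C clipped")
    celsius <- pmin(pmax(celsius, 0), 40)
  }
  celsius / 40
}

#' One-hot weather encoding
#'
#' `sunny -> [1,0,0]`, `cloudy -> [0,1,0]`, `rainy -> [0,0,1]`.
#'
#' @param kind Character vector of weather kinds.
#' @return Numeric matrix `length(kind) x 3`.
#' @export
encode_weather <- function(kind) {
  idx <- match(kind, WEATHER_KINDS)
  if (anyNA(idx)) {
    stop("unknown weather kind: ",
         paste(unique(kind[is.na(idx)]), collapse = ", "))
  }
  out <- matrix(0, length(kind), 3, dimnames = list(NULL, WEATHER_KINDS))
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' One-hot place encoding
#'
#' @param place_id Character vector of place ids to encode.
#' @param place_ids The full ordered set of encodable place ids.
#' @return Numeric matrix `length(place_id) x length(place_ids)`.
#' @export
encode_place <- function(place_id, place_ids) {
  idx <- match(place_id, place_ids)
  if (anyNA(idx)) {
    stop("unknown place id: ",
         paste(unique(place_id[is.na(idx)]), collapse = ", "))
  }
  out <- matrix(0, length(place_id), length(place_ids),
                dimnames = list(NULL, place_ids))
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' Feature matrix for the community sociability predictor
#'
#' Builds the input block for the Community Time-Specific Adjusted RI
#' regressor: workday flag, season (fuzzy 4-vector by default, or a
#' 3-neuron one-hot dropping winter as reference), scaled temperature,
#' walk predisposition (already standardized by the data pipeline), and the
#' day-slot indicator.
#'
#' @param records Data frame with columns `date`, `workday` (logical),
#'   `temperature_c`, `walk_predisposition`, `slot`
#'   (`morning`/`noon`/`afternoon`).
#' @param season_style `"fuzzy"` (default) or `"onehot3"`.
#' @return Numeric feature matrix.
#' @export
encode_ri_features <- function(records, season_style = c("fuzzy", "onehot3")) {
  season_style <- match.arg(season_style)
  season <- encode_season(records$date)
  if (season_style == "onehot3") {
    m <- max.col(season, ties.method = "first")
    hot <- matrix(0, nrow(season), 4, dimnames = dimnames(season))
    hot[cbind(seq_along(m), m)] <- 1
    # winter is the reference level and is dropped
    season <- hot[, c("spring", "summer", "autumn"), drop = FALSE]
  }
  slot <- matrix(0, nrow(records), 3,
                 dimnames = list(NULL, c("morning", "noon", "afternoon")))
  si <- match(records$slot, colnames(slot))
  if (anyNA(si)) stop("unknown day slot in records")
  slot[cbind(seq_len(nrow(records)), si)] <- 1
  cbind(workday = as.numeric(records$workday), season,
        temperature = encode_temperature(records$temperature_c),
        walk = records$walk_predisposition, slot)
}

#' Feature matrix for the place-popularity predictor
#'
#' Place one-hot block followed by the 9 remaining values: fuzzy season (4),
#' encoded hour (1), one-hot weather (3), scaled temperature (1).
#'
#' @param records Data frame with columns `place_id`, `date`, `hour`
#'   (integer hour of day, within 6..23), `weather`, `temperature_c`.
#' @param place_ids Ordered set of predictable place ids.
#' @return Numeric feature matrix with `length(place_ids) + 9` columns.
#' @export
encode_pi_features <- function(records, place_ids) {
  cbind(
    encode_place(records$place_id, place_ids),
    encode_season(records$date),
    hour = encode_hour(records$hour * 3600),
    encode_weather(records$weather),
    temperature = encode_temperature(records$temperature_c)
  )
}
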