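PLACE_CATEGORIES <- c("apartment_private", "apartment_common", "public")

#' Construct a place map
#'
#' A place map assigns every place (localization cluster) a human-readable
#' label and a category: a resident's private room, a shared apartment area
#' (kitchen, living room, ...), or a public place of the facility (piazza,
#' gym, cafeteria, ...).
#'
#' @param place_id Character vector of unique place identifiers.
#' @param label Character vector of labels (defaults to `place_id`).
#' @param category Character vector; one of `"apartment_private"`,
#'   `"apartment_common"`, `"public"`.
#' @return A tibble of class `place_map`.
#' @examples
#' place_map(c("R1", "C1", "P1"), category = c("apartment_private",
#'   "apartment_common", "public"))
#' @export
place_map <- function(place_id, label = place_id, category) {
  place_id <- as.character(place_id)
  if (anyDuplicated(place_id)) stop("place ids must be unique")
  category <- match.arg(as.character(category), PLACE_CATEGORIES,
                        several.ok = TRUE)
  if (length(category) == 1L) category <- rep(category, length(place_id))
  stopifnot(length(category) == length(place_id),
            length(label) == length(place_id))
  out <- tibble::tibble(place_id = place_id, label = as.character(label),
                        category = category)
  class(out) <- c("place_map", class(out))
  out
}

#' Read / write a place map
#'
#' CSV or YAML with fields `place_id`, `label`, `category`.
#'
#' @param path File path; `.yml`/`.yaml` is parsed as YAML, anything else as
#'   CSV with a header row.
#' @return A [place_map()].
#' @export
read_place_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(raw, as.data.frame))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("place_id", "category")
  if (!all(need %in% names(df))) {
    stop("place map must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$label)) df$label <- df$place_id
  place_map(df$place_id, df$label, df$category)
}

#' @rdname read_place_map
#' @param map A [place_map()].
#' @export
write_place_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

place_categories <- function(map, place_id) {
  idx <- match(place_id, map$place_id)
  out <- map$category[idx]
  out[is.na(idx)] <- "unknown"
  out
}
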