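# Independent reference implementations used to cross-check the package's
# continuity filter, plus small fixture builders.

# Moving median via the compiled Turlach/Stuetzle running median in stats;
# endrule = "keep" leaves the first and last floor(k/2) values unchanged,
# which is exactly the boundary-copy rule.
oracle_moving_median <- function(v, k) {
  as.integer(stats::runmed(v, k, endrule = "keep"))
}

# Run filter via run-length encoding: zero every run of ones shorter than
# min_run slots.
oracle_duration_filter <- function(m, min_run) {
  r <- rle(m)
  r$values[r$values == 1L & r$lengths < min_run] <- 0L
  inverse.rle(r)
}

oracle_filtered_ri <- function(v, k = 5L, min_run = 6L) {
  sum(oracle_duration_filter(oracle_moving_median(v, k), min_run)) / length(v)
}

# A day_traces object from per-resident place sequences given as a named
# list of character vectors of length 8640 (NA allowed).
traces_from_sequences <- function(seqs, date = as.Date("2021-03-01")) {
  places <- sort(unique(stats::na.omit(unlist(seqs, use.names = FALSE))))
  codes <- do.call(rbind, lapply(seqs, function(s) match(s, places)))
  day_traces(date, names(seqs), codes, places)
}

# A trace that stays at `place` over the given slot indices and in a
# private fallback place elsewhere.
sequence_at <- function(place, slots_at, fallback, n_slots = 8640L) {
  s <- rep(fallback, n_slots)
  s[slots_at] <- place
  s
}

# The printed co-location example vector, extended with ones (the row ends
# in a long interaction).
table1_vector <- function(n = 30L) {
  v <- c(1, 1, 0, 0, 1, 1, 1, 0, 0, 0, 0, rep(1, n - 11))
  as.integer(v)
}

tiny_village <- function(seed, ...) {
  village_config(n_residents = 16L, residents_per_apartment = 8L,
                 n_public_places = 4L, seed = seed, ...)
}
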