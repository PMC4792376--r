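# From raw beacon records to encounters and daily cumulative contacts.
#
# Processing chain: RSSI threshold (per record) -> tick-level pair
# observations -> maximal runs of consecutive ticks ("encounters") ->
# per-pair accumulation ("cumulative contact", x recordings = x/3 minutes
# at the 20-second tick).

check_record_cols <- function(records) {
  need <- c("receiver_id", "sender_id", "timestamp", "rssi")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste("beacon records lack columns:", paste(miss, collapse = ", ")),
          class = "schoolcontacts_parse_error")
  }
  invisible(records)
}

#' Keep beacon records at or above a signal-strength threshold
#'
#' The deployment calibration puts about -80 dB at a face-to-face
#' separation of 3 m, so the default threshold keeps records made within
#' conversational range. Applied per record, before directions are
#' combined.
#'
#' @param records Beacon-record tibble (`receiver_id`, `sender_id`,
#'   `timestamp`, `rssi`).
#' @param rssi_threshold Minimum RSSI in dB (default -80); records with
#'   `rssi >= rssi_threshold` are kept, input order preserved.
#' @return Filtered tibble.
#' @export
filter_by_rssi <- function(records, rssi_threshold = -80) {
  check_record_cols(records)
  records %>% filter(.data$rssi >= rssi_threshold)
}

#' Drop records involving non-student motes
#'
#' Staff and stationary motes wore or housed sensors too, but student
#' contact networks are built from student-student records only.
#'
#' @inheritParams filter_by_rssi
#' @param roster Roster tibble with `node_id` and `role`.
#' @return Records whose both endpoints are students.
#' @export
filter_students <- function(records, roster) {
  check_record_cols(records)
  students <- roster$node_id[roster$role == "student"]
  records %>%
    filter(.data$receiver_id %in% students, .data$sender_id %in% students)
}

#' Collapse directed records into tick-level pair observations
#'
#' Timestamps map to tick indices by `floor(timestamp / tick_seconds)` on
#' the shared mote clock. Under the `"union"` rule a pair-tick exists if
#' either mote heard the other during that tick; under `"mutual"` both
#' directions are required. Duplicates collapse to a single pair-tick.
#'
#' @inheritParams filter_by_rssi
#' @param tick_seconds Beacon interval in seconds (default 20).
#' @param rule `"union"` (default; robust to one-sided data loss) or
#'   `"mutual"`.
#' @return Tibble `id_a`, `id_b`, `tick` with `id_a < id_b`, one row per
#'   pair-tick, sorted.
#' @export
records_to_pair_ticks <- function(records, tick_seconds = 20, rule = c("union", "mutual")) {
  rule <- match.arg(rule)
  check_record_cols(records)
  if (any(!nzchar(records$receiver_id)) || any(!nzchar(records$sender_id)) ||
      anyNA(records$receiver_id) || anyNA(records$sender_id)) {
    abort("malformed node ids in beacon records", class = "schoolcontacts_parse_error")
  }
  if (any(records$receiver_id == records$sender_id)) {
    abort("self-records (receiver == sender) are malformed",
          class = "schoolcontacts_parse_error")
  }
  obs <- records %>%
    mutate(
      tick = as.integer(floor(.data$timestamp / tick_seconds)),
      id_a = pmin(.data$receiver_id, .data$sender_id),
      id_b = pmax(.data$receiver_id, .data$sender_id),
      fwd = .data$receiver_id < .data$sender_id
    )
  if (rule == "union") {
    out <- obs %>% distinct(.data$id_a, .data$id_b, .data$tick)
  } else {
    out <- obs %>%
      distinct(.data$id_a, .data$id_b, .data$tick, .data$fwd) %>%
      count(.data$id_a, .data$id_b, .data$tick) %>%
      filter(.data$n == 2L) %>%
      select(-"n")
  }
  out %>% arrange(.data$id_a, .data$id_b, .data$tick)
}

#' Segment pair-ticks into encounters
#'
#' An encounter is a maximal run of ticks in which a pair stays in
#' proximity: with the default `max_gap_ticks = 0` two observations belong
#' to the same encounter only if their ticks are strictly consecutive
#' (each recording standing for a continuous 20-second contact). A
#' positive `max_gap_ticks` additionally bridges short dropouts; duration
#' always counts observed ticks, not the bridged span.
#'
#' @param pair_ticks Tibble from [records_to_pair_ticks()].
#' @param max_gap_ticks Largest bridged gap, in missing ticks (default 0).
#' @param tick_seconds Beacon interval in seconds.
#' @return Tibble `id_a`, `id_b`, `start_tick`, `n_ticks`, `start_s`,
#'   `duration_s` with `duration_s = n_ticks * tick_seconds`.
#' @export
pair_ticks_to_encounters <- function(pair_ticks, max_gap_ticks = 0, tick_seconds = 20) {
  stopifnot(max_gap_ticks >= 0)
  if (nrow(pair_ticks) == 0L) {
    return(tibble(
      id_a = character(0), id_b = character(0), start_tick = integer(0),
      n_ticks = integer(0), start_s = numeric(0), duration_s = numeric(0)
    ))
  }
  pair_ticks %>%
    arrange(.data$id_a, .data$id_b, .data$tick) %>%
    group_by(.data$id_a, .data$id_b) %>%
    mutate(
      new_run = is.na(lag(.data$tick)) |
        (.data$tick - lag(.data$tick)) > (max_gap_ticks + 1L),
      run = cumsum(.data$new_run)
    ) %>%
    group_by(.data$id_a, .data$id_b, .data$run) %>%
    summarise(
      start_tick = min(.data$tick),
      n_ticks = dplyr::n(),
      .groups = "drop"
    ) %>%
    select(-"run") %>%
    mutate(
      start_s = .data$start_tick * tick_seconds,
      duration_s = .data$n_ticks * tick_seconds
    ) %>%
    arrange(.data$id_a, .data$id_b, .data$start_tick)
}

#' Accumulate encounters into daily cumulative contacts
#'
#' Per unordered pair over the deployment day: `total_recordings` is the
#' summed tick count, `cumulative_minutes = total_recordings / 3` (each
#' recording is one 20-second tick), `n_encounters` the number of runs.
#'
#' @param encounters Tibble from [pair_ticks_to_encounters()].
#' @param tick_seconds Beacon interval in seconds; minutes are
#'   `recordings * tick_seconds / 60`.
#' @return Tibble `id_a`, `id_b`, `total_recordings`, `cumulative_minutes`,
#'   `n_encounters`.
#' @export
encounters_to_contacts <- function(encounters, tick_seconds = 20) {
  if (nrow(encounters) == 0L) {
    return(tibble(
      id_a = character(0), id_b = character(0), total_recordings = integer(0),
      cumulative_minutes = numeric(0), n_encounters = integer(0)
    ))
  }
  encounters %>%
    group_by(.data$id_a, .data$id_b) %>%
    summarise(
      total_recordings = sum(.data$n_ticks),
      n_encounters = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(cumulative_minutes = .data$total_recordings * tick_seconds / 60) %>%
    select("id_a", "id_b", "total_recordings", "cumulative_minutes", "n_encounters") %>%
    arrange(.data$id_a, .data$id_b)
}

#' Run the full ingest chain
#'
#' Convenience wrapper: RSSI filter, optional student-only filter,
#' pair-ticks, encounters, contacts.
#'
#' @inheritParams filter_by_rssi
#' @inheritParams records_to_pair_ticks
#' @inheritParams pair_ticks_to_encounters
#' @param roster Optional roster; when given, non-student records are
#'   dropped first.
#' @return List with tibbles `pair_ticks`, `encounters`, `contacts`.
#' @export
ingest_beacon_log <- function(records, roster = NULL, rssi_threshold = -80,
                              tick_seconds = 20, rule = c("union", "mutual"),
                              max_gap_ticks = 0) {
  rule <- match.arg(rule)
  rec <- filter_by_rssi(records, rssi_threshold)
  if (!is.null(roster)) rec <- filter_students(rec, roster)
  ticks <- records_to_pair_ticks(rec, tick_seconds, rule)
  enc <- pair_ticks_to_encounters(ticks, max_gap_ticks, tick_seconds)
  list(
    pair_ticks = ticks,
    encounters = enc,
    contacts = encounters_to_contacts(enc, tick_seconds)
  )
}
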