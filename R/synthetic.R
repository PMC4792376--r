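# Synthetic school day: roster, per-period room schedule, beacon log.
#
# All randomness is driven by config$seed; the three stages draw from
# distinct seeded streams so that e.g. regenerating only the roster does
# not shift the log.

stage_seed <- function(config, stage) {
  offs <- c(roster = 11L, schedule = 29L, log = 47L)
  (config$seed %% 100000L) * 1000L + offs[[stage]]
}

#' Generate a synthetic school roster
#'
#' One row per mote wearer: students (grade x classroom cohorts of
#' `class_size`), plus optional staff and stationary motes. Node ids are
#' stable zero-padded labels, so identical configs and seeds give
#' identical rosters.
#'
#' @param config A [school_config()].
#' @return Tibble with columns `node_id`, `grade`, `classroom`, `role`.
#' @examples
#' generate_roster(school_config(n_grades = 2, classrooms_per_grade = 1, class_size = 3))
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "school_config"))
  set.seed(stage_seed(config, "roster"))
  grid <- tidyr::expand_grid(
    grade_i = seq_len(config$n_grades),
    class_i = seq_len(config$classrooms_per_grade),
    slot = seq_len(config$class_size)
  )
  students <- grid %>%
    mutate(
      node_id = sprintf("S%04d", row_number()),
      grade = sprintf("G%d", .data$grade_i),
      classroom = sprintf("G%dC%d", .data$grade_i, .data$class_i),
      role = "student"
    ) %>%
    select("node_id", "grade", "classroom", "role")
  extras <- list(students)
  if (config$n_staff > 0L) {
    extras <- c(extras, list(tibble(
      node_id = sprintf("T%03d", seq_len(config$n_staff)),
      grade = NA_character_, classroom = NA_character_, role = "staff"
    )))
  }
  if (config$n_stationary > 0L) {
    extras <- c(extras, list(tibble(
      node_id = sprintf("X%03d", seq_len(config$n_stationary)),
      grade = NA_character_, classroom = NA_character_, role = "stationary"
    )))
  }
  bind_rows(extras)
}

room_labels <- function(config) {
  tidyr::expand_grid(
    grade_i = seq_len(config$n_grades),
    class_i = seq_len(config$classrooms_per_grade)
  ) %>%
    mutate(room = sprintf("G%dC%d", .data$grade_i, .data$class_i)) %>%
    pull("room")
}

#' Assign students to rooms for every period
#'
#' Cohort mode sends each classroom cohort to its own room for every class
#' period; individualized mode draws an independent room (across all
#' grades) per student per class period. Break periods scatter all
#' students over `n_break_rooms` common rooms; lunch periods put each
#' grade-group from `lunch_groups` into its own cafeteria room.
#'
#' @param config A [school_config()].
#' @param roster Roster from [generate_roster()] (students only are
#'   scheduled).
#' @return Tibble with one row per student x period: `node_id`, `period`,
#'   `kind`, `start_s`, `end_s`, `room`.
#' @export
generate_schedule <- function(config, roster) {
  stopifnot(inherits(config, "school_config"))
  force(roster)
  set.seed(stage_seed(config, "schedule"))
  students <- roster %>% filter(.data$role == "student")
  rooms <- room_labels(config)
  grade_of <- setNames(students$grade, students$node_id)
  lunch_room_of_grade <- character(0)
  for (gi in seq_along(config$lunch_groups)) {
    for (g in config$lunch_groups[[gi]]) {
      lunch_room_of_grade[sprintf("G%d", g)] <- sprintf("LUNCH%d", gi)
    }
  }
  per <- config$periods %>% mutate(period = row_number())
  out <- purrr::pmap(per, function(start_s, end_s, kind, period) {
    room <- switch(kind,
      class = if (config$schedule_mode == "cohort") {
        students$classroom
      } else {
        sample(rooms, nrow(students), replace = TRUE)
      },
      `break` = sample(sprintf("HALL%d", seq_len(config$n_break_rooms)),
                       nrow(students), replace = TRUE),
      lunch = unname(lunch_room_of_grade[students$grade])
    )
    tibble(
      node_id = students$node_id,
      period = period, kind = kind, start_s = start_s, end_s = end_s,
      room = room
    )
  })
  bind_rows(out)
}

# pmf proportional to d^beta on min_ticks..max_ticks
bounded_powerlaw_pmf <- function(beta, min_ticks, max_ticks) {
  d <- seq.int(min_ticks, max_ticks)
  p <- d^beta
  p / sum(p)
}

# one pair's alternating off/on renewal process within a period of L ticks;
# returns encounter start ticks (0-based within period) and durations
simulate_pair_encounters <- function(L, p_start, beta, min_ticks) {
  if (L < min_ticks || p_start <= 0) {
    return(list(start = integer(0), len = integer(0)))
  }
  pmf <- bounded_powerlaw_pmf(beta, min_ticks, L)
  supp <- seq.int(min_ticks, L)
  starts <- integer(0)
  lens <- integer(0)
  t <- 0L
  first <- TRUE
  repeat {
    # at least one out-of-range tick separates successive encounters, so
    # sampled encounters coincide with observed maximal runs
    gap <- rgeom(1L, p_start) + (if (first) 0L else 1L)
    first <- FALSE
    s <- t + gap
    if (s > L - min_ticks) break
    d <- sample(supp, 1L, prob = pmf)
    d <- min(d, L - s)  # clip at period end
    starts <- c(starts, s)
    lens <- c(lens, d)
    t <- s + d
    if (t >= L) break
  }
  list(start = starts, len = lens)
}

all_pairs <- function(ids) {
  n <- length(ids)
  if (n < 2L) {
    return(tibble(id_a = character(0), id_b = character(0)))
  }
  idx <- utils::combn(n, 2L)
  tibble(id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]])
}

#' Simulate a beacon log for one school day
#'
#' Walks the period schedule and, for every pair of students sharing a
#' room, simulates an alternating process of idle gaps (geometric in
#' ticks) and encounters with power-law durations clipped at the period
#' end. During breaks and lunch, pairs in *different* rooms additionally
#' start minimum-length background encounters with probability
#' `p_background` per tick. Each in-range pair-tick emits two directed
#' beacon records (both motes hear each other) with RSSI drawn from the
#' near-field signal model; `emit_far = TRUE` adds below-threshold records
#' for same-room pairs outside any encounter, and `p_drop` removes
#' individual records to emulate flash-memory loss.
#'
#' The planted ground truth is attached for round-trip testing:
#' `planted_pair_ticks()` returns the exact set of in-range pair-ticks,
#' `planted_encounters()` the sampled encounter list.
#'
#' @param config A [school_config()].
#' @param roster Roster from [generate_roster()].
#' @param schedule Schedule from [generate_schedule()].
#' @return Tibble of beacon records `receiver_id`, `sender_id`,
#'   `timestamp` (seconds from midnight), `rssi` (dB), sorted by
#'   timestamp then receiver; ground truth in attributes.
#' @export
simulate_beacon_log <- function(config, roster, schedule) {
  stopifnot(inherits(config, "school_config"))
  # force lazily supplied inputs before seeding: their own generation
  # touches the RNG and must not interleave with the log stream
  force(roster)
  force(schedule)
  set.seed(stage_seed(config, "log"))
  tick_s <- config$tick_seconds
  enc <- list()
  k <- 0L
  per <- config$periods %>% mutate(period = row_number())
  for (pi in seq_len(nrow(per))) {
    p <- per[pi, ]
    tick0 <- p$start_s %/% tick_s
    L <- (p$end_s - p$start_s) %/% tick_s
    sched_p <- schedule %>% filter(.data$period == p$period)
    room_members <- split(sched_p$node_id, sched_p$room)
    p_room <- switch(p$kind,
      class = config$p_start,
      lunch = config$p_start_lunch,
      config$p_start_common
    )
    for (members in room_members) {
      pr <- all_pairs(sort(members))
      if (nrow(pr) == 0L) next
      for (i in seq_len(nrow(pr))) {
        e <- simulate_pair_encounters(L, p_room, config$duration_exponent,
                                      config$min_encounter_ticks)
        if (length(e$start)) {
          k <- k + 1L
          enc[[k]] <- tibble(
            id_a = pr$id_a[[i]], id_b = pr$id_b[[i]],
            start_tick = tick0 + e$start, n_ticks = e$len
          )
        }
      }
    }
    if (p$kind %in% c("break", "lunch") && config$p_background > 0) {
      room_of <- setNames(sched_p$room, sched_p$node_id)
      pr <- all_pairs(sort(sched_p$node_id)) %>%
        filter(room_of[.data$id_a] != room_of[.data$id_b])
      if (nrow(pr)) {
        # at most one background meeting per pair per period keeps the
        # cross-room signal sparse and short
        hit <- runif(nrow(pr)) < (1 - (1 - config$p_background)^L)
        if (any(hit)) {
          hp <- pr[hit, ]
          st <- sample.int(max(L - config$min_encounter_ticks + 1L, 1L),
                           nrow(hp), replace = TRUE) - 1L
          k <- k + 1L
          enc[[k]] <- tibble(
            id_a = hp$id_a, id_b = hp$id_b,
            start_tick = tick0 + st,
            n_ticks = pmin(config$min_encounter_ticks, L - st)
          )
        }
      }
    }
  }
  encounters <- bind_rows(enc)
  if (nrow(encounters) == 0L) {
    ticks <- tibble(id_a = character(0), id_b = character(0), tick = integer(0))
  } else {
    ticks <- encounters %>%
      mutate(.row = row_number()) %>%
      tidyr::uncount(.data$n_ticks, .id = "off") %>%
      mutate(tick = .data$start_tick + .data$off - 1L) %>%
      distinct(.data$id_a, .data$id_b, .data$tick)
  }
  rec <- bind_rows(
    ticks %>% rename(receiver_id = "id_a", sender_id = "id_b"),
    ticks %>% rename(receiver_id = "id_b", sender_id = "id_a")
  ) %>%
    mutate(
      timestamp = .data$tick * tick_s,
      rssi = rnorm(n(), config$rssi_mean_near, config$rssi_sd)
    )
  if (config$emit_far) {
    far <- far_pair_ticks(config, schedule, ticks)
    if (nrow(far)) {
      rec <- bind_rows(rec, bind_rows(
        far %>% rename(receiver_id = "id_a", sender_id = "id_b"),
        far %>% rename(receiver_id = "id_b", sender_id = "id_a")
      ) %>%
        mutate(
          timestamp = .data$tick * tick_s,
          rssi = rnorm(n(), config$rssi_mean_far, config$rssi_sd)
        ))
    }
  }
  if (config$p_drop > 0) {
    rec <- rec %>% filter(runif(n()) >= config$p_drop)
  }
  rec <- rec %>%
    select("receiver_id", "sender_id", "timestamp", "rssi") %>%
    arrange(.data$timestamp, .data$receiver_id, .data$sender_id)
  attr(rec, "planted_encounters") <- encounters
  attr(rec, "planted_pair_ticks") <- ticks %>% arrange(.data$id_a, .data$id_b, .data$tick)
  rec
}

# same-room pair-ticks that are not inside any encounter
far_pair_ticks <- function(config, schedule, in_range) {
  tick_s <- config$tick_seconds
  per <- config$periods %>% mutate(period = row_number())
  out <- list()
  for (pi in seq_len(nrow(per))) {
    p <- per[pi, ]
    tick0 <- p$start_s %/% tick_s
    L <- (p$end_s - p$start_s) %/% tick_s
    sched_p <- schedule %>% filter(.data$period == p$period)
    for (members in split(sched_p$node_id, sched_p$room)) {
      pr <- all_pairs(sort(members))
      if (nrow(pr) == 0L) next
      out[[length(out) + 1L]] <- tidyr::expand_grid(pr, tick = tick0 + seq_len(L) - 1L)
    }
  }
  if (!length(out)) {
    return(tibble(id_a = character(0), id_b = character(0), tick = integer(0)))
  }
  bind_rows(out) %>% dplyr::anti_join(in_range, by = c("id_a", "id_b", "tick"))
}

#' Ground truth planted by the simulator
#'
#' @param log A beacon log from [simulate_beacon_log()].
#' @return `planted_encounters()`: tibble of sampled encounters (`id_a`,
#'   `id_b`, `start_tick`, `n_ticks`; overlapping background meetings are
#'   possible). `planted_pair_ticks()`: the deduplicated set of in-range
#'   pair-ticks actually emitted.
#' @export
planted_encounters <- function(log) attr(log, "planted_encounters")

#' @rdname planted_encounters
#' @export
planted_pair_ticks <- function(log) attr(log, "planted_pair_ticks")
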