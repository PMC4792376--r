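# School-day configuration: structure, schedule, radio model, seed.

#' Parse a clock time to seconds from midnight
#'
#' Accepts `"HH:MM"` or `"HH:MM:SS"` strings, or a numeric already in seconds.
#'
#' @param x Clock time string or numeric seconds.
#' @return Integer seconds from midnight.
#' @examples
#' clock_seconds("08:30")
#' @export
clock_seconds <- function(x) {
  if (is.numeric(x)) {
    return(as.integer(x))
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.integer(p)
    if (length(p) == 2L) p <- c(p, 0L)
    if (length(p) != 3L || anyNA(p)) {
      abort(paste0("cannot parse clock time ", deparse(x)), class = "schoolcontacts_config_error")
    }
    p[[1L]] * 3600L + p[[2L]] * 60L + p[[3L]]
  }, integer(1))
}

#' Default school-day period table
#'
#' A schedule template for a single deployment day: five class periods
#' interleaved with two short breaks and a lunch period, spanning roughly
#' the 8:30am-3pm window over which motes are typically worn.
#'
#' @param day_start,day_end Clock times bounding the day.
#' @return A tibble with columns `start_s`, `end_s`, `kind`
#'   (one of `"class"`, `"break"`, `"lunch"`).
#' @export
default_periods <- function(day_start = "08:30", day_end = "15:00") {
  tibble(
    start = c("08:30", "10:00", "10:15", "11:45", "12:30", "14:00", "14:15"),
    end   = c("10:00", "10:15", "11:45", "12:30", "14:00", "14:15", "15:00"),
    kind  = c("class", "break", "class", "lunch", "class", "break", "class")
  ) %>%
    mutate(start_s = clock_seconds(.data$start), end_s = clock_seconds(.data$end)) %>%
    select("start_s", "end_s", "kind")
}

#' Configure a synthetic school day
#'
#' Bundles every parameter of the synthetic generator: school structure
#' (grades, classrooms, class size), the day's period schedule, the
#' scheduling regime (`"cohort"` keeps each classroom together all day, as
#' in elementary and middle schools; `"individualized"` reassigns every
#' student to a grade-mixed room each class period, as in US high schools),
#' the encounter process, and the radio signal model.
#'
#' Encounters between co-located students start independently per pair at
#' rate `p_start` (classrooms) or `p_start_common` (cafeterias/hallways
#' during breaks and lunch) per 20-second tick, and last a number of ticks
#' drawn from a discrete power law with exponent `duration_exponent`,
#' clipped at the end of the containing period. Students in *different*
#' rooms during breaks/lunch additionally meet briefly with probability
#' `p_background` per pair-tick.
#'
#' @param n_grades Number of grades.
#' @param classrooms_per_grade Classrooms per grade.
#' @param class_size Students per classroom (>= 2).
#' @param tick_seconds Beacon interval in seconds (motes transmit and
#'   listen on this cycle).
#' @param day_start,day_end Clock times bounding the deployment.
#' @param periods Period table as from [default_periods()]; periods must
#'   tile `[day_start, day_end]` without gaps or overlap.
#' @param schedule_mode `"cohort"` or `"individualized"`.
#' @param p_start Per-pair per-tick probability that two students sharing a
#'   classroom begin a new encounter.
#' @param p_start_common Same, for shared common rooms during breaks (and
#'   lunch unless `p_start_lunch` is given): hallway crowding.
#' @param p_start_lunch Cafeteria encounter-start probability; defaults to
#'   `p_start_common`. Seated lunches keep this low even when hallways
#'   are crowded.
#' @param p_background Per-pair per-tick probability of a minimum-length
#'   encounter between students in different rooms during breaks/lunch.
#' @param duration_exponent Power-law exponent (negative, < -0.5) of the
#'   encounter-duration distribution in ticks.
#' @param min_encounter_ticks Minimum encounter length in ticks.
#' @param n_break_rooms Number of common rooms students scatter into
#'   during break periods.
#' @param lunch_groups List of integer vectors of grade indices sharing a
#'   lunch room; defaults to consecutive grade pairs.
#' @param rssi_mean_near,rssi_sd,rssi_mean_far Signal-strength model (dB):
#'   records between in-range pairs draw RSSI from
#'   `Normal(rssi_mean_near, rssi_sd)`; when `emit_far = TRUE`,
#'   out-of-range same-room pairs also emit records at
#'   `Normal(rssi_mean_far, rssi_sd)`.
#' @param emit_far Emit below-threshold records for out-of-range pairs?
#' @param p_drop Per-record drop probability (models asymmetric data loss).
#' @param n_staff,n_stationary Extra non-student motes added to the roster
#'   (excluded from student networks downstream).
#' @param seed Integer seed; identical configs and seeds reproduce
#'   byte-identical logs.
#' @return A `school_config` object (validated named list).
#' @examples
#' cfg <- school_config(n_grades = 2, classrooms_per_grade = 1, class_size = 5)
#' cfg$n_students
#' @export
school_config <- function(n_grades = 4,
                          classrooms_per_grade = 2,
                          class_size = 12,
                          tick_seconds = 20,
                          day_start = "08:30",
                          day_end = "15:00",
                          periods = default_periods(day_start, day_end),
                          schedule_mode = c("cohort", "individualized"),
                          p_start = 0.2,
                          p_start_common = 0.02,
                          p_start_lunch = NULL,
                          p_background = 0.002,
                          duration_exponent = -2.5,
                          min_encounter_ticks = 1,
                          n_break_rooms = 4,
                          lunch_groups = NULL,
                          rssi_mean_near = -65,
                          rssi_sd = 5,
                          rssi_mean_far = -90,
                          emit_far = FALSE,
                          p_drop = 0,
                          n_staff = 0,
                          n_stationary = 0,
                          seed = 1L) {
  schedule_mode <- match.arg(schedule_mode)
  periods <- as_tibble(periods)
  if (!all(c("start_s", "end_s", "kind") %in% names(periods))) {
    if (all(c("start", "end", "kind") %in% names(periods))) {
      periods <- periods %>%
        mutate(start_s = clock_seconds(.data$start), end_s = clock_seconds(.data$end)) %>%
        select("start_s", "end_s", "kind")
    } else {
      abort("periods needs columns start_s/end_s/kind (or start/end/kind)",
            class = "schoolcontacts_config_error")
    }
  }
  cfg <- list(
    n_grades = as.integer(n_grades),
    classrooms_per_grade = as.integer(classrooms_per_grade),
    class_size = as.integer(class_size),
    tick_seconds = as.integer(tick_seconds),
    day_start_s = clock_seconds(day_start),
    day_end_s = clock_seconds(day_end),
    periods = periods %>% arrange(.data$start_s),
    schedule_mode = schedule_mode,
    p_start = p_start,
    p_start_common = p_start_common,
    p_start_lunch = if (is.null(p_start_lunch)) p_start_common else p_start_lunch,
    p_background = p_background,
    duration_exponent = duration_exponent,
    min_encounter_ticks = as.integer(min_encounter_ticks),
    n_break_rooms = as.integer(n_break_rooms),
    lunch_groups = lunch_groups,
    rssi_mean_near = rssi_mean_near,
    rssi_sd = rssi_sd,
    rssi_mean_far = rssi_mean_far,
    emit_far = isTRUE(emit_far),
    p_drop = p_drop,
    n_staff = as.integer(n_staff),
    n_stationary = as.integer(n_stationary),
    seed = as.integer(seed)
  )
  cfg$n_students <- cfg$n_grades * cfg$classrooms_per_grade * cfg$class_size
  if (is.null(cfg$lunch_groups)) {
    cfg$lunch_groups <- default_lunch_groups(cfg$n_grades)
  }
  class(cfg) <- "school_config"
  validate_school_config(cfg)
  cfg
}

#' Canonical school scenarios
#'
#' Two preset parameterisations spanning the observed range of school
#' mixing. `"elementary"` uses the cohort schedule, quiet common rooms
#' and grade-paired lunch slots: classroom cohorts dominate, grade
#' modularity is high, and break-time degree barely moves. `"highschool"`
#' uses individualized (grade-mixed) class schedules, a single shared
#' cafeteria and crowded hallways during breaks: the network mixes across
#' grades, modularity is low, and average degree spikes whenever students
#' can roam.
#'
#' @param scenario `"elementary"` or `"highschool"`.
#' @param seed Integer seed.
#' @param ... Further arguments passed on to [school_config()].
#' @return A `school_config`.
#' @examples
#' school_scenario("highschool", seed = 3)
#' @export
school_scenario <- function(scenario = c("elementary", "highschool"), seed = 1L, ...) {
  scenario <- match.arg(scenario)
  if (scenario == "elementary") {
    school_config(schedule_mode = "cohort", seed = seed, ...)
  } else {
    dots <- list(...)
    ng <- dots$n_grades %||% formals(school_config)$n_grades
    do.call(school_config, c(
      list(
        schedule_mode = "individualized",
        p_start_common = 0.1,
        p_start_lunch = 0.02,
        lunch_groups = list(seq_len(ng)),  # one shared cafeteria
        seed = seed
      ),
      dots
    ))
  }
}

default_lunch_groups <- function(n_grades) {
  grades <- seq_len(n_grades)
  split(grades, ceiling(grades / 2))
}

validate_school_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "schoolcontacts_config_error")
  if (cfg$n_grades < 1L || cfg$classrooms_per_grade < 1L) bad("need at least one grade and classroom")
  if (cfg$class_size < 2L) bad("class_size must be >= 2")
  if (cfg$tick_seconds <= 0L) bad("tick_seconds must be positive")
  if (!(cfg$duration_exponent < -0.5)) bad("duration_exponent must be < -0.5")
  for (p in c("p_start", "p_start_common", "p_start_lunch", "p_background", "p_drop")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad(paste(p, "must be a probability in [0, 1]"))
  }
  if (cfg$min_encounter_ticks < 1L) bad("min_encounter_ticks must be >= 1")
  per <- cfg$periods
  if (nrow(per) == 0L) bad("periods is empty")
  if (per$start_s[1L] != cfg$day_start_s || per$end_s[nrow(per)] != cfg$day_end_s) {
    bad("periods must span exactly [day_start, day_end]")
  }
  if (any(per$end_s <= per$start_s)) bad("each period must have positive length")
  if (nrow(per) > 1L && any(per$start_s[-1L] != per$end_s[-nrow(per)])) {
    bad("periods must tile the day without gaps or overlap")
  }
  if (!all(per$kind %in% c("class", "break", "lunch"))) bad("period kind must be class/break/lunch")
  if (!setequal(unlist(cfg$lunch_groups), seq_len(cfg$n_grades))) {
    bad("lunch_groups must partition the grades")
  }
  invisible(cfg)
}

#' @export
print.school_config <- function(x, ...) {
  cat(sprintf(
    "<school_config> %d grades x %d classrooms x %d students (%s schedule), seed %d\n",
    x$n_grades, x$classrooms_per_grade, x$class_size, x$schedule_mode, x$seed
  ))
  cat(sprintf(
    "  day %05.2f-%05.2f h, %d periods, tick %d s, duration exponent %.2f\n",
    x$day_start_s / 3600, x$day_end_s / 3600, nrow(x$periods),
    x$tick_seconds, x$duration_exponent
  ))
  invisible(x)
}

#' Read or write a school configuration as YAML
#'
#' The on-disk form mirrors the [school_config()] arguments; `periods` is a
#' list of `{start, end, kind}` maps with clock-time strings.
#'
#' @param path File path.
#' @return `read_school_config()` returns a `school_config`;
#'   `write_school_config()` returns `path` invisibly.
#' @export
read_school_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$periods)) {
    raw$periods <- dplyr::bind_rows(lapply(raw$periods, as_tibble))
  }
  known <- names(formals(school_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warn(paste("ignoring unknown config keys:", paste(extra, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(school_config, raw)
}

#' @rdname read_school_config
#' @param config A `school_config`.
#' @export
write_school_config <- function(config, path) {
  stopifnot(inherits(config, "school_config"))
  per <- config$periods
  out <- list(
    n_grades = config$n_grades,
    classrooms_per_grade = config$classrooms_per_grade,
    class_size = config$class_size,
    tick_seconds = config$tick_seconds,
    day_start = config$day_start_s,
    day_end = config$day_end_s,
    periods = purrr::pmap(per, function(start_s, end_s, kind) {
      list(start_s = start_s, end_s = end_s, kind = kind)
    }),
    schedule_mode = config$schedule_mode,
    p_start = config$p_start,
    p_start_common = config$p_start_common,
    p_start_lunch = config$p_start_lunch,
    p_background = config$p_background,
    duration_exponent = config$duration_exponent,
    min_encounter_ticks = config$min_encounter_ticks,
    n_break_rooms = config$n_break_rooms,
    lunch_groups = unname(lapply(config$lunch_groups, as.integer)),
    rssi_mean_near = config$rssi_mean_near,
    rssi_sd = config$rssi_sd,
    rssi_mean_far = config$rssi_mean_far,
    emit_far = config$emit_far,
    p_drop = config$p_drop,
    n_staff = config$n_staff,
    n_stationary = config$n_stationary,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
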