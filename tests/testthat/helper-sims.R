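# Seeded synthetic schools shared across test files (simulated once per
# test session).

.sim_cache <- new.env(parent = emptyenv())

sim_school <- function(key, cfg) {
  if (!exists(key, envir = .sim_cache)) {
    roster <- generate_roster(cfg)
    schedule <- generate_schedule(cfg, roster)
    log <- simulate_beacon_log(cfg, roster, schedule)
    ing <- ingest_beacon_log(log, roster)
    assign(key, list(cfg = cfg, roster = roster, schedule = schedule,
                     log = log, ing = ing), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# small cohort school: 3 grades x 1 classroom x 10 students
elem_small <- function() {
  sim_school("elem_small", school_scenario(
    "elementary", seed = 11, n_grades = 3, classrooms_per_grade = 1,
    class_size = 10
  ))
}

# small individualized school with shared hallways: 2 x 2 x 8
hs_small <- function() {
  sim_school("hs_small", school_scenario(
    "highschool", seed = 5, n_grades = 2, classrooms_per_grade = 2,
    class_size = 8, n_break_rooms = 2
  ))
}

# full-size study-condition schools (4 grades x 2 classrooms x 12)
elem_full <- function() sim_school("elem_full", school_scenario("elementary", seed = 7))
hs_full <- function() sim_school("hs_full", school_scenario("highschool", seed = 7))

period_kind_of <- function(cfg, t) {
  k <- cfg$periods$kind[cfg$periods$start_s <= t & t < cfg$periods$end_s]
  if (length(k)) k[1] else NA_character_
}
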