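test_that("roster has the configured structure and is deterministic", {
  cfg <- school_config(n_grades = 2, classrooms_per_grade = 2, class_size = 10, seed = 3)
  r <- generate_roster(cfg)
  expect_equal(nrow(r), 40L)
  expect_equal(dplyr::n_distinct(r$classroom), 4L)
  expect_identical(r, generate_roster(cfg))
  wide <- generate_roster(school_config(n_grades = 5, classrooms_per_grade = 1,
                                        class_size = 30, seed = 1))
  expect_true(all(table(wide$grade) == 30))
  expect_true(!anyDuplicated(wide$node_id))
})

test_that("staff and stationary motes join the roster with their roles", {
  cfg <- school_config(n_grades = 1, classrooms_per_grade = 1, class_size = 3,
                       n_staff = 2, n_stationary = 4, seed = 1)
  r <- generate_roster(cfg)
  expect_equal(unname(table(r$role)[c("student", "staff", "stationary")]),
               c(3L, 2L, 4L), ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(school_config(class_size = 1), class = "schoolcontacts_config_error")
  expect_error(school_config(duration_exponent = -0.3), class = "schoolcontacts_config_error")
  expect_error(school_config(p_background = 1.5), class = "schoolcontacts_config_error")
  bad_periods <- tibble::tibble(start_s = c(30600, 40000), end_s = c(39000, 54000),
                                kind = c("class", "class"))
  expect_error(school_config(periods = bad_periods), class = "schoolcontacts_config_error")
})

test_that("cohort schedules keep classrooms together; breaks use common rooms", {
  cfg <- school_config(n_grades = 2, classrooms_per_grade = 2, class_size = 5,
                       schedule_mode = "cohort", seed = 9)
  r <- generate_roster(cfg)
  s <- generate_schedule(cfg, r)
  cls <- s[s$kind == "class", ]
  by_room <- tapply(cls$room, paste(r$classroom[match(cls$node_id, r$node_id)], cls$period),
                    function(x) length(unique(x)))
  expect_true(all(by_room == 1))
  expect_true(all(grepl("^HALL", s$room[s$kind == "break"])))
  expect_true(all(grepl("^LUNCH", s$room[s$kind == "lunch"])))
})

test_that("individualized schedules mix grades within rooms", {
  sim <- hs_small()
  gr <- stats::setNames(sim$roster$grade, sim$roster$node_id)
  cls <- sim$schedule[sim$schedule$kind == "class", ]
  n_grades_by_room <- tapply(gr[cls$node_id], paste(cls$period, cls$room),
                             function(x) length(unique(x)))
  expect_true(any(n_grades_by_room > 1))
})

test_that("beacon logs respect the clock and the room structure", {
  cfg <- school_config(n_grades = 2, classrooms_per_grade = 2, class_size = 5,
                       p_background = 0, seed = 13)
  r <- generate_roster(cfg)
  s <- generate_schedule(cfg, r)
  log <- simulate_beacon_log(cfg, r, s)
  expect_true(all(log$timestamp >= cfg$day_start_s & log$timestamp <= cfg$day_end_s))
  expect_true(all((log$timestamp - cfg$day_start_s) %% cfg$tick_seconds == 0))
  # with no background process, class-period records stay within classrooms
  room_of <- stats::setNames(r$classroom, r$node_id)
  class_per <- cfg$periods[cfg$periods$kind == "class", ]
  in_class <- vapply(log$timestamp, function(t) {
    any(class_per$start_s <= t & t < class_per$end_s)
  }, logical(1))
  expect_true(all(room_of[log$receiver_id[in_class]] == room_of[log$sender_id[in_class]]))
})

test_that("identical config and seed give byte-identical logs", {
  cfg <- school_config(n_grades = 2, classrooms_per_grade = 1, class_size = 6, seed = 5)
  r1 <- generate_roster(cfg)
  log1 <- simulate_beacon_log(cfg, r1, generate_schedule(cfg, r1))
  r2 <- generate_roster(cfg)
  log2 <- simulate_beacon_log(cfg, r2, generate_schedule(cfg, r2))
  expect_identical(log1, log2)
})

test_that("ingest round trip recovers exactly the planted pair-ticks", {
  # narrow RSSI noise: the -80 dB cut sits > 5 sd from both signal means,
  # so thresholding is a clean separator and the recovery is exact
  cfg <- school_config(n_grades = 2, classrooms_per_grade = 1, class_size = 6,
                       emit_far = TRUE, rssi_sd = 2, seed = 21)
  r <- generate_roster(cfg)
  log <- simulate_beacon_log(cfg, r, generate_schedule(cfg, r))
  expect_true(any(log$rssi < -80))  # far records really present
  got <- records_to_pair_ticks(filter_by_rssi(log, -80), cfg$tick_seconds)
  planted <- dplyr::arrange(planted_pair_ticks(log), id_a, id_b, tick)
  expect_equal(as.data.frame(got), as.data.frame(planted), ignore_attr = TRUE)
})

test_that("per-record drops break one-sided records, union rule repairs them", {
  cfg <- school_config(n_grades = 1, classrooms_per_grade = 1, class_size = 8,
                       p_drop = 0.3, seed = 31)
  r <- generate_roster(cfg)
  log <- simulate_beacon_log(cfg, r, generate_schedule(cfg, r))
  union_ticks <- records_to_pair_ticks(log, cfg$tick_seconds, "union")
  mutual_ticks <- records_to_pair_ticks(log, cfg$tick_seconds, "mutual")
  planted <- planted_pair_ticks(log)
  expect_lt(nrow(mutual_ticks), nrow(union_ticks))
  expect_lte(nrow(union_ticks), nrow(planted))
  # union recovers every pair-tick where at least one direction survived
  expect_gt(nrow(union_ticks) / nrow(planted), 1 - 2 * 0.3)
})

test_that("simulated encounter durations recover the configured exponent", {
  sim <- elem_full()
  enc <- sim$ing$encounters
  expect_gte(nrow(enc), 20000)
  fit <- fit_power_law(enc$n_ticks, discrete = TRUE,
                       xmin = sim$cfg$min_encounter_ticks)
  expect_lt(abs(fit$beta - sim$cfg$duration_exponent), 0.15)
})
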