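rec <- function(rx, tx, ts, rssi = -60) {
  tibble::tibble(receiver_id = rx, sender_id = tx, timestamp = ts, rssi = rssi)
}

test_that("RSSI filter keeps records at or above the threshold, in order", {
  r <- rec(c("a", "a", "a"), c("b", "b", "b"), c(0, 20, 40), rssi = c(-70, -80, -95))
  expect_equal(filter_by_rssi(r, -80)$rssi, c(-70, -80))
  expect_equal(filter_by_rssi(r, -Inf), r)
  expect_equal(nrow(filter_by_rssi(r[0, ], -80)), 0L)
})

test_that("pair-tick rules collapse directions correctly", {
  both <- dplyr::bind_rows(rec("a", "b", 7 * 20), rec("b", "a", 7 * 20 + 5))
  expect_equal(records_to_pair_ticks(both, rule = "union"),
               tibble::tibble(id_a = "a", id_b = "b", tick = 7L))
  expect_equal(records_to_pair_ticks(both, rule = "mutual"),
               tibble::tibble(id_a = "a", id_b = "b", tick = 7L))
  one <- rec("a", "b", 7 * 20)
  expect_equal(nrow(records_to_pair_ticks(one, rule = "union")), 1L)
  expect_equal(nrow(records_to_pair_ticks(one, rule = "mutual")), 0L)
})

test_that("three pair-ticks make one minute of cumulative contact", {
  r <- rec(rep("a", 3), rep("b", 3), c(0, 20, 40))
  out <- ingest_beacon_log(r)
  expect_equal(out$contacts$total_recordings, 3L)
  expect_equal(out$contacts$cumulative_minutes, 1)
})

test_that("malformed records are rejected", {
  expect_error(records_to_pair_ticks(rec("a", "a", 0)), class = "schoolcontacts_parse_error")
  expect_error(records_to_pair_ticks(rec("a", NA_character_, 0)),
               class = "schoolcontacts_parse_error")
})

test_that("encounter segmentation follows the consecutive-tick rule", {
  pt <- function(ticks) tibble::tibble(id_a = "a", id_b = "b", tick = as.integer(ticks))
  e1 <- pair_ticks_to_encounters(pt(c(7, 8, 9)))
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$n_ticks, 3L)
  expect_equal(e1$duration_s, 60)
  e2 <- pair_ticks_to_encounters(pt(c(7, 9)), max_gap_ticks = 0)
  expect_equal(e2$n_ticks, c(1L, 1L))
  expect_equal(e2$duration_s, c(20, 20))
  e3 <- pair_ticks_to_encounters(pt(c(7, 9)), max_gap_ticks = 1)
  expect_equal(nrow(e3), 1L)
  expect_equal(e3$n_ticks, 2L)  # duration counts observed ticks, not the span
})

test_that("contacts accumulate encounters with the recordings/3 rule", {
  enc <- tibble::tibble(id_a = "a", id_b = "b", start_tick = c(0L, 10L),
                        n_ticks = c(3L, 6L))
  cc <- encounters_to_contacts(enc)
  expect_equal(cc$total_recordings, 9L)
  expect_equal(cc$cumulative_minutes, 3)
  expect_equal(cc$n_encounters, 2L)
  expect_equal(nrow(encounters_to_contacts(enc[0, ])), 0L)
})

test_that("cumulative minutes are invariant to how 15 pair-ticks split into runs", {
  # any arrangement of 15 ticks gives 5 minutes exactly
  set.seed(42)
  for (i in 1:10) {
    ticks <- sort(sample.int(60, 15))
    pt <- tibble::tibble(id_a = "x", id_b = "y", tick = ticks)
    cc <- encounters_to_contacts(pair_ticks_to_encounters(pt))
    expect_equal(cc$total_recordings, 15L)
    expect_equal(cc$cumulative_minutes, 5)
  }
})

test_that("ingest matches brute-force enumeration on random small logs", {
  set.seed(301)
  for (case in 1:8) {
    n <- sample(10:50, 1)
    ids <- sprintf("m%d", 1:6)
    pairs <- t(utils::combn(ids, 2))
    pick <- sample.int(nrow(pairs), n, replace = TRUE)
    swap <- runif(n) < 0.5
    records <- tibble::tibble(
      receiver_id = ifelse(swap, pairs[pick, 2], pairs[pick, 1]),
      sender_id = ifelse(swap, pairs[pick, 1], pairs[pick, 2]),
      timestamp = sample(0:900, n, replace = TRUE),
      rssi = runif(n, -100, -50)
    )
    out <- ingest_beacon_log(records, rssi_threshold = -80)
    oracle <- brute_contacts(records, -80)
    expect_equal(
      out$contacts[c("id_a", "id_b", "total_recordings")],
      oracle,
      ignore_attr = TRUE
    )
    # conservation: recordings total equals the distinct pair-tick count
    expect_equal(sum(out$contacts$total_recordings), nrow(out$pair_ticks))
    expect_equal(out$contacts$cumulative_minutes,
                 out$contacts$total_recordings / 3)
    # segmentation partitions the pair-ticks
    expect_equal(sum(out$encounters$n_ticks), nrow(out$pair_ticks))
    covered <- out$encounters[rep(seq_len(nrow(out$encounters)), out$encounters$n_ticks),
                              c("id_a", "id_b", "start_tick")]
    covered$tick <- covered$start_tick + sequence(out$encounters$n_ticks) - 1L
    expect_equal(
      dplyr::arrange(covered[c("id_a", "id_b", "tick")], id_a, id_b, tick),
      out$pair_ticks,
      ignore_attr = TRUE
    )
  }
})

test_that("lowering the RSSI threshold never decreases cumulative minutes", {
  set.seed(17)
  n <- 200
  records <- tibble::tibble(
    receiver_id = sample(c("a", "b", "c"), n, replace = TRUE),
    sender_id = sample(c("d", "e"), n, replace = TRUE),
    timestamp = sample(0:2000, n, replace = TRUE),
    rssi = runif(n, -100, -50)
  )
  strict <- ingest_beacon_log(records, rssi_threshold = -70)$contacts
  loose <- ingest_beacon_log(records, rssi_threshold = -90)$contacts
  joined <- dplyr::left_join(
    strict, loose,
    by = c("id_a", "id_b"), suffix = c("_strict", "_loose")
  )
  expect_true(all(joined$cumulative_minutes_loose >= joined$cumulative_minutes_strict))
})

test_that("non-student records are dropped for student networks", {
  roster <- tibble::tibble(
    node_id = c("s1", "s2", "t1", "x1"),
    grade = c("G1", "G1", NA, NA),
    classroom = c("G1C1", "G1C1", NA, NA),
    role = c("student", "student", "staff", "stationary")
  )
  records <- dplyr::bind_rows(
    rec("s1", "s2", 0), rec("s1", "t1", 0), rec("x1", "s2", 20)
  )
  out <- ingest_beacon_log(records, roster)
  expect_equal(nrow(out$contacts), 1L)
  expect_equal(out$contacts$id_a, "s1")
  expect_equal(out$contacts$id_b, "s2")
})
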