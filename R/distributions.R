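# Empirical duration distributions: encounter durations, gaps between
# encounters, encounters per pair, cumulative contact durations, degree
# histograms.

#' Collect a duration sample from encounters or contacts
#'
#' The four quantities whose distributions characterise the temporal
#' texture of a deployment day:
#' * `encounter_duration` — seconds per encounter;
#' * `inter_encounter_gap` — per pair, seconds between the end of one
#'   encounter (exclusive) and the start of the next;
#' * `encounters_per_pair` — number of encounters per pair;
#' * `contact_duration` — cumulative minutes per pair.
#'
#' @param x Encounter tibble (first three kinds) or contact tibble
#'   (`contact_duration`).
#' @param kind One of the four kinds above.
#' @param tick_seconds Beacon interval in seconds.
#' @return Tibble `value`, `kind`; gaps exist only for pairs with at
#'   least two encounters.
#' @examples
#' enc <- tibble::tibble(
#'   id_a = "a", id_b = "b", start_tick = c(1L, 10L), n_ticks = c(3L, 2L)
#' )
#' collect_durations(enc, "inter_encounter_gap")
#' @export
collect_durations <- function(x,
                              kind = c("encounter_duration", "inter_encounter_gap",
                                       "encounters_per_pair", "contact_duration"),
                              tick_seconds = 20) {
  kind <- match.arg(kind)
  values <- switch(kind,
    encounter_duration = x$n_ticks * tick_seconds,
    inter_encounter_gap = {
      x %>%
        arrange(.data$id_a, .data$id_b, .data$start_tick) %>%
        group_by(.data$id_a, .data$id_b) %>%
        mutate(gap_ticks = .data$start_tick - lag(.data$start_tick) - lag(.data$n_ticks)) %>%
        ungroup() %>%
        filter(!is.na(.data$gap_ticks)) %>%
        pull("gap_ticks") * tick_seconds
    },
    encounters_per_pair = {
      x %>% count(.data$id_a, .data$id_b) %>% pull("n")
    },
    contact_duration = x$cumulative_minutes
  )
  tibble(value = as.numeric(values), kind = kind)
}

#' Proportion of values on one side of a bound
#'
#' Computed on the unthresholded contact list, e.g. the share of all
#' contacts lasting at most 5 minutes.
#'
#' @param values Numeric sample (or a `value` column tibble from
#'   [collect_durations()]).
#' @param bound Positive bound, same units as the values.
#' @param side `"le"` (values `<= bound`) or `"gt"` (values `> bound`).
#' @return Proportion in `[0, 1]`.
#' @export
fraction_within <- function(values, bound, side = c("le", "gt")) {
  side <- match.arg(side)
  if (is.data.frame(values)) values <- values$value
  stopifnot(bound > 0, length(values) > 0)
  if (side == "le") mean(values <= bound) else mean(values > bound)
}

#' Degree histogram of a contact network
#'
#' @param net A `contact_network`.
#' @return Tibble `k`, `n_k` over `k = 0 .. max(degree)`, class
#'   `degree_histogram`; `sum(n_k)` equals the node count.
#' @export
degree_distribution_table <- function(net) {
  deg <- igraph::degree(as_igraph(net))
  ks <- seq(0L, max(deg, 0L))
  out <- tibble(
    k = ks,
    n_k = vapply(ks, function(k) sum(deg == k), integer(1))
  )
  class(out) <- c("degree_histogram", class(out))
  out
}

#' Relative-frequency table of a duration sample
#'
#' @param sample Tibble from [collect_durations()] (or numeric vector).
#' @return Tibble `value`, `rel_freq` summing to 1.
#' @export
relative_frequency <- function(sample) {
  values <- if (is.data.frame(sample)) sample$value else sample
  tibble(value = values) %>%
    count(.data$value, name = "n") %>%
    mutate(rel_freq = .data$n / sum(.data$n)) %>%
    select("value", "rel_freq")
}

#' Exponential-rate estimate for signal strengths
#'
#' Encounter signal strengths (as magnitudes of the negative dB
#' readings above the minimum observed) are well described by an
#' exponential law; the MLE rate is `1 / mean(|rssi| - min|rssi|)`.
#'
#' @param records Beacon-record tibble with an `rssi` column.
#' @return One-row tibble `rate`, `mean_excess`, `n`.
#' @export
rssi_exponential_rate <- function(records) {
  mag <- abs(records$rssi)
  excess <- mag - min(mag)
  tibble(rate = 1 / mean(excess), mean_excess = mean(excess), n = length(mag))
}
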