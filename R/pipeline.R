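# End-to-end pipeline: (simulate) -> ingest -> network metrics ->
# modularity -> duration distributions, with all tables written as CSV.

#' Run the full analysis pipeline
#'
#' Two entry modes: pass a [school_config()] to simulate a school day
#' first, or pass file paths (`beacon_log` + `roster`, or a prebuilt
#' `network` + `roster`) to analyse recorded data. The stages then run in
#' order — ingest (RSSI threshold, pair-ticks, encounters, contacts),
#' network build at the contact-duration threshold, summary statistics,
#' grade/classroom modularity with threshold sweeps, contact matrices,
#' overlap curve, time-binned degree, duration distributions and
#' power-law fits — and every table is written under `out_dir`.
#'
#' Defaults reproduce the standard deployment settings without any
#' flags: -80 dB RSSI cut, 20-second ticks, union pair rule, 5-minute
#' contact threshold, 10-recording sweep step.
#'
#' @param input A `school_config`, or a named list with elements
#'   `beacon_log` and `roster` (file paths), or `network` and `roster`.
#' @param out_dir Output directory (created if needed).
#' @param rssi_threshold RSSI cut in dB (default -80).
#' @param tick_seconds Beacon interval (default 20 s).
#' @param contact_threshold_minutes Strict contact-duration threshold
#'   (default 5 minutes).
#' @param pair_rule `"union"` or `"mutual"`.
#' @param sweep_step Modularity sweep step in recordings (default 10).
#' @param write_raw Also write the simulated beacon log and roster?
#' @param verbose Log stage progress and counts to stderr.
#' @return Invisibly, a list with `roster`, `contacts`, `encounters`,
#'   `network`, `summary`, `modularity`, `contact_matrix_grade`,
#'   `overlap_curve`, `time_binned_degree`, `fits`, `files`.
#' @export
run_pipeline <- function(input, out_dir,
                         rssi_threshold = -80, tick_seconds = 20,
                         contact_threshold_minutes = 5,
                         pair_rule = c("union", "mutual"),
                         sweep_step = 10, write_raw = FALSE, verbose = TRUE) {
  pair_rule <- match.arg(pair_rule)
  log_msg <- function(...) if (verbose) message("[schoolcontacts] ", sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(as_tibble(x), p)
    files[[length(files) + 1L]] <<- p
    p
  }

  prebuilt <- NULL
  encounters <- NULL
  if (inherits(input, "school_config")) {
    log_msg("simulating school day (seed %d)", input$seed)
    roster <- generate_roster(input)
    schedule <- generate_schedule(input, roster)
    records <- simulate_beacon_log(input, roster, schedule)
    tick_seconds <- input$tick_seconds
    if (write_raw) {
      emit(records, "beacon_log.csv")
    }
  } else if (!is.null(input$beacon_log)) {
    roster <- read_roster(input$roster)
    records <- read_beacon_log(input$beacon_log)
  } else if (!is.null(input$network)) {
    roster <- read_roster(input$roster)
    prebuilt <- read_network(input$network, roster = roster)
    records <- NULL
  } else {
    abort("input must be a school_config, or list(beacon_log=, roster=) or list(network=, roster=)",
          class = "schoolcontacts_config_error")
  }
  emit(roster, "roster.csv")

  if (is.null(prebuilt)) {
    log_msg("ingest: %d raw records, RSSI >= %g dB, %s rule",
            nrow(records), rssi_threshold, pair_rule)
    ing <- ingest_beacon_log(records, roster, rssi_threshold, tick_seconds, pair_rule)
    encounters <- ing$encounters
    contacts <- ing$contacts
    log_msg("ingest: %d pair-ticks, %d encounters, %d contacts",
            nrow(ing$pair_ticks), nrow(encounters), nrow(contacts))
    emit(contacts, "contacts.csv")
    net <- build_network(contacts, roster, contact_threshold_minutes)
  } else {
    log_msg("prebuilt network input: skipping ingest")
    contacts <- tidy(prebuilt) %>%
      mutate(
        cumulative_minutes = .data$weight,
        total_recordings = as.integer(round(.data$weight * 60 / tick_seconds)),
        n_encounters = NA_integer_
      )
    net <- build_network(contacts, roster, contact_threshold_minutes)
  }
  log_msg("network: %d nodes, %d edges at > %g min",
          igraph::gorder(as_igraph(net)), igraph::gsize(as_igraph(net)),
          contact_threshold_minutes)

  summary_tab <- glance(net)
  emit(summary_tab, "network_summary.csv")
  emit(node_metrics(net), "node_metrics.csv")
  write_network(net, file.path(out_dir, "network.csv"), "edge_csv")
  write_network(net, file.path(out_dir, "network.net"), "pajek")
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  files <- c(files, file.path(out_dir, c("network.csv", "network.net", "network.graphml")))

  have_labels <- all(c("grade", "classroom") %in% names(network_nodes(net))) &&
    !anyNA(network_nodes(net)$grade)
  mod_tab <- NULL
  if (have_labels && igraph::gsize(as_igraph(net)) > 0) {
    mod_tab <- purrr::map(c("grade", "classroom"), function(level) {
      part <- network_partition(net, level)
      tibble(
        level = level,
        q_weighted = modularity_score(net, part, weighted = TRUE),
        q_binary = modularity_score(net, part, weighted = FALSE)
      )
    }) %>% bind_rows()
    emit(mod_tab, "modularity.csv")
    for (level in c("grade", "classroom")) {
      sweep <- modularity_vs_threshold(contacts, roster, level,
                                       step_recordings = sweep_step,
                                       tick_seconds = tick_seconds)
      emit(sweep, sprintf("modularity_sweep_%s.csv", level))
    }
    M <- contact_matrix(net, "grade")
    emit(as_tibble(M, rownames = "grade"), "contact_matrix_grade.csv")
  } else {
    M <- NULL
    log_msg("no grade/classroom labels: skipping modularity and contact matrices")
  }

  curve <- overlap_vs_weight_curve(net)
  emit(curve, "overlap_curve.csv")
  emit(degree_distribution_table(net), "degree_distribution.csv")

  fits <- list()
  tbd <- NULL
  if (!is.null(encounters) && nrow(encounters)) {
    tbd <- time_binned_degree(encounters, roster, tick_seconds = tick_seconds)
    emit(tbd, "time_binned_degree.csv")
    enc_sample <- collect_durations(encounters, "encounter_duration", tick_seconds)
    con_sample <- collect_durations(contacts, "contact_duration")
    emit(relative_frequency(enc_sample), "encounter_duration_freq.csv")
    emit(relative_frequency(con_sample), "contact_duration_freq.csv")
    fits$encounter_duration <- tryCatch(
      fit_power_law(enc_sample$value / tick_seconds, discrete = TRUE),
      schoolcontacts_fit_error = function(e) NULL
    )
    fits$contact_duration <- tryCatch(
      fit_power_law(con_sample$value, discrete = FALSE),
      schoolcontacts_fit_error = function(e) NULL
    )
    fit_lines <- purrr::imap_chr(fits, function(f, nm) {
      if (is.null(f)) {
        sprintf("%s: no fit (too few points)", nm)
      } else {
        sprintf("%s: beta %.4f xmin %g KS %.4f n_tail %d of %d",
                nm, f$beta, f$xmin, f$ks, f$n_tail, f$n)
      }
    })
    writeLines(fit_lines, file.path(out_dir, "powerlaw_fits.txt"))
    files <- c(files, file.path(out_dir, "powerlaw_fits.txt"))
  }

  log_msg("done: %d output files in %s", length(files), out_dir)
  invisible(list(
    roster = roster, contacts = contacts, encounters = encounters,
    network = net, summary = summary_tab, modularity = mod_tab,
    contact_matrix_grade = M, overlap_curve = curve,
    time_binned_degree = tbd, fits = fits, files = files
  ))
}
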