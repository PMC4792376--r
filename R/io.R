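# File formats: beacon-log / roster / contact CSVs, edge-list CSV,
# Pajek .net with companion .clu partitions, GraphML.

read_csv_quiet <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read and write beacon logs
#'
#' CSV dialect `receiver_id,sender_id,timestamp,rssi`.
#'
#' @param path File path.
#' @return `read_beacon_log()` a beacon-record tibble;
#'   writers return `path` invisibly.
#' @export
read_beacon_log <- function(path) {
  out <- read_csv_quiet(path, readr::cols(
    receiver_id = readr::col_character(),
    sender_id = readr::col_character(),
    timestamp = readr::col_double(),
    rssi = readr::col_double()
  ))
  check_record_cols(out)
}

#' @rdname read_beacon_log
#' @param records Beacon-record tibble.
#' @export
write_beacon_log <- function(records, path) {
  check_record_cols(records)
  readr::write_csv(records[c("receiver_id", "sender_id", "timestamp", "rssi")], path)
  invisible(path)
}

#' Read and write rosters
#'
#' CSV dialect `node_id,grade,classroom,role`.
#'
#' @param path File path.
#' @return `read_roster()` a roster tibble; the writer returns `path`
#'   invisibly.
#' @export
read_roster <- function(path) {
  read_csv_quiet(path, readr::cols(
    node_id = readr::col_character(),
    grade = readr::col_character(),
    classroom = readr::col_character(),
    role = readr::col_character()
  ))
}

#' @rdname read_roster
#' @param roster Roster tibble.
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(roster[c("node_id", "grade", "classroom", "role")], path)
  invisible(path)
}

#' Read and write cumulative contacts
#'
#' CSV dialect `id_a,id_b,recordings,minutes,encounters`.
#'
#' @param path File path.
#' @return `read_contacts()` a contact tibble (package column names);
#'   the writer returns `path` invisibly.
#' @export
read_contacts <- function(path) {
  read_csv_quiet(path, readr::cols(
    id_a = readr::col_character(),
    id_b = readr::col_character(),
    recordings = readr::col_integer(),
    minutes = readr::col_double(),
    encounters = readr::col_integer()
  )) %>%
    rename(total_recordings = "recordings", cumulative_minutes = "minutes",
           n_encounters = "encounters")
}

#' @rdname read_contacts
#' @param contacts Contact tibble.
#' @export
write_contacts <- function(contacts, path) {
  contacts %>%
    select(
      "id_a", "id_b", recordings = "total_recordings",
      minutes = "cumulative_minutes", encounters = "n_encounters"
    ) %>%
    readr::write_csv(path)
  invisible(path)
}

#' Read a weighted network file
#'
#' Accepts the three formats school contact networks circulate in:
#' edge-list CSV (`id_a,id_b,weight`), Pajek `.net`
#' (`*Vertices` / `*Edges` sections, weight in the third edge column), and
#' GraphML (nodes and edges with a `weight` attribute). Duplicate edges
#' are merged by summing weights, with a warning. Node attributes come
#' from embedded attributes (GraphML) and/or an optional roster.
#'
#' @param path File path.
#' @param format `"edge_csv"`, `"pajek"` or `"graphml"`; guessed from the
#'   extension by default.
#' @param roster Optional roster whose grade/classroom/role attach to the
#'   nodes.
#' @return A `contact_network`.
#' @export
read_network <- function(path, format = c("auto", "edge_csv", "pajek", "graphml"),
                         roster = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "edge_csv", net = "pajek", graphml = "graphml",
      abort(paste("cannot guess network format from extension of", path),
            class = "schoolcontacts_parse_error")
    )
  }
  edges <- switch(format,
    edge_csv = read_csv_quiet(path, readr::cols(
      id_a = readr::col_character(), id_b = readr::col_character(),
      weight = readr::col_double()
    )),
    pajek = read_pajek_edges(path),
    graphml = NULL
  )
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse", edge.attr.comb = list(weight = "sum"))
    if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id)) {
      igraph::V(g)$name <- igraph::V(g)$id
    }
    ends <- igraph::ends(g, igraph::E(g))
    edges <- tibble(
      id_a = ends[, 1L], id_b = ends[, 2L],
      weight = if (is.null(igraph::E(g)$weight)) rep(1, nrow(ends)) else igraph::E(g)$weight
    )
    embedded <- tibble(node_id = igraph::V(g)$name)
    for (a in setdiff(igraph::vertex_attr_names(g), c("name", "id"))) {
      embedded[[a]] <- igraph::vertex_attr(g, a)
    }
  } else {
    embedded <- NULL
  }
  edges <- edges %>%
    mutate(
      a = pmin(.data$id_a, .data$id_b),
      b = pmax(.data$id_a, .data$id_b)
    ) %>%
    select(id_a = "a", id_b = "b", "weight")
  if (any(edges$id_a == edges$id_b)) {
    warn("dropping self-loop edges")
    edges <- edges %>% filter(.data$id_a != .data$id_b)
  }
  if (anyDuplicated(edges[c("id_a", "id_b")])) {
    warn("duplicate edges merged by summing weights")
    edges <- edges %>%
      group_by(.data$id_a, .data$id_b) %>%
      summarise(weight = sum(.data$weight), .groups = "drop")
  }
  nodes <- tibble(node_id = sort(unique(c(edges$id_a, edges$id_b))))
  if (!is.null(embedded)) nodes <- nodes %>% left_join(embedded, by = "node_id")
  if (!is.null(roster)) {
    nodes <- nodes %>%
      left_join(roster %>% select(dplyr::any_of(c("node_id", "grade", "classroom", "role"))),
                by = "node_id")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  new_contact_network(g)
}

read_pajek_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vline <- grep("^\\*vertices", lines, ignore.case = TRUE)
  eline <- grep("^\\*(edges|arcs)", lines, ignore.case = TRUE)
  if (length(vline) != 1L || length(eline) < 1L) {
    abort(paste("not a Pajek network file (missing *Vertices/*Edges):", path),
          class = "schoolcontacts_parse_error")
  }
  nv <- as.integer(strsplit(trimws(lines[vline]), "\\s+")[[1L]][2L])
  vdef <- lines[(vline + 1L):(vline + nv)]
  vparsed <- lapply(seq_along(vdef), function(i) {
    m <- regmatches(vdef[i], regexec('^\\s*(\\d+)\\s+"([^"]*)"', vdef[i]))[[1L]]
    if (length(m) < 3L) {
      abort(sprintf("malformed Pajek vertex line %d: %s", vline + i, vdef[i]),
            class = "schoolcontacts_parse_error")
    }
    m[2:3]
  })
  names_tab <- setNames(
    vapply(vparsed, `[[`, character(1), 2L),
    vapply(vparsed, `[[`, character(1), 1L)
  )
  elines <- lines[(eline[1L] + 1L):length(lines)]
  elines <- elines[nzchar(trimws(elines)) & !grepl("^\\*", elines)]
  parts <- strsplit(trimws(elines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    abort(sprintf("malformed Pajek edge line %d", eline[1L] + bad[1L]),
          class = "schoolcontacts_parse_error")
  }
  tibble(
    id_a = names_tab[vapply(parts, `[[`, character(1), 1L)],
    id_b = names_tab[vapply(parts, `[[`, character(1), 2L)],
    weight = vapply(parts, function(p) {
      if (length(p) >= 3L) as.numeric(p[3L]) else 1
    }, numeric(1))
  )
}

#' Write a contact network
#'
#' `edge_csv` writes `id_a,id_b,weight`; `pajek` writes a `*Vertices` /
#' `*Edges` file (weights in the third column) and, when the nodes carry
#' grade/classroom labels, companion `.clu` partition files aligned to
#' the vertex order (`<path base>_grade.clu`, `<path base>_classroom.clu`);
#' `graphml` embeds node attributes.
#'
#' @param net A `contact_network`.
#' @param path Output path.
#' @param format `"edge_csv"`, `"pajek"` or `"graphml"`; guessed from the
#'   extension by default.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "edge_csv", "pajek", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "edge_csv", net = "pajek", graphml = "graphml",
      abort(paste("cannot guess network format from extension of", path),
            class = "schoolcontacts_parse_error")
    )
  }
  g <- as_igraph(net)
  if (format == "edge_csv") {
    readr::write_csv(tidy(net)[c("id_a", "id_b", "weight")], path)
  } else if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ids <- igraph::V(g)$name
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    lines <- c(
      sprintf("*Vertices %d", length(ids)),
      sprintf('%d "%s"', seq_along(ids), ids),
      "*Edges",
      if (igraph::gsize(g) > 0) {
        sprintf("%d %d %g", ends[, 1L], ends[, 2L], igraph::E(g)$weight)
      }
    )
    writeLines(lines, path)
    base <- sub("\\.net$", "", path)
    for (level in c("grade", "classroom")) {
      lab <- igraph::vertex_attr(g, level)
      if (!is.null(lab) && !anyNA(lab)) {
        writeLines(
          c(sprintf("*Vertices %d", length(ids)),
            as.character(as.integer(factor(lab)))),
          paste0(base, "_", level, ".clu")
        )
      }
    }
  }
  invisible(path)
}

#' Read a Pajek .clu partition
#'
#' @param path `.clu` file path.
#' @param node_ids Node ids in the `.net` vertex order the file is
#'   aligned to.
#' @return Partition tibble `node_id`, `label`.
#' @export
read_clu <- function(path, node_ids) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^\\*vertices", lines, ignore.case = TRUE)
  if (length(header)) lines <- lines[-header]
  if (length(lines) != length(node_ids)) {
    abort(sprintf(".clu has %d entries for %d nodes", length(lines), length(node_ids)),
          class = "schoolcontacts_parse_error")
  }
  tibble(node_id = node_ids, label = trimws(lines))
}
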