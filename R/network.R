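# Weighted student contact network and its summary statistics.
#
# A contact_network is an igraph graph (undirected, no self-loops, edge
# weight = cumulative contact minutes) plus node attributes grade /
# classroom / role, wrapped so the tabular surface stays tibbles.

#' Build the weighted contact network
#'
#' Keeps student-student contacts whose cumulative duration strictly
#' exceeds `threshold_minutes` (contacts of at most the threshold are
#' ignored; the default 5 minutes separates weak from strong school
#' contacts). Nodes are the students with at least one surviving edge —
#' the `n` reported for school networks.
#'
#' @param contacts Contact tibble from [encounters_to_contacts()] (columns
#'   `id_a`, `id_b`, `cumulative_minutes`; other columns kept as edge
#'   attributes).
#' @param roster Roster tibble (`node_id`, `grade`, `classroom`, `role`);
#'   every contact endpoint must appear in it.
#' @param threshold_minutes Strict lower bound on edge weight (default 5).
#' @return A `contact_network` object.
#' @examples
#' contacts <- tibble::tibble(
#'   id_a = c("a", "a"), id_b = c("b", "c"),
#'   cumulative_minutes = c(10, 3)
#' )
#' roster <- tibble::tibble(
#'   node_id = c("a", "b", "c"), grade = "G1",
#'   classroom = "G1C1", role = "student"
#' )
#' net <- build_network(contacts, roster)
#' glance(net)
#' @export
build_network <- function(contacts, roster, threshold_minutes = 5) {
  stopifnot(threshold_minutes >= 0)
  missing_ids <- setdiff(
    unique(c(contacts$id_a, contacts$id_b)), roster$node_id
  )
  if (length(missing_ids)) {
    abort(paste("contacts reference ids absent from roster:",
                paste(head(missing_ids, 5L), collapse = ", ")),
          class = "schoolcontacts_consistency_error")
  }
  students <- roster %>% filter(.data$role == "student")
  kept <- contacts %>%
    filter(
      .data$id_a %in% students$node_id,
      .data$id_b %in% students$node_id,
      .data$cumulative_minutes > threshold_minutes
    )
  nodes <- students %>%
    filter(.data$node_id %in% c(kept$id_a, kept$id_b))
  g <- igraph::graph_from_data_frame(
    d = kept %>%
      mutate(weight = .data$cumulative_minutes) %>%
      select(-"cumulative_minutes"),
    directed = FALSE,
    vertices = nodes
  )
  new_contact_network(g, threshold_minutes)
}

new_contact_network <- function(g, threshold_minutes = NA_real_) {
  stopifnot(igraph::is_igraph(g), !igraph::is_directed(g))
  if (igraph::gsize(g) > 0 && is.null(igraph::E(g)$weight)) {
    igraph::E(g)$weight <- 1
  }
  structure(
    list(graph = g, threshold_minutes = threshold_minutes),
    class = "contact_network"
  )
}

#' Access the underlying igraph graph
#' @param net A `contact_network`.
#' @return The igraph object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  net$graph
}

#' @export
print.contact_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf(
    "<contact_network> %d nodes, %d edges, total weight %.1f min%s\n",
    igraph::gorder(g), igraph::gsize(g), total_weight(x),
    if (is.na(x$threshold_minutes)) "" else
      sprintf(" (> %g min contacts)", x$threshold_minutes)
  ))
  invisible(x)
}

total_weight <- function(net) {
  g <- net$graph
  if (igraph::gsize(g) == 0) 0 else sum(igraph::E(g)$weight)
}

#' Edge table of a contact network
#'
#' @param x A `contact_network`.
#' @param ... Unused.
#' @return Tibble `id_a`, `id_b`, `weight` (cumulative minutes) plus any
#'   further edge attributes.
#' @exportS3Method generics::tidy
tidy.contact_network <- function(x, ...) {
  g <- x$graph
  if (igraph::gsize(g) == 0) {
    return(tibble(id_a = character(0), id_b = character(0), weight = numeric(0)))
  }
  ends <- igraph::ends(g, igraph::E(g))
  extras <- setdiff(igraph::edge_attr_names(g), "weight")
  out <- tibble(
    id_a = pmin(ends[, 1L], ends[, 2L]),
    id_b = pmax(ends[, 1L], ends[, 2L]),
    weight = igraph::E(g)$weight
  )
  for (a in extras) out[[a]] <- igraph::edge_attr(g, a)
  out %>% arrange(.data$id_a, .data$id_b)
}

#' Node table of a contact network
#'
#' @param net A `contact_network`.
#' @return Tibble `node_id` plus stored attributes (grade, classroom,
#'   role, ...).
#' @export
network_nodes <- function(net) {
  g <- as_igraph(net)
  out <- tibble(node_id = igraph::V(g)$name)
  for (a in setdiff(igraph::vertex_attr_names(g), "name")) {
    out[[a]] <- igraph::vertex_attr(g, a)
  }
  out
}

#' Density of the contact network
#'
#' Realized fraction of possible contacts, `2 m / (n (n - 1))`.
#'
#' @param net A `contact_network` with at least 2 nodes.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(net) {
  g <- as_igraph(net)
  n <- igraph::gorder(g)
  if (n < 2L) {
    abort("density is undefined for networks with fewer than 2 nodes",
          class = "schoolcontacts_domain_error")
  }
  2 * igraph::gsize(g) / (n * (n - 1))
}

#' Per-student degree, strength and clustering
#'
#' Degree is the number of distinct contacts a student accumulated;
#' strength the total minutes spent with them; `mean_minutes_per_contact`
#' their ratio (the per-student "average duration per contact").
#' Clustering is the binary local clustering coefficient of the
#' thresholded graph (0 for degree < 2).
#'
#' @param net A `contact_network`.
#' @return Tibble `node_id`, `grade`, `classroom` (when stored), `degree`,
#'   `strength`, `mean_minutes_per_contact`, `clustering`.
#' @export
node_metrics <- function(net) {
  g <- as_igraph(net)
  nodes <- network_nodes(net)
  deg <- unname(igraph::degree(g))
  str <- if (igraph::gsize(g) == 0) rep(0, igraph::gorder(g)) else unname(igraph::strength(g))
  cc <- unname(igraph::transitivity(g, type = "local", isolates = "zero", weights = NA))
  nodes %>%
    mutate(
      degree = as.integer(deg),
      strength = as.numeric(str),
      mean_minutes_per_contact = ifelse(deg > 0, str / deg, NA_real_),
      clustering = ifelse(deg >= 2, cc, 0)
    )
}

#' One-row summary of a contact network
#'
#' The school-level summary: node count `n`, density `delta`, and
#' mean / sd / standard error (sd over sqrt(n)) across students of degree
#' `d`, per-contact duration `s` (minutes) and local clustering `cc`.
#'
#' @param x A `contact_network`.
#' @param ... Unused.
#' @return One-row tibble `n`, `m`, `delta`, `d`, `d_sd`, `d_se`, `s`,
#'   `s_sd`, `s_se`, `cc`, `cc_sd`, `cc_se`, `total_weight`.
#' @exportS3Method generics::glance
glance.contact_network <- function(x, ...) {
  nm <- node_metrics(x)
  n <- nrow(nm)
  se <- function(v) sd(v) / sqrt(length(v))
  tibble(
    n = n,
    m = igraph::gsize(as_igraph(x)),
    delta = if (n >= 2) network_density(x) else NA_real_,
    d = mean(nm$degree), d_sd = sd(nm$degree), d_se = se(nm$degree),
    s = mean(nm$mean_minutes_per_contact),
    s_sd = sd(nm$mean_minutes_per_contact),
    s_se = se(nm$mean_minutes_per_contact),
    cc = mean(nm$clustering), cc_sd = sd(nm$clustering), cc_se = se(nm$clustering),
    total_weight = total_weight(x)
  )
}

neighbor_sets <- function(g) {
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  lapply(adj, function(v) as.integer(v))
}

#' Overlap ratio of one edge
#'
#' For an edge (i, j), `O_ij = n_ij / (k_i - 1 + k_j - 1 - n_ij)` with
#' `n_ij` the number of common contacts; defined as 0 when the
#' denominator vanishes (both endpoints pendant).
#'
#' @param net A `contact_network`.
#' @param i,j Node ids joined by an edge.
#' @return Overlap ratio in `[0, 1]`.
#' @export
overlap <- function(net, i, j) {
  g <- as_igraph(net)
  vi <- match(i, igraph::V(g)$name)
  vj <- match(j, igraph::V(g)$name)
  eid <- if (is.na(vi) || is.na(vj)) 0 else igraph::get_edge_ids(g, c(vi, vj))
  if (eid == 0) {
    abort(sprintf("(%s, %s) is not an edge of the network", i, j),
          class = "schoolcontacts_domain_error")
  }
  ki <- igraph::degree(g, vi)
  kj <- igraph::degree(g, vj)
  nij <- length(intersect(
    as.integer(igraph::neighbors(g, vi)),
    as.integer(igraph::neighbors(g, vj))
  ))
  den <- unname(ki) - 1 + unname(kj) - 1 - nij
  if (den <= 0) 0 else nij / den
}

#' Overlap ratio of every edge
#'
#' @param net A `contact_network`.
#' @return [tidy()] edge table with added `n_common`, `overlap`.
#' @export
edge_overlap <- function(net) {
  g <- as_igraph(net)
  ed <- tidy(net)
  if (nrow(ed) == 0L) {
    return(ed %>% mutate(n_common = integer(0), overlap = numeric(0)))
  }
  nbr <- neighbor_sets(g)
  deg <- unname(igraph::degree(g))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  # recompute in igraph edge order, then join back to the sorted tidy table
  raw <- tibble(
    id_a = pmin(igraph::V(g)$name[ends[, 1L]], igraph::V(g)$name[ends[, 2L]]),
    id_b = pmax(igraph::V(g)$name[ends[, 1L]], igraph::V(g)$name[ends[, 2L]]),
    n_common = vapply(seq_len(nrow(ends)), function(e) {
      length(intersect(nbr[[ends[e, 1L]]], nbr[[ends[e, 2L]]]))
    }, integer(1)),
    den = deg[ends[, 1L]] + deg[ends[, 2L]] - 2 - vapply(
      seq_len(nrow(ends)), function(e) {
        length(intersect(nbr[[ends[e, 1L]]], nbr[[ends[e, 2L]]]))
      }, integer(1))
  ) %>%
    mutate(overlap = ifelse(.data$den <= 0, 0, .data$n_common / .data$den)) %>%
    select(-"den")
  ed %>% left_join(raw, by = c("id_a", "id_b"))
}

#' Average overlap ratio by contact-duration bin
#'
#' Bins the edges by weight (cumulative minutes) and averages the overlap
#' ratio within each bin — long-duration contacts sit inside clique-like
#' classroom groups, so overlap typically grows with duration.
#'
#' @param net A `contact_network`.
#' @param weight_bins Increasing numeric bin edges covering the observed
#'   weights; defaults to ten equal-width bins.
#' @return Tibble `bin_low`, `bin_high`, `bin_mid`, `n_edges`,
#'   `mean_overlap` (empty bins flagged by `n_edges = 0` and `NA` mean),
#'   class `overlap_curve`.
#' @export
overlap_vs_weight_curve <- function(net, weight_bins = NULL) {
  eo <- edge_overlap(net)
  if (is.null(weight_bins)) {
    rng <- range(eo$weight, 0)
    weight_bins <- seq(rng[1L], max(rng[2L], rng[1L] + 1e-9), length.out = 11L)
  }
  weight_bins <- sort(unique(weight_bins))
  if (nrow(eo) && (min(eo$weight) < weight_bins[1L] ||
                   max(eo$weight) > weight_bins[length(weight_bins)])) {
    abort("weight_bins must cover the observed edge weights",
          class = "schoolcontacts_domain_error")
  }
  idx <- if (nrow(eo)) {
    pmin(findInterval(eo$weight, weight_bins, rightmost.closed = TRUE),
         length(weight_bins) - 1L)
  } else integer(0)
  out <- tibble(
    bin = seq_len(length(weight_bins) - 1L),
    bin_low = weight_bins[-length(weight_bins)],
    bin_high = weight_bins[-1L]
  ) %>%
    mutate(bin_mid = (.data$bin_low + .data$bin_high) / 2)
  agg <- tibble(bin = idx, overlap = eo$overlap) %>%
    group_by(.data$bin) %>%
    summarise(n_edges = dplyr::n(), mean_overlap = mean(.data$overlap), .groups = "drop")
  out <- out %>%
    left_join(agg, by = "bin") %>%
    mutate(n_edges = ifelse(is.na(.data$n_edges), 0L, .data$n_edges)) %>%
    select(-"bin")
  class(out) <- c("overlap_curve", class(out))
  out
}

#' Grade or classroom contact matrix
#'
#' Mixing matrix normalised per pair of students: off-diagonal cells are
#' edges between groups g and h divided by `n_g * n_h`; diagonal cells are
#' within-group edges divided by `n_g (n_g - 1) / 2`.
#'
#' @param net A `contact_network` whose nodes carry the grouping label.
#' @param grouping `"grade"` or `"classroom"`.
#' @return Symmetric matrix with group labels as dimnames.
#' @export
contact_matrix <- function(net, grouping = c("grade", "classroom")) {
  grouping <- match.arg(grouping)
  g <- as_igraph(net)
  lab <- igraph::vertex_attr(g, grouping)
  if (is.null(lab) || anyNA(lab)) {
    abort(sprintf("every node needs a non-missing %s label", grouping),
          class = "schoolcontacts_consistency_error")
  }
  groups <- sort(unique(lab))
  sizes <- table(factor(lab, levels = groups))
  M <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  if (igraph::gsize(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    ga <- lab[ends[, 1L]]
    gb <- lab[ends[, 2L]]
    for (e in seq_len(nrow(ends))) {
      M[ga[e], gb[e]] <- M[ga[e], gb[e]] + 1
      if (ga[e] != gb[e]) M[gb[e], ga[e]] <- M[gb[e], ga[e]] + 1
    }
  }
  for (a in groups) {
    for (b in groups) {
      denom <- if (a == b) {
        max(sizes[[a]] * (sizes[[a]] - 1) / 2, 1)
      } else {
        sizes[[a]] * sizes[[b]]
      }
      M[a, b] <- M[a, b] / denom
    }
  }
  M
}

#' Average degree in consecutive time bins
#'
#' For each bin (default 3 minutes) and each student, counts distinct
#' partners sharing at least one pair-tick in the bin, then averages over
#' all tagged students — a direct view of schedule-driven mixing (break
#' and lunch bins spike where students can roam).
#'
#' @param encounters Encounter tibble from [pair_ticks_to_encounters()].
#' @param roster Optional roster; its students define the averaging
#'   denominator (otherwise every node seen in `encounters`).
#' @param bin_seconds Bin width, a positive multiple of `tick_seconds`
#'   (default 180).
#' @param tick_seconds Beacon interval in seconds.
#' @param start_tick First tick of the deployment; defaults to the
#'   earliest encounter tick.
#' @return Tibble `bin`, `start_s`, `mean_degree`, class
#'   `degree_timecourse`. Bins with no observations average 0.
#' @export
time_binned_degree <- function(encounters, roster = NULL, bin_seconds = 180,
                               tick_seconds = 20, start_tick = NULL) {
  if (bin_seconds <= 0 || bin_seconds %% tick_seconds != 0) {
    abort("bin_seconds must be a positive multiple of tick_seconds",
          class = "schoolcontacts_domain_error")
  }
  ticks_per_bin <- bin_seconds %/% tick_seconds
  students <- if (!is.null(roster)) {
    roster$node_id[roster$role == "student"]
  } else {
    sort(unique(c(encounters$id_a, encounters$id_b)))
  }
  n_students <- length(students)
  if (nrow(encounters) == 0L || n_students == 0L) {
    out <- tibble(bin = integer(0), start_s = numeric(0), mean_degree = numeric(0))
    class(out) <- c("degree_timecourse", class(out))
    return(out)
  }
  if (is.null(start_tick)) start_tick <- min(encounters$start_tick)
  ticks <- encounters %>%
    mutate(.row = row_number()) %>%
    tidyr::uncount(.data$n_ticks, .id = "off") %>%
    mutate(
      tick = .data$start_tick + .data$off - 1L,
      bin = (.data$tick - .env$start_tick) %/% ticks_per_bin
    ) %>%
    filter(.data$id_a %in% students, .data$id_b %in% students)
  per_student <- bind_rows(
    ticks %>% select(node = "id_a", partner = "id_b", "bin"),
    ticks %>% select(node = "id_b", partner = "id_a", "bin")
  ) %>%
    distinct(.data$node, .data$partner, .data$bin) %>%
    count(.data$bin, .data$node, name = "degree")
  out <- per_student %>%
    group_by(.data$bin) %>%
    summarise(mean_degree = sum(.data$degree) / n_students, .groups = "drop") %>%
    tidyr::complete(bin = seq(0L, max(.data$bin)), fill = list(mean_degree = 0)) %>%
    mutate(start_s = (.env$start_tick + .data$bin * ticks_per_bin) * tick_seconds) %>%
    select("bin", "start_s", "mean_degree")
  class(out) <- c("degree_timecourse", class(out))
  out
}
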