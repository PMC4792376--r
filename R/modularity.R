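# Weighted modularity of a contact network against an external partition
# (grades or classrooms), and its behaviour under a threshold sweep.

#' Extract a grade or classroom partition from node attributes
#'
#' Partitions are always externally given (school structure), never
#' inferred from the network.
#'
#' @param x A `contact_network` or a roster tibble.
#' @param level `"grade"` or `"classroom"`.
#' @return Tibble `node_id`, `label` with attribute `level`.
#' @export
network_partition <- function(x, level = c("grade", "classroom")) {
  level <- match.arg(level)
  nodes <- if (inherits(x, "contact_network")) {
    network_nodes(x)
  } else {
    x %>% filter(.data$role == "student") %>% rename(node_id = "node_id")
  }
  if (!level %in% names(nodes) || anyNA(nodes[[level]])) {
    abort(sprintf("nodes lack a complete %s label", level),
          class = "schoolcontacts_consistency_error")
  }
  out <- tibble(node_id = nodes$node_id, label = as.character(nodes[[level]]))
  attr(out, "level") <- level
  out
}

as_partition_vector <- function(partition, node_ids) {
  if (is.data.frame(partition)) {
    lab <- setNames(as.character(partition$label), partition$node_id)
  } else if (!is.null(names(partition))) {
    lab <- setNames(as.character(partition), names(partition))
  } else {
    abort("partition must be a node_id/label table or a named vector",
          class = "schoolcontacts_domain_error")
  }
  miss <- setdiff(node_ids, names(lab))
  if (length(miss)) {
    abort(paste("partition misses nodes:", paste(head(miss, 5L), collapse = ", ")),
          class = "schoolcontacts_consistency_error")
  }
  unname(lab[node_ids])
}

#' Modularity of a network under a given partition
#'
#' Weighted Newman-Girvan modularity:
#' `Q = (1 / 2W) * sum_ij (w_ij - s_i s_j / 2W) * [c_i == c_j]`, with
#' `s_i` the node strengths and `W` the total edge weight — the excess of
#' within-community weight over the expectation of a strength-preserving
#' random rewiring. With `weighted = FALSE` all surviving edges count 1
#' and the classic unweighted form results.
#'
#' @param net A `contact_network` with at least one edge.
#' @param partition Tibble `node_id`/`label` (see [network_partition()])
#'   or a named label vector covering every node.
#' @param weighted Use edge weights (default) or the binarized graph.
#' @return Modularity Q in `[-1/2, 1)`.
#' @examples
#' # two disconnected triangles split by triangle: strong communities
#' contacts <- tibble::tibble(
#'   id_a = c("a", "a", "b", "d", "d", "e"),
#'   id_b = c("b", "c", "c", "e", "f", "f"),
#'   cumulative_minutes = 10
#' )
#' roster <- tibble::tibble(
#'   node_id = letters[1:6], grade = rep(c("G1", "G2"), each = 3),
#'   classroom = rep(c("G1C1", "G2C1"), each = 3), role = "student"
#' )
#' net <- build_network(contacts, roster, threshold_minutes = 0)
#' modularity_score(net, network_partition(net, "grade"))
#' @export
modularity_score <- function(net, partition, weighted = TRUE) {
  g <- as_igraph(net)
  if (igraph::gsize(g) == 0) {
    abort("modularity is undefined on a network without edges",
          class = "schoolcontacts_domain_error")
  }
  labels <- as_partition_vector(partition, igraph::V(g)$name)
  w <- if (weighted) igraph::E(g)$weight else rep(1, igraph::gsize(g))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  W <- sum(w)
  s <- rep(0, igraph::gorder(g))
  for (e in seq_along(w)) {
    s[ends[e, 1L]] <- s[ends[e, 1L]] + w[e]
    s[ends[e, 2L]] <- s[ends[e, 2L]] + w[e]
  }
  same <- labels[ends[, 1L]] == labels[ends[, 2L]]
  within_w <- sum(w[same])
  # sum over communities of (strength share)^2
  comm_strength <- tapply(s, labels, sum)
  expected <- sum((comm_strength / (2 * W))^2)
  within_w / W - expected
}

#' Modularity across a sweep of contact-duration thresholds
#'
#' Rebuilds the network for thresholds `t = 0, step, 2 step, ...`
#' recordings (keeping contacts with `total_recordings > t`; 10
#' recordings = 3 minutes 20 seconds at the 20-second tick) and evaluates
#' modularity against the partition restricted to the surviving nodes.
#' Deleting weak inter-group contacts first raises Q; past the point
#' where within-group contacts start to go, Q decays and eventually the
#' score is unreliable (too few edges or a single surviving community),
#' which the `reliable` flag records.
#'
#' @param contacts Contact tibble (`total_recordings` column required).
#' @param roster Roster tibble.
#' @param level `"grade"` or `"classroom"`.
#' @param step_recordings Threshold increment in recordings (default 10).
#' @param max_recordings Last threshold; defaults to the largest contact,
#'   so the sweep always ends at an empty network's doorstep.
#' @param weighted Weighted or binary modularity at each point.
#' @param tick_seconds Beacon interval (minutes conversion only).
#' @return Tibble `threshold_recordings`, `threshold_minutes`, `q`,
#'   `n_nodes`, `n_edges`, `n_communities`, `reliable`; class
#'   `modularity_curve`.
#' @export
modularity_vs_threshold <- function(contacts, roster, level = c("grade", "classroom"),
                                    step_recordings = 10, max_recordings = NULL,
                                    weighted = TRUE, tick_seconds = 20) {
  level <- match.arg(level)
  stopifnot(step_recordings >= 1)
  if (is.null(max_recordings)) {
    max_recordings <- if (nrow(contacts)) max(contacts$total_recordings) else 0
  }
  thresholds <- seq(0, max_recordings, by = step_recordings)
  students <- roster %>% filter(.data$role == "student")
  rows <- purrr::map(thresholds, function(t) {
    kept <- contacts %>% filter(.data$total_recordings > t)
    net <- build_network(kept, roster, threshold_minutes = 0)
    n_nodes <- igraph::gorder(as_igraph(net))
    n_edges <- igraph::gsize(as_igraph(net))
    if (n_edges == 0L) {
      return(tibble(
        threshold_recordings = t, q = NA_real_, n_nodes = n_nodes,
        n_edges = n_edges, n_communities = 0L, reliable = FALSE
      ))
    }
    part <- network_partition(net, level)
    q <- modularity_score(net, part, weighted = weighted)
    k <- dplyr::n_distinct(part$label)
    tibble(
      threshold_recordings = t, q = q, n_nodes = n_nodes,
      n_edges = n_edges, n_communities = k, reliable = k >= 2L
    )
  })
  out <- bind_rows(rows) %>%
    mutate(threshold_minutes = .data$threshold_recordings * tick_seconds / 60) %>%
    select("threshold_recordings", "threshold_minutes", "q", "n_nodes",
           "n_edges", "n_communities", "reliable")
  attr(out, "level") <- level
  class(out) <- c("modularity_curve", class(out))
  out
}
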