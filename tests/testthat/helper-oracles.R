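# Brute-force oracles and in-code fixtures. The oracles enumerate the
# defining sums directly and stay independent of the package internals.

toy_roster <- function(labels, classroom = NULL) {
  tibble::tibble(
    node_id = names(labels),
    grade = as.character(labels),
    classroom = if (is.null(classroom)) {
      as.character(labels)
    } else {
      as.character(classroom[names(labels)])
    },
    role = "student"
  )
}

# edges: tibble id_a, id_b, weight -> contact_network (threshold 0 keeps all)
toy_network <- function(edges, labels = NULL, threshold = 0) {
  ids <- sort(unique(c(edges$id_a, edges$id_b)))
  if (is.null(labels)) labels <- stats::setNames(rep("G1", length(ids)), ids)
  contacts <- edges
  contacts$cumulative_minutes <- contacts$weight
  build_network(contacts, toy_roster(labels), threshold_minutes = threshold)
}

adj_matrix <- function(edges, weighted = TRUE) {
  ids <- sort(unique(c(edges$id_a, edges$id_b)))
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    w <- if (weighted) edges$weight[r] else 1
    A[edges$id_a[r], edges$id_b[r]] <- A[edges$id_a[r], edges$id_b[r]] + w
    A[edges$id_b[r], edges$id_a[r]] <- A[edges$id_b[r], edges$id_a[r]] + w
  }
  A
}

# direct evaluation of Q = (1/2W) sum_ij (A_ij - s_i s_j / 2W) [c_i == c_j]
brute_modularity <- function(edges, labels, weighted = TRUE) {
  A <- adj_matrix(edges, weighted)
  ids <- rownames(A)
  two_w <- sum(A)
  s <- rowSums(A)
  q <- 0
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (labels[[ids[i]]] == labels[[ids[j]]]) {
        q <- q + A[i, j] - s[i] * s[j] / two_w
      }
    }
  }
  unname(q / two_w)
}

brute_local_cc <- function(edges) {
  A <- (adj_matrix(edges) > 0) * 1
  ids <- rownames(A)
  vapply(ids, function(i) {
    nb <- ids[A[i, ] > 0]
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

brute_overlap <- function(edges, i, j) {
  A <- (adj_matrix(edges) > 0) * 1
  ni <- rownames(A)[A[i, ] > 0]
  nj <- rownames(A)[A[j, ] > 0]
  nij <- length(intersect(ni, nj))
  den <- length(ni) - 1 + length(nj) - 1 - nij
  if (den <= 0) 0 else nij / den
}

# Erdos-Renyi edge table with random weights
rand_edges <- function(n_nodes, p = 0.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  prs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(prs)) < p
  if (!any(keep)) keep[sample.int(nrow(prs), 1)] <- TRUE
  tibble::tibble(
    id_a = prs[keep, 1], id_b = prs[keep, 2],
    weight = round(stats::runif(sum(keep), 0.5, 10), 2)
  )
}

# brute-force ingest: contacts recomputed by direct enumeration of the
# distinct (pair, tick) set
brute_contacts <- function(records, rssi_threshold, tick_seconds = 20) {
  kept <- records[records$rssi >= rssi_threshold, ]
  if (nrow(kept) == 0) {
    return(tibble::tibble(id_a = character(0), id_b = character(0),
                          total_recordings = integer(0)))
  }
  key <- unique(data.frame(
    id_a = pmin(kept$receiver_id, kept$sender_id),
    id_b = pmax(kept$receiver_id, kept$sender_id),
    tick = floor(kept$timestamp / tick_seconds)
  ))
  agg <- stats::aggregate(tick ~ id_a + id_b, data = key, FUN = length)
  names(agg)[3] <- "total_recordings"
  tibble::as_tibble(agg[order(agg$id_a, agg$id_b), ])
}
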