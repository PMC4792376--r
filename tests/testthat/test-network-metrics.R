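test_that("the contact-duration threshold is strict", {
  contacts <- tibble::tibble(
    id_a = c("a", "b", "c"), id_b = c("b", "c", "d"),
    cumulative_minutes = c(4.9, 5.0, 5.1)
  )
  roster <- toy_roster(stats::setNames(rep("G1", 4), c("a", "b", "c", "d")))
  net <- build_network(contacts, roster, threshold_minutes = 5)
  expect_equal(nrow(tidy(net)), 1L)
  expect_equal(tidy(net)$weight, 5.1)
  expect_equal(igraph::gorder(as_igraph(net)), 2L)  # nodes need a surviving edge
  all_net <- build_network(contacts, roster, threshold_minutes = 0)
  expect_equal(nrow(tidy(all_net)), 3L)
  expect_error(build_network(dplyr::mutate(contacts, id_a = c("zz", "b", "c")), roster),
               class = "schoolcontacts_consistency_error")
})

test_that("density matches its defining ratio", {
  k4 <- tibble::tibble(
    id_a = c("a", "a", "a", "b", "b", "c"),
    id_b = c("b", "c", "d", "c", "d", "d"), weight = 1
  )
  expect_equal(network_density(toy_network(k4)), 1)
  e <- rand_edges(7, 0.4, seed = 2)
  net <- toy_network(e)
  n <- igraph::gorder(as_igraph(net))
  expect_equal(network_density(net), 2 * nrow(e) / (n * (n - 1)))
  single <- toy_network(tibble::tibble(id_a = "a", id_b = "b", weight = 1))
  expect_equal(network_density(single), 1)
})

test_that("degree, strength and per-contact duration for a star", {
  star <- tibble::tibble(id_a = "hub", id_b = c("x", "y", "z"),
                         weight = c(10, 20, 30))
  nm <- node_metrics(toy_network(star))
  hub <- nm[nm$node_id == "hub", ]
  expect_equal(hub$degree, 3L)
  expect_equal(hub$strength, 60)
  expect_equal(hub$mean_minutes_per_contact, 20)
  expect_equal(hub$clustering, 0)
})

test_that("clustering is 1 on a triangle and 0 on a star", {
  tri <- tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"), weight = 1)
  expect_equal(node_metrics(toy_network(tri))$clustering, rep(1, 3))
  star <- tibble::tibble(id_a = "h", id_b = c("x", "y", "z"), weight = 1)
  expect_equal(node_metrics(toy_network(star))$clustering, rep(0, 4))
})

test_that("overlap ratio follows its definition, including degenerate edges", {
  tri <- tibble::tibble(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"), weight = 1)
  expect_equal(overlap(toy_network(tri), "a", "b"), 1)
  pend <- tibble::tibble(id_a = "a", id_b = "b", weight = 1)
  expect_equal(overlap(toy_network(pend), "a", "b"), 0)
  expect_error(overlap(toy_network(tri), "a", "zz"), class = "schoolcontacts_domain_error")
  # two 4-cliques sharing the edge (i,j), plus one extra private
  # neighbour each: k_i = k_j = 6, n_ij = 4 -> 4 / (5 + 5 - 4) = 2/3
  cl <- tibble::tibble(
    id_a = c("i", "i", "i", "j", "j", "a", "i", "i", "j", "j", "c", "i", "j"),
    id_b = c("j", "a", "b", "a", "b", "b", "c", "d", "c", "d", "d", "p", "q"),
    weight = 1
  )
  net <- toy_network(cl)
  expect_equal(overlap(net, "i", "j"), brute_overlap(cl, "i", "j"))
  expect_equal(overlap(net, "i", "j"), 2 / 3)
})

test_that("metrics agree with brute force on random small graphs", {
  for (seed in 1:6) {
    e <- rand_edges(sample(4:8, 1), 0.5, seed = seed)
    net <- toy_network(e)
    nm <- node_metrics(net)
    # bounds and sum rules
    expect_true(network_density(net) >= 0 && network_density(net) <= 1)
    expect_true(all(nm$clustering >= 0 & nm$clustering <= 1))
    expect_equal(sum(nm$degree), 2 * nrow(e))
    expect_equal(sum(nm$strength), 2 * sum(e$weight))
    # clustering equals enumeration
    cc <- brute_local_cc(e)
    expect_equal(stats::setNames(nm$clustering, nm$node_id), cc[nm$node_id])
    # overlap equals enumeration on every edge
    eo <- edge_overlap(net)
    for (r in seq_len(nrow(eo))) {
      expect_equal(eo$overlap[r], brute_overlap(e, eo$id_a[r], eo$id_b[r]))
    }
  }
})

test_that("overlap-weight curve reduces to the mean on a single bin", {
  e <- rand_edges(6, 0.6, seed = 4)
  net <- toy_network(e)
  cv <- overlap_vs_weight_curve(net, weight_bins = c(0, 11))
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$mean_overlap, mean(edge_overlap(net)$overlap))
  expect_equal(cv$n_edges, nrow(e))
})

test_that("overlap grows with contact duration in a cohort school", {
  sim <- elem_small()
  net <- build_network(sim$ing$contacts, sim$roster, 5)
  cv <- overlap_vs_weight_curve(net)
  filled <- cv[cv$n_edges > 0, ]
  top <- filled$mean_overlap[filled$bin_mid > stats::median(cv$bin_mid)]
  bottom <- filled$mean_overlap[filled$bin_mid <= stats::median(cv$bin_mid)]
  expect_gt(mean(top), mean(bottom))
  expect_gt(stats::cor(filled$bin_mid, filled$mean_overlap, method = "spearman"), 0)
})

test_that("contact matrices normalise by pairs and detect block structure", {
  labels <- stats::setNames(c("G1", "G1", "G1", "G2", "G2", "G2"),
                            c("a", "b", "c", "d", "e", "f"))
  within <- tibble::tibble(id_a = c("a", "a", "b", "d", "d", "e"),
                           id_b = c("b", "c", "c", "e", "f", "f"), weight = 1)
  M <- contact_matrix(toy_network(within, labels), "grade")
  expect_equal(M, t(M))
  expect_equal(diag(M), c(G1 = 1, G2 = 1))
  expect_equal(M["G1", "G2"], 0)
  # unlabeled node errors
  nolab <- stats::setNames(c("G1", NA, "G1", "G2", "G2", "G2"), names(labels))
  expect_error(contact_matrix(toy_network(within, nolab), "grade"),
               class = "schoolcontacts_consistency_error")
  # total reconstruction: cells x pair counts give back the edge count
  e <- rand_edges(8, 0.5, seed = 10)
  lab <- stats::setNames(rep(c("G1", "G2"), 4), sprintf("n%02d", 1:8))
  net <- toy_network(e, lab)
  M2 <- contact_matrix(net, "grade")
  sizes <- table(network_nodes(net)$grade)
  total <- 0
  for (a in rownames(M2)) for (b in colnames(M2)) {
    if (a < b) total <- total + M2[a, b] * sizes[[a]] * sizes[[b]]
    if (a == b) total <- total + M2[a, a] * sizes[[a]] * (sizes[[a]] - 1) / 2
  }
  expect_equal(unname(total), nrow(e))
})

test_that("cohort schools concentrate contacts on the diagonal", {
  sim <- elem_small()
  net <- build_network(sim$ing$contacts, sim$roster, 5)
  M <- contact_matrix(net, "grade")
  for (i in seq_len(nrow(M))) {
    expect_true(all(M[i, i] > M[i, -i]))
  }
})

test_that("time-binned degree counts distinct partners per bin", {
  # one pair in contact every tick -> degree 1 in every bin for both
  enc <- tibble::tibble(id_a = "a", id_b = "b", start_tick = 0L, n_ticks = 27L)
  tb <- time_binned_degree(enc, bin_seconds = 180, tick_seconds = 20)
  expect_equal(tb$mean_degree, rep(1, 3))
  # a silent middle bin averages zero
  enc2 <- tibble::tibble(id_a = "a", id_b = "b", start_tick = c(0L, 20L),
                         n_ticks = c(2L, 2L))
  tb2 <- time_binned_degree(enc2, bin_seconds = 180, tick_seconds = 20)
  expect_equal(tb2$mean_degree[2], 0)
  expect_error(time_binned_degree(enc, bin_seconds = 50, tick_seconds = 20),
               class = "schoolcontacts_domain_error")
})

test_that("degree peaks during breaks in an individualized school", {
  sim <- hs_small()
  tb <- time_binned_degree(sim$ing$encounters, sim$roster,
                           tick_seconds = sim$cfg$tick_seconds)
  kinds <- vapply(tb$start_s, function(t) period_kind_of(sim$cfg, t), character(1))
  expect_gt(mean(tb$mean_degree[kinds == "break"], na.rm = TRUE),
            mean(tb$mean_degree[kinds == "class"], na.rm = TRUE))
})

test_that("network summary reports node-level means with standard errors", {
  sim <- elem_small()
  net <- build_network(sim$ing$contacts, sim$roster, 5)
  gl <- glance(net)
  nm <- node_metrics(net)
  expect_equal(gl$n, nrow(nm))
  expect_equal(gl$d, mean(nm$degree))
  expect_equal(gl$d_se, stats::sd(nm$degree) / sqrt(nrow(nm)))
  expect_equal(gl$s, mean(nm$mean_minutes_per_contact))
  expect_true(gl$cc >= 0 && gl$cc <= 1)
})
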