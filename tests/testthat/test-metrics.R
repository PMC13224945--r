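test_that("degrees count self-loops twice and the mean follows 2|E|/|V|", {
  net <- toy_network(c("A", "B"), c("B", "C"))
  deg <- degree_stats(net)
  expect_equal(deg$total_degree, c(1, 2, 1))
  expect_equal(attr(deg, "mean_total_degree"), 1.33)

  loop <- toy_network(c("A", "A"), c("B", "A"))
  deg2 <- degree_stats(loop)
  expect_equal(deg2$total_degree[deg2$title == "A"], 3) # loop counts in + out
  expect_equal(attr(deg2, "mean_total_degree"), 2)
})

test_that("betweenness on hand-checkable graphs", {
  chain <- toy_network(c("A", "B"), c("B", "C"))
  expect_equal(betweenness_centrality(chain),
               c(A = 0, B = 1, C = 0))
  diamond <- toy_network(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  expect_equal(betweenness_centrality(diamond),
               c(A = 0, B = 0.5, C = 0.5, D = 0))
  # pair-normalised mode divides by (N-1)(N-2)
  expect_equal(betweenness_centrality(chain, mode = "pair_normalised"),
               c(A = 0, B = 0.5, C = 0))
})

test_that("stress counts whole shortest paths through a node", {
  chain <- toy_network(c("A", "B"), c("B", "C"))
  expect_equal(stress_centrality(chain), c(A = 0, B = 1, C = 0))
  diamond <- toy_network(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  expect_equal(stress_centrality(diamond), c(A = 0, B = 1, C = 1, D = 0))
})

test_that("out-eccentricity is the distance to the farthest reachable node", {
  n <- 8
  chain <- toy_network(sprintf("N%d", 1:(n - 1)), sprintf("N%d", 2:n))
  ecc <- out_eccentricity(chain)
  expect_equal(unname(ecc[sprintf("N%d", 1:n)]), seq(n - 1, 0))
  # sink and disconnected nodes score 0; unreachable nodes don't enter the max
  disc <- toy_network(c("A", "C"), c("B", "D"))
  expect_equal(out_eccentricity(disc), c(A = 1, B = 0, C = 1, D = 0))
})

test_that("flow classification is a total partition", {
  expect_equal(classify_flow(c(3, 1, 2), c(1, 3, 2)),
               c("convergent", "divergent", "balanced"))
  for (seed in 1:10) {
    net <- random_network(seed)
    m <- network_metrics(net)
    expect_equal(sum(m$flow_class == "convergent") +
                   sum(m$flow_class == "divergent") +
                   sum(m$flow_class == "balanced"), nrow(m))
  }
})

test_that("simple path occurrence on hand-checkable graphs", {
  chain <- toy_network(c("M", "K1", "K2"), c("K1", "K2", "A"),
                       roles = c(M = "MIE", A = "AO"))
  spo <- simple_path_occurrence(chain)
  expect_equal(spo$occurrence, c(A = 0, K1 = 1, K2 = 1, M = 0))
  expect_equal(spo$path_length_histogram, c("3" = 1L))
  expect_equal(spo$n_paths, 1)

  diamond <- toy_network(c("M", "M", "B", "C"), c("B", "C", "A", "A"),
                         roles = c(M = "MIE", A = "AO"))
  spo2 <- simple_path_occurrence(diamond)
  expect_equal(spo2$occurrence[c("B", "C")], c(B = 1, C = 1))
  expect_equal(spo2$path_length_histogram, c("2" = 2L))
})

test_that("path enumeration respects the cap", {
  net <- toy_network(c("M", "M", "B", "C"), c("B", "C", "A", "A"),
                     roles = c(M = "MIE", A = "AO"))
  expect_error(simple_path_occurrence(net, cap = 1), "cap")
})

test_that("betweenness and eccentricity agree with igraph on random graphs", {
  for (seed in 1:25) {
    net <- subnetwork(random_network(seed), drop_self_loops = TRUE)
    g <- as_igraph(net)
    expect_equal(
      unname(betweenness_centrality(net)[igraph::V(g)$name]),
      unname(igraph::betweenness(g, directed = TRUE)),
      tolerance = 1e-9
    )
    expect_equal(
      unname(out_eccentricity(net)[igraph::V(g)$name]),
      unname(igraph::eccentricity(g, mode = "out")),
      tolerance = 1e-9
    )
  }
})

test_that("combined importance normalises min-max, sums, and ranks with title ties", {
  m <- tibble::tibble(
    title = c("a", "b", "c"),
    total_degree = c(1, 5, 3),
    betweenness = c(0, 4, 2),
    stress = c(2, 10, 6)
  )
  out <- combined_importance(m)
  expect_equal(out$combined_score, c(0, 3, 1.5))
  expect_equal(out$rank, c(3, 1, 2))
  # a zero-range component contributes 0 to everyone
  m2 <- m
  m2$stress <- 7
  out2 <- combined_importance(m2)
  expect_equal(out2$combined_score, c(0, 2, 1))
  # affine rescaling of one component leaves scores unchanged
  m3 <- m
  m3$betweenness <- 100 * m3$betweenness + 12
  expect_equal(combined_importance(m3)$combined_score, out$combined_score)
  expect_error(combined_importance(m, components = "nope"), "Unknown")
})

test_that("metric table is internally consistent on random networks", {
  for (seed in c(2, 13, 40)) {
    net <- random_network(seed)
    m <- network_metrics(net)
    expect_equal(m$total_degree, m$in_degree + m$out_degree)
    expect_equal(attr(m, "mean_total_degree"),
                 round_half_up(2 * nrow(net$edges) / nrow(net$nodes), 2))
    # total internal slots equal sum over paths of (length - 1)
    hist <- attr(m, "path_length_histogram")
    expect_equal(sum(m$simple_path_occurrence),
                 sum((as.integer(names(hist)) - 1L) * hist))
  }
})

test_that("occurrence is monotone non-increasing under edge deletion", {
  for (seed in c(4, 17)) {
    net <- random_network(seed, n_range = 5:8, p = 0.3)
    if (nrow(net$edges) < 2) next
    before <- simple_path_occurrence(net)$occurrence
    drop <- withr::with_seed(seed, sample(nrow(net$edges), 1))
    keep <- rep(TRUE, nrow(net$edges))
    keep[drop] <- FALSE
    after <- simple_path_occurrence(subnetwork(net, edge_keep = keep))$occurrence
    expect_true(all(after <= before))
  }
})

test_that("adjacent-only mode restricts every metric to the adjacent subgraph", {
  net <- toy_network(c("M", "K1", "M"), c("K1", "A", "A"),
                     roles = c(M = "MIE", A = "AO"),
                     adjacency = c("adjacent", "adjacent", "non-adjacent"))
  m_all <- network_metrics(net)
  m_adj <- network_metrics(net, include_non_adjacent = FALSE)
  expect_equal(m_all$total_degree[m_all$title == "M"], 2)
  expect_equal(m_adj$total_degree[m_adj$title == "M"], 1)
  expect_equal(attr(m_all, "n_simple_paths"), 2)
  expect_equal(attr(m_adj, "n_simple_paths"), 1)
})
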