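test_that("an empty rule set yields an empty network", {
  co <- toy_cohort6()
  rules <- mine_pairwise(co, "all6", mining_config(std_lift_threshold = 1))
  g <- build_network(rules, co)
  expect_equal(igraph::vcount(g), 0)
  expect_equal(igraph::ecount(g), 0)
})

test_that("rule directions collapse to single edges with co-occurrence weights", {
  # 3 of 6 subjects have both a and b
  co <- toy_cohort6()
  rules <- mine_pairwise(co, "all6", mining_config(std_lift_threshold = 0))
  expect_true(all(c("a b", "b a") %in%
                    paste(rules$antecedent, rules$consequent)))
  g <- build_network(rules, co)
  expect_equal(igraph::ecount(g), 3)  # one edge per unordered pair
  eid <- igraph::get_edge_ids(g, c("a", "b"))
  expect_equal(igraph::E(g)$weight[eid],
               sum(co$a == 1 & co$b == 1))
  expect_equal(igraph::E(g)$weight[eid], 2)
  # node prevalence conserved from the cohort
  expect_equal(igraph::V(g)$prevalence[igraph::V(g)$name == "a"],
               weighted_prevalence(co, "a", "all6"))
  # stratum mismatch rejected
  co2 <- co
  co2$stratum <- "other"
  attr(co2, "condition_names") <- condition_names(co)
  expect_error(build_network(rules, co2), "stratum")
})

two_triangles <- function() {
  igraph::graph_from_data_frame(
    data.frame(from = c("a", "a", "b", "d", "d", "e"),
               to = c("b", "c", "c", "e", "f", "f"),
               weight = 1),
    directed = FALSE)
}

test_that("fast-greedy recovers the optimum on two disjoint triangles", {
  g <- two_triangles()
  cp <- detect_communities(g)
  expect_equal(length(unique(cp$membership)), 2)
  expect_equal(cp$modularity, 0.5)
  # same groups as exhaustive search over all 4140-ish partitions
  best <- oracle_best_partition(graph_adjacency(g))
  expect_equal(best$q, 0.5)
  expect_equal(unname(cp$membership[c("a", "b", "c")]),
               rep(cp$membership[["a"]], 3))
  expect_equal(unname(cp$membership[c("d", "e", "f")]),
               rep(cp$membership[["d"]], 3))
})

test_that("greedy modularity matches exhaustive search on small graphs", {
  set.seed(77)
  worst_gap <- 0
  for (i in 1:6) {
    n <- sample(5:8, 1)
    adj <- matrix(0, n, n)
    repeat {  # connected-ish random weighted graph
      upper <- which(upper.tri(adj))
      on <- upper[runif(length(upper)) < 0.45]
      if (length(on) >= n - 1) break
    }
    adj[on] <- sample(1:5, length(on), replace = TRUE)
    adj <- adj + t(adj)
    rownames(adj) <- colnames(adj) <- letters[1:n]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::ecount(g) == 0) next
    cp <- detect_communities(g)
    best <- oracle_best_partition(graph_adjacency(g))
    gap <- best$q - cp$modularity
    expect_gte(gap, -1e-9)   # greedy can never beat the optimum
    expect_gte(cp$modularity, 0)
    worst_gap <- max(worst_gap, gap)
  }
  if (worst_gap > 1e-9) {
    message(sprintf("greedy vs exhaustive modularity gap up to %.4f",
                    worst_gap))
  }
  expect_lt(worst_gap, 0.2)
})

test_that("complete graphs give the trivial optimum", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- letters[1:6]
  igraph::E(g)$weight <- 1
  cp <- detect_communities(g)
  best <- oracle_best_partition(graph_adjacency(g))
  expect_equal(cp$modularity, best$q)
  expect_equal(cp$modularity, 0)
})

test_that("modularity matches hand evaluation and is relabel-invariant", {
  g <- two_triangles()
  split <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_score(g, split), 0.5)
  expect_equal(modularity_score(g, split),
               oracle_modularity(graph_adjacency(g), split[igraph::V(g)$name]))
  relabel <- c(a = 9, b = 9, c = 9, d = 4, e = 4, f = 4)
  expect_equal(modularity_score(g, relabel), 0.5)
  allone <- c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 1)
  expect_equal(modularity_score(g, allone), 0)
  expect_error(modularity_score(g, c(a = 1, b = 1)), "missing node")
})

test_that("stored modularity is self-consistent with recomputation", {
  co <- generate_cohort(planted_pair_spec(seed = 31, n = 1500))
  rules <- mine_pairwise(co, "female", mining_config(0.1))
  g <- build_network(rules, co)
  cp <- detect_communities(g)
  expect_lt(abs(cp$modularity -
                  modularity_score(g, cp$membership)), 1e-9)
  expect_lt(abs(cp$modularity -
                  oracle_modularity(graph_adjacency(g),
                                    cp$membership[igraph::V(g)$name])),
            1e-9)
  # membership partitions the node set
  expect_setequal(names(cp$membership), igraph::V(g)$name)
})

test_that("a single-node network returns one community with zero modularity", {
  g <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g)$name <- "only"
  cp <- detect_communities(g)
  expect_equal(unname(cp$membership), 1)
  expect_equal(cp$modularity, 0)
  expect_error(detect_communities(igraph::make_empty_graph(0)), "empty")
})
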