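#' Build the comorbidity network from a pruned rule set
#'
#' One node per condition appearing in at least one retained rule, one
#' undirected edge per unordered condition pair with a retained rule in
#' either direction. Following the usual comorbidity-network drawing
#' conventions, each node carries the condition's weighted prevalence
#' (drives node size) and each edge carries the unweighted number of
#' stratum participants having both conditions (drives edge width).
#' Conditions with no retained rule are excluded.
#'
#' @param ruleset a `rule_set` from [mine_pairwise()].
#' @param cohort the [cohort_table()] the rules were mined from; its
#'   stratum labels must include the rule set's stratum.
#' @return an [igraph::igraph] graph with vertex attribute `prevalence`,
#'   edge attribute `weight` (co-occurrence count) and graph attribute
#'   `stratum`.
#' @export
build_network <- function(ruleset, cohort) {
  stratum <- attr(ruleset, "stratum")
  if (!stratum %in% cohort$stratum) {
    stop("rule set stratum '", stratum, "' not present in cohort")
  }
  if (nrow(ruleset) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::set_graph_attr(g, "stratum", stratum)
    return(g)
  }
  a <- pmin(ruleset$antecedent, ruleset$consequent)
  b <- pmax(ruleset$antecedent, ruleset$consequent)
  pairs <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  x <- indicator_matrix(cohort, stratum)
  pairs$weight <- mapply(function(u, v) sum(x[, u] & x[, v]),
                         pairs$a, pairs$b)
  nodes <- sort(unique(c(pairs$a, pairs$b)))
  vert <- data.frame(
    name = nodes,
    prevalence = vapply(nodes, weighted_prevalence, numeric(1),
                        cohort = cohort, stratum = stratum),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = vert)
  igraph::set_graph_attr(g, "stratum", stratum)
}

#' Detect disease communities by fast-greedy modularity maximisation
#'
#' Runs agglomerative greedy modularity optimisation (Clauset-Newman-Moore
#' as implemented in igraph): starting from singleton communities, the
#' merge giving the largest modularity increase is applied repeatedly, and
#' the partition at peak modularity along the merge path is returned. By
#' default the co-occurrence counts are used as edge weights.
#'
#' @param network a graph from [build_network()] (or any undirected
#'   igraph graph with a `weight` edge attribute).
#' @param use_edge_weights use co-occurrence counts as weights (default
#'   `TRUE`); `FALSE` treats all edges equally.
#' @return a `community_partition`: list with `membership` (named integer
#'   vector), `modularity` (Q at the returned partition), `merges` and
#'   `modularity_history` (Q after each agglomeration step), and
#'   `use_edge_weights`.
#' @export
detect_communities <- function(network, use_edge_weights = TRUE) {
  if (igraph::vcount(network) == 0) stop("network is empty")
  if (igraph::ecount(network) == 0) {
    membership <- stats::setNames(seq_len(igraph::vcount(network)),
                                  igraph::V(network)$name)
    return(structure(list(membership = membership, modularity = 0,
                          merges = NULL, modularity_history = numeric(0),
                          use_edge_weights = use_edge_weights),
                     class = "community_partition"))
  }
  w <- if (use_edge_weights) igraph::E(network)$weight else NA
  fg <- igraph::cluster_fast_greedy(network, weights = w)
  # partition at peak modularity along the merge path (first peak); the
  # final all-in-one partition (Q = 0) is always on the path, so Q >= 0
  peak <- which.max(fg$modularity) - 1L
  membership <- igraph::cut_at(fg, steps = peak)
  names(membership) <- igraph::V(network)$name
  q <- modularity_score(network, membership, use_edge_weights)
  structure(list(
    membership = membership,
    modularity = q,
    merges = fg$merges,
    modularity_history = fg$modularity,
    use_edge_weights = use_edge_weights
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", max(x$membership), " communities, Q = ",
      format(x$modularity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Newman modularity of a partition of the comorbidity network
#'
#' Q = sum over communities of [W_c / W - (S_c / 2W)^2], where W is the
#' total edge weight, W_c the weight inside community c and S_c the summed
#' degree-weight of its nodes: the fraction of edge weight falling within
#' communities minus its expectation under a degree-preserving random
#' graph.
#'
#' @param network an undirected igraph graph.
#' @param membership community assignment: named vector covering every
#'   node, or an unnamed vector in vertex order.
#' @param use_edge_weights use the `weight` edge attribute (default
#'   `TRUE`).
#' @return modularity Q.
#' @export
modularity_score <- function(network, membership, use_edge_weights = TRUE) {
  vn <- igraph::V(network)$name
  if (!is.null(names(membership))) {
    if (!all(vn %in% names(membership))) {
      stop("membership is missing node(s): ",
           paste(setdiff(vn, names(membership)), collapse = ", "))
    }
    membership <- membership[vn]
  } else if (length(membership) != length(vn)) {
    stop("membership must cover all ", length(vn), " nodes")
  }
  w <- if (use_edge_weights) igraph::E(network)$weight else NULL
  igraph::modularity(network, as.integer(factor(membership)), weights = w)
}
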