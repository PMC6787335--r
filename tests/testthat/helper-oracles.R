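# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: quadrature instead of mvtnorm, subset counting
# instead of matrix algebra, exhaustive partition search instead of greedy
# agglomeration.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method.
gl_nodes <- function(k) {
  i <- seq_len(k - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Upper-orthant probability P(Z1 > a, Z2 > b) of a standard bivariate
# normal with correlation rho, by 1-D reduction and Gauss-Legendre
# quadrature: integrate phi(x) * P(Z2 > b | Z1 = x) over x in [a, a + 12].
oracle_orthant <- function(p_a, p_b, rho, k = 240) {
  a <- qnorm(1 - p_a)
  b <- qnorm(1 - p_b)
  if (abs(rho) >= 1 - 1e-12) {
    return(if (rho > 0) min(p_a, p_b) else max(p_a + p_b - 1, 0))
  }
  gl <- gl_nodes(k)
  lo <- a
  hi <- max(a + 12, 12)
  x <- (hi - lo) / 2 * gl$x + (hi + lo) / 2
  f <- dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  (hi - lo) / 2 * sum(gl$w * f)
}

# Brute-force rule statistics for ordered antecedent/consequent condition
# sets, by direct subset counting over the rows of a cohort.
oracle_rule <- function(cohort, stratum, set_a, set_b, weighted = TRUE) {
  rows <- which(cohort$stratum == stratum)
  w <- if (weighted) cohort$weight[rows] else rep(1, length(rows))
  has <- function(set) {
    hit <- rep(TRUE, length(rows))
    for (cond in set) hit <- hit & cohort[[cond]][rows] == 1
    hit
  }
  a <- has(set_a); b <- has(set_b)
  p_a <- sum(w[a]) / sum(w)
  p_b <- sum(w[b]) / sum(w)
  joint <- sum(w[a & b]) / sum(w)
  list(p_a = p_a, p_b = p_b, joint = joint,
       confidence = joint / p_a, lift = joint / (p_a * p_b))
}

# All partitions of n labelled items, as a list of membership vectors
# (restricted growth strings). Bell(8) = 4140, small enough to enumerate.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (g in seq_len(k + 1)) recurse(c(prefix, g), max(k, g))
  }
  recurse(integer(0), 0)
  out
}

# Newman modularity computed directly from a weighted adjacency matrix.
oracle_modularity <- function(adj, membership) {
  two_w <- sum(adj)
  if (two_w == 0) return(0)
  deg <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - outer(deg, deg) / two_w)[same]) / two_w
}

# Exhaustive modularity maximisation over all partitions (<= 8 nodes).
oracle_best_partition <- function(adj) {
  parts <- all_partitions(nrow(adj))
  qs <- vapply(parts, oracle_modularity, numeric(1), adj = adj)
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# weighted adjacency matrix of an igraph graph, nodes in V order
graph_adjacency <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
}
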