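# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's own code paths.

# random simple undirected graph with named vertices, no isolated guarantee
random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
}

# transition probabilities computed from explicit BFS shortest distances
oracle_transition_probs <- function(g, prev, curr, p, q) {
  vn <- igraph::V(g)$name
  nbrs <- vn[as.integer(igraph::neighbors(g, match(curr, vn)))]
  if (is.null(prev)) {
    w <- rep(1, length(nbrs))
  } else {
    d <- igraph::distances(g, v = prev, to = nbrs)[1, ]
    w <- ifelse(d == 0, 1 / p, ifelse(d == 1, 1, 1 / q))
  }
  stats::setNames(w / sum(w), nbrs)
}

# O(n^3) triangle enumeration on an adjacency matrix
oracle_triangles <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  out <- list()
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (A[i, j] && A[i, k] && A[j, k]) out[[length(out) + 1]] <- c(i, j, k)
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

# pairwise AUC by counting positive-negative comparisons
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# element-wise GIP kernel double loop
oracle_gip <- function(m) {
  delta <- 1 / mean(rowSums(m^2))
  n <- nrow(m)
  s <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s[i, j] <- exp(-delta * sum((m[i, ] - m[j, ])^2))
  }
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}

# toy 4-partite graph: 2 lnc, 2 mi, 2 mr, 2 dis with a few edges
toy_hetero_graph <- function() {
  hetero_graph(
    nodes = list(lnc = c("l1", "l2"), mi = c("m1", "m2"),
                 mr = c("r1", "r2"), dis = c("d1", "d2")),
    edges = data.frame(
      source = c("l1", "l1", "m1", "m1", "r1", "l2"),
      target = c("m1", "r1", "r1", "d1", "d1", "m2"),
      relation = c("lnc-mi", "lnc-mr", "mi-mr", "mi-dis", "mr-dis", "lnc-mi"))
  )
}

# cached tiny benchmark bundle shared across tests
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_benchmark(synth_preset("tiny", seed = 0))
    cache
  }
})

# small deterministic embedding fixture
toy_embedding <- function() {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1), d = c(2, 0))
  class(m) <- c("embedding_table", class(m))
  m
}
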