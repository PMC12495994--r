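#' Random-walk configuration
#'
#' Parameters of the biased second-order random walk used to build the
#' embedding corpus: return parameter `p` (propensity to revisit the previous
#' node), in-out parameter `q` (depth- vs breadth-first bias), walk length and
#' number of walks started per node. `p = q = 1` gives unbiased walks.
#'
#' @param p,q positive biasing parameters.
#' @param walk_length integer walk length (>= 2).
#' @param walks_per_node integer number of walks per start node.
#' @param seed integer seed.
#' @return A `walk_config` list.
#' @export
walk_config <- function(p = 1, q = 1, walk_length = 80, walks_per_node = 10,
                        seed = 1L) {
  if (p <= 0 || q <= 0) stop_config("p and q must be positive")
  if (walk_length < 2) stop_config("walk_length must be >= 2")
  if (walks_per_node < 1) stop_config("walks_per_node must be >= 1")
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Biased transition probabilities of the second-order walk
#'
#' Given the previous and current node of a walk, returns the transition
#' distribution over the current node's neighbors: weight `1/p` for stepping
#' back to the previous node, `1` for a candidate at distance 1 from the
#' previous node, `1/q` for a candidate at distance 2, normalized to sum to
#' one. At a walk start (`prev = NULL`) the step is uniform.
#'
#' @param g an igraph graph.
#' @param prev previous node name or `NULL` at the walk start.
#' @param curr current node name.
#' @param cfg a [walk_config()].
#' @return Named probability vector over the neighbors of `curr`.
#' @export
biased_transition_probs <- function(g, prev, curr, cfg = walk_config()) {
  vn <- igraph::V(g)$name
  curr_i <- match(curr, vn)
  if (is.na(curr_i)) stop_config("unknown node '%s'", curr)
  nbrs <- as.integer(igraph::neighbors(g, curr_i))
  if (length(nbrs) == 0) stop_config("node '%s' is isolated", curr)
  if (is.null(prev)) {
    w <- rep(1, length(nbrs))
  } else {
    prev_i <- match(prev, vn)
    if (is.na(prev_i)) stop_config("unknown node '%s'", prev)
    prev_nbrs <- as.integer(igraph::neighbors(g, prev_i))
    if (!(curr_i %in% prev_nbrs)) {
      stop_config("prev must be a neighbor of curr")
    }
    w <- vapply(nbrs, function(c) {
      if (c == prev_i) 1 / cfg$p
      else if (c %in% prev_nbrs) 1
      else 1 / cfg$q
    }, 1.0)
  }
  setNames(w / sum(w), vn[nbrs])
}

#' Generate a biased random-walk corpus
#'
#' Starts `walks_per_node` walks from every node and extends each up to
#' `walk_length` steps with [biased_transition_probs()] semantics (isolated
#' nodes yield length-1 walks). Deterministic given `cfg$seed`.
#'
#' @inheritParams biased_transition_probs
#' @return List of character vectors (node-name sequences).
#' @export
generate_walks <- function(g, cfg = walk_config()) {
  if (igraph::vcount(g) == 0) stop_config("graph is empty")
  csr <- graph_csr(g)
  walks <- cpp_generate_walks(csr$adj, csr$ptr, cfg$p, cfg$q,
                              cfg$walk_length, cfg$walks_per_node, cfg$seed)
  vn <- igraph::V(g)$name
  lapply(walks, function(w) vn[w + 1L])
}

#' Noise distribution for negative sampling
#'
#' Unigram noise distribution proportional to node degree raised to 3/4,
#' the standard skip-gram choice.
#'
#' @param degrees named numeric vector of node degrees.
#' @return Named probability vector.
#' @export
noise_distribution <- function(degrees) {
  w <- pmax(degrees, 0)^0.75
  if (sum(w) == 0) w <- rep(1, length(w))
  setNames(w / sum(w), names(degrees))
}

#' Train skip-gram node embeddings with negative sampling
#'
#' Optimizes the skip-gram objective over the walk corpus: for each
#' center--context pair within `window`, maximize `log sigma(z_u . z_v)` plus
#' `K` negative terms `log sigma(-z_n . z_v)` with noise nodes drawn from a
#' distribution proportional to `degree^{3/4}`. Plain SGD with a linearly
#' decaying learning rate; byte-identical results under a fixed seed.
#'
#' @param walks corpus from [generate_walks()].
#' @param g the graph the walks were generated on (for node set and degrees).
#' @param dim embedding dimension.
#' @param window context window half-width.
#' @param K negatives per positive pair.
#' @param epochs passes over the corpus.
#' @param lr initial learning rate.
#' @param seed integer seed.
#' @return An `embedding_table`: numeric matrix (nodes x dim, rownames = node
#'   names) with attribute `epoch_objective` (mean sampled objective per
#'   epoch, non-decreasing on average).
#' @export
train_node_embeddings <- function(walks, g, dim = 64, window = 5, K = 5,
                                  epochs = 5, lr = 0.025, seed = 1L) {
  if (dim <= 0) stop_config("embedding dimension must be positive")
  if (length(walks) == 0) stop_config("empty walk corpus")
  vn <- igraph::V(g)$name
  iw <- lapply(walks, function(w) match(w, vn) - 1L)
  deg <- igraph::degree(g)
  noise <- noise_distribution(setNames(as.numeric(deg), vn))
  fit <- cpp_train_sgns(iw, length(vn), as.integer(dim), as.integer(window),
                        as.integer(K), as.integer(epochs), lr,
                        as.numeric(noise), as.integer(seed))
  emb <- fit$embedding
  rownames(emb) <- vn
  attr(emb, "epoch_objective") <- fit$epoch_objective
  class(emb) <- c("embedding_table", class(emb))
  emb
}

#' Cosine similarity matrix of node embeddings
#'
#' @param emb embedding matrix with rownames.
#' @param nodes node names to include (default: all).
#' @return Symmetric similarity matrix with unit diagonal, values in
#'   `[-1, 1]`.
#' @export
cosine_similarity_matrix <- function(emb, nodes = rownames(emb)) {
  missing <- setdiff(nodes, rownames(emb))
  if (length(missing)) {
    stop_config("missing embeddings for: %s", paste(head(missing, 5), collapse = ", "))
  }
  z <- emb[nodes, , drop = FALSE]
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop_config("zero-norm embedding vector")
  zn <- z / nrm
  s <- tcrossprod(zn)
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  s <- (s + t(s)) / 2
  dimnames(s) <- list(nodes, nodes)
  s
}

# ---------------------------------------------------------------------------
# Disease DAG semantic similarity (Wang-style decay over shared ancestors)

#' Construct a disease ontology DAG
#'
#' Directed acyclic parent-to-child structure over disease terms with a
#' semantic contribution factor `mu`: each generation away from a disease
#' contributes a factor `mu` less to its semantic value.
#'
#' @param edges data.frame with columns `parent`, `child`.
#' @param nodes optional character vector of all disease terms (defaults to
#'   terms seen in `edges`); isolated terms are allowed and act as roots.
#' @param mu contribution factor in (0, 1]; default 0.5.
#' @return A `disease_dag` with parent/children adjacency lists.
#' @export
disease_dag <- function(edges, nodes = NULL, mu = 0.5) {
  if (mu <= 0 || mu > 1) stop_config("mu must lie in (0, 1]")
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  nodes <- unique(c(nodes, edges$parent, edges$child))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) stop_config("disease hierarchy contains a cycle")
  parents <- lapply(igraph::as_adj_list(g, mode = "in"),
                    function(v) nodes[as.integer(v)])
  children <- lapply(igraph::as_adj_list(g, mode = "out"),
                     function(v) nodes[as.integer(v)])
  names(parents) <- names(children) <- nodes
  structure(list(nodes = nodes, parents = parents, children = children,
                 mu = mu),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  roots <- sum(vapply(x$parents, length, 1L) == 0)
  cat(sprintf("disease_dag: %d terms, %d root(s), mu = %g\n",
              length(x$nodes), roots, x$mu))
  invisible(x)
}

# d plus all its ancestors
dag_ancestry <- function(dag, d) {
  if (!(d %in% dag$nodes)) stop_config("unknown disease '%s'", d)
  seen <- character()
  frontier <- d
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  unique(seen)
}

# semantic contribution of every ancestry member of d, as a named vector
dag_contributions <- function(dag, d) {
  anc <- dag_ancestry(dag, d)
  val <- setNames(rep(NA_real_, length(anc)), anc)
  val[d] <- 1
  # ancestors resolved by repeated relaxation: D(X) = mu * max over children
  # of X that lie in the ancestry. Acyclicity guarantees convergence.
  todo <- setdiff(anc, d)
  while (length(todo)) {
    progressed <- FALSE
    for (x in todo) {
      ch <- intersect(dag$children[[x]], anc)
      if (length(ch) && all(!is.na(val[ch]))) {
        val[x] <- dag$mu * max(val[ch])
        progressed <- TRUE
      }
    }
    todo <- names(val)[is.na(val)]
    if (!progressed && length(todo)) {
      stop_config("inconsistent ancestry for '%s'", d)
    }
  }
  val
}

#' Semantic contribution of an ancestor to a disease
#'
#' `D_d(d) = 1`; for an ancestor `X`, `D_d(X) = mu * max(D_d(X'))` over the
#' children `X'` of `X` that lie in the ancestry of `d`. The contribution
#' decays geometrically with the generation gap.
#'
#' @param dag a [disease_dag()].
#' @param d disease term.
#' @param X `d` itself or one of its ancestors.
#' @return Contribution score in (0, 1].
#' @export
semantic_contribution <- function(dag, d, X) {
  val <- dag_contributions(dag, d)
  if (!(X %in% names(val))) {
    stop_config("'%s' is not '%s' or one of its ancestors", X, d)
  }
  unname(val[X])
}

#' Semantic value of a disease
#'
#' Sum of the semantic contributions of the disease and all its ancestors;
#' at least 1 (the self term).
#'
#' @inheritParams semantic_contribution
#' @return Numeric semantic value `DV(d) >= 1`.
#' @export
semantic_value <- function(dag, d) {
  sum(dag_contributions(dag, d))
}

#' Semantic similarity of two diseases
#'
#' Shared-ancestor similarity: the contributions of the common ancestry
#' members to both diseases, normalized by the two semantic values. Equal
#' terms score 1, terms with disjoint ancestries score 0.
#'
#' @inheritParams semantic_contribution
#' @param i,j disease terms.
#' @return Similarity in `[0, 1]`.
#' @export
semantic_similarity <- function(dag, i, j) {
  vi <- dag_contributions(dag, i)
  vj <- dag_contributions(dag, j)
  shared <- intersect(names(vi), names(vj))
  if (!length(shared)) return(0)
  sum(vi[shared] + vj[shared]) / (sum(vi) + sum(vj))
}

#' Semantic similarity matrix over a set of diseases
#'
#' @param dag a [disease_dag()].
#' @param diseases disease terms (default: all DAG terms).
#' @return Symmetric matrix with unit diagonal.
#' @export
semantic_similarity_matrix <- function(dag, diseases = dag$nodes) {
  contr <- lapply(diseases, function(d) dag_contributions(dag, d))
  dv <- vapply(contr, sum, 1.0)
  n <- length(diseases)
  s <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (a in seq_len(n)) {
    for (b in a:n) {
      shared <- intersect(names(contr[[a]]), names(contr[[b]]))
      val <- if (length(shared)) {
        sum(contr[[a]][shared] + contr[[b]][shared]) / (dv[a] + dv[b])
      } else 0
      s[a, b] <- s[b, a] <- val
    }
  }
  diag(s) <- 1
  s
}

# ---------------------------------------------------------------------------
# Gaussian interaction profile (GIP) kernel similarity

#' GIP kernel bandwidth
#'
#' Reciprocal of the mean squared norm of the binary interaction profiles.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @return Positive bandwidth scalar.
#' @export
gip_bandwidth <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1) stop_config("need at least one profile")
  msq <- mean(rowSums(profiles^2))
  if (msq == 0) stop_config("all interaction profiles are zero")
  1 / msq
}

#' GIP kernel similarity matrix
#'
#' Gaussian kernel over interaction profiles,
#' `exp(-bandwidth * ||beta_i - beta_j||^2)`, with the bandwidth set by
#' [gip_bandwidth()]. Unit diagonal; values in (0, 1].
#'
#' @param assoc binary association matrix, one profile per row (rownames are
#'   the entity ids).
#' @return Symmetric similarity matrix.
#' @export
gip_similarity <- function(assoc) {
  assoc <- as.matrix(assoc)
  if (nrow(assoc) == 0 || ncol(assoc) == 0) stop_config("empty association matrix")
  delta <- gip_bandwidth(assoc)
  sq <- rowSums(assoc^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(assoc)
  d2[d2 < 0] <- 0
  s <- exp(-delta * d2)
  diag(s) <- 1
  s <- (s + t(s)) / 2
  dimnames(s) <- list(rownames(assoc), rownames(assoc))
  s
}

# ---------------------------------------------------------------------------
# Block assembly

#' Assemble the disease similarity block
#'
#' Uses DAG semantic similarity for disease pairs where both terms carry
#' ontology information, and GIP kernel similarity (from the RNA--disease
#' association profiles) for pairs involving a disease without it.
#'
#' @param dag a [disease_dag()] or `NULL` if no ontology is available.
#' @param assoc binary disease-by-RNA association matrix (one row per
#'   disease) used for the GIP fallback; may be `NULL` when `dag` covers
#'   every disease.
#' @param diseases the disease ids the block must cover (default: rows of
#'   `assoc`, else DAG terms).
#' @return Symmetric disease similarity block with unit diagonal.
#' @export
assemble_disease_similarity <- function(dag, assoc,
                                        diseases = if (!is.null(assoc)) rownames(assoc) else dag$nodes) {
  in_dag <- if (is.null(dag)) rep(FALSE, length(diseases)) else diseases %in% dag$nodes
  has_profile <- if (is.null(assoc)) rep(FALSE, length(diseases)) else diseases %in% rownames(assoc)
  orphan <- diseases[!in_dag & !has_profile]
  if (length(orphan)) {
    stop_config("disease(s) with neither ontology nor interaction profile: %s",
                paste(head(orphan, 5), collapse = ", "))
  }
  n <- length(diseases)
  out <- matrix(0, n, n, dimnames = list(diseases, diseases))
  if (any(in_dag)) {
    ds <- semantic_similarity_matrix(dag, diseases[in_dag])
    out[in_dag, in_dag] <- ds
  }
  need_gip <- !(outer(in_dag, in_dag, "&"))
  if (any(need_gip)) {
    if (is.null(assoc)) stop_config("GIP fallback needed but no association matrix given")
    if (!all(diseases %in% rownames(assoc))) {
      stop_config("association matrix must cover every disease for the GIP fallback")
    }
    gs <- gip_similarity(assoc[diseases, , drop = FALSE])
    out[need_gip] <- gs[need_gip]
  }
  diag(out) <- 1
  out
}

#' Assemble a per-type RNA similarity block
#'
#' Functional similarity (e.g. a precomputed miRNA functional similarity
#' matrix) is used where it is defined; the network-embedding similarity
#' fills the remaining pairs, complementing incomplete functional coverage.
#'
#' @param network_sim square network-embedding similarity over the type's
#'   nodes (rownames = ids).
#' @param functional_sim optional matrix over a subset of the same ids;
#'   `NA` entries are treated as undefined.
#' @return Symmetric similarity block over the nodes of `network_sim`.
#' @export
assemble_rna_similarity <- function(network_sim, functional_sim = NULL) {
  out <- as.matrix(network_sim)
  if (!is.null(functional_sim)) {
    fs <- as.matrix(functional_sim)
    ids <- rownames(fs)
    if (is.null(ids) || !all(ids %in% rownames(out)) ||
        !identical(rownames(fs), colnames(fs))) {
      stop_config("functional similarity index does not match the node index")
    }
    sub <- out[ids, ids, drop = FALSE]
    take <- !is.na(fs)
    sub[take] <- fs[take]
    out[ids, ids] <- sub
  }
  out <- (out + t(out)) / 2
  out
}
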