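#' Attention parameters
#'
#' Projection matrix `W0` (feature to attention space), attention vector `W`
#' over the concatenated projected pair, and the LeakyReLU negative slope.
#' Node features are randomly generated, so the default parameters are drawn
#' i.i.d. standard normal under a seed.
#'
#' @param feat_dim input feature dimension.
#' @param proj_dim projection dimension.
#' @param leaky_slope negative slope of the LeakyReLU.
#' @param seed integer seed.
#' @return An `attention_params` list with `W0` (proj_dim x feat_dim), `W`
#'   (length 2 * proj_dim) and `leaky_slope`.
#' @export
attention_params <- function(feat_dim, proj_dim = 8, leaky_slope = 0.2,
                             seed = 1L) {
  set.seed(seed)
  structure(list(
    W0 = matrix(rnorm(proj_dim * feat_dim, sd = 1 / sqrt(feat_dim)),
                proj_dim, feat_dim),
    W = rnorm(2 * proj_dim, sd = 1 / sqrt(2 * proj_dim)),
    leaky_slope = leaky_slope
  ), class = "attention_params")
}

#' Pairwise attention coefficients over a support graph
#'
#' For each directed pair (i, j) with j a neighbor of i, the raw score is
#' `LeakyReLU(W [W0 h_i || W0 h_j])`; coefficients are softmax-normalized
#' over each node's neighborhood, so every non-isolated node's row sums to
#' one and all values lie in (0, 1).
#'
#' @param features numeric matrix of node features (rownames = node names).
#' @param g support graph (igraph) whose vertex names index `features`.
#' @param params an [attention_params()].
#' @return An `attention_map`: data.frame with columns `i`, `j`, `alpha`
#'   holding one row per directed edge.
#' @export
attention_coefficients <- function(features, g, params) {
  vn <- igraph::V(g)$name
  if (!all(vn %in% rownames(features))) {
    stop_config("every node needs a feature vector")
  }
  X <- features[vn, , drop = FALSE]
  P <- X %*% t(params$W0)               # n x proj_dim
  pd <- ncol(P)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) {
    return(structure(data.frame(i = character(), j = character(),
                                alpha = numeric()),
                     class = c("attention_map", "data.frame")))
  }
  # both directions: softmax is per source neighborhood
  src <- c(el[, 1], el[, 2])
  dst <- c(el[, 2], el[, 1])
  raw <- leaky_relu(
    P[src, , drop = FALSE] %*% params$W[seq_len(pd)] +
      P[dst, , drop = FALSE] %*% params$W[pd + seq_len(pd)],
    params$leaky_slope
  )[, 1]
  # numerically stable softmax per source node
  mx <- tapply(raw, src, max)[as.character(src)]
  ex <- exp(raw - mx)
  tot <- tapply(ex, src, sum)[as.character(src)]
  alpha <- as.numeric(ex / tot)
  out <- data.frame(i = vn[src], j = vn[dst], alpha = alpha,
                    stringsAsFactors = FALSE)
  structure(out, class = c("attention_map", "data.frame"))
}

# symmetrize a directed attention map: alpha_ij <- max(alpha'_ij, alpha'_ji)
symmetrize_attention <- function(attn) {
  a <- pmin(attn$i, attn$j)
  b <- pmax(attn$i, attn$j)
  key <- paste(a, b, sep = "\r")
  alpha <- tapply(attn$alpha, key, max)
  parts <- do.call(rbind, strsplit(names(alpha), "\r", fixed = TRUE))
  structure(data.frame(i = parts[, 1], j = parts[, 2],
                       alpha = as.numeric(alpha),
                       stringsAsFactors = FALSE),
            class = c("attention_map", "data.frame"))
}

#' Share attention across triangle motifs
#'
#' Within every triangle the three edge coefficients are replaced by their
#' maximum. The map is first symmetrized (undirected edge value = max of the
#' two directed coefficients), then the triangle max rule is iterated to its
#' fixpoint so that edge-overlapping triangles yield a well-defined result
#' (connected triangle components share their component maximum).
#'
#' @param attn an [attention_coefficients()] map.
#' @param triangles a [enumerate_triangles()] set whose vertex names match
#'   the map's node names.
#' @return Symmetric `attention_map` with one row per undirected edge.
#' @export
share_triangle_attention <- function(attn, triangles) {
  sym <- symmetrize_attention(attn)
  if (nrow(triangles) == 0) return(sym)
  vn <- attr(triangles, "names_map")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  val <- setNames(sym$alpha, key(sym$i, sym$j))
  tri_edges <- rbind(
    cbind(vn[triangles[, 1]], vn[triangles[, 2]]),
    cbind(vn[triangles[, 1]], vn[triangles[, 3]]),
    cbind(vn[triangles[, 2]], vn[triangles[, 3]]))
  tri_keys <- matrix(key(tri_edges[, 1], tri_edges[, 2]), ncol = 3)
  missing <- setdiff(as.vector(tri_keys), names(val))
  if (length(missing)) {
    stop_config("attention map lacks %d triangle edge(s)", length(missing))
  }
  repeat {
    m <- matrix(val[tri_keys], ncol = 3)
    tri_max <- pmax(m[, 1], m[, 2], m[, 3])
    changed <- FALSE
    for (c_ in 1:3) {
      upd <- tapply(tri_max, tri_keys[, c_], max)
      sel <- names(upd)
      delta <- upd > val[sel]
      if (any(delta)) {
        val[sel[delta]] <- upd[delta]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sym$alpha <- unname(val[key(sym$i, sym$j)])
  sym
}

#' Augment a similarity block with attention coefficients
#'
#' Adds the (shared, symmetrized) attention coefficient to the similarity
#' entry of every same-type pair present in the attention map; entries
#' without a coefficient are unchanged.
#'
#' @param block square similarity matrix (rownames = ids).
#' @param attn a (shared) `attention_map`.
#' @return Augmented symmetric block of the same shape.
#' @export
augment_similarity <- function(block, attn) {
  out <- as.matrix(block)
  ids <- rownames(out)
  sel <- attn$i %in% ids & attn$j %in% ids
  if (any(sel)) {
    a <- attn[sel, , drop = FALSE]
    # symmetrize defensively in case a raw (directed) map is passed
    a <- symmetrize_attention(a)
    ii <- cbind(match(a$i, ids), match(a$j, ids))
    out[ii] <- out[ii] + a$alpha
    out[ii[, c(2, 1), drop = FALSE]] <- out[ii]
  }
  out
}
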