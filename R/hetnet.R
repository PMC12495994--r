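#' Block association matrix of the heterogeneous network
#'
#' Builds the symmetric `N_v x N_v` adjacency whose off-diagonal blocks are
#' the six binary inter-type association matrices (block order lncRNA,
#' miRNA, mRNA, disease). Diagonal blocks are left zero; they are later
#' filled with similarity (enhanced adjacency) or triangle co-occurrence
#' (higher-order adjacency) blocks.
#'
#' @param hg a [hetero_graph()].
#' @return Sparse symmetric matrix with dimnames and attribute `blocks`
#'   (the per-type index ranges).
#' @export
build_association_matrix <- function(hg) {
  n <- n_nodes(hg)
  if (nrow(hg$edges)) {
    i <- unname(hg$index[hg$edges$source])
    j <- unname(hg$index[hg$edges$target])
    R <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
    R@x[] <- 1  # dedupe any coincident entries to binary
  } else {
    R <- Matrix::Matrix(0, n, n, sparse = TRUE)
  }
  dimnames(R) <- list(names(hg$index), names(hg$index))
  attr(R, "blocks") <- block_indices(hg)
  R
}

#' Support graph hosting the triangle motifs
#'
#' Same-type nodes never share association edges, so 3-cliques containing a
#' same-type pair can only exist on an augmented graph: the support graph
#' has all inter-type association edges plus an intra-type edge wherever the
#' corresponding similarity is at least `tau` (diagonal excluded).
#'
#' @param hg a [hetero_graph()].
#' @param sims named list of per-type similarity matrices (`lnc`, `mi`,
#'   `mr`, `dis`), each with rownames matching the type's node ids.
#' @param tau similarity threshold in `[0, 1]` (or above 1 to disable
#'   intra-type edges).
#' @return An undirected igraph over all nodes.
#' @export
build_support_graph <- function(hg, sims, tau = 0.5) {
  g <- association_igraph(hg)
  extra <- list()
  for (ty in NODE_TYPES) {
    ids <- hg$nodes[[ty]]
    if (length(ids) < 2 || is.null(sims[[ty]])) next
    s <- as.matrix(sims[[ty]])[ids, ids, drop = FALSE]
    hit <- which(s >= tau & upper.tri(s), arr.ind = TRUE)
    if (nrow(hit)) {
      extra[[ty]] <- rbind(hg$index[ids[hit[, 1]]], hg$index[ids[hit[, 2]]])
    }
  }
  if (length(extra)) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, extra)))
  }
  igraph::simplify(g)
}

#' Enumerate the triangles (3-cliques) of a graph
#'
#' @param g an undirected igraph.
#' @return A `triangle_set`: integer matrix with one triangle per row,
#'   vertex indices sorted within rows, rows in lexicographic order;
#'   attribute `names` carries the vertex names.
#' @export
enumerate_triangles <- function(g) {
  tri <- matrix(as.integer(igraph::triangles(g)), ncol = 3, byrow = TRUE)
  if (nrow(tri)) {
    tri <- t(apply(tri, 1, sort))
    tri <- tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
  }
  structure(tri, names_map = igraph::V(g)$name, class = "triangle_set")
}

#' Higher-order co-occurrence blocks from triangles
#'
#' For each node type, `H_type(i, j) = 1` when nodes `i` and `j` are of that
#' type and co-occur in at least one triangle of the support graph; motifs
#' are taken as maximal evidence, so the entry saturates at 1. Zero diagonal.
#'
#' @param triangles a [enumerate_triangles()] result on the support graph.
#' @param hg the [hetero_graph()] supplying the node typing.
#' @return Named list of symmetric binary matrices `lnc`, `mi`, `mr`, `dis`.
#' @export
higher_order_blocks <- function(triangles, hg) {
  blocks <- lapply(NODE_TYPES, function(ty) {
    ids <- hg$nodes[[ty]]
    matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  })
  names(blocks) <- NODE_TYPES
  if (nrow(triangles) == 0) return(blocks)
  vn <- attr(triangles, "names_map")
  pair_cols <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pc in pair_cols) {
    a <- vn[triangles[, pc[1]]]
    b <- vn[triangles[, pc[2]]]
    ta <- hg$type[a]
    tb <- hg$type[b]
    same <- which(ta == tb)
    for (k in same) {
      ty <- ta[[k]]
      blocks[[ty]][a[k], b[k]] <- 1
      blocks[[ty]][b[k], a[k]] <- 1
    }
  }
  blocks
}

# replace the diagonal blocks of R with the supplied per-type blocks
replace_diagonal_blocks <- function(R, blocks_by_type, hg) {
  out <- as(R, "CsparseMatrix")
  idx <- block_indices(hg)
  out <- as.matrix(out)
  for (ty in NODE_TYPES) {
    ii <- idx[[ty]]
    if (!length(ii)) next
    b <- as.matrix(blocks_by_type[[ty]])
    if (!all(dim(b) == c(length(ii), length(ii)))) {
      stop_config("diagonal block for type '%s' has wrong shape", ty)
    }
    out[ii, ii] <- b
  }
  out <- Matrix::Matrix(out, sparse = TRUE)
  dimnames(out) <- dimnames(R)
  attr(out, "blocks") <- idx
  out
}

#' Enhanced adjacency matrix
#'
#' The association matrix with its diagonal blocks replaced by the
#' attention-augmented similarity blocks: first-layer message passing mixes
#' association links with (augmented) same-type similarity.
#'
#' @param R association matrix from [build_association_matrix()].
#' @param aug_sims named list of augmented per-type similarity blocks.
#' @param hg the [hetero_graph()].
#' @return Sparse symmetric matrix `A_e`.
#' @export
build_enhanced_adjacency <- function(R, aug_sims, hg) {
  Ae <- replace_diagonal_blocks(R, aug_sims, hg)
  assert_symmetric(Ae, what = "enhanced adjacency")
  Ae
}

#' Higher-order adjacency matrix
#'
#' The association matrix with its diagonal blocks replaced by the binary
#' triangle co-occurrence blocks: second-layer message passing aggregates
#' over higher-order (motif) neighborhoods.
#'
#' @param R association matrix from [build_association_matrix()].
#' @param H named list of triangle co-occurrence blocks from
#'   [higher_order_blocks()].
#' @param hg the [hetero_graph()].
#' @return Sparse symmetric binary matrix `A_h`.
#' @export
build_higher_order_adjacency <- function(R, H, hg) {
  Ah <- replace_diagonal_blocks(R, H, hg)
  assert_symmetric(Ah, what = "higher-order adjacency")
  Ah
}

#' Optionally normalize an adjacency matrix
#'
#' `mode = "none"` returns the matrix unchanged (the propagation rule is
#' defined on the raw matrices); `mode = "sym"` applies the symmetric
#' normalization `D^{-1/2} (A + I) D^{-1/2}` with self-loops guaranteeing
#' positive degrees, available for numerical stability on large graphs.
#'
#' @param A square matrix.
#' @param mode `"none"` or `"sym"`.
#' @return Matrix of the same shape.
#' @export
normalize_adjacency <- function(A, mode = c("none", "sym")) {
  mode <- match.arg(mode)
  if (mode == "none") return(A)
  n <- nrow(A)
  Ai <- A + Matrix::Diagonal(n)
  d <- Matrix::rowSums(abs(Ai))
  Dinv <- Matrix::Diagonal(n, 1 / sqrt(d))
  out <- Dinv %*% Ai %*% Dinv
  dimnames(out) <- dimnames(A)
  out
}
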