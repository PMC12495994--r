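#' Relation tags of the heterogeneous ceRNA--disease network
#'
#' The six inter-type relations of the four-partite network, in the fixed
#' block order lncRNA, miRNA, mRNA, disease.
#' @export
RELATIONS <- c("lnc-mi", "lnc-mr", "lnc-dis", "mi-mr", "mi-dis", "mr-dis")

NODE_TYPES <- c("lnc", "mi", "mr", "dis")

relation_types <- function(rel) strsplit(rel, "-", fixed = TRUE)[[1]]

#' Construct a heterogeneous ceRNA--disease graph
#'
#' A typed node set (lncRNA, miRNA, mRNA, disease) plus undirected inter-type
#' association edges. Intra-type edges are not representable: same-type
#' relationships enter later through similarity matrices and triangle motifs.
#'
#' @param nodes named list with character vectors `lnc`, `mi`, `mr`, `dis`;
#'   ids must be unique across all types.
#' @param edges data.frame with columns `source`, `target`, `relation`
#'   (one of [RELATIONS]); `source` must be of the relation's first type and
#'   `target` of its second. Duplicate edges are removed with a warning.
#' @return An object of class `hetero_graph` with elements `nodes`, `edges`,
#'   `index` (id to 1-based global index, block order lnc, mi, mr, dis) and
#'   `type` (id to type).
#' @export
hetero_graph <- function(nodes, edges = NULL) {
  stopifnot(is.list(nodes))
  missing_types <- setdiff(NODE_TYPES, names(nodes))
  if (length(missing_types)) {
    nodes[missing_types] <- list(character())
  }
  nodes <- lapply(nodes[NODE_TYPES], function(x) as.character(x))
  all_ids <- unlist(nodes, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop_config("node ids must be unique across types (duplicated: %s)",
                paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  type <- rep(NODE_TYPES, vapply(nodes, length, 1L))
  names(type) <- all_ids
  index <- seq_along(all_ids)
  names(index) <- all_ids

  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "relation") %in% names(edges)))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  bad_rel <- setdiff(unique(edges$relation), RELATIONS)
  if (length(bad_rel)) {
    stop_config("unknown relation tag(s): %s", paste(bad_rel, collapse = ", "))
  }
  unknown <- setdiff(c(edges$source, edges$target), all_ids)
  if (length(unknown)) {
    stop_config("edge references unknown node(s): %s",
                paste(head(unknown, 5), collapse = ", "))
  }
  for (rel in unique(edges$relation)) {
    tt <- relation_types(rel)
    sel <- edges$relation == rel
    if (!all(type[edges$source[sel]] == tt[1]) ||
        !all(type[edges$target[sel]] == tt[2])) {
      stop_config("edge endpoints do not match relation %s", rel)
    }
  }
  key <- paste(edges$source, edges$target, edges$relation)
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(sprintf("removed %d duplicate edge(s)", ndup), call. = FALSE)
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, index = index, type = type),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("hetero_graph:",
      sprintf("%d lncRNA, %d miRNA, %d mRNA, %d disease nodes; %d edges\n",
              length(x$nodes$lnc), length(x$nodes$mi), length(x$nodes$mr),
              length(x$nodes$dis), nrow(x$edges)))
  tab <- table(factor(x$edges$relation, levels = RELATIONS))
  cat("  edges by relation:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

n_nodes <- function(hg) length(hg$index)

#' Block index ranges of a heterogeneous graph
#'
#' @param hg a [hetero_graph()].
#' @return Named list of integer vectors giving each type's global indices.
#' @export
block_indices <- function(hg) {
  sizes <- vapply(hg$nodes, length, 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  out <- Map(function(s, e) if (e >= s) s:e else integer(), starts, ends)
  names(out) <- NODE_TYPES
  out
}

# igraph over the association edges only (all node types, no intra-type edges)
association_igraph <- function(hg) {
  g <- igraph::make_empty_graph(n = n_nodes(hg), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = names(hg$index))
  if (nrow(hg$edges)) {
    ei <- rbind(hg$index[hg$edges$source], hg$index[hg$edges$target])
    g <- igraph::add_edges(g, as.vector(ei))
  }
  g
}

# sorted CSR adjacency (0-based) for the C++ walkers
graph_csr <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(v) sort(unique(as.integer(v))) - 1L)
  lens <- vapply(adj, length, 1L)
  list(adj = as.integer(unlist(adj, use.names = FALSE)),
       ptr = as.integer(c(0L, cumsum(lens))),
       n = n)
}
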