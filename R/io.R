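#' Read a heterogeneous graph from a TSV edge list
#'
#' Three tab-separated columns `source`, `target`, `relation` (header
#' auto-detected: a first line whose third field is not a valid relation tag
#' and whose fields match the column names is treated as a header).
#' Malformed rows and unknown relation tags raise an error citing the line
#' number; duplicate edges are deduplicated with a warning. Node sets are
#' inferred from the edges by first-seen order within each type.
#'
#' @param path TSV file path.
#' @return A [hetero_graph()].
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(hetero_graph(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- trimws(fields[[1]])
  if (length(f1) >= 3 && !(f1[3] %in% RELATIONS)) {
    if (identical(tolower(f1[1:3]), c("source", "target", "relation"))) {
      start <- 2L
    } else {
      stop_config("line 1: unknown relation tag '%s'", f1[3])
    }
  }
  rows <- vector("list", length(lines) - start + 1L)
  for (i in seq(start, length(lines))) {
    f <- trimws(fields[[i]])
    if (length(f) != 3 || any(!nzchar(f))) {
      stop_config("line %d: expected 3 tab-separated fields", i)
    }
    if (!(f[3] %in% RELATIONS)) {
      stop_config("line %d: unknown relation tag '%s'", i, f[3])
    }
    rows[[i - start + 1L]] <- f
  }
  m <- do.call(rbind, rows)
  edges <- data.frame(source = m[, 1], target = m[, 2], relation = m[, 3],
                      stringsAsFactors = FALSE)
  nodes <- list()
  for (ty in NODE_TYPES) nodes[[ty]] <- character()
  for (rel in RELATIONS) {
    tt <- relation_types(rel)
    sel <- edges$relation == rel
    nodes[[tt[1]]] <- c(nodes[[tt[1]]], edges$source[sel])
    nodes[[tt[2]]] <- c(nodes[[tt[2]]], edges$target[sel])
  }
  nodes <- lapply(nodes, unique)
  hetero_graph(nodes, edges)
}

#' Write a heterogeneous graph as a TSV edge list
#'
#' Rows are written in a stable sort order (relation, source, target) so
#' output is deterministic given the graph.
#'
#' @param hg a [hetero_graph()].
#' @param path output path.
#' @export
write_graph <- function(hg, path) {
  e <- hg$edges[order(hg$edges$relation, hg$edges$source, hg$edges$target), ]
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read triplet--disease samples from a TSV file
#'
#' Five tab-separated columns `lnc`, `mi`, `mr`, `dis`, `label`; labels must
#' parse as 0 or 1. Header auto-detected. Empty files yield an empty
#' sample table.
#'
#' @param path TSV file path.
#' @return data.frame with columns `lnc`, `mi`, `mr`, `dis`, `label`.
#' @export
read_samples <- function(path) {
  empty <- data.frame(lnc = character(), mi = character(), mr = character(),
                      dis = character(), label = integer())
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- trimws(fields[[1]])
  if (length(f1) == 5 && is.na(suppressWarnings(as.integer(f1[5])))) start <- 2L
  if (start > length(lines)) return(empty)
  out <- vector("list", length(lines) - start + 1L)
  for (i in seq(start, length(lines))) {
    f <- trimws(fields[[i]])
    if (length(f) != 5) stop_config("line %d: expected 5 tab-separated fields", i)
    lab <- suppressWarnings(as.integer(f[5]))
    if (is.na(lab) || !(lab %in% c(0L, 1L))) {
      stop_config("line %d: label must be 0 or 1 (got '%s')", i, f[5])
    }
    out[[i - start + 1L]] <- data.frame(lnc = f[1], mi = f[2], mr = f[3],
                                        dis = f[4], label = lab,
                                        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  key <- paste(res$lnc, res$mi, res$mr, res$dis)
  both <- intersect(key[res$label == 1], key[res$label == 0])
  if (length(both)) stop_config("sample(s) appear with both labels")
  res
}

#' Write triplet--disease samples as TSV
#'
#' @param samples data.frame with columns `lnc`, `mi`, `mr`, `dis`, `label`.
#' @param path output path.
#' @export
write_samples <- function(samples, path) {
  s <- samples[order(samples$lnc, samples$mi, samples$mr, samples$dis), ]
  write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease ontology from a parent--child TSV
#'
#' Two tab-separated columns `parent`, `child` (header optional).
#'
#' @param path TSV file path.
#' @param mu contribution factor.
#' @return A [disease_dag()].
#' @export
read_dag <- function(path, mu = 0.5) {
  df <- read.delim(path, header = FALSE, col.names = c("parent", "child"),
                   colClasses = "character")
  if (nrow(df) && identical(tolower(unlist(df[1, ])),
                            c(parent = "parent", child = "child"))) {
    df <- df[-1, , drop = FALSE]
  }
  disease_dag(df, mu = mu)
}

#' Write a disease ontology as a parent--child TSV
#' @param dag a [disease_dag()].
#' @param path output path.
#' @export
write_dag <- function(dag, path) {
  rows <- do.call(rbind, lapply(dag$nodes, function(p) {
    ch <- dag$children[[p]]
    if (length(ch)) data.frame(parent = p, child = ch) else NULL
  }))
  if (is.null(rows)) rows <- data.frame(parent = character(), child = character())
  rows <- rows[order(rows$parent, rows$child), ]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a labeled dense matrix as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a labeled dense matrix from TSV
#' @param path TSV file path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Load a run configuration from YAML (or JSON)
#'
#' Unknown keys are rejected; values override the [pipeline_config()] and
#' nested [walk_config()] / [train_config()] defaults.
#'
#' @param path YAML or JSON file.
#' @return A [pipeline_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  top_keys <- c("walk", "train", "tau", "sgns_dim", "sgns_window", "sgns_K",
                "sgns_epochs", "attention_dim", "attention", "higher_order",
                "sampler", "classifier", "seed")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown)) {
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  walk_args <- raw$walk %||% list()
  unknown <- setdiff(names(walk_args), names(formals(walk_config)))
  if (length(unknown)) stop_config("unknown walk key(s): %s", paste(unknown, collapse = ", "))
  train_args <- raw$train %||% list()
  unknown <- setdiff(names(train_args), names(formals(train_config)))
  if (length(unknown)) stop_config("unknown train key(s): %s", paste(unknown, collapse = ", "))
  args <- raw[setdiff(names(raw), c("walk", "train"))]
  args$walk <- do.call(walk_config, walk_args)
  args$train <- do.call(train_config, train_args)
  do.call(pipeline_config, args)
}

#' Write the resolved configuration and run manifest as JSON
#'
#' @param cfg a [pipeline_config()].
#' @param path output path.
#' @param extra optional named list merged into the manifest.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  man <- c(list(package = "ceRNAdis",
                version = as.character(utils::packageVersion("ceRNAdis")),
                config = unclass_deep(cfg)),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
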