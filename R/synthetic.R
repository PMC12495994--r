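#' Synthetic benchmark configuration
#'
#' Controls the planted-signal generator: node counts per type, number of
#' regulatory modules, within-module (`p_intra`) and background (`p_noise`)
#' interaction probabilities, the number of positive triplet--disease
#' associations and the fraction of them (`signal`) that respect module
#' structure (disease drawn from the triplet miRNA's module rather than
#' uniformly).
#'
#' @param n_lnc,n_mi,n_mr,n_dis node counts (each >= `n_modules`).
#' @param n_modules number of planted modules.
#' @param p_intra within-module edge probability for lnc--mi and mi--mr.
#' @param p_noise background edge probability (cross-module lnc--mi / mi--mr
#'   and all lnc--mr, RNA--disease background edges).
#' @param n_pos number of positive associations to plant.
#' @param signal fraction of positives respecting module structure, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_lnc = 218L, n_mi = 605L, n_mr = 1051L,
                         n_dis = 314L, n_modules = 20L, p_intra = 0.05,
                         p_noise = 0.002, n_pos = 2115L, signal = 0.9,
                         seed = 0L) {
  counts <- c(n_lnc, n_mi, n_mr, n_dis)
  if (any(counts < n_modules)) stop_config("each node count must be >= n_modules")
  for (p in c(p_intra, p_noise, signal)) {
    if (p < 0 || p > 1) stop_config("probabilities must lie in [0, 1]")
  }
  structure(list(n_lnc = as.integer(n_lnc), n_mi = as.integer(n_mi),
                 n_mr = as.integer(n_mr), n_dis = as.integer(n_dis),
                 n_modules = as.integer(n_modules), p_intra = p_intra,
                 p_noise = p_noise, n_pos = as.integer(n_pos),
                 signal = signal, seed = as.integer(seed)),
            class = "synth_config")
}

#' Named benchmark presets
#'
#' `"dataset1"` mirrors the scale of the curated ceRNA--disease compendium
#' used as the method's reference corpus (218 lncRNAs, 605 miRNAs, 1051
#' mRNAs, 314 diseases, 2115 associations). `"mid"` is a desk-scale
#' benchmark for end-to-end runs and `"tiny"` a unit-test scale.
#'
#' @param preset one of `"dataset1"`, `"mid"`, `"tiny"`.
#' @param seed integer seed.
#' @return A [synth_config()].
#' @export
synth_preset <- function(preset = c("mid", "tiny", "dataset1"), seed = 0L) {
  preset <- match.arg(preset)
  switch(preset,
    dataset1 = synth_config(seed = seed),
    mid = synth_config(n_lnc = 60L, n_mi = 120L, n_mr = 180L, n_dis = 40L,
                       n_modules = 6L, p_intra = 0.15, p_noise = 0.005,
                       n_pos = 400L, signal = 0.9, seed = seed),
    tiny = synth_config(n_lnc = 20L, n_mi = 40L, n_mr = 60L, n_dis = 15L,
                        n_modules = 3L, p_intra = 0.3, p_noise = 0.02,
                        n_pos = 60L, signal = 0.9, seed = seed)
  )
}

# vectorized Bernoulli edge draw between two node sets with module structure
draw_pairs <- function(ids_a, ids_b, mod_a, mod_b, p_same, p_diff) {
  same <- outer(mod_a, mod_b, "==")
  p <- ifelse(same, p_same, p_diff)
  hit <- which(matrix(runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
  data.frame(source = ids_a[hit[, 1]], target = ids_b[hit[, 2]],
             stringsAsFactors = FALSE)
}

#' Generate a random disease ontology forest
#'
#' One root per module with a random tree beneath: each non-root disease
#' attaches to a uniformly chosen earlier disease of its module, so every
#' disease is reachable from its module root and the structure is acyclic.
#' Same-module diseases therefore share ancestry (high semantic similarity)
#' while cross-module pairs share none.
#'
#' @param n_dis number of diseases.
#' @param n_modules number of modules (roots).
#' @param seed integer seed.
#' @param ids optional disease ids (default `dis1..disN`).
#' @param modules optional module label per disease; default assigns
#'   round-robin.
#' @param mu contribution factor of the DAG.
#' @return List with `dag` (a [disease_dag()]) and `modules` (named labels).
#' @export
generate_disease_dag <- function(n_dis, n_modules, seed = 0L, ids = NULL,
                                 modules = NULL, mu = 0.5) {
  if (n_dis < n_modules) stop_config("n_dis must be >= n_modules")
  set.seed(derive_seed(seed, "disease-dag"))
  if (is.null(ids)) ids <- paste0("dis", seq_len(n_dis))
  if (is.null(modules)) {
    modules <- setNames(rep_len(seq_len(n_modules), n_dis), ids)
  }
  edges <- list()
  for (m in unique(modules)) {
    members <- ids[modules == m]
    if (length(members) < 2) next
    parent_pick <- vapply(seq_along(members)[-1], function(i) {
      members[sample.int(i - 1L, 1L)]
    }, "")
    edges[[as.character(m)]] <- data.frame(parent = parent_pick,
                                           child = members[-1],
                                           stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parent = character(), child = character())
  list(dag = disease_dag(edges, nodes = ids, mu = mu),
       modules = modules)
}

#' Generate a seeded synthetic ceRNA--disease benchmark
#'
#' Partitions nodes of every type into modules, draws lnc--mi and mi--mr
#' interactions with probability `p_intra` within a module and `p_noise`
#' across, sparse background lnc--mr and RNA--disease edges with `p_noise`,
#' and plants `n_pos` positive triplet--disease associations: each positive
#' is a structurally valid triplet (both interactions exist, shared miRNA)
#' paired -- with probability `signal` -- with a disease from the miRNA's
#' module, otherwise with a uniformly random disease. A module-aligned
#' disease ontology is generated alongside. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()] or preset name for [synth_preset()].
#' @return A `benchmark_bundle`: list with `graph` ([hetero_graph()]),
#'   `positives` (data.frame `lnc`, `mi`, `mr`, `dis`, `label` = 1), `dag`,
#'   `modules` (named module label per node) and `config`.
#' @export
generate_benchmark <- function(cfg = synth_preset("mid")) {
  if (is.character(cfg)) cfg <- synth_preset(cfg)
  set.seed(derive_seed(cfg$seed, "benchmark"))
  ids <- list(lnc = paste0("lnc", seq_len(cfg$n_lnc)),
              mi = paste0("mi", seq_len(cfg$n_mi)),
              mr = paste0("mr", seq_len(cfg$n_mr)),
              dis = paste0("dis", seq_len(cfg$n_dis)))
  # round-robin then shuffled module labels guarantee every module is
  # populated in every type
  mods <- lapply(ids, function(v) {
    setNames(sample(rep_len(seq_len(cfg$n_modules), length(v))), v)
  })

  lnc_mi <- draw_pairs(ids$lnc, ids$mi, mods$lnc, mods$mi,
                       cfg$p_intra, cfg$p_noise)
  mi_mr <- draw_pairs(ids$mi, ids$mr, mods$mi, mods$mr,
                      cfg$p_intra, cfg$p_noise)
  lnc_mr <- draw_pairs(ids$lnc, ids$mr, mods$lnc, mods$mr,
                       cfg$p_noise, cfg$p_noise)
  lnc_dis <- draw_pairs(ids$lnc, ids$dis, mods$lnc, mods$dis,
                        cfg$p_noise, cfg$p_noise)
  mi_dis <- draw_pairs(ids$mi, ids$dis, mods$mi, mods$dis,
                       cfg$p_noise, cfg$p_noise)
  mr_dis <- draw_pairs(ids$mr, ids$dis, mods$mr, mods$dis,
                       cfg$p_noise, cfg$p_noise)
  tag <- function(df, rel) { df$relation <- rep(rel, nrow(df)); df }
  edges <- rbind(
    tag(lnc_mi, "lnc-mi"), tag(lnc_mr, "lnc-mr"), tag(lnc_dis, "lnc-dis"),
    tag(mi_mr, "mi-mr"), tag(mi_dis, "mi-dis"), tag(mr_dis, "mr-dis"))
  hg <- hetero_graph(ids, edges)

  lnc_by_mi <- split(lnc_mi$source, lnc_mi$target)
  mr_by_mi <- split(mi_mr$target, mi_mr$source)
  eligible_mi <- intersect(names(lnc_by_mi), names(mr_by_mi))
  if (!length(eligible_mi)) {
    stop_config("no miRNA has both lncRNA and mRNA partners; raise p_intra")
  }
  dis_by_mod <- split(ids$dis, mods$dis)

  got <- 0L; tries <- 0L
  max_tries <- 200L * cfg$n_pos
  seen <- character(0)
  out <- vector("list", cfg$n_pos)
  while (got < cfg$n_pos) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_config("n_pos = %d appears infeasible for this configuration (planted %d)",
                  cfg$n_pos, got)
    }
    mi <- eligible_mi[sample.int(length(eligible_mi), 1L)]
    lncs <- lnc_by_mi[[mi]]; mrs <- mr_by_mi[[mi]]
    lnc <- lncs[sample.int(length(lncs), 1L)]
    mr <- mrs[sample.int(length(mrs), 1L)]
    if (runif(1) < cfg$signal) {
      pool <- dis_by_mod[[as.character(mods$mi[mi])]]
      dis <- pool[sample.int(length(pool), 1L)]
    } else {
      dis <- ids$dis[sample.int(cfg$n_dis, 1L)]
    }
    key <- paste(lnc, mi, mr, dis, sep = "\r")
    if (key %in% seen) next
    got <- got + 1L
    seen <- c(seen, key)
    out[[got]] <- data.frame(lnc = lnc, mi = mi, mr = mr, dis = dis,
                             stringsAsFactors = FALSE)
  }
  positives <- cbind(do.call(rbind, out), label = 1L)

  dag_out <- generate_disease_dag(cfg$n_dis, cfg$n_modules, seed = cfg$seed,
                                  ids = ids$dis, modules = mods$dis)
  structure(list(graph = hg, positives = positives, dag = dag_out$dag,
                 modules = unlist(unname(mods)), config = cfg),
            class = "benchmark_bundle")
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat("benchmark_bundle\n")
  print(x$graph)
  cat(sprintf("  %d positive triplet-disease associations, %d modules, signal %.2f, seed %d\n",
              nrow(x$positives), x$config$n_modules, x$config$signal,
              x$config$seed))
  invisible(x)
}

#' Interaction edge lists of a benchmark bundle
#'
#' Convenience accessor returning the validated lnc--mi and mi--mr
#' interaction lists in the column layout the negative sampler consumes.
#'
#' @param bundle a [generate_benchmark()] result.
#' @return List with data.frames `lnc_mi` (`lnc`, `mi`) and `mi_mr`
#'   (`mi`, `mr`).
#' @export
interaction_lists <- function(bundle) {
  e <- bundle$graph$edges
  lm <- e[e$relation == "lnc-mi", ]
  mm <- e[e$relation == "mi-mr", ]
  list(lnc_mi = data.frame(lnc = lm$source, mi = lm$target,
                           stringsAsFactors = FALSE),
       mi_mr = data.frame(mi = mm$source, mr = mm$target,
                          stringsAsFactors = FALSE))
}
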