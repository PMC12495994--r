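#' Pipeline configuration
#'
#' Bundles the stage configurations of the full prediction pipeline and the
#' ablation switches: `attention` toggles the triangle-shared attention
#' augmentation of the similarity blocks, `higher_order` toggles the
#' triangle co-occurrence second layer (off replaces `A_h` with the
#' identity, i.e. a plain one-layer GCN), and `sampler` selects the
#' structure-consistent or the uniform random negative sampler.
#'
#' @param walk a [walk_config()] for the embedding corpus.
#' @param train a [train_config()] for the GCN.
#' @param tau support-graph similarity threshold in `[0, 1]`.
#' @param sgns_dim,sgns_window,sgns_K,sgns_epochs skip-gram settings.
#' @param attention_dim feature dimension of the random attention inputs.
#' @param attention,higher_order logical ablation switches.
#' @param sampler `"structured"` or `"random"`.
#' @param classifier `"gbt"` or `"logistic"` head.
#' @param seed integer global seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(walk = walk_config(walk_length = 40,
                                               walks_per_node = 10),
                            train = train_config(),
                            tau = 0.5,
                            sgns_dim = 64L, sgns_window = 5L, sgns_K = 5L,
                            sgns_epochs = 3L,
                            attention_dim = 32L,
                            attention = TRUE, higher_order = TRUE,
                            sampler = c("structured", "random"),
                            classifier = c("gbt", "logistic"),
                            seed = 0L) {
  sampler <- match.arg(sampler)
  classifier <- match.arg(classifier)
  structure(list(walk = walk, train = train, tau = tau,
                 sgns_dim = as.integer(sgns_dim),
                 sgns_window = as.integer(sgns_window),
                 sgns_K = as.integer(sgns_K),
                 sgns_epochs = as.integer(sgns_epochs),
                 attention_dim = as.integer(attention_dim),
                 attention = attention, higher_order = higher_order,
                 sampler = sampler, classifier = classifier,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# add RNA-disease association edges implied by a set of positive samples
graph_with_positive_edges <- function(hg, positives) {
  derived <- rbind(
    data.frame(source = positives$lnc, target = positives$dis,
               relation = "lnc-dis", stringsAsFactors = FALSE),
    data.frame(source = positives$mi, target = positives$dis,
               relation = "mi-dis", stringsAsFactors = FALSE),
    data.frame(source = positives$mr, target = positives$dis,
               relation = "mr-dis", stringsAsFactors = FALSE))
  edges <- rbind(hg$edges, derived)
  edges <- edges[!duplicated(paste(edges$source, edges$target, edges$relation)), ]
  hetero_graph(hg$nodes, edges)
}

#' Build the network representation for a training split
#'
#' Runs the similarity and adjacency construction stages on the association
#' graph induced by the background interactions plus the *training*
#' positives (test associations never enter the graph): random-walk
#' embeddings and per-type cosine similarity, disease semantic/GIP
#' similarity, support graph, triangles, attention augmentation, and the
#' enhanced and higher-order adjacency matrices.
#'
#' @param bundle a [generate_benchmark()] bundle (or an equivalent list
#'   with `graph`, `dag`).
#' @param train_pos data.frame of training positives.
#' @param cfg a [pipeline_config()].
#' @return List with `graph`, `R`, `Ae`, `Ah`, `sims`, `A_D`, `support`,
#'   `triangles`, `attention`.
#' @export
build_network <- function(bundle, train_pos, cfg = pipeline_config()) {
  hg <- graph_with_positive_edges(bundle$graph, train_pos)
  g <- association_igraph(hg)

  wcfg <- cfg$walk
  wcfg$seed <- derive_seed(cfg$seed, "walks")
  walks <- generate_walks(g, wcfg)
  emb <- train_node_embeddings(walks, g, dim = cfg$sgns_dim,
                               window = cfg$sgns_window, K = cfg$sgns_K,
                               epochs = cfg$sgns_epochs,
                               seed = derive_seed(cfg$seed, "sgns"))

  sims <- list()
  for (ty in c("lnc", "mi", "mr")) {
    net_sim <- cosine_similarity_matrix(emb, hg$nodes[[ty]])
    sims[[ty]] <- assemble_rna_similarity(net_sim)
  }
  # disease block: ontology semantic similarity with GIP kernel fallback,
  # profiles taken over RNA partners in the training graph
  R <- build_association_matrix(hg)
  idx <- block_indices(hg)
  dis_profiles <- as.matrix(R[idx$dis, -idx$dis, drop = FALSE])
  rownames(dis_profiles) <- hg$nodes$dis
  sims$dis <- assemble_disease_similarity(bundle$dag, dis_profiles,
                                          diseases = hg$nodes$dis)

  support <- build_support_graph(hg, sims, tau = cfg$tau)
  triangles <- enumerate_triangles(support)

  aug <- sims
  attn <- NULL
  if (cfg$attention) {
    set.seed(derive_seed(cfg$seed, "attention-features"))
    feats <- matrix(rnorm(n_nodes(hg) * cfg$attention_dim),
                    n_nodes(hg), cfg$attention_dim,
                    dimnames = list(names(hg$index), NULL))
    ap <- attention_params(cfg$attention_dim,
                           seed = derive_seed(cfg$seed, "attention-params"))
    attn <- attention_coefficients(feats, support, ap)
    attn <- share_triangle_attention(attn, triangles)
    for (ty in NODE_TYPES) {
      aug[[ty]] <- augment_similarity(sims[[ty]], attn)
    }
  }
  Ae <- build_enhanced_adjacency(R, aug, hg)
  Ah <- if (cfg$higher_order) {
    build_higher_order_adjacency(R, higher_order_blocks(triangles, hg), hg)
  } else {
    di <- Matrix::Diagonal(n_nodes(hg))
    dimnames(di) <- dimnames(R)
    di
  }
  list(graph = hg, R = R, Ae = Ae, Ah = Ah, sims = sims, A_D = sims$dis,
       support = support, triangles = triangles, attention = attn)
}

split_holdout <- function(n, train_ratio, seed) {
  set.seed(derive_seed(seed, "holdout-split"))
  n_train <- max(1L, round(train_ratio * n))
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(n_train)]),
       test = sort(idx[-seq_len(n_train)]))
}

draw_negatives <- function(bundle, positives, n, cfg, seed_label,
                           sampler = cfg$sampler) {
  if (sampler == "structured") {
    il <- interaction_lists(bundle)
    sample_negatives(positives, il$lnc_mi, il$mi_mr,
                     bundle$graph$nodes$dis, n,
                     seed = derive_seed(cfg$seed, seed_label))
  } else {
    sample_negatives_random(positives, bundle$graph, n,
                            seed = derive_seed(cfg$seed, seed_label))
  }
}

#' Run the full prediction pipeline on a benchmark
#'
#' Splits the positives into train/test, builds the network representation
#' from background interactions plus training positives only, samples 1:1
#' negatives, trains the higher-order GCN, fits the classifier head on the
#' concatenated triplet/disease embeddings and evaluates on the held-out
#' samples.
#'
#' @param bundle a [generate_benchmark()] bundle.
#' @param cfg a [pipeline_config()].
#' @param permute_labels logical; permute the training labels (negative
#'   control -- held-out performance should fall to chance).
#' @return List with `metrics` (a [evaluate()] report), `scores`, `test`
#'   (the held-out samples), `fit`, `net`, `train` (the training samples)
#'   and `cfg`.
#' @export
run_pipeline <- function(bundle, cfg = pipeline_config(),
                         permute_labels = FALSE) {
  pos <- bundle$positives
  sp <- split_holdout(nrow(pos), cfg$train$train_ratio, cfg$seed)
  train_pos <- pos[sp$train, , drop = FALSE]
  test_pos <- pos[sp$test, , drop = FALSE]

  net <- build_network(bundle, train_pos, cfg)

  # evaluation protocol is fixed: held-out negatives always come from the
  # structure-consistent sampler, so ablating the training-time sampler
  # changes the training signal, never the difficulty of the test set
  neg_all <- draw_negatives(bundle, pos, nrow(pos), cfg, "negatives",
                            sampler = "structured")
  train_neg <- neg_all[sp$train, , drop = FALSE]
  test_neg <- neg_all[sp$test, , drop = FALSE]
  if (cfg$sampler != "structured") {
    train_neg <- draw_negatives(bundle, pos, length(sp$train), cfg,
                                "train-negatives")
  }

  train_samples <- rbind(cbind(train_pos[c("lnc", "mi", "mr", "dis")], label = 1L),
                         cbind(train_neg[c("lnc", "mi", "mr", "dis")], label = 0L))
  if (permute_labels) {
    set.seed(derive_seed(cfg$seed, "label-permutation"))
    train_samples$label <- sample(train_samples$label)
  }
  tr_pos <- train_samples[train_samples$label == 1L, , drop = FALSE]
  tr_neg <- train_samples[train_samples$label == 0L, , drop = FALSE]

  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cfg$seed, "gcn")
  fit <- train_model(net$Ae, net$Ah, tr_pos, tr_neg, tcfg)

  test_samples <- rbind(cbind(test_pos[c("lnc", "mi", "mr", "dis")], label = 1L),
                        cbind(test_neg[c("lnc", "mi", "mr", "dis")], label = 0L))
  ftr <- assemble_features(fit, train_samples)
  fte <- assemble_features(fit, test_samples)
  scores <- fit_predict_classifier(ftr, fte, kind = cfg$classifier,
                                   seed = derive_seed(cfg$seed, "classifier"))
  metrics <- evaluate(scores, test_samples$label)
  list(metrics = metrics, scores = scores, test = test_samples, fit = fit,
       net = net, train = train_samples, cfg = cfg)
}

#' Repeated-holdout evaluation
#'
#' Repeats the holdout pipeline with re-derived split/sampler seeds and
#' reports the mean and standard deviation of every metric.
#'
#' @param bundle a [generate_benchmark()] bundle.
#' @param cfg a [pipeline_config()].
#' @param repeats number of repetitions.
#' @return List with `runs` (data.frame of per-run metrics) and `summary`
#'   (data.frame of metric, mean, sd).
#' @export
repeated_holdout <- function(bundle, cfg = pipeline_config(), repeats = 30L) {
  metrics <- c("auc_roc", "auc_pr", "accuracy", "precision", "recall", "f1")
  runs <- lapply(seq_len(repeats), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, paste0("repeat-", r))
    res <- run_pipeline(bundle, cfg_r)
    as.data.frame(res$metrics[metrics])
  })
  runs <- cbind(repeat_ = seq_len(repeats), do.call(rbind, runs))
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(runs[[m]]), 1.0),
    sd = vapply(metrics, function(m) stats::sd(runs[[m]]), 1.0),
    row.names = NULL)
  list(runs = runs, summary = summary)
}

#' Cross-validated evaluation
#'
#' k-fold evaluation over the positive associations with 1:1 negatives.
#' In `disease_stratified` mode the folds partition diseases, so the test
#' diseases of each fold are disjoint from its training diseases (cold
#' start); the assertion is checked on every fold.
#'
#' @param bundle a [generate_benchmark()] bundle.
#' @param cfg a [pipeline_config()].
#' @param k number of folds.
#' @param mode `"random"` or `"disease_stratified"`.
#' @return List with `results` (long-format data.frame: fold, metric,
#'   value), `folds` (the assignment) and `fold_similarity` (a
#'   [fold_similarity_analysis()] on the disease block of the last fold's
#'   network).
#' @export
cross_validate <- function(bundle, cfg = pipeline_config(), k = 5L,
                           mode = c("random", "disease_stratified")) {
  mode <- match.arg(mode)
  pos <- bundle$positives
  folds <- make_folds(pos, k = k, mode = mode,
                      seed = derive_seed(cfg$seed, "cv"))
  # test negatives come from the fixed structured protocol (see run_pipeline)
  neg_all <- draw_negatives(bundle, pos, nrow(pos), cfg, "cv-negatives",
                            sampler = "structured")
  metrics <- c("auc_roc", "auc_pr", "accuracy", "precision", "recall", "f1")
  rows <- list()
  A_D <- NULL
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_pos <- pos[-test_idx, , drop = FALSE]
    test_pos <- pos[test_idx, , drop = FALSE]
    if (mode == "disease_stratified") {
      stopifnot(length(intersect(unique(train_pos$dis),
                                 unique(test_pos$dis))) == 0)
    }
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(cfg$seed, paste0("cv-fold-", f))
    net <- build_network(bundle, train_pos, cfg_f)
    tcfg <- cfg_f$train
    tcfg$seed <- derive_seed(cfg_f$seed, "gcn")
    train_neg <- if (cfg$sampler == "structured") {
      neg_all[-test_idx, , drop = FALSE]
    } else {
      draw_negatives(bundle, pos, nrow(train_pos), cfg_f, "cv-train-negatives")
    }
    fit <- train_model(net$Ae, net$Ah,
                       train_pos[c("lnc", "mi", "mr", "dis")],
                       train_neg[c("lnc", "mi", "mr", "dis")],
                       tcfg)
    train_samples <- rbind(cbind(train_pos[c("lnc", "mi", "mr", "dis")], label = 1L),
                           cbind(train_neg[c("lnc", "mi", "mr", "dis")], label = 0L))
    test_samples <- rbind(cbind(test_pos[c("lnc", "mi", "mr", "dis")], label = 1L),
                          cbind(neg_all[test_idx, c("lnc", "mi", "mr", "dis")], label = 0L))
    scores <- fit_predict_classifier(assemble_features(fit, train_samples),
                                     assemble_features(fit, test_samples),
                                     kind = cfg$classifier,
                                     seed = derive_seed(cfg_f$seed, "classifier"))
    rep <- evaluate(scores, test_samples$label)
    rows[[f]] <- data.frame(fold = f, metric = metrics,
                            value = unlist(rep[metrics], use.names = FALSE))
    A_D <- net$A_D
  }
  list(results = do.call(rbind, rows), folds = folds,
       fold_similarity = fold_similarity_analysis(A_D, pos, folds))
}
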