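#' Assemble per-sample feature vectors
#'
#' Each row is the concatenation of the triplet embedding and the disease
#' embedding (width `2 d`), in sample order.
#'
#' @param fit a trained model from [train_model()] (or any list with
#'   `embeddings`, `params`, `cfg`).
#' @param samples data.frame with columns `lnc`, `mi`, `mr`, `dis` and
#'   optionally `label`.
#' @return List with `x` (feature matrix) and `y` (labels or `NULL`).
#' @export
assemble_features <- function(fit, samples) {
  H <- fit$embeddings
  refs <- unique(c(samples$lnc, samples$mi, samples$mr, samples$dis))
  missing <- setdiff(refs, rownames(H))
  if (length(missing)) {
    stop_config("missing embedding for: %s", paste(head(missing, 5), collapse = ", "))
  }
  if (nrow(samples) == 0) {
    return(list(x = matrix(0, 0, 2 * ncol(H)), y = NULL))
  }
  T <- triplet_embedding(H[samples$lnc, , drop = FALSE],
                         H[samples$mi, , drop = FALSE],
                         H[samples$mr, , drop = FALSE],
                         params = fit$params, mode = fit$cfg$triplet_mode,
                         leaky_slope = fit$cfg$leaky_slope)
  x <- unname(cbind(T, H[samples$dis, , drop = FALSE]))
  list(x = x, y = if ("label" %in% names(samples)) samples$label else NULL)
}

#' Fit a classifier head and score test samples
#'
#' `kind = "gbt"` fits a gradient boosted tree ensemble (200 trees, depth 6,
#' learning rate 0.05, single thread for determinism); `kind = "logistic"`
#' fits a plain logistic regression. Scores are association probabilities.
#'
#' @param train list with `x`, `y` from [assemble_features()].
#' @param test list with `x` from [assemble_features()].
#' @param kind `"gbt"` or `"logistic"`.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta boosted-tree hyperparameters.
#' @return Numeric score vector in `[0, 1]`, one per test row.
#' @export
fit_predict_classifier <- function(train, test, kind = c("gbt", "logistic"),
                                   seed = 1L, nrounds = 200L, max_depth = 6L,
                                   eta = 0.05) {
  kind <- match.arg(kind)
  if (length(unique(train$y)) < 2) {
    stop_config("training set must contain both classes")
  }
  if (kind == "gbt") {
    set.seed(derive_seed(seed, "gbt"))
    dtrain <- xgboost::xgb.DMatrix(train$x, label = train$y)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = derive_seed(seed, "gbt")),
      data = dtrain, nrounds = nrounds, verbose = 0)
    as.numeric(predict(booster, xgboost::xgb.DMatrix(test$x)))
  } else {
    df_tr <- data.frame(y = train$y, train$x)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                       family = stats::binomial()))
    df_te <- data.frame(test$x)
    colnames(df_te) <- colnames(df_tr)[-1]
    as.numeric(suppressWarnings(predict(fit, df_te, type = "response")))
  }
}

#' AUC-ROC by the rank formula
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, with ties counted one half (Mann--Whitney statistic).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_config("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC-PR by step-wise integration
#'
#' Area under the precision--recall curve computed by summing precision over
#' each recall increment of the score-sorted sample sequence (no
#' interpolation); tied scores are processed as one block.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in `[0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop_config("AUC-PR needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # aggregate tied scores into blocks
  blocks <- split(seq_along(s), match(s, unique(s)))
  tp <- 0; fp <- 0; area <- 0
  for (b in blocks) {
    tp_new <- tp + sum(y[b] == 1)
    fp_new <- fp + sum(y[b] == 0)
    if (tp_new > tp) {
      prec <- tp_new / (tp_new + fp_new)
      area <- area + prec * (tp_new - tp) / n1
    }
    tp <- tp_new; fp <- fp_new
  }
  area
}

#' Threshold metrics and a full metrics report
#'
#' Computes AUC-ROC (rank formula) and AUC-PR (step integration); when
#' `threshold` is `NULL`, selects the score threshold maximizing F1 over the
#' unique score values, then reports accuracy, precision, recall and F1 at
#' the chosen threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels (both classes required).
#' @param threshold decision threshold, or `NULL` to pick the F1 optimum.
#' @return A `metrics_report` list: `auc_roc`, `auc_pr`, `accuracy`,
#'   `precision`, `recall`, `f1`, `threshold`, `n_pos`, `n_neg`.
#' @export
evaluate <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_config("evaluation needs both classes")
  if (is.null(threshold)) {
    cands <- unique(sort(scores))
    f1s <- vapply(cands, function(th) threshold_f1(scores, labels, th), 1.0)
    threshold <- cands[which.max(f1s)]
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(
    auc_roc = auc_roc(scores, labels),
    auc_pr = auc_pr(scores, labels),
    accuracy = mean(pred == labels),
    precision = precision, recall = recall, f1 = f1,
    threshold = threshold,
    n_pos = sum(labels == 1), n_neg = sum(labels == 0)
  ), class = "metrics_report")
}

threshold_f1 <- function(scores, labels, th) {
  pred <- as.integer(scores >= th)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("AUC-ROC %.4f | AUC-PR %.4f | ACC %.4f | P %.4f | ",
                     "R %.4f | F1 %.4f (threshold %.3f; %d pos / %d neg)\n"),
              x$auc_roc, x$auc_pr, x$accuracy, x$precision, x$recall, x$f1,
              x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

#' Cross-validation fold assignment
#'
#' `mode = "random"` shuffles samples into `k` near-equal folds.
#' `mode = "disease_stratified"` partitions *diseases* into `k` groups by a
#' greedy largest-first bin packing on sample counts, and every sample
#' follows its disease, so no disease id ever spans two folds -- the
#' cold-start protocol where test diseases are unseen in training.
#'
#' @param samples data.frame with a `dis` column.
#' @param k number of folds (>= 2).
#' @param mode `"random"` or `"disease_stratified"`.
#' @param seed integer seed.
#' @return A `fold_assignment`: integer vector of fold indices (1..k) per
#'   sample, with attributes `mode` and `k`.
#' @export
make_folds <- function(samples, k = 5L, mode = c("random", "disease_stratified"),
                       seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(samples)
  if (k < 2) stop_config("k must be >= 2")
  set.seed(derive_seed(seed, paste0("folds-", mode)))
  if (mode == "random") {
    fold <- sample(rep(seq_len(k), length.out = n))
  } else {
    counts <- sort(table(samples$dis), decreasing = TRUE)
    if (length(counts) < k) stop_config("need at least k distinct diseases")
    # shuffle within equal counts so ties break by seed, then greedy pack
    ord <- order(-as.integer(counts), sample.int(length(counts)))
    counts <- counts[ord]
    load <- numeric(k)
    group <- integer(length(counts))
    for (i in seq_along(counts)) {
      g <- which.min(load)
      group[i] <- g
      load[g] <- load[g] + counts[i]
    }
    names(group) <- names(counts)
    fold <- unname(group[samples$dis])
  }
  structure(fold, mode = mode, k = as.integer(k), class = "fold_assignment")
}

#' Intra- vs inter-fold disease similarity distributions
#'
#' Splits all unordered sample pairs by whether the two samples share a
#' fold and returns the distributions of their disease similarities with
#' the two means. Under disease-stratified folding, samples of one disease
#' always share a fold, so the intra-fold distribution picks up the
#' within-disease (and, on module-clustered data, within-module) mass and
#' its mean exceeds the inter-fold mean.
#'
#' @param A_D disease similarity matrix (dimnames = disease ids).
#' @param samples data.frame with `dis` column the folds refer to.
#' @param folds a [make_folds()] assignment for `samples`.
#' @return List with `intra`, `inter` (numeric vectors) and `mean_intra`,
#'   `mean_inter`.
#' @export
fold_similarity_analysis <- function(A_D, samples, folds) {
  missing <- setdiff(unique(samples$dis), rownames(A_D))
  if (length(missing)) stop_config("similarity matrix misses %d disease(s)", length(missing))
  s <- A_D[samples$dis, samples$dis, drop = FALSE]
  f <- as.integer(folds)
  same <- outer(f, f, "==")
  ut <- upper.tri(s)
  intra <- s[ut & same]
  inter <- s[ut & !same]
  list(intra = intra, inter = inter,
       mean_intra = if (length(intra)) mean(intra) else NA_real_,
       mean_inter = if (length(inter)) mean(inter) else NA_real_)
}

#' Network topology metrics
#'
#' Means over nodes of eigenvector centrality (principal eigenvector of the
#' adjacency by power iteration, L2-normalized), closeness centrality with
#' per-component normalization (Wasserman--Faust: `((n_c - 1) / (n - 1)) *
#' ((n_c - 1) / sum of distances)` within each component, 0 for isolated
#' nodes) and degree centrality (`degree / (n - 1)`).
#'
#' @param g an undirected igraph with at least 2 nodes.
#' @param iter,tol power-iteration budget and convergence tolerance.
#' @return List with `aec`, `acc`, `adc`.
#' @export
topology_metrics <- function(g, iter = 1000L, tol = 1e-8) {
  n <- igraph::vcount(g)
  if (n < 2) stop_config("graph needs at least 2 nodes")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  # eigenvector centrality: power iteration with the +I shift (same principal
  # eigenvector, but convergent on bipartite graphs where plain iteration
  # oscillates between the +/- lambda eigenpair), L2 unit norm
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(iter)) {
    x_new <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) { x <- rep(0, n); break }
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  aec <- mean(abs(x))
  # closeness, component-normalized
  dmat <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    dd <- dmat[i, ]
    reach <- is.finite(dd) & seq_len(n) != i
    nc <- sum(reach)
    if (nc == 0) return(0)
    (nc / (n - 1)) * (nc / sum(dd[reach]))
  }, 1.0)
  acc <- mean(clo)
  adc <- mean(igraph::degree(g) / (n - 1))
  list(aec = aec, acc = acc, adc = adc)
}

#' Welch two-sample significance test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-sided p-value, for comparing per-run AUC distributions
#' of two methods. Degenerate zero-variance groups with equal means return
#' `t = 0, p = 1` by convention.
#'
#' @param a,b numeric vectors of per-run metric values (length >= 2 each).
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_significance <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_config("need >= 2 runs per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_, p_value = 0))
  }
  ht <- stats::t.test(a, b)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Rank candidate predictions
#'
#' Sorts scored (triplet, disease) candidates by decreasing score, breaking
#' ties lexicographically on (lnc, mi, mr, dis), and returns the top `k`.
#'
#' @param candidates data.frame with columns `lnc`, `mi`, `mr`, `dis`,
#'   `score`; must already exclude training positives.
#' @param disease optional disease id to restrict the ranking to.
#' @param k maximum list length.
#' @return data.frame of at most `k` rows in rank order.
#' @export
rank_predictions <- function(candidates, disease = NULL, k = 20L) {
  df <- candidates
  if (!is.null(disease)) df <- df[df$dis == disease, , drop = FALSE]
  ord <- order(-df$score, df$lnc, df$mi, df$mr, df$dis)
  out <- df[head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
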