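fake_fit <- function(ids, d = 2, seed = 1) {
  set.seed(seed)
  H <- matrix(rnorm(length(ids) * d), length(ids), d,
              dimnames = list(ids, NULL))
  list(embeddings = H, params = NULL,
       cfg = list(triplet_mode = "weighted", leaky_slope = 0.2))
}

test_that("feature assembly concatenates triplet and disease embeddings in order", {
  fit <- fake_fit(c("l1", "m1", "r1", "d1"))
  H <- fit$embeddings
  s <- data.frame(lnc = "l1", mi = "m1", mr = "r1", dis = "d1", label = 1L)
  ft <- assemble_features(fit, s)
  expect_equal(dim(ft$x), c(1L, 4L))
  expect_equal(ft$x[1, ], c(colMeans(H[c("l1", "m1", "r1"), ]), H["d1", ]))
  expect_equal(ft$y, 1L)
  # explicit concatenation check with hand-built embeddings
  fit2 <- fit
  fit2$embeddings <- rbind(l1 = c(1, 2), m1 = c(1, 2), r1 = c(1, 2),
                           d1 = c(3, 4))
  expect_equal(assemble_features(fit2, s)$x[1, ], c(1, 2, 3, 4))
  # empty sample list and order contract
  expect_equal(nrow(assemble_features(fit, s[0, ])$x), 0)
  s2 <- rbind(s, data.frame(lnc = "l1", mi = "m1", mr = "r1", dis = "d1",
                            label = 0L))
  perm <- assemble_features(fit, s2[2:1, ])
  expect_equal(perm$x, assemble_features(fit, s2)$x[2:1, , drop = FALSE])
  s_bad <- s; s_bad$dis <- "nope"
  expect_error(assemble_features(fit, s_bad), "missing")
})

test_that("classifier heads separate separable data and stay at chance on permuted labels", {
  set.seed(21)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  tr <- list(x = x[1:80, ], y = y[1:80])
  te <- list(x = x[81:n, ], y = y[81:n])
  sep_tr <- list(x = cbind(tr$y * 10 + rnorm(80, sd = 0.01), rnorm(80)), y = tr$y)
  sep_te <- list(x = cbind(te$y * 10 + rnorm(40, sd = 0.01), rnorm(40)), y = te$y)
  for (kind in c("gbt", "logistic")) {
    sc <- fit_predict_classifier(sep_tr, sep_te, kind = kind, seed = 1)
    expect_equal(auc_roc(sc, sep_te$y), 1)
    expect_true(all(sc >= 0 & sc <= 1))
  }
  # permuted labels give chance-level AUC on average
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    yp <- sample(tr$y)
    sc <- fit_predict_classifier(list(x = tr$x, y = yp), te, kind = "gbt",
                                 seed = s, nrounds = 30)
    auc_roc(sc, te$y)
  }, 1.0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
  # determinism
  s1 <- fit_predict_classifier(tr, te, kind = "gbt", seed = 9)
  s2 <- fit_predict_classifier(tr, te, kind = "gbt", seed = 9)
  expect_identical(s1, s2)
  expect_error(fit_predict_classifier(list(x = tr$x, y = rep(1, 80)), te),
               "both classes")
})

test_that("evaluation metrics match brute-force pair counting and the worked case", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_roc(scores, labels), oracle_auc(scores, labels))
  }
  # AUC-PR step integration equals a manual accumulation
  labels <- c(1, 0, 1, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  # sorted: precision at each positive: 1/1, 2/3, 3/4 ; each adds 1/3
  expect_equal(auc_pr(scores, labels), (1 + 2 / 3 + 3 / 4) / 3)
  rep <- evaluate(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(rep$auc_roc, 0.75)
  expect_true(all(unlist(rep[c("accuracy", "precision", "recall", "f1")]) >= 0))
  expect_true(all(unlist(rep[c("accuracy", "precision", "recall", "f1")]) <= 1))
  # threshold selection maximizes F1 over observed scores
  best <- max(vapply(unique(c(0.9, 0.8, 0.4, 0.1)),
                     function(th) ceRNAdis:::threshold_f1(c(0.9, 0.8, 0.4, 0.1),
                                                          c(1, 0, 1, 0), th), 1.0))
  expect_equal(rep$f1, best)
  # fixed threshold respected
  rep2 <- evaluate(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0), threshold = 0.55)
  expect_equal(rep2$threshold, 0.55)
  expect_error(evaluate(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("fold assignment contracts hold for both modes", {
  samples <- data.frame(dis = rep(paste0("d", 1:4), times = c(10, 9, 1, 6)))
  f <- make_folds(samples, k = 5, mode = "random", seed = 2)
  expect_equal(sort(as.integer(table(f))), c(5, 5, 5, 5, 6))
  expect_equal(length(f), nrow(samples))
  fs <- make_folds(samples, k = 2, mode = "disease_stratified", seed = 2)
  # each disease fully inside one fold
  per_dis <- tapply(as.integer(fs), samples$dis, function(x) length(unique(x)))
  expect_true(all(per_dis == 1))
  # greedy largest-first on counts (10, 9, 6, 1): 10 -> A, 9 -> B, 6 -> B
  # (lighter), 1 -> A, giving loads {11, 15}
  loads <- sort(as.integer(tapply(rep(1, nrow(samples)), fs, sum)))
  expect_equal(loads, c(11, 15))
  expect_error(make_folds(samples, k = 5, mode = "disease_stratified"),
               "diseases")
  # degenerate greedy case: counts (10, 9, 1) pack into loads {10} and {9, 1}
  s2 <- data.frame(dis = rep(c("a", "b", "c"), times = c(10, 9, 1)))
  f2 <- make_folds(s2, k = 2, mode = "disease_stratified", seed = 1)
  expect_setequal(as.integer(tapply(rep(1, 20), f2, sum)), c(10, 10))
})

test_that("fold similarity analysis separates intra from inter distributions", {
  A <- matrix(0.1, 4, 4, dimnames = list(paste0("d", 1:4), paste0("d", 1:4)))
  A[1:2, 1:2] <- 0.9; A[3:4, 3:4] <- 0.9; diag(A) <- 1
  samples <- data.frame(dis = paste0("d", 1:4))
  folds <- structure(c(1L, 1L, 2L, 2L), mode = "disease_stratified", k = 2L,
                     class = "fold_assignment")
  fs <- fold_similarity_analysis(A, samples, folds)
  expect_equal(fs$mean_intra, 0.9)
  expect_equal(fs$mean_inter, 0.1)
  expect_gt(fs$mean_intra, fs$mean_inter)
  # single fold -> empty inter distribution
  one <- structure(rep(1L, 4), mode = "random", k = 1L,
                   class = "fold_assignment")
  expect_length(fold_similarity_analysis(A, samples, one)$inter, 0)
  # brute-force double loop agreement on a random instance
  set.seed(13)
  n <- 8
  S <- matrix(runif(n * n), n, n,
              dimnames = list(paste0("x", 1:n), paste0("x", 1:n)))
  S <- (S + t(S)) / 2
  samples2 <- data.frame(dis = paste0("x", 1:n))
  f2 <- make_folds(samples2, k = 3, mode = "random", seed = 5)
  res <- fold_similarity_analysis(S, samples2, f2)
  manual_intra <- c(); manual_inter <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (f2[i] == f2[j]) manual_intra <- c(manual_intra, S[i, j])
    else manual_inter <- c(manual_inter, S[i, j])
  }
  expect_equal(sort(res$intra), sort(manual_intra))
  expect_equal(sort(res$inter), sort(manual_inter))
})

test_that("topology metrics match closed forms and brute-force oracles", {
  k4 <- igraph::make_full_graph(4)
  tm <- topology_metrics(k4)
  expect_equal(tm$adc, 1)
  expect_equal(tm$aec, 0.5)  # principal eigenvector of K4 is uniform, L2 unit
  star <- igraph::make_star(4, mode = "undirected")
  expect_equal(topology_metrics(star)$adc, (1 + 3 * (1 / 3)) / 4)
  for (rep in 1:50) {
    g <- random_graph(sample(4:30, 1), runif(1, 0.15, 0.5), seed = 300 + rep)
    tm <- topology_metrics(g)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    if (sum(A) == 0) next
    ev <- eigen(A, symmetric = TRUE)
    vals <- sort(ev$values, decreasing = TRUE)
    # a tied top eigenvalue (e.g. two disjoint edges) has no unique principal
    # eigenvector; the comparison is only defined in the generic case
    if (length(vals) > 1 && vals[1] - vals[2] < 1e-8) next
    v <- ev$vectors[, which.max(ev$values)]
    v <- abs(v) / sqrt(sum(v^2))
    expect_equal(tm$aec, mean(v), tolerance = 1e-5)
    n <- nrow(A)
    dmat <- igraph::distances(g)
    clo <- vapply(seq_len(n), function(i) {
      dd <- dmat[i, ]; reach <- is.finite(dd) & seq_len(n) != i
      nc <- sum(reach)
      if (nc == 0) 0 else (nc / (n - 1)) * (nc / sum(dd[reach]))
    }, 1.0)
    expect_equal(tm$acc, mean(clo), tolerance = 1e-10)
    expect_equal(tm$adc, mean(rowSums(A)) / (n - 1), tolerance = 1e-12)
  }
  expect_error(topology_metrics(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
})

test_that("Welch test matches the textbook formula and degenerate conventions", {
  same <- c(0.5, 0.5, 0.5)
  res <- welch_significance(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  a <- c(0.9, 0.91, 0.92); b <- c(0.7, 0.71, 0.72)
  res2 <- welch_significance(a, b)
  expect_lt(res2$p_value, 0.01)
  # hand Welch formula
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(res2$t, tstat)
  set.seed(17)
  for (rep in 1:100) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 2))
    res3 <- welch_significance(x, y)
    se2 <- var(x) / length(x) + var(y) / length(y)
    t_manual <- (mean(x) - mean(y)) / sqrt(se2)
    df_manual <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                          (var(y) / length(y))^2 / (length(y) - 1))
    p_manual <- 2 * stats::pt(-abs(t_manual), df_manual)
    expect_equal(res3$t, t_manual, tolerance = 1e-12)
    expect_equal(res3$p_value, p_manual, tolerance = 1e-12)
  }
  expect_error(welch_significance(1, c(1, 2)), "runs")
})

test_that("prediction ranking sorts by score with lexicographic tie-breaks", {
  cand <- data.frame(lnc = c("l2", "l1", "l1"), mi = c("m1", "m1", "m1"),
                     mr = c("r1", "r1", "r2"), dis = c("d1", "d1", "d2"),
                     score = c(0.5, 0.9, 0.5))
  top <- rank_predictions(cand, k = 2)
  expect_equal(top$lnc, c("l1", "l1"))
  expect_equal(top$score, c(0.9, 0.5))
  # k beyond the candidate count returns the full sorted list
  expect_equal(nrow(rank_predictions(cand, k = 10)), 3)
  # all-equal scores fall back to lexicographic order
  cand$score <- 0.5
  expect_equal(rank_predictions(cand, k = 3)$lnc, c("l1", "l1", "l2"))
  # random scores: prefix of a full sort
  set.seed(23)
  cand2 <- data.frame(lnc = sample(letters, 20, TRUE), mi = "m", mr = "r",
                      dis = sample(c("d1", "d2"), 20, TRUE),
                      score = runif(20))
  full <- rank_predictions(cand2, k = 20)
  expect_equal(rank_predictions(cand2, k = 5), full[1:5, ])
  expect_true(all(diff(full$score) <= 0))
  # disease restriction
  only_d1 <- rank_predictions(cand2, disease = "d1", k = 20)
  expect_true(all(only_d1$dis == "d1"))
})
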