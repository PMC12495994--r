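test_that("biased transition probabilities follow the p/q weighting", {
  path3 <- igraph::make_graph(~ a - b - c)
  # all weights equal when p = q = 1
  expect_equal(biased_transition_probs(path3, "a", "b", walk_config(p = 1, q = 1)),
               c(a = 0.5, c = 0.5))
  # d(prev, a) = 0 -> 1/p = 2; d(prev, c) = 2 -> 1/q = 0.5
  expect_equal(biased_transition_probs(path3, "a", "b", walk_config(p = 0.5, q = 2)),
               c(a = 0.8, c = 0.2))
  # in a triangle the non-prev candidate is at distance 1 -> weight 1
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  expect_equal(biased_transition_probs(tri, "a", "b", walk_config(p = 1, q = 1)),
               c(a = 0.5, c = 0.5))
  # walk start is uniform
  expect_equal(biased_transition_probs(path3, NULL, "b", walk_config(p = 9, q = 9)),
               c(a = 0.5, c = 0.5))
  # isolated node errors
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  iso <- igraph::set_vertex_attr(iso, "name", value = "x")
  expect_error(biased_transition_probs(iso, NULL, "x"), "isolated")
})

test_that("transition probabilities match the BFS-distance oracle on random graphs", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    g <- random_graph(n, runif(1, 0.1, 0.5), seed = rep)
    deg <- igraph::degree(g)
    cand <- which(deg > 0)
    if (!length(cand)) next
    curr <- igraph::V(g)$name[sample(cand, 1)]
    nbrs <- names(oracle_transition_probs(g, NULL, curr, 1, 1))
    prev <- sample(nbrs, 1)
    p <- runif(1, 0.25, 4); q <- runif(1, 0.25, 4)
    expect_equal(
      biased_transition_probs(g, prev, curr, walk_config(p = p, q = q)),
      oracle_transition_probs(g, prev, curr, p, q),
      tolerance = 1e-12)
  }
})

test_that("walk generation respects structure, determinism and the exact transition law", {
  edge <- igraph::make_graph(~ a - b)
  cfg <- walk_config(walk_length = 3, walks_per_node = 4, seed = 7)
  walks <- generate_walks(edge, cfg)
  expect_length(walks, 8)
  for (w in walks) {
    expect_true(identical(w, c("a", "b", "a")) || identical(w, c("b", "a", "b")))
  }
  expect_identical(generate_walks(edge, cfg), generate_walks(edge, cfg))
  expect_false(identical(generate_walks(edge, walk_config(walk_length = 3,
                                                          walks_per_node = 4,
                                                          seed = 8))[[1]],
                         NULL))

  # empirical next-step frequencies from (prev, curr) match the exact law
  g <- igraph::make_graph(~ a - b, b - c, b - d, a - c)
  cfg2 <- walk_config(p = 0.5, q = 2, walk_length = 3, walks_per_node = 5000,
                      seed = 11)
  walks <- generate_walks(g, cfg2)
  third <- vapply(Filter(function(w) w[1] == "a" && w[2] == "b", walks),
                  function(w) w[3], "")
  probs <- biased_transition_probs(g, "a", "b", cfg2)
  n <- length(third)
  for (nb in names(probs)) {
    phat <- mean(third == nb)
    se <- sqrt(probs[[nb]] * (1 - probs[[nb]]) / n)
    expect_lt(abs(phat - probs[[nb]]), 3 * se + 1e-9)
  }

  # isolated nodes yield length-1 walks
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  iso <- igraph::set_vertex_attr(iso, "name", value = c("x", "y"))
  expect_true(all(lengths(generate_walks(iso, cfg)) == 1))
})

test_that("skip-gram embeddings separate cliques, improve the objective and are reproducible", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))  # weak bridge keeps one component
  g <- igraph::set_vertex_attr(g, "name", value = paste0("n", 1:10))
  cfg <- walk_config(walk_length = 20, walks_per_node = 10, seed = 3)
  for (seed in 0:4) {
    walks <- generate_walks(g, walk_config(walk_length = 20, walks_per_node = 10,
                                           seed = seed))
    emb <- train_node_embeddings(walks, g, dim = 16, epochs = 3, seed = seed)
    expect_equal(dim(emb), c(10L, 16L))
    s <- cosine_similarity_matrix(emb)
    a <- 1:5; b <- 6:10
    intra <- c(s[a, a][upper.tri(s[a, a])], s[b, b][upper.tri(s[b, b])])
    inter <- as.vector(s[a, b])
    expect_gt(mean(intra), mean(inter))
  }
  # objective trends upward
  walks <- generate_walks(g, cfg)
  emb <- train_node_embeddings(walks, g, dim = 16, epochs = 6, seed = 1)
  obj <- attr(emb, "epoch_objective")
  expect_gt(mean(tail(obj, 2)), mean(head(obj, 2)))
  # byte-identical determinism
  emb2 <- train_node_embeddings(walks, g, dim = 16, epochs = 6, seed = 1)
  expect_identical(unclass(emb), unclass(emb2))
  expect_error(train_node_embeddings(walks, g, dim = 0), "positive")
})

test_that("negative-sampling noise frequencies follow degree^(3/4)", {
  degrees <- c(a = 1, b = 16, c = 81, d = 256)
  probs <- noise_distribution(degrees)
  expect_equal(unname(probs), unname(degrees^0.75 / sum(degrees^0.75)))
  draws <- ceRNAdis:::cpp_sample_noise(as.numeric(probs), 40000L, 5L)
  freq <- tabulate(draws, nbins = 4) / 40000
  for (i in 1:4) {
    se <- sqrt(probs[i] * (1 - probs[i]) / 40000)
    expect_lt(abs(freq[i] - probs[i]), 4 * se)
  }
})

test_that("cosine similarity matrix matches closed forms and contracts", {
  emb <- toy_embedding()
  s <- cosine_similarity_matrix(emb)
  expect_equal(s["a", "b"], 0)            # orthogonal
  expect_equal(s["a", "d"], 1)            # same direction
  expect_equal(s["c", "a"], 1 / sqrt(2))  # (1,1) vs (1,0)
  expect_equal(diag(s), setNames(rep(1, 4), rownames(emb)))
  expect_equal(s, t(s))
  expect_true(all(s >= -1 & s <= 1))
  zero <- rbind(z = c(0, 0), emb)
  expect_error(cosine_similarity_matrix(zero), "zero-norm")
  expect_error(cosine_similarity_matrix(emb, c("a", "nope")), "missing")
})

test_that("semantic contribution and value follow the recursive decay", {
  chain <- disease_dag(data.frame(parent = c("A", "B"), child = c("B", "C")),
                       mu = 0.5)
  expect_equal(semantic_contribution(chain, "C", "C"), 1)
  expect_equal(semantic_contribution(chain, "B", "A"), 0.5)
  expect_equal(semantic_contribution(chain, "C", "A"), 0.25)
  expect_equal(semantic_value(chain, "A"), 1)
  expect_equal(semantic_value(chain, "B"), 1.5)
  expect_equal(semantic_value(chain, "C"), 1.75)
  expect_error(semantic_contribution(chain, "B", "C"), "ancestors")
  expect_error(semantic_value(chain, "nope"), "unknown")
  # contributions never increase walking up an ancestor chain
  set.seed(1)
  for (mu in c(0.3, 0.5, 1)) {
    dag <- disease_dag(data.frame(parent = c("r", "r", "x", "x", "y"),
                                  child = c("x", "y", "z", "w", "w")),
                       mu = mu)
    v <- ceRNAdis:::dag_contributions(dag, "w")
    for (node in names(v)) {
      for (par in intersect(dag$parents[[node]], names(v))) {
        expect_lte(v[[par]], v[[node]])
      }
    }
  }
})

test_that("semantic similarity matches hand evaluation and handles disjoint ancestries", {
  chain <- disease_dag(data.frame(parent = "A", child = "B"), mu = 0.5)
  expect_equal(semantic_similarity(chain, "A", "B"), 1.5 / 2.5)
  expect_equal(semantic_similarity(chain, "B", "B"), 1)
  two_roots <- disease_dag(data.frame(parent = character(), child = character()),
                           nodes = c("R1", "R2"))
  expect_equal(semantic_similarity(two_roots, "R1", "R2"), 0)
  m <- semantic_similarity_matrix(chain)
  expect_equal(m["A", "B"], 0.6)
  expect_equal(diag(m), c(A = 1, B = 1))
  expect_equal(m, t(m))
  expect_error(disease_dag(data.frame(parent = c("A", "B"), child = c("B", "A"))),
               "cycle")
})

test_that("GIP bandwidth and kernel match the definition and the brute-force oracle", {
  one_hot <- diag(4)
  expect_equal(gip_bandwidth(one_hot), 1)
  expect_equal(gip_bandwidth(rbind(c(1, 0, 0), c(1, 1, 1))), 0.5)
  m <- rbind(c(1, 0), c(0, 1))
  expect_equal(gip_bandwidth(2 * m), gip_bandwidth(m) / 4)
  expect_error(gip_bandwidth(matrix(0, 2, 2)), "zero")

  # identical profiles score 1; two differing bits with delta 1 give exp(-2)
  prof <- rbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0),
                c = c(0, 1, 1, 0), d = c(1, 1, 0, 0))
  s <- gip_similarity(prof)
  expect_equal(s["a", "b"], 1)
  expect_equal(diag(s), c(a = 1, b = 1, c = 1, d = 1))
  delta1 <- rbind(x = c(1, 0), y = c(0, 1))  # norms 1 -> delta = 1
  expect_equal(gip_similarity(delta1)["x", "y"], exp(-2))

  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(rbinom(100, 1, 0.4), 10, 10,
                dimnames = list(paste0("d", 1:10), NULL))
    if (all(rowSums(m) == 0)) next
    expect_equal(gip_similarity(m), oracle_gip(m), tolerance = 1e-12)
    # invariance under simultaneous row permutation
    perm <- sample(10)
    expect_equal(unname(gip_similarity(m[perm, ])),
                 unname(gip_similarity(m)[perm, perm]), tolerance = 1e-12)
  }
})

test_that("disease similarity assembly dispatches between semantic and GIP sources", {
  dag <- disease_dag(data.frame(parent = "A", child = "B"), mu = 0.5)
  prof <- rbind(A = c(1, 0, 0), B = c(1, 1, 0), C = c(0, 1, 1))
  # all diseases in DAG -> pure semantic
  full_dag <- disease_dag(data.frame(parent = c("A", "A"), child = c("B", "C")))
  s1 <- assemble_disease_similarity(full_dag, NULL, diseases = c("A", "B", "C"))
  expect_equal(s1, semantic_similarity_matrix(full_dag, c("A", "B", "C")))
  # no DAG -> pure GIP
  s2 <- assemble_disease_similarity(NULL, prof)
  expect_equal(s2, gip_similarity(prof))
  # mixed: pairs fully inside the DAG take semantic, others GIP
  s3 <- assemble_disease_similarity(dag, prof, diseases = c("A", "B", "C"))
  gs <- gip_similarity(prof)
  for (i in c("A", "B", "C")) for (j in c("A", "B", "C")) {
    expected <- if (i == j) 1
      else if (i %in% dag$nodes && j %in% dag$nodes) semantic_similarity(dag, i, j)
      else gs[i, j]
    expect_equal(s3[i, j], expected)
  }
  expect_error(assemble_disease_similarity(dag, NULL, diseases = c("A", "Z")),
               "neither")
})

test_that("RNA similarity assembly overlays functional similarity where defined", {
  net <- cosine_similarity_matrix(toy_embedding())
  expect_equal(assemble_rna_similarity(net), net)
  fs_full <- matrix(0.9, 4, 4, dimnames = dimnames(net))
  diag(fs_full) <- 1
  expect_equal(assemble_rna_similarity(net, fs_full), fs_full)
  # partial coverage: FS pairs replaced, NA entries keep network values
  fs <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "c"), c("a", "c")))
  fs["a", "c"] <- fs["c", "a"] <- 0.42
  mixed <- assemble_rna_similarity(net, fs)
  expect_equal(mixed["a", "c"], 0.42)
  expect_equal(mixed["a", "b"], net["a", "b"])
  expect_equal(mixed, t(mixed))
  bad <- matrix(1, 2, 2, dimnames = list(c("a", "zz"), c("a", "zz")))
  expect_error(assemble_rna_similarity(net, bad), "index")
})
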