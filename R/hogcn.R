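#' Training configuration for the higher-order GCN
#'
#' Defaults follow the reference experimental settings: 300 epochs, learning
#' rate 0.001, dropout 0.5, hidden size 128, embedding size 64, train ratio
#' 0.8.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param dropout dropout probability on the hidden GCN layer (training only).
#' @param hidden hidden layer width.
#' @param embed embedding dimension `d` (also the width of the initial
#'   embedding matrix `H0`).
#' @param train_ratio fraction of samples used for training in holdout
#'   protocols.
#' @param triplet_mode `"mlp"` (two-layer perceptron on the concatenated RNA
#'   embeddings) or `"weighted"` (learned convex combination).
#' @param leaky_slope LeakyReLU negative slope.
#' @param seed integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, learning_rate = 0.001, dropout = 0.5,
                         hidden = 128L, embed = 64L, train_ratio = 0.8,
                         triplet_mode = c("mlp", "weighted"),
                         leaky_slope = 0.2, seed = 1L) {
  triplet_mode <- match.arg(triplet_mode)
  if (train_ratio <= 0 || train_ratio >= 1) stop_config("train_ratio must lie in (0,1)")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must lie in [0,1)")
  if (epochs < 1 || hidden < 1 || embed < 1) stop_config("epochs, hidden, embed must be positive")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 dropout = dropout, hidden = as.integer(hidden),
                 embed = as.integer(embed), train_ratio = train_ratio,
                 triplet_mode = triplet_mode, leaky_slope = leaky_slope,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize model parameters
#'
#' Randomly initialized embedding matrix `H0` and trainable weights: GCN
#' layers `W1`, `W2`, bilinear score matrix `Wp`, the triplet MLP weights,
#' and the logits of the triplet mixing weights (softmax-normalized so the
#' three weights sum to one).
#'
#' @param n_nodes number of graph nodes.
#' @param cfg a [train_config()].
#' @return A `model_params` list.
#' @export
model_params <- function(n_nodes, cfg = train_config()) {
  d0 <- cfg$embed; h <- cfg$hidden; d <- cfg$embed
  set.seed(derive_seed(cfg$seed, "gcn-init"))
  glorot <- function(a, b) matrix(rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
  structure(list(
    H0 = matrix(rnorm(n_nodes * d0, sd = 0.1), n_nodes, d0),
    W1 = glorot(d0, h),
    W2 = glorot(h, d),
    Wp = glorot(d, d),
    M1 = glorot(3 * d, d),
    M2 = glorot(d, d),
    mix_logits = c(0, 0, 0)
  ), class = "model_params")
}

#' Two-layer higher-order GCN propagation
#'
#' Computes `H = A_h %*% LeakyReLU(A_e %*% H0 %*% W1) %*% W2`: the first
#' layer aggregates over the enhanced (similarity + attention) adjacency,
#' the second over the higher-order (triangle co-occurrence) adjacency.
#' Dropout on the hidden layer is applied only when `dropout_active`.
#'
#' @param Ae,Ah the enhanced and higher-order adjacency matrices.
#' @param params a [model_params()].
#' @param cfg a [train_config()].
#' @param dropout_active logical; apply dropout (training mode).
#' @param dropout_seed seed for the dropout mask.
#' @return Embedding matrix `H` (`n_nodes` x `embed`), rownames taken from
#'   `Ae`.
#' @export
propagate <- function(Ae, Ah, params, cfg = train_config(),
                      dropout_active = FALSE, dropout_seed = 0L) {
  if (nrow(params$H0) != nrow(Ae) || nrow(Ae) != nrow(Ah)) {
    stop_config("adjacency / H0 dimensions do not match")
  }
  fw <- gcn_forward(Ae, Ah, params, cfg, dropout_active, dropout_seed)
  H <- fw$H
  rownames(H) <- rownames(Ae)
  H
}

# forward pass with cached intermediates for backprop
gcn_forward <- function(Ae, Ah, params, cfg, dropout_active, dropout_seed) {
  P <- as.matrix(Ae %*% params$H0)
  Z1 <- P %*% params$W1
  Hh <- leaky_relu(Z1, cfg$leaky_slope)
  mask <- NULL
  if (dropout_active && cfg$dropout > 0) {
    set.seed(derive_seed(dropout_seed, "dropout"))
    mask <- matrix(runif(length(Hh)) >= cfg$dropout, nrow(Hh), ncol(Hh)) /
      (1 - cfg$dropout)
    Hh <- Hh * mask
  }
  Q <- as.matrix(Ah %*% Hh)
  H <- Q %*% params$W2
  list(P = P, Z1 = Z1, mask = mask, Q = Q, H = H)
}

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# triplet embedding for row matrices L, M, R (m x d each)
triplet_embed_rows <- function(L, M, R, params, cfg) {
  if (cfg$triplet_mode == "mlp") {
    C <- cbind(L, M, R)
    Z2 <- C %*% params$M1
    U <- leaky_relu(Z2, cfg$leaky_slope)
    T <- U %*% params$M2
    list(T = T, C = C, Z2 = Z2, U = U)
  } else {
    w <- softmax(params$mix_logits)
    list(T = w[1] * L + w[2] * M + w[3] * R, w = w)
  }
}

#' Embed a ceRNA triplet
#'
#' Combines the lncRNA, miRNA and mRNA embeddings into a single triplet
#' representation, either through a two-layer perceptron on their
#' concatenation (`mode = "mlp"`) or as a learned convex combination
#' (`mode = "weighted"`, mixing weights softmax-normalized).
#'
#' @param h_lnc,h_mi,h_mr embedding vectors (or m x d matrices of rows).
#' @param params a [model_params()]; when `NULL` and `mode = "weighted"`,
#'   equal weights are used.
#' @param mode `"mlp"` or `"weighted"`.
#' @param leaky_slope LeakyReLU slope for the MLP path.
#' @return Triplet embedding of dimension `d` (or an m x d matrix).
#' @export
triplet_embedding <- function(h_lnc, h_mi, h_mr, params = NULL,
                              mode = c("mlp", "weighted"), leaky_slope = 0.2) {
  mode <- match.arg(mode)
  vec_in <- is.null(dim(h_lnc))
  L <- rbind(h_lnc); M <- rbind(h_mi); R <- rbind(h_mr)
  if (ncol(L) != ncol(M) || ncol(M) != ncol(R)) {
    stop_config("triplet member embeddings must share one dimension")
  }
  if (mode == "mlp") {
    if (is.null(params)) stop_config("mlp mode requires model parameters")
    cfg <- list(triplet_mode = "mlp", leaky_slope = leaky_slope)
    out <- triplet_embed_rows(L, M, R, params, cfg)$T
  } else {
    w <- if (is.null(params)) rep(1 / 3, 3) else softmax(params$mix_logits)
    out <- w[1] * L + w[2] * M + w[3] * R
  }
  if (vec_in) out[1, ] else out
}

#' Bilinear link probability
#'
#' `sigmoid(h_triplet %*% Wp %*% h_disease)`: the probability that the
#' triplet is associated with the disease.
#'
#' @param h_triplet triplet embedding vector or m x d matrix of rows.
#' @param h_disease disease embedding vector or m x d matrix of rows.
#' @param Wp d x d bilinear weight matrix.
#' @return Probability (vector) in (0, 1).
#' @export
link_probability <- function(h_triplet, h_disease, Wp) {
  T <- rbind(h_triplet); D <- rbind(h_disease)
  s <- rowSums((T %*% Wp) * D)
  out <- sigmoid(s)
  if (is.null(dim(h_triplet)) && is.null(dim(h_disease))) unname(out[1]) else unname(out)
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

sample_indices <- function(samples, index) {
  list(l = unname(index[samples$lnc]), m = unname(index[samples$mi]),
       r = unname(index[samples$mr]), d = unname(index[samples$dis]))
}

#' Train the higher-order GCN link predictor
#'
#' Full-batch gradient training of the propagation weights, the triplet
#' combiner and the bilinear score matrix under binary cross-entropy on
#' labelled (triplet, disease) samples, using Adam. All randomness
#' (initialization, dropout masks) derives from `cfg$seed`, so a fixed seed
#' reproduces the final loss exactly.
#'
#' @param Ae,Ah enhanced and higher-order adjacency matrices (dimnames are
#'   the node ids).
#' @param positives data.frame with columns `lnc`, `mi`, `mr`, `dis` (label
#'   1 samples).
#' @param negatives data.frame of the same shape (label 0 samples).
#' @param cfg a [train_config()].
#' @param verbose print loss every 50 epochs.
#' @return List with `params` (trained [model_params()]), `embeddings`
#'   (final inference-mode node embeddings), `loss` (per-epoch training
#'   loss) and `cfg`.
#' @export
train_model <- function(Ae, Ah, positives, negatives, cfg = train_config(),
                        verbose = FALSE) {
  if (nrow(positives) == 0) stop_config("no positive samples")
  node_ids <- rownames(Ae)
  index <- setNames(seq_along(node_ids), node_ids)
  pos <- sample_indices(positives, index)
  neg <- sample_indices(negatives, index)
  if (anyNA(unlist(pos)) || anyNA(unlist(neg))) {
    stop_config("sample references a node absent from the adjacency")
  }
  li <- c(pos$l, neg$l); mi <- c(pos$m, neg$m)
  ri <- c(pos$r, neg$r); di <- c(pos$d, neg$d)
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))
  m <- length(y)

  params <- model_params(length(node_ids), cfg)
  state <- list(par = unclass(params),
                m = lapply(unclass(params), function(p) p * 0),
                v = lapply(unclass(params), function(p) p * 0))
  slope <- cfg$leaky_slope
  d <- cfg$embed
  loss_hist <- numeric(cfg$epochs)
  AeT <- Matrix::t(Ae); AhT <- Matrix::t(Ah)

  for (ep in seq_len(cfg$epochs)) {
    par <- state$par
    fw <- gcn_forward(Ae, Ah, par, cfg, dropout_active = cfg$dropout > 0,
                      dropout_seed = derive_seed(cfg$seed, paste0("ep", ep)))
    H <- fw$H
    L <- H[li, , drop = FALSE]; M <- H[mi, , drop = FALSE]
    R <- H[ri, , drop = FALSE]; D <- H[di, , drop = FALSE]
    te <- triplet_embed_rows(L, M, R, par, cfg)
    T <- te$T
    TW <- T %*% par$Wp
    s <- rowSums(TW * D)
    yhat <- sigmoid(s)
    loss_hist[ep] <- -mean(y * log(yhat + 1e-12) + (1 - y) * log(1 - yhat + 1e-12))

    ds <- (yhat - y) / m
    grads <- list()
    grads$Wp <- crossprod(T, D * ds)
    dT <- (D %*% t(par$Wp)) * ds
    dD <- TW * ds
    if (cfg$triplet_mode == "mlp") {
      grads$M2 <- crossprod(te$U, dT)
      dU <- dT %*% t(par$M2)
      dZ2 <- dU * leaky_relu_grad(te$Z2, slope)
      grads$M1 <- crossprod(te$C, dZ2)
      dC <- dZ2 %*% t(par$M1)
      dL <- dC[, 1:d, drop = FALSE]
      dM <- dC[, d + 1:d, drop = FALSE]
      dR <- dC[, 2 * d + 1:d, drop = FALSE]
      grads$mix_logits <- c(0, 0, 0)
    } else {
      w <- te$w
      dL <- w[1] * dT; dM <- w[2] * dT; dR <- w[3] * dT
      g <- c(sum(dT * L), sum(dT * M), sum(dT * R))
      grads$mix_logits <- w * (g - sum(w * g))
      grads$M1 <- par$M1 * 0; grads$M2 <- par$M2 * 0
    }
    all_idx <- c(li, mi, ri, di)
    agg <- rowsum(rbind(dL, dM, dR, dD), group = all_idx)
    dH <- matrix(0, nrow(H), d)
    dH[as.integer(rownames(agg)), ] <- agg

    grads$W2 <- crossprod(fw$Q, dH)
    dQ <- dH %*% t(par$W2)
    dHh <- as.matrix(AhT %*% dQ)
    if (!is.null(fw$mask)) dHh <- dHh * fw$mask
    dZ1 <- dHh * leaky_relu_grad(fw$Z1, slope)
    grads$W1 <- crossprod(fw$P, dZ1)
    dP <- dZ1 %*% t(par$W1)
    grads$H0 <- as.matrix(AeT %*% dP)

    state <- adam_step(state, grads, cfg$learning_rate, ep)
    if (verbose && ep %% 50 == 0) {
      message(sprintf("epoch %d: loss %.5f", ep, loss_hist[ep]))
    }
  }
  params <- structure(state$par, class = "model_params")
  H <- propagate(Ae, Ah, params, cfg, dropout_active = FALSE)
  list(params = params, embeddings = H, loss = loss_hist, cfg = cfg)
}

#' Score (triplet, disease) samples with a trained model
#'
#' @param fit result of [train_model()].
#' @param samples data.frame with columns `lnc`, `mi`, `mr`, `dis`.
#' @return Probability vector from the bilinear score head.
#' @export
predict_links <- function(fit, samples) {
  H <- fit$embeddings
  T <- triplet_embedding(H[samples$lnc, , drop = FALSE],
                         H[samples$mi, , drop = FALSE],
                         H[samples$mr, , drop = FALSE],
                         params = fit$params, mode = fit$cfg$triplet_mode,
                         leaky_slope = fit$cfg$leaky_slope)
  link_probability(T, H[samples$dis, , drop = FALSE], fit$params$Wp)
}
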