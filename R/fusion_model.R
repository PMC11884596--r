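#' Fusion model configuration
#'
#' The trainable core: a two-layer graph convolutional encoder over the
#' site-centred structure graph, a cross-attention block whose queries
#' are projected sequence-embedding tokens and whose keys/values are
#' the graph-encoder outputs, a self-attention block over the fused
#' tokens, and a three-hidden-layer classifier (widths 256, 256, 512)
#' ending in a sigmoid. Defaults mirror the reference architecture:
#' embedding dimension 256, a single attention head, dropout 0.3.
#'
#' @param embed_dim Fusion width C.
#' @param n_heads Number of attention heads d (C must be divisible by d).
#' @param gcn_layers Graph-encoder depth (1 or 2 supported).
#' @param classifier_widths Hidden-layer widths of the classifier.
#' @param dropout Dropout rate on classifier hidden layers.
#' @param query_window Half-width of the sequence query window (0 gives
#'   the two-token `[global; site]` query).
#' @param attention_scale `"sqrt"` divides attention logits by
#'   `sqrt(C/d)` (standard scaled dot-product); `"linear"` divides by
#'   `C/d`.
#' @param pool_token If `TRUE` (default) the mean-pooled graph-encoder
#'   output joins the fused tokens entering self-attention, so the
#'   classifier sees the compacted subgraph summary alongside the
#'   cross-attended tokens.
#' @param center_token If `TRUE` (default) a linear projection of the
#'   centre node's raw 35-dimensional feature vector -- the
#'   phosphorylation site itself -- joins the fused tokens. The
#'   subgraph is site-centred by construction and the site residue's
#'   own structural state carries signal that both mean pooling and
#'   neighbourhood aggregation dilute; this readout keeps it
#'   addressable.
#' @param ablation Character vector from `c("no_gcn", "no_esm",
#'   "no_cross", "no_self")` switching off model branches.
#' @param seed Seed for parameter initialisation.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(embed_dim = 256, n_heads = 1, gcn_layers = 2,
                          classifier_widths = c(256, 256, 512),
                          dropout = 0.3, query_window = 0,
                          attention_scale = c("sqrt", "linear"),
                          pool_token = TRUE, center_token = TRUE,
                          ablation = character(0), seed = 1) {
  stopifnot(embed_dim %% n_heads == 0, all(classifier_widths > 0),
            dropout >= 0, dropout < 1, gcn_layers %in% c(1, 2),
            all(ablation %in% c("no_gcn", "no_esm", "no_cross", "no_self")))
  structure(list(embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 gcn_layers = as.integer(gcn_layers),
                 classifier_widths = as.integer(classifier_widths),
                 dropout = dropout, query_window = as.integer(query_window),
                 attention_scale = match.arg(attention_scale),
                 pool_token = isTRUE(pool_token),
                 center_token = isTRUE(center_token),
                 ablation = ablation, seed = as.integer(seed)),
            class = "fusion_config")
}

attention_tau <- function(C, d, scale) {
  if (scale == "sqrt") sqrt(C / d) else C / d
}

n_query_tokens <- function(config) 2L + 2L * config$query_window

n_fused_tokens <- function(config) {
  ctr <- as.integer(isTRUE(config$center_token))
  if ("no_esm" %in% config$ablation) return(1L + ctr)
  nq <- n_query_tokens(config)
  if ("no_gcn" %in% config$ablation) return(nq)
  if ("no_cross" %in% config$ablation) return(nq + 1L + ctr)
  nq + as.integer(isTRUE(config$pool_token)) + ctr
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialise fusion-model parameters
#'
#' @param config A [fusion_config()].
#' @param d_graph Node-feature width (default 35).
#' @param d_embed Sequence-embedding width D.
#' @return Named list of parameter matrices/vectors. Classifier
#'   parameters are those whose names start with `"cls_"`; everything
#'   else belongs to the embedding layers (the transfer-learning split).
#' @export
init_fusion_params <- function(config, d_graph = 35, d_embed = 64) {
  C <- config$embed_dim
  w <- config$classifier_widths
  din <- n_fused_tokens(config) * C
  with_local_seed(derive_seed(config$seed, "init"), {
    p <- list(Wp = glorot(d_embed, C), bp = numeric(C),
              Wc = glorot(d_graph, C), bc = numeric(C),
              Wg1 = glorot(d_graph, C), bg1 = numeric(C),
              Wg2 = glorot(C, C), bg2 = numeric(C),
              Wq = glorot(C, C), Wk = glorot(C, C),
              Wv = glorot(C, C), Wo = glorot(C, C),
              Sq = glorot(C, C), Sk = glorot(C, C),
              Sv = glorot(C, C), So = glorot(C, C),
              cls_W1 = glorot(din, w[1]), cls_b1 = numeric(w[1]),
              cls_W2 = glorot(w[1], w[2]), cls_b2 = numeric(w[2]),
              cls_W3 = glorot(w[2], w[3]), cls_b3 = numeric(w[3]),
              cls_W4 = glorot(w[3], 1), cls_b4 = numeric(1))
    p
  })
}

#' Scaled dot-product attention
#'
#' The attention primitive shared by the cross-attention and
#' self-attention blocks: `softmax(q %*% t(k) / tau) %*% v` with
#' `tau = sqrt(C/d)` (or `C/d` under the linear scaling variant), one
#' output row per query row, each softmax row summing to 1.
#'
#' @param q Query matrix (m x C).
#' @param k,v Key and value matrices (n x C each).
#' @param n_heads Head count d entering the scale.
#' @param scale `"sqrt"` or `"linear"`.
#' @return List with `output` (m x C) and `weights` (m x n softmax rows).
#' @export
scaled_attention <- function(q, k, v, n_heads = 1,
                             scale = c("sqrt", "linear")) {
  scale <- match.arg(scale)
  q <- as.matrix(q); k <- as.matrix(k); v <- as.matrix(v)
  if (nrow(k) == 0) {
    stop_pf("attention requires at least one key", "phosfusion_shape_error")
  }
  stopifnot(ncol(q) == ncol(k), nrow(k) == nrow(v))
  tau <- attention_tau(ncol(q), n_heads, scale)
  s <- q %*% t(k) / tau
  s <- s - apply(s, 1, max)
  e <- exp(s)
  a <- e / rowSums(e)
  list(output = a %*% v, weights = a)
}

#' Cross-attention between sequence queries and graph nodes
#'
#' @param q Query token matrix (projected sequence embeddings).
#' @param k,v Graph-encoder node outputs.
#' @param config A [fusion_config()] supplying head count and scaling.
#' @return Fused token matrix, one row per query token.
#' @export
cross_attention <- function(q, k, v, config = fusion_config()) {
  scaled_attention(q, k, v, config$n_heads, config$attention_scale)$output
}

#' Self-attention over fused tokens
#'
#' @param tokens Token matrix.
#' @param config A [fusion_config()].
#' @return Token matrix of the same shape.
#' @export
self_attention <- function(tokens, config = fusion_config()) {
  scaled_attention(tokens, tokens, tokens, config$n_heads,
                   config$attention_scale)$output
}

#' Binary cross-entropy loss
#'
#' `-[y log(p) + (1 - y) log(1 - p)]`, with probabilities clamped to
#' `[eps, 1 - eps]` for stability; the batch loss is the mean.
#'
#' @param y 0/1 labels.
#' @param y_hat Predicted probabilities.
#' @param eps Clamping epsilon.
#' @return Mean loss (scalar).
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

# Symmetric-normalised neighbourhood aggregation over a batched edge
# list (self-loops included): out[dst] = sum_e w_e * M[src_e].
gcn_aggregate <- function(M, edges) {
  out <- rowsum(edges$w * M[edges$src, , drop = FALSE], edges$dst)
  dimnames(out) <- NULL
  out
}

# Normalised-adjacency edge list (with self-loops) for one graph given
# a plain edge data frame over local node indices 1..n.
normalized_edges <- function(ei, ej, n) {
  src <- c(ei, ej, seq_len(n))
  dst <- c(ej, ei, seq_len(n))
  deg <- as.numeric(rowsum(rep(1, length(src)), src))
  w <- 1 / sqrt(deg[src] * deg[dst])
  list(src = src, dst = dst, w = w)
}

#' Encode a residue graph with the graph-convolutional branch
#'
#' Applies the configured number of symmetric-normalised aggregation
#' layers (35 -> C on entry, rectified-linear between layers, linear
#' output) and mean-pools the node outputs into a graph vector.
#'
#' @param graph A featurized `residue_graph` (see [featurize_nodes()]).
#' @param params Parameter list from [init_fusion_params()].
#' @param config A [fusion_config()].
#' @return List with `nodes` (n x C matrix used as attention keys and
#'   values) and `pooled` (length-C mean over nodes).
#' @export
graph_encode <- function(graph, params, config = fusion_config()) {
  if (is.null(graph$node_features)) {
    stop_pf("graph has no node features; call featurize_nodes() first",
            "phosfusion_shape_error")
  }
  n <- length(graph$node_ids)
  if (n == 0) stop_pf("empty graph", "phosfusion_shape_error")
  ei <- match(graph$edges$i, graph$node_ids)
  ej <- match(graph$edges$j, graph$node_ids)
  edges <- normalized_edges(ei, ej, n)
  X <- graph$node_features
  Z1 <- gcn_aggregate(X, edges)
  H <- Z1 %*% params$Wg1
  H <- sweep(H, 2, params$bg1, "+")
  if (config$gcn_layers >= 2) {
    H <- pmax(H, 0)
    Z2 <- gcn_aggregate(H, edges)
    H <- sweep(Z2 %*% params$Wg2, 2, params$bg2, "+")
  }
  list(nodes = H, pooled = colMeans(H))
}

#' Classify fused tokens into a probability
#'
#' Concatenates the tokens and applies the three-hidden-layer
#' classifier (rectified-linear activations, dropout in training mode
#' only) ending in a sigmoid.
#'
#' @param tokens Token matrix (tokens x C) for one site, or a
#'   B x (tokens*C) matrix of pre-flattened batches.
#' @param params Parameter list.
#' @param config A [fusion_config()].
#' @param train Logical; enables dropout.
#' @return Probability vector in (0, 1).
#' @export
classify <- function(tokens, params, config = fusion_config(),
                     train = FALSE) {
  Z <- if (is.matrix(tokens) && ncol(tokens) == ncol(params$cls_W1)) tokens
  else matrix(as.numeric(t(tokens)), 1)
  masks <- if (train && config$dropout > 0) {
    lapply(config$classifier_widths, function(w) {
      matrix(stats::rbinom(nrow(Z) * w, 1, 1 - config$dropout) /
               (1 - config$dropout), nrow(Z), w)
    })
  } else NULL
  mlp_forward(Z, params, masks)$p
}

# Classifier forward shared by classify() and the batched trainer.
mlp_forward <- function(Z, params, masks = NULL) {
  a1p <- sweep(Z %*% params$cls_W1, 2, params$cls_b1, "+")
  a1 <- pmax(a1p, 0)
  a1d <- if (is.null(masks)) a1 else a1 * masks[[1]]
  a2p <- sweep(a1d %*% params$cls_W2, 2, params$cls_b2, "+")
  a2 <- pmax(a2p, 0)
  a2d <- if (is.null(masks)) a2 else a2 * masks[[2]]
  a3p <- sweep(a2d %*% params$cls_W3, 2, params$cls_b3, "+")
  a3 <- pmax(a3p, 0)
  a3d <- if (is.null(masks)) a3 else a3 * masks[[3]]
  logit <- as.numeric(a3d %*% params$cls_W4) + params$cls_b4
  list(p = 1 / (1 + exp(-logit)), logit = logit, Z = Z,
       a1p = a1p, a1d = a1d, a2p = a2p, a2d = a2d, a3p = a3p, a3d = a3d,
       masks = masks)
}

mlp_backward <- function(cache, params, dlogit) {
  g <- list()
  dlogit <- matrix(dlogit, ncol = 1)
  g$cls_W4 <- t(cache$a3d) %*% dlogit
  g$cls_b4 <- sum(dlogit)
  da3 <- dlogit %*% t(params$cls_W4)
  if (!is.null(cache$masks)) da3 <- da3 * cache$masks[[3]]
  da3 <- da3 * (cache$a3p > 0)
  g$cls_W3 <- t(cache$a2d) %*% da3
  g$cls_b3 <- colSums(da3)
  da2 <- da3 %*% t(params$cls_W3)
  if (!is.null(cache$masks)) da2 <- da2 * cache$masks[[2]]
  da2 <- da2 * (cache$a2p > 0)
  g$cls_W2 <- t(cache$a1d) %*% da2
  g$cls_b2 <- colSums(da2)
  da1 <- da2 %*% t(params$cls_W2)
  if (!is.null(cache$masks)) da1 <- da1 * cache$masks[[1]]
  da1 <- da1 * (cache$a1p > 0)
  g$cls_W1 <- t(cache$Z) %*% da1
  g$cls_b1 <- colSums(da1)
  g$dZ <- da1 %*% t(params$cls_W1)
  g
}

# Grouped softmax over scores s (length N) with group index g (1..B):
# softmax within each group. Every group must be non-empty.
grouped_softmax <- function(s, g, B) {
  m <- vapply(split(s, factor(g, levels = seq_len(B))), max, numeric(1))
  e <- exp(s - m[g])
  z <- as.numeric(rowsum(e, g))
  e / z[g]
}

# Batched forward pass over a tensorised batch (see dataset_batch()).
# Returns probabilities plus every intermediate needed by the backward
# pass. `masks` are classifier dropout masks (NULL in eval mode).
fusion_forward_batch <- function(params, batch, config, masks = NULL) {
  abl <- config$ablation
  C <- config$embed_dim
  tau <- attention_tau(C, config$n_heads, config$attention_scale)
  B <- batch$B
  cache <- list(masks = masks)
  use_graph <- !("no_gcn" %in% abl)
  use_seq <- !("no_esm" %in% abl)
  use_cross <- use_graph && use_seq && !("no_cross" %in% abl)
  use_self <- !("no_self" %in% abl)

  P <- NULL
  if (use_seq) {
    Tq <- n_query_tokens(config)
    P <- lapply(seq_len(Tq), function(t) {
      Qt <- matrix(batch$Q[, t, ], nrow = B)
      sweep(Qt %*% params$Wp, 2, params$bp, "+")
    })
  }
  H2 <- NULL; pooled <- NULL
  if (use_graph) {
    Z1 <- gcn_aggregate(batch$X, batch$edges)
    H1p <- sweep(Z1 %*% params$Wg1, 2, params$bg1, "+")
    if (config$gcn_layers >= 2) {
      H1 <- pmax(H1p, 0)
      Z2 <- gcn_aggregate(H1, batch$edges)
      H2 <- sweep(Z2 %*% params$Wg2, 2, params$bg2, "+")
      cache$Z2 <- Z2
    } else {
      H2 <- H1p
    }
    cache$Z1 <- Z1; cache$H1p <- H1p
    pooled <- rowsum(H2, batch$g) / batch$n_nodes
    cache$H2 <- H2; cache$pooled <- pooled
  }
  if (use_cross) {
    K <- H2 %*% params$Wk
    V <- H2 %*% params$Wv
    Qx <- lapply(P, function(p) p %*% params$Wq)
    A <- list(); O <- list(); U <- list()
    for (t in seq_along(P)) {
      s <- rowSums(K * Qx[[t]][batch$g, , drop = FALSE]) / tau
      A[[t]] <- grouped_softmax(s, batch$g, B)
      O[[t]] <- rowsum(A[[t]] * V, batch$g)
      U[[t]] <- O[[t]] %*% params$Wo
    }
    cache$K <- K; cache$V <- V; cache$Qx <- Qx; cache$A <- A; cache$O <- O
    if (isTRUE(config$pool_token)) U <- c(U, list(pooled))
  } else if (!use_seq) {
    U <- list(pooled)
  } else if (!use_graph) {
    U <- P
  } else {
    U <- c(P, list(pooled))
  }
  if (use_graph && isTRUE(config$center_token)) {
    Xc <- batch$X[batch$center_rows, , drop = FALSE]
    cache$Xc <- Xc
    U <- c(U, list(sweep(Xc %*% params$Wc, 2, params$bc, "+")))
  }
  cache$P <- P; cache$U <- U
  Tn <- length(U)
  if (use_self) {
    q2 <- lapply(U, function(u) u %*% params$Sq)
    k2 <- lapply(U, function(u) u %*% params$Sk)
    v2 <- lapply(U, function(u) u %*% params$Sv)
    Sarr <- array(0, c(B, Tn, Tn))
    for (t in seq_len(Tn)) for (tp in seq_len(Tn)) {
      Sarr[, t, tp] <- rowSums(q2[[t]] * k2[[tp]]) / tau
    }
    Aself <- array(0, c(B, Tn, Tn))
    for (t in seq_len(Tn)) {
      st <- matrix(Sarr[, t, ], B, Tn)
      e <- exp(st - apply(st, 1, max))
      Aself[, t, ] <- e / rowSums(e)
    }
    Sout <- list()
    for (t in seq_len(Tn)) {
      acc <- matrix(0, B, C)
      for (tp in seq_len(Tn)) {
        acc <- acc + matrix(Aself[, t, tp], B, C) * v2[[tp]]
      }
      Sout[[t]] <- acc %*% params$So
      cache[[paste0("selfacc", t)]] <- acc
    }
    cache$q2 <- q2; cache$k2 <- k2; cache$v2 <- v2; cache$Aself <- Aself
  } else {
    Sout <- U
  }
  cache$Sout <- Sout
  Z <- do.call(cbind, Sout)
  mlp <- mlp_forward(Z, params, masks)
  cache$mlp <- mlp
  list(p = mlp$p, cache = cache)
}

# Batched backward pass; returns gradients with the same names/shapes
# as the parameter list. `dlogit` is dLoss/dlogit per site.
fusion_backward_batch <- function(params, batch, config, cache, dlogit) {
  abl <- config$ablation
  C <- config$embed_dim
  tau <- attention_tau(C, config$n_heads, config$attention_scale)
  B <- batch$B
  use_graph <- !("no_gcn" %in% abl)
  use_seq <- !("no_esm" %in% abl)
  use_cross <- use_graph && use_seq && !("no_cross" %in% abl)
  use_self <- !("no_self" %in% abl)
  g <- lapply(params, function(x) if (is.matrix(x))
    matrix(0, nrow(x), ncol(x)) else numeric(length(x)))

  mg <- mlp_backward(cache$mlp, params, dlogit)
  for (nm in setdiff(names(mg), "dZ")) g[[nm]] <- mg[[nm]]
  U <- cache$U
  Tn <- length(U)
  dS <- lapply(seq_len(Tn), function(t) {
    mg$dZ[, ((t - 1) * C + 1):(t * C), drop = FALSE]
  })
  if (use_self) {
    Aself <- cache$Aself; q2 <- cache$q2; k2 <- cache$k2; v2 <- cache$v2
    dq2 <- lapply(seq_len(Tn), function(t) matrix(0, B, C))
    dk2 <- lapply(seq_len(Tn), function(t) matrix(0, B, C))
    dv2 <- lapply(seq_len(Tn), function(t) matrix(0, B, C))
    dU <- lapply(seq_len(Tn), function(t) matrix(0, B, C))
    dA <- array(0, c(B, Tn, Tn))
    for (t in seq_len(Tn)) {
      acc <- cache[[paste0("selfacc", t)]]
      dacc <- dS[[t]] %*% t(params$So)
      g$So <- g$So + t(acc) %*% dS[[t]]
      for (tp in seq_len(Tn)) {
        dv2[[tp]] <- dv2[[tp]] + matrix(Aself[, t, tp], B, C) * dacc
        dA[, t, tp] <- rowSums(dacc * v2[[tp]])
      }
    }
    for (t in seq_len(Tn)) {
      rs <- rowSums(matrix(Aself[, t, ] * dA[, t, ], B, Tn))
      for (tp in seq_len(Tn)) {
        ds <- Aself[, t, tp] * (dA[, t, tp] - rs)
        dq2[[t]] <- dq2[[t]] + matrix(ds, B, C) * k2[[tp]] / tau
        dk2[[tp]] <- dk2[[tp]] + matrix(ds, B, C) * q2[[t]] / tau
      }
    }
    for (t in seq_len(Tn)) {
      g$Sq <- g$Sq + t(U[[t]]) %*% dq2[[t]]
      g$Sk <- g$Sk + t(U[[t]]) %*% dk2[[t]]
      g$Sv <- g$Sv + t(U[[t]]) %*% dv2[[t]]
      dU[[t]] <- dq2[[t]] %*% t(params$Sq) + dk2[[t]] %*% t(params$Sk) +
        dv2[[t]] %*% t(params$Sv)
    }
  } else {
    dU <- dS
  }

  dH2 <- if (use_graph) matrix(0, nrow(cache$H2), C) else NULL
  dpooled <- NULL
  dP <- NULL
  n_main <- Tn
  if (use_graph && isTRUE(config$center_token)) {
    dctr <- dU[[Tn]]
    g$Wc <- t(cache$Xc) %*% dctr
    g$bc <- colSums(dctr)
    n_main <- Tn - 1L
  }
  if (use_cross) {
    K <- cache$K; V <- cache$V; Qx <- cache$Qx; A <- cache$A; P <- cache$P
    if (isTRUE(config$pool_token)) dpooled <- dU[[n_main]]
    dK <- matrix(0, nrow(K), C)
    dV <- matrix(0, nrow(V), C)
    dP <- lapply(seq_along(P), function(t) matrix(0, B, C))
    for (t in seq_along(P)) {
      dO <- dU[[t]] %*% t(params$Wo)
      g$Wo <- g$Wo + t(cache$O[[t]]) %*% dU[[t]]
      dOg <- dO[batch$g, , drop = FALSE]
      dV <- dV + A[[t]] * dOg
      dAt <- rowSums(V * dOg)
      rs <- as.numeric(rowsum(A[[t]] * dAt, batch$g))
      dst <- A[[t]] * (dAt - rs[batch$g]) / tau
      dQxt <- rowsum(dst * K, batch$g)
      dK <- dK + dst * Qx[[t]][batch$g, , drop = FALSE]
      g$Wq <- g$Wq + t(P[[t]]) %*% dQxt
      dP[[t]] <- dQxt %*% t(params$Wq)
    }
    g$Wk <- t(cache$H2) %*% dK
    g$Wv <- t(cache$H2) %*% dV
    dH2 <- dH2 + dK %*% t(params$Wk) + dV %*% t(params$Wv)
  } else if (!use_seq) {
    dpooled <- dU[[1]]
  } else if (!use_graph) {
    dP <- dU
  } else {
    dP <- dU[seq_len(n_main - 1)]
    dpooled <- dU[[n_main]]
  }
  if (!is.null(dpooled)) {
    dH2 <- dH2 + dpooled[batch$g, , drop = FALSE] / batch$n_nodes[batch$g]
  }
  if (use_graph) {
    if (config$gcn_layers >= 2) {
      g$Wg2 <- t(cache$Z2) %*% dH2
      g$bg2 <- colSums(dH2)
      dZ2 <- dH2 %*% t(params$Wg2)
      dH1 <- gcn_aggregate(dZ2, batch$edges)
      dH1p <- dH1 * (cache$H1p > 0)
    } else {
      dH1p <- dH2
    }
    g$Wg1 <- t(cache$Z1) %*% dH1p
    g$bg1 <- colSums(dH1p)
  }
  if (use_seq) {
    for (t in seq_along(dP)) {
      Qt <- matrix(batch$Q[, t, , drop = TRUE], nrow = B)
      g$Wp <- g$Wp + t(Qt) %*% dP[[t]]
      g$bp <- g$bp + colSums(dP[[t]])
    }
  }
  g
}

# Mean BCE loss and full gradient for one batch. Dropout masks are
# drawn from the current RNG state when train = TRUE. Optional
# per-sample weights rescale both the loss and its gradient.
fusion_loss_grad <- function(params, batch, config, train = FALSE,
                             sample_weights = NULL) {
  masks <- NULL
  if (train && config$dropout > 0) {
    masks <- lapply(config$classifier_widths, function(w) {
      matrix(stats::rbinom(batch$B * w, 1, 1 - config$dropout) /
               (1 - config$dropout), batch$B, w)
    })
  }
  fw <- fusion_forward_batch(params, batch, config, masks)
  w <- sample_weights %||% rep(1, batch$B)
  p <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
  loss <- mean(-w * (batch$y * log(p) + (1 - batch$y) * log(1 - p)))
  dlogit <- w * (fw$p - batch$y) / batch$B
  grads <- fusion_backward_batch(params, batch, config, fw$cache, dlogit)
  list(loss = loss, p = fw$p, grads = grads)
}

#' AdamW optimiser state
#'
#' Decoupled-weight-decay Adam: moment estimates with bias correction,
#' and weight decay applied directly to weight matrices (not biases).
#'
#' @param params Parameter list.
#' @return Optimiser state.
#' @export
adamw_init <- function(params) {
  zero <- lapply(params, function(x) if (is.matrix(x))
    matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
  list(m = zero, v = zero, t = 0L)
}

#' One AdamW update
#'
#' @param params,grads,state Parameters, gradients, optimiser state.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @return List with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    decay <- if (is.matrix(params[[nm]])) weight_decay else 0
    params[[nm]] <- params[[nm]] - lr * (upd + decay * params[[nm]])
  }
  list(params = params, state = state)
}
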