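test_that("scaled attention reproduces its closed forms", {
  set.seed(8)
  C <- 8
  q <- matrix(rnorm(C), 1)
  v <- matrix(rnorm(C), 1)
  att <- scaled_attention(q, matrix(rnorm(C), 1), v)
  expect_equal(att$weights[1, 1], 1)
  expect_equal(att$output, v)
  # identical keys: output equals the value average regardless of query
  k5 <- matrix(rep(rnorm(C), each = 5), 5)
  v5 <- matrix(rnorm(5 * C), 5)
  a2 <- scaled_attention(q, k5, v5)
  expect_equal(a2$output[1, ], colMeans(v5), tolerance = 1e-9)
  a2b <- scaled_attention(matrix(rnorm(C), 1), k5, v5)
  expect_equal(a2$output, a2b$output, tolerance = 1e-9)
})

test_that("attention matches a dense softmax-matmul oracle and is row-stochastic", {
  set.seed(9)
  C <- 8
  q <- matrix(rnorm(2 * C), 2)
  k <- matrix(rnorm(5 * C), 5)
  v <- matrix(rnorm(5 * C), 5)
  att <- scaled_attention(q, k, v)
  s <- q %*% t(k) / sqrt(C)
  w <- exp(s) / rowSums(exp(s))
  expect_equal(att$output, w %*% v, tolerance = 1e-6)
  expect_equal(rowSums(att$weights), c(1, 1), tolerance = 1e-6)
  # the scaling divisor grows as sqrt(C) with a single head
  qq <- cbind(q, q); kk <- cbind(k, k); vv <- cbind(v, v)
  s2 <- qq %*% t(kk) / sqrt(2 * C)
  w2 <- exp(s2) / rowSums(exp(s2))
  expect_equal(scaled_attention(qq, kk, vv)$weights, w2,
               tolerance = 1e-9)
  expect_error(scaled_attention(q, k[0, , drop = FALSE],
                                v[0, , drop = FALSE]),
               class = "phosfusion_shape_error")
})

test_that("self-attention preserves shape and symmetry", {
  set.seed(10)
  tok <- matrix(rnorm(24), 3, 8)
  out <- self_attention(tok)
  expect_equal(dim(out), dim(tok))
  two <- rbind(tok[1, ], tok[1, ])
  out2 <- self_attention(two)
  expect_equal(out2[1, ], out2[2, ])
  one <- self_attention(tok[1, , drop = FALSE])
  expect_equal(one, tok[1, , drop = FALSE], tolerance = 1e-9)
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bce_loss(1, 1 - 1e-9), 0, tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)),
               mean(c(-log(0.9), -log(0.9))), tolerance = 1e-12)
  expect_true(is.finite(bce_loss(1, 0)))  # clamped
})

test_that("graph encoder handles degenerate and permuted graphs", {
  cfg <- fusion_config(embed_dim = 6, gcn_layers = 1, seed = 2)
  params <- init_fusion_params(cfg, d_graph = 35, d_embed = 8)
  prot <- protein_record("P", "S", cbind(0, 0, 0), 50)
  g <- featurize_nodes(build_site_subgraph(prot, 1), prot)
  enc <- graph_encode(g, params, cfg)
  # single node, one layer: affine map of the node features
  expect_equal(enc$nodes[1, ],
               as.numeric(g$node_features %*% params$Wg1 + params$bg1),
               tolerance = 1e-9)
  expect_error(graph_encode(build_site_subgraph(prot, 1), params, cfg),
               class = "phosfusion_shape_error")
})

test_that("graph encoding matches a dense normalised-adjacency oracle", {
  cfg <- fusion_config(embed_dim = 5, gcn_layers = 2, seed = 3)
  params <- init_fusion_params(cfg, d_graph = 35, d_embed = 8)
  prot <- straight_protein(4)
  g <- featurize_nodes(build_site_subgraph(prot, 2), prot)
  enc <- graph_encode(g, params, cfg)
  n <- length(g$node_ids)
  A <- matrix(0, n, n)
  ei <- match(g$edges$i, g$node_ids); ej <- match(g$edges$j, g$node_ids)
  A[cbind(ei, ej)] <- 1; A[cbind(ej, ei)] <- 1
  Ahat <- A + diag(n)
  Dm <- diag(1 / sqrt(rowSums(Ahat)))
  Ahat <- Dm %*% Ahat %*% Dm
  H1 <- pmax(sweep(Ahat %*% g$node_features %*% params$Wg1, 2,
                   params$bg1, "+"), 0)
  H2 <- sweep(Ahat %*% H1 %*% params$Wg2, 2, params$bg2, "+")
  expect_equal(enc$nodes, H2, tolerance = 1e-6)
  expect_equal(enc$pooled, colMeans(H2), tolerance = 1e-6)
})

test_that("classifier obeys its fixed points and determinism", {
  cfg <- fusion_config(embed_dim = 4, classifier_widths = c(6, 6, 6),
                       seed = 4)
  params <- init_fusion_params(cfg, d_embed = 8)
  zero <- params
  for (nm in names(zero)) {
    if (startsWith(nm, "cls_")) zero[[nm]][] <- 0
  }
  tok <- matrix(rnorm(nrow(params$cls_W1)), ncol = 4)
  expect_equal(classify(tok, zero, cfg), 0.5)
  p1 <- classify(tok, params, cfg)
  expect_identical(p1, classify(tok, params, cfg))
  expect_true(p1 > 0 && p1 < 1)
})

test_that("autodiff gradients match finite differences", {
  study <- tiny_study()
  cfg <- fusion_config(embed_dim = 6, classifier_widths = c(6, 6, 6),
                       dropout = 0, seed = 7)
  params <- init_fusion_params(cfg, d_graph = 35, d_embed = 16)
  batch <- phosfusion:::dataset_batch(study$ds, 1:10)
  lg <- phosfusion:::fusion_loss_grad(params, batch, cfg)
  set.seed(12)
  checked <- 0
  for (nm in sample(names(params))) {
    j <- sample(length(params[[nm]]), 1)
    eps <- 1e-5
    up <- params; up[[nm]][j] <- up[[nm]][j] + eps
    dn <- params; dn[[nm]][j] <- dn[[nm]][j] - eps
    fd <- (phosfusion:::fusion_loss_grad(up, batch, cfg)$loss -
             phosfusion:::fusion_loss_grad(dn, batch, cfg)$loss) / (2 * eps)
    an <- lg$grads[[nm]][j]
    if (abs(fd) > 1e-8 || abs(an) > 1e-8) {
      expect_equal(an, fd, tolerance = 1e-4)
      checked <- checked + 1
    }
    if (checked >= 10) break
  }
  expect_gte(checked, 10)
})

test_that("the forward pass is deterministic and seed-sensitive", {
  study <- tiny_study()
  cfg <- fusion_config(embed_dim = 6, seed = 7)
  params <- init_fusion_params(cfg, d_graph = 35, d_embed = 16)
  batch <- phosfusion:::dataset_batch(study$ds, 1:8)
  l1 <- phosfusion:::fusion_loss_grad(params, batch, cfg)
  l2 <- phosfusion:::fusion_loss_grad(params, batch, cfg)
  expect_identical(l1$loss, l2$loss)
  expect_identical(l1$grads, l2$grads)
  params2 <- init_fusion_params(fusion_config(embed_dim = 6, seed = 8),
                                d_graph = 35, d_embed = 16)
  expect_false(identical(params, params2))
})

test_that("AdamW decays weights but not biases", {
  params <- list(W = matrix(1, 2, 2), b = c(1, 1))
  grads <- list(W = matrix(0, 2, 2), b = c(0, 0))
  st <- adamw_init(params)
  out <- adamw_step(params, grads, st, lr = 0.1, weight_decay = 0.5)
  expect_true(all(out$params$W < 1))
  expect_equal(out$params$b, c(1, 1))
})
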