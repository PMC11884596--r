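# Shared fixtures and independent oracles, built in code.

# Straight-chain protein with 3.8 A C-alpha spacing along x.
straight_protein <- function(n, seq = NULL, plddt = NULL) {
  seq <- seq %||% paste(rep("A", n), collapse = "")
  protein_record("CHAIN", seq,
                 cbind(3.8 * (seq_len(n) - 1), 0, 0),
                 plddt %||% rep(50, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random compact protein: coordinates from a jittered 3.8 A walk.
random_protein <- function(n, acc = "RND", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ca <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- rnorm(3)
    ca[i, ] <- ca[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
  }
  aa <- sample(c("A", "S", "T", "Y", "G", "L", "K"), n, replace = TRUE)
  sc <- ca + matrix(rnorm(3 * n), n, 3) / 2
  sc[aa == "G", ] <- NA
  protein_record(acc, paste(aa, collapse = ""), ca,
                 runif(n, 20, 100), sc)
}

# Brute-force site-subgraph oracle: membership and edge set from
# all-pairs distances, independent of the package's implementation.
subgraph_oracle <- function(protein, site, radius = 8, k = 3) {
  ca <- protein$ca_coords
  L <- nrow(ca)
  d <- as.matrix(dist(ca))
  nodes <- sort(unique(c(site, which(d[site, ] < radius),
                         setdiff(order(d[site, ]), site)[seq_len(min(k, L - 1))])))
  pairs <- t(combn(nodes, 2))
  keep <- apply(pairs, 1, function(p) {
    d[p[1], p[2]] < radius || p[2] - p[1] == 1 ||
      (p[1] == site && p[2] %in% setdiff(order(d[site, ]), site)[1:k]) ||
      (p[2] == site && p[1] %in% setdiff(order(d[site, ]), site)[1:k])
  })
  list(nodes = nodes,
       edges = pairs[keep, , drop = FALSE])
}

# Ideal alpha-helix coordinates (shared geometry for SS tests).
helix_coords <- function(n, rise = 1.5, radius = 2.3, twist = 100) {
  t <- seq_len(n) - 1
  ang <- t * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), rise * t)
}

# Naive O(n^2) metric oracles.
naive_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

naive_aupr <- function(y, s) {
  if (!sum(y == 1) || all(y == 1)) return(NA_real_)
  th <- sort(unique(s), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in th) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    prec <- tp / sum(pred)
    rec <- tp / sum(y == 1)
    area <- area + (rec - prev_r) * prec
    prev_r <- rec
  }
  area
}

naive_metrics <- function(y, s, thr = 0.5) {
  pred <- as.integer(s > thr)
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  den <- sqrt(as.numeric(tp + fn) * (tn + fp) * (tp + fp) * (tn + fn))
  list(accuracy = (tp + tn) / length(y), precision = prec, recall = rec,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
       mcc = if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den)
}

# Random adjacency matrix on n nodes with edge probability p.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# Dense eigendecomposition oracle for eigenvector centrality,
# normalised per connected component like the implementation.
eigen_centrality_oracle <- function(A) {
  comp <- phosfusion:::connected_components(A)
  out <- numeric(nrow(A))
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) {
      out[idx] <- 1
      next
    }
    ev <- eigen(A[idx, idx], symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    out[idx] <- v / sqrt(sum(v^2))
  }
  out
}

# Tiny trainable dataset shared by training tests (built once).
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- generate_synthetic_dataset(
        synth_config(n_proteins = 20, length_range = c(50, 80), seed = 5))
      ds <- build_model_dataset(dat$proteins, dat$sites, graph_config(),
                                embedder_config(mock_dim = 16, seed = 5))
      cache <<- list(dat = dat, ds = ds)
    }
    cache
  }
})
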