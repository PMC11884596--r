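test_that("subgraph membership and edges match the brute-force oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    prot <- random_protein(n)
    site <- sample(n, 1)
    g <- build_site_subgraph(prot, site)
    oracle <- subgraph_oracle(prot, site)
    expect_equal(g$node_ids, oracle$nodes)
    got <- g$edges[order(g$edges$i, g$edges$j), c("i", "j")]
    want <- oracle$edges[order(oracle$edges[, 1], oracle$edges[, 2]), ,
                         drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(want))
  }
})

test_that("k-NN rule admits neighbours beyond the radius", {
  prot <- protein_record("P", "SA", rbind(c(0, 0, 0), c(10, 0, 0)),
                         c(50, 50))
  g <- build_site_subgraph(prot, 1)
  expect_equal(g$node_ids, c(1L, 2L))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$tag, "knn")
})

test_that("straight-chain node set matches the distance rule plus k-NN", {
  prot <- straight_protein(11)
  g <- build_site_subgraph(prot, 6)
  # within 8 A: indices 5-7 (3.8 A) and 4,8 (7.6 A); k-NN adds nothing new
  expect_equal(g$node_ids, 4:8)
  # adjacent pairs both within radius and sequence-adjacent: one edge
  expect_equal(anyDuplicated(g$edges[, c("i", "j")]), 0)
  pair45 <- g$edges[g$edges$i == 4 & g$edges$j == 5, ]
  expect_equal(nrow(pair45), 1)
})

test_that("degenerate subgraph cases behave per contract", {
  single <- protein_record("P", "S", cbind(0, 0, 0), 50)
  g <- build_site_subgraph(single, 1)
  expect_equal(g$node_ids, 1L)
  expect_equal(nrow(g$edges), 0)
  expect_error(build_site_subgraph(single, 2),
               class = "phosfusion_out_of_range")
})

test_that("geometric secondary structure recovers helices and strands", {
  helix <- protein_record("H", paste(rep("A", 20), collapse = ""),
                          helix_coords(20), rep(90, 20))
  ss <- assign_secondary_structure(helix)
  expect_true(all(ss[3:18] == "H"))
  extended <- straight_protein(12)
  ss_e <- assign_secondary_structure(extended)
  expect_false(any(ss_e == "H"))
  expect_true(all(ss_e %in% c("E", "C")))
  expect_equal(assign_secondary_structure(straight_protein(3)),
               rep("C", 3))
})

test_that("RSA is high for exposed residues, low for buried, and clipped", {
  iso <- protein_record("I", "A", cbind(0, 0, 0), 50, cbind(1.5, 0, 0))
  expect_equal(compute_rsa(iso), 1)
  # residue at the centre of a dense cluster of 30 residues within 6 A
  set.seed(4)
  shell <- t(vapply(1:30, function(i) {
    u <- rnorm(3); 4.5 * u / sqrt(sum(u^2))
  }, numeric(3)))
  ca <- rbind(c(0, 0, 0), shell)
  prot <- protein_record("C", paste(rep("L", 31), collapse = ""), ca,
                         rep(50, 31), ca + 0.5)
  expect_lt(compute_rsa(prot)[1], 0.2)
  # implementation point count agrees with a high-resolution oracle
  expect_lt(max(abs(compute_rsa(prot, n_points = 92) -
                      compute_rsa(prot, n_points = 960))), 0.05)
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(eigenvector_centrality(K4), rep(0.5, 4), tolerance = 1e-8)
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  cs <- eigenvector_centrality(star)
  expect_equal(which.max(cs), 1L)
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    A <- random_adjacency(n)
    expect_equal(eigenvector_centrality(A), eigen_centrality_oracle(A),
                 tolerance = 1e-6)
  }
  expect_length(eigenvector_centrality(matrix(0, 0, 0)), 0)
})

test_that("centrality is permutation-equivariant", {
  set.seed(31)
  for (rep in 1:10) {
    A <- random_adjacency(7)
    perm <- sample(7)
    expect_equal(eigenvector_centrality(A[perm, perm]),
                 eigenvector_centrality(A)[perm], tolerance = 1e-6)
  }
})

test_that("node features follow the 35-dimensional layout", {
  layout <- node_feature_layout()
  expect_equal(max(unlist(layout)), 35)
  expect_equal(sum(lengths(layout)), 35)

  prot <- protein_record("P", "GASTY",
                         cbind(3.8 * (0:4), 0, 0), c(30, 40, 50, 60, 70),
                         rbind(c(NA, NA, NA), c(3.8 + 1.5, 0, 0),
                               c(8.1, 0, 0), c(11.9, 0, 0),
                               c(15.7, 0, 0)))
  g <- featurize_nodes(build_site_subgraph(prot, 3), prot)
  X <- g$node_features
  expect_equal(ncol(X), 35)
  expect_false(any(!is.finite(X)))
  expect_equal(unname(rowSums(X[, layout$aa_onehot])), rep(1, 5))
  expect_equal(unname(rowSums(X[, layout$ss_onehot])), rep(1, 5))
  expect_true(all(X[, layout$rsa] >= 0 & X[, layout$rsa] <= 1))
  # glycine: zero sidechain vector; alanine: Cbeta offset (1.5, 0, 0)
  gly <- which(g$node_ids == 1)
  ala <- which(g$node_ids == 2)
  expect_equal(unname(X[gly, layout$sidechain_vector]), c(0, 0, 0))
  expect_equal(unname(X[ala, layout$sidechain_vector]), c(1.5, 0, 0))
  # unit pLDDT scaling
  expect_equal(unname(X[, layout$plddt]), c(30, 40, 50, 60, 70) / 100)
})

test_that("degree feature equals incident edges under subgraph scope", {
  set.seed(41)
  prot <- random_protein(20)
  cfg <- graph_config(centrality_scope = "subgraph")
  g <- featurize_nodes(build_site_subgraph(prot, 10, cfg), prot, cfg)
  layout <- node_feature_layout()
  deg <- vapply(g$node_ids, function(v) {
    sum(g$edges$i == v | g$edges$j == v)
  }, numeric(1))
  expect_equal(unname(g$node_features[, layout$degree]), deg)
})

test_that("unknown residues get a zero one-hot with a warning", {
  prot <- protein_record("P", "AXA", cbind(3.8 * (0:2), 0, 0),
                         rep(50, 3))
  expect_warning(g <- featurize_nodes(build_site_subgraph(prot, 2), prot),
                 "unknown residue")
  layout <- node_feature_layout()
  expect_equal(sum(g$node_features[2, layout$aa_onehot]), 0)
})
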