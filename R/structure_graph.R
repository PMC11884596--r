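#' Structure-graph configuration
#'
#' @param radius Contact radius in Angstrom for distance edges and for
#'   expanding the site-centred subgraph (default 8).
#' @param knn_k Number of nearest neighbours of the site guaranteed to
#'   be included (default 3).
#' @param feature_plddt_scale `"unit"` scales pLDDT to `[0, 1]` in the
#'   feature vector; `"raw"` keeps the 0-100 scale.
#' @param centrality_scope Whether the degree and eigenvector-centrality
#'   features are computed on the whole-protein contact graph (default)
#'   or on the extracted subgraph.
#' @return A `graph_config` list.
#' @export
graph_config <- function(radius = 8, knn_k = 3,
                         feature_plddt_scale = c("unit", "raw"),
                         centrality_scope = c("whole_protein", "subgraph")) {
  stopifnot(radius > 0, knn_k >= 1)
  structure(list(radius = radius, knn_k = as.integer(knn_k),
                 feature_plddt_scale = match.arg(feature_plddt_scale),
                 centrality_scope = match.arg(centrality_scope)),
            class = "graph_config")
}

#' Node feature layout
#'
#' The 35-dimensional per-node feature vector is laid out as: 20-way
#' amino-acid one-hot, relative solvent accessibility (1), pLDDT (1),
#' sidechain direction vector (3), 8-state secondary-structure one-hot,
#' node degree (1) and eigenvector centrality (1). The widths
#' 20+1+1+3+8+1+1 are the unique integer split of the seven residue
#' properties consistent with a 35-dimensional total.
#'
#' @return Named list mapping each block to its column indices.
#' @export
node_feature_layout <- function() {
  list(aa_onehot = 1:20, rsa = 21L, plddt = 22L, sidechain_vector = 23:25,
       ss_onehot = 26:33, degree = 34L, eigenvector_centrality = 35L)
}

# Whole-protein C-alpha contact adjacency (logical matrix, no self
# contacts): residues closer than `radius` Angstrom.
contact_adjacency <- function(ca_coords, radius = 8) {
  d <- as.matrix(stats::dist(ca_coords))
  adj <- d < radius
  diag(adj) <- FALSE
  adj
}

#' Build the site-centred local structure graph
#'
#' The node set is the site plus all residues whose C-alpha lies within
#' `radius` Angstrom of the site's C-alpha, plus the `knn_k` nearest
#' residues to the site (so the nearest neighbours are included even
#' beyond the radius). Edges combine three rules: distance edges between
#' any node pair closer than `radius`; k-NN edges from the centre to its
#' `knn_k` nearest residues; peptide edges between sequence-adjacent
#' nodes. A pair satisfying several rules gets exactly one edge, tagged
#' with the first matching rule in the order distance, knn, peptide.
#'
#' @param protein A [protein_record()].
#' @param site_position 1-based residue index of the phosphorylation site.
#' @param config A [graph_config()].
#' @return A `residue_graph`: list with `node_ids` (sorted residue
#'   indices), `center`, `edges` (data frame `i`, `j`, `tag` with
#'   `i < j`, residue indices) and `node_features` (`NULL` until
#'   [featurize_nodes()] is called).
#' @export
build_site_subgraph <- function(protein, site_position,
                                config = graph_config()) {
  L <- nchar(protein$sequence)
  site_position <- as.integer(site_position)
  if (site_position < 1 || site_position > L) {
    stop_pf("site position %d outside sequence of length %d",
            "phosfusion_out_of_range", site_position, L)
  }
  ca <- protein$ca_coords
  d_center <- sqrt(colSums((t(ca) - ca[site_position, ])^2))
  within <- which(d_center < config$radius)
  others <- setdiff(seq_len(L), site_position)
  knn <- others[order(d_center[others])][seq_len(min(config$knn_k,
                                                     length(others)))]
  nodes <- sort(unique(c(site_position, within, knn)))
  n <- length(nodes)
  edges <- data.frame(i = integer(0), j = integer(0), tag = character(0))
  if (n > 1) {
    sub_d <- as.matrix(stats::dist(ca[nodes, , drop = FALSE]))
    pair <- which(upper.tri(sub_d) & sub_d < config$radius, arr.ind = TRUE)
    e_dist <- data.frame(i = nodes[pair[, 1]], j = nodes[pair[, 2]],
                         tag = rep("distance", nrow(pair)))
    e_knn <- data.frame(i = pmin(site_position, knn),
                        j = pmax(site_position, knn),
                        tag = rep("knn", length(knn)))
    adjacent <- nodes[which(diff(nodes) == 1)]
    e_pep <- data.frame(i = adjacent, j = adjacent + 1L,
                        tag = rep("peptide", length(adjacent)))
    edges <- rbind(e_dist, e_knn, e_pep)
    edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(node_ids = nodes, center = site_position, edges = edges,
                 node_features = NULL),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> centre %d: %d nodes, %d edges%s\n",
              x$center, length(x$node_ids), nrow(x$edges),
              if (is.null(x$node_features)) "" else ", featurized"))
  invisible(x)
}

#' Assign secondary structure from C-alpha geometry
#'
#' Geometric three-state assignment in the spirit of P-SEA: for residue
#' i the distances d(i, i+2), d(i, i+3) and d(i, i+4) are compared with
#' their ideal alpha-helix values (5.43, 5.05 and 6.20 Angstrom for a
#' 1.5 Angstrom rise, 2.3 Angstrom radius, 100 degrees per residue);
#' windows matching all three mark residues i..i+4 as H. Extended
#' stretches (d(i, i+2) > 6.3 and d(i, i+3) > 9.0) mark i..i+3 as E.
#' Everything else is coil. Chains shorter than 5 residues are all C.
#' An external DSSP backend can replace this assigner where the full
#' 8-state alphabet is required; the built-in one only emits H/E/C.
#'
#' @param protein A [protein_record()].
#' @return Character vector over `c("H", "E", "C")`, one per residue.
#' @export
assign_secondary_structure <- function(protein) {
  ca <- protein$ca_coords
  L <- nrow(ca)
  ss <- rep("C", L)
  if (L < 5) return(ss)
  d_k <- function(k) {
    i <- seq_len(L - k)
    sqrt(rowSums((ca[i + k, , drop = FALSE] - ca[i, , drop = FALSE])^2))
  }
  d2 <- d_k(2); d3 <- d_k(3); d4 <- d_k(4)
  helix_start <- which(abs(d2[seq_len(L - 4)] - 5.43) < 0.55 &
                         abs(d3[seq_len(L - 4)] - 5.05) < 0.55 &
                         abs(d4 - 6.20) < 0.55)
  for (i in helix_start) ss[i:(i + 4)] <- "H"
  ext_start <- which(d2[seq_len(L - 3)] > 6.3 & d3 > 9.0)
  for (i in ext_start) {
    idx <- i:(i + 3)
    ss[idx][ss[idx] != "H"] <- "E"
  }
  ss
}

# Residue-specific sidechain pseudo-atom radii (Angstrom), a coarse
# monotone map of sidechain size; 0 means no sidechain sphere (glycine).
SIDECHAIN_RADIUS <- c(A = 1.9, C = 2.2, D = 2.3, E = 2.5, F = 2.9, G = 0,
                      H = 2.7, I = 2.6, K = 2.7, L = 2.6, M = 2.7, N = 2.3,
                      P = 2.3, Q = 2.5, R = 2.9, S = 2.0, T = 2.3, V = 2.4,
                      W = 3.1, Y = 2.9, X = 2.4)

# Theoretical maximum accessible surface areas (Angstrom^2) per residue
# (Tien et al. 2013 theoretical values), used to normalise ASA to RSA.
MAX_ASA <- c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104,
             H = 224, I = 197, K = 236, L = 201, M = 224, N = 195,
             P = 159, Q = 225, R = 274, S = 155, T = 172, V = 174,
             W = 285, Y = 263, X = 200)

#' Relative solvent accessibility from a sphere model
#'
#' Shrake-Rupley numeric accessible surface over a reduced
#' representation: each residue contributes a backbone sphere at its
#' C-alpha (radius 2.0 Angstrom) and, when present, a sidechain sphere
#' at the sidechain centre with a residue-specific radius. The
#' accessible area of each residue's spheres (probe 1.4 Angstrom) is
#' divided by the residue's theoretical maximum ASA and clipped to
#' `[0, 1]`. A coarse but monotone accessibility measure; a DSSP
#' backend can be substituted where all-atom accuracy is needed.
#'
#' @param protein A [protein_record()].
#' @param n_points Sphere sample points per atom (default 92).
#' @param probe Probe radius in Angstrom.
#' @return Numeric vector of per-residue RSA values in `[0, 1]`.
#' @export
compute_rsa <- function(protein, n_points = 92, probe = 1.4) {
  L <- nchar(protein$sequence)
  aa <- strsplit(protein$sequence, "")[[1]]
  aa[!(aa %in% names(SIDECHAIN_RADIUS))] <- "X"
  centers <- protein$ca_coords
  radii <- rep(2.0, L)
  res_of <- seq_len(L)
  sc_ok <- !is.na(protein$sidechain_centers[, 1]) & SIDECHAIN_RADIUS[aa] > 0
  if (any(sc_ok)) {
    centers <- rbind(centers, protein$sidechain_centers[sc_ok, , drop = FALSE])
    radii <- c(radii, unname(SIDECHAIN_RADIUS[aa[sc_ok]]))
    res_of <- c(res_of, which(sc_ok))
  }
  pts <- fibonacci_sphere(n_points)
  R <- radii + probe
  n_atoms <- length(R)
  asa_atom <- numeric(n_atoms)
  d2mat <- as.matrix(stats::dist(centers))
  for (a in seq_len(n_atoms)) {
    nb <- which(d2mat[a, ] < R[a] + R & seq_len(n_atoms) != a)
    surf <- sweep(pts * R[a], 2, centers[a, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      occluded <- rep(FALSE, n_points)
      for (b in nb) {
        dd <- colSums((t(surf) - centers[b, ])^2)
        occluded <- occluded | dd < R[b]^2
        if (all(occluded)) break
      }
      acc <- sum(!occluded)
    }
    asa_atom[a] <- 4 * pi * R[a]^2 * acc / n_points
  }
  asa <- as.numeric(rowsum(asa_atom, res_of))
  pmin(1, asa / unname(MAX_ASA[aa]))
}

# Deterministic quasi-uniform points on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Eigenvector centrality by power iteration
#'
#' Principal eigenvector of the adjacency matrix, computed per connected
#' component by power iteration from the uniform vector (tolerance 1e-8,
#' at most 1000 iterations), with nonnegative entries and each
#' component's sub-vector L2-normalised. A single-node component scores
#' 1 (its trivial normalised eigenvector).
#'
#' @param adjacency Symmetric binary matrix without self-loops.
#' @param tol,max_iter Power-iteration controls.
#' @return Numeric vector of per-node scores (empty for an empty graph).
#' @export
eigenvector_centrality <- function(adjacency, tol = 1e-8, max_iter = 1000) {
  n <- nrow(adjacency)
  if (is.null(n) || n == 0) return(numeric(0))
  adjacency <- (adjacency != 0) * 1
  comp <- connected_components(adjacency)
  score <- numeric(n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) {
      score[idx] <- 1
      next
    }
    A <- adjacency[idx, idx, drop = FALSE]
    v <- rep(1 / sqrt(length(idx)), length(idx))
    for (it in seq_len(max_iter)) {
      # spectral shift (A + I) guarantees convergence on bipartite
      # components, whose unshifted spectrum is symmetric; the
      # principal eigenvector is unchanged
      w <- as.numeric(A %*% v) + v
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      w <- w / nw
      if (max(abs(w - v)) < tol) {
        v <- w
        break
      }
      v <- w
    }
    score[idx] <- abs(v)
  }
  score
}

# Connected components of an undirected adjacency matrix (BFS).
connected_components <- function(adjacency) {
  n <- nrow(adjacency)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adjacency[v, ] != 0 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# Per-protein structural context shared by featurization and the site
# statistics module: secondary structure, RSA, whole-protein contact
# degree and eigenvector centrality. Computed once per protein.
protein_site_features <- function(protein, config = graph_config()) {
  adj <- contact_adjacency(protein$ca_coords, config$radius)
  list(ss = assign_secondary_structure(protein),
       rsa = compute_rsa(protein),
       degree = rowSums(adj),
       centrality = eigenvector_centrality(adj))
}

#' Compute 35-dimensional node features for a residue graph
#'
#' Fills `graph$node_features` per [node_feature_layout()]: amino-acid
#' one-hot (unknown letters get an all-zero block with a warning), RSA,
#' pLDDT (unit-scaled by default), the C-alpha-to-sidechain-centre
#' vector (zero when no sidechain centre exists), 8-state secondary
#' structure one-hot, degree and eigenvector centrality. Degree and
#' centrality come from the whole-protein contact graph or from the
#' subgraph, per `config$centrality_scope`.
#'
#' @param graph A `residue_graph` from [build_site_subgraph()].
#' @param protein The owning [protein_record()].
#' @param config A [graph_config()].
#' @param context Optional precomputed `protein_site_features()` list,
#'   to avoid recomputation across the many sites of one protein.
#' @return The graph with a `node_features` matrix (nodes x 35).
#' @export
featurize_nodes <- function(graph, protein, config = graph_config(),
                            context = NULL) {
  nodes <- graph$node_ids
  n <- length(nodes)
  if (is.null(context)) context <- protein_site_features(protein, config)
  feats <- matrix(0, n, 35)
  layout <- node_feature_layout()
  aa <- strsplit(protein$sequence, "")[[1]][nodes]
  hit <- match(aa, AA_ALPHABET)
  if (anyNA(hit)) {
    warning(sprintf("%d node(s) with unknown residue letter: all-zero one-hot",
                    sum(is.na(hit))))
  }
  for (t in seq_len(n)) {
    if (!is.na(hit[t])) feats[t, layout$aa_onehot[hit[t]]] <- 1
  }
  feats[, layout$rsa] <- context$rsa[nodes]
  pl <- protein$plddt[nodes]
  feats[, layout$plddt] <- if (config$feature_plddt_scale == "unit")
    pl / 100 else pl
  sc <- protein$sidechain_centers[nodes, , drop = FALSE] -
    protein$ca_coords[nodes, , drop = FALSE]
  sc[is.na(sc)] <- 0
  feats[, layout$sidechain_vector] <- sc
  ss_hit <- match(context$ss[nodes], SS8_ALPHABET)
  for (t in seq_len(n)) feats[t, layout$ss_onehot[ss_hit[t]]] <- 1
  if (config$centrality_scope == "whole_protein") {
    feats[, layout$degree] <- context$degree[nodes]
    feats[, layout$eigenvector_centrality] <- context$centrality[nodes]
  } else {
    adj <- matrix(0, n, n)
    if (nrow(graph$edges) > 0) {
      ei <- match(graph$edges$i, nodes)
      ej <- match(graph$edges$j, nodes)
      adj[cbind(ei, ej)] <- 1
      adj[cbind(ej, ei)] <- 1
    }
    feats[, layout$degree] <- rowSums(adj)
    feats[, layout$eigenvector_centrality] <- eigenvector_centrality(adj)
  }
  graph$node_features <- feats
  graph
}
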