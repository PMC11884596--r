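#' Synthetic-data configuration
#'
#' Generates toy single-chain proteins whose statistical structure
#' mirrors what the model assumes about real phosphoproteomes: chains
#' alternate ideal alpha-helix segments (high pLDDT, 70-95) and
#' self-avoiding random-coil segments (low pLDDT, 30-60); candidate
#' phosphosites (S/T/Y) are planted along the chain and their
#' functional labels are drawn from a logistic rule over coil location,
#' whole-protein eigenvector centrality and a +1-proline motif, so
#' functional sites end up enriched in flexible, low-confidence,
#' high-centrality regions. Non-site residues use segment-typed letter
#' frequencies (helix formers in helices, coil formers in coils), so
#' local sequence carries structural context the way real sequences do.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Chain length range (residues).
#' @param helix_len,coil_len Mean extra length of helix/coil segments
#'   beyond their minima (5 and 4 residues).
#' @param plddt_helix,plddt_coil Uniform pLDDT ranges per segment type.
#' @param site_rate Expected planted sites per residue.
#' @param p_motif Probability of forcing a proline at site position +1.
#' @param weights Planted logistic weights, named `w_coil`,
#'   `w_centrality`, `w_motif`, `bias` (functional-site rule).
#' @param weights_induced Planted weights for the enzyme regulatory
#'   rule (`v_coil`, `v_centrality`, `v_motif`, `bias`), partially
#'   overlapping with `weights` so transfer learning helps.
#' @param seed Integer seed; fixes every draw including label draws.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 200, length_range = c(60, 180),
                         helix_len = 6, coil_len = 5,
                         plddt_helix = c(70, 95), plddt_coil = c(30, 60),
                         site_rate = 0.085, p_motif = 0.35,
                         weights = c(w_coil = 4.0, w_centrality = 1.0,
                                     w_motif = 1.5, bias = -2.5),
                         weights_induced = c(v_coil = 2.5,
                                             v_centrality = 1.0,
                                             v_motif = -1.5, bias = -0.8),
                         seed = 1) {
  stopifnot(n_proteins >= 1, length_range[1] >= 10, site_rate > 0,
            p_motif >= 0, p_motif <= 1, all(is.finite(weights)),
            all(is.finite(weights_induced)))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 helix_len = helix_len, coil_len = coil_len,
                 plddt_helix = plddt_helix, plddt_coil = plddt_coil,
                 site_rate = site_rate, p_motif = p_motif,
                 weights = weights, weights_induced = weights_induced,
                 seed = as.integer(seed)),
            class = "synth_config")
}

HELIX_LETTERS <- c(A = 0.22, L = 0.20, E = 0.15, K = 0.13, M = 0.10,
                   Q = 0.08, I = 0.07, R = 0.05)
COIL_LETTERS <- c(G = 0.22, P = 0.18, N = 0.14, D = 0.14, S = 0.12,
                  T = 0.10, K = 0.05, Q = 0.05)

# Ideal alpha-helix C-alpha trace: rise 1.5 A, radius 2.3 A, 100
# degrees per residue (consecutive separation about 3.83 A).
ideal_helix_coords <- function(n) {
  t <- seq_len(n) - 1
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# One synthetic backbone: list(ca, segment type per residue).
generate_backbone <- function(L, config) {
  seg_type <- character(0)
  ca <- matrix(numeric(0), 0, 3)
  current_type <- sample(c("helix", "coil"), 1)
  while (nrow(ca) < L) {
    n_seg <- if (current_type == "helix") {
      5 + stats::rpois(1, config$helix_len)
    } else {
      4 + stats::rpois(1, config$coil_len)
    }
    n_seg <- min(n_seg, L - nrow(ca))
    if (current_type == "helix" && n_seg >= 1) {
      placed <- FALSE
      for (try in 1:20) {
        R <- random_rotation()
        local <- ideal_helix_coords(n_seg) %*% t(R)
        start <- if (nrow(ca) == 0) c(0, 0, 0) else
          ca[nrow(ca), ] + 3.8 * random_unit()
        cand <- sweep(local, 2, local[1, ] - start, "-")
        if (nrow(ca) == 0 || min_dist(cand, ca) > 3.0) {
          placed <- TRUE
          break
        }
      }
      ca <- rbind(ca, cand)
    } else {
      for (i in seq_len(n_seg)) {
        prev <- if (nrow(ca) == 0) c(0, 0, 0) else ca[nrow(ca), ]
        best <- NULL
        for (try in 1:50) {
          cand <- prev + 3.8 * random_unit()
          others <- if (nrow(ca) > 1)
            ca[seq_len(nrow(ca) - 1), , drop = FALSE] else NULL
          if (is.null(others) || min_dist(matrix(cand, 1), others) > 3.2) {
            best <- cand
            break
          }
          best <- best %||% cand
        }
        if (nrow(ca) == 0) best <- c(0, 0, 0)
        ca <- rbind(ca, best)
      }
    }
    seg_type <- c(seg_type, rep(current_type, n_seg))
    current_type <- if (current_type == "helix") "coil" else "helix"
  }
  list(ca = ca[seq_len(L), , drop = FALSE], segment = seg_type[seq_len(L)])
}

min_dist <- function(A, B) {
  min(vapply(seq_len(nrow(A)), function(i) {
    min(sqrt(colSums((t(B) - A[i, ])^2)))
  }, numeric(1)))
}

#' Generate synthetic proteins
#'
#' @param config A [synth_config()].
#' @return List with `proteins` (named list of [protein_record()]),
#'   `segments` (per-protein segment-type vectors) and `site_positions`
#'   (per-protein planted candidate positions).
#' @export
generate_proteins <- function(config = synth_config()) {
  with_local_seed(derive_seed(config$seed, "proteins"), {
    proteins <- list()
    segments <- list()
    site_positions <- list()
    for (pi in seq_len(config$n_proteins)) {
      acc <- sprintf("SYN%04d", pi)
      L <- sample(config$length_range[1]:config$length_range[2], 1)
      bb <- generate_backbone(L, config)
      n_sites <- max(1L, round(L * config$site_rate))
      pos <- sort(sample(2:(L - 1), min(n_sites, L - 2)))
      # keep sites two residues apart so the +1 motif slot never
      # collides with another site
      pos <- pos[c(TRUE, diff(pos) >= 2)]
      seq_letters <- vapply(bb$segment, function(st) {
        tab <- if (st == "helix") HELIX_LETTERS else COIL_LETTERS
        sample(names(tab), 1, prob = tab)
      }, character(1))
      seq_letters[pos] <- sample(c("S", "T", "Y"), length(pos),
                                 replace = TRUE)
      has_motif <- stats::runif(length(pos)) < config$p_motif
      seq_letters[pos[has_motif] + 1L] <- "P"
      plddt <- ifelse(bb$segment == "helix",
                      stats::runif(L, config$plddt_helix[1],
                                   config$plddt_helix[2]),
                      stats::runif(L, config$plddt_coil[1],
                                   config$plddt_coil[2]))
      sc <- bb$ca + t(vapply(seq_len(L), function(i) random_unit(),
                             numeric(3)))
      sc[seq_letters == "G", ] <- NA_real_
      proteins[[acc]] <- protein_record(acc, paste(seq_letters,
                                                   collapse = ""),
                                        bb$ca, plddt, sc)
      segments[[acc]] <- bb$segment
      site_positions[[acc]] <- pos
    }
    list(proteins = proteins, segments = segments,
         site_positions = site_positions)
  })
}

#' Plant functional and regulatory labels on synthetic sites
#'
#' For each candidate site the true functional probability is
#' `sigmoid(w_coil * coil + w_centrality * z + w_motif * motif + bias)`
#' with `coil` the true segment indicator, `z` the dataset-standardised
#' whole-protein eigenvector centrality of the site residue and `motif`
#' the +1-proline indicator; the label is a Bernoulli draw. A second
#' partially overlapping rule generates the induced/inhibited truth for
#' the enzyme regulatory task. Every generative quantity is recorded.
#'
#' @param generated Output of [generate_proteins()].
#' @param config The same [synth_config()].
#' @param graph_cfg Graph configuration for the centrality feature.
#' @return List with `sites` (data frame ready for the curation and
#'   training modules, with `annotations` reflecting the labels) and
#'   `ground_truth` (per-site generative features and probabilities).
#' @export
plant_labels <- function(generated, config = synth_config(),
                         graph_cfg = graph_config()) {
  proteins <- generated$proteins
  rows <- list()
  for (acc in names(proteins)) {
    prot <- proteins[[acc]]
    pos <- generated$site_positions[[acc]]
    adj <- contact_adjacency(prot$ca_coords, graph_cfg$radius)
    cent <- eigenvector_centrality(adj)
    seg <- generated$segments[[acc]]
    seqc <- strsplit(prot$sequence, "")[[1]]
    rows[[acc]] <- data.frame(
      accession = acc, position = pos,
      residue = seqc[pos],
      coil = as.integer(seg[pos] == "coil"),
      centrality = cent[pos],
      motif = as.integer(seqc[pmin(pos + 1L, length(seqc))] == "P"),
      plddt = prot$plddt[pos], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  z <- (tab$centrality - mean(tab$centrality)) / stats::sd(tab$centrality)
  w <- config$weights
  eta <- w[["w_coil"]] * tab$coil + w[["w_centrality"]] * z +
    w[["w_motif"]] * tab$motif + w[["bias"]]
  p_fun <- 1 / (1 + exp(-eta))
  v <- config$weights_induced
  eta2 <- v[["v_coil"]] * tab$coil + v[["v_centrality"]] * z +
    v[["v_motif"]] * tab$motif + v[["bias"]]
  p_ind <- 1 / (1 + exp(-eta2))
  with_local_seed(derive_seed(config$seed, "labels"), {
    y <- stats::rbinom(nrow(tab), 1, p_fun)
    y_ind <- stats::rbinom(nrow(tab), 1, p_ind)
    ann <- ifelse(y == 1, "regulatory", "")
    enzyme <- y == 1
    ann[enzyme] <- paste0(ann[enzyme], ";enzymatic activity, ",
                          ifelse(y_ind[enzyme] == 1, "induced", "inhibited"))
    sites <- data.frame(accession = tab$accession, position = tab$position,
                        residue = tab$residue, annotations = ann,
                        functional_label = y, induced_label = y_ind,
                        stringsAsFactors = FALSE)
    attr(sites, "ann_delim") <- ";"
    gt <- cbind(tab[, c("accession", "position", "coil", "centrality",
                        "motif", "plddt")],
                centrality_z = z, true_prob = p_fun,
                true_prob_induced = p_ind, functional_label = y,
                induced_label = y_ind)
    list(sites = sites, ground_truth = gt)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_proteins()] then [plant_labels()].
#'
#' @param config A [synth_config()].
#' @param graph_cfg A [graph_config()].
#' @return List with `proteins`, `sites`, `ground_truth`, `segments`.
#' @export
generate_synthetic_dataset <- function(config = synth_config(),
                                       graph_cfg = graph_config()) {
  gen <- generate_proteins(config)
  pl <- plant_labels(gen, config, graph_cfg)
  list(proteins = gen$proteins, sites = pl$sites,
       ground_truth = pl$ground_truth, segments = gen$segments)
}

#' Write a synthetic dataset to disk
#'
#' Produces one PDB per protein (pLDDT in the B-factor column, a CB
#' pseudo-atom at the sidechain centre), a FASTA of all sequences, the
#' site table as TSV and the ground truth as JSON.
#'
#' @param dataset Output of [generate_synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  for (acc in names(dataset$proteins)) {
    write_protein_pdb(dataset$proteins[[acc]],
                      file.path(dir, "structures", paste0(acc, ".pdb")))
  }
  write_fasta(vapply(dataset$proteins, function(p) p$sequence, ""),
              file.path(dir, "sequences.fasta"))
  utils::write.table(dataset$sites, file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Write a protein record as a minimal PDB file
#'
#' CA atoms carry the pLDDT in the B-factor column; residues with a
#' sidechain centre get a CB pseudo-atom there.
#'
#' @param protein A [protein_record()].
#' @param path Output path.
#' @export
write_protein_pdb <- function(protein, path) {
  aa3 <- vapply(strsplit(protein$sequence, "")[[1]], function(a) {
    out <- suppressWarnings(bio3d::aa123(a))
    if (is.na(out) || a == "X") "UNK" else out
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  fmt <- "ATOM  %5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s"
  for (i in seq_len(nchar(protein$sequence))) {
    serial <- serial + 1L
    writeLines(sprintf(fmt, serial, "CA", aa3[i], i,
                       protein$ca_coords[i, 1], protein$ca_coords[i, 2],
                       protein$ca_coords[i, 3], 1.0, protein$plddt[i],
                       "C"), con)
    if (!is.na(protein$sidechain_centers[i, 1])) {
      serial <- serial + 1L
      writeLines(sprintf(fmt, serial, "CB", aa3[i], i,
                         protein$sidechain_centers[i, 1],
                         protein$sidechain_centers[i, 2],
                         protein$sidechain_centers[i, 3], 1.0,
                         protein$plddt[i], "C"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
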