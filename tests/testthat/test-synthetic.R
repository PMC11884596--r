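test_that("generated backbones respect geometric constraints", {
  gen <- generate_proteins(synth_config(n_proteins = 5,
                                        length_range = c(40, 80),
                                        seed = 8))
  for (acc in names(gen$proteins)) {
    p <- gen$proteins[[acc]]
    ca <- p$ca_coords
    step <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
    expect_true(all(step >= 3.6 & step <= 4.0))
    expect_true(all(p$plddt >= 0 & p$plddt <= 100))
    # pLDDT regimes track the segment type
    seg <- gen$segments[[acc]]
    expect_true(all(p$plddt[seg == "helix"] >= 70))
    expect_true(all(p$plddt[seg == "coil"] <= 60))
    # glycine has no sidechain centre, others do
    aa <- strsplit(p$sequence, "")[[1]]
    expect_true(all(is.na(p$sidechain_centers[aa == "G", 1])))
    expect_true(all(!is.na(p$sidechain_centers[aa != "G", 1])))
    # planted candidate sites are S/T/Y
    expect_true(all(aa[gen$site_positions[[acc]]] %in% c("S", "T", "Y")))
  }
})

test_that("helix segments are recognised by the secondary-structure assigner", {
  gen <- generate_proteins(synth_config(n_proteins = 6,
                                        length_range = c(60, 100),
                                        seed = 9))
  rates <- vapply(names(gen$proteins), function(acc) {
    ss <- assign_secondary_structure(gen$proteins[[acc]])
    seg <- gen$segments[[acc]]
    # interior helix residues: 2 positions from the segment ends
    interior <- seg == "helix" &
      c(FALSE, FALSE, seg[-c(1, 2)] == "helix") &
      c(seg[-c(1, 2)] == "helix", FALSE, FALSE)
    if (!sum(interior)) return(NA_real_)
    mean(ss[interior] == "H")
  }, numeric(1))
  expect_gte(mean(rates, na.rm = TRUE), 0.8)
})

test_that("generation is fully deterministic under a fixed seed", {
  c1 <- generate_synthetic_dataset(synth_config(n_proteins = 3, seed = 10))
  c2 <- generate_synthetic_dataset(synth_config(n_proteins = 3, seed = 10))
  expect_identical(c1$sites, c2$sites)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$proteins$SYN0001$ca_coords,
                   c2$proteins$SYN0001$ca_coords)
})

test_that("planted probabilities follow the logistic rule", {
  gen <- generate_proteins(synth_config(n_proteins = 4, seed = 12))
  flat <- plant_labels(gen, synth_config(
    n_proteins = 4, seed = 12,
    weights = c(w_coil = 0, w_centrality = 0, w_motif = 0, bias = 0)))
  expect_true(all(flat$ground_truth$true_prob == 0.5))
  sat <- plant_labels(gen, synth_config(
    n_proteins = 4, seed = 12,
    weights = c(w_coil = 50, w_centrality = 0, w_motif = 0, bias = -25)))
  gt <- sat$ground_truth
  expect_true(all(gt$true_prob[gt$coil == 1] > 0.999))
  expect_true(all(gt$true_prob[gt$coil == 0] < 0.001))
})

test_that("planted weights are recoverable by logistic regression", {
  dat <- generate_synthetic_dataset(synth_config(n_proteins = 500,
                                                 seed = 13))
  gt <- dat$ground_truth
  expect_gte(nrow(gt), 4000)
  fit <- glm(functional_label ~ coil + centrality_z + motif, data = gt,
             family = binomial)
  w <- synth_config()$weights
  est <- coef(fit)
  expect_lt(abs(est[["coil"]] - w[["w_coil"]]) / w[["w_coil"]], 0.2)
  expect_lt(abs(est[["centrality_z"]] - w[["w_centrality"]]) /
              w[["w_centrality"]], 0.2)
  expect_lt(abs(est[["motif"]] - w[["w_motif"]]) / w[["w_motif"]], 0.2)
})

test_that("positives carry the expected structural signatures", {
  dat <- generate_synthetic_dataset(synth_config(seed = 14))
  gt <- dat$ground_truth
  expect_gte(nrow(gt), 1000)
  pos <- gt$functional_label == 1
  expect_gt(mean(gt$coil[pos]), mean(gt$coil[!pos]))
  expect_gt(mean(gt$centrality[pos]), mean(gt$centrality[!pos]))
  expect_gt(mean(gt$plddt[!pos]), mean(gt$plddt[pos]))
})

test_that("a written synthetic dataset is readable by the io module", {
  dat <- generate_synthetic_dataset(synth_config(n_proteins = 2,
                                                 length_range = c(30, 40),
                                                 seed = 15))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(dat, dir)
  sites <- read_site_table(file.path(dir, "sites.tsv"))
  expect_equal(nrow(sites), nrow(dat$sites))
  prot <- read_structure(file.path(dir, "structures", "SYN0001.pdb"))
  expect_equal(prot$sequence, dat$proteins$SYN0001$sequence)
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  expect_equal(unname(seqs["SYN0002"]), dat$proteins$SYN0002$sequence)
  expect_true(all(validate_sites(sites, list(SYN0001 = prot,
                                             SYN0002 = read_structure(
                                               file.path(dir, "structures",
                                                         "SYN0002.pdb"))))))
})
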