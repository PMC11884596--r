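make_sites <- function(anns) {
  s <- data.frame(accession = sprintf("P%d", seq_along(anns)),
                  position = 1L, residue = "S", annotations = anns,
                  stringsAsFactors = FALSE)
  attr(s, "ann_delim") <- ";"
  s
}

test_that("functional labels follow the annotation rule", {
  s <- label_functional(make_sites(c("regulatory", "",
                                     "disease-associated",
                                     "protein conformation",
                                     "regulatory;disease-associated")))
  expect_equal(s$functional_label, c(1L, 0L, 1L, 0L, 1L))
})

test_that("regulatory labels resolve conflicts toward inhibited", {
  s <- label_regulatory(make_sites(c(
    "enzymatic activity, inhibited;enzymatic activity, induced",
    "enzymatic activity, induced",
    "protein conformation",
    "enzymatic activity, inhibited")))
  expect_equal(as.character(s$regulatory_label),
               c("inhibited", "induced", "inhibited"))
  expect_equal(nrow(s), 3)  # unannotated site dropped
})

test_that("protein/site filters remove isoforms and mismatches, and are idempotent", {
  prots <- list(P1 = straight_protein(6, "ASTYGA"),
                `P2-2` = straight_protein(5, "AAAAA"),
                P3 = straight_protein(4, "STYS"))
  sites <- data.frame(accession = c("P1", "P1", "P2-2", "P3", "P9"),
                      position = c(2, 3, 1, 2, 1),
                      residue = c("S", "S", "A", "T", "S"),
                      annotations = "")
  out <- suppressMessages(filter_proteins(prots, sites,
                                          structures = c("P1", "P3")))
  expect_equal(names(out$proteins), c("P1", "P3"))
  # kept: P1 pos2 (S matches), P3 pos2 (T matches); dropped: P1 pos3
  # mismatch, isoform's site, unknown accession
  expect_equal(nrow(out$sites), 2)
  again <- suppressMessages(filter_proteins(out$proteins, out$sites,
                                            structures = c("P1", "P3")))
  expect_identical(again$sites, out$sites)
  expect_identical(names(again$proteins), names(out$proteins))

  clean <- suppressMessages(filter_proteins(prots["P1"],
                                            sites[1, , drop = FALSE]))
  expect_equal(nrow(clean$sites), 1)
})

test_that("redundancy reduction collapses near-identical sequences only", {
  s1 <- paste(rep("ACDEFGHIKL", 6), collapse = "")
  s2 <- s1
  substr(s2, 5, 5) <- "W"   # one substitution: identity 59/60
  s3 <- paste(rep("MNPQRSTVWY", 6), collapse = "")
  red <- reduce_redundancy(c(a = s1, b = s2, c = s3), threshold = 0.8)
  expect_equal(length(red$representatives), 2)
  expect_equal(red$clusters[1], red$clusters[2])
  expect_false(red$clusters[3] == red$clusters[1])

  two <- reduce_redundancy(c(x = s1, y = s1), threshold = 0.8)
  expect_equal(length(two$representatives), 1)
})

test_that("greedy clustering matches a Needleman-Wunsch identity oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(7)
  base <- vapply(1:4, function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                 50, replace = TRUE), collapse = "")
  }, character(1))
  # 10 sequences: 4 seeds plus mutated copies at ~90% identity
  mutate <- function(s, k) {
    pos <- sample(nchar(s), k)
    for (p in pos) substr(s, p, p) <- sample(c("M", "N", "P", "Q"), 1)
    s
  }
  seqs <- c(base, vapply(base, mutate, "", k = 5),
            mutate(base[1], 4), mutate(base[2], 3))
  names(seqs) <- sprintf("s%02d", seq_along(seqs))

  nw_identity <- function(a, b) {
    al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = NULL,
                                        gapOpening = 10, gapExtension = 4)
    Biostrings::nmatch(al) / min(nchar(a), nchar(b))
  }
  greedy_oracle <- function(seqs, thr) {
    ord <- order(-nchar(seqs))
    reps <- integer(0)
    cl <- integer(length(seqs))
    for (i in ord) {
      hit <- 0L
      for (ci in seq_along(reps)) {
        if (nw_identity(seqs[[reps[ci]]], seqs[[i]]) >= thr) {
          hit <- ci; break
        }
      }
      if (hit == 0L) {
        reps <- c(reps, i); cl[i] <- length(reps)
      } else cl[i] <- hit
    }
    cl
  }
  got <- reduce_redundancy(seqs, threshold = 0.8)
  want <- greedy_oracle(seqs, 0.8)
  # same partition (cluster ids may be permuted)
  expect_equal(length(unique(got$clusters)), length(unique(want)))
  for (cl in unique(want)) {
    members <- which(want == cl)
    expect_equal(length(unique(got$clusters[members])), 1)
  }
})

test_that("splits are balanced, disjoint, exhaustive and reproducible", {
  set.seed(1)
  sites <- data.frame(accession = sprintf("P%d", 1:1100),
                      position = 1L, residue = "S",
                      functional_label = c(rep(1, 100), rep(0, 1000)))
  cfg <- curation_config(seed = 9)
  sp <- make_splits(sites, cfg)
  expect_equal(sort(unique(sp$neg_set)), 1:3)
  for (ns in 1:3) {
    one <- sp[sp$neg_set == ns, ]
    # 1:1 undersampling keeps 100 negatives per negative set
    expect_equal(sum(sites$functional_label[one$site] == 0), 100)
    expect_equal(anyDuplicated(one$site), 0)
    lab <- sites$functional_label[one$site]
    for (role in c("train", "test")) {
      n1 <- sum(lab[one$role == role] == 1)
      n0 <- sum(lab[one$role == role] == 0)
      expect_lte(abs(n1 - n0), 1)
    }
    folds <- one$fold[one$role == "train"]
    expect_true(all(!is.na(folds)))
    expect_equal(sort(unique(folds)), 1:5)
    expect_true(all(is.na(one$fold[one$role == "test"])))
    # roughly 4:1 train:test
    expect_equal(sum(one$role == "test") / nrow(one), 0.2,
                 tolerance = 0.02)
  }
  # distinct undersamples across negative sets
  neg1 <- sort(sp$site[sp$neg_set == 1 &
                         sites$functional_label[sp$site] == 0])
  neg2 <- sort(sp$site[sp$neg_set == 2 &
                         sites$functional_label[sp$site] == 0])
  expect_false(identical(neg1, neg2))
  expect_identical(make_splits(sites, cfg), sp)

  sp3 <- make_splits(sites, curation_config(pos_neg_ratio = 3, seed = 9))
  expect_equal(sum(sites$functional_label[sp3$site[sp3$neg_set == 1]] == 0),
               300)
  tiny <- sites[c(1:3, 101:200), ]
  expect_error(make_splits(tiny, curation_config(seed = 1)),
               class = "phosfusion_config_error")
})

test_that("protein-level grouping keeps proteins on one side of the split", {
  sites <- data.frame(accession = rep(sprintf("P%d", 1:40), each = 5),
                      position = rep(1:5, 40), residue = "S",
                      functional_label = rep(c(1, 0), 100))
  sp <- make_splits(sites, curation_config(group_by_protein = TRUE,
                                           n_negative_sets = 1, seed = 3))
  roles <- tapply(sp$role, sites$accession[sp$site],
                  function(r) length(unique(r)))
  expect_true(all(roles == 1))
})
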