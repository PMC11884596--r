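#' Curation configuration
#'
#' Defaults follow the curation protocol of the functional-site corpus:
#' sequence redundancy removed at 0.8 identity, negatives undersampled
#' to a 1:1 ratio, a 4:1 train/test split, three independent negative
#' sets and five-fold cross-validation.
#'
#' @param identity_threshold Sequence-identity threshold in (0.5, 1].
#' @param pos_neg_ratio Negatives sampled per positive (1 = balanced).
#' @param train_test_ratio Train:test ratio as a length-2 integer vector.
#' @param n_negative_sets Number of independent negative undersamples.
#' @param n_folds Cross-validation folds (>= 2).
#' @param group_by_protein If `TRUE`, all sites of a protein stay on the
#'   same side of the train/test split (leakage-aware variant; default
#'   `FALSE`, plain site-level splitting).
#' @param seed Integer seed.
#' @return A `curation_config` list.
#' @export
curation_config <- function(identity_threshold = 0.8, pos_neg_ratio = 1,
                            train_test_ratio = c(4, 1),
                            n_negative_sets = 3, n_folds = 5,
                            group_by_protein = FALSE, seed = 1) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1,
            pos_neg_ratio > 0, all(train_test_ratio > 0), n_folds >= 2,
            n_negative_sets >= 1)
  structure(list(identity_threshold = identity_threshold,
                 pos_neg_ratio = pos_neg_ratio,
                 train_test_ratio = train_test_ratio,
                 n_negative_sets = as.integer(n_negative_sets),
                 n_folds = as.integer(n_folds),
                 group_by_protein = isTRUE(group_by_protein),
                 seed = as.integer(seed)),
            class = "curation_config")
}

#' Label sites as functional / non-functional
#'
#' A site is functional (label 1) when its annotation set contains a
#' regulatory-function or disease-association tag; sites without any
#' such annotation are non-functional (label 0).
#'
#' @param sites Site data frame (see [read_site_table()]).
#' @param functional_tags Annotation strings that confer the functional
#'   label.
#' @return `sites` with an integer `functional_label` column.
#' @export
label_functional <- function(sites,
                             functional_tags = c("regulatory",
                                                 "disease-associated")) {
  anns <- split_annotations(sites)
  sites$functional_label <- vapply(anns, function(a) {
    as.integer(any(a %in% functional_tags))
  }, integer(1))
  sites
}

#' Label enzyme sites by regulatory type
#'
#' Keeps only sites carrying an enzymatic-activity annotation and labels
#' them `inhibited` or `induced`. When a site carries both tags the
#' inhibited label wins, so conflicting annotations cannot produce an
#' induced site. The caller is responsible for restricting `sites` to
#' enzymes.
#'
#' @param sites Site data frame.
#' @param induced_tag,inhibited_tag Annotation strings for the two classes.
#' @return The subset of `sites` with a `regulatory_label` factor column
#'   (levels `induced`, `inhibited`).
#' @export
label_regulatory <- function(sites,
                             induced_tag = "enzymatic activity, induced",
                             inhibited_tag = "enzymatic activity, inhibited") {
  anns <- split_annotations(sites)
  lab <- vapply(anns, function(a) {
    if (inhibited_tag %in% a) "inhibited"
    else if (induced_tag %in% a) "induced"
    else NA_character_
  }, character(1))
  keep <- !is.na(lab)
  out <- sites[keep, , drop = FALSE]
  out$regulatory_label <- factor(lab[keep], levels = c("induced", "inhibited"))
  out
}

#' Filter proteins and sites for model building
#'
#' Applies, in order: 1) removal of isoform accessions (hyphen-numbered
#' suffix); 2) removal of proteins without a structure; 3) removal of
#' sites whose protein was removed, whose position is out of bounds or
#' whose residue letter mismatches the sequence. Counts removed at each
#' stage are attached as the `"filter_log"` attribute. Filters only; no
#' errors are raised for removed entries.
#'
#' @param proteins Named list of [protein_record()] or named character
#'   vector of sequences, keyed by accession.
#' @param sites Site data frame.
#' @param structures Optional character vector of accessions that have a
#'   structure; `NULL` means every protein has one.
#' @return List with `proteins`, `sites` and a `filter_log` data frame.
#' @export
filter_proteins <- function(proteins, sites, structures = NULL) {
  log <- list()
  acc <- names(proteins)
  iso <- grepl("-[0-9]+$", acc)
  log$isoform_proteins <- sum(iso)
  proteins <- proteins[!iso]
  acc <- names(proteins)
  if (!is.null(structures)) {
    has_struct <- acc %in% structures
    log$missing_structure <- sum(!has_struct)
    proteins <- proteins[has_struct]
    acc <- names(proteins)
  } else {
    log$missing_structure <- 0L
  }
  in_prot <- sites$accession %in% acc
  log$sites_without_protein <- sum(!in_prot)
  sites <- sites[in_prot, , drop = FALSE]
  ok <- validate_sites(sites, proteins)
  log$sites_residue_mismatch <- sum(!ok)
  sites <- sites[ok, , drop = FALSE]
  log <- data.frame(stage = names(log), removed = unlist(log, use.names = FALSE))
  message(paste(sprintf("%s: %d removed", log$stage, log$removed),
                collapse = "; "))
  structure(list(proteins = proteins, sites = sites, filter_log = log))
}

# Ungapped k-mer-anchored identity between two sequences: shared k-mers
# vote for a diagonal; the best diagonal defines an ungapped alignment
# whose matched positions are divided by the shorter sequence length.
kmer_identity <- function(s1, s2, k = 5) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < k || n2 < k) {
    return(as.numeric(s1 == s2))
  }
  km1 <- substring(s1, 1:(n1 - k + 1), k:n1)
  km2 <- substring(s2, 1:(n2 - k + 1), k:n2)
  pos2 <- split(seq_along(km2), km2)
  hits1 <- which(km1 %in% names(pos2))
  if (length(hits1) == 0) return(0)
  diags <- unlist(lapply(hits1, function(i) i - pos2[[km1[[i]]]]),
                  use.names = FALSE)
  tab <- table(diags)
  best <- as.integer(names(tab)[which.max(tab)])
  # ungapped alignment at offset `best` (s1 index = s2 index + best)
  j <- seq_len(n2)
  i <- j + best
  ok <- i >= 1 & i <= n1
  if (!any(ok)) return(0)
  a <- strsplit(s1, "")[[1]][i[ok]]
  b <- strsplit(s2, "")[[1]][j[ok]]
  sum(a == b) / min(n1, n2)
}

#' Reduce sequence redundancy by greedy clustering
#'
#' Greedy longest-first clustering with a k-mer-anchored ungapped
#' identity: sequences are visited from longest to shortest, each either
#' joining the first existing cluster whose representative it matches at
#' `threshold` identity or founding a new cluster. This mirrors the
#' semantics of cd-hit at the same threshold without re-implementing its
#' heuristics; an external cd-hit binary can be swapped in via
#' `backend`.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0.5, 1].
#' @param k Anchor k-mer length.
#' @param backend `"builtin"` or a path to a cd-hit executable.
#' @return List with `representatives` (named character vector) and
#'   `clusters` (integer vector mapping each input to its cluster).
#' @export
reduce_redundancy <- function(seqs, threshold = 0.8, k = 5,
                              backend = "builtin") {
  stopifnot(threshold > 0.5, threshold <= 1)
  if (backend != "builtin") {
    return(reduce_redundancy_cdhit(seqs, threshold, backend))
  }
  ord <- order(-nchar(seqs))
  reps <- integer(0)
  cluster <- integer(length(seqs))
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      if (kmer_identity(seqs[[reps[ci]]], seqs[[i]], k) >= threshold) {
        cluster[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  list(representatives = seqs[reps], clusters = cluster)
}

# External cd-hit backend: same interface, delegated clustering.
reduce_redundancy_cdhit <- function(seqs, threshold, cdhit_bin) {
  if (Sys.which(cdhit_bin) == "" && !file.exists(cdhit_bin)) {
    stop_pf("cd-hit backend not found: %s", "phosfusion_backend_error",
            cdhit_bin)
  }
  td <- tempfile("cdhit")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fin <- file.path(td, "in.fasta")
  fout <- file.path(td, "out.fasta")
  write_fasta(seqs, fin)
  status <- system2(cdhit_bin, c("-i", fin, "-o", fout, "-c", threshold,
                                 "-n", "5", "-d", "0"), stdout = FALSE)
  if (status != 0) {
    stop_pf("cd-hit exited with status %d", "phosfusion_backend_error", status)
  }
  reps <- read_fasta(fout)
  cl <- readLines(paste0(fout, ".clstr"))
  cluster <- integer(length(seqs))
  ci <- 0L
  for (line in cl) {
    if (startsWith(line, ">")) ci <- ci + 1L
    else {
      id <- sub(".*>(\\S+)\\.\\.\\..*", "\\1", line)
      cluster[match(id, names(seqs))] <- ci
    }
  }
  list(representatives = reps, clusters = cluster)
}

#' Build balanced train/test splits with cross-validation folds
#'
#' For each of `n_negative_sets` independent undersamples: negatives are
#' drawn at `pos_neg_ratio` negatives per positive, the balanced set is
#' split train:test at `train_test_ratio` (stratified by class), and the
#' training sites are partitioned into `n_folds` stratified folds. Fully
#' reproducible from `config$seed`.
#'
#' @param sites Site data frame with a `functional_label` (or other
#'   0/1 column named by `label_col`).
#' @param config A [curation_config()].
#' @param label_col Name of the 0/1 label column.
#' @return Data frame with columns `site` (row index into `sites`),
#'   `neg_set`, `role` (`"train"`/`"test"`) and `fold` (`NA` for test).
#' @export
make_splits <- function(sites, config = curation_config(),
                        label_col = "functional_label") {
  y <- sites[[label_col]]
  pos <- which(y == 1)
  neg <- which(y == 0)
  n_neg_wanted <- round(length(pos) * config$pos_neg_ratio)
  if (length(pos) < config$n_folds || length(neg) < min(n_neg_wanted,
                                                        config$n_folds)) {
    stop_pf("not enough sites per class for %d folds",
            "phosfusion_config_error", config$n_folds)
  }
  ratio <- config$train_test_ratio
  test_frac <- ratio[[2]] / sum(ratio)
  out <- list()
  for (ns in seq_len(config$n_negative_sets)) {
    res <- with_local_seed(derive_seed(config$seed, paste0("negset", ns)), {
      neg_s <- sample(neg, min(n_neg_wanted, length(neg)))
      assign_one <- function(idx) {
        # stratified train/test then folds, per class
        idx <- sample(idx)
        n_test <- round(length(idx) * test_frac)
        test <- idx[seq_len(n_test)]
        train <- idx[-seq_len(n_test)]
        fold <- rep(seq_len(config$n_folds), length.out = length(train))
        list(test = test, train = train, fold = fold)
      }
      if (config$group_by_protein) {
        all_idx <- c(pos, neg_s)
        prots <- sample(unique(sites$accession[all_idx]))
        n_test_p <- max(1, round(length(prots) * test_frac))
        test_prots <- prots[seq_len(n_test_p)]
        is_test <- sites$accession[all_idx] %in% test_prots
        test <- all_idx[is_test]
        train <- sample(all_idx[!is_test])
        fold <- rep(seq_len(config$n_folds), length.out = length(train))
        data.frame(site = c(test, train), neg_set = ns,
                   role = c(rep("test", length(test)),
                            rep("train", length(train))),
                   fold = c(rep(NA_integer_, length(test)), fold))
      } else {
        ap <- assign_one(pos)
        an <- assign_one(neg_s)
        data.frame(site = c(ap$test, an$test, ap$train, an$train),
                   neg_set = ns,
                   role = c(rep("test", length(ap$test) + length(an$test)),
                            rep("train", length(ap$train) + length(an$train))),
                   fold = c(rep(NA_integer_, length(ap$test) + length(an$test)),
                            ap$fold, an$fold))
      }
    })
    out[[ns]] <- res
  }
  do.call(rbind, out)
}
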