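#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 128, learning
#' rate 1e-4, 50 epochs per fold with early stopping (patience 5 on
#' validation AUROC), AdamW.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate AdamW learning rate.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience in epochs (validation AUROC).
#' @param weight_decay Decoupled weight decay.
#' @param class_weighting If `TRUE`, per-sample losses are weighted by
#'   inverse class frequency (off by default).
#' @param seed Integer seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 128, learning_rate = 1e-4,
                         epochs = 50, patience = 5, weight_decay = 0.01,
                         class_weighting = FALSE, seed = 1) {
  stopifnot(batch_size > 0, learning_rate > 0, epochs > 0, patience > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Assemble the tensorised model dataset
#'
#' Builds, for every site, the featurized site-centred subgraph and the
#' raw sequence-embedding query tokens, and packs them into flat arrays
#' so training batches can be sliced cheaply. Per-protein structural
#' context (secondary structure, RSA, contact degree/centrality) and
#' embeddings are computed once per protein.
#'
#' @param proteins Named list of [protein_record()].
#' @param sites Site data frame (accession, position, residue, plus a
#'   label column).
#' @param graph_cfg A [graph_config()].
#' @param embed_cfg An [embedder_config()].
#' @param query_window Half-width of the sequence query window.
#' @param label_col Name of the 0/1 label column (may be absent for
#'   prediction-only datasets).
#' @param standardize Z-score the non-one-hot node-feature columns
#'   (RSA, pLDDT, sidechain vector, degree, centrality) over the
#'   dataset, so all features enter the encoder on a comparable scale;
#'   the scaling is stored in `feature_scaling` and reused by
#'   [apply_feature_scaling()] for prediction-time datasets. Graph
#'   objects themselves always keep raw features.
#' @return A `fusion_dataset` list.
#' @export
build_model_dataset <- function(proteins, sites,
                                graph_cfg = graph_config(),
                                embed_cfg = embedder_config(),
                                query_window = 0,
                                label_col = "functional_label",
                                standardize = TRUE) {
  S <- nrow(sites)
  Tq <- 2L + 2L * as.integer(query_window)
  D <- embed_cfg$mock_dim
  Xs <- vector("list", S)
  edges_s <- vector("list", S)
  n_nodes <- integer(S)
  center_local <- integer(S)
  Q <- array(0, c(S, Tq, D))
  ctx_cache <- list()
  emb_cache <- list()
  for (i in seq_len(S)) {
    acc <- sites$accession[[i]]
    prot <- proteins[[acc]]
    if (is.null(prot)) {
      stop_pf("no protein record for accession %s",
              "phosfusion_config_error", acc)
    }
    if (is.null(ctx_cache[[acc]])) {
      ctx_cache[[acc]] <- protein_site_features(prot, graph_cfg)
      emb_cache[[acc]] <- embed_sequence(prot$sequence, embed_cfg)
    }
    gr <- build_site_subgraph(prot, sites$position[[i]], graph_cfg)
    gr <- featurize_nodes(gr, prot, graph_cfg, context = ctx_cache[[acc]])
    n <- length(gr$node_ids)
    Xs[[i]] <- gr$node_features
    ei <- match(gr$edges$i, gr$node_ids)
    ej <- match(gr$edges$j, gr$node_ids)
    edges_s[[i]] <- normalized_edges(ei, ej, n)
    n_nodes[[i]] <- n
    center_local[[i]] <- match(gr$center, gr$node_ids)
    Q[i, , ] <- build_query(emb_cache[[acc]], sites$position[[i]],
                            window = query_window)
  }
  y <- if (label_col %in% names(sites)) as.numeric(sites[[label_col]]) else
    rep(NA_real_, S)
  X <- do.call(rbind, Xs)
  scaling <- NULL
  if (isTRUE(standardize)) {
    layout <- node_feature_layout()
    cols <- c(layout$rsa, layout$plddt, layout$sidechain_vector,
              layout$degree, layout$eigenvector_centrality)
    mu <- colMeans(X[, cols, drop = FALSE])
    sd_ <- apply(X[, cols, drop = FALSE], 2, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    X[, cols] <- sweep(sweep(X[, cols, drop = FALSE], 2, mu), 2, sd_, "/")
    scaling <- list(cols = cols, mean = mu, sd = sd_)
  }
  structure(list(X = X, feature_scaling = scaling, edges = edges_s,
                 n_nodes = n_nodes, center_local = center_local,
                 node_offset = c(0L, cumsum(n_nodes))[seq_len(S)],
                 Q = Q, y = y, sites = sites, d_embed = D,
                 query_window = as.integer(query_window),
                 plddt = vapply(seq_len(S), function(i) {
                   proteins[[sites$accession[[i]]]]$plddt[[sites$position[[i]]]]
                 }, numeric(1))),
            class = "fusion_dataset")
}

#' Apply a stored feature scaling to another dataset
#'
#' Rescales an unstandardised dataset's node features with the
#' mean/spread recorded in a training dataset, so prediction-time
#' inputs match the representation a model was trained on.
#'
#' @param ds A `fusion_dataset` built with `standardize = FALSE`.
#' @param scaling A `feature_scaling` list from a training dataset.
#' @return The rescaled dataset.
#' @export
apply_feature_scaling <- function(ds, scaling) {
  if (is.null(scaling)) return(ds)
  ds$X[, scaling$cols] <- sweep(sweep(ds$X[, scaling$cols, drop = FALSE],
                                      2, scaling$mean), 2, scaling$sd, "/")
  ds$feature_scaling <- scaling
  ds
}

# Slice a tensorised batch for a set of site indices.
dataset_batch <- function(ds, idx) {
  B <- length(idx)
  n <- ds$n_nodes[idx]
  node_rows <- unlist(lapply(idx, function(i) {
    ds$node_offset[i] + seq_len(ds$n_nodes[i])
  }), use.names = FALSE)
  off <- c(0L, cumsum(n))[seq_len(B)]
  src <- unlist(lapply(seq_len(B), function(b) {
    ds$edges[[idx[b]]]$src + off[b]
  }), use.names = FALSE)
  dst <- unlist(lapply(seq_len(B), function(b) {
    ds$edges[[idx[b]]]$dst + off[b]
  }), use.names = FALSE)
  w <- unlist(lapply(idx, function(i) ds$edges[[i]]$w), use.names = FALSE)
  list(X = ds$X[node_rows, , drop = FALSE],
       g = rep(seq_len(B), n), n_nodes = n,
       center_rows = off + ds$center_local[idx],
       edges = list(src = src, dst = dst, w = w),
       Q = ds$Q[idx, , , drop = FALSE], y = ds$y[idx], B = B)
}

#' Predict probabilities for dataset sites
#'
#' @param params Parameter list (or a checkpoint's `$params`).
#' @param ds A `fusion_dataset`.
#' @param idx Site indices (default all).
#' @param config A [fusion_config()].
#' @param chunk Evaluation chunk size.
#' @return Numeric probability vector.
#' @export
predict_fusion <- function(params, ds, idx = seq_len(nrow(ds$sites)),
                           config = fusion_config(), chunk = 512) {
  if (!is.null(params$params)) {
    config <- params$config
    params <- params$params
  }
  p <- numeric(length(idx))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / chunk))) {
    batch <- dataset_batch(ds, idx[s])
    p[s] <- fusion_forward_batch(params, batch, config)$p
  }
  p
}

#' Train the fusion model with early stopping
#'
#' Minibatch AdamW training; after every epoch the validation AUROC is
#' computed and the parameters of the best epoch are kept. Training
#' stops when the validation AUROC has not improved for
#' `train_cfg$patience` epochs. Fully seeded: the same seed, data and
#' configuration reproduce the loss trajectory exactly.
#'
#' @param ds A `fusion_dataset`.
#' @param train_idx,val_idx Site indices for training and validation.
#' @param config A [fusion_config()].
#' @param train_cfg A [train_config()].
#' @param init Optional initial parameters (warm start / transfer).
#' @return A `fusion_checkpoint`: list with `params`, `config`,
#'   `train_cfg`, `history` (per-epoch loss and validation AUROC),
#'   `best_epoch`, `val_auroc`.
#' @export
train_fusion <- function(ds, train_idx, val_idx,
                         config = fusion_config(),
                         train_cfg = train_config(), init = NULL) {
  if (length(train_idx) == 0 || length(val_idx) == 0) {
    stop_pf("empty training or validation fold", "phosfusion_config_error")
  }
  params <- init %||% init_fusion_params(config, d_graph = ncol(ds$X),
                                         d_embed = ds$d_embed)
  wts <- NULL
  if (train_cfg$class_weighting) {
    y <- ds$y[train_idx]
    wts <- ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
  }
  with_local_seed(derive_seed(train_cfg$seed, "train"), {
    state <- adamw_init(params)
    best <- list(auroc = -Inf, params = params, epoch = 0L)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_auroc = numeric(0))
    stall <- 0L
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample(train_idx)
      losses <- numeric(0)
      for (s in split(seq_along(ord),
                      ceiling(seq_along(ord) / train_cfg$batch_size))) {
        batch <- dataset_batch(ds, ord[s])
        bw <- if (is.null(wts)) NULL else wts[match(ord[s], train_idx)]
        lg <- fusion_loss_grad(params, batch, config, train = TRUE,
                               sample_weights = bw)
        upd <- adamw_step(params, lg$grads, state,
                          lr = train_cfg$learning_rate,
                          weight_decay = train_cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, lg$loss)
      }
      pv <- predict_fusion(params, ds, val_idx, config)
      va <- auroc_score(ds$y[val_idx], pv)
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = mean(losses),
                                           val_auroc = va))
      if (!is.na(va) && va > best$auroc) {
        best <- list(auroc = va, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_cfg$patience) break
      }
    }
    structure(list(params = best$params, config = config,
                   train_cfg = train_cfg, history = history,
                   best_epoch = best$epoch, val_auroc = best$auroc,
                   d_embed = ds$d_embed, d_graph = ncol(ds$X)),
              class = "fusion_checkpoint")
  })
}

#' @export
print.fusion_checkpoint <- function(x, ...) {
  cat(sprintf("<fusion_checkpoint> best epoch %d, val AUROC %.3f\n",
              x$best_epoch, x$val_auroc))
  invisible(x)
}

#' Cross-validated training
#'
#' For each fold k of one negative set: trains on the remaining
#' training folds, early-stops on fold k's AUROC and reports metrics on
#' the held-out test split. Returns per-fold checkpoints and metrics
#' plus their mean.
#'
#' @param ds A `fusion_dataset`.
#' @param splits Split assignment from [make_splits()] (rows of one
#'   negative set; if several are present, `neg_set` selects one).
#' @param config,train_cfg Model and training configuration.
#' @param neg_set Which negative set to use (default 1).
#' @param folds Which folds to run (default all).
#' @return List with `checkpoints`, `fold_metrics` (list of
#'   [compute_metrics()] reports), `mean_metrics`, `test_scores`.
#' @export
train_cv <- function(ds, splits, config = fusion_config(),
                     train_cfg = train_config(), neg_set = 1,
                     folds = NULL) {
  sp <- splits[splits$neg_set == neg_set, , drop = FALSE]
  test_idx <- sp$site[sp$role == "test"]
  tr <- sp[sp$role == "train", , drop = FALSE]
  folds <- folds %||% sort(unique(tr$fold))
  checkpoints <- list()
  fold_metrics <- list()
  score_sum <- numeric(length(test_idx))
  for (k in folds) {
    tcfg <- train_cfg
    tcfg$seed <- derive_seed(train_cfg$seed, paste0("fold", k))
    ck <- train_fusion(ds, tr$site[tr$fold != k], tr$site[tr$fold == k],
                       config, tcfg)
    sc <- predict_fusion(ck$params, ds, test_idx, config)
    checkpoints[[as.character(k)]] <- ck
    fold_metrics[[as.character(k)]] <- compute_metrics(ds$y[test_idx], sc)
    score_sum <- score_sum + sc
  }
  mm <- Reduce(`+`, lapply(fold_metrics, function(m) unlist(m))) /
    length(fold_metrics)
  list(checkpoints = checkpoints, fold_metrics = fold_metrics,
       mean_metrics = as.list(mm), test_idx = test_idx,
       test_scores = score_sum / length(folds))
}

# Parameter-name split used by the transfer-learning modes: classifier
# parameters are prefixed "cls_"; everything else is an embedding layer.
is_classifier_param <- function(nm) startsWith(nm, "cls_")

#' Initial parameters for a transfer-learning mode
#'
#' `transfer_all` copies every teacher parameter bitwise;
#' `transfer_embed_only` copies all embedding layers and freshly
#' initialises the classifier; `scratch` (and `multitask`) initialise
#' everything fresh.
#'
#' @param teacher A `fusion_checkpoint` (may be `NULL` for `scratch`).
#' @param mode Transfer mode.
#' @param config Model configuration (defaults to the teacher's).
#' @param d_graph,d_embed Input widths for fresh initialisation.
#' @return Parameter list.
#' @export
transfer_init <- function(teacher,
                          mode = c("scratch", "multitask",
                                   "transfer_embed_only", "transfer_all"),
                          config = NULL, d_graph = 35, d_embed = 64) {
  mode <- match.arg(mode)
  config <- config %||% teacher$config
  if (mode == "transfer_all") return(teacher$params)
  p <- init_fusion_params(config, d_graph = d_graph, d_embed = d_embed)
  if (mode == "transfer_embed_only") {
    for (nm in names(p)) {
      if (!is_classifier_param(nm)) p[[nm]] <- teacher$params[[nm]]
    }
  }
  p
}

#' Fine-tune a regulatory-type model from a functional-site teacher
#'
#' Implements the four small-data strategies: `scratch` (ignore the
#' teacher), `transfer_embed_only` (copy all embedding layers, classifier
#' freshly initialised), `transfer_all` (copy every parameter) and
#' `multitask` (joint training on both datasets with the summed BCE
#' loss; the enzyme head is returned). Positive class is `induced`.
#'
#' @param teacher A `fusion_checkpoint` (ignored for `scratch` and
#'   `multitask` initialisation aside from its configuration).
#' @param ds Enzyme-site `fusion_dataset` (labels 1 = induced).
#' @param train_idx,val_idx Training/validation indices in `ds`.
#' @param mode One of `"scratch"`, `"multitask"`,
#'   `"transfer_embed_only"`, `"transfer_all"`.
#' @param train_cfg A [train_config()].
#' @param primary_ds,primary_idx Primary-task dataset and indices
#'   (required for `multitask`).
#' @param config Model configuration (defaults to the teacher's).
#' @return A `fusion_checkpoint` for the regulatory-type task.
#' @export
finetune <- function(teacher, ds, train_idx, val_idx,
                     mode = c("scratch", "multitask",
                              "transfer_embed_only", "transfer_all"),
                     train_cfg = train_config(), primary_ds = NULL,
                     primary_idx = NULL, config = NULL) {
  mode <- match.arg(mode)
  config <- config %||% teacher$config
  init <- if (mode %in% c("scratch", "multitask")) NULL else
    transfer_init(teacher, mode, config, d_graph = ncol(ds$X),
                  d_embed = ds$d_embed)
  if (mode != "multitask") {
    return(train_fusion(ds, train_idx, val_idx, config, train_cfg,
                        init = init))
  }
  if (is.null(primary_ds)) {
    stop_pf("multitask mode requires primary_ds", "phosfusion_config_error")
  }
  train_multitask(ds, train_idx, val_idx, primary_ds,
                  primary_idx %||% seq_len(nrow(primary_ds$sites)),
                  config, train_cfg)
}

#' Joint multi-task loss
#'
#' The sum of the two binary cross-entropy losses, each computed with
#' its own classifier head over shared embedding layers.
#'
#' @param params Parameter list containing shared layers, the primary
#'   head (`cls_*`) and the enzyme head (`cls2_*`).
#' @param batch_primary,batch_enzyme Tensorised batches.
#' @param config A [fusion_config()].
#' @return List with `total`, `loss_primary`, `loss_enzyme`.
#' @export
multitask_loss <- function(params, batch_primary, batch_enzyme,
                           config = fusion_config()) {
  pa <- params[!startsWith(names(params), "cls2_")]
  pb <- params[!is_classifier_param(names(params))]
  head_b <- params[startsWith(names(params), "cls2_")]
  names(head_b) <- sub("^cls2_", "cls_", names(head_b))
  pb <- c(pb, head_b)
  la <- bce_loss(batch_primary$y,
                 fusion_forward_batch(pa, batch_primary, config)$p)
  lb <- bce_loss(batch_enzyme$y,
                 fusion_forward_batch(pb, batch_enzyme, config)$p)
  list(total = la + lb, loss_primary = la, loss_enzyme = lb)
}

# Multi-task trainer: each step draws one batch per task, sums the BCE
# losses (gradients of shared layers add), and early-stops on the
# enzyme task's validation AUROC. Returns the enzyme-head checkpoint.
train_multitask <- function(ds_enz, train_idx, val_idx, ds_pri, pri_idx,
                            config, train_cfg) {
  base <- init_fusion_params(config, d_graph = ncol(ds_enz$X),
                             d_embed = ds_enz$d_embed)
  head2 <- base[is_classifier_param(names(base))]
  names(head2) <- sub("^cls_", "cls2_", names(head2))
  params <- c(base, head2)
  with_local_seed(derive_seed(train_cfg$seed, "multitask"), {
    state <- adamw_init(params)
    best <- list(auroc = -Inf, params = params, epoch = 0L)
    stall <- 0L
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_auroc = numeric(0))
    for (epoch in seq_len(train_cfg$epochs)) {
      ordE <- sample(train_idx)
      losses <- numeric(0)
      bs <- train_cfg$batch_size
      n_steps <- ceiling(length(ordE) / bs)
      for (s in seq_len(n_steps)) {
        idxE <- ordE[((s - 1) * bs + 1):min(s * bs, length(ordE))]
        idxP <- sample(pri_idx, min(bs, length(pri_idx)))
        bE <- dataset_batch(ds_enz, idxE)
        bP <- dataset_batch(ds_pri, idxP)
        pa <- params[!startsWith(names(params), "cls2_")]
        lgA <- fusion_loss_grad(pa, bP, config, train = TRUE)
        pb <- params[!is_classifier_param(names(params))]
        hb <- params[startsWith(names(params), "cls2_")]
        names(hb) <- sub("^cls2_", "cls_", names(hb))
        lgB <- fusion_loss_grad(c(pb, hb), bE, config, train = TRUE)
        grads <- lapply(names(params), function(nm) {
          if (startsWith(nm, "cls2_")) {
            lgB$grads[[sub("^cls2_", "cls_", nm)]]
          } else if (is_classifier_param(nm)) {
            lgA$grads[[nm]]
          } else {
            lgA$grads[[nm]] + lgB$grads[[nm]]
          }
        })
        names(grads) <- names(params)
        upd <- adamw_step(params, grads, state,
                          lr = train_cfg$learning_rate,
                          weight_decay = train_cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, lgA$loss + lgB$loss)
      }
      pb <- params[!is_classifier_param(names(params))]
      hb <- params[startsWith(names(params), "cls2_")]
      names(hb) <- sub("^cls2_", "cls_", names(hb))
      pv <- predict_fusion(c(pb, hb), ds_enz, val_idx, config)
      va <- auroc_score(ds_enz$y[val_idx], pv)
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = mean(losses),
                                           val_auroc = va))
      if (!is.na(va) && va > best$auroc) {
        best <- list(auroc = va, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_cfg$patience) break
      }
    }
    pb <- best$params[!is_classifier_param(names(best$params))]
    hb <- best$params[startsWith(names(best$params), "cls2_")]
    names(hb) <- sub("^cls2_", "cls_", names(hb))
    structure(list(params = c(pb[!startsWith(names(pb), "cls2_")], hb),
                   config = config, train_cfg = train_cfg,
                   history = history, best_epoch = best$epoch,
                   val_auroc = best$auroc, d_embed = ds_enz$d_embed,
                   d_graph = ncol(ds_enz$X)),
              class = "fusion_checkpoint")
  })
}

# ---- knowledge distillation into a sequence-only student MLP ----

student_input <- function(ds, idx) {
  Tq <- dim(ds$Q)[2]
  D <- dim(ds$Q)[3]
  matrix(ds$Q[idx, , , drop = FALSE], length(idx), Tq * D)
}

init_student_params <- function(d_in, widths, seed = 1) {
  with_local_seed(derive_seed(seed, "student"), {
    list(cls_W1 = glorot(d_in, widths[1]), cls_b1 = numeric(widths[1]),
         cls_W2 = glorot(widths[1], widths[2]), cls_b2 = numeric(widths[2]),
         cls_W3 = glorot(widths[2], widths[3]), cls_b3 = numeric(widths[3]),
         cls_W4 = glorot(widths[3], 1), cls_b4 = numeric(1))
  })
}

#' Distill the fusion teacher into a sequence-only student MLP
#'
#' Trains a three-hidden-layer multilayer perceptron that consumes only
#' the flattened sequence-embedding query tokens (never any graph
#' feature) on the teacher's predicted probabilities as soft targets,
#' transferring the structure-derived signal into a sequence-only
#' predictor.
#'
#' @param teacher A `fusion_checkpoint`.
#' @param ds A `fusion_dataset` providing the distillation transfer
#'   set. Distillation needs no labels, so `ds` may include extra
#'   unlabeled sites scored by the teacher.
#' @param train_idx Sites used for distillation.
#' @param widths Student hidden widths (3 layers).
#' @param train_cfg A [train_config()]; its `patience` early-stops on
#'   the held-back validation correlation with the teacher.
#' @param val_frac Fraction of `train_idx` held back to select the
#'   best epoch by student-teacher correlation.
#' @return A `student_checkpoint` list with `params`, `widths`,
#'   `val_cor` and the teacher scores used.
#' @export
distill_student <- function(teacher, ds, train_idx,
                            widths = c(128, 128, 128),
                            train_cfg = train_config(), val_frac = 0.15) {
  stopifnot(length(widths) == 3)
  soft <- predict_fusion(teacher$params, ds, train_idx, teacher$config)
  Zall <- student_input(ds, train_idx)
  params <- init_student_params(ncol(Zall), widths, train_cfg$seed)
  with_local_seed(derive_seed(train_cfg$seed, "distill"), {
    n <- length(train_idx)
    vi <- sample(n, max(1L, round(val_frac * n)))
    ti <- setdiff(seq_len(n), vi)
    state <- adamw_init(params)
    best <- list(r = -Inf, params = params, epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample(ti)
      for (s in split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))) {
        fw <- mlp_forward(Zall[s, , drop = FALSE], params)
        dlogit <- (fw$p - soft[s]) / length(s)
        g <- mlp_backward(fw, params, dlogit)
        g$dZ <- NULL
        upd <- adamw_step(params, g, state, lr = train_cfg$learning_rate,
                          weight_decay = train_cfg$weight_decay)
        params <- upd$params
        state <- upd$state
      }
      rv <- suppressWarnings(
        stats::cor(soft[vi], mlp_forward(Zall[vi, , drop = FALSE],
                                         params)$p))
      if (!is.na(rv) && rv > best$r) {
        best <- list(r = rv, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_cfg$patience) break
      }
    }
    structure(list(params = best$params, widths = widths,
                   val_cor = best$r, best_epoch = best$epoch,
                   teacher_scores = soft, query_window = ds$query_window),
              class = "student_checkpoint")
  })
}

#' Predict with a distilled student
#'
#' @param student A `student_checkpoint`.
#' @param ds A `fusion_dataset`.
#' @param idx Site indices.
#' @return Probability vector.
#' @export
predict_student <- function(student, ds, idx = seq_len(nrow(ds$sites))) {
  mlp_forward(student_input(ds, idx), student$params)$p
}

# ---- checkpoint persistence (versioned JSON, text-only) ----

#' Save a checkpoint as JSON
#'
#' Single-file text archive: format version, configuration, named
#' parameter tensors and training metadata.
#'
#' @param checkpoint A `fusion_checkpoint` or `student_checkpoint`.
#' @param path Output path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  payload <- unclass(checkpoint)
  for (nm in c("config", "train_cfg")) {
    if (!is.null(payload[[nm]])) payload[[nm]] <- unclass(payload[[nm]])
  }
  obj <- list(format = "phosfusion-checkpoint", version = 1L,
              class = class(checkpoint)[[1]],
              payload = payload)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a checkpoint saved with [save_checkpoint()]
#'
#' @param path Path to the JSON checkpoint.
#' @return The restored checkpoint object.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop_pf("checkpoint not found: %s", "phosfusion_parse_error", path)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "phosfusion-checkpoint")) {
    stop_pf("not a phosfusion checkpoint: %s", "phosfusion_parse_error", path)
  }
  ck <- obj$payload
  ck$params <- lapply(ck$params, function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    if (is.data.frame(x)) x <- as.matrix(x)
    x
  })
  for (nm in names(ck$params)) {
    if (startsWith(nm, "cls_b") || nm %in% c("bp", "bg1", "bg2")) {
      ck$params[[nm]] <- as.numeric(ck$params[[nm]])
    }
  }
  if (!is.null(ck$config)) {
    cfgcls <- if (identical(obj$class, "student_checkpoint")) NULL else
      "fusion_config"
    if (!is.null(cfgcls)) {
      ck$config$ablation <- as.character(ck$config$ablation %||% character(0))
      class(ck$config) <- cfgcls
    }
  }
  class(ck) <- obj$class
  ck
}
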