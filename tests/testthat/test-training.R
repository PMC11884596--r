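small_cfg <- function(seed = 3) {
  fusion_config(embed_dim = 8, classifier_widths = c(8, 8, 8),
                dropout = 0.2, seed = seed)
}
small_tcfg <- function(seed = 3, epochs = 4) {
  train_config(batch_size = 32, learning_rate = 2e-3, epochs = epochs,
               patience = 3, seed = seed)
}

test_that("training is reproducible and early stopping keeps the best epoch", {
  study <- tiny_study()
  ds <- study$ds
  n <- nrow(ds$sites)
  set.seed(2)
  idx <- sample(n)
  tr <- idx[1:round(0.7 * n)]
  va <- setdiff(idx, tr)
  ck1 <- train_fusion(ds, tr, va, small_cfg(), small_tcfg())
  ck2 <- train_fusion(ds, tr, va, small_cfg(), small_tcfg())
  expect_identical(ck1$history, ck2$history)
  expect_identical(ck1$params, ck2$params)
  expect_equal(ck1$val_auroc, max(ck1$history$val_auroc))
  expect_equal(ck1$history$val_auroc[ck1$best_epoch], ck1$val_auroc)
  # a different training seed changes the trajectory
  ck3 <- train_fusion(ds, tr, va, small_cfg(), small_tcfg(seed = 4))
  expect_false(identical(ck1$history$loss, ck3$history$loss))
  expect_error(train_fusion(ds, integer(0), va, small_cfg(), small_tcfg()),
               class = "phosfusion_config_error")
})

test_that("cross-validated training reports per-fold and mean metrics", {
  study <- tiny_study()
  sites <- study$dat$sites
  sp <- make_splits(sites, curation_config(n_negative_sets = 1,
                                           n_folds = 2, seed = 6))
  cv <- train_cv(study$ds, sp, small_cfg(), small_tcfg(epochs = 2))
  expect_length(cv$fold_metrics, 2)
  expect_equal(cv$mean_metrics$auroc,
               mean(vapply(cv$fold_metrics, function(m) m$auroc,
                           numeric(1))))
  expect_length(cv$test_scores, length(cv$test_idx))
  expect_true(all(cv$test_scores >= 0 & cv$test_scores <= 1))
})

test_that("transfer modes copy exactly the promised parameters", {
  study <- tiny_study()
  ds <- study$ds
  cfg <- small_cfg()
  teacher <- train_fusion(ds, 1:40, 41:60, cfg, small_tcfg(epochs = 1))
  # transfer_all: bitwise-identical initialisation (before any step)
  expect_identical(transfer_init(teacher, "transfer_all"),
                   teacher$params)
  # transfer_embed_only: classifier reinitialised, all else copied
  p_embed <- transfer_init(teacher, "transfer_embed_only",
                           d_graph = ncol(ds$X), d_embed = ds$d_embed)
  cls <- grep("^cls_", names(p_embed), value = TRUE)
  emb <- setdiff(names(p_embed), cls)
  expect_identical(p_embed[emb], teacher$params[emb])
  fresh <- init_fusion_params(cfg, d_graph = ncol(ds$X),
                              d_embed = ds$d_embed)
  for (nm in cls) {
    expect_identical(p_embed[[nm]], fresh[[nm]])
    expect_false(isTRUE(all.equal(p_embed[[nm]], teacher$params[[nm]])))
  }
})

test_that("warm-started fine-tuning trains and multitask loss is the BCE sum", {
  study <- tiny_study()
  ds <- study$ds
  cfg <- small_cfg()
  teacher <- train_fusion(ds, 1:40, 41:60, cfg, small_tcfg(epochs = 1))
  ck <- finetune(teacher, ds, 1:40, 41:60, mode = "transfer_embed_only",
                 train_cfg = small_tcfg(epochs = 1))
  expect_s3_class(ck, "fusion_checkpoint")

  base <- init_fusion_params(cfg, d_graph = ncol(ds$X),
                             d_embed = ds$d_embed)
  head2 <- base[grep("^cls_", names(base))]
  names(head2) <- sub("^cls_", "cls2_", names(head2))
  params <- c(base, head2)
  bA <- phosfusion:::dataset_batch(ds, 1:16)
  bB <- phosfusion:::dataset_batch(ds, 17:32)
  mt <- multitask_loss(params, bA, bB, cfg)
  pa <- params[!startsWith(names(params), "cls2_")]
  la <- bce_loss(bA$y, phosfusion:::fusion_forward_batch(pa, bA, cfg)$p)
  pb <- params[!grepl("^cls_", names(params))]
  hb <- params[startsWith(names(params), "cls2_")]
  names(hb) <- sub("^cls2_", "cls_", names(hb))
  lb <- bce_loss(bB$y, phosfusion:::fusion_forward_batch(c(pb, hb),
                                                         bB, cfg)$p)
  expect_equal(mt$total, la + lb, tolerance = 1e-12)
  expect_equal(mt$loss_primary, la)
  expect_equal(mt$loss_enzyme, lb)

  mtck <- finetune(NULL, ds, 1:40, 41:60, mode = "multitask",
                   train_cfg = small_tcfg(epochs = 1), primary_ds = ds,
                   primary_idx = 1:40, config = cfg)
  expect_s3_class(mtck, "fusion_checkpoint")
  expect_error(finetune(NULL, ds, 1:40, 41:60, mode = "multitask",
                        train_cfg = small_tcfg(epochs = 1), config = cfg),
               class = "phosfusion_config_error")
})

test_that("the distilled student never sees graph features", {
  study <- tiny_study()
  ds <- study$ds
  cfg <- small_cfg()
  teacher <- train_fusion(ds, 1:40, 41:60, cfg, small_tcfg(epochs = 2))
  student <- distill_student(teacher, ds, 1:60,
                             widths = c(16, 16, 16),
                             train_cfg = small_tcfg(epochs = 3))
  p1 <- predict_student(student, ds, 61:70)
  ds_perturbed <- ds
  ds_perturbed$X <- ds$X + matrix(rnorm(length(ds$X)), nrow(ds$X))
  expect_identical(p1, predict_student(student, ds_perturbed, 61:70))
  # an untrained student stays near one half
  fresh <- student
  fresh$params <- phosfusion:::init_student_params(
    ncol(phosfusion:::student_input(ds, 1)), c(16, 16, 16), 1)
  p0 <- predict_student(fresh, ds, 1:20)
  expect_true(all(abs(p0 - 0.5) < 0.2))
})

test_that("checkpoints survive a JSON round-trip", {
  study <- tiny_study()
  ds <- study$ds
  cfg <- small_cfg()
  ck <- train_fusion(ds, 1:40, 41:60, cfg, small_tcfg(epochs = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(ck, f)
  rd <- load_checkpoint(f)
  expect_equal(rd$params, ck$params, tolerance = 1e-12)
  p1 <- predict_fusion(ck$params, ds, 1:10, cfg)
  p2 <- predict_fusion(rd$params, ds, 1:10, rd$config)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(load_checkpoint(tempfile()),
               class = "phosfusion_parse_error")
})

test_that("class weighting reweights the training loss", {
  study <- tiny_study()
  ds <- study$ds
  tc <- small_tcfg(epochs = 1)
  tc$class_weighting <- TRUE
  ck <- train_fusion(ds, 1:50, 51:60, small_cfg(), tc)
  expect_s3_class(ck, "fusion_checkpoint")
})
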