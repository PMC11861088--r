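micro_pairs <- function(n = 8L, seed = 50L) lapply(seq_len(n), random_pair,
                                                   seed = seed)

test_that("pretraining is deterministic under a fixed seed", {
  pairs <- micro_pairs(8)
  cfg <- pretrain_config(epochs = 2, batch_size = 8, seed = 11,
                         queue_capacity = 32L)
  a <- pretrain(pairs, cfg, micro_enc(), micro_dec())
  b <- pretrain(pairs, cfg, micro_enc(), micro_dec())
  expect_identical(noduleSSL:::par_l2(a$network$encoder, b$network$encoder), 0)
  expect_identical(noduleSSL:::par_l2(a$network$decoder, b$network$decoder), 0)
  expect_identical(a$queue$keys, b$queue$keys)
  expect_identical(a$log, b$log)
})

test_that("pretraining logs both loss branches and a decreasing mse", {
  pairs <- micro_pairs(8)
  cfg <- pretrain_config(epochs = 3, batch_size = 8, seed = 4,
                         queue_capacity = 32L)
  pt <- pretrain(pairs, cfg, micro_enc(), micro_dec())
  expect_s3_class(pt, "ssl_pretrain")
  expect_true(all(is.finite(pt$log$l_mse)))
  expect_true(all(is.finite(pt$log$l_infonce)))
  expect_lt(pt$log$l_mse[3], pt$log$l_mse[1])
  # momentum encoder has moved away from the (updated) encoder but not by
  # gradient descent: it equals the momentum average of the trajectory
  expect_gt(noduleSSL:::par_l2(pt$network$momentum, pt$network$encoder), 0)
})

test_that("disabling the contrastive branch reproduces plain masked AE", {
  pairs <- micro_pairs(8)
  cfg <- pretrain_config(epochs = 2, batch_size = 8, seed = 6,
                         enable_contrastive = FALSE)
  pt <- pretrain(pairs, cfg, micro_enc(), micro_dec())
  expect_true(all(is.na(pt$log$l_infonce)))
  expect_identical(nrow(pt$queue$keys), 0L) # dictionary untouched
  # the momentum encoder receives no updates in this mode
  init <- init_network(micro_enc(), micro_dec(), 2500L,
                       seed = derive_seed(6, 1))
  expect_identical(noduleSSL:::par_l2(pt$network$momentum, init$encoder), 0)
  expect_gt(noduleSSL:::par_l2(pt$network$encoder, init$encoder), 0)
})

test_that("disabling the generative branch reproduces pure contrastive SSL", {
  pairs <- micro_pairs(8)
  cfg <- pretrain_config(epochs = 2, batch_size = 8, seed = 6,
                         enable_generative = FALSE, queue_capacity = 32L)
  pt <- pretrain(pairs, cfg, micro_enc(), micro_dec())
  expect_true(all(is.na(pt$log$l_mse)))
  expect_equal(pt$log$l_total, pt$log$l_infonce)
  # decoder parameters never updated
  init <- init_network(micro_enc(), micro_dec(), 2500L,
                       seed = derive_seed(6, 1))
  expect_identical(noduleSSL:::par_l2(pt$network$decoder, init$decoder), 0)
  expect_error(pretrain_config(enable_generative = FALSE,
                               enable_contrastive = FALSE), "at least one")
})

test_that("learning-rate milestones drop by the stated factor", {
  expect_equal(lr_at_epoch(1, 0.01, c(0.6, 0.8), 100), 0.01)
  expect_equal(lr_at_epoch(60, 0.01, c(0.6, 0.8), 100), 0.01)
  expect_equal(lr_at_epoch(61, 0.01, c(0.6, 0.8), 100), 0.001)
  expect_equal(lr_at_epoch(81, 0.01, c(0.6, 0.8), 100), 1e-4)
  # raw-epoch override
  expect_equal(lr_at_epoch(41, 1e-3, c(40, 70), 100), 1e-4)
  expect_equal(lr_at_epoch(100, 1e-3, c(40, 70), 100), 1e-5)
})

test_that("early stopping halts exactly after the patience window", {
  expect_identical(early_stop_epoch(c(1, 0.9, 0.95, 0.95), patience = 2), 4L)
  expect_identical(early_stop_epoch(c(1, 0.9, 0.8, 0.7), patience = 2), 4L)
  expect_identical(early_stop_epoch(rep(1, 15), patience = 10), 11L)
  v <- c(0.7, 0.6, 0.65, 0.64, 0.63, 0.66, 0.61, rep(0.62, 10))
  # best at epoch 2 (0.60); the tenth non-improving epoch is epoch 12
  expect_identical(early_stop_epoch(v, patience = 10), 12L)
  v2 <- c(0.7, 0.6, 0.65, 0.64, 0.59, rep(0.62, 12))
  # improvement at epoch 5 resets the patience window
  expect_identical(early_stop_epoch(v2, patience = 10), 15L)
})

test_that("fine-tuning produces one trained head and report per fold", {
  set.seed(2)
  mk <- function(i, lab) structure(list(
    axial = matrix(ifelse(lab == 1, 0.7, 0.3), 250, 250) +
      matrix(stats::rnorm(62500, sd = 0.02), 250, 250),
    coronal = matrix(0.5, 250, 250), label = lab,
    case_id = paste0("c", i),
    tag = list(rotation_k = 0L, flip = FALSE, translation_index = 0L)),
    class = "montage_pair")
  pairs <- c(lapply(1:8, mk, lab = 0L), lapply(9:16, mk, lab = 1L))
  net <- init_network(micro_enc(), micro_dec(), 2500L, seed = 4)
  cfg <- finetune_config(epochs = 3, batch_size = 8, folds = 3,
                         test_fraction = 0.25, seed = 5)
  cl <- finetune(net, pairs, cfg)
  expect_s3_class(cl, "ssl_classifier")
  expect_length(cl$folds, 3L)
  expect_length(cl$reports, 3L)
  expect_true(all(vapply(cl$reports, function(r)
    r$stopped_epoch <= 3L && length(r$val_losses) == r$stopped_epoch,
    logical(1))))
  # held-out predictions: case-level, probabilities sum to one
  expect_identical(nrow(cl$test), 4L)
  p <- predict(cl, pairs[cl$test_idx])
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_equal(unname(p[, 2]), cl$test$p_malignant, tolerance = 1e-12)
  # repeated prediction is deterministic
  expect_identical(predict(cl, pairs[[1]]), predict(cl, pairs[[1]]))
})

test_that("an ensemble of identical folds equals a single fold", {
  net <- init_network(micro_enc(), micro_dec(), 2500L, seed = 9)
  fold <- list(params = list(encoder = net$encoder,
                             head = list(W = matrix(stats::rnorm(32, sd = 0.1),
                                                    16, 2),
                                         b = c(0.1, -0.1))),
               norm = list(mu = rep(0, 16), inv_sigma = rep(1, 16)))
  one <- structure(list(folds = list(fold), enc_cfg = net$enc_cfg),
                   class = "ssl_classifier")
  three <- structure(list(folds = list(fold, fold, fold),
                          enc_cfg = net$enc_cfg),
                     class = "ssl_classifier")
  m <- random_pair(1)$axial
  expect_equal(predict(one, m), predict(three, m), tolerance = 1e-12)
})

test_that("uninformative inputs yield chance-level held-out accuracy", {
  base <- matrix(0.4, 250, 250)
  pairs <- lapply(1:16, function(i) structure(list(
    axial = base, coronal = base, label = as.integer(i <= 8),
    case_id = paste0("u", i),
    tag = list(rotation_k = 0L, flip = FALSE, translation_index = 0L)),
    class = "montage_pair"))
  net <- init_network(micro_enc(), micro_dec(), 2500L, seed = 12)
  cfg <- finetune_config(epochs = 2, batch_size = 8, folds = 2,
                         test_fraction = 0.25, seed = 3)
  cl <- finetune(net, pairs, cfg)
  acc <- mean((cl$test$p_malignant >= 0.5) == (cl$test$label == 1))
  expect_lte(abs(acc - 0.5), 0.1 + 1e-9)
})

test_that("stratified splitting keeps both classes everywhere", {
  labels <- c(rep(1L, 30), rep(0L, 20))
  noduleSSL:::with_seed(4, {
    te <- noduleSSL:::stratified_split(labels, 0.2)
    expect_identical(length(te), 10L) # 6 + 4
    expect_true(all(c(0, 1) %in% labels[te]))
    fold <- noduleSSL:::stratified_folds(labels[-te], 5)
    for (f in 1:5) expect_true(all(c(0, 1) %in% labels[-te][fold == f]))
  })
})
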