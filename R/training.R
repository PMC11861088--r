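# Pretraining (hybrid masked-reconstruction + momentum-contrast) and
# cross-validated fine-tuning with early stopping.

#' Pretraining configuration
#'
#' Defaults follow the reference optimisation protocol: AdamW with betas
#' (0.9, 0.95), batch size 64, 100 epochs at initial learning rate 1e-2,
#' dropped by 0.1 at 60% and 80% of the epoch budget; mask ratio 0.5;
#' queue of 700 keys of dimension 128; momentum fraction 0.01.
#'
#' @param batch_size mini-batch size
#' @param epochs pretraining epochs
#' @param lr initial learning rate
#' @param betas AdamW beta coefficients
#' @param weight_decay decoupled weight decay (weight matrices only)
#' @param lr_milestones schedule milestones as fractions of `epochs` (or raw
#'   epoch numbers)
#' @param lr_factor multiplicative drop at each milestone
#' @param mask_ratio montage patch mask ratio in [0, 1]
#' @param tau InfoNCE temperature
#' @param lambda convex weight of the reconstruction loss in the hybrid
#'   objective
#' @param momentum_m momentum-encoder update fraction
#' @param queue_capacity,queue_dim contrastive dictionary size and key width
#' @param enable_generative,enable_contrastive loss-branch toggles (at least
#'   one must be on); disabling one reproduces the pure masked-autoencoder
#'   or pure momentum-contrast ablations
#' @param enable_montage_dp whether the multi-planar 5x5 montage input is
#'   used (`FALSE` corresponds to the single-central-slice ablation input;
#'   honoured at data preparation, see [augment_case()])
#' @param seed RNG seed governing initialisation, shuffling and masking
#' @export
pretrain_config <- function(batch_size = 64L, epochs = 100L, lr = 1e-2,
                            betas = c(0.9, 0.95), weight_decay = 0.05,
                            lr_milestones = c(0.6, 0.8), lr_factor = 0.1,
                            mask_ratio = 0.5, tau = 0.07, lambda = 0.5,
                            momentum_m = 0.01, queue_capacity = 700L,
                            queue_dim = 128L, enable_generative = TRUE,
                            enable_contrastive = TRUE,
                            enable_montage_dp = TRUE, seed = 1L) {
  if (!enable_generative && !enable_contrastive)
    stop("at least one of the generative/contrastive branches must be enabled")
  if (mask_ratio < 0 || mask_ratio > 1) stop("mask_ratio must lie in [0, 1]")
  structure(as.list(environment()), class = "pretrain_config")
}

#' Fine-tuning configuration
#'
#' Defaults: 100 epochs at learning rate 1e-3 dropped by 0.1 at epochs 40
#' and 70, early stopping after 10 non-improving validation epochs,
#' case-level 8:2 train:test split with 5-fold cross-validation inside the
#' training portion.
#'
#' @param epochs maximum fine-tuning epochs per fold
#' @param batch_size mini-batch size
#' @param lr initial learning rate
#' @param betas AdamW betas
#' @param weight_decay decoupled weight decay
#' @param lr_milestones schedule milestones (fractions of `epochs` or raw)
#' @param lr_factor drop factor
#' @param early_stop_patience consecutive non-improving validation epochs
#'   before halting (>= 1)
#' @param test_fraction held-out test share of cases (default 0.2)
#' @param folds cross-validation folds (>= 2)
#' @param seed RNG seed for the split and shuffling
#' @export
finetune_config <- function(epochs = 100L, batch_size = 64L, lr = 1e-3,
                            betas = c(0.9, 0.95), weight_decay = 0.05,
                            lr_milestones = c(40, 70), lr_factor = 0.1,
                            early_stop_patience = 10L, test_fraction = 0.2,
                            folds = 5L, seed = 1L) {
  if (early_stop_patience < 1) stop("patience must be >= 1")
  if (folds < 2) stop("folds must be >= 2")
  structure(as.list(environment()), class = "finetune_config")
}

# stack flattened axial/coronal patch matrices once per pair
prep_pair_matrices <- function(pairs) {
  lapply(pairs, function(p) list(
    axial = flatten_patches(partition_patches(p$axial)),
    coronal = flatten_patches(partition_patches(p$coronal)),
    label = p$label, case_id = p$case_id))
}

# grads assembled in whatever order; AdamW/momentum walks match by name
encoder_grads_tree <- function(emb_g, vit_g) {
  list(patch_W = emb_g$patch_W, patch_b = emb_g$patch_b, cls = emb_g$cls,
       blocks = vit_g$blocks, lnf_g = vit_g$lnf_g, lnf_b = vit_g$lnf_b)
}

reorder_like <- function(g, p) {
  if (!is.list(p)) return(g)
  if (!is.null(names(p))) g <- g[names(p)]
  mapply(reorder_like, g, p, SIMPLIFY = FALSE)
}

#' Hybrid self-supervised pretraining
#'
#' Per step: a mini-batch of montage pairs is masked independently per view;
#' the encoder embeds the visible axial patches while the momentum encoder
#' embeds the visible coronal patches; the flattening heads produce the
#' 128-dim query and key; InfoNCE is computed against the queue; the decoder
#' reconstructs the masked axial patches for the pixel MSE; the combined
#' loss updates encoder, decoder and query head by AdamW; the momentum
#' encoder and key head then receive their momentum update and the key
#' batch is enqueued.
#'
#' @param pairs list of `montage_pair` objects (the pretraining dataset)
#' @param config a [pretrain_config()]
#' @param enc_cfg,dec_cfg network configurations
#' @param network optionally, an [init_network()] to continue training
#' @param verbose print a line per epoch
#' @return object of class `ssl_pretrain`: the trained `network`, the final
#'   `queue`, the per-step `log` (epoch, step, l_mse, l_infonce, l_total,
#'   lr), and the configurations
#' @export
pretrain <- function(pairs, config = pretrain_config(),
                     enc_cfg = encoder_config(), dec_cfg = decoder_config(),
                     network = NULL, verbose = FALSE) {
  if (length(pairs) == 0) stop("empty pretraining dataset")
  data <- prep_pair_matrices(pairs)
  patch_dim <- ncol(data[[1]]$axial)
  set.seed(config$seed)
  net <- network %||% init_network(enc_cfg, dec_cfg, patch_dim,
                                   seed = derive_seed(config$seed, 1))
  enc_cfg <- net$enc_cfg; dec_cfg <- net$dec_cfg
  d <- enc_cfg$d_model
  # the dictionary starts pre-filled with random unit keys (the reference
  # momentum-contrast convention), so the InfoNCE scale is stationary from
  # the first step instead of ramping up while the queue fills
  queue <- new_queue(config$queue_capacity, config$queue_dim)
  if (config$enable_contrastive) {
    init_keys <- matrix(stats::rnorm(config$queue_capacity * config$queue_dim),
                        config$queue_capacity)
    queue <- update_queue(queue, init_keys / sqrt(rowSums(init_keys^2)))
  }
  gen <- config$enable_generative
  con <- config$enable_contrastive
  w_mse <- if (gen && con) config$lambda else if (gen) 1 else 0
  w_nce <- if (gen && con) 1 - config$lambda else if (con) 1 else 0

  trainable <- c("encoder", if (gen) "decoder", if (con) "q_head")
  opt <- adamw_init(net[trainable])

  n_mask <- floor(25 * config$mask_ratio + 0.5)
  n_vis <- 25L - n_mask
  if (gen && n_mask == 0)
    warning("mask ratio 0: the generative branch has nothing to reconstruct")
  if (n_vis == 0) stop("mask ratio 1 leaves no visible patches to encode")

  n <- length(data)
  log_rows <- list()
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(epoch, config$lr, config$lr_milestones, config$epochs,
                      config$lr_factor)
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + config$batch_size - 1, n)]
      B <- length(idx)
      step <- step + 1L

      mask_ax <- mask_co <- vis_ax <- vis_co <- vector("list", B)
      for (b in seq_len(B)) {
        mi <- sort(sample.int(25L, n_mask)) - 1L
        mask_ax[[b]] <- mi; vis_ax[[b]] <- setdiff(0:24, mi)
        mi <- sort(sample.int(25L, n_mask)) - 1L
        mask_co[[b]] <- mi; vis_co[[b]] <- setdiff(0:24, mi)
      }

      Xvis_ax <- do.call(rbind, lapply(seq_len(B), function(b)
        data[[idx[b]]]$axial[vis_ax[[b]] + 1L, , drop = FALSE]))
      emb <- embed_batch_fwd(Xvis_ax, vis_ax, net$encoder, d, n_vis, B)
      ev <- nn_vit_fwd(emb$X, net$encoder$blocks, net$encoder$lnf_g,
                       net$encoder$lnf_b, enc_cfg$n_heads, n_vis + 1L, B)
      dLat <- matrix(0, nrow(ev$Y), d)

      l_nce <- NA_real_; K <- NULL
      grads_qh <- NULL
      if (con) {
        Xvis_co <- do.call(rbind, lapply(seq_len(B), function(b)
          data[[idx[b]]]$coronal[vis_co[[b]] + 1L, , drop = FALSE]))
        emk <- embed_batch_fwd(Xvis_co, vis_co, net$momentum, d, n_vis, B)
        mk <- nn_vit_fwd(emk$X, net$momentum$blocks, net$momentum$lnf_g,
                         net$momentum$lnf_b, enc_cfg$n_heads, n_vis + 1L, B)
        K <- flatten_fwd(mk$Y, net$k_head, n_vis + 1L, B)$Q
        fq <- flatten_fwd(ev$Y, net$q_head, n_vis + 1L, B)
        nce <- infonce_batch(fq$Q, K, queue, config$tau)
        l_nce <- nce$loss
        fb <- flatten_bwd(w_nce * nce$dQ, net$q_head, fq$cache)
        dLat <- dLat + fb$dL
        grads_qh <- fb$grads
      }

      l_mse <- NA_real_
      grads_dec <- NULL
      if (gen && n_mask > 0) {
        dc <- decoder_fwd(ev$Y, vis_ax, mask_ax, net$decoder, dec_cfg,
                          n_vis, B)
        Tm <- do.call(rbind, lapply(seq_len(B), function(b)
          data[[idx[b]]]$axial[mask_ax[[b]] + 1L, , drop = FALSE]))
        R <- dc$pred - Tm
        l_mse <- mean(R^2)
        dP <- (2 * w_mse / length(R)) * R
        db <- decoder_bwd(dP, net$decoder, dec_cfg, dc)
        dLat <- dLat + db$dL
        grads_dec <- db$grads
      }

      l_tot <- w_mse * (if (is.na(l_mse)) 0 else l_mse) +
        w_nce * (if (is.na(l_nce)) 0 else l_nce)
      if (!is.finite(l_tot))
        stop(sprintf("non-finite loss at epoch %d step %d (mse=%g, nce=%g)",
                     epoch, step, l_mse, l_nce))

      vb <- nn_vit_bwd(dLat, net$encoder$blocks, ev$cache)
      eb <- embed_batch_bwd(vb$dX, net$encoder, emb$cache)
      grads <- list(encoder = encoder_grads_tree(eb$grads, vb$grads))
      if (gen) grads$decoder <- grads_dec
      if (con) grads$q_head <- grads_qh
      grads <- reorder_like(grads[trainable], net[trainable])

      upd <- adamw_step(net[trainable], grads, opt, lr,
                        betas = config$betas,
                        weight_decay = config$weight_decay)
      opt <- upd$state
      for (nm in trainable) net[[nm]] <- upd$params[[nm]]

      if (con) {
        net$momentum <- momentum_update(net$encoder, net$momentum,
                                        config$momentum_m)
        net$k_head <- momentum_update(net$q_head, net$k_head,
                                      config$momentum_m)
        queue <- update_queue(queue, K)
      }

      log_rows[[step]] <- data.frame(epoch = epoch, step = step,
                                     l_mse = l_mse, l_infonce = l_nce,
                                     l_total = l_tot, lr = lr)
    }
    if (verbose) {
      le <- do.call(rbind, log_rows)
      le <- le[le$epoch == epoch, ]
      message(sprintf("epoch %3d  L=%.5f (mse=%.5f, nce=%.5f) lr=%g",
                      epoch, mean(le$l_total), mean(le$l_mse),
                      mean(le$l_infonce), lr))
    }
  }
  structure(list(network = net, queue = queue, config = config,
                 enc_cfg = enc_cfg, dec_cfg = dec_cfg,
                 log = do.call(rbind, log_rows)),
            class = "ssl_pretrain")
}

#' @export
print.ssl_pretrain <- function(x, ...) {
  cat(sprintf("<ssl_pretrain> %d epochs, %d steps; final loss %.5f; queue %d/%d\n",
              max(x$log$epoch), nrow(x$log), x$log$l_total[nrow(x$log)],
              nrow(x$queue$keys), x$queue$capacity))
  invisible(x)
}

#' @export
summary.ssl_pretrain <- function(object, ...) {
  by_ep <- aggregate(l_total ~ epoch, data = object$log, FUN = mean)
  cat("Per-epoch mean total loss:\n")
  print(utils::head(by_ep, 3)); cat("...\n"); print(utils::tail(by_ep, 3))
  invisible(by_ep)
}

# softmax cross-entropy on 2-class logits; labels in {0,1}
ce_fwd <- function(logits, labels) {
  m <- pmax(logits[, 1], logits[, 2])
  lse <- m + log(exp(logits[, 1] - m) + exp(logits[, 2] - m))
  ll <- logits[cbind(seq_len(nrow(logits)), labels + 1L)]
  P <- exp(logits - lse)
  list(loss = mean(lse - ll), P = P)
}

#' Early-stopping halt epoch
#'
#' Given a sequence of per-epoch validation losses, returns the epoch after
#' which training halts: the first epoch at which the loss has not improved
#' for `patience` consecutive epochs (or the last epoch if never triggered).
#' @param val_losses numeric vector of validation losses by epoch
#' @param patience consecutive non-improving epochs tolerated
#' @export
early_stop_epoch <- function(val_losses, patience = 10L) {
  best <- Inf; since <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - 1e-12) {
      best <- val_losses[e]; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) return(e)
    }
  }
  length(val_losses)
}

stratified_split <- function(labels, test_fraction) {
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_t <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, n_t))
  }
  sort(test)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(tapply(labels, fold, function(x) length(unique(x))) < 2))
    stop("a class is absent from a fold; use more cases or fewer folds")
  fold
}

# The two-class head is a plain linear layer on the class-token output,
# parameterised in standardised coordinates: logits = W'((cls - mu)/sigma) + b'.
# mu/sigma are fixed per-feature statistics of the fold-training features at
# initialisation, so this is an exact affine reparameterisation of a linear
# head that conditions the optimisation (the class-token spread is small
# early in training and Adam's per-step displacement is bounded).
finetune_forward <- function(Xflat, params, norm, enc_cfg, B) {
  cf <- classifier_fwd(Xflat, params$encoder, enc_cfg, B)
  Z <- (cf$cls - rep(norm$mu, each = B)) * rep(norm$inv_sigma, each = B)
  logits <- nn_linear_fwd(Z, params$head$W, params$head$b)
  list(logits = logits, cf = cf, Z = Z)
}

#' Fine-tune the pretrained encoder for benign/malignant classification
#'
#' Case-level stratified 8:2 train:test split, then stratified k-fold
#' cross-validation within the training portion. Each fold fine-tunes the
#' full encoder plus a fresh two-class fully connected head on the class
#' token, with early stopping on the fold-validation loss; the returned
#' classifier is the fold ensemble (mean softmax).
#'
#' @param pretrained an `ssl_pretrain` object (or an `ssl_network`)
#' @param pairs list of labelled `montage_pair` objects, one per case (the
#'   unaugmented dataset); the axial montage is classified
#' @param config a [finetune_config()]
#' @param verbose print per-fold progress
#' @return object of class `ssl_classifier` with fold parameter sets,
#'   per-fold validation reports, the held-out test indices and ensemble
#'   test predictions
#' @export
finetune <- function(pretrained, pairs, config = finetune_config(),
                     verbose = FALSE) {
  net <- if (inherits(pretrained, "ssl_pretrain")) pretrained$network
         else pretrained
  enc_cfg <- net$enc_cfg
  data <- prep_pair_matrices(pairs)
  labels <- vapply(data, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2) stop("need both classes for fine-tuning")
  set.seed(config$seed)
  test_idx <- stratified_split(labels, config$test_fraction)
  train_idx <- setdiff(seq_along(data), test_idx)
  fold_of <- stratified_folds(labels[train_idx], config$folds)

  eval_loss <- function(params, norm, idx) {
    # batched evaluation to bound memory
    tot <- 0; n <- 0
    for (s0 in seq(1, length(idx), by = config$batch_size)) {
      ii <- idx[s0:min(s0 + config$batch_size - 1, length(idx))]
      X <- do.call(rbind, lapply(ii, function(i) data[[i]]$axial))
      fw <- finetune_forward(X, params, norm, enc_cfg, length(ii))
      tot <- tot + ce_fwd(fw$logits, labels[ii])$loss * length(ii)
      n <- n + length(ii)
    }
    tot / n
  }

  cls_features <- function(encoder, idx) {
    do.call(rbind, lapply(seq(1, length(idx), by = config$batch_size),
      function(s0) {
        ii <- idx[s0:min(s0 + config$batch_size - 1, length(idx))]
        X <- do.call(rbind, lapply(ii, function(i) data[[i]]$axial))
        classifier_fwd(X, encoder, enc_cfg, length(ii))$cls
      }))
  }

  folds <- vector("list", config$folds)
  reports <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- train_idx[fold_of != f]
    va <- train_idx[fold_of == f]
    # standardisation statistics of the class-token features on fold-train
    Ftr <- cls_features(net$encoder, tr)
    norm <- list(mu = colMeans(Ftr),
                 inv_sigma = 1 / pmax(apply(Ftr, 2, stats::sd), 1e-4))
    params <- list(encoder = net$encoder,
                   head = list(W = matrix(0, enc_cfg$d_model, 2),
                               b = rep(0, 2)))
    opt <- adamw_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    since <- 0L
    val_curve <- numeric(0)
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(epoch, config$lr, config$lr_milestones,
                        config$epochs, config$lr_factor)
      perm <- sample(tr)
      for (s0 in seq(1, length(perm), by = config$batch_size)) {
        ii <- perm[s0:min(s0 + config$batch_size - 1, length(perm))]
        B <- length(ii)
        X <- do.call(rbind, lapply(ii, function(i) data[[i]]$axial))
        fw <- finetune_forward(X, params, norm, enc_cfg, B)
        ce <- ce_fwd(fw$logits, labels[ii])
        if (!is.finite(ce$loss))
          stop(sprintf("non-finite fine-tuning loss (fold %d epoch %d)",
                       f, epoch))
        onehot <- matrix(0, B, 2)
        onehot[cbind(seq_len(B), labels[ii] + 1L)] <- 1
        dlogits <- (ce$P - onehot) / B
        lh <- nn_linear_bwd(dlogits, fw$Z, params$head$W)
        dcls <- lh$dX * rep(norm$inv_sigma, each = B)
        cb <- classifier_bwd(dcls, params$encoder, enc_cfg, fw$cf$cache)
        grads <- list(encoder = cb$grads,
                      head = list(W = lh$dW, b = lh$db))
        grads <- reorder_like(grads, params)
        upd <- adamw_step(params, grads, opt, lr, betas = config$betas,
                          weight_decay = config$weight_decay)
        params <- upd$params; opt <- upd$state
      }
      vl <- eval_loss(params, norm, va)
      val_curve <- c(val_curve, vl)
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = params, epoch = epoch)
        since <- 0L
      } else {
        since <- since + 1L
        if (since >= config$early_stop_patience) break
      }
    }
    if (verbose)
      message(sprintf("fold %d: stopped after epoch %d (best %.5f @ %d)",
                      f, length(val_curve), best$loss, best$epoch))
    folds[[f]] <- list(params = best$params, norm = norm)
    reports[[f]] <- list(val_losses = val_curve, best_epoch = best$epoch,
                         stopped_epoch = length(val_curve),
                         n_train = length(tr), n_val = length(va))
  }

  obj <- structure(list(folds = folds, enc_cfg = enc_cfg,
                        config = config, reports = reports,
                        test_idx = test_idx,
                        case_ids = vapply(data, `[[`, character(1), "case_id"),
                        labels = labels),
                   class = "ssl_classifier")
  Xt <- lapply(test_idx, function(i) data[[i]]$axial)
  probs <- predict_flat(obj, Xt)
  obj$test <- data.frame(case_id = obj$case_ids[test_idx],
                         label = labels[test_idx],
                         p_malignant = probs[, 2])
  obj
}

# internal: predict from a list of flattened 25 x patch_dim matrices
predict_flat <- function(object, Xlist) {
  B <- length(Xlist)
  X <- do.call(rbind, Xlist)
  acc <- matrix(0, B, 2)
  for (fold in object$folds) {
    fw <- finetune_forward(X, fold$params, fold$norm, object$enc_cfg, B)
    m <- pmax(fw$logits[, 1], fw$logits[, 2])
    lse <- m + log(exp(fw$logits[, 1] - m) + exp(fw$logits[, 2] - m))
    acc <- acc + exp(fw$logits - lse)
  }
  P <- acc / length(object$folds)
  colnames(P) <- c("p_benign", "p_malignant")
  P
}

#' Predict class probabilities for montages
#'
#' Fold-ensemble prediction: the mean of the per-fold softmax outputs.
#' Probabilities are non-negative and sum to one per case.
#'
#' @param object an `ssl_classifier`
#' @param newdata a `montage_pair`, a list of them, or a single montage
#'   matrix
#' @param ... unused
#' @return matrix with columns `p_benign`, `p_malignant`
#' @export
predict.ssl_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "montage_pair")) newdata <- list(newdata)
  if (is.matrix(newdata)) {
    Xlist <- list(flatten_patches(partition_patches(newdata)))
  } else {
    Xlist <- lapply(newdata, function(p) {
      m <- if (inherits(p, "montage_pair")) p$axial else p
      flatten_patches(partition_patches(m))
    })
  }
  predict_flat(object, Xlist)
}

#' @rdname predict.ssl_classifier
#' @export
predict_proba <- function(object, newdata, ...) {
  predict(object, newdata, ...)
}

#' @export
print.ssl_classifier <- function(x, ...) {
  cat(sprintf("<ssl_classifier> %d-fold ensemble, %d test cases held out\n",
              length(x$folds), length(x$test_idx)))
  if (!is.null(x$test)) {
    cat("held-out test predictions available in $test\n")
  }
  invisible(x)
}

#' @export
summary.ssl_classifier <- function(object, ...) {
  stopped <- vapply(object$reports, `[[`, numeric(1), "stopped_epoch")
  cat(sprintf("folds stopped at epochs: %s\n", paste(stopped, collapse = ", ")))
  if (!is.null(object$test)) {
    m <- evaluate_predictions(object$test$p_malignant, object$test$label,
                              n_boot = 200, seed = 1)
    cat(sprintf("held-out: AUC %.3f (%.3f-%.3f), ACC %.3f, SEN %.3f, SPE %.3f\n",
                m$auc, m$auc_ci[1], m$auc_ci[2], m$acc, m$sen, m$spe))
  }
  invisible(object)
}

#' Mask-ratio sweep harness
#'
#' Pretrains and fine-tunes once per mask ratio and reports held-out
#' classification metrics for each over the standard ablation grid
#' (20%...90%).
#'
#' @param pretrain_pairs montage pairs for pretraining
#' @param finetune_pairs unaugmented labelled pairs for fine-tuning
#' @param ratios mask ratios to sweep
#' @param pre_cfg,fin_cfg base configurations (the mask ratio is overridden)
#' @param enc_cfg,dec_cfg network configurations
#' @param verbose print progress
#' @return data.frame with one row per ratio (auc, acc, sen, spe)
#' @export
sweep_mask_ratio <- function(pretrain_pairs, finetune_pairs,
                             ratios = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7,
                                        0.75, 0.8, 0.9),
                             pre_cfg = pretrain_config(),
                             fin_cfg = finetune_config(),
                             enc_cfg = encoder_config(),
                             dec_cfg = decoder_config(), verbose = FALSE) {
  rows <- lapply(ratios, function(r) {
    cfg <- pre_cfg; cfg$mask_ratio <- r
    pt <- pretrain(pretrain_pairs, cfg, enc_cfg, dec_cfg)
    cl <- finetune(pt, finetune_pairs, fin_cfg)
    m <- evaluate_predictions(cl$test$p_malignant, cl$test$label,
                              n_boot = 200, seed = fin_cfg$seed)
    if (verbose) message(sprintf("ratio %.2f: AUC %.3f ACC %.3f", r, m$auc, m$acc))
    data.frame(mask_ratio = r, auc = m$auc, acc = m$acc, sen = m$sen,
               spe = m$spe)
  })
  do.call(rbind, rows)
}
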