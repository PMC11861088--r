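# Classification metrics (accuracy, sensitivity, specificity, ROC AUC with
# stratified percentile-bootstrap CI) and image-fidelity metrics for
# reconstructions (MAE, MSE, PSNR, SSIM).

#' Confusion counts at a decision threshold
#'
#' Scores at or above the threshold are called positive (ties count as
#' positive calls); label 1 is the positive (malignant) class by default.
#'
#' @param scores per-case probabilities/scores
#' @param labels binary labels (0/1)
#' @param threshold decision threshold (default 0.5)
#' @return object of class `confusion_counts`: list(TP, TN, FP, FN)
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  call_pos <- scores >= threshold
  structure(list(TP = sum(call_pos & labels == 1),
                 TN = sum(!call_pos & labels == 0),
                 FP = sum(call_pos & labels == 0),
                 FN = sum(!call_pos & labels == 1),
                 threshold = threshold),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN); SEN = TP/(TP+FN); SPE = TN/(TN+FP).
#' A metric whose denominator is zero is reported as `NA`.
#'
#' @param c a [confusion_counts()] object (or list with TP/TN/FP/FN)
#' @return list(acc, sen, spe)
#' @export
classification_metrics <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) stop("all confusion counts are zero")
  list(acc = (c$TP + c$TN) / tot,
       sen = if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_,
       spe = if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_)
}

#' ROC AUC (Mann-Whitney concordance)
#'
#' The trapezoidal integral of TPR over FPR across all thresholds, computed
#' as the pairwise concordance probability with ties counted one half.
#'
#' @param scores,labels as in [confusion_counts()]; both classes must be
#'   present
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with a stratified percentile-bootstrap confidence interval
#'
#' Cases are resampled with replacement within each class; the CI is the
#' percentile interval of the bootstrap AUC distribution.
#'
#' @param scores,labels as in [roc_auc()]
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed RNG seed for resampling
#' @param conf_level confidence level (default 0.95)
#' @return list(auc, auc_ci = c(lower, upper), n_boot)
#' @export
roc_auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L,
                       conf_level = 0.95) {
  auc <- roc_auc(scores, labels)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    roc_auc(scores[j], labels[j])
  }, numeric(1)))
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  list(auc = auc, auc_ci = ci, n_boot = n_boot)
}

#' Youden-J optimal threshold
#'
#' The score threshold maximising sensitivity + specificity - 1.
#' @param scores,labels as in [roc_auc()]
#' @export
youden_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    m <- classification_metrics(confusion_counts(scores, labels, t))
    m$sen + m$spe - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Full classification report
#'
#' @param scores,labels as in [roc_auc()]
#' @param threshold operating threshold for ACC/SEN/SPE; `"youden"` selects
#'   the Youden-J point
#' @param n_boot,seed,conf_level bootstrap settings for the AUC CI
#' @return object of class `metric_report`: auc, auc_ci, acc, sen, spe,
#'   threshold, n
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5,
                                 n_boot = 2000L, seed = 1L,
                                 conf_level = 0.95) {
  if (identical(threshold, "youden")) threshold <- youden_threshold(scores, labels)
  a <- roc_auc_ci(scores, labels, n_boot, seed, conf_level)
  m <- classification_metrics(confusion_counts(scores, labels, threshold))
  structure(list(auc = a$auc, auc_ci = a$auc_ci, acc = m$acc, sen = m$sen,
                 spe = m$spe, threshold = threshold, n = length(scores)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)  ACC %.3f  SEN %.3f  SPE %.3f  (n=%d, t=%.3g)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$acc, x$sen, x$spe, x$n,
              x$threshold))
  invisible(x)
}

# separable Gaussian kernel, normalised
gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# valid-region 2D convolution with a separable kernel
conv2_valid_sep <- function(X, k) {
  s <- length(k)
  H <- nrow(X) - s + 1L; W <- ncol(X) - s + 1L
  if (H < 1 || W < 1) stop("image smaller than the filter window")
  # rows
  R <- matrix(0, H, ncol(X))
  for (i in seq_len(s)) R <- R + k[i] * X[i:(i + H - 1), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_len(s)) out <- out + k[j] * R[, j:(j + W - 1), drop = FALSE]
  out
}

#' Structural similarity index (SSIM)
#'
#' Gaussian-weighted SSIM with the standard constants (k1 = 0.01,
#' k2 = 0.03, 11-pixel window, sigma = 1.5) on data range `data_range`;
#' the reported value is the mean of the SSIM map over all fully interior
#' (valid) windows.
#'
#' @param x,y images (matrices) of equal size
#' @param data_range value range of the data (1 for normalised montages)
#' @param window,sigma Gaussian window size and width
#' @export
ssim_index <- function(x, y, data_range = 1, window = 11L, sigma = 1.5) {
  if (!all(dim(x) == dim(y))) stop("image shapes differ")
  k <- gaussian_kernel_1d(window, sigma)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- conv2_valid_sep(x, k); my <- conv2_valid_sep(y, k)
  sxx <- conv2_valid_sep(x * x, k) - mx^2
  syy <- conv2_valid_sep(y * y, k) - my^2
  sxy <- conv2_valid_sep(x * y, k) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx^2 + my^2 + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Reconstruction fidelity metrics
#'
#' MAE, MSE, PSNR and SSIM between a predicted and a target image on the
#' stated data range (1 for normalised montages; PSNR is infinite for
#' identical images).
#'
#' @param predicted,target images (matrices) of equal shape
#' @param data_range value range (default 1)
#' @return object of class `recon_report`: list(mae, mse, psnr, ssim)
#' @export
reconstruction_metrics <- function(predicted, target, data_range = 1) {
  if (!all(dim(predicted) == dim(target))) stop("image shapes differ")
  d <- predicted - target
  mae <- mean(abs(d))
  mse <- mean(d^2)
  psnr <- if (mse == 0) Inf else 10 * log10(data_range^2 / mse)
  structure(list(mae = mae, mse = mse, psnr = psnr,
                 ssim = ssim_index(predicted, target, data_range)),
            class = "recon_report")
}

#' @export
print.recon_report <- function(x, ...) {
  cat(sprintf("MAE %.4f  MSE %.5f  PSNR %s dB  SSIM %.4f\n",
              x$mae, x$mse,
              if (is.infinite(x$psnr)) "Inf" else sprintf("%.2f", x$psnr),
              x$ssim))
  invisible(x)
}

#' Reconstruct a full montage from a trained model
#'
#' Runs one masked forward pass and pastes the decoder's masked-patch
#' predictions into the montage (visible patches keep their true pixels),
#' the standard visualisation/evaluation mode for masked autoencoders.
#'
#' @param pretrained an `ssl_pretrain` object
#' @param montage a 250 x 250 montage matrix
#' @param plan a [sample_mask()] plan
#' @return list with `reconstruction` (paste-in image), `predicted_only`
#'   (masked patches replaced, visible zeroed elsewhere is not included),
#'   and the per-patch predictions
#' @export
reconstruct_montage <- function(pretrained, montage, plan) {
  net <- pretrained$network
  X <- flatten_patches(partition_patches(montage))
  proj <- list(W = net$encoder$patch_W, b = net$encoder$patch_b,
               class_token = net$encoder$cls)
  tb <- embed_visible_tokens(X, plan, proj)
  lat <- encode(tb, net)
  pred <- decode_masked(lat, plan, net)
  p <- sqrt(ncol(X))
  rec <- montage
  for (j in seq_along(plan$indices)) {
    s <- plan$indices[j]
    r <- p * (s %/% 5); cc <- p * (s %% 5)
    rec[(r + 1):(r + p), (cc + 1):(cc + p)] <-
      matrix(pred[j, ], p, p, byrow = TRUE)
  }
  list(reconstruction = rec, predictions = pred)
}
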