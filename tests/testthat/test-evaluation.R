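test_that("confusion counts and derived metrics match hand computation", {
  cc <- confusion_counts(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 1))
  expect_identical(cc$TP, 2L); expect_identical(cc$FN, 1L)
  expect_identical(cc$TN, 1L); expect_identical(cc$FP, 0L)
  m <- classification_metrics(cc)
  expect_equal(m$acc, 0.75)
  expect_equal(m$sen, 2 / 3)
  expect_equal(m$spe, 1)
  # perfect classifier
  mp <- classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(unlist(mp), c(acc = 1, sen = 1, spe = 1))
  # threshold 0 calls everything positive
  c0 <- confusion_counts(c(0.2, 0.9), c(0, 1), threshold = 0)
  expect_identical(c0$FN + c0$TN, 0L)
  # ties at the threshold count as positive calls
  ct <- confusion_counts(c(0.5), c(1), threshold = 0.5)
  expect_identical(ct$TP, 1L)
  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")
})

test_that("relabelling the classes swaps sensitivity and specificity", {
  noduleSSL:::with_seed(3, {
    s <- stats::runif(40); l <- rbinom(40, 1, 0.5)
    # mirror the scores about 0.5 and flip the labels: the roles swap
    s2 <- 1 - s
    keep <- abs(s - 0.5) > 1e-9
    m2 <- classification_metrics(confusion_counts(s2[keep] + 1e-12,
                                                  1 - l[keep]))
    m1k <- classification_metrics(confusion_counts(s[keep], l[keep]))
    expect_equal(m2$sen, m1k$spe, tolerance = 1e-12)
    expect_equal(m2$spe, m1k$sen, tolerance = 1e-12)
  })
})

test_that("accuracy is the prevalence-weighted blend of SEN and SPE", {
  noduleSSL:::with_seed(8, {
    for (i in 1:10) {
      s <- stats::runif(60)
      l <- rbinom(60, 1, 0.4)
      if (length(unique(l)) < 2) next
      m <- classification_metrics(confusion_counts(s, l))
      prev <- mean(l)
      expect_equal(m$acc, prev * m$sen + (1 - prev) * m$spe,
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC matches worked examples and the exhaustive pairwise oracle", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  pairwise_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  noduleSSL:::with_seed(17, {
    for (i in 1:30) {
      n <- sample(4:50, 1)
      s <- round(stats::runif(n), 2) # rounding induces ties
      l <- rbinom(n, 1, 0.5)
      if (length(unique(l)) < 2) next
      expect_equal(roc_auc(s, l), pairwise_auc(s, l), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  noduleSSL:::with_seed(5, {
    for (i in 1:10) {
      s <- stats::runif(50)
      l <- rbinom(50, 1, 0.5)
      if (length(unique(l)) < 2) next
      ref <- as.numeric(suppressMessages(pROC::auc(l, s,
                                                   direction = "<",
                                                   quiet = TRUE)))
      expect_equal(roc_auc(s, l), ref, tolerance = 1e-10)
    }
  })
})

test_that("null-model AUC concentrates around one half", {
  aucs <- vapply(1:20, function(i) {
    noduleSSL:::with_seed(200 + i, {
      s <- stats::runif(200)
      l <- rbinom(200, 1, 0.5)
      roc_auc(s, l)
    })
  }, numeric(1))
  expect_gt(mean(aucs > 0.4 & aucs < 0.6), 0.9)
})

test_that("bootstrap CI covers the point AUC and narrows with sample size", {
  noduleSSL:::with_seed(31, {
    make <- function(n) {
      l <- rep(c(0, 1), each = n / 2)
      s <- stats::rnorm(n, mean = l) # moderately separated
      list(s = s, l = l)
    }
    small <- make(40); big <- make(400)
    ci_s <- roc_auc_ci(small$s, small$l, n_boot = 500, seed = 1)
    ci_b <- roc_auc_ci(big$s, big$l, n_boot = 500, seed = 1)
    expect_true(ci_s$auc_ci[1] <= ci_s$auc && ci_s$auc <= ci_s$auc_ci[2])
    expect_true(ci_b$auc_ci[1] <= ci_b$auc && ci_b$auc <= ci_b$auc_ci[2])
    expect_lt(diff(ci_b$auc_ci), diff(ci_s$auc_ci))
    # deterministic under the seed
    ci_s2 <- roc_auc_ci(small$s, small$l, n_boot = 500, seed = 1)
    expect_identical(ci_s$auc_ci, ci_s2$auc_ci)
  })
})

test_that("reconstruction metrics satisfy their identities", {
  noduleSSL:::with_seed(12, {
    x <- matrix(stats::runif(64 * 64), 64, 64)
    r0 <- reconstruction_metrics(x, x)
    expect_identical(r0$mae, 0)
    expect_identical(r0$mse, 0)
    expect_identical(r0$psnr, Inf)
    expect_equal(r0$ssim, 1)
    # constant offset of 0.1 on range-1 data: MSE 0.01, PSNR 20 dB
    xo <- pmin(x, 0.9)
    ro <- reconstruction_metrics(xo + 0.1, xo)
    expect_equal(ro$mse, 0.01, tolerance = 1e-12)
    expect_equal(ro$psnr, 20, tolerance = 1e-9)
    expect_equal(ro$mae, 0.1, tolerance = 1e-12)
    expect_error(reconstruction_metrics(x, x[1:10, 1:10]), "shapes")
  })
})

test_that("SSIM matches a brute-force windowed oracle and sign behaviour", {
  g <- outer(0:63, 0:63, function(i, j) (i + j) / 126) # diagonal ramp
  noduleSSL:::with_seed(21, {
    y <- pmin(pmax(g + stats::rnorm(64 * 64, sd = 0.05), 0), 1)
    # brute-force per-window SSIM with the same Gaussian weights
    k <- noduleSSL:::gaussian_kernel_1d(11, 1.5)
    w2 <- outer(k, k)
    c1 <- 0.01^2; c2 <- 0.03^2
    vals <- c()
    for (i in seq(1, 54, by = 7)) for (j in seq(1, 54, by = 7)) {
      wx <- g[i:(i + 10), j:(j + 10)]; wy <- y[i:(i + 10), j:(j + 10)]
      mx <- sum(w2 * wx); my <- sum(w2 * wy)
      sxx <- sum(w2 * wx^2) - mx^2; syy <- sum(w2 * wy^2) - my^2
      sxy <- sum(w2 * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + c1) * (2 * sxy + c2)) /
                        ((mx^2 + my^2 + c1) * (sxx + syy + c2)))
    }
    # the implementation's full map, sampled at the same valid positions
    mget <- function(a, b) {
      num_map <- noduleSSL:::conv2_valid_sep
      # recompute the SSIM map directly for comparison
      mx <- num_map(a, k); my <- num_map(b, k)
      sxx <- num_map(a * a, k) - mx^2; syy <- num_map(b * b, k) - my^2
      sxy <- num_map(a * b, k) - mx * my
      ((2 * mx * my + c1) * (2 * sxy + c2)) /
        ((mx^2 + my^2 + c1) * (sxx + syy + c2))
    }
    smap <- mget(g, y)
    idx <- 1
    for (i in seq(1, 54, by = 7)) for (j in seq(1, 54, by = 7)) {
      expect_equal(smap[i, j], vals[idx], tolerance = 1e-10)
      idx <- idx + 1
    }
  })
  # negated contrast: anticorrelated windows give negative mean SSIM once
  # the local variance dominates the stabilising constant
  ramp <- matrix(rep((0:63) / 63, 64), 64, 64)
  expect_lt(ssim_index(ramp, 1 - ramp), 0)
  # similarity decreases with noise
  noduleSSL:::with_seed(22, {
    y1 <- pmin(pmax(g + stats::rnorm(64 * 64, sd = 0.02), 0), 1)
    y2 <- pmin(pmax(g + stats::rnorm(64 * 64, sd = 0.2), 0), 1)
    expect_gt(ssim_index(g, y1), ssim_index(g, y2))
  })
})

test_that("the Youden threshold maximises SEN + SPE - 1", {
  noduleSSL:::with_seed(44, {
    s <- c(stats::rnorm(30, 0.3, 0.1), stats::rnorm(30, 0.7, 0.1))
    l <- rep(c(0, 1), each = 30)
    t_star <- youden_threshold(s, l)
    j_at <- function(t) {
      m <- classification_metrics(confusion_counts(s, l, t))
      m$sen + m$spe - 1
    }
    j_star <- j_at(t_star)
    for (t in stats::quantile(s, seq(0.05, 0.95, 0.1)))
      expect_lte(j_at(t), j_star + 1e-12)
  })
})
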