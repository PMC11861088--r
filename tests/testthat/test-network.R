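test_that("encoding preserves sequence shape and is deterministic", {
  net <- init_network(micro_enc(), micro_dec(), patch_dim = 100L, seed = 2)
  grid <- array(stats::runif(25 * 10 * 10), c(25, 10, 10))
  plan <- sample_mask(25L, 0.5, seed = 1)
  proj <- list(W = net$encoder$patch_W, b = net$encoder$patch_b,
               class_token = net$encoder$cls)
  tb <- embed_visible_tokens(grid, plan, proj)
  y1 <- encode(tb, net)
  expect_identical(dim(y1), c(13L, 16L))
  expect_identical(encode(tb, net), y1)
  # changing a masked-out patch leaves the encoding unchanged
  grid2 <- grid
  grid2[plan$indices[1] + 1L, , ] <- 0.123
  tb2 <- embed_visible_tokens(grid2, plan, proj)
  expect_identical(encode(tb2, net), y1)
  expect_error(encode(matrix(0, 3, 5), net), "d_model")
})

test_that("momentum updates follow the exponential moving average exactly", {
  e <- list(W = matrix(1, 3, 3), b = rep(1, 3))
  m0 <- list(W = matrix(0, 3, 3), b = rep(0, 3))
  # fixed point
  expect_identical(momentum_update(e, e, 0.01), e)
  # single step arithmetic
  m1 <- momentum_update(e, m0, 0.01)
  expect_equal(m1$W[1, 1], 0.01)
  # geometric decay towards a frozen encoder over t = 100 steps
  m <- m0
  for (t in 1:100) m <- momentum_update(e, m, 0.01)
  expect_equal(m$W[2, 2], 1 - 0.99^100, tolerance = 1e-12)
  # m = 1 copies the encoder (degenerate limit)
  expect_identical(momentum_update(e, m0, 1), e)
  expect_error(momentum_update(e, list(W = matrix(0, 2, 2)), 0.01), "match")
  expect_error(momentum_update(e, m0, 0), "m must")
})

test_that("momentum encoder mirrors the encoder structurally", {
  net <- init_network(micro_enc(), micro_dec(), patch_dim = 100L, seed = 3)
  expect_identical(net$momentum, net$encoder)
  expect_identical(noduleSSL:::par_count(net$momentum),
                   noduleSSL:::par_count(net$encoder))
  up <- momentum_update(net$encoder, net$momentum, 0.01)
  # still the encoder at initialisation (up to floating-point rounding)
  expect_equal(noduleSSL:::par_l2(up, net$encoder), 0, tolerance = 1e-12)
})

test_that("flattened features are 128-dim unit vectors", {
  net <- init_network(micro_enc(), micro_dec(), patch_dim = 100L, seed = 4)
  lat <- matrix(stats::rnorm(13 * 16), 13, 16)
  q <- flatten_features(lat, net$q_head)
  expect_length(q, 128L)
  expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-6)
  # kernel-1 convolution + mean pool: duplicating the sequence is a no-op
  q2 <- flatten_features(rbind(lat, lat), net$q_head)
  expect_equal(q2, q, tolerance = 1e-12)
  # q and k heads are distinct parameter sets after independent updates
  expect_error(flatten_features(matrix(numeric(0), 0, 16), net$q_head),
               "non-empty")
})

test_that("masked decoding yields one pixel vector per masked patch", {
  net <- init_network(micro_enc(), micro_dec(), patch_dim = 100L, seed = 5)
  grid <- array(stats::runif(25 * 10 * 10), c(25, 10, 10))
  proj <- list(W = net$encoder$patch_W, b = net$encoder$patch_b,
               class_token = net$encoder$cls)
  plan <- sample_mask(25L, 0.5, seed = 2)
  lat <- encode(embed_visible_tokens(grid, plan, proj), net)
  pred <- decode_masked(lat, plan, net)
  expect_identical(dim(pred), c(13L, 100L))
  # nothing masked: empty prediction, zero reconstruction loss
  plan0 <- sample_mask(25L, 0, seed = 1)
  lat0 <- encode(embed_visible_tokens(grid, plan0, proj), net)
  pred0 <- decode_masked(lat0, plan0, net)
  expect_identical(nrow(pred0), 0L)
  expect_identical(masked_mse_loss(pred0, pred0), 0)
  expect_error(decode_masked(lat[1:5, ], plan, net), "inconsistent")
})

test_that("decoder predictions are invariant to visible-token permutation", {
  net <- init_network(micro_enc(), micro_dec(), patch_dim = 100L, seed = 6)
  n_vis <- 12L
  vis <- sort(sample(0:24, n_vis))
  masked <- setdiff(0:24, vis)
  Xflat <- matrix(stats::runif(25 * 100), 25, 100)
  embed_one <- function(order) {
    tok <- Xflat[vis[order] + 1L, , drop = FALSE] %*% net$encoder$patch_W
    tok <- tok + rep(net$encoder$patch_b, each = n_vis) +
      positional_embedding(vis[order], 16L)
    rbind(net$encoder$cls, tok)
  }
  perm <- sample(n_vis)
  lat_a <- encode(embed_one(seq_len(n_vis)), net)
  lat_b <- encode(embed_one(perm), net)
  # attention is permutation-equivariant over patch tokens
  expect_equal(lat_b[-1, ][order(perm), ], lat_a[-1, ], tolerance = 1e-10)
  out_a <- noduleSSL:::decoder_fwd(lat_a, list(vis), list(masked),
                                   net$decoder, net$dec_cfg, n_vis, 1L)
  out_b <- noduleSSL:::decoder_fwd(lat_b, list(vis[perm]), list(masked),
                                   net$decoder, net$dec_cfg, n_vis, 1L)
  expect_equal(out_a$pred, out_b$pred, tolerance = 1e-8)
})

test_that("analytic gradients of the hybrid objective match finite differences", {
  set.seed(42)
  enc_cfg <- encoder_config(depth = 1L, d_model = 8L, n_heads = 2L)
  dec_cfg <- decoder_config(depth = 1L, d_model = 8L, n_heads = 2L)
  patch_dim <- 16L
  net <- init_network(enc_cfg, dec_cfg, patch_dim, seed = 3L)
  B <- 2L
  n_mask <- 13L; n_vis <- 25L - n_mask
  Xa <- lapply(1:B, function(i) matrix(stats::runif(25 * patch_dim), 25, patch_dim))
  mask_l <- lapply(1:B, function(i) sort(sample(0:24, n_mask)))
  vis_l <- lapply(mask_l, function(m) setdiff(0:24, m))
  queue <- update_queue(new_queue(10, 128), {
    k <- matrix(stats::rnorm(5 * 128), 5); k / sqrt(rowSums(k^2))
  })
  K <- matrix(stats::rnorm(B * 128), B); K <- K / sqrt(rowSums(K^2))
  lam <- 0.4; tau <- 0.07

  loss_and_grads <- function(net, want_grads = TRUE) {
    Xvis <- do.call(rbind, lapply(1:B, function(b)
      Xa[[b]][vis_l[[b]] + 1, , drop = FALSE]))
    emb <- noduleSSL:::embed_batch_fwd(Xvis, vis_l, net$encoder, 8L, n_vis, B)
    ev <- noduleSSL:::nn_vit_fwd(emb$X, net$encoder$blocks, net$encoder$lnf_g,
                                 net$encoder$lnf_b, 2L, n_vis + 1L, B)
    fq <- noduleSSL:::flatten_fwd(ev$Y, net$q_head, n_vis + 1L, B)
    nce <- noduleSSL:::infonce_batch(fq$Q, K, queue, tau)
    dc <- noduleSSL:::decoder_fwd(ev$Y, vis_l, mask_l, net$decoder, dec_cfg,
                                  n_vis, B)
    Tm <- do.call(rbind, lapply(1:B, function(b)
      Xa[[b]][mask_l[[b]] + 1, , drop = FALSE]))
    R <- dc$pred - Tm
    L <- lam * mean(R^2) + (1 - lam) * nce$loss
    if (!want_grads) return(L)
    fb <- noduleSSL:::flatten_bwd((1 - lam) * nce$dQ, net$q_head, fq$cache)
    db <- noduleSSL:::decoder_bwd((2 * lam / length(R)) * R, net$decoder,
                                  dec_cfg, dc)
    vb <- noduleSSL:::nn_vit_bwd(fb$dL + db$dL, net$encoder$blocks, ev$cache)
    eb <- noduleSSL:::embed_batch_bwd(vb$dX, net$encoder, emb$cache)
    g <- list(encoder = noduleSSL:::encoder_grads_tree(eb$grads, vb$grads),
              decoder = db$grads, q_head = fb$grads)
    noduleSSL:::reorder_like(g, net[c("encoder", "decoder", "q_head")])
  }

  grads <- loss_and_grads(net)
  eps <- 1e-6
  get_leaf <- function(l, path) { for (p in path) l <- l[[p]]; l }
  set_leaf <- function(l, path, v) {
    if (length(path) == 1) { l[[path[[1]]]] <- v; return(l) }
    l[[path[[1]]]] <- set_leaf(l[[path[[1]]]], path[-1], v)
    l
  }
  # spot-check representative leaves across all three components
  paths <- list(list("encoder", "patch_W"), list("encoder", "cls"),
                list("encoder", "blocks", 1L, "qkv_W"),
                list("encoder", "blocks", 1L, "ln2_g"),
                list("decoder", "mask_token"), list("decoder", "adapter_W"),
                list("decoder", "head_W"),
                list("q_head", "conv_W"), list("q_head", "out_W"))
  for (path in paths) {
    leaf <- get_leaf(net, path)
    gl <- get_leaf(grads, path)
    for (i in sample(length(leaf), 2)) {
      l2 <- leaf; l2[i] <- l2[i] + eps
      Lp <- loss_and_grads(set_leaf(net, path, l2), want_grads = FALSE)
      l2[i] <- leaf[i] - eps
      Lm <- loss_and_grads(set_leaf(net, path, l2), want_grads = FALSE)
      num <- (Lp - Lm) / (2 * eps)
      expect_equal(gl[i], num, tolerance = 1e-3)
    }
  }
})
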