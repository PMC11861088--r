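# The asymmetric encoder-decoder, the momentum encoder and the feature
# flattening heads.
#
# The encoder is a standard pre-norm ViT (GELU MLP, ratio 4) operating on
# visible patch tokens plus a leading class token. The decoder is a narrower
# ViT that receives adapted visible latents plus one shared learnable mask
# token (with sinusoidal position embeddings) at every masked position and
# predicts raw pixels for the masked patches. The flattening heads apply a
# kernel-1 one-dimensional convolution over the token axis, mean-pool, map
# to 128 dimensions and L2-normalise.

#' Encoder configuration
#'
#' @param preset `"large"` (24 blocks, width 1024, 16 heads; the ViT-Large
#'   scale used on clinical data) or `"tiny"` (2 blocks, width 64, 4 heads;
#'   CPU-friendly for phantom experiments and tests)
#' @param depth,d_model,n_heads override individual fields
#' @export
encoder_config <- function(preset = c("tiny", "large"), depth = NULL,
                           d_model = NULL, n_heads = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 large = list(depth = 24L, d_model = 1024L, n_heads = 16L),
                 tiny = list(depth = 2L, d_model = 64L, n_heads = 4L))
  cfg <- list(depth = as.integer(depth %||% base$depth),
              d_model = as.integer(d_model %||% base$d_model),
              n_heads = as.integer(n_heads %||% base$n_heads),
              preset = preset)
  if (cfg$d_model %% cfg$n_heads != 0)
    stop("d_model must be divisible by n_heads")
  if (cfg$d_model %% 2 != 0) stop("d_model must be even")
  class(cfg) <- "encoder_config"
  cfg
}

#' Decoder configuration
#'
#' @param preset `"large"` (8 blocks, width 512) or `"tiny"` (1 block,
#'   width 32)
#' @param depth,d_model,n_heads overrides
#' @export
decoder_config <- function(preset = c("tiny", "large"), depth = NULL,
                           d_model = NULL, n_heads = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
                 large = list(depth = 8L, d_model = 512L, n_heads = 16L),
                 tiny = list(depth = 1L, d_model = 32L, n_heads = 4L))
  cfg <- list(depth = as.integer(depth %||% base$depth),
              d_model = as.integer(d_model %||% base$d_model),
              n_heads = as.integer(n_heads %||% base$n_heads),
              preset = preset)
  if (cfg$d_model %% cfg$n_heads != 0)
    stop("d_model must be divisible by n_heads")
  class(cfg) <- "decoder_config"
  cfg
}

init_encoder_params <- function(cfg, patch_dim) {
  d <- cfg$d_model
  list(patch_W = nn_rmat(patch_dim, d), patch_b = rep(0, d),
       cls = stats::rnorm(d, sd = 0.02),
       blocks = lapply(seq_len(cfg$depth), function(i) nn_init_block(d)),
       lnf_g = rep(1, d), lnf_b = rep(0, d))
}

init_head_params <- function(d_in, d_out = 128L) {
  list(conv_W = nn_rmat(d_in, d_in), conv_b = rep(0, d_in),
       out_W = nn_rmat(d_in, d_out), out_b = rep(0, d_out))
}

#' Initialise the full network
#'
#' The momentum encoder starts as an exact copy of the encoder; the key-path
#' flattening head starts from its own initialisation (the two views carry
#' individual heads). Both are subsequently updated only through
#' [momentum_update()].
#'
#' @param enc_cfg an [encoder_config()]
#' @param dec_cfg a [decoder_config()]
#' @param patch_dim flattened patch length (2500 for 50 x 50 patches)
#' @param seed RNG seed for initialisation
#' @return object of class `ssl_network`
#' @export
init_network <- function(enc_cfg = encoder_config(),
                         dec_cfg = decoder_config(),
                         patch_dim = 2500L, seed = 1L) {
  with_seed(seed, {
    d_enc <- enc_cfg$d_model; d_dec <- dec_cfg$d_model
    encoder <- init_encoder_params(enc_cfg, patch_dim)
    decoder <- list(adapter_W = nn_rmat(d_enc, d_dec),
                    adapter_b = rep(0, d_dec),
                    mask_token = stats::rnorm(d_dec, sd = 0.02),
                    blocks = lapply(seq_len(dec_cfg$depth),
                                    function(i) nn_init_block(d_dec)),
                    lnf_g = rep(1, d_dec), lnf_b = rep(0, d_dec),
                    head_W = nn_rmat(d_dec, patch_dim),
                    head_b = rep(0, patch_dim))
    q_head <- init_head_params(d_enc)
    # the two views use individual flattening heads: the key head starts
    # from its own draw and subsequently momentum-tracks the query head
    k_head <- init_head_params(d_enc)
    structure(list(enc_cfg = enc_cfg, dec_cfg = dec_cfg,
                   patch_dim = as.integer(patch_dim),
                   encoder = encoder, momentum = encoder,
                   decoder = decoder, q_head = q_head, k_head = k_head),
              class = "ssl_network")
  })
}

#' @export
print.ssl_network <- function(x, ...) {
  cat(sprintf(paste0("<ssl_network> encoder %d blocks x %d dim (%d heads), ",
                     "decoder %d x %d; %s parameters per encoder\n"),
              x$enc_cfg$depth, x$enc_cfg$d_model, x$enc_cfg$n_heads,
              x$dec_cfg$depth, x$dec_cfg$d_model,
              format(par_count(x$encoder), big.mark = ",")))
  invisible(x)
}

#' Encode a token batch
#'
#' Runs the transformer encoder over a single sample's tokens (class token
#' first). Output length and order equal the input; only visible-patch
#' content influences the result.
#'
#' @param tokens a `token_batch` from [embed_visible_tokens()], or a plain
#'   n x d_model matrix
#' @param network an `ssl_network`
#' @param which `"encoder"` or `"momentum"`
#' @return n x d_model matrix of latent tokens
#' @export
encode <- function(tokens, network, which = c("encoder", "momentum")) {
  which <- match.arg(which)
  X <- if (inherits(tokens, "token_batch")) tokens$tokens else tokens
  if (!is.matrix(X) || ncol(X) != network$enc_cfg$d_model)
    stop("token width does not match encoder d_model")
  p <- network[[which]]
  nn_vit_fwd(X, p$blocks, p$lnf_g, p$lnf_b, network$enc_cfg$n_heads,
             nrow(X), 1L)$Y
}

#' Momentum (exponential moving average) parameter update
#'
#' Every momentum parameter moves towards its encoder counterpart:
#' `theta_m <- (1 - m) * theta_m + m * theta_e`. With the default `m = 0.01`
#' only 1% of the encoder update is transferred per step; `m = 1` copies the
#' encoder exactly.
#'
#' @param encoder_params,momentum_params structurally identical parameter
#'   trees
#' @param m update fraction in (0, 1]
#' @export
momentum_update <- function(encoder_params, momentum_params, m = 0.01) {
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  par_map2(momentum_params, encoder_params,
           function(old, new) (1 - m) * old + m * new)
}

# batched flatten head: L is (B*n) x d, returns unit rows B x 128 + cache
flatten_fwd <- function(L, head, n, B) {
  C <- nn_linear_fwd(L, head$conv_W, head$conv_b)
  grp <- rep(seq_len(B), each = n)
  Pm <- rowsum(C, grp, reorder = FALSE) / n
  Z <- nn_linear_fwd(Pm, head$out_W, head$out_b)
  nrm <- sqrt(rowSums(Z^2))
  nrm <- pmax(nrm, 1e-12)
  Q <- Z / nrm
  list(Q = Q, cache = list(L = L, Pm = Pm, Z = Z, nrm = nrm, Q = Q,
                           n = n, B = B))
}

flatten_bwd <- function(dQ, head, cache) {
  Q <- cache$Q; nrm <- cache$nrm
  dZ <- (dQ - Q * rowSums(dQ * Q)) / nrm
  lo <- nn_linear_bwd(dZ, cache$Pm, head$out_W)
  dC <- lo$dX[rep(seq_len(cache$B), each = cache$n), , drop = FALSE] / cache$n
  lc <- nn_linear_bwd(dC, cache$L, head$conv_W)
  list(dL = lc$dX,
       grads = list(conv_W = lc$dW, conv_b = lc$db,
                    out_W = lo$dW, out_b = lo$db))
}

#' Flatten encoder latents to a 128-dim unit vector
#'
#' Kernel-1 one-dimensional convolution over the token axis (embedding
#' dimensions as channels), mean-pool over positions, linear map to 128 and
#' Euclidean normalisation. The query and key paths carry separate head
#' parameters (`network$q_head`, `network$k_head`).
#'
#' @param latents n x d_model latent token matrix (single sample)
#' @param head a head parameter list, e.g. `network$q_head`
#' @return unit-norm numeric vector of length 128
#' @export
flatten_features <- function(latents, head) {
  if (!is.matrix(latents) || nrow(latents) == 0)
    stop("latents must be a non-empty token matrix")
  drop(flatten_fwd(latents, head, nrow(latents), 1L)$Q)
}

# Build the decoder input sequence for a batch. vis_list holds 0-based
# visible positions per sample (ascending); latents are (B*(nv+1)) x d_enc
# with the class token first per sample. Returns the (B*26) x d_dec input,
# plus bookkeeping for the backward pass.
decoder_seq_build <- function(A, vis_list, mask_token, pe_dec, n_vis, B) {
  d_dec <- ncol(A)
  n_seq <- 26L
  # 0 = mask token, else row index into A (class token or a visible latent)
  src_row <- integer(B * n_seq)
  for (b in seq_len(B)) {
    a0 <- (b - 1) * (n_vis + 1)
    r0 <- (b - 1) * n_seq
    src_row[r0 + 1] <- a0 + 1L
    vis <- vis_list[[b]]
    if (length(vis)) src_row[r0 + 2L + vis] <- a0 + 1L + seq_along(vis)
  }
  X <- A[pmax(src_row, 1L), , drop = FALSE]
  is_mask <- src_row == 0L
  if (any(is_mask))
    X[is_mask, ] <- matrix(mask_token, sum(is_mask), d_dec, byrow = TRUE)
  # position embeddings on every patch token (none on the class token)
  pe_all <- rbind(0, pe_dec)[rep.int(c(1L, 2:26), B), , drop = FALSE]
  X <- X + pe_all
  list(X = X, src_row = src_row, n_seq = n_seq)
}

# forward through the decoder for a batch; returns predictions for masked
# patches ((sum of masked counts) x patch_dim, samples concatenated in order,
# masked positions ascending within a sample) and a cache
decoder_fwd <- function(L, vis_list, mask_list, dec, dec_cfg, n_vis, B) {
  A <- nn_linear_fwd(L, dec$adapter_W, dec$adapter_b)
  pe_dec <- positional_embedding(0:24, ncol(A))
  sq <- decoder_seq_build(A, vis_list, dec$mask_token, pe_dec, n_vis, B)
  vt <- nn_vit_fwd(sq$X, dec$blocks, dec$lnf_g, dec$lnf_b, dec_cfg$n_heads,
                   sq$n_seq, B)
  # rows of the masked positions, in mask-index order per sample
  mrows <- unlist(lapply(seq_len(B), function(b)
    (b - 1) * sq$n_seq + 2L + mask_list[[b]]))
  D <- vt$Y[mrows, , drop = FALSE]
  P <- nn_linear_fwd(D, dec$head_W, dec$head_b)
  list(pred = P,
       cache = list(L = L, A = A, sq = sq, vt = vt$cache, D = D,
                    mrows = mrows, n_vis = n_vis, B = B))
}

decoder_bwd <- function(dP, dec, dec_cfg, fwd) {
  cache <- fwd$cache
  lb <- nn_linear_bwd(dP, cache$D, dec$head_W)
  dY <- matrix(0, nrow(cache$sq$X), ncol(cache$sq$X))
  dY[cache$mrows, ] <- lb$dX
  vb <- nn_vit_bwd(dY, dec$blocks, cache$vt)
  dX <- vb$dX
  # route back through the sequence construction
  dA <- matrix(0, nrow(cache$A), ncol(cache$A))
  d_mask <- rep(0, ncol(cache$A))
  src <- cache$sq$src_row
  from_A <- src > 0
  if (any(from_A)) {
    idx <- src[from_A]
    dAsub <- rowsum(dX[from_A, , drop = FALSE], idx, reorder = FALSE)
    dA[as.integer(rownames(dAsub)), ] <- dAsub
  }
  if (any(!from_A)) d_mask <- colSums(dX[!from_A, , drop = FALSE])
  la <- nn_linear_bwd(dA, cache$L, dec$adapter_W)
  list(dL = la$dX,
       grads = list(adapter_W = la$dW, adapter_b = la$db,
                    mask_token = d_mask,
                    blocks = vb$grads$blocks,
                    lnf_g = vb$grads$lnf_g, lnf_b = vb$grads$lnf_b,
                    head_W = lb$dW, head_b = lb$db))
}

#' Predict pixel values of masked patches from visible latents
#'
#' Visible latents (class token first) are projected from encoder to decoder
#' width; the single shared learnable mask token, summed with the sinusoidal
#' embedding of its position, stands in at every masked position. The
#' decoder output at the masked positions is mapped to raw patch pixels.
#'
#' @param visible_latents (n_visible + 1) x d_enc matrix from [encode()]
#' @param plan the [sample_mask()] plan used when embedding
#' @param network an `ssl_network`
#' @return matrix `n_masked x patch_dim` of predicted pixels, rows in
#'   ascending masked-index order (0 rows when nothing is masked)
#' @export
decode_masked <- function(visible_latents, plan, network) {
  n_vis <- 25L - length(plan$indices)
  if (nrow(visible_latents) != n_vis + 1L)
    stop("mask plan inconsistent with latent count")
  if (length(plan$indices) == 0L)
    return(matrix(numeric(0), 0, network$patch_dim))
  vis <- setdiff(0:24, plan$indices)
  out <- decoder_fwd(visible_latents, list(vis), list(plan$indices),
                     network$decoder, network$dec_cfg, n_vis, 1L)
  out$pred
}

# batched masked embedding: Xvis is the stacked visible flattened patches
# ((B*nv) x patch_dim, sample-major); vis_list holds 0-based visible
# positions per sample. Produces the (B*(nv+1)) x d token matrix with the
# class token leading each sample.
embed_batch_fwd <- function(Xvis, vis_list, enc, d, n_vis, B) {
  Tk <- nn_linear_fwd(Xvis, enc$patch_W, enc$patch_b)
  pe_rows <- unlist(vis_list) + 1L
  pe <- positional_embedding(0:24, d)
  Tk <- Tk + pe[pe_rows, , drop = FALSE]
  n_seq <- n_vis + 1L
  cls_rows <- (seq_len(B) - 1L) * n_seq + 1L
  X <- matrix(0, B * n_seq, d)
  X[cls_rows, ] <- matrix(enc$cls, B, d, byrow = TRUE)
  X[-cls_rows, ] <- Tk
  list(X = X, cache = list(Xvis = Xvis, n_vis = n_vis, B = B, n_seq = n_seq,
                           cls_rows = cls_rows))
}

embed_batch_bwd <- function(dX, enc, cache) {
  cls_rows <- cache$cls_rows
  dcls <- colSums(dX[cls_rows, , drop = FALSE])
  dTk <- dX[-cls_rows, , drop = FALSE]
  lp <- nn_linear_bwd(dTk, cache$Xvis, enc$patch_W)
  list(grads = list(patch_W = lp$dW, patch_b = lp$db, cls = dcls))
}

# full-visibility classifier forward: grids is (B*25) x patch_dim of
# flattened patches (all visible); returns class-token latents (B x d) cache
classifier_fwd <- function(Xflat, enc, enc_cfg, B) {
  d <- enc_cfg$d_model
  pe <- positional_embedding(0:24, d)
  Tk <- nn_linear_fwd(Xflat, enc$patch_W, enc$patch_b) +
    pe[rep(1:25, times = B), , drop = FALSE]
  n_seq <- 26L
  cls_rows <- (seq_len(B) - 1L) * n_seq + 1L
  X <- matrix(0, B * n_seq, d)
  X[cls_rows, ] <- matrix(enc$cls, B, d, byrow = TRUE)
  X[-cls_rows, ] <- Tk
  vt <- nn_vit_fwd(X, enc$blocks, enc$lnf_g, enc$lnf_b, enc_cfg$n_heads,
                   n_seq, B)
  list(cls = vt$Y[cls_rows, , drop = FALSE],
       cache = list(Xflat = Xflat, vt = vt$cache, n_seq = n_seq, B = B,
                    cls_rows = cls_rows))
}

classifier_bwd <- function(dcls, enc, enc_cfg, cache) {
  B <- cache$B; n_seq <- cache$n_seq
  dY <- matrix(0, nrow = B * n_seq, ncol = enc_cfg$d_model)
  dY[cache$cls_rows, ] <- dcls
  vb <- nn_vit_bwd(dY, enc$blocks, cache$vt)
  dX <- vb$dX
  dcls_tok <- colSums(dX[cache$cls_rows, , drop = FALSE])
  dTk <- dX[-cache$cls_rows, , drop = FALSE]
  lp <- nn_linear_bwd(dTk, cache$Xflat, enc$patch_W)
  list(grads = list(patch_W = lp$dW, patch_b = lp$db, cls = dcls_tok,
                    blocks = vb$grads$blocks,
                    lnf_g = vb$grads$lnf_g, lnf_b = vb$grads$lnf_b))
}
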