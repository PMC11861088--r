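# Montage tokenisation: patch partition, random mask sampling, sinusoidal
# position embeddings, and embedding of the visible patches.

#' Partition a montage into its 5x5 grid of patches
#'
#' Inverse of [assemble_montage()]: patch `s` (0-based, row-major) is
#' `montage[P*floor(s/5) + 1:P, P*(s mod 5) + 1:P]`.
#'
#' @param montage square matrix whose side is divisible by 5 (250 x 250 in
#'   the standard pipeline)
#' @return array `c(25, P, P)`
#' @export
partition_patches <- function(montage) {
  if (!is.matrix(montage) || nrow(montage) != ncol(montage) ||
      nrow(montage) %% 5 != 0)
    stop("montage must be a square matrix with side divisible by 5")
  p <- nrow(montage) %/% 5L
  dim(montage) <- c(p, 5L, p, 5L)       # (row-in-patch, patch-row, col, patch-col)
  out <- aperm(montage, c(4L, 2L, 1L, 3L)) # patch index = 5*(patch-row-1)+patch-col
  dim(out) <- c(25L, p, p)
  out
}

#' Flatten patches row-major into a matrix of pixel vectors
#'
#' Row-major flattening (pixels of a patch row are contiguous) is the fixed
#' convention shared by the tokenizer and the decoder's reconstruction
#' targets.
#' @param patches array `c(25, P, P)` from [partition_patches()]
#' @return 25 x P^2 matrix
#' @export
flatten_patches <- function(patches) {
  d <- dim(patches)
  out <- aperm(patches, c(1, 3, 2)) # row-major: column index varies fastest
  dim(out) <- c(d[1], d[2] * d[3])
  out
}

#' Sample a random mask plan over montage patches
#'
#' Masks `floor(n * ratio + 0.5)` patches (round half up), drawn uniformly
#' without replacement; fully determined by `seed`.
#'
#' @param n_patches number of patches (default 25)
#' @param ratio mask ratio in [0, 1] (default 0.5, the best-performing ratio)
#' @param seed integer seed
#' @return object of class `mask_plan`: list with `masked` (logical vector),
#'   `indices` (0-based masked patch indices, ascending), `ratio`, `seed`
#' @export
sample_mask <- function(n_patches = 25L, ratio = 0.5, seed = 1L) {
  if (ratio < 0 || ratio > 1) stop("ratio must lie in [0, 1]")
  k <- floor(n_patches * ratio + 0.5)
  masked <- logical(n_patches)
  if (k > 0) {
    idx <- with_seed(seed, sample.int(n_patches, k))
    masked[idx] <- TRUE
  }
  structure(list(masked = masked, indices = sort(which(masked)) - 1L,
                 ratio = ratio, seed = as.integer(seed)),
            class = "mask_plan")
}

#' Sinusoidal position embedding
#'
#' Component `2i` (0-based even) is `sin(pos / 10000^(2i/d_model))` and
#' component `2i+1` is `cos(pos / 10000^(2i/d_model))`.
#'
#' @param pos non-negative position index (scalar or vector)
#' @param d_model even embedding width
#' @return a `d_model` vector, or a `length(pos) x d_model` matrix
#' @export
positional_embedding <- function(pos, d_model) {
  if (d_model %% 2 != 0) stop("d_model must be even")
  if (any(pos < 0)) stop("pos must be non-negative")
  i <- 0:(d_model / 2 - 1)
  freq <- 1 / 10000^(2 * i / d_model)
  ang <- outer(pos, freq)
  out <- matrix(0, length(pos), d_model)
  out[, 2 * i + 1] <- sin(ang)
  out[, 2 * i + 2] <- cos(ang)
  if (length(pos) == 1L) drop(out) else out
}

#' Embed the visible (unmasked) patches as encoder tokens
#'
#' Each visible patch is flattened row-major, linearly projected to
#' `d_model`, and summed with its sinusoidal position embedding; a learnable
#' class token (carrying no position embedding) is prepended. Masked patch
#' content never enters the result.
#'
#' @param grid array `c(25, P, P)` from [partition_patches()] (or an already
#'   flattened 25 x P^2 matrix)
#' @param plan a [sample_mask()] plan of length 25
#' @param projection list with `W` (P^2 x d_model), `b` (d_model), and
#'   `class_token` (d_model)
#' @return object of class `token_batch`: `tokens` ((n_visible + 1) x
#'   d_model matrix, class token first), `positions` (0-based visible patch
#'   indices, ascending), `d_model`
#' @export
embed_visible_tokens <- function(grid, plan, projection) {
  if (length(plan$masked) != 25L) stop("mask plan must cover 25 patches")
  X <- if (is.matrix(grid)) grid else flatten_patches(grid)
  if (ncol(X) != nrow(projection$W))
    stop("projection width does not match flattened patch size")
  d_model <- ncol(projection$W)
  vis <- which(!plan$masked) # 1-based
  tok <- X[vis, , drop = FALSE] %*% projection$W
  tok <- sweep(tok, 2, projection$b, "+")
  tok <- tok + positional_embedding(vis - 1, d_model)
  tokens <- rbind(matrix(projection$class_token, 1, d_model), tok)
  structure(list(tokens = tokens, positions = vis - 1L, d_model = d_model),
            class = "token_batch")
}
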