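# The hybrid objective: queue-backed InfoNCE, masked-pixel MSE, and their
# convex combination.

#' Create an empty FIFO key queue
#'
#' The contrastive dictionary: a first-in-first-out bank of L2-normalised
#' key vectors. After warm-up it holds exactly `capacity` entries.
#'
#' @param capacity maximum number of keys (default 700)
#' @param dim key dimensionality (default 128)
#' @export
new_queue <- function(capacity = 700L, dim = 128L) {
  structure(list(capacity = as.integer(capacity), dim = as.integer(dim),
                 keys = matrix(numeric(0), 0, dim)),
            class = "key_queue")
}

#' @export
print.key_queue <- function(x, ...) {
  cat(sprintf("<key_queue> %d / %d keys of dim %d\n",
              nrow(x$keys), x$capacity, x$dim))
  invisible(x)
}

#' Enqueue a batch of keys, dequeuing the oldest on overflow
#'
#' Keys are appended in order; if the queue would exceed its capacity the
#' oldest entries are dropped, so the newest key is always at the tail.
#'
#' @param queue a [new_queue()]
#' @param new_keys numeric matrix (n x dim) or a single key vector
#' @export
update_queue <- function(queue, new_keys) {
  if (is.null(dim(new_keys))) new_keys <- matrix(new_keys, 1)
  if (ncol(new_keys) != queue$dim)
    stop("key dimensionality does not match the queue")
  keys <- rbind(queue$keys, new_keys)
  if (nrow(keys) > queue$capacity)
    keys <- keys[(nrow(keys) - queue$capacity + 1):nrow(keys), , drop = FALSE]
  queue$keys <- keys
  queue
}

#' InfoNCE contrastive loss against the queue
#'
#' `L = -log( exp(q.k+ / tau) / (exp(q.k+ / tau) + sum_i exp(q.k_i / tau)) )`
#' where the sum runs over the (negative) keys currently in the queue; the
#' positive term appears exactly once in the denominator. With an empty
#' queue the loss is 0.
#'
#' @param q_plus query vector
#' @param k_plus_pos positive key vector
#' @param queue a [new_queue()] holding the negative keys
#' @param tau temperature (> 0, default 0.07)
#' @export
infonce_loss <- function(q_plus, k_plus_pos, queue, tau = 0.07) {
  if (tau <= 0) stop("tau must be positive")
  if (length(q_plus) != length(k_plus_pos))
    stop("q and k dimensions disagree")
  pos <- sum(q_plus * k_plus_pos) / tau
  if (nrow(queue$keys) == 0) return(0)
  neg <- drop(queue$keys %*% q_plus) / tau
  -(pos - logsumexp(c(pos, neg)))
}

#' Mean squared error over masked pixels
#'
#' `L = (1/N) * sum_i (x_i - xhat_i)^2` with `N` the number of masked
#' pixels; defined as 0 when nothing is masked.
#'
#' @param predicted,target numeric vectors/matrices of equal length (the
#'   masked-pixel predictions and ground truth)
#' @export
masked_mse_loss <- function(predicted, target) {
  if (length(predicted) != length(target))
    stop("predicted and target lengths differ")
  if (length(predicted) == 0) return(0)
  mean((predicted - target)^2)
}

#' Convex combination of the reconstruction and contrastive losses
#'
#' `L = lambda * L_MSE + (1 - lambda) * L_InfoNCE`. `lambda = 1` is the pure
#' generative (masked-autoencoder) objective; `lambda = 0` the pure
#' contrastive one.
#'
#' @param l_mse,l_infonce component losses
#' @param lam combination coefficient in [0, 1]
#' @export
total_loss <- function(l_mse, l_infonce, lam = 0.5) {
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  lam * l_mse + (1 - lam) * l_infonce
}

# batched InfoNCE with gradient wrt q only (keys are detached):
# Q, K are B x dim (rows unit-norm); returns mean loss and dQ
infonce_batch <- function(Q, K, queue, tau) {
  B <- nrow(Q)
  nneg <- nrow(queue$keys)
  losses <- numeric(B)
  dQ <- matrix(0, B, ncol(Q))
  Kq <- queue$keys
  negs <- if (nneg > 0) Q %*% t(Kq) / tau else matrix(numeric(0), B, 0)
  pos <- rowSums(Q * K) / tau
  for (b in seq_len(B)) {
    logits <- c(pos[b], if (nneg > 0) negs[b, ] else numeric(0))
    lse <- logsumexp(logits)
    losses[b] <- -(logits[1] - lse)
    p <- exp(logits - lse)
    gk <- (p[1] - 1) * K[b, ]
    if (nneg > 0) gk <- gk + drop(crossprod(Kq, p[-1]))
    dQ[b, ] <- gk / tau
  }
  list(loss = mean(losses), dQ = dQ / B)
}
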