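# AdamW with decoupled weight decay over nested parameter trees, plus the
# step-wise multi-milestone learning-rate schedule.

adamw_init <- function(params) {
  list(m = par_zeros_like(params), v = par_zeros_like(params), t = 0L)
}

# One decoupled-weight-decay Adam step. Weight decay is applied to weight
# matrices only (vectors: biases, layer-norm gains, tokens are exempt).
adamw_step <- function(params, grads, state, lr, betas = c(0.9, 0.95),
                       eps = 1e-8, weight_decay = 0.05) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (is.matrix(p) && weight_decay > 0) upd <- upd + weight_decay * p
    list(p = p - lr * upd, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

#' Milestone learning-rate schedule
#'
#' The base rate is multiplied by `factor` at each milestone. Milestones are
#' given as fractions of the total epoch budget (so the reference protocol's
#' shape is preserved at any budget); raw epoch numbers > 1 are also
#' accepted.
#'
#' @param epoch current epoch (1-based)
#' @param base_lr initial learning rate
#' @param milestones numeric vector: fractions in (0, 1] or raw epochs
#' @param total_epochs total epochs configured
#' @param factor multiplicative drop (default 0.1)
#' @export
lr_at_epoch <- function(epoch, base_lr, milestones, total_epochs,
                        factor = 0.1) {
  ms <- ifelse(milestones <= 1, round(milestones * total_epochs), milestones)
  base_lr * factor^sum(epoch > ms)
}
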