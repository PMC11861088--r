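#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' perturb the caller's random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-case seed from a master seed
#'
#' Deterministic integer mixing; result is always in [1, 2^31 - 2] so it is a
#' valid R seed. Distinct indices give distinct seeds for any master seed.
#' @param master integer master seed
#' @param index case index (1-based)
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m) + 1
  x <- (x * 48271) %% m         # minimal-standard LCG step on the master
  x <- (x + as.numeric(index) * 2654435761) %% m  # Knuth multiplicative hash
  x <- (x * 48271) %% m
  as.integer(x %% (m - 1) + 1)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Rotate a matrix by k quarter turns (counter-clockwise)
#' @keywords internal
rot90_mat <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

#' Mirror a matrix left-right (horizontal flip)
#' @keywords internal
flip_h_mat <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
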