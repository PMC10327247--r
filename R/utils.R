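# Small numerical helpers shared across the package.

#' Numerically stable log-sum-exp over the rows of a matrix
#'
#' @param m numeric matrix.
#' @return numeric vector, one entry per row.
#' @keywords internal
row_logsumexp <- function(m) {
  matrixStats::rowLogSumExps(m)
}

#' Row-wise softmax
#' @keywords internal
#' @noRd
row_softmax <- function(m) {
  e <- exp(m - matrixStats::rowMaxs(m))
  e / rowSums(e)
}

#' @noRd
softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' @noRd
softplus_inv <- function(y) log(expm1(y))

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Centered moving average of a series
#'
#' Window-`w` trailing moving average; the output has length
#' `length(x) - w + 1`.
#'
#' @param x numeric vector.
#' @param w window length, `1 <= w <= length(x)`.
#' @export
moving_average <- function(x, w = 10L) {
  w <- as.integer(w)
  if (w < 1L || w > length(x)) {
    stop("window `w` must lie in [1, length(x)]", call. = FALSE)
  }
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):(length(x) + 1L)] - cs[1L:(length(x) - w + 1L)]) / w
}

# ---- Adam over a nested list of numeric arrays --------------------------

#' @noRd
adam_init <- function(params) {
  zero <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zero, v = zero, t = 0L)
}

#' One Adam update over a nested parameter list
#'
#' `params` and `grads` must share the same nesting structure.
#' @noRd
adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.99,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      walk(p, g, m, v)
    }
  }
  out <- rec(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

#' @noRd
check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}
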