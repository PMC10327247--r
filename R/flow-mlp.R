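# Residual MLP conditioner mapping a context row (theta, xi) to the raw
# spline parameters of one bijector layer.  Plain matrix algebra with a
# hand-written backward pass; caches are kept per forward call.

#' @noRd
mlp_init <- function(ctx_dim, width, n_blocks, out_dim, out_bias) {
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  blocks <- lapply(seq_len(n_blocks), function(r) {
    list(W1 = he(width, width), b1 = rep(0, width),
         W2 = he(width, width), b2 = rep(0, width))
  })
  list(W_in = he(ctx_dim, width), b_in = rep(0, width),
       blocks = blocks,
       # zero head => every spline starts as the identity transform
       W_out = matrix(0, width, out_dim), b_out = out_bias)
}

#' @noRd
addb <- function(M, b) M + rep(b, each = nrow(M))

#' @noRd
mlp_forward <- function(par, C) {
  h <- addb(C %*% par$W_in, par$b_in)
  blocks_cache <- vector("list", length(par$blocks))
  for (r in seq_along(par$blocks)) {
    bl <- par$blocks[[r]]
    a <- relu(h)
    v <- addb(a %*% bl$W1, bl$b1)
    vr <- relu(v)
    h_new <- h + addb(vr %*% bl$W2, bl$b2)
    blocks_cache[[r]] <- list(h_in = h, a = a, v = v, vr = vr)
    h <- h_new
  }
  af <- relu(h)
  raw <- addb(af %*% par$W_out, par$b_out)
  list(raw = raw, cache = list(C = C, blocks = blocks_cache, h = h, af = af))
}

# Backward pass: upstream gradient G on `raw` -> parameter gradients and
# the gradient on the context rows.
#' @noRd
mlp_backward <- function(par, cache, G) {
  gW_out <- crossprod(cache$af, G)
  gb_out <- colSums(G)
  g_h <- (G %*% t(par$W_out)) * (cache$h > 0)
  g_blocks <- vector("list", length(par$blocks))
  for (r in rev(seq_along(par$blocks))) {
    bl <- par$blocks[[r]]
    bc <- cache$blocks[[r]]
    g_vr <- g_h %*% t(bl$W2)
    gW2 <- crossprod(bc$vr, g_h)
    gb2 <- colSums(g_h)
    g_v <- g_vr * (bc$v > 0)
    g_a <- g_v %*% t(bl$W1)
    gW1 <- crossprod(bc$a, g_v)
    gb1 <- colSums(g_v)
    g_h <- g_h + g_a * (bc$h_in > 0)
    g_blocks[[r]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  gW_in <- crossprod(cache$C, g_h)
  gb_in <- colSums(g_h)
  g_C <- g_h %*% t(par$W_in)
  list(grads = list(W_in = gW_in, b_in = gb_in, blocks = g_blocks,
                    W_out = gW_out, b_out = gb_out),
       g_C = g_C)
}
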