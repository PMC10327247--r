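# Amortized conditional density estimator p_phi(y | theta, xi): a
# conditional neural spline flow over scalar response coordinates.
#
# In the default factorized mode a single 1-D flow models y_i given the
# context (theta, xi_i) and the D coordinates are summed, matching
# simulators whose responses are conditionally independent across design
# coordinates.  A joint autoregressive mode conditions coordinate i on
# (theta, xi, y_{<i}) for simulators that do not factorize; both modes
# coincide exactly at D = 1.
#
# All densities are reported in ORIGINAL units; standardization of y and
# of the context is part of the model (change-of-variables included).

#' Construct a conditional normalizing-flow density estimator
#'
#' @param theta_dim number of simulator parameters entering the context.
#' @param design_dim number of design coordinates D (fixed only in joint
#'   mode; the factorized flow is amortized over coordinates and works for
#'   any D).
#' @param factorized model `y_i | theta, xi_i` independently (default) or
#'   jointly/autoregressively.
#' @param n_layers number of spline bijector layers.
#' @param n_bins spline bins per layer.
#' @param n_blocks residual blocks in each conditioner network.
#' @param width hidden width of the conditioner networks.
#' @param tail_bound spline support half-width in standardized units;
#'   the transform is the identity outside `[-tail_bound, tail_bound]`.
#' @return an object of class `lfpce_flow`.
#' @export
conditional_flow <- function(theta_dim, design_dim = 1L, factorized = TRUE,
                             n_layers = 5L, n_bins = 4L, n_blocks = 4L,
                             width = 128L, tail_bound = 10) {
  stopifnot(n_layers >= 1L, n_bins >= 2L, n_blocks >= 0L, width >= 1L,
            tail_bound > 0)
  ctx_dim <- if (factorized) theta_dim + 1L
  else theta_dim + design_dim + (design_dim - 1L)
  out_dim <- rqs_param_count(n_bins)
  bias <- rqs_identity_bias(n_bins)
  params <- lapply(seq_len(n_layers), function(t) {
    mlp_init(ctx_dim, width, n_blocks, out_dim, bias)
  })
  structure(list(
    arch = list(n_layers = n_layers, n_bins = n_bins, n_blocks = n_blocks,
                width = width, tail_bound = tail_bound,
                factorized = factorized),
    theta_dim = theta_dim, design_dim = design_dim, ctx_dim = ctx_dim,
    params = params,
    std = list(y_shift = 0, y_scale = 1,
               theta_shift = rep(0, theta_dim),
               theta_scale = rep(1, theta_dim),
               xi_shift = 0, xi_scale = 1)
  ), class = "lfpce_flow")
}

#' @export
print.lfpce_flow <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<conditional spline flow: %d layers x %d bins, %d x %d conditioners, %s>\n",
    a$n_layers, a$n_bins, a$n_blocks, a$width,
    if (a$factorized) "factorized" else "joint (autoregressive)"))
  cat(sprintf("  context dim %d, ~%d weights\n", x$ctx_dim,
              flow_n_weights(x)))
  invisible(x)
}

#' Total number of learnable weights in the flow
#' @export
flow_n_weights <- function(flow) {
  sum(rapply(flow$params, length, how = "unlist"))
}

#' Freeze standardization statistics from a calibration set
#'
#' Fixes the affine standardization of responses and contexts from a
#' warm-up sample; densities remain exact in original units through the
#' change-of-variables term.  Responses are scaled by their 99.9% absolute
#' range so that the calibration data fills ~90% of the spline support
#' `[-tail_bound, tail_bound]`: scaling by the marginal standard deviation
#' instead would park all the mass in the middle bins and waste most of
#' the spline's resolution on empty space, visibly blurring sharp
#' conditionals.
#'
#' @param flow an `lfpce_flow`.
#' @param y response matrix from calibration simulations.
#' @param theta parameter draws used for calibration.
#' @param xi_values numeric vector/matrix of design values spanning the
#'   design box.
#' @export
fit_standardizer <- function(flow, y, theta, xi_values) {
  guard <- function(s) {
    s[!is.finite(s)] <- 1  # degenerate calibration set (e.g. one row)
    pmax(s, 1e-8)
  }
  y_shift <- mean(y)
  y_range <- stats::quantile(abs(as.vector(y) - y_shift), 0.999,
                             names = FALSE)
  flow$std <- list(
    y_shift = y_shift,
    y_scale = guard(y_range / (0.9 * flow$arch$tail_bound)),
    theta_shift = colMeans(as.matrix(theta)),
    theta_scale = guard(apply(as.matrix(theta), 2L, stats::sd)),
    xi_shift = mean(xi_values),
    xi_scale = guard(stats::sd(as.vector(xi_values))))
  flow
}

#' @noRd
std_theta <- function(flow, theta) {
  sweep(sweep(as.matrix(theta), 2L, flow$std$theta_shift, `-`),
        2L, flow$std$theta_scale, `/`)
}

#' @noRd
std_xi <- function(flow, xiv) (xiv - flow$std$xi_shift) / flow$std$xi_scale

#' @noRd
std_y <- function(flow, y) (y - flow$std$y_shift) / flow$std$y_scale

# ---- core engine (standardized space) -----------------------------------

#' @noRd
group_rowsum <- function(M, idx, U) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  r <- rowsum(M, group = idx)
  out <- matrix(0, U, ncol(M))
  out[as.integer(rownames(r)), ] <- r
  out
}

# Forward: scalar inputs x (one per row), shared context rows C with a
# row -> context index map.  Returns standardized-space log density.
#' @noRd
flow_core_forward <- function(flow, x, C, idx, mlp_pre = NULL) {
  K <- flow$arch$n_bins; B <- flow$arch$tail_bound
  nl <- flow$arch$n_layers
  sp_caches <- vector("list", nl)
  mlp <- vector("list", nl)
  ld <- numeric(length(x))
  for (t in seq_len(nl)) {
    mf <- if (is.null(mlp_pre)) mlp_forward(flow$params[[t]], C)
    else mlp_pre[[t]]
    raw <- mf$raw[idx, , drop = FALSE]
    sf <- rqs_forward(x, raw, K, B)
    x <- sf$y
    ld <- ld + sf$logdet
    sp_caches[[t]] <- sf$cache
    mlp[[t]] <- mf
  }
  list(z = x, logp = stats::dnorm(x, log = TRUE) + ld,
       sp_caches = sp_caches, mlp = mlp,
       idx = idx, U = nrow(C))
}

# Backward: per-row outer weights gw on the standardized log density.
# Returns flow-weight gradients, context-row gradients and the gradient
# on the scalar inputs.
#' @noRd
flow_core_backward <- function(flow, fwd, gw) {
  nl <- flow$arch$n_layers
  g_x <- gw * (-fwd$z)
  G_C <- 0
  param_grads <- vector("list", nl)
  for (t in rev(seq_len(nl))) {
    spb <- rqs_backward(fwd$sp_caches[[t]], g_y = g_x, g_ld = gw)
    G_raw_u <- group_rowsum(spb$G_raw, fwd$idx, fwd$U)
    mb <- mlp_backward(flow$params[[t]], fwd$mlp[[t]]$cache, G_raw_u)
    param_grads[[t]] <- mb$grads
    G_C <- G_C + mb$g_C
    g_x <- spb$g_x
  }
  list(param_grads = param_grads, G_C = G_C, g_x = g_x)
}

# Build the context matrix for a batch of (theta row, xi coordinate)
# pairs.  `y_prev` (standardized responses) is needed in joint mode only.
#' @noRd
flow_build_ctx <- function(flow, theta_rows, xiv, y_prev_std = NULL) {
  Tn <- nrow(theta_rows); D <- length(xiv)
  th_std <- std_theta(flow, theta_rows)
  xi_std <- std_xi(flow, xiv)
  if (flow$arch$factorized) {
    C <- cbind(th_std[rep(seq_len(Tn), each = D), , drop = FALSE],
               rep(xi_std, Tn))
  } else {
    if (D != flow$design_dim) {
      stop("joint-mode flow was built for a different design dimension",
           call. = FALSE)
    }
    hist_dim <- D - 1L
    Cth <- th_std[rep(seq_len(Tn), each = D), , drop = FALSE]
    Cxi <- matrix(rep(xi_std, each = Tn * D), Tn * D, D)
    H <- matrix(0, Tn * D, hist_dim)
    if (hist_dim > 0L) {
      for (i in 2:D) {
        rows <- seq(i, Tn * D, by = D)
        H[rows, 1:(i - 1L)] <- y_prev_std[, 1:(i - 1L), drop = FALSE]
      }
    }
    C <- cbind(Cth, Cxi, H)
  }
  C
}

# ---- public density interface -------------------------------------------

#' Exact conditional log-density of responses
#'
#' Log-density of each response row under its parameter row at design
#' `xi`, in original units.  One of `y`, `theta` may have a single row,
#' in which case it is broadcast.
#'
#' @param flow an `lfpce_flow`.
#' @param y `n x D` response matrix (or a length-D vector).
#' @param theta `n x p` parameter matrix (or a length-p vector).
#' @param xi design vector.
#' @return numeric vector of log-densities.
#' @export
flow_log_prob <- function(flow, y, theta, xi) {
  pe <- flow_pair_eval(flow, y, theta, xi)
  pe$logp
}

#' Log-density with analytic gradients
#'
#' As [flow_log_prob()], additionally returning the gradients of
#' `sum(weights * log p)` with respect to the flow weights, the parameter
#' rows, the design coordinates and the responses.  This is the gradient
#' oracle used by the joint training loop and by the finite-difference
#' contract tests.
#'
#' @inheritParams flow_log_prob
#' @param weights per-row outer weights (default all 1).
#' @return list with `logp`, `g_theta` (`n x p`), `g_xi` (length D),
#'   `g_y` (`n x D`) and `param_grads` (nested list matching
#'   `flow$params`).
#' @export
flow_log_prob_grad <- function(flow, y, theta, xi, weights = NULL) {
  pe <- flow_pair_eval(flow, y, theta, xi)
  n <- length(pe$logp); D <- pe$D
  if (is.null(weights)) weights <- rep(1, n)
  gw <- rep(weights, each = D)
  bk <- flow_core_backward(flow, pe$fwd, gw)
  grads <- flow_ctx_grads(flow, bk, pe, weights)
  c(list(logp = pe$logp, param_grads = bk$param_grads), grads)
}

# Shared evaluation for diagonal (row-wise) pairing of y and theta.
#' @noRd
flow_pair_eval <- function(flow, y, theta, xi) {
  xi <- as_design(xi)
  xiv <- xi$values
  D <- length(xiv)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  y <- as.matrix(y)
  if (ncol(y) != D) stop("`y` must have D columns", call. = FALSE)
  theta <- as_param_matrix(theta, flow$theta_dim)
  n <- max(nrow(y), nrow(theta))
  if (nrow(y) == 1L && n > 1L) y <- y[rep(1L, n), , drop = FALSE]
  if (nrow(theta) == 1L && n > 1L) theta <- theta[rep(1L, n), , drop = FALSE]
  if (nrow(y) != nrow(theta)) {
    stop("batch sizes of `y` and `theta` do not conform", call. = FALSE)
  }
  if (!all(is.finite(y)) || !all(is.finite(theta))) {
    stop("non-finite inputs to the density estimator", call. = FALSE)
  }
  y_std <- std_y(flow, y)
  C <- flow_build_ctx(flow, theta, xiv, y_prev_std = y_std)
  x <- as.vector(t(y_std))          # row (n, i) at position (n-1)*D + i
  idx <- seq_along(x)               # one context per row
  fwd <- flow_core_forward(flow, x, C, idx)
  logp_rows <- fwd$logp - log(flow$std$y_scale)
  logp <- unname(rowsum(logp_rows, rep(seq_len(n), each = D))[, 1L])
  list(logp = logp, fwd = fwd, n = n, D = D, y_std = y_std)
}

# Map context-row gradients back to (theta, xi, y) in original units.
#' @noRd
flow_ctx_grads <- function(flow, bk, pe, weights) {
  n <- pe$n; D <- pe$D; p <- flow$theta_dim
  G_C <- bk$G_C
  n_grp <- rep(seq_len(n), each = D)
  i_grp <- rep(seq_len(D), n)
  g_theta <- rowsum(G_C[, 1:p, drop = FALSE], n_grp)
  g_theta <- unname(sweep(g_theta, 2L, flow$std$theta_scale, `/`))
  if (flow$arch$factorized) {
    g_xi <- unname(rowsum(G_C[, p + 1L], i_grp)[, 1L]) / flow$std$xi_scale
  } else {
    cols <- (p + 1L):(p + D)
    g_xi <- colSums(G_C[, cols, drop = FALSE]) / flow$std$xi_scale
  }
  g_y <- matrix(bk$g_x, n, D, byrow = TRUE) / flow$std$y_scale
  if (!flow$arch$factorized && D > 1L) {
    # responses also enter later coordinates' contexts
    hist_cols <- (p + D + 1L):(p + 2L * D - 1L)
    GH <- G_C[, hist_cols, drop = FALSE]
    for (i in 2:D) {
      rows <- which(i_grp == i)
      g_y[, 1:(i - 1L)] <- g_y[, 1:(i - 1L)] +
        GH[rows, 1:(i - 1L), drop = FALSE] / flow$std$y_scale
    }
  }
  list(g_theta = g_theta, g_xi = g_xi, g_y = g_y)
}

# ---- contrastive evaluation (shared contexts) ---------------------------

# Log-density matrix for the contrastive bound: rows n = 1..N of y
# against column 0 (the generating theta0_n) and columns 1..L (shared
# contrastive draws).  Factorized mode shares conditioner work across the
# (theta row, coordinate) grid; this is the training hot path.
#' @noRd
flow_contrastive_eval <- function(flow, y, theta0, theta_c, xi,
                                  mlp_pre = NULL) {
  xi <- as_design(xi); xiv <- xi$values
  D <- length(xiv)
  N <- nrow(y); L <- nrow(theta_c)
  Theta <- rbind(theta0, theta_c)
  y_std <- std_y(flow, y)
  if (!flow$arch$factorized) {
    # fall back to the generic row-wise engine on the expanded pairing
    tq <- as.vector(vapply(seq_len(N), function(n) c(n, N + seq_len(L)),
                           integer(L + 1L)))
    ylong <- y_std[rep(seq_len(N), each = L + 1L), , drop = FALSE] *
      flow$std$y_scale + flow$std$y_shift
    pe <- flow_pair_eval(flow, ylong, Theta[tq, , drop = FALSE], xi)
    return(list(M = matrix(pe$logp, N, L + 1L, byrow = TRUE),
                pe = pe, mode = "joint", N = N, L = L, D = D))
  }
  C <- flow_build_ctx(flow, Theta, xiv)               # (N+L)*D contexts
  tq <- as.vector(vapply(seq_len(N), function(n) c(n, N + seq_len(L)),
                         integer(L + 1L)))            # pair -> theta row
  yt <- t(y_std)                                      # D x N
  x <- as.vector(yt[, rep(seq_len(N), each = L + 1L)])
  idx <- rep((tq - 1L) * D, each = D) + rep(seq_len(D), length(tq))
  fwd <- flow_core_forward(flow, x, C, idx, mlp_pre = mlp_pre)
  logp_rows <- fwd$logp - log(flow$std$y_scale)
  q_grp <- rep(seq_along(tq), each = D)
  M <- matrix(rowsum(logp_rows, q_grp)[, 1L], N, L + 1L, byrow = TRUE)
  list(M = M, fwd = fwd, mode = "factorized", N = N, L = L, D = D, tq = tq)
}

# Backward for the factorized contrastive evaluation.  G_M: upstream
# gradient on the N x (L+1) log-density matrix.
#' @noRd
flow_contrastive_backward <- function(flow, ce, G_M) {
  if (ce$mode != "factorized") {
    w <- as.vector(t(G_M))
    bk <- flow_core_backward(flow, ce$pe$fwd, rep(w, each = ce$D))
    grads <- flow_ctx_grads(flow, bk, ce$pe, w)
    n_grp <- rep(seq_len(ce$N), each = ce$L + 1L)
    g_y <- rowsum(grads$g_y, n_grp)
    return(list(param_grads = bk$param_grads, g_xi = grads$g_xi, g_y = g_y))
  }
  N <- ce$N; L <- ce$L; D <- ce$D; p <- flow$theta_dim
  gw <- rep(as.vector(t(G_M)), each = D)
  bk <- flow_core_backward(flow, ce$fwd, gw)
  i_grp_ctx <- rep(seq_len(D), N + L)
  g_xi <- unname(rowsum(bk$G_C[, p + 1L], i_grp_ctx)[, 1L]) /
    flow$std$xi_scale
  # response gradient: sum the L+1 pair rows that share each y_n
  q_per_row <- rep(seq_len(N * (L + 1L)), each = D)
  n_per_row <- (q_per_row - 1L) %/% (L + 1L) + 1L
  i_per_row <- rep(seq_len(D), N * (L + 1L))
  key <- (n_per_row - 1L) * D + i_per_row
  g_y_vec <- rowsum(bk$g_x, key)[, 1L] / flow$std$y_scale
  g_y <- matrix(g_y_vec, N, D, byrow = TRUE)
  list(param_grads = bk$param_grads, g_xi = g_xi, g_y = g_y)
}

# ---- sampling -----------------------------------------------------------

#' Draw responses from the flow
#'
#' `n` draws per parameter row via the inverse spline transforms; the
#' returned matrix stacks the `n` draws for `theta[1, ]`, then for
#' `theta[2, ]`, and so on.
#'
#' @inheritParams flow_log_prob
#' @param n draws per parameter row (>= 1).
#' @param path if `TRUE`, also return the information needed for pathwise
#'   design gradients of the samples (factorized mode only).
#' @return `(m*n) x D` response matrix (with attribute `"path"` when
#'   requested).
#' @export
flow_sample <- function(flow, theta, xi, n = 1L, path = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  xi <- as_design(xi); xiv <- xi$values
  D <- length(xiv)
  theta <- as_param_matrix(theta, flow$theta_dim)
  m <- nrow(theta)
  K <- flow$arch$n_bins; B <- flow$arch$tail_bound
  nl <- flow$arch$n_layers
  if (!flow$arch$factorized) {
    return(flow_sample_joint(flow, theta, xiv, n))
  }
  C <- flow_build_ctx(flow, theta, xiv)     # m*D contexts
  idx <- (rep(seq_len(m), each = n * D) - 1L) * D +
    rep(rep(seq_len(D), times = n), m)
  nrows <- m * n * D
  x <- stats::rnorm(nrows)
  raws <- vector("list", nl)
  mlp_caches <- vector("list", nl)
  xs <- vector("list", nl)                  # x AFTER inverting layer t
  for (t in rev(seq_len(nl))) {
    mf <- mlp_forward(flow$params[[t]], C)
    inv <- rqs_inverse(x, mf$raw[idx, , drop = FALSE], K, B)
    x <- inv$x
    raws[[t]] <- inv$cache
    mlp_caches[[t]] <- mf$cache
    xs[[t]] <- x
  }
  y <- matrix(flow$std$y_shift + flow$std$y_scale * x, m * n, D,
              byrow = TRUE)
  if (path) {
    attr(y, "path") <- list(sp_caches = raws, mlp_caches = mlp_caches,
                            idx = idx, U = nrow(C), m = m, n = n, D = D)
  }
  y
}

# Pathwise vector-Jacobian product for sampled responses: given weights
# w on the (m*n) x D samples, return d sum(w * y) / d xi (and theta).
#' @noRd
flow_sample_ctx_grad <- function(flow, y, w) {
  pa <- attr(y, "path")
  if (is.null(pa)) stop("sample was not drawn with `path = TRUE`",
                        call. = FALSE)
  nl <- flow$arch$n_layers
  p <- flow$theta_dim; D <- pa$D
  w_rows <- as.vector(t(w)) * flow$std$y_scale   # per scalar row, y units
  # multiplier m_t = d y_std / d x_t = prod_{t' < t} 1/f'(x_{t'})
  G_C <- 0
  mult <- rep(1, length(w_rows))
  for (t in seq_len(nl)) {
    dydx <- rqs_dydx(pa$sp_caches[[t]])
    seed <- -w_rows * mult / dydx
    spb <- rqs_backward(pa$sp_caches[[t]], g_y = seed, g_ld = 0 * seed)
    G_raw_u <- group_rowsum(spb$G_raw, pa$idx, pa$U)
    mb <- mlp_backward(flow$params[[t]], pa$mlp_caches[[t]], G_raw_u)
    G_C <- G_C + mb$g_C
    mult <- mult / dydx
  }
  i_grp <- rep(seq_len(D), pa$U / D)
  g_xi <- unname(rowsum(G_C[, p + 1L], i_grp)[, 1L]) / flow$std$xi_scale
  m_grp <- rep(seq_len(pa$m), each = D)
  g_theta <- unname(sweep(rowsum(G_C[, 1:p, drop = FALSE], m_grp), 2L,
                          flow$std$theta_scale, `/`))
  list(g_xi = g_xi, g_theta = g_theta)
}

#' @noRd
flow_sample_joint <- function(flow, theta, xiv, n) {
  D <- length(xiv)
  m <- nrow(theta)
  K <- flow$arch$n_bins; B <- flow$arch$tail_bound
  nl <- flow$arch$n_layers
  th_rep <- theta[rep(seq_len(m), each = n), , drop = FALSE]
  y_std <- matrix(0, m * n, D)
  for (i in seq_len(D)) {
    C_full <- flow_build_ctx(flow, th_rep, xiv, y_prev_std = y_std)
    rows <- seq(i, nrow(C_full), by = D)
    C <- C_full[rows, , drop = FALSE]
    x <- stats::rnorm(m * n)
    for (t in rev(seq_len(nl))) {
      raw <- mlp_forward(flow$params[[t]], C)$raw
      x <- rqs_inverse(x, raw, K, B)$x
    }
    y_std[, i] <- x
  }
  flow$std$y_shift + flow$std$y_scale * y_std
}

# ---- maximum-likelihood fitting -----------------------------------------

#' Fit the flow by maximum likelihood on (theta, xi, y) triples
#'
#' Plain amortized neural likelihood estimation: minimize the mean
#' negative log-likelihood with Adam over minibatches.
#'
#' @param flow an `lfpce_flow`.
#' @param theta `n x p` parameter draws.
#' @param xi either one design vector shared by all rows or an `n x D`
#'   matrix giving each sample its own design values.
#' @param y `n x D` simulated responses.
#' @param steps number of Adam steps.
#' @param lr learning rate.
#' @param batch_size minibatch size (default: full batch up to 256).
#' @param standardize refit the standardizer from this dataset first.
#' @return list with the trained `flow` and the per-step `loss` trace
#'   (mean negative log-likelihood of the minibatch).
#' @export
fit_mle <- function(flow, theta, xi, y, steps = 200L, lr = 1e-3,
                    batch_size = NULL, standardize = TRUE) {
  y <- as.matrix(y)
  theta <- as_param_matrix(theta, flow$theta_dim)
  n <- nrow(y)
  if (n < 1L) stop("empty dataset", call. = FALSE)
  per_row_xi <- is.matrix(xi) && nrow(xi) == n && !inherits(xi, "lfpce_design")
  xiv_all <- if (per_row_xi) xi else
    matrix(as_design(xi)$values, n, ncol(y), byrow = TRUE)
  if (standardize) {
    flow <- fit_standardizer(flow, y, theta, xiv_all)
  }
  if (is.null(batch_size)) batch_size <- min(n, 256L)
  ad <- adam_init(flow$params)
  loss <- numeric(steps)
  lo <- min(xiv_all) - 1; hi <- max(xiv_all) + 1
  for (s in seq_len(steps)) {
    take <- if (batch_size >= n) seq_len(n) else
      sample.int(n, batch_size)
    m <- length(take)
    # per-row designs: evaluate row-wise with a design made of that row's
    # values; the factorized context only ever sees scalar xi_i, so we can
    # treat each minibatch row as its own D-coordinate design
    gr <- fit_mle_batch_grad(flow, theta[take, , drop = FALSE],
                             xiv_all[take, , drop = FALSE],
                             y[take, , drop = FALSE], lo, hi)
    loss[s] <- gr$nll
    st <- adam_step(ad, flow$params, gr$param_grads, lr)
    flow$params <- st$params
    ad <- st$state
  }
  list(flow = flow, loss = loss)
}

#' @noRd
fit_mle_batch_grad <- function(flow, theta, xim, y, lo, hi) {
  m <- nrow(y); D <- ncol(y)
  if (flow$arch$factorized) {
    # flatten (row, coordinate) pairs into a D=1 evaluation
    yy <- matrix(as.vector(t(y)), ncol = 1L)
    tt <- theta[rep(seq_len(m), each = D), , drop = FALSE]
    xiv <- as.vector(t(xim))
    y_std <- std_y(flow, yy)
    th_std <- std_theta(flow, tt)
    C <- cbind(th_std, std_xi(flow, xiv))
    fwd <- flow_core_forward(flow, as.vector(y_std), C, seq_len(m * D))
    logp <- fwd$logp - log(flow$std$y_scale)
    gw <- rep(-1 / (m * D), m * D)
    bk <- flow_core_backward(flow, fwd, gw)
    list(nll = -mean(logp), param_grads = bk$param_grads)
  } else {
    # joint mode trains against one shared design per minibatch
    gr <- flow_log_prob_grad(flow, y, theta,
                             design_vector(xim[1L, ], lo, hi),
                             weights = rep(-1 / m, m))
    list(nll = -mean(gr$logp), param_grads = gr$param_grads)
  }
}
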