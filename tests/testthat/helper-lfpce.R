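# Shared fixtures: a desk-scale flow (small conditioners, same bijector
# structure) and a perturbed copy whose splines are non-trivial.

small_flow <- function(theta_dim = 2L, design_dim = 1L, factorized = TRUE,
                       n_layers = 3L, width = 16L, n_blocks = 2L) {
  conditional_flow(theta_dim = theta_dim, design_dim = design_dim,
                   factorized = factorized, n_layers = n_layers,
                   n_bins = 4L, n_blocks = n_blocks, width = width)
}

# random non-identity weights plus a plausible standardizer
perturbed_flow <- function(seed = 1, ...) {
  set.seed(seed)
  fl <- small_flow(...)
  fl$params <- rapply(fl$params, function(w) w + stats::rnorm(length(w),
                                                              sd = 0.1),
                      how = "replace")
  fit_standardizer(fl, matrix(rnorm(200, 1, 2)),
                   matrix(rnorm(400), 200, 2), runif(200, -10, 10))
}

# central finite difference of f at x
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# conjugate posterior of the linear-Gaussian model, zero-mean normal prior
conjugate_posterior <- function(xi_values, y, prior_scale, noise_sd = 1) {
  X <- cbind(1, xi_values)
  Sp_inv <- diag(1 / prior_scale^2, 2L)
  Sigma <- solve(Sp_inv + crossprod(X) / noise_sd^2)
  mu <- Sigma %*% (crossprod(X, y) / noise_sd^2)
  list(mean = as.numeric(mu), cov = Sigma)
}
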