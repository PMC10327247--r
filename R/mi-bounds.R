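# Contrastive lower bounds on expected information gain (EIG) and the
# tractable-model oracles used to validate them.
#
# All information quantities are in nats.  The contrastive estimators
# share one piece of arithmetic: for each outer sample n, contrast the
# log-density of y_n under its generating parameter (column 0) against
# the densities under L fresh prior draws; the self term is INCLUDED in
# the denominator, which caps the bound at log(L + 1).

#' @noRd
bound_estimate <- function(value, n_outer, n_contrastive, lambda_reg = 0,
                           estimator_name = "lfpce") {
  structure(list(value = value, n_outer = n_outer,
                 n_contrastive = n_contrastive, lambda_reg = lambda_reg,
                 estimator_name = estimator_name),
            class = "lfpce_bound")
}

#' @export
print.lfpce_bound <- function(x, ...) {
  cat(sprintf("<%s bound: %.4f nats (N=%d, L=%d, ceiling log(L+1)=%.4f)>\n",
              x$estimator_name, x$value, x$n_outer, x$n_contrastive,
              log(x$n_contrastive + 1)), ...)
  invisible(x)
}

#' @noRd
contrastive_core <- function(logp0, logp_contrastive) {
  logp0 <- as.numeric(logp0)
  M <- as.matrix(logp_contrastive)
  if (nrow(M) != length(logp0)) {
    stop("`logp0` and `logp_contrastive` have mismatched outer sizes",
         call. = FALSE)
  }
  if (!all(is.finite(logp0)) || !all(is.finite(M))) {
    stop("non-finite log-densities", call. = FALSE)
  }
  full <- unname(cbind(logp0, M))
  list(logp0 = logp0, lse = row_logsumexp(full), L = ncol(M),
       N = length(logp0), full = full)
}

#' Likelihood-free prior-contrastive EIG lower bound
#'
#' `mean_n [ log p(y_n | theta0_n) - log mean_{l=0..L} p(y_n | theta_l) ]`
#' where column 0 is the self term.  With flow densities this is the
#' LF-PCE bound; with exact likelihoods it is the classic PCE bound.
#'
#' @param logp0 length-N vector: log-density of each y under its
#'   generating parameter.
#' @param logp_contrastive `N x L` matrix: log-densities under the
#'   contrastive prior draws.
#' @return an `lfpce_bound` object; its `value` never exceeds
#'   `log(L + 1)`.
#' @export
lfpce_bound <- function(logp0, logp_contrastive) {
  cc <- contrastive_core(logp0, logp_contrastive)
  value <- mean(cc$logp0 - (cc$lse - log(cc$L + 1)))
  bound_estimate(value, cc$N, cc$L, estimator_name = "lfpce")
}

#' PCE bound from exact likelihoods
#'
#' Identical arithmetic to [lfpce_bound()]; the separate name records that
#' the inputs are exact (tractable-model) log-likelihoods rather than
#' flow densities.
#'
#' @inheritParams lfpce_bound
#' @export
pce_bound <- function(logp0, logp_contrastive) {
  out <- lfpce_bound(logp0, logp_contrastive)
  out$estimator_name <- "pce"
  out
}

#' Contrastive ratio-estimation loss
#'
#' The classifier-style objective `mean_n [ logp0_n - logsumexp_l ]`
#' without the `1/(L+1)` normalization; it equals the LF-PCE bound minus
#' `log(L + 1)` exactly.
#'
#' @inheritParams lfpce_bound
#' @return scalar value (<= 0 whenever the self term dominates nothing).
#' @export
cre_loss <- function(logp0, logp_contrastive) {
  cc <- contrastive_core(logp0, logp_contrastive)
  mean(cc$logp0 - cc$lse)
}

#' Regularized LF-PCE training loss
#'
#' `-( lfpce_bound + lambda * mean(logp0) )`, to be minimized.  The
#' lambda term is the per-sample maximum-likelihood regularizer that
#' stabilizes flow training while designs move.
#'
#' @inheritParams lfpce_bound
#' @param lambda_reg non-negative regularization weight.
#' @export
regularized_lfpce_loss <- function(logp0, logp_contrastive, lambda_reg = 0) {
  if (lambda_reg < 0) stop("`lambda_reg` must be >= 0", call. = FALSE)
  b <- lfpce_bound(logp0, logp_contrastive)
  -(b$value + lambda_reg * mean(logp0))
}

# Gradient of the regularized loss with respect to the N x (L+1)
# log-density matrix [logp0 | contrastive]; used by the training loop.
#' @noRd
contrastive_loss_grad <- function(logp0, logp_contrastive, lambda_reg = 0) {
  cc <- contrastive_core(logp0, logp_contrastive)
  W <- row_softmax(cc$full)            # d logsumexp / d entries
  G <- W / cc$N                        # from -lfpce: + softmax/N ...
  G[, 1L] <- G[, 1L] - (1 + lambda_reg) / cc$N
  loss <- -(mean(cc$logp0 - (cc$lse - log(cc$L + 1))) +
              lambda_reg * mean(cc$logp0))
  list(loss = loss,
       bound = mean(cc$logp0 - (cc$lse - log(cc$L + 1))),
       G = G)
}

#' Assemble one Monte-Carlo contrastive batch
#'
#' Draws N generating parameters and L shared contrastive parameters from
#' the prior and simulates one response row per generating parameter at
#' the current design.
#'
#' @param prior an [normal_prior()].
#' @param simulator an `lfpce_simulator`.
#' @param xi design vector.
#' @param N number of outer (generating) samples.
#' @param L number of contrastive samples.
#' @return list with `theta0` (`N x p`), `y` (`N x D`),
#'   `theta_contrastive` (`L x p`).
#' @export
assemble_contrastive_batch <- function(prior, simulator, xi, N = 10L,
                                       L = 50L) {
  N <- as.integer(N); L <- as.integer(L)
  if (N < 1L || L < 1L) stop("N and L must be >= 1", call. = FALSE)
  theta0 <- sample_prior(prior, N)
  y <- simulate_batch(simulator, theta0, xi)
  theta_c <- sample_prior(prior, L)
  structure(list(theta0 = theta0, y = y, theta_contrastive = theta_c),
            class = "lfpce_contrastive_batch")
}

# ---- oracles ------------------------------------------------------------

#' Closed-form EIG of the conjugate linear-Gaussian model
#'
#' For `y = theta0 + theta1 * xi + eps`, `eps ~ N(0, noise_sd^2)`, with an
#' independent normal prior on `(theta0, theta1)`, the mutual information
#' between y and theta is
#' `0.5 * log det( I_2 + noise_sd^-2 * Sigma_prior * X'X )`
#' with `X = [1, xi]` the D x 2 design matrix.
#'
#' @param xi design vector.
#' @param prior_scale length-2 vector of prior standard deviations.
#' @param noise_sd positive noise standard deviation.
#' @return EIG in nats.
#' @export
analytic_eig_gaussian <- function(xi, prior_scale, noise_sd = 1) {
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  xiv <- as_design(xi)$values
  X <- cbind(1, xiv)
  S <- diag(prior_scale^2, 2L)
  M <- diag(2L) + (S %*% crossprod(X)) / noise_sd^2
  0.5 * as.numeric(determinant(M, logarithm = TRUE)$modulus)
}

#' Nested Monte Carlo EIG estimate for tractable simulators
#'
#' Brute-force two-level estimate of the mutual information: outer draws
#' `(theta_n, y_n)` from the joint, inner marginal-likelihood averages
#' over a shared set of fresh prior draws.  Consistent as both sizes grow;
#' used only as a validation oracle.
#'
#' @param simulator an `lfpce_simulator` with a `loglik` component.
#' @param prior an [normal_prior()].
#' @param xi design vector.
#' @param n_outer,n_inner Monte-Carlo sample sizes (>= 1).
#' @return EIG estimate in nats.
#' @export
nmc_eig <- function(simulator, prior, xi, n_outer = 2000L, n_inner = 2000L) {
  if (is.null(simulator$loglik)) {
    stop("`simulator` has no tractable log-likelihood", call. = FALSE)
  }
  if (n_inner < 1L || n_outer < 1L) {
    stop("sample sizes must be >= 1", call. = FALSE)
  }
  theta0 <- sample_prior(prior, n_outer)
  y <- simulate_batch(simulator, theta0, xi)
  ll0 <- simulator$loglik(theta0, xi, y)
  theta_in <- sample_prior(prior, n_inner)
  # marginal log-likelihood of each y over the shared inner set
  Lm <- matrix(0, n_outer, n_inner)
  for (m in seq_len(n_inner)) {
    Lm[, m] <- simulator$loglik(theta_in[m, , drop = FALSE], xi, y)
  }
  log_marg <- row_logsumexp(Lm) - log(n_inner)
  mean(ll0 - log_marg)
}
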