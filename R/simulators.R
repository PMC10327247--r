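# Priors, design vectors and the reference simulators.
#
# The simulator contract is deliberately black-box: a forward map
# (parameter batch, design vector) -> response batch that consumes R's
# global RNG stream.  Determinism is obtained the base-R way, by
# `set.seed()` before the call.

#' Independent normal prior over simulator parameters
#'
#' @param mean numeric vector of component means.
#' @param scale numeric vector of positive component standard deviations.
#' @return an object of class `lfpce_prior`.
#' @examples
#' pr <- normal_prior(mean = c(0, 0), scale = c(3, 3))
#' th <- sample_prior(pr, 5)
#' log_prior(pr, th)
#' @export
normal_prior <- function(mean = c(0, 0), scale = c(3, 3)) {
  if (length(mean) != length(scale)) {
    stop("`mean` and `scale` must have the same length", call. = FALSE)
  }
  if (any(scale < 0)) stop("`scale` must be non-negative", call. = FALSE)
  structure(list(mean = as.numeric(mean), scale = as.numeric(scale),
                 dimension = length(mean)),
            class = "lfpce_prior")
}

#' Draw i.i.d. parameter vectors from a prior
#'
#' @param prior an `lfpce_prior`.
#' @param n number of draws (>= 1).
#' @return an `n x dimension` matrix.
#' @export
sample_prior <- function(prior, n) {
  stopifnot(inherits(prior, "lfpce_prior"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  p <- prior$dimension
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(sweep(z, 2L, prior$scale, `*`), 2L, prior$mean, `+`)
}

#' Prior log-density of a parameter batch
#'
#' @param prior an `lfpce_prior`.
#' @param theta matrix of parameter rows (or a single vector).
#' @return numeric vector of log-densities, one per row.
#' @export
log_prior <- function(prior, theta) {
  stopifnot(inherits(prior, "lfpce_prior"))
  theta <- as_param_matrix(theta, prior$dimension)
  lp <- 0
  for (j in seq_len(prior$dimension)) {
    lp <- lp + stats::dnorm(theta[, j], prior$mean[j], prior$scale[j],
                            log = TRUE)
  }
  lp
}

#' Gradient of the log prior density in theta
#' @keywords internal
log_prior_grad <- function(prior, theta) {
  theta <- as_param_matrix(theta, prior$dimension)
  -sweep(sweep(theta, 2L, prior$mean, `-`), 2L, prior$scale^2, `/`)
}

#' @noRd
as_param_matrix <- function(theta, p) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  theta <- as.matrix(theta)
  if (ncol(theta) != p) {
    stop(sprintf("parameter batch has %d columns, expected %d",
                 ncol(theta), p), call. = FALSE)
  }
  theta
}

# ---- design vectors -----------------------------------------------------

#' Construct a bounded design vector
#'
#' The experiment specification xi: D real measurement locations with a
#' shared box constraint.
#'
#' @param values numeric vector of length D >= 1.
#' @param lower,upper box bounds; every entry must satisfy
#'   `lower <= value <= upper`.
#' @return an object of class `lfpce_design`.
#' @export
design_vector <- function(values, lower = -10, upper = 10) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("design needs D >= 1 entries", call. = FALSE)
  if (lower >= upper) stop("`lower` must be < `upper`", call. = FALSE)
  if (any(values < lower - 1e-12) || any(values > upper + 1e-12)) {
    stop("design values outside [lower, upper]", call. = FALSE)
  }
  structure(list(values = pmin(pmax(values, lower), upper),
                 lower = lower, upper = upper),
            class = "lfpce_design")
}

#' @export
print.lfpce_design <- function(x, ...) {
  cat(sprintf("<design D=%d in [%g, %g]>\n", length(x$values),
              x$lower, x$upper))
  print(x$values)
  invisible(x)
}

#' @noRd
as_design <- function(xi, lower = -10, upper = 10) {
  if (inherits(xi, "lfpce_design")) xi else design_vector(xi, lower, upper)
}

# ---- simulator contract -------------------------------------------------

#' Wrap a forward map as a black-box simulator
#'
#' @param forward function `(theta, xi)` returning an `n x D` response
#'   matrix for an `n x p` parameter batch; it may consume the global RNG.
#' @param param_dimension number of parameter columns the map expects.
#' @param differentiable whether analytic response gradients exist
#'   (informational; the training loop never requires them).
#' @param loglik optional exact log-likelihood `(theta, xi, y) -> vector`,
#'   present only for tractable reference models.
#' @return an object of class `lfpce_simulator`.
#' @export
simulator_spec <- function(forward, param_dimension, differentiable = FALSE,
                           loglik = NULL) {
  stopifnot(is.function(forward))
  structure(list(forward = forward, param_dimension = param_dimension,
                 differentiable = differentiable, loglik = loglik),
            class = "lfpce_simulator")
}

#' @noRd
simulate_batch <- function(sim, theta, xi) {
  theta <- as_param_matrix(theta, sim$param_dimension)
  y <- sim$forward(theta, as_design(xi))
  if (nrow(y) != nrow(theta)) {
    stop("simulator returned a batch of the wrong size", call. = FALSE)
  }
  y
}

# ---- reference models ---------------------------------------------------

#' The noisy linear regression simulator
#'
#' Responses follow `y_i = theta0 + theta1 * xi_i + eps_i + nu_i` with
#' Gaussian noise `eps ~ N(0, gaussian_noise_sd^2)` and Gamma noise
#' `nu ~ Gamma(shape, rate)` (mean `shape/rate`), independently across the
#' D design coordinates.  The Gamma source makes the likelihood
#' non-Gaussian, hence intractable for conjugate analysis.
#'
#' @param gaussian_noise_sd standard deviation of the Gaussian source.
#' @param gamma_shape,gamma_rate shape/rate of the Gamma source
#'   (`Gamma(2, 2)` has mean 1, variance 0.5).
#' @param noise_free if `TRUE`, both noise sources are degenerate at zero;
#'   used to expose the deterministic core in unit tests.
#' @return an `lfpce_simulator`.
#' @export
noisy_linear_model <- function(gaussian_noise_sd = 1, gamma_shape = 2,
                               gamma_rate = 2, noise_free = FALSE) {
  if (!noise_free && gaussian_noise_sd <= 0) {
    stop("`gaussian_noise_sd` must be positive", call. = FALSE)
  }
  fwd <- function(theta, xi) {
    theta <- as_param_matrix(theta, 2L)
    xi <- as_design(xi)
    n <- nrow(theta); D <- length(xi$values)
    mu <- theta[, 1L] + outer(theta[, 2L], xi$values)
    if (noise_free) return(mu)
    eps <- matrix(stats::rnorm(n * D, sd = gaussian_noise_sd), n, D)
    nu <- matrix(stats::rgamma(n * D, shape = gamma_shape, rate = gamma_rate),
                 n, D)
    mu + eps + nu
  }
  sim <- simulator_spec(fwd, param_dimension = 2L, differentiable = FALSE)
  sim$gaussian_noise_sd <- gaussian_noise_sd
  sim$gamma_shape <- gamma_shape
  sim$gamma_rate <- gamma_rate
  sim$noise_free <- noise_free
  sim
}

#' Simulate from the noisy linear model
#'
#' Convenience wrapper around the simulator's forward map.
#'
#' @param model a simulator from [noisy_linear_model()].
#' @param theta `n x 2` matrix (offset, gradient) or a length-2 vector.
#' @param xi design vector (an [design_vector()] or plain numeric).
#' @return `n x D` response matrix.
#' @export
simulate_noisy_linear <- function(model, theta, xi) {
  simulate_batch(model, theta, xi)
}

#' Fully Gaussian linear simulator with tractable likelihood
#'
#' Same linear mean structure as [noisy_linear_model()] but purely Gaussian
#' noise, so the exact likelihood [gaussian_linear_loglik()] and the
#' analytic information gain are available.  Used throughout as the
#' validation oracle model.
#'
#' @param noise_sd positive Gaussian noise standard deviation.
#' @export
gaussian_linear_model <- function(noise_sd = 1) {
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  fwd <- function(theta, xi) {
    theta <- as_param_matrix(theta, 2L)
    xi <- as_design(xi)
    n <- nrow(theta); D <- length(xi$values)
    mu <- theta[, 1L] + outer(theta[, 2L], xi$values)
    mu + matrix(stats::rnorm(n * D, sd = noise_sd), n, D)
  }
  ll <- function(theta, xi, y) gaussian_linear_loglik(theta, xi, y, noise_sd)
  sim <- simulator_spec(fwd, param_dimension = 2L, differentiable = TRUE,
                        loglik = ll)
  sim$noise_sd <- noise_sd
  sim
}

#' Exact log-likelihood of the Gaussian linear model
#'
#' Normal log-density of each response row under mean
#' `theta0 + theta1 * xi`, summed over the D coordinates.  Either `theta`
#' or `y` may have a single row, in which case it is broadcast against the
#' other.
#'
#' @param theta `n x 2` parameter batch (or one row).
#' @param xi design vector.
#' @param y `m x D` response batch (or one row).
#' @param noise_sd positive noise standard deviation.
#' @return numeric vector of length `max(n, m)`.
#' @export
gaussian_linear_loglik <- function(theta, xi, y, noise_sd = 1) {
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  theta <- as_param_matrix(theta, 2L)
  xi <- as_design(xi)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (ncol(y) != length(xi$values)) {
    stop("`y` must have D columns matching the design", call. = FALSE)
  }
  n <- nrow(theta); m <- nrow(y)
  if (n != m) {
    if (n == 1L) theta <- theta[rep(1L, m), , drop = FALSE]
    else if (m == 1L) y <- y[rep(1L, n), , drop = FALSE]
    else stop("batch sizes of `theta` and `y` do not conform", call. = FALSE)
  }
  mu <- theta[, 1L] + outer(theta[, 2L], xi$values)
  rowSums(stats::dnorm(y, mean = mu, sd = noise_sd, log = TRUE))
}
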