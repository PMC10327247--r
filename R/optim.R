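# The joint stochastic-gradient loop: one Adam step on the flow weights
# and one on the design vector per contrastive batch, both taken from the
# same regularized LF-PCE loss.

#' Training configuration for the joint loop
#'
#' Defaults follow the reference noisy-linear study: N = 10 outer
#' samples, L = 50 contrastive samples, Adam with betas (0.9, 0.99),
#' learning rates 1e-3 (flow) and 1e-2 (designs), designs boxed in
#' [-10, 10].
#'
#' @param n_steps number of gradient steps.
#' @param n_outer N, outer Monte-Carlo samples per step.
#' @param n_contrastive L, contrastive samples per step.
#' @param lambda_reg likelihood-regularizer weight (>= 0).
#' @param flow_lr,design_lr Adam learning rates.
#' @param adam_beta1,adam_beta2 Adam moment decays, in [0, 1).
#' @param design_bounds length-2 vector (low, high), low < high.
#' @param design_gradient_mode `"flow_resample"` (default): the design
#'   gradient is taken on a batch of responses re-drawn from the flow's
#'   own reparameterizable sampler, giving a full pathwise gradient
#'   through both the sampling distribution and the conditioning inputs
#'   (flow weights are still trained on simulator responses);
#'   `"conditioning_path"`: simulator responses only, with the design
#'   gradient flowing solely through the flow's conditioning inputs —
#'   simulator-faithful but a much weaker ascent signal, since its
#'   leading term vanishes in expectation once the flow matches the
#'   likelihood.
#' @param seed integer RNG seed for the whole run.
#' @param eig_eval_contrastive contrastive count used by [evaluate_eig()].
#' @param n_calib simulations used to freeze the standardizer before
#'   training.
#' @param trace_thin keep a design snapshot every `trace_thin` steps.
#' @export
train_config <- function(n_steps = 5000L, n_outer = 10L, n_contrastive = 50L,
                         lambda_reg = 0, flow_lr = 1e-3, design_lr = 1e-2,
                         adam_beta1 = 0.9, adam_beta2 = 0.99,
                         design_bounds = c(-10, 10),
                         design_gradient_mode = c("flow_resample",
                                                  "conditioning_path"),
                         seed = 1L, eig_eval_contrastive = 500L,
                         n_calib = 2000L, trace_thin = 50L) {
  design_gradient_mode <- match.arg(design_gradient_mode)
  stopifnot(flow_lr > 0, design_lr > 0,
            adam_beta1 >= 0, adam_beta1 < 1,
            adam_beta2 >= 0, adam_beta2 < 1,
            lambda_reg >= 0, n_steps >= 1, n_outer >= 1, n_contrastive >= 1)
  if (design_bounds[1L] >= design_bounds[2L]) {
    stop("design_bounds must satisfy low < high", call. = FALSE)
  }
  structure(list(n_steps = as.integer(n_steps), n_outer = as.integer(n_outer),
                 n_contrastive = as.integer(n_contrastive),
                 lambda_reg = lambda_reg, flow_lr = flow_lr,
                 design_lr = design_lr, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, design_bounds = design_bounds,
                 design_gradient_mode = design_gradient_mode,
                 seed = as.integer(seed),
                 eig_eval_contrastive = as.integer(eig_eval_contrastive),
                 n_calib = as.integer(n_calib),
                 trace_thin = as.integer(trace_thin)),
            class = "lfpce_config")
}

#' Random design initialization
#'
#' i.i.d. uniform draws over the design box.
#'
#' @param D design dimension (>= 1).
#' @param bounds length-2 vector (low, high).
#' @return an [design_vector()].
#' @export
init_designs <- function(D, bounds = c(-10, 10)) {
  D <- as.integer(D)
  if (D < 1L) stop("`D` must be >= 1", call. = FALSE)
  if (bounds[1L] >= bounds[2L]) stop("low must be < high", call. = FALSE)
  design_vector(stats::runif(D, bounds[1L], bounds[2L]),
                bounds[1L], bounds[2L])
}

#' Jointly optimize flow weights and designs on the LF-PCE loss
#'
#' Per step: draw a contrastive batch at the current design, evaluate the
#' regularized LF-PCE loss through the flow, take one Adam step on the
#' flow weights and one on the design coordinates from the same loss, and
#' clip the design back into its box.  A step producing a non-finite loss
#' aborts the run with the offending step recorded (divergence frequency
#' is itself a quantity of interest).
#'
#' @param simulator an `lfpce_simulator`.
#' @param prior an [normal_prior()].
#' @param flow an `lfpce_flow` (its standardizer is frozen from
#'   `n_calib` calibration simulations before the first step).
#' @param config a [train_config()].
#' @param xi optional initial design; default: uniform in the box.
#' @return list with `flow`, `xi` (optimized design), `trace`
#'   (one data-frame row per completed step), `designs` (thinned design
#'   snapshots), `diverged` flag and `divergence_step`.
#' @export
train_joint <- function(simulator, prior, flow, config, xi = NULL) {
  stopifnot(inherits(config, "lfpce_config"))
  set.seed(config$seed)
  lo <- config$design_bounds[1L]; hi <- config$design_bounds[2L]
  if (is.null(xi)) {
    if (is.null(flow$design_dim)) stop("flow lacks a design dimension")
    xi <- init_designs(if (flow$arch$factorized) flow$design_dim
                       else flow$design_dim, config$design_bounds)
  }
  xi <- as_design(xi, lo, hi)
  D <- length(xi$values)

  # freeze standardization from calibration runs at random designs
  th_cal <- sample_prior(prior, config$n_calib)
  xi_cal <- matrix(stats::runif(config$n_calib * D, lo, hi),
                   config$n_calib, D)
  y_cal <- do.call(rbind, lapply(seq_len(config$n_calib), function(k) {
    simulate_batch(simulator, th_cal[k, , drop = FALSE],
                   design_vector(xi_cal[k, ], lo, hi))
  }))
  ok <- rowSums(!is.finite(y_cal)) == 0L
  if (any(ok)) {
    flow <- fit_standardizer(flow, y_cal[ok, , drop = FALSE],
                             th_cal[ok, , drop = FALSE],
                             xi_cal[ok, , drop = FALSE])
  }

  ad_flow <- adam_init(flow$params)
  ad_xi <- adam_init(list(xi = xi$values))
  xiv <- xi$values
  ns <- config$n_steps
  trace <- data.frame(step = integer(ns), bound = numeric(ns),
                      loss = numeric(ns), mean_abs_design_grad = numeric(ns),
                      lambda = config$lambda_reg, L = config$n_contrastive,
                      N = config$n_outer, D = D, seed = config$seed)
  snaps <- list()
  diverged <- FALSE; div_step <- NA_integer_

  for (s in seq_len(ns)) {
    cur_xi <- design_vector(xiv, lo, hi)
    batch <- assemble_contrastive_batch(prior, simulator, cur_xi,
                                        config$n_outer, config$n_contrastive)
    lg <- NULL
    if (all(is.finite(batch$y))) {
      ce <- flow_contrastive_eval(flow, batch$y, batch$theta0,
                                  batch$theta_contrastive, cur_xi)
      if (all(is.finite(ce$M))) {
        lg <- contrastive_loss_grad(ce$M[, 1L], ce$M[, -1L, drop = FALSE],
                                    config$lambda_reg)
      }
    }
    if (is.null(lg) || !is.finite(lg$loss)) {
      diverged <- TRUE; div_step <- s
      trace <- trace[seq_len(s - 1L), , drop = FALSE]
      warning(sprintf("non-finite loss at step %d; run aborted", s),
              call. = FALSE)
      break
    }
    bk <- flow_contrastive_backward(flow, ce, lg$G)
    g_xi <- if (config$design_gradient_mode == "flow_resample") {
      # full pathwise gradient from a flow-resampled batch replaces the
      # conditioning-only gradient of the simulator batch
      flow_resample_design_grad(flow, batch, cur_xi, config$lambda_reg,
                                mlp_pre = if (ce$mode == "factorized")
                                  ce$fwd$mlp else NULL)
    } else {
      bk$g_xi
    }

    st <- adam_step(ad_flow, flow$params, bk$param_grads, config$flow_lr,
                    config$adam_beta1, config$adam_beta2)
    flow$params <- st$params; ad_flow <- st$state
    sx <- adam_step(ad_xi, list(xi = xiv), list(xi = g_xi),
                    config$design_lr, config$adam_beta1, config$adam_beta2)
    xiv <- pmin(pmax(sx$params$xi, lo), hi)
    ad_xi <- sx$state

    trace$step[s] <- s
    trace$bound[s] <- lg$bound
    trace$loss[s] <- lg$loss
    trace$mean_abs_design_grad[s] <- mean(abs(g_xi))
    trace$lambda[s] <- config$lambda_reg
    if (s %% config$trace_thin == 0L || s == ns) {
      snaps[[length(snaps) + 1L]] <- c(step = s, xiv)
    }
  }
  designs <- if (length(snaps)) do.call(rbind, snaps) else NULL
  list(flow = flow, xi = design_vector(xiv, lo, hi), trace = trace,
       designs = designs, diverged = diverged, divergence_step = div_step,
       config = config)
}

# Pathwise design gradient: re-draw responses from the flow's own sampler
# at (theta0, xi) and differentiate the same contrastive loss through the
# sampling path as well as the conditioning inputs.
#' @noRd
flow_resample_design_grad <- function(flow, batch, xi, lambda_reg,
                                      mlp_pre = NULL) {
  yr <- flow_sample(flow, batch$theta0, xi, n = 1L, path = TRUE)
  ce <- flow_contrastive_eval(flow, yr, batch$theta0,
                              batch$theta_contrastive, xi,
                              mlp_pre = mlp_pre)
  lg <- contrastive_loss_grad(ce$M[, 1L], ce$M[, -1L, drop = FALSE],
                              lambda_reg)
  bk <- flow_contrastive_backward(flow, ce, lg$G)
  path_g <- flow_sample_ctx_grad(flow, yr, bk$g_y)
  bk$g_xi + path_g$g_xi
}

#' Fresh-sample LF-PCE evaluation of a trained flow at a fixed design
#'
#' No parameter updates: one large contrastive batch, one bound value.
#'
#' @inheritParams train_joint
#' @param xi the design at which to evaluate.
#' @param n_outer,n_contrastive evaluation Monte-Carlo sizes.
#' @return an `lfpce_bound`.
#' @export
evaluate_eig <- function(flow, simulator, prior, xi, n_outer = 100L,
                         n_contrastive = 500L) {
  batch <- assemble_contrastive_batch(prior, simulator, xi,
                                      n_outer, n_contrastive)
  ce <- flow_contrastive_eval(flow, batch$y, batch$theta0,
                              batch$theta_contrastive, as_design(xi))
  lfpce_bound(ce$M[, 1L], ce$M[, -1L, drop = FALSE])
}
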