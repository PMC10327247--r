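# Joint optimization loop: initialization, Adam, feasibility, determinism
# and qualitative design dynamics.

test_that("design initialization is uniform over the box", {
  expect_error(init_designs(0), ">= 1")
  expect_error(init_designs(2, c(3, 3)), "low")
  set.seed(1)
  d <- init_designs(1e5, c(-10, 10))
  expect_length(d$values, 1e5)
  expect_gte(min(d$values), -10)
  expect_lte(max(d$values), 10)
  expect_equal(mean(d$values), 0, tolerance = 0.1)
  set.seed(4); a <- init_designs(3)
  set.seed(4); b <- init_designs(3)
  expect_identical(a, b)
  expect_length(init_designs(1)$values, 1L)
})

test_that("Adam drives a quadratic to its minimum over nested parameters", {
  params <- list(a = matrix(c(5, -3), 2, 1), b = list(c = 2))
  st <- lfpce:::adam_init(params)
  for (i in 1:2000) {
    grads <- list(a = 2 * params$a, b = list(c = 2 * params$b$c))
    out <- lfpce:::adam_step(st, params, grads, lr = 0.05)
    params <- out$params; st <- out$state
  }
  # Adam hovers near the optimum rather than converging exactly
  expect_lt(max(abs(unlist(params))), 1e-2)
})

test_that("train_config validates its fields", {
  expect_error(train_config(flow_lr = 0), "flow_lr")
  expect_error(train_config(adam_beta1 = 1), "adam_beta1")
  expect_error(train_config(design_bounds = c(2, -2)), "low < high")
  expect_error(train_config(lambda_reg = -1), "lambda_reg")
  cfg <- train_config()
  expect_equal(cfg$n_outer, 10L)
  expect_equal(cfg$n_contrastive, 50L)
  expect_equal(cfg$design_gradient_mode, "flow_resample")
})

test_that("training keeps designs feasible, is deterministic and bookkeeps", {
  prior <- normal_prior(c(0, 0), c(3, 3))
  sim <- noisy_linear_model()
  run <- function() {
    set.seed(99)  # identical weight init; train_joint seeds the rest
    fl <- small_flow(design_dim = 2L)
    train_joint(sim, prior, fl,
                train_config(n_steps = 40L, seed = 123L, n_calib = 200L,
                             trace_thin = 10L))
  }
  out <- run()
  expect_equal(nrow(out$trace), 40L)
  expect_false(out$diverged)
  # feasibility after every snapshot
  expect_true(all(out$designs[, -1] >= -10 & out$designs[, -1] <= 10))
  expect_true(all(out$xi$values >= -10 & out$xi$values <= 10))
  # bitwise determinism under the same config and seed
  out2 <- run()
  expect_identical(out$trace, out2$trace)
  expect_identical(out$xi$values, out2$xi$values)
  # bound respects the ceiling at every step
  expect_true(all(out$trace$bound <= log(51)))
})

test_that("both design-gradient modes run and agree on bookkeeping", {
  prior <- normal_prior(c(0, 0), c(3, 3))
  sim <- noisy_linear_model()
  for (mode in c("conditioning_path", "flow_resample")) {
    fl <- small_flow(design_dim = 1L)
    out <- train_joint(sim, prior, fl,
                       train_config(n_steps = 15L, seed = 5L,
                                    n_calib = 100L,
                                    design_gradient_mode = mode))
    expect_equal(nrow(out$trace), 15L)
    expect_true(all(is.finite(out$trace$mean_abs_design_grad)))
  }
})

test_that("designs drift under slope-certain vs offset-certain priors as the
           analytic EIG dictates", {
  sim <- gaussian_linear_model(noise_sd = 1)
  run_drift <- function(prior_scale, seed) {
    prior <- normal_prior(c(0, 0), prior_scale)
    set.seed(seed)
    fl <- small_flow(design_dim = 2L, width = 32L)
    xi0 <- c(-2, 3)
    out <- train_joint(sim, prior, fl,
                       train_config(n_steps = 600L, seed = seed,
                                    n_calib = 400L),
                       xi = design_vector(xi0))
    out$xi$values
  }
  # offset-certain: EIG increases in |xi| -> clear outward drift
  xi_offset_certain <- run_drift(c(1e-3, 3), seed = 31)
  expect_gt(mean(abs(xi_offset_certain)) - 2.5, 0.5)
  # slope-certain: EIG constant in xi -> designs stay interior, no
  # systematic pull to the boundary (only optimizer noise)
  xi_slope_certain <- run_drift(c(3, 1e-3), seed = 31)
  expect_lt(max(abs(xi_slope_certain)), 9)
})

test_that("evaluate_eig respects the ceiling and is seed-stable", {
  prior <- normal_prior(c(0, 0), c(3, 3))
  sim <- gaussian_linear_model(noise_sd = 1)
  fl <- perturbed_flow(seed = 17)
  xi <- design_vector(2)
  set.seed(1)
  e1 <- evaluate_eig(fl, sim, prior, xi, n_outer = 200, n_contrastive = 100)
  expect_lte(e1$value, log(101))
  set.seed(2)
  e2 <- evaluate_eig(fl, sim, prior, xi, n_outer = 200, n_contrastive = 100)
  # two fresh evaluations agree within loose Monte-Carlo slack
  expect_equal(e1$value, e2$value, tolerance = 0.5)
  set.seed(3); a <- evaluate_eig(fl, sim, prior, xi, 50, 50)
  set.seed(3); b <- evaluate_eig(fl, sim, prior, xi, 50, 50)
  expect_identical(a$value, b$value)
})
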