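# Contrastive bound arithmetic, exact identities and the tractable-model
# oracles.

test_that("contrastive bound arithmetic matches hand computation", {
  # N=1, L=1, p0=0.5, p1=0.25: denominator mean (0.5+0.25)/2=0.375
  b <- lfpce_bound(log(0.5), matrix(log(0.25), 1, 1))
  expect_equal(b$value, log(0.5 / 0.375))
  expect_equal(b$value, log(4 / 3))

  # all densities equal -> bound is exactly zero
  expect_equal(lfpce_bound(rep(-3.2, 5), matrix(-3.2, 5, 7))$value, 0)
  # ... and cre is exactly -log(L+1)
  expect_equal(cre_loss(rep(-3.2, 5), matrix(-3.2, 5, 7)), -log(8))

  # pce is the same arithmetic under a different provenance label
  set.seed(1)
  l0 <- rnorm(6); M <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(pce_bound(l0, M)$value, lfpce_bound(l0, M)$value)

  expect_error(lfpce_bound(rnorm(3), matrix(0, 4, 2)), "mismatch")
  expect_error(lfpce_bound(c(1, NA), matrix(0, 2, 2)), "non-finite")
})

test_that("exact identities and the log(L+1) ceiling hold on random inputs", {
  set.seed(99)
  for (rep in 1:20) {
    N <- sample(1:20, 1); L <- sample(1:30, 1)
    l0 <- rnorm(N, sd = 10)
    M <- matrix(rnorm(N * L, sd = 10), N, L)
    lf <- lfpce_bound(l0, M)$value
    # algebraic identity lfpce = cre + log(L+1)
    expect_equal(lf, cre_loss(l0, M) + log(L + 1), tolerance = 1e-10)
    # bias ceiling
    expect_lte(lf, log(L + 1))
    # lambda = 0 loss is exactly the negated bound
    expect_equal(regularized_lfpce_loss(l0, M, 0), -lf)
  }
  # ceiling attained when contrastive densities vanish
  expect_equal(lfpce_bound(0, matrix(-745, 1, 9))$value, log(10),
               tolerance = 1e-6)
})

test_that("the lambda regularizer enters linearly", {
  set.seed(2)
  l0 <- rnorm(8) - 5   # negative mean log-density
  M <- matrix(rnorm(8 * 5), 8, 5)
  losses <- sapply(c(0, 0.1, 1), function(lam) {
    regularized_lfpce_loss(l0, M, lam)
  })
  # d loss / d lambda = -mean(logp0) > 0 here, so strictly increasing
  expect_true(all(diff(losses) > 0))
  expect_equal(losses[2] - losses[1], -0.1 * mean(l0))
  expect_error(regularized_lfpce_loss(l0, M, -0.5), ">= 0")
})

test_that("loss gradient in the log-density matrix matches finite differences", {
  set.seed(3)
  N <- 4; L <- 6
  l0 <- rnorm(N); M <- matrix(rnorm(N * L), N, L)
  lg <- lfpce:::contrastive_loss_grad(l0, M, lambda_reg = 0.3)
  expect_equal(lg$loss, regularized_lfpce_loss(l0, M, 0.3))
  full <- cbind(l0, M)
  g_fd <- matrix(fd_grad(function(v) {
    fm <- matrix(v, N, L + 1)
    regularized_lfpce_loss(fm[, 1], fm[, -1], 0.3)
  }, as.vector(full)), N, L + 1)
  expect_equal(lg$G, g_fd, tolerance = 1e-6)
})

test_that("analytic Gaussian EIG has its closed-form values and monotonicity", {
  # no prior uncertainty, no information
  expect_equal(analytic_eig_gaussian(design_vector(3), c(0, 0), 1), 0)
  # D=1, xi=0, prior N(0,9) on both: only the offset is informed
  expect_equal(analytic_eig_gaussian(design_vector(0), c(3, 3), 1),
               0.5 * log(10))
  # gradient-only uncertainty: nondecreasing in |xi|
  eigs <- sapply(c(0, 1, 3, 10), function(x) {
    analytic_eig_gaussian(design_vector(x), c(0, 3), 1)
  })
  expect_true(all(diff(eigs) > 0))
  # nondecreasing in each prior variance
  e1 <- analytic_eig_gaussian(design_vector(2), c(1, 1), 1)
  e2 <- analytic_eig_gaussian(design_vector(2), c(2, 1), 1)
  e3 <- analytic_eig_gaussian(design_vector(2), c(2, 3), 1)
  expect_true(e1 < e2 && e2 < e3)
})

test_that("PCE with exact likelihoods converges to the analytic EIG from below", {
  prior <- normal_prior(c(0, 0), c(3, 3))
  sim <- gaussian_linear_model(noise_sd = 1)
  xi <- design_vector(0)
  truth <- analytic_eig_gaussian(xi, c(3, 3), 1)

  # common random numbers: one outer batch, nested contrastive subsets
  set.seed(11)
  N <- 3000L; Lmax <- 256L
  th0 <- sample_prior(prior, N)
  y <- sim$forward(th0, xi)
  l0 <- sim$loglik(th0, xi, y)
  thc <- sample_prior(prior, Lmax)
  M <- vapply(seq_len(Lmax), function(l) {
    sim$loglik(thc[l, , drop = FALSE], xi, y)
  }, numeric(N))
  # at each L, average over all disjoint column blocks so the small-L
  # estimates are not dominated by the variance of a single tiny
  # contrastive set
  vals <- sapply(c(4, 16, 64, 256), function(L) {
    blocks <- split(seq_len(Lmax), rep(seq_len(Lmax / L), each = L))
    mean(vapply(blocks, function(cols) {
      pce_bound(l0, M[, cols, drop = FALSE])$value
    }, 0))
  })
  expect_true(all(diff(vals) > 0))          # tighter with more contrastive
  expect_true(all(vals < truth + 0.05))     # a lower bound (MC slack)
  expect_equal(vals[4], truth, tolerance = 0.12)
})

test_that("nested Monte Carlo agrees with the analytic oracle", {
  prior <- normal_prior(c(0, 0), c(3, 3))
  sim <- gaussian_linear_model(noise_sd = 1)
  set.seed(21)
  est <- nmc_eig(sim, prior, design_vector(0), n_outer = 3000,
                 n_inner = 3000)
  expect_equal(est, 0.5 * log(10), tolerance = 0.06)

  # monotonicity across designs under gradient-only uncertainty
  prior2 <- normal_prior(c(0, 0), c(1e-6, 3))
  sim2 <- gaussian_linear_model(noise_sd = 1)
  set.seed(22)
  lo <- nmc_eig(sim2, prior2, design_vector(0), 2000, 2000)
  hi <- nmc_eig(sim2, prior2, design_vector(10), 2000, 2000)
  expect_lt(lo, hi)

  set.seed(5); a <- nmc_eig(sim, prior, design_vector(1), 200, 200)
  set.seed(5); b <- nmc_eig(sim, prior, design_vector(1), 200, 200)
  expect_identical(a, b)
  expect_error(nmc_eig(noisy_linear_model(), prior, design_vector(1)),
               "tractable")
})

test_that("contrastive batches have the stated shapes and reproducibility", {
  prior <- normal_prior(c(0, 0), c(3, 3))
  sim <- noisy_linear_model()
  xi <- design_vector(c(-1, 2, 5))
  set.seed(31)
  b <- assemble_contrastive_batch(prior, sim, xi, N = 10, L = 50)
  expect_equal(dim(b$theta0), c(10L, 2L))
  expect_equal(dim(b$y), c(10L, 3L))
  expect_equal(dim(b$theta_contrastive), c(50L, 2L))
  set.seed(31)
  b2 <- assemble_contrastive_batch(prior, sim, xi, N = 10, L = 50)
  expect_identical(b, b2)
  expect_error(assemble_contrastive_batch(prior, sim, xi, N = 0, L = 5),
               ">= 1")

  # per-step density-evaluation count N*(L+1): the bound consumes exactly
  # one self column plus L contrastive columns
  M <- matrix(rnorm(10 * 50), 10, 50)
  expect_equal(length(rnorm(10)) * (ncol(M) + 1), 510)
})

test_that("a perfect flow makes LF-PCE coincide with exact-likelihood PCE", {
  prior <- normal_prior(c(0, 0), c(3, 3))
  sim <- gaussian_linear_model(noise_sd = 1)
  xi <- design_vector(2)
  set.seed(41)
  b <- assemble_contrastive_batch(prior, sim, xi, N = 200, L = 100)
  l0 <- sim$loglik(b$theta0, xi, b$y)
  M <- sapply(seq_len(100), function(l) {
    sim$loglik(b$theta_contrastive[l, , drop = FALSE], xi, b$y)
  })
  expect_equal(lfpce_bound(l0, M)$value, pce_bound(l0, M)$value)
  expect_lte(lfpce_bound(l0, M)$value, log(101))
})
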