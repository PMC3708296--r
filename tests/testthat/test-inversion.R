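# Variational Laplace: linear-Gaussian exactness, self-consistency,
# recovery, and the evidence matrix.

test_that("free energy matches the closed-form linear-Gaussian evidence", {
  set.seed(14)
  N <- 60; p <- 4
  G <- matrix(rnorm(N * p), N, p)
  mu0 <- rep(0, p)
  C0 <- diag(c(1, 0.5, 2, 0.25))
  lambda <- 4                       # known noise precision
  theta_true <- c(0.3, -0.7, 0.2, 0.5)
  y <- drop(G %*% theta_true) + rnorm(N, 0, 1 / sqrt(lambda))
  fit <- laplaceFit(y, function(th) drop(G %*% th), mu0, C0, lambda = lambda)
  # analytic log evidence of the linear-Gaussian model
  S_y <- diag(N) / lambda + G %*% C0 %*% t(G)
  L <- chol(S_y)
  z <- backsolve(L, y - drop(G %*% mu0), transpose = TRUE)
  logev <- -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
  expect_lt(abs(fit$F - logev), 0.1)
  # analytic posterior mean
  Sp <- solve(lambda * crossprod(G) + solve(C0))
  mp <- drop(Sp %*% (lambda * crossprod(G, y) + solve(C0) %*% mu0))
  expect_equal(fit$mean, mp, tolerance = 1e-5)
  expect_equal(fit$cov, Sp, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("the bound property holds in the linear-Gaussian surrogate", {
  set.seed(2)
  N <- 40; p <- 3
  G <- matrix(rnorm(N * p), N, p)
  y <- rnorm(N)
  lambda <- 2
  fit <- laplaceFit(y, function(th) drop(G %*% th), rep(0, p), diag(p),
                    lambda = lambda)
  loglik_at_mean <- -lambda / 2 * sum((y - G %*% fit$mean)^2) +
    N / 2 * log(lambda / (2 * pi))
  expect_lte(fit$F, loglik_at_mean)
  # complexity (KL) is nonnegative: F = accuracy - KL <= expected loglik
  d <- fit$mean
  kl <- 0.5 * (sum(diag(solve(diag(p), fit$cov))) + sum(d^2) - p -
               determinant(fit$cov)$modulus)
  expect_gte(as.numeric(kl), 0)
})

test_that("noiseless data at the prior mean keeps the posterior there", {
  m <- findModel(the_space, "sparse", "anterior")
  p <- defaultNMMParams(m)            # exactly the prior-mean parameters
  tax <- seq(-100, 400, by = 1000 / 333)
  wf <- list(standard = waveforms(integrateModel(m, p, "standard", tax)),
             deviant = waveforms(integrateModel(m, p, "deviant", tax)))
  ev <- manual_evoked(wf, tax)
  fit <- invertModel(m, ev)
  ps <- sqrt(mmnet:::.build_map(m, priorSpec())$pvar)
  expect_true(all(abs(posteriorMean(fit)) < ps))
  # free-energy trace never decreases between accepted iterations
  expect_true(all(diff(fit@Ftrace) > -0.05))
})

test_that("modulation is recovered on a noisy synthetic subject", {
  m <- findModel(the_space, "sparse", "anterior")
  cfg <- simulationConfig(model_id = modelId(m), n_subjects = 1L,
                          jitter_sd = 0, jitter_sd_mod = 0, seed = 5L)
  ev <- simulateEvoked(cfg, 1L, noise_rel = 0.1, space = the_space)
  fit <- invertModel(m, ev, n_starts = 2)
  bt <- attr(ev, "groundTruth")$params$B[m@modulationMask]   # ln 1.5
  be <- posteriorMean(fit)[grep("^B\\[", names(posteriorMean(fit)))]
  expect_true(all(abs(be - bt) < 0.5 * max(abs(bt))))
  # the modulated model must beat a no-modulation variant on these data
  cfg0 <- simulationConfig(model_id = modelId(m), b_mean = 0,
                           intrinsic_mod = 0, n_subjects = 1L,
                           jitter_sd = 0, jitter_sd_mod = 0, seed = 5L)
  fit0_ev <- ev
  # refit same data under a prior forcing no modulation via zero variance
  fit0 <- invertModel(m, fit0_ev, priors = priorSpec(mod_var = 1e-12))
  expect_gt(freeEnergy(fit), freeEnergy(fit0))
})

test_that("F is invariant to condition ordering in the container", {
  m <- findModel(the_space, "sparse", "all")
  cfg <- simulationConfig(model_id = modelId(m), n_subjects = 1L, seed = 7L)
  ev <- simulateEvoked(cfg, 1L, noise_rel = 0.1, space = the_space)
  ev2 <- methods::initialize(ev, waveforms = rev(waveforms(ev)))
  f1 <- invertModel(m, ev, max_iter = 16L)
  f2 <- invertModel(m, ev2, max_iter = 16L)
  expect_equal(freeEnergy(f1), freeEnergy(f2), tolerance = 1e-6)
})

test_that("evidence matrix is complete, deterministic, and resumable", {
  sub <- new("ModelSpace", models = models(the_space)[c(11, 12, 6)])
  cfg <- simulationConfig(model_id = 12L, n_subjects = 2L, seed = 13L)
  evs <- lapply(1:2, function(s) simulateEvoked(cfg, s, 0.1, the_space))
  E <- computeEvidenceMatrix(evs, sub, max_iter = 24L)
  expect_true(all(is.finite(evidence(E))))
  expect_equal(dim(evidence(E)), c(2L, 3L))
  # identical subjects give matching rows (start draws differ per subject,
  # so agreement is to optimiser precision, not bit-level)
  evs_same <- list(evs[[1]], evs[[1]])
  E2 <- computeEvidenceMatrix(evs_same, sub, max_iter = 24L)
  expect_equal(evidence(E2)[1, ], evidence(E2)[2, ], tolerance = 1e-5)
  # resuming reuses completed fits
  E3 <- computeEvidenceMatrix(evs, sub, max_iter = 24L, resume_from = E)
  expect_equal(evidence(E3), evidence(E), tolerance = 1e-10)
})

test_that("missing conditions and bad windows are refused", {
  tax <- seq(0, 100, by = 3)
  w <- matrix(0, 6, length(tax), dimnames = list(nodeNames(), NULL))
  ev <- manual_evoked(list(standard = w), tax)
  m <- the_space[[11]]
  expect_error(invertModel(m, ev), "deviant")
  ev2 <- manual_evoked(list(standard = w, deviant = w), tax)
  expect_error(invertModel(m, ev2, window_ms = c(300, 400)), "window")
})
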