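# Trial-level synthetic data: determinism, noise statistics, blink and
# epoch bookkeeping.

sseq <- generateSequence(small_seq_config())

test_that("without stochastic terms every epoch equals the noiseless response", {
  cfg <- simulationConfig(n_subjects = 1L, noise_sd = 0, blink_prob = 0,
                          eog_noise_uV = 0, jitter_sd = 0, jitter_sd_mod = 0,
                          seed = 8L)
  ep <- simulateSubject(sseq, cfg, 1L, the_space)
  gt <- attr(ep, "groundTruth")
  m <- the_space[[gt$model_id]]
  std <- waveforms(integrateModel(m, gt$params, "standard",
                                  timeAxis(ep), samplingRate(ep)))
  d <- epochData(ep)
  idx <- which(epochConditions(ep) == "standard")
  for (i in idx[1:3])
    expect_equal(d[i, 1:6, ], unname(std), tolerance = 1e-12)
  expect_equal(max(abs(d[idx[1], , ] - d[idx[2], , ])), 0)
  # deviant trials share one response regardless of type label
  dv <- which(epochConditions(ep) != "standard")
  expect_equal(max(abs(d[dv[1], 1:6, ] - d[dv[2], 1:6, ])), 0)
})

test_that("trial-mean error shrinks as sigma/sqrt(n)", {
  # law of large numbers at n = 400 standard epochs
  sq <- generateSequence(sequenceConfig(n_blocks = 1L,
                                        alternating_tones_per_block = 800L,
                                        lead_in_standards = 0L, seed = 4))
  sigma <- 0.5
  cfg <- simulationConfig(n_subjects = 1L, noise_sd = sigma, blink_prob = 0,
                          eog_noise_uV = 0, jitter_sd = 0, jitter_sd_mod = 0,
                          seed = 21L)
  ep <- simulateSubject(sq, cfg, 1L, the_space)
  gt <- attr(ep, "groundTruth")
  m <- the_space[[gt$model_id]]
  std <- waveforms(integrateModel(m, gt$params, "standard",
                                  timeAxis(ep), samplingRate(ep)))
  idx <- epochConditions(ep) == "standard"
  n <- sum(idx)
  expect_equal(n, 400)
  avg <- apply(epochData(ep)[idx, 1:6, ], c(2, 3), mean)
  err <- sqrt(mean((avg - std)^2))
  expect_lt(abs(err - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.2)
})

test_that("one epoch per analysed event, labels from the sequence", {
  cfg <- simulationConfig(n_subjects = 1L, seed = 2L)
  ep <- simulateSubject(sseq, cfg, 1L, the_space)
  ev <- toneEvents(sseq)
  analysed <- ev[!ev$is_lead_in, ]
  expect_equal(dim(epochData(ep))[1], nrow(analysed))
  expect_equal(epochConditions(ep), analysed$label)
  expect_equal(sum(epochConditions(ep) == "standard"),
               sum(epochConditions(ep) != "standard"))
})

test_that("cohorts are reproducible and jitter-free cohorts are homogeneous", {
  cfg <- simulationConfig(n_subjects = 3L, jitter_sd = 0, jitter_sd_mod = 0,
                          noise_sd = 0, blink_prob = 0, eog_noise_uV = 0,
                          seed = 31L)
  a <- simulateCohort(cfg, the_space, small_seq_config())
  b <- simulateCohort(cfg, the_space, small_seq_config())
  expect_identical(epochData(a$epochs[[2]]), epochData(b$epochs[[2]]))
  # no jitter, no noise: all subjects identical
  expect_equal(epochData(a$epochs[[1]]), epochData(a$epochs[[3]]))
  expect_equal(a$model_id, cfg$model_id)
  expect_length(a$truth, 3)
})

test_that("deviant equals standard exactly when the generator has no modulation", {
  cfg <- simulationConfig(b_mean = 0, intrinsic_mod = 0, noise_sd = 0,
                          blink_prob = 0, eog_noise_uV = 0, jitter_sd = 0,
                          jitter_sd_mod = 0, n_subjects = 1L, seed = 3L)
  ep <- simulateSubject(sseq, cfg, 1L, the_space)
  d <- epochData(ep)
  i_std <- which(epochConditions(ep) == "standard")[1]
  i_dev <- which(epochConditions(ep) != "standard")[1]
  expect_equal(d[i_std, 1:6, ], d[i_dev, 1:6, ])
  # and differ when modulation is present
  cfg2 <- simulationConfig(noise_sd = 0, blink_prob = 0, eog_noise_uV = 0,
                           jitter_sd = 0, jitter_sd_mod = 0, n_subjects = 1L,
                           seed = 3L)
  ep2 <- simulateSubject(sseq, cfg2, 1L, the_space)
  d2 <- epochData(ep2)
  expect_gt(max(abs(d2[i_std, 1:6, ] - d2[i_dev, 1:6, ])), 0.1)
})

test_that("blinks appear on EOG at the configured rate and leak into sources", {
  cfg <- simulationConfig(n_subjects = 1L, noise_sd = 0, blink_prob = 0.5,
                          eog_noise_uV = 0, jitter_sd = 0, jitter_sd_mod = 0,
                          seed = 17L)
  ep <- simulateSubject(sseq, cfg, 1L, the_space)
  eogpk <- apply(abs(epochData(ep)[, 7, ]), 1, max)
  frac <- mean(eogpk > 100)
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
  # a blinked epoch's sources differ from a clean epoch of the same condition
  ib <- which(eogpk > 100 & epochConditions(ep) == "standard")[1]
  ic <- which(eogpk == 0 & epochConditions(ep) == "standard")[1]
  expect_gt(max(abs(epochData(ep)[ib, 1:6, ] - epochData(ep)[ic, 1:6, ])), 0.05)
})

test_that("applyTypeEffects perturbs only the targeted conditions", {
  tax <- seq(-100, 400, by = 1000 / 333)
  w <- matrix(exp(-((tax - 150) / 30)^2 / 2), 6, length(tax), byrow = TRUE,
              dimnames = list(nodeNames(), NULL))
  ev <- manual_evoked(list(standard = w, gap = w, frequency = w), tax)
  fx <- list(gap = c(0.5, 30), frequency = c(1, 0))
  out <- applyTypeEffects(ev, fx)
  expect_equal(waveforms(out, "standard"), w)
  expect_equal(waveforms(out, "frequency"), w)
  g <- waveforms(out, "gap")
  expect_equal(max(g), 0.5, tolerance = 0.01)            # scaled
  expect_equal(tax[which.max(g[1, ])] - tax[which.max(w[1, ])], 30,
               tolerance = 1000 / 333)                    # shifted later
})

test_that("simulateEvoked shares ground truth with the trial generator", {
  cfg <- simulationConfig(n_subjects = 2L, seed = 9L)
  ev <- simulateEvoked(cfg, 2L, noise_rel = 0, space = the_space)
  ep <- simulateSubject(sseq, cfg, 2L, the_space)
  pe <- attr(ev, "groundTruth")$params
  pt <- attr(ep, "groundTruth")$params
  expect_equal(pe$B, pt$B)
  expect_equal(pe$He, pt$He)
  # noiseless evoked equals the integrated response
  m <- the_space[[cfg$model_id]]
  std <- waveforms(integrateModel(m, pe, "standard", timeAxis(ev), 333))
  expect_equal(waveforms(ev, "standard"), std)
})

test_that("invalid simulation configs are refused", {
  expect_error(simulationConfig(window_ms = c(0, 200)), "0-250|250")
  expect_error(simulationConfig(blink_prob = 1.5), "blink_prob")
  expect_error(simulationConfig(sr = -1), "sampling")
})
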