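# Filtering, baseline correction, EOG rejection, robust averaging.

test_that("a DC epoch passes the 40 Hz lowpass essentially unchanged", {
  tr <- list(matrix(5, 6, 160))
  ep <- manual_epochs(tr)
  out <- filterEpochs(ep, filterSpec("lowpass", 40, 24))
  expect_lt(max(abs(epochData(out)[1, 1:6, ] - 5)) / 5, 1e-6)
})

test_that("an 80 Hz sinusoid is attenuated by at least 12 dB at 40 Hz cutoff", {
  sr <- 333
  t <- (0:159) / sr
  s <- sin(2 * pi * 80 * t)
  ep <- manual_epochs(list(rbind(s, s, s, s, s, s)))
  out <- filterEpochs(ep, filterSpec("lowpass", 40, 24))
  mid <- 40:120                       # avoid edge transients
  gain <- max(abs(epochData(out)[1, 1, mid])) / max(abs(s[mid]))
  expect_lt(20 * log10(gain), -12)
})

test_that("slow drift is suppressed by the 1 Hz highpass", {
  sr <- 333
  t <- (0:166) / sr
  d <- sin(2 * pi * 0.1 * t + 0.3)
  ep <- manual_epochs(list(rbind(d, d, d, d, d, d)))
  out <- filterEpochs(ep, filterSpec("highpass", 1, 6))
  expect_lt(max(abs(epochData(out)[1, 1, ])), max(abs(d)))
})

test_that("cutoff at or above Nyquist is refused", {
  ep <- manual_epochs(list(matrix(0, 6, 50)))
  expect_error(filterEpochs(ep, filterSpec("lowpass", 200, 24)), "Nyquist")
})

test_that("baseline correction zeroes constants and preserves steps", {
  nt <- 167
  time <- -100 + (0:(nt - 1)) * 1000 / 333
  const <- matrix(4, 6, nt)
  step <- matrix(2, 6, nt); step[, time > 0] <- 5
  ep <- manual_epochs(list(const, step))
  out <- epochData(baselineCorrect(ep, c(-100, 0)))
  expect_equal(max(abs(out[1, 1:6, ])), 0)
  expect_equal(unique(as.vector(out[2, 1:6, time > 0])), 3)
  # idempotence: mean over the baseline window is 0 afterwards
  set.seed(1)
  rnd <- matrix(rnorm(6 * nt), 6, nt)
  out2 <- epochData(baselineCorrect(manual_epochs(list(rnd))))
  expect_lt(max(abs(apply(out2[1, 1:6, time >= -100 & time <= 0], 1, mean))), 1e-9)
})

test_that("EOG rejection matches a brute-force scan exactly", {
  set.seed(42)
  ntr <- 40
  trials <- replicate(ntr, matrix(rnorm(6 * 100), 6, 100), simplify = FALSE)
  eog <- replicate(ntr, rnorm(100, 0, 20), simplify = FALSE)
  blinky <- sample(ntr, 7)
  for (i in blinky) eog[[i]][50] <- 200 * sign(rnorm(1))
  conds <- rep(c("standard", "deviant"), length.out = ntr)
  ep <- manual_epochs(trials, eog, conds)
  res <- rejectEpochs(ep, 150)
  # oracle: exhaustive scan over epochs
  bad <- vapply(seq_len(ntr), function(i) max(abs(eog[[i]])) > 150, logical(1))
  expect_equal(sum(res$report$rejected), sum(bad))
  expect_equal(dim(epochData(res$epochs))[1], ntr - sum(bad))
  by_cond <- tapply(bad, conds, sum)
  got <- stats::setNames(res$report$rejected, res$report$condition)
  expect_equal(as.numeric(got[names(by_cond)]), as.numeric(by_cond))
})

test_that("rejection edge cases: none above threshold, zero threshold", {
  trials <- replicate(5, matrix(0, 6, 50), simplify = FALSE)
  eog <- replicate(5, rep(1, 50), simplify = FALSE)
  ep <- manual_epochs(trials, eog)
  expect_equal(sum(rejectEpochs(ep, 150)$report$rejected), 0)
  expect_equal(sum(rejectEpochs(ep, 0)$report$rejected), 5)
})

test_that("identical epochs average to themselves; robust equals plain without outliers", {
  set.seed(7)
  base <- matrix(rnorm(6 * 80), 6, 80)
  ep <- manual_epochs(replicate(10, base, simplify = FALSE))
  ev <- averageEpochs(ep, robust = TRUE)
  expect_equal(waveforms(ev, "standard")[1:6, ], base, tolerance = 1e-12,
               ignore_attr = TRUE)
  # clean but non-identical epochs: robust and plain agree to 1e-6
  eps <- replicate(30, base + matrix(rnorm(6 * 80, 0, 0.05), 6, 80),
                   simplify = FALSE)
  ep2 <- manual_epochs(eps)
  r <- waveforms(averageEpochs(ep2, robust = TRUE), "standard")
  p <- waveforms(averageEpochs(ep2, robust = FALSE), "standard")
  expect_lt(max(abs(r - p)), 1e-2 * stats::sd(base))
})

test_that("robust average resists a gross outlier epoch where plain does not", {
  set.seed(11)
  base <- matrix(sin(2 * pi * (1:100) / 50), 6, 100, byrow = TRUE)
  clean <- replicate(50, base + matrix(rnorm(600, 0, 0.02), 6, 100),
                     simplify = FALSE)
  outlier <- base; outlier[, 30:60] <- outlier[, 30:60] + 100
  ep <- manual_epochs(c(clean, list(outlier)))
  rob <- averageEpochs(ep, robust = TRUE, return_weights = TRUE)
  pl <- averageEpochs(ep, robust = FALSE)
  cm <- Reduce(`+`, clean) / length(clean)
  err_r <- abs(waveforms(rob, "standard")[1:6, 30:60] - cm[, 30:60])
  err_p <- abs(waveforms(pl, "standard")[1:6, 30:60] - cm[, 30:60])
  expect_true(all(err_r < err_p))
  w <- attr(rob, "weights")$standard
  expect_true(all(w[51, 1:6, 30:60] < 0.5))   # outlier down-weighted
})

test_that("averaging fewer than two epochs is an error", {
  ep <- manual_epochs(list(matrix(0, 6, 20)))
  expect_error(averageEpochs(ep), "insufficient|>= 2")
})

test_that("the dcm preprocessing profile fills rejection bookkeeping", {
  seq <- generateSequence(small_seq_config())
  cfg <- simulationConfig(n_subjects = 1L, seed = 5L, blink_prob = 0.3)
  ep <- simulateSubject(seq, cfg, 1L, the_space)
  ev <- preprocessEpochs(ep, "dcm")
  expect_setequal(names(waveforms(ev)), c("standard", "deviant"))
  tot <- trialsUsed(ev) + trialsRejected(ev)
  expect_equal(sum(tot), length(epochConditions(ep)))
  expect_gt(sum(trialsRejected(ev)), 0)   # 30% blinks at 200 uV must reject some
  expect_false(is.null(attr(ev, "manifest")))
})
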