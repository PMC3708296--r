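# Forward model: fixed points, linear observation, condition coupling,
# solver accuracy against an independent reference integration.

mod_sa <- findModel(the_space, "sparse", "anterior")
tt <- seq(0, 280, by = 1000 / 333)

test_that("zero-amplitude input leaves every source at rest", {
  p <- defaultNMMParams(mod_sa)
  p$input$amplitude <- 0
  r <- integrateModel(mod_sa, p, "standard", tt)
  expect_equal(max(abs(waveforms(r))), 0)
})

test_that("observation is linear: doubling gains doubles the output", {
  p <- defaultNMMParams(mod_sa)
  r1 <- waveforms(integrateModel(mod_sa, p, "standard", tt))
  p$obs_gain <- p$obs_gain * 2
  r2 <- waveforms(integrateModel(mod_sa, p, "standard", tt))
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("with no modulation, standard and deviant responses are identical", {
  p <- defaultNMMParams(mod_sa)        # B = 0, intrinsic_mod = 0
  s <- waveforms(integrateModel(mod_sa, p, "standard", tt))
  d <- waveforms(integrateModel(mod_sa, p, "deviant", tt))
  expect_identical(s, d)
})

test_that("condition couplings apply exp(B) exactly where masked", {
  m <- findModel(the_space, "partial", "anterior")
  p <- defaultNMMParams(m)
  expect_equal(conditionCouplings(p, m, "deviant")$A_forward,
               conditionCouplings(p, m, "standard")$A_forward)  # B = 0
  # ln 2 on one modulated forward edge doubles exactly that coupling
  lt <- which(nodeNames() == "temporal.L"); lf <- which(nodeNames() == "frontal.L")
  p$B[lf, lt] <- log(2)
  cc_s <- conditionCouplings(p, m, "standard")
  cc_d <- conditionCouplings(p, m, "deviant")
  expect_equal(cc_d$A_forward[lf, lt], 2 * cc_s$A_forward[lf, lt])
  other <- cc_d$A_forward; other[lf, lt] <- cc_s$A_forward[lf, lt]
  expect_equal(other, cc_s$A_forward)
  # anterior scheme: interhemispheric couplings are never modulated
  p2 <- defaultNMMParams(m)
  p2$B[m@modulationMask] <- 0.7
  expect_equal(conditionCouplings(p2, m, "deviant")$A_lateral,
               conditionCouplings(p2, m, "standard")$A_lateral)
})

test_that("B outside the modulation mask is a validation error", {
  p <- defaultNMMParams(mod_sa)
  p$B[which(nodeNames() == "parietal.L"), which(nodeNames() == "temporal.L")] <- 0.3
  expect_error(conditionCouplings(p, mod_sa, "deviant"), "mask")
})

test_that("single-node response matches a high-order reference solution", {
  skip_if_not_installed("deSolve")
  # isolated node, no delays: the same equations integrated by lsoda
  m <- mod_sa
  p <- defaultNMMParams(m)
  p$A_forward[] <- 0; p$A_backward[] <- 0; p$A_lateral[] <- 0
  p$delay_intra_ms <- 0; p$delay_inter_ms <- 0
  mine <- integrateModel(m, p, "standard", tt, oversample = 4L)
  sig <- function(v) 2 * p$e0 / (1 + exp(p$r * (p$v0 - v))) -
    2 * p$e0 / (1 + exp(p$r * p$v0))
  gam <- p$gamma
  ode_rhs <- function(t, x, parms) {
    u <- mmnet:::.driving_input(t, p$input$onset_ms, p$input$dispersion_ms,
                                p$input$amplitude)
    s9 <- sig(x[2] - x[3]); s1 <- sig(x[1]); s7 <- sig(x[7])
    He <- p$He[1]; Hi <- p$Hi[1]; te <- p$taue[1]; ti <- p$taui[1]
    list(c(x[4],
           x[5],
           x[6],
           He / te * (gam[1] * s9 + u) - 2 * x[4] / te - x[1] / te^2,
           He / te * (gam[2] * s1) - 2 * x[5] / te - x[2] / te^2,
           Hi / ti * (gam[4] * s7) - 2 * x[6] / ti - x[3] / ti^2,
           x[8],
           He / te * (gam[3] * s9) - 2 * x[8] / te - x[7] / te^2))
  }
  ref <- deSolve::lsoda(rep(0, 8), tt, ode_rhs, NULL, rtol = 1e-10, atol = 1e-12)
  vref <- ref[, 3] - ref[, 4]          # pyramidal depolarisation
  vmine <- waveforms(mine)[1, ]
  pk_ref <- which.max(abs(vref)); pk_mine <- which.max(abs(vmine))
  expect_lt(abs(vref[pk_ref] - vmine[pk_mine]) / abs(vref[pk_ref]), 0.01)
  expect_lt(abs(tt[pk_ref] - tt[pk_mine]), 1000 / 333 + 1e-9)
  expect_lt(sqrt(mean((vref - vmine)^2)) / sqrt(mean(vref^2)), 0.01)
})

test_that("default dynamics stay finite and bounded over 0-400 ms", {
  for (m in list(the_space[[1]], the_space[[6]], the_space[[11]])) {
    p <- defaultNMMParams(m)
    p$B[m@modulationMask] <- log(1.5)
    p$intrinsic_mod[] <- log(1.2)
    w <- waveforms(integrateModel(m, p, "deviant", seq(0, 400, by = 2)))
    expect_true(all(is.finite(w)))
    expect_lt(max(abs(w)), 100)        # mV; bounded, not blowing up
  }
})

test_that("halving the integration step changes the response by < 0.5% RMS", {
  p <- defaultNMMParams(mod_sa)
  a <- waveforms(integrateModel(mod_sa, p, "standard", tt, oversample = 4L))
  b <- waveforms(integrateModel(mod_sa, p, "standard", tt, oversample = 8L))
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(b^2)), 0.005)
})

test_that("numerically unstable parameter regimes raise a named error", {
  p <- defaultNMMParams(mod_sa)
  p$taue <- p$taue / 200               # stiffer than the fixed step resolves
  p$taui <- p$taui / 200
  expect_error(integrateModel(mod_sa, p, "standard", tt), "diverged")
})

test_that("parameter validation enforces mask consistency and positivity", {
  p <- defaultNMMParams(mod_sa)
  p$A_lateral[1, 2] <- 4               # sparse model has no lateral edges
  expect_error(integrateModel(mod_sa, p, "standard", tt), "mask")
  p2 <- defaultNMMParams(mod_sa)
  p2$taue <- -p2$taue
  expect_error(integrateModel(mod_sa, p2, "standard", tt), "time constants")
})
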