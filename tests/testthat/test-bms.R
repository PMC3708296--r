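# Random-effects Bayesian model selection: Dirichlet posterior, exceedance
# probabilities, family-level inference.

# Independent oracle for K = 2: P(r1 > 1/2) under the Beta marginal of the
# Dirichlet posterior, by direct numerical integration of the density.
beta_xp_oracle <- function(a1, a2) {
  stats::integrate(function(r) stats::dbeta(r, a1, a2), 0.5, 1,
                   rel.tol = 1e-10)$value
}

test_that("equal evidences give symmetric r and xp", {
  Fm <- matrix(0, 6, 2)
  b <- rfxBMS(Fm, n_samples = 1e5, seed = 4)
  expect_equal(unname(posteriorProb(b)), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(exceedanceProb(b)), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(exceedanceProb(b)), 1)
})

test_that("a 5-nat advantage in every subject drives alpha and xp", {
  Fm <- cbind(rep(5, 8), rep(0, 8))
  b <- rfxBMS(Fm, n_samples = 1e5, seed = 9)
  a <- dirichletAlpha(b)
  expect_equal(unname(a[1]), 9, tolerance = 0.05)   # alpha0 + 8
  expect_equal(unname(a[2]), 1, tolerance = 0.05)
  expect_gt(exceedanceProb(b)[1], 0.95)
  # sampling xp matches the Beta-integration oracle
  expect_equal(unname(exceedanceProb(b)[1]), beta_xp_oracle(a[1], a[2]),
               tolerance = 0.01)
})

test_that("sampling xp matches numeric Beta integration across posteriors", {
  for (spec in list(c(3, 2), c(7.5, 1.2), c(2, 2), c(1.1, 9))) {
    # build a 2-model evidence matrix whose VB posterior we then query
    Fm <- cbind(c(rep(3, round(spec[1]) - 1), rep(0, round(spec[2]) - 1)),
                c(rep(0, round(spec[1]) - 1), rep(3, round(spec[2]) - 1)))
    b <- rfxBMS(Fm, n_samples = 1e6, seed = 21)
    a <- dirichletAlpha(b)
    expect_equal(unname(exceedanceProb(b)[1]), beta_xp_oracle(a[1], a[2]),
                 tolerance = 0.01, label = paste(spec, collapse = "/"))
  }
})

test_that("adding a per-subject constant leaves the result unchanged", {
  set.seed(5)
  Fm <- matrix(rnorm(8 * 4, sd = 2), 8, 4)
  b1 <- rfxBMS(Fm, n_samples = 1e5, seed = 2)
  b2 <- rfxBMS(Fm + rnorm(8, sd = 50), n_samples = 1e5, seed = 2)
  expect_equal(dirichletAlpha(b1), dirichletAlpha(b2), tolerance = 1e-6)
  expect_equal(exceedanceProb(b1), exceedanceProb(b2), tolerance = 1e-9)
})

test_that("raising one subject's evidence for a model never lowers its alpha", {
  set.seed(8)
  Fm <- matrix(rnorm(6 * 3), 6, 3)
  a0 <- dirichletAlpha(rfxBMS(Fm, n_samples = 1e4, seed = 1))
  for (bump in c(0.5, 2, 10)) {
    Fm2 <- Fm; Fm2[3, 2] <- Fm2[3, 2] + bump
    a1 <- dirichletAlpha(rfxBMS(Fm2, n_samples = 1e4, seed = 1))
    expect_gte(a1[2] + 1e-8, a0[2])
    a0 <- a1
  }
})

test_that("non-finite evidences are refused", {
  Fm <- matrix(0, 3, 2); Fm[2, 1] <- NA
  expect_error(rfxBMS(Fm, n_samples = 1e4), "finite")
  expect_error(rfxBMS(matrix(0, 3, 2), n_samples = 100), "1e4|10000")
})

test_that("singleton families reduce family BMS to model-level BMS", {
  set.seed(13)
  Fm <- matrix(rnorm(10 * 3, sd = 1.5), 10, 3,
               dimnames = list(NULL, c("1", "2", "3")))
  part <- c(`1` = "f1", `2` = "f2", `3` = "f3")
  fb <- familyBMS(Fm, part, n_samples = 1e5, seed = 6)
  mb <- rfxBMS(Fm, n_samples = 1e5, seed = 6)
  expect_equal(unname(posteriorProb(fb)), unname(posteriorProb(mb)),
               tolerance = 1e-6)
  expect_equal(unname(exceedanceProb(fb)), unname(exceedanceProb(mb)),
               tolerance = 0.01)
})

test_that("exchangeable evidences over 3 equal families give xp near 1/3", {
  Fm <- matrix(0, 9, 6, dimnames = list(NULL, as.character(1:6)))
  part <- stats::setNames(rep(c("a", "b", "c"), each = 2), 1:6)
  fb <- familyBMS(Fm, part, n_samples = 1e6, seed = 3)
  expect_equal(unname(exceedanceProb(fb)), rep(1 / 3, 3), tolerance = 0.01)
  expect_equal(sum(posteriorProb(fb)), 1, tolerance = 1e-9)
})

test_that("evidence concentrated on one family's model lifts that family", {
  Fm <- matrix(0, 8, 6, dimnames = list(NULL, as.character(1:6)))
  part <- stats::setNames(rep(c("a", "b", "c"), each = 2), 1:6)
  Fm[, 5] <- 8                         # model 5 belongs to family c
  fb <- familyBMS(Fm, part, n_samples = 1e5, seed = 31)
  xp <- exceedanceProb(fb)
  expect_true(which.max(xp) == which(names(xp) == "c"))
  expect_gt(xp["c"], max(xp[c("a", "b")]))
})

test_that("within-family restriction behaves and refuses singletons", {
  Fm <- matrix(0, 8, 6, dimnames = list(NULL, as.character(1:6)))
  part <- stats::setNames(c("a", "a", "a", "a", "a", "solo"), 1:6)
  wb <- withinFamilyBMS(Fm, part, "a", n_samples = 1e5, seed = 2)
  expect_equal(unname(exceedanceProb(wb)), rep(0.2, 5), tolerance = 0.015)
  expect_error(withinFamilyBMS(Fm, part, "solo"), "fewer than 2")
  # winner-takes-all within the family
  Fm[, 2] <- 12
  wb2 <- withinFamilyBMS(Fm, part, "a", n_samples = 1e5, seed = 2)
  expect_gt(exceedanceProb(wb2)["2"], 0.95)
  # restriction covers each model exactly once across families
  members <- c(names(exceedanceProb(wb)), "6")
  expect_setequal(members, colnames(Fm))
})

test_that("fixed-effects group evidence is the column sum", {
  Fm <- rbind(c(1, 2), c(3, 5))
  expect_equal(unname(ffxLogGroupEvidence(Fm)), c(4, 7))
  expect_equal(unname(ffxLogGroupEvidence(Fm[1, , drop = FALSE])), c(1, 2))
  same <- rbind(c(2, 1), c(2, 1), c(2, 1))
  expect_equal(unname(ffxLogGroupEvidence(same)), 3 * c(2, 1))
})
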