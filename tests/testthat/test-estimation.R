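test_that("AICc arithmetic and its limits", {
  expect_equal(computeAICc(100, 0, 50), 100)
  ## large-sample limit: correction vanishes
  expect_equal(computeAICc(200, 5, 1e9), 200 + 10, tolerance = 1e-6)
  ## small-sample correction at realistic sizes
  expect_equal(computeAICc(533.24, 13, 140), 562.12, tolerance = 0.02)
  expect_error(computeAICc(100, 10, 11), "exceed")
})

test_that("Wald intervals back-transform from the link scale", {
  expect_equal(waldInterval(0, 0, "logit"), c(0.5, 0.5))
  ci <- waldInterval(qlogis(0.47), 0.29, "logit")
  expect_equal(ci, c(0.33, 0.61), tolerance = 0.01)
  ## probability intervals stay inside [0,1] for any inputs
  set.seed(2)
  for (i in 1:20) {
    ci <- waldInterval(rnorm(1, 0, 5), rexp(1, 1 / 3), "logit")
    expect_true(all(ci >= 0 & ci <= 1) && ci[1] <= ci[2])
  }
})

test_that("numerical rank counts identifiable parameters", {
  expect_equal(numericalNp(diag(c(5, 3))), 2L)
  expect_equal(numericalNp(diag(c(5, 3, 1e-12))), 2L)
  expect_equal(numericalNp(matrix(0, 2, 2)), 0L)
})

test_that("uninformative data yields rank-deficient information", {
  ## everyone released once and never seen again: resighting, recovery and
  ## mortality are mutually confounded
  ev <- matrix(0L, 30, 4)
  ev[, 1] <- 3L
  x <- encounterHistories(ev, sex = rep("M", 30), ageAtMarking = rep(2, 30))
  st <- modelStructure("M", "1+", resight = "constant",
                       estimateInit = FALSE)
  fit <- suppressWarnings(fitModel(x, st, nStarts = 2, seed = 1))
  expect_lt(fit@np, length(fit@theta))
})

test_that("degenerate perfect data drives estimates to the boundaries", {
  ## every animal observed at every occasion and none die
  ev <- matrix(2L, 15, 5)
  x <- encounterHistories(ev, sex = rep("F", 15), ageAtMarking = rep(3, 15),
                          markingOccasion = rep(1L, 15))
  st <- modelStructure("F", "1+", resight = "constant",
                       estimateInit = FALSE)
  fit <- suppressWarnings(fitModel(x, st, nStarts = 1, seed = 2))
  est <- estimates(fit)
  expect_gt(est$estimate[est$parameter == "p"], 0.99)
  expect_lt(est$estimate[est$parameter == "mPoach[1+]"], 0.01)
  expect_lt(est$estimate[est$parameter == "mOther[1+]"], 0.01)
  expect_true("p" %in% fit@boundary)
})

test_that("refitting from the reported optimum reproduces it", {
  sim <- simulateHistories(scaledDesign("M", 150), presetParameters("M"),
                           seed = 17)
  st <- presetStructure("M")
  fit <- fitModel(sim, st, nStarts = 0, seed = 1,
                  init = deflate(presetParameters("M"), st))
  refit <- fitModel(sim, st, nStarts = 0, seed = 1, init = fit@theta)
  expect_equal(refit@deviance, fit@deviance, tolerance = 1e-7)
})

test_that("nested models keep deviance monotone", {
  sim <- simulateHistories(scaledDesign("F", 250), presetParameters("F"),
                           seed = 23)
  mk <- function(m) modelStructure("F", "1,2:7,8+", mortality = m,
                                   resight = "constant")
  fitA <- fitModel(sim, mk("additive"), nStarts = 2, seed = 3)
  fitC <- fitModel(sim, mk("constant_poach"), nStarts = 2, seed = 3)
  ## start the interactive fit from both restricted optima: its deviance can
  ## then only improve on them
  stI <- mk("interactive")
  inits <- list(deflate(inflate(fitA@theta, mk("additive"), 10L), stI),
                deflate(inflate(fitC@theta, mk("constant_poach"), 10L), stI))
  fitI <- fitModel(sim, stI, nStarts = 0, seed = 3, init = inits)
  expect_lte(fitI@deviance, fitA@deviance + 1e-6)
  expect_lte(fitI@deviance, fitC@deviance + 1e-6)
})

test_that("effective sample size counts non-zero events per sex", {
  ev <- rbind(c(2, 0, 2), c(3, 8, 0), c(1, 1, 1))
  x <- encounterHistories(ev, sex = c("F", "F", "M"),
                          ageAtMarking = c(2, 3, 4))
  expect_equal(essOf(x), 7L)
  expect_equal(essOf(x, "F"), 4L)
  expect_equal(essOf(x, "M"), 3L)
})
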