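## stub fit with a given estimates table, for averaging arithmetic tests
.stubFit <- function(est, aicc = 100, label = "stub") {
  st <- modelStructure("F", "1+", label = label)
  new("MultieventFit", structure = st, theta = c(x = 0), logLik = -aicc / 2,
      deviance = aicc, np = 1L, ess = 100L, aicc = aicc,
      vcov = matrix(1, 1, 1), estimates = est, converged = TRUE,
      boundary = character(0), nStarts = 0L, seed = 1L,
      details = list(fingerprint = c(n = 1, nOcc = 1, ess = 1, evSum = 1)))
}

test_that("Akaike weights follow the exponential rescaling", {
  expect_equal(akaikeWeights(42), 1)
  w <- akaikeWeights(c(10, 12, 14))
  expect_equal(sum(w), 1)
  ## invariance to adding a constant
  expect_equal(akaikeWeights(c(110, 112, 114)), w)
  ## monotone decreasing in AICc
  expect_true(all(diff(w) < 0))
})

test_that("model table sorts, restricts weights to candidates, and checks data", {
  sim <- simulateHistories(scaledDesign("M", 120), presetParameters("M"),
                           seed = 13)
  mk <- function(m) modelStructure("M", "1:3,4:7,8+", mortality = m,
                                   resight = "by_mark")
  fits <- lapply(list(interactive = "interactive", additive = "additive",
                      constant_poach = "constant_poach"),
                 function(m) fitModel(sim, mk(m), nStarts = 1, seed = 5,
                   init = deflate(presetParameters("M"), mk(m))))
  tab <- buildModelTable(fits, candidates = names(fits))
  expect_equal(tab@table$dAicc[1], 0)
  expect_true(all(diff(tab@table$aicc) >= 0))
  expect_equal(sum(tab@table$weight), 1, tolerance = 1e-12)

  ## permuting the fit list leaves the table unchanged
  tab2 <- buildModelTable(fits[c(3, 1, 2)], candidates = names(fits))
  expect_equal(tab2@table, tab@table)

  ## weights only over the designated candidate subset
  tab3 <- buildModelTable(fits, candidates = c("interactive", "additive"))
  expect_equal(sum(tab3@table$weight, na.rm = TRUE), 1)
  expect_true(is.na(tab3@table$weight[tab3@table$model == "constant_poach"]))

  ## fits on different data are refused
  other <- fits
  other$interactive@details$fingerprint["evSum"] <- -1
  expect_error(buildModelTable(other), "identical data")
})

test_that("model averaging reproduces hand arithmetic", {
  estOf <- function(e, s) data.frame(parameter = "mPoach[1+]", estimate = e,
    se = s, lcl = NA_real_, ucl = NA_real_, boundary = FALSE)
  f1 <- .stubFit(estOf(0.2, 0)); f2 <- .stubFit(estOf(0.4, 0))
  avg <- modelAverage(list(f1, f2), c(0.5, 0.5))
  expect_equal(avg$estimate, 0.3)
  expect_equal(avg$se, 0.1)  # purely between-model spread

  ## single model: identity
  f3 <- .stubFit(estOf(0.25, 0.05))
  one <- modelAverage(list(f3), 1)
  expect_equal(one$estimate, 0.25)
  expect_equal(one$se, 0.05)

  ## unconditional SE is never below the weighted conditional component
  f4 <- .stubFit(estOf(0.3, 0.02)); f5 <- .stubFit(estOf(0.35, 0.04))
  w <- c(0.7, 0.3)
  avg2 <- modelAverage(list(f4, f5), w)
  expect_gte(avg2$se, sum(w * c(0.02, 0.04)) - 1e-12)
  ## convexity: averaged value inside the per-model range
  expect_true(avg2$estimate >= 0.3 && avg2$estimate <= 0.35)

  ## a parameter missing from one model is an error naming the model
  f6 <- .stubFit(data.frame(parameter = "other", estimate = 0.1, se = 0.01,
                            lcl = NA, ucl = NA, boundary = FALSE))
  expect_error(modelAverage(list(f4, f6), c(0.5, 0.5),
                            parameters = "mPoach[1+]"), "missing in model")
})

test_that("relative poaching mortality is the poached share of total mortality", {
  avg <- data.frame(parameter = c("mPoach[1]", "mPoach[8+]",
                                  "mOther[1]", "mOther[8+]"),
                    estimate = c(0.1, 0.2, 0.3, 0.2),
                    se = 0, lcl = NA, ucl = NA)
  rel <- relativePoachingMortality(avg)
  expect_equal(rel$relPoach, c(0.25, 0.5))
  expect_equal(rel$ageClass, c("1", "8+"))
})
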