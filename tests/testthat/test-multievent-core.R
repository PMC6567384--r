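## small helper: parameter set with explicit scalar values over nOcc occasions
.ps <- function(mP, mO, lambda = c(0, 0), D = 0, pc = 0.5, pt = 0.5,
                r = 0.5, rGps = 1, delta = 0.8, nOcc = 4L, ages = "1+") {
  parameterSet(ages = ages, mPoach = mP, mOther = mO, lambdaGps = lambda,
               dropOff = D, pCollar = pc, pTag = pt, recovery = r,
               rGps = rGps, delta = delta, nOccasions = nOcc)
}

test_that("mark kernel composes signal loss and drop-off", {
  p0 <- .ps(0.1, 0.1, lambda = c(0, 0), D = 0)
  expect_equal(buildMarkKernel(p0, 1), diag(4),
               ignore_attr = TRUE)

  ## female-like values: second-year signal loss 0.39, no drop-off
  pF <- .ps(0.1, 0.1, lambda = c(0, 0.39), D = 0)
  expect_equal(unname(buildMarkKernel(pF, 2)[1L, ]), c(0.61, 0.39, 0, 0))

  ## male-like values: loss 0.27, drop-off 0.15
  pM <- .ps(0.1, 0.1, lambda = c(0.27, 0.27), D = 0.15)
  K <- buildMarkKernel(pM, 2)
  expect_equal(unname(K[1L, 4L]), 0.15)
  expect_equal(unname(K[1L, 2L]), 0.27 * 0.85)
})

test_that("transition matrix routes deaths by cause and post-kernel mark", {
  ## old-male-like values: survival 0.541, poaching 0.255, other 0.204
  p <- .ps(0.255, 0.204)
  Tm <- buildTransition(p, 1, 1)
  expect_equal(unname(Tm["A_TAG", "A_TAG"]), 0.541)
  expect_equal(unname(Tm["A_TAG", "ND_P_X"]), 0.255)
  expect_equal(unname(Tm["A_TAG", "ND_O_X"]), 0.204)
  ## a working-GPS animal that keeps its collar dies into the GPS dead states
  expect_equal(unname(Tm["A_GPS", "ND_P_GPS"]), 0.255)
  ## zero mortality: block-diagonal, alive states move only by the kernel
  p0 <- .ps(0, 0, lambda = c(0.2, 0.3), D = 0.1)
  T0 <- buildTransition(p0, 1, 2)
  expect_equal(T0[1:4, 1:4], buildMarkKernel(p0, 2), ignore_attr = TRUE)
  expect_true(all(T0[1:4, 5:9] == 0))
})

test_that("event matrix encodes detection, recovery and cause determination", {
  p <- .ps(0.1, 0.1, r = 0.5, delta = 0.8)
  E <- buildEventMatrix(p, 2)
  ## working GPS: perfect detection, always code 1
  expect_equal(unname(E["A_GPS", ]), c(0, 1, rep(0, 9)))
  ## non-GPS poached: code 6 with r*delta, code 10 with r*(1-delta)
  expect_equal(unname(E["ND_P_X", "6"]), 0.40)
  expect_equal(unname(E["ND_P_X", "10"]), 0.10)
  expect_equal(unname(E["ND_P_X", "0"]), 0.50)
  ## long dead: never observed
  expect_equal(unname(E["DEAD", "0"]), 1)
})

test_that("transition and event rows are conserved for random parameters", {
  set.seed(33)
  for (i in 1:25) {
    p <- randomParameterSet(nOcc = 4L)
    for (a in seq_len(nClasses(p@agePartition))) for (d in 1:2)
      expect_equal(rowSums(buildTransition(p, a, d)), rep(1, 9),
                   tolerance = 1e-12, ignore_attr = TRUE)
    for (t in 1:4)
      expect_equal(rowSums(buildEventMatrix(p, t)), rep(1, 9),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("release-only and perfect-detection histories have probability 1", {
  p <- .ps(0.2, 0.3)
  expect_equal(historyLogLik(c(0, 0, 0, 2), 4, 3, p), 0)
  ## no mortality, no mark dynamics: a GPS animal yields code 1 for certain
  p1 <- .ps(0, 0, lambda = c(0, 0), D = 0, nOcc = 3L)
  expect_equal(historyLogLik(c(1, 1, 1), 1, 2, p1), 0)
})

test_that("zero-probability histories return -Inf", {
  p1 <- .ps(0, 0, lambda = c(0, 0), D = 0, nOcc = 3L)
  ## a GPS animal cannot be missed while mortality and signal loss are zero
  expect_equal(historyLogLik(c(1, 0, 1), 1, 2, p1), -Inf)
})

test_that("forward algorithm equals exhaustive path enumeration", {
  set.seed(123)
  for (i in 1:10) {
    p <- randomParameterSet("1:2,3+", nOcc = 4L)
    h <- randomShortHistory(p, 4L, seed = 1000 + i)
    expect_equal(historyLogLik(h$events, h$t0, h$age0, p, useInit = TRUE),
                 bruteForceLogLik(h$events, h$t0, h$age0, p, useInit = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("event alphabet is complete over one-step futures", {
  set.seed(9)
  for (i in 1:5) {
    p <- randomParameterSet("1+", nOcc = 2L)
    for (rel in 1:3) {
      tot <- sum(vapply(0:10, function(e) {
        ll <- historyLogLik(c(rel, e), 1, 3, p)
        if (is.finite(ll)) exp(ll) else 0
      }, 1.0))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("dataset likelihood is additive and label-invariant", {
  p <- presetParameters("F", nOccasions = 6L)
  st <- modelStructure("F", "1,2:7,8+", resight = "constant")
  sim <- simulateHistories(scaledDesign("F", 60), presetParameters("F"),
                           seed = 21)
  th <- deflate(presetParameters("F"), st)
  base <- datasetLogLik(sim, th, st)
  ## permuting individuals leaves the total unchanged
  perm <- sample(nrow(sim))
  expect_equal(datasetLogLik(sim[perm, ], th, st)$logLik, base$logLik)
  expect_equal(base$deviance, -2 * base$logLik)

  ## duplicated histories contribute exactly twice
  two <- rbind(c(2, 2, 0, 0), c(2, 2, 0, 0))
  x2 <- encounterHistories(two, sex = c("F", "F"), ageAtMarking = c(2, 2))
  one <- encounterHistories(two[1, , drop = FALSE], sex = "F",
                            ageAtMarking = 2)
  st4 <- modelStructure("F", "1+", resight = "constant",
                        estimateInit = FALSE)
  th4 <- rnorm(nrow(buildParameterIndex(st4, 4L)))
  expect_equal(datasetLogLik(x2, th4, st4)$logLik,
               2 * datasetLogLik(one, th4, st4)$logLik)
})

test_that("compiled forward pass matches the R reference on a full dataset", {
  sim <- smallSimulatedDataset(seed = 31)
  st <- presetStructure("M")
  th <- deflate(presetParameters("M"), st)
  res <- datasetLogLik(sim, th, st)
  pr <- inflate(th, st, 10L)
  ev <- eventCodes(sim); t0 <- markingOccasion(sim)
  a0 <- ageAtMarking(sim); sx <- sexOf(sim)
  idx <- which(sx == "M")
  llR <- sum(vapply(idx, function(i)
    historyLogLik(ev[i, ], t0[i], a0[i], pr, useInit = TRUE), 1.0))
  expect_equal(res$logLik, llR, tolerance = 1e-10)
})
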