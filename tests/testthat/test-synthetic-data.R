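test_that("presets encode the study's demographic rates", {
  pm <- presetParameters("M")
  expect_equal(pm@mPoach[3], 0.255)
  expect_equal(pm@mPoach + pm@mOther + c(0.753, 0.902, 0.541), rep(1, 3),
               tolerance = 1e-12)
  pf <- presetParameters("F")
  expect_equal(pf@dropOff, 0)
  expect_equal(pf@lambdaGps[2], 0.39)
  expect_equal(pf@delta, 0.82)
})

test_that("default design mirrors the marking effort", {
  d <- defaultStudyDesign()
  agg <- aggregate(n ~ sex + mark, d@cohorts, sum)
  get <- function(sx, mk) agg$n[agg$sex == sx & agg$mark == mk]
  expect_equal(get("M", "gps") + get("F", "gps"), 29L)
  expect_equal(sum(agg$n[agg$sex == "M"]), 56L)
  expect_equal(sum(agg$n[agg$sex == "F"]), 85L)
  expect_true(all(d@cohorts$occasion <= 9L))
})

test_that("simulation is deterministic in (design, params, seed)", {
  a <- smallSimulatedDataset(seed = 3)
  b <- smallSimulatedDataset(seed = 3)
  expect_identical(eventCodes(a), eventCodes(b))
  expect_identical(simTruth(a), simTruth(b))
  c <- smallSimulatedDataset(seed = 4)
  expect_false(identical(eventCodes(a), eventCodes(c)))
})

test_that("forced death and forced detection behave deterministically", {
  d <- scaledDesign("F", 40)
  ## certain death in the first interval: one dead code or silence, then 0
  pDead <- parameterSet("1+", mPoach = 0.6, mOther = 0.4, lambdaGps = c(0, 0),
    dropOff = 0, pCollar = 0.7, pTag = 0.7, recovery = 0.5, delta = 0.8,
    nOccasions = 10L)
  sim <- simulateHistories(d, pDead, seed = 6)
  ev <- eventCodes(sim); t0 <- markingOccasion(sim)
  for (i in seq_len(nrow(ev))) {
    after <- ev[i, -seq_len(t0[i])]
    expect_true(all(after[-1L] == 0L))
    expect_true(after[1L] == 0L || after[1L] %in% 5:10)
  }
  ## immortality with certain detection: optical collars emit 2 forever
  pLive <- parameterSet("1+", mPoach = 0, mOther = 0, lambdaGps = c(0, 0),
    dropOff = 0, pCollar = 1, pTag = 1, recovery = 0.5, delta = 0.8,
    nOccasions = 10L)
  sim2 <- simulateHistories(d, pLive, seed = 6)
  ev2 <- eventCodes(sim2); t02 <- markingOccasion(sim2)
  col <- simTruth(sim2)$mark == "collar"
  for (i in which(col))
    expect_true(all(ev2[i, seq(t02[i] + 1L, 10L)] == 2L))
})

test_that("emitted codes are consistent with the recorded latent truth", {
  sim <- smallSimulatedDataset(seed = 8)
  ev <- eventCodes(sim); tr <- simTruth(sim)
  for (i in seq_len(nrow(ev))) {
    dead <- ev[i, ev[i, ] %in% 5:10]
    if (length(dead) == 0L) {
      expect_true(is.na(tr$deathOccasion[i]) || !tr$recovered[i])
      next
    }
    expect_true(tr$recovered[i])
    expect_equal(which(ev[i, ] %in% 5:10), tr$deathOccasion[i])
    if (dead %in% c(5, 6)) expect_equal(tr$cause[i], "poached")
    if (dead %in% c(7, 8)) expect_equal(tr$cause[i], "other")
    expect_equal(dead %in% 5:8, tr$determined[i])
    ## GPS-coded recoveries only for animals in the working-GPS state
    if (dead %in% c(5, 7, 9)) {
      path <- as.integer(strsplit(tr$statePath[i], ",")[[1]])
      expect_true(path[tr$deathOccasion[i] - tr$markingOccasion[i] + 1L]
                  %in% c(5L, 7L))
    }
  }
})

test_that("one-step event frequencies match the analytic emission row", {
  ## 10,000 optical-collared animals over one interval
  d <- studyDesign(2L, data.frame(occasion = 1L, sex = "F",
                                  mark = "collar", n = 10000L))
  p <- presetParameters("F", nOccasions = 2L)
  sim <- simulateHistories(d, p, seed = 101)
  ev2 <- eventCodes(sim)[, 2L]
  ## analytic one-step law: transition from A_COL then emission
  Tm <- buildTransition(p, ageClassOf(p@agePartition, 2), 1)
  ## mix over the simulated age distribution
  ages <- ageAtMarking(sim)
  probs <- rowMeans(vapply(ages, function(a) {
    ac <- ageClassOf(p@agePartition, a)
    as.numeric(t(buildTransition(p, ac, 1)[3L, ]) %*%
                 buildEventMatrix(p, 2L))
  }, numeric(11)))
  emp <- tabulate(ev2 + 1L, nbins = 11L) / length(ev2)
  se <- sqrt(probs * (1 - probs) / length(ev2))
  expect_true(all(abs(emp - probs) <= 3 * se + 1e-9))
})

test_that("an empty recovery experiment yields an empty report", {
  out <- recoveryExperiment(scaledDesign("F", 10), presetParameters("F"),
                            presetStructure("F"), nReplicates = 0L)
  expect_equal(nrow(out$report), 0L)
  expect_equal(out$nFailed, 0L)
})
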