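## Shared fixtures: random valid parameter sets, an exhaustive-enumeration
## likelihood oracle independent of the forward algorithm, a plain CJS
## simulator for the goodness-of-fit calibration, and scaled study designs.

## random parameter set over a partition; mortality triples drawn uniformly
## on the simplex
randomParameterSet <- function(ages = "1,2:7,8+", nOcc = 5L) {
  ap <- agePartition(ages)
  A <- nClasses(ap)
  g <- matrix(stats::rexp(3L * A), A, 3L)
  m <- g / rowSums(g)
  parameterSet(ages = ap, mPoach = m[, 1L], mOther = m[, 2L],
    lambdaGps = stats::runif(2), dropOff = stats::runif(1),
    pCollar = c(0, stats::runif(nOcc - 1L)),
    pTag = c(0, stats::runif(nOcc - 1L)),
    recovery = c(0, stats::runif(nOcc - 1L)),
    rGps = stats::runif(1), delta = stats::runif(1),
    initProp = as.numeric(stats::rexp(3)), nOccasions = nOcc)
}

## exhaustive sum over all latent state paths; independent of the forward
## recursion in every way except the shared matrix builders
bruteForceLogLik <- function(events, t0, age0, params, useInit = FALSE) {
  nOcc <- length(events)
  s0 <- switch(as.character(events[t0]), "1" = 1L, "2" = 3L, "3" = 4L)
  mark0 <- switch(as.character(events[t0]), "1" = 1L, "2" = 2L, "3" = 3L)
  base <- if (useInit) log(params@initProp[mark0]) else 0
  if (t0 >= nOcc) return(base)
  steps <- seq(t0 + 1L, nOcc)
  L <- length(steps)
  ## per-step matrices cached outside the path enumeration
  Ts <- lapply(steps, function(t) {
    ac <- ageClassOf(params@agePartition, age0 + (t - 1L - t0))
    buildTransition(params, ac, min(t - t0, 2L))
  })
  Es <- lapply(steps, function(t) buildEventMatrix(params, t))
  paths <- as.matrix(expand.grid(rep(list(1:9), L)))
  total <- 0
  for (rowi in seq_len(nrow(paths))) {
    pr <- 1
    prev <- s0
    for (si in seq_len(L)) {
      s <- paths[rowi, si]
      pr <- pr * Ts[[si]][prev, s] * Es[[si]][s, events[steps[si]] + 1L]
      if (pr == 0) break
      prev <- s
    }
    total <- total + pr
  }
  if (total <= 0) return(-Inf)
  base + log(total)
}

## random short, structurally valid encounter history for the oracle tests:
## latent-process draw under the given parameters
randomShortHistory <- function(params, nOcc, seed) {
  set.seed(seed)
  t0 <- sample.int(max(1L, nOcc - 1L), 1L)
  mark <- sample(1:3, 1L)
  age0 <- sample(1:10, 1L)
  state <- c(1L, 3L, 4L)[mark]
  ev <- integer(nOcc)
  ev[t0] <- mark
  if (t0 < nOcc) for (t in seq(t0 + 1L, nOcc)) {
    ac <- ageClassOf(params@agePartition, age0 + (t - 1L - t0))
    d <- min(t - t0, 2L)
    state <- sample.int(9L, 1L, prob = buildTransition(params, ac, d)[state, ])
    ev[t] <- sample.int(11L, 1L, prob = buildEventMatrix(params, t)[state, ]) - 1L
    if (state == 9L) break
  }
  list(events = ev, t0 = t0, age0 = age0)
}

## time-dependent CJS simulator (binary detections), written without any of
## the package's process machinery
simulateCJS <- function(n, K, phi, p, seed, nTransients = 0L) {
  set.seed(seed)
  rel <- sample(seq_len(K - 2L), n, replace = TRUE)
  X <- matrix(0L, n + nTransients, K)
  for (i in seq_len(n)) {
    X[i, rel[i]] <- 1L
    alive <- TRUE
    for (t in seq(rel[i] + 1L, K)) {
      if (!alive) break
      alive <- stats::runif(1) < phi[t - 1L]
      if (alive && stats::runif(1) < p[t]) X[i, t] <- 1L
    }
  }
  if (nTransients > 0L) {
    relT <- sample(seq_len(K - 2L), nTransients, replace = TRUE)
    for (i in seq_len(nTransients)) X[n + i, relT[i]] <- 1L
  }
  X[rowSums(X) > 0L, , drop = FALSE]
}

## single-sex study design with the default cohort profile rescaled to a
## total of n individuals
scaledDesign <- function(sex, n) {
  ch <- defaultStudyDesign()@cohorts
  ch <- ch[ch$sex == sex, , drop = FALSE]
  ch$n <- round(ch$n * n / sum(ch$n))
  studyDesign(10L, ch)
}

## small mixed-sex dataset for fast fitting tests
smallSimulatedDataset <- function(seed = 11, scale = 1) {
  simulateHistories(defaultStudyDesign(scale),
                    list(M = presetParameters("M"),
                         F = presetParameters("F")), seed = seed)
}
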