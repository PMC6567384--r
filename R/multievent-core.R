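## The 9-state / 11-event hidden-Markov process.
##
## States: 1 A_GPS (alive, working GPS), 2 A_GPSoff (alive, inactive GPS
## collar), 3 A_COL (alive, optical collar), 4 A_TAG (alive, ear tags only),
## 5-8 newly dead (poached/other x GPS/other marks), 9 absorbing dead.
##
## Within an annual interval the transition is decomposed as mark dynamics
## first (GPS signal loss, collar drop-off), then survival/mortality; a
## newly-dead state inherits the post-kernel mark group. The event matrix
## maps states to the observation codes 0-10 at the closing occasion.

#' Alive-state mark-transition kernel
#'
#' 4x4 annual kernel over the alive states. A working GPS loses its signal
#' with probability \code{lambdaGps[d]} (deployment-year class \code{d}) and
#' the collar drops off (reverting the animal to ear tags only) with
#' probability \code{dropOff}; drop-off takes precedence. Optical-collar and
#' ear-tag-only states are static.
#'
#' @param params a \linkS4class{ParameterSet}
#' @param deploymentClass 1 (first year after deployment) or 2 (later)
#' @return 4x4 row-stochastic matrix over (A_GPS, A_GPSoff, A_COL, A_TAG)
#' @export
buildMarkKernel <- function(params, deploymentClass) {
  l <- params@lambdaGps[deploymentClass]
  D <- params@dropOff
  K <- matrix(0, 4L, 4L, dimnames = list(.STATES[1:4], .STATES[1:4]))
  K[1L, ] <- c((1 - l) * (1 - D), l * (1 - D), 0, D)
  K[2L, ] <- c(0, 1 - D, 0, D)
  K[3L, 3L] <- 1
  K[4L, 4L] <- 1
  K
}

#' Annual state-transition matrix
#'
#' Composes the mark kernel with cause-specific mortality for one age class:
#' an animal alive in post-kernel mark state k survives with probability
#' \code{1 - mPoach[a] - mOther[a]}, is poached with probability
#' \code{mPoach[a]} (entering ND_P_GPS if k is the working-GPS state, else
#' ND_P_X), or dies of another cause analogously. Newly-dead states move to
#' the absorbing dead state; dead is absorbing.
#'
#' @param params a \linkS4class{ParameterSet}
#' @param ageClass 1-based age-class index (age at the start of the interval)
#' @param deploymentClass GPS deployment-year class (1 or 2)
#' @return 9x9 row-stochastic matrix
#' @export
buildTransition <- function(params, ageClass, deploymentClass) {
  K <- buildMarkKernel(params, deploymentClass)
  mp <- params@mPoach[ageClass]; mo <- params@mOther[ageClass]
  phi <- 1 - mp - mo
  Tm <- matrix(0, 9L, 9L, dimnames = list(.STATES, .STATES))
  for (i in 1:4) {
    Tm[i, 1:4] <- K[i, ] * phi
    gps <- K[i, 1L]; oth <- sum(K[i, 2:4])
    Tm[i, 5L] <- gps * mp; Tm[i, 6L] <- oth * mp
    Tm[i, 7L] <- gps * mo; Tm[i, 8L] <- oth * mo
  }
  Tm[5:9, 9L] <- 1
  Tm
}

#' Event (observation) matrix at one occasion
#'
#' Row-stochastic 9x11 matrix of P(code | state). Working-GPS animals are
#' detected with certainty (code 1). Collar-like live states (optical collar,
#' inactive GPS) are resighted with \code{pCollar[t]} (codes 2/4), ear-tag
#' animals with \code{pTag[t]} (code 3). Newly-dead animals are recovered
#' with probability \code{rGps} (working GPS) or \code{recovery[t]}
#' (otherwise); a recovered carcass has its cause determined with probability
#' \code{delta}, yielding the cause-specific code, and is otherwise reported
#' with an unknown-cause code (9/10). The long-dead state is never observed.
#'
#' @param params a \linkS4class{ParameterSet}
#' @param occasion 1-based occasion index
#' @return 9x11 matrix; columns are codes 0-10
#' @export
buildEventMatrix <- function(params, occasion) {
  pc <- params@pCollar[occasion]; pt <- params@pTag[occasion]
  r <- params@recovery[occasion]; rg <- params@rGps; d <- params@delta
  E <- matrix(0, 9L, 11L, dimnames = list(.STATES, as.character(0:10)))
  E[1L, 2L] <- 1                                    # A_GPS -> code 1
  E[2L, 5L] <- pc; E[2L, 1L] <- 1 - pc              # A_GPSoff -> code 4
  E[3L, 3L] <- pc; E[3L, 1L] <- 1 - pc              # A_COL -> code 2
  E[4L, 4L] <- pt; E[4L, 1L] <- 1 - pt              # A_TAG -> code 3
  E[5L, 6L] <- rg * d; E[5L, 10L] <- rg * (1 - d); E[5L, 1L] <- 1 - rg
  E[6L, 7L] <- r * d;  E[6L, 11L] <- r * (1 - d);  E[6L, 1L] <- 1 - r
  E[7L, 8L] <- rg * d; E[7L, 10L] <- rg * (1 - d); E[7L, 1L] <- 1 - rg
  E[8L, 9L] <- r * d;  E[8L, 11L] <- r * (1 - d);  E[8L, 1L] <- 1 - r
  E[9L, 1L] <- 1
  E
}

## initial latent state implied by a release code (1 -> A_GPS, 2 -> A_COL,
## 3 -> A_TAG)
.initialState <- function(releaseCode) {
  s <- c(`1` = 1L, `2` = 3L, `3` = 4L)[as.character(releaseCode)]
  if (anyNA(s)) stop("release code must be in {1,2,3}")
  unname(s)
}

## mark type (1 gps, 2 collar, 3 tag) of a release code
.initialMark <- function(releaseCode)
  unname(c(`1` = 1L, `2` = 2L, `3` = 3L)[as.character(releaseCode)])

#' Forward-algorithm log-likelihood of one history (reference implementation)
#'
#' Scaled forward recursion over the latent states, conditioned on the
#' release: the marking occasion contributes the initial-state proportion
#' when \code{initProp} is being modelled (log pi of the released mark type)
#' and zero otherwise. Age class advances one year per occasion; GPS
#' deployment age is tracked from the marking occasion. Kept in plain R as
#' the readable counterpart of the compiled dataset likelihood.
#'
#' @param events integer code vector over all occasions
#' @param markingOccasion 1-based release occasion
#' @param ageAtMarking age (years) at release
#' @param params a \linkS4class{ParameterSet}
#' @param useInit add the log initial-proportion term (default FALSE)
#' @return log-likelihood contribution; \code{-Inf} if the history has zero
#'   probability under \code{params}
#' @export
historyLogLik <- function(events, markingOccasion, ageAtMarking, params,
                          useInit = FALSE) {
  t0 <- as.integer(markingOccasion)
  nOcc <- length(events)
  s0 <- .initialState(events[t0])
  alpha <- numeric(9L); alpha[s0] <- 1
  ll <- if (useInit) log(params@initProp[.initialMark(events[t0])]) else 0
  if (t0 >= nOcc) return(ll)
  for (t in seq(t0 + 1L, nOcc)) {
    age <- ageAtMarking + (t - 1L - t0)
    ac <- ageClassOf(params@agePartition, age)
    d <- min(t - t0, 2L)
    Tm <- buildTransition(params, ac, d)
    E <- buildEventMatrix(params, t)
    alpha <- as.numeric(crossprod(Tm, alpha)) * E[, events[t] + 1L]
    s <- sum(alpha)
    if (s <= 0) return(-Inf)
    alpha <- alpha / s
    ll <- ll + log(s)
  }
  ll
}

## Precompute the data-side structures the compiled forward pass needs.
## Identical histories (same release occasion, age and code sequence) are
## aggregated with multiplicity weights.
.prepLikData <- function(x, structure) {
  stopifnot(is(x, "EncounterHistories"))
  sel <- sexOf(x) == structure@sex
  if (!any(sel)) stop("no individuals of sex ", structure@sex)
  ev <- eventCodes(x)[sel, , drop = FALSE]
  t0 <- markingOccasion(x)[sel]
  age0 <- ageAtMarking(x)[sel]
  nOcc <- ncol(ev)
  key <- paste(t0, age0, apply(ev, 1L, paste, collapse = "."))
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  ev <- ev[first, , drop = FALSE]; t0 <- t0[first]; age0 <- age0[first]
  n <- nrow(ev)
  ap <- structure@agePartition
  A <- nClasses(ap)
  ## transition-slice index for the interval ending at occasion t:
  ## (ageClass - 1) * 2 + deploymentClass
  tmIdx <- matrix(0L, n, nOcc)
  for (i in seq_len(n)) {
    if (t0[i] >= nOcc) next
    tt <- seq(t0[i] + 1L, nOcc)
    ac <- ageClassOf(ap, age0[i] + (tt - 1L - t0[i]))
    d <- pmin(tt - t0[i], 2L)
    tmIdx[i, tt] <- (ac - 1L) * 2L + d
  }
  s0 <- vapply(seq_len(n), function(i) .initialState(ev[i, t0[i]]), 1L)
  mark0 <- vapply(seq_len(n), function(i) .initialMark(ev[i, t0[i]]), 1L)
  list(events = ev, t0 = as.integer(t0), s0 = s0, mark0 = mark0,
       age0 = as.integer(age0), tmIdx = tmIdx, w = w, nOcc = nOcc, A = A,
       ids = rownames(eventCodes(x))[sel][first],
       nIndividuals = sum(sel))
}

## Build the transition cube (transposed slices, for left-multiplication)
## and the emission cube for a parameter set.
.likCubes <- function(params, nOcc) {
  A <- nClasses(params@agePartition)
  trans <- array(0, c(9L, 9L, A * 2L))
  for (a in seq_len(A)) for (d in 1:2)
    trans[, , (a - 1L) * 2L + d] <- t(buildTransition(params, a, d))
  emit <- array(0, c(9L, 11L, nOcc))
  for (t in seq_len(nOcc)) emit[, , t] <- buildEventMatrix(params, t)
  list(trans = trans, emit = emit)
}

#' Dataset log-likelihood and deviance
#'
#' Sums the forward-algorithm contributions of all histories of the
#' structure's sex under the parameters implied by \code{theta}. Computed in
#' compiled code; identical histories are aggregated.
#'
#' @param x an \linkS4class{EncounterHistories}
#' @param theta link-scale free-parameter vector (see
#'   \code{\link{buildParameterIndex}})
#' @param structure a \linkS4class{ModelStructure}
#' @return list: \code{logLik}, \code{deviance} (-2 logLik), and (when the
#'   likelihood is degenerate) \code{zeroProbIds}, the offending individuals
#' @export
datasetLogLik <- function(x, theta, structure) {
  prep <- .prepLikData(x, structure)
  params <- inflate(theta, structure, prep$nOcc)
  out <- .forwardCore(prep, params, structure@estimateInit)
  bad <- which(!is.finite(out$perHistory))
  list(logLik = out$logLik, deviance = -2 * out$logLik,
       zeroProbIds = if (length(bad)) prep$ids[bad] else character(0))
}

## shared driver: prep + params -> compiled forward pass
.forwardCore <- function(prep, params, useInit) {
  cubes <- .likCubes(params, prep$nOcc)
  logInit <- if (useInit) log(params@initProp)[prep$mark0]
             else numeric(nrow(prep$events))
  cppForwardLogLik(cubes$trans, cubes$emit, prep$events, prep$t0, prep$s0,
                   prep$tmIdx, prep$w, logInit)
}
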