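#' Define a candidate model structure
#'
#' @param sex "M" or "F"
#' @param ages age-partition specification string or
#'   \linkS4class{AgePartition}
#' @param mortality "interactive", "additive" or "constant_poach"
#' @param resight "constant", "by_mark", "by_time", "mark_plus_time" or
#'   "mark_by_time"
#' @param recovery "constant" or "by_time"
#' @param estimateInit estimate initial mark-type proportions (default TRUE)
#' @param rGps fixed recovery probability of working-GPS deaths (default 1)
#' @param label optional model label
#' @return a \linkS4class{ModelStructure}
#' @examples
#' modelStructure("F", "1,2:7,8+", mortality = "constant_poach",
#'                resight = "by_time")
#' @export
modelStructure <- function(sex, ages, mortality = "interactive",
                           resight = "constant", recovery = "constant",
                           estimateInit = TRUE, rGps = 1, label = NULL) {
  ap <- if (is(ages, "AgePartition")) ages else agePartition(ages)
  if (is.null(label))
    label <- paste0(sex, ":", mortality, "/", resight, "/", recovery,
                    "/A(", ap@spec, ")")
  new("ModelStructure", label = label, sex = sex, agePartition = ap,
      mortality = mortality, resight = resight, recovery = recovery,
      estimateInit = estimateInit, rGps = rGps)
}

setMethod("show", "ModelStructure", function(object) {
  cat("ModelStructure", object@label, "\n")
  cat("  mortality:", object@mortality, " ages:", object@agePartition@spec,
      "\n  resight:", object@resight, " recovery:", object@recovery,
      " init:", if (object@estimateInit) "estimated" else "conditioned", "\n")
})

#' Free-parameter index of a model structure
#'
#' Enumerates, in their fixed order, the link-scale free parameters implied
#' by a structure over a given occasion span. Blocks: mortality (multinomial
#' logit), GPS signal loss (2 deployment-year logits), drop-off, resighting,
#' recovery, cause determination, and (optionally) initial mark proportions.
#' Resighting and recovery time effects are indexed by occasions 2..T.
#'
#' @param structure a \linkS4class{ModelStructure}
#' @param nOccasions number of annual occasions in the data
#' @return data.frame with columns \code{block}, \code{name}, \code{link};
#'   one row per free parameter, in vector order
#' @export
buildParameterIndex <- function(structure, nOccasions) {
  A <- nClasses(structure@agePartition)
  lab <- classLabels(structure@agePartition)
  occ <- seq(2L, nOccasions)
  rows <- list()
  add <- function(block, name, link = "logit")
    rows[[length(rows) + 1L]] <<- data.frame(block = block, name = name,
                                             link = link)
  switch(structure@mortality,
    interactive = for (a in seq_len(A)) {
      add("mortality", paste0("etaPoach[", lab[a], "]"), "mlogit")
      add("mortality", paste0("etaOther[", lab[a], "]"), "mlogit")
    },
    additive = {
      for (a in seq_len(A)) add("mortality", paste0("etaAge[", lab[a], "]"),
                                "mlogit")
      add("mortality", "etaPoachOffset", "mlogit")
    },
    constant_poach = {
      add("mortality", "etaPoach", "mlogit")
      for (a in seq_len(A)) add("mortality", paste0("etaOther[", lab[a], "]"),
                                "mlogit")
    })
  add("gpsLoss", "lambda[1st]"); add("gpsLoss", "lambda[2nd+]")
  add("dropOff", "D")
  switch(structure@resight,
    constant = add("resight", "p"),
    by_mark = { add("resight", "p[collar]"); add("resight", "p[tag]") },
    by_time = for (t in occ) add("resight", paste0("p[t", t, "]")),
    mark_plus_time = {
      for (t in occ) add("resight", paste0("p[t", t, "]"))
      add("resight", "p[tagOffset]")
    },
    mark_by_time = {
      for (t in occ) add("resight", paste0("p[collar,t", t, "]"))
      for (t in occ) add("resight", paste0("p[tag,t", t, "]"))
    })
  switch(structure@recovery,
    constant = add("recovery", "r"),
    by_time = for (t in occ) add("recovery", paste0("r[t", t, "]")))
  add("delta", "delta")
  if (structure@estimateInit) {
    add("init", "pi[gps]", "mlogit")
    add("init", "pi[collar]", "mlogit")
  }
  do.call(rbind, rows)
}

## free-parameter count without materializing the index (hot path)
.nParams <- function(structure, nOccasions) {
  A <- nClasses(structure@agePartition)
  nt <- nOccasions - 1L
  k <- switch(structure@mortality, interactive = 2L * A, additive = A + 1L,
              constant_poach = 1L + A)
  k <- k + 3L  # lambda (2) + dropOff
  k <- k + switch(structure@resight, constant = 1L, by_mark = 2L,
                  by_time = nt, mark_plus_time = nt + 1L,
                  mark_by_time = 2L * nt)
  k <- k + switch(structure@recovery, constant = 1L, by_time = nt)
  k <- k + 1L  # delta
  if (structure@estimateInit) k <- k + 2L
  k
}

#' Construct a real-scale parameter set directly
#'
#' @param ages partition spec or \linkS4class{AgePartition}
#' @param mPoach,mOther per-age-class annual mortality probabilities
#' @param lambdaGps length-2 GPS signal-loss probabilities (deployment year
#'   1, 2+)
#' @param dropOff annual collar drop-off probability
#' @param pCollar,pTag resighting probabilities; scalars are recycled over
#'   occasions 2..nOccasions (occasion 1 is structurally 0)
#' @param recovery recovery probability; scalar recycled likewise
#' @param rGps recovery probability of working-GPS deaths
#' @param delta cause-determination probability
#' @param initProp initial mark proportions (gps, collar, tag)
#' @param nOccasions occasion span
#' @return a \linkS4class{ParameterSet}
#' @export
parameterSet <- function(ages, mPoach, mOther, lambdaGps, dropOff,
                         pCollar, pTag, recovery, rGps = 1, delta,
                         initProp = c(1, 1, 1) / 3, nOccasions = 10L) {
  ap <- if (is(ages, "AgePartition")) ages else agePartition(ages)
  expand <- function(v) {
    if (length(v) == nOccasions) return(as.numeric(v))
    stopifnot(length(v) == 1L)
    c(0, rep(as.numeric(v), nOccasions - 1L))
  }
  new("ParameterSet", agePartition = ap, mPoach = as.numeric(mPoach),
      mOther = as.numeric(mOther), lambdaGps = as.numeric(lambdaGps),
      dropOff = as.numeric(dropOff), pCollar = expand(pCollar),
      pTag = expand(pTag), recovery = expand(recovery),
      rGps = as.numeric(rGps), delta = as.numeric(delta),
      initProp = as.numeric(initProp) / sum(initProp))
}

#' @rdname nOccasions
#' @export
setMethod("nOccasions", "ParameterSet", function(x) length(x@pCollar))

setMethod("show", "ParameterSet", function(object) {
  lab <- classLabels(object@agePartition)
  cat("ParameterSet over", nOccasions(object), "occasions\n")
  m <- rbind(poach = object@mPoach, other = object@mOther,
             survival = 1 - object@mPoach - object@mOther)
  colnames(m) <- lab
  print(round(m, 3))
  cat(sprintf("  lambdaGps = (%.3f, %.3f)  dropOff = %.3f  delta = %.3f\n",
              object@lambdaGps[1], object@lambdaGps[2], object@dropOff,
              object@delta))
  cat(sprintf("  mean resight: collar %.3f, tag %.3f; mean recovery %.3f (rGps = %.2f)\n",
              mean(object@pCollar[-1L]), mean(object@pTag[-1L]),
              mean(object@recovery[-1L]), object@rGps))
})

#' Map a free-parameter vector to real-scale probabilities
#'
#' The inverse-link transform: binomial parameters through the inverse
#' logit, each age class's (poach, other, survive) triple through the
#' inverse multinomial logit with survival as reference. Every finite vector
#' maps into the valid probability region.
#'
#' @param theta numeric vector ordered as in
#'   \code{\link{buildParameterIndex}}
#' @param structure a \linkS4class{ModelStructure}
#' @param nOccasions occasion span
#' @return a \linkS4class{ParameterSet}
#' @export
inflate <- function(theta, structure, nOccasions) {
  nExpected <- .nParams(structure, nOccasions)
  if (length(theta) != nExpected)
    stop("theta has length ", length(theta), ", structure needs ", nExpected)
  if (!all(is.finite(theta))) stop("theta must be finite")
  A <- nClasses(structure@agePartition)
  pos <- 0L
  take <- function(k) {
    out <- theta[pos + seq_len(k)]; pos <<- pos + k; out
  }
  eta <- switch(structure@mortality,
    interactive = {
      v <- take(2L * A)
      cbind(etaP = v[seq(1L, 2L * A, 2L)], etaO = v[seq(2L, 2L * A, 2L)])
    },
    additive = {
      alpha <- take(A); kappa <- take(1L)
      cbind(etaP = alpha + kappa, etaO = alpha)
    },
    constant_poach = {
      ep <- take(1L); eo <- take(A)
      cbind(etaP = rep(ep, A), etaO = eo)
    })
  m <- mlogitInv(eta[, 1L], eta[, 2L])
  lambda <- invLogit(take(2L))
  D <- invLogit(take(1L))
  occ <- seq(2L, nOccasions)
  pCollar <- pTag <- numeric(nOccasions)
  switch(structure@resight,
    constant = { p <- invLogit(take(1L)); pCollar[occ] <- pTag[occ] <- p },
    by_mark = {
      pCollar[occ] <- invLogit(take(1L)); pTag[occ] <- invLogit(take(1L))
    },
    by_time = {
      p <- invLogit(take(length(occ))); pCollar[occ] <- pTag[occ] <- p
    },
    mark_plus_time = {
      b <- take(length(occ)); off <- take(1L)
      pCollar[occ] <- invLogit(b); pTag[occ] <- invLogit(b + off)
    },
    mark_by_time = {
      pCollar[occ] <- invLogit(take(length(occ)))
      pTag[occ] <- invLogit(take(length(occ)))
    })
  r <- numeric(nOccasions)
  switch(structure@recovery,
    constant = r[occ] <- invLogit(take(1L)),
    by_time = r[occ] <- invLogit(take(length(occ))))
  delta <- invLogit(take(1L))
  initProp <- c(1, 1, 1) / 3
  if (structure@estimateInit) {
    ## softmax over (gps, collar, tag = reference)
    g <- take(2L)
    v <- exp(c(g, 0) - max(c(g, 0)))
    initProp <- v / sum(v)
  }
  stopifnot(pos == nExpected)
  new("ParameterSet", agePartition = structure@agePartition,
      mPoach = unname(m[, "poach"]), mOther = unname(m[, "other"]),
      lambdaGps = unname(lambda), dropOff = unname(D), pCollar = pCollar,
      pTag = pTag, recovery = r, rGps = structure@rGps,
      delta = unname(delta), initProp = unname(initProp))
}

#' Project a parameter set back onto a structure's link scale
#'
#' Exact inverse of \code{\link{inflate}} for parameter sets lying in the
#' image of the structure (probabilities strictly inside (0,1); for the
#' additive structure, a constant poach/other log-odds gap across classes).
#' Boundary probabilities are clamped at \code{eps} before linking.
#'
#' @param params a \linkS4class{ParameterSet}
#' @param structure a \linkS4class{ModelStructure}
#' @param eps clamping tolerance for boundary probabilities
#' @return named numeric vector theta
#' @export
deflate <- function(params, structure, eps = 1e-6) {
  nOcc <- nOccasions(params)
  A <- nClasses(structure@agePartition)
  stopifnot(nClasses(params@agePartition) == A)
  mP <- .clampP(params@mPoach, eps); mO <- .clampP(params@mOther, eps)
  eta <- mlogitLink(mP, mO)
  th <- switch(structure@mortality,
    interactive = as.numeric(t(eta)),
    additive = c(eta[, "etaO"], mean(eta[, "etaP"] - eta[, "etaO"])),
    constant_poach = c(mean(eta[, "etaP"]), eta[, "etaO"]))
  occ <- seq(2L, nOcc)
  lg <- function(p) logit(.clampP(p, eps))
  th <- c(th, lg(params@lambdaGps), lg(params@dropOff))
  th <- c(th, switch(structure@resight,
    constant = lg(mean(params@pCollar[occ])),
    by_mark = c(lg(params@pCollar[occ][1L]), lg(params@pTag[occ][1L])),
    by_time = lg(params@pCollar[occ]),
    mark_plus_time = c(lg(params@pCollar[occ]),
                       mean(lg(params@pTag[occ]) - lg(params@pCollar[occ]))),
    mark_by_time = c(lg(params@pCollar[occ]), lg(params@pTag[occ]))))
  th <- c(th, switch(structure@recovery,
    constant = lg(params@recovery[occ][1L]),
    by_time = lg(params@recovery[occ])))
  th <- c(th, lg(params@delta))
  if (structure@estimateInit) {
    ip <- pmax(params@initProp, eps)
    th <- c(th, log(ip[1L] / ip[3L]), log(ip[2L] / ip[3L]))
  }
  idx <- buildParameterIndex(structure, nOcc)
  stats::setNames(th, idx$name)
}
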