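#' Effective sample size of a dataset
#'
#' Total number of non-zero event codes (releases, resightings and
#' recoveries) across the histories, the sample-size notion used in the AICc
#' correction. Computed per sex when \code{sex} is given.
#'
#' @param x an \linkS4class{EncounterHistories}
#' @param sex optional "M"/"F" restriction
#' @return integer
#' @export
essOf <- function(x, sex = NULL) {
  stopifnot(is(x, "EncounterHistories"))
  ev <- eventCodes(x)
  if (!is.null(sex)) ev <- ev[sexOf(x) == sex, , drop = FALSE]
  sum(ev != 0L)
}

#' Small-sample-corrected AIC
#'
#' \code{aicc = deviance + 2 np + 2 np (np + 1) / (ess - np - 1)}.
#'
#' @param deviance -2 maximized log-likelihood
#' @param np number of identifiable parameters
#' @param ess effective sample size (must exceed np + 1)
#' @return numeric
#' @examples
#' computeAICc(533.24, 13, 140)  # 562.13
#' @export
computeAICc <- function(deviance, np, ess) {
  if (ess <= np + 1)
    stop("effective sample size must exceed np + 1")
  deviance + 2 * np + 2 * np * (np + 1) / (ess - np - 1)
}

#' Wald confidence interval on a link scale
#'
#' \code{estimate +/- 1.96 se} on the link scale, back-transformed; for the
#' logit link the interval is asymmetric on the probability scale and always
#' inside [0,1].
#'
#' @param estimate link-scale estimate
#' @param se link-scale standard error
#' @param link "logit" or "identity"
#' @return numeric length-2 vector (lower, upper)
#' @export
waldInterval <- function(estimate, se, link = c("logit", "identity")) {
  link <- match.arg(link)
  ci <- estimate + c(-1, 1) * 1.96 * se
  if (link == "logit") ci <- invLogit(ci)
  ci
}

#' Count numerically identifiable parameters
#'
#' Rank of the observed information at the optimum: the number of singular
#' values of the Hessian exceeding \code{threshold} times the largest.
#'
#' @param hessian Hessian of the negative log-likelihood at the MLE
#' @param threshold relative singular-value cutoff (default 1e-6)
#' @return integer
#' @export
numericalNp <- function(hessian, threshold = 1e-6) {
  sv <- svd(hessian)$d
  if (!length(sv) || max(sv) <= 0) return(0L)
  sum(sv > threshold * max(sv))
}

## Moore-Penrose pseudo-inverse (for singular information matrices)
.ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Named real-scale parameter vector reported for a fit; the mortality block
## is always expanded per age class so models with coarser effect structures
## (e.g. age-constant poaching) remain comparable and averageable.
.realParams <- function(params, structure) {
  lab <- classLabels(structure@agePartition)
  nOcc <- nOccasions(params)
  occ <- seq(2L, nOcc)
  out <- c(
    stats::setNames(params@mPoach, paste0("mPoach[", lab, "]")),
    stats::setNames(params@mOther, paste0("mOther[", lab, "]")),
    stats::setNames(1 - params@mPoach - params@mOther,
                    paste0("phi[", lab, "]")),
    "lambda[1st]" = params@lambdaGps[1L],
    "lambda[2nd+]" = params@lambdaGps[2L],
    "D" = params@dropOff)
  out <- c(out, switch(structure@resight,
    constant = c("p" = params@pCollar[2L]),
    by_mark = c("p[collar]" = params@pCollar[2L],
                "p[tag]" = params@pTag[2L]),
    {
      c(stats::setNames(params@pCollar[occ], paste0("p[collar,t", occ, "]")),
        stats::setNames(params@pTag[occ], paste0("p[tag,t", occ, "]")))
    }))
  out <- c(out, switch(structure@recovery,
    constant = c("r" = params@recovery[2L]),
    by_time = stats::setNames(params@recovery[occ], paste0("r[t", occ, "]"))))
  out <- c(out, "delta" = params@delta)
  if (structure@estimateInit)
    out <- c(out, stats::setNames(params@initProp,
                                  paste0("pi[", .MARK_TYPES, "]")))
  out
}

## central-difference Jacobian of theta -> realParams
.realJacobian <- function(theta, structure, nOcc, h = 1e-5) {
  f <- function(th) .realParams(inflate(th, structure, nOcc), structure)
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta),
              dimnames = list(names(f0), names(theta)))
  for (j in seq_along(theta)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  J
}

#' Fit one candidate model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of the multievent likelihood from one
#' null (all-zero) start plus \code{nStarts} seeded random starts (the
#' likelihood can be multimodal); the best optimum is kept. Standard errors
#' come from the inverse observed information on the link scale, transformed
#' to the probability scale by the delta method; parameters estimated at a
#' boundary are flagged and reported without SE. The identifiable-parameter
#' count is the numerical rank of the Hessian.
#'
#' @param x an \linkS4class{EncounterHistories} (individuals of the
#'   structure's sex are selected automatically)
#' @param structure a \linkS4class{ModelStructure}
#' @param nStarts number of random initial vectors (default 10)
#' @param seed RNG seed for the random starts
#' @param init optional extra starting vector(s): a numeric vector or a list
#'   of them (e.g. a previous optimum, or \code{deflate} of known values)
#' @param control passed to \code{\link[stats]{optim}} (maxit, reltol)
#' @param npThreshold relative singular-value cutoff for
#'   \code{\link{numericalNp}}
#' @return a \linkS4class{MultieventFit}
#' @export
fitModel <- function(x, structure, nStarts = 10L, seed = 1L, init = NULL,
                     control = list(), npThreshold = 1e-6) {
  prep <- .prepLikData(x, structure)
  idx <- buildParameterIndex(structure, prep$nOcc)
  k <- nrow(idx)
  nll <- function(theta) {
    out <- .forwardCore(prep, inflate(theta, structure, prep$nOcc),
                        structure@estimateInit)
    if (!is.finite(out$logLik)) 1e10 else -out$logLik
  }
  starts <- list(rep(0, k))
  if (!is.null(init)) {
    if (is.numeric(init)) init <- list(init)
    starts <- c(starts, lapply(init, function(v) {
      stopifnot(length(v) == k); as.numeric(v)
    }))
  }
  if (nStarts > 0L) {
    set.seed(seed)
    starts <- c(starts, lapply(seq_len(nStarts),
                               function(i) stats::rnorm(k, 0, 1.5)))
  }
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  runs <- lapply(starts, function(s)
    tryCatch(stats::optim(s, nll, method = "BFGS", control = ctl),
             error = function(e) list(value = Inf, convergence = 99L,
                                      message = conditionMessage(e))))
  vals <- vapply(runs, function(r) r$value, 1.0)
  if (!any(is.finite(vals)) || min(vals) >= 1e10)
    stop("no start converged to a finite optimum; start values: ",
         paste(signif(vals, 6), collapse = ", "))
  best <- runs[[which.min(vals)]]
  theta <- stats::setNames(best$par, idx$name)
  logL <- -best$value
  H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
  np <- if (is.null(H)) k else numericalNp(H, npThreshold)
  V <- if (is.null(H)) matrix(NA_real_, k, k) else .ginv(H)
  params <- inflate(theta, structure, prep$nOcc)
  real <- .realParams(params, structure)
  J <- .realJacobian(theta, structure, prep$nOcc)
  seReal <- if (is.null(H)) rep(NA_real_, length(real))
            else sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  boundaryTol <- 1e-4
  onBoundary <- real < boundaryTol | real > 1 - boundaryTol
  est <- data.frame(parameter = names(real), estimate = unname(real),
                    se = unname(seReal), lcl = NA_real_, ucl = NA_real_,
                    boundary = unname(onBoundary),
                    stringsAsFactors = FALSE)
  usable <- !onBoundary & is.finite(seReal) & seReal > 0
  for (i in which(usable)) {
    seLink <- est$se[i] / (est$estimate[i] * (1 - est$estimate[i]))
    ci <- waldInterval(logit(est$estimate[i]), seLink, "logit")
    est$lcl[i] <- ci[1L]; est$ucl[i] <- ci[2L]
  }
  est$se[onBoundary] <- NA_real_
  ess <- sum(prep$w * rowSums(prep$events != 0L))
  fit <- new("MultieventFit", structure = structure, theta = theta,
    logLik = logL, deviance = -2 * logL, np = as.integer(np),
    ess = as.integer(ess),
    aicc = computeAICc(-2 * logL, np, ess),
    vcov = if (is.null(H)) matrix(NA_real_, k, k) else V,
    estimates = est, converged = best$convergence == 0L,
    boundary = names(real)[onBoundary],
    nStarts = as.integer(nStarts), seed = as.integer(seed),
    details = list(startValues = vals,
                   fingerprint = c(n = prep$nIndividuals, nOcc = prep$nOcc,
                                   ess = ess,
                                   evSum = sum(prep$w * rowSums(prep$events))),
                   hessianOk = !is.null(H)))
  fit
}

#' @rdname estimates
#' @export
setMethod("estimates", "MultieventFit", function(x) x@estimates)

#' @rdname aicc
#' @export
setMethod("aicc", "MultieventFit", function(x) x@aicc)

#' @rdname devianceOf
#' @export
setMethod("devianceOf", "MultieventFit", function(x) x@deviance)

setMethod("show", "MultieventFit", function(object) {
  cat("MultieventFit:", object@structure@label, "\n")
  cat(sprintf("  deviance %.2f  np %d  ess %d  AICc %.2f  converged: %s\n",
              object@deviance, object@np, object@ess, object@aicc,
              object@converged))
  if (length(object@boundary))
    cat("  boundary estimates:", paste(object@boundary, collapse = ", "),
        "\n")
  mort <- object@estimates[grepl("^(mPoach|mOther|phi)\\[",
                                 object@estimates$parameter), ]
  print(mort, row.names = FALSE, digits = 3)
})
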