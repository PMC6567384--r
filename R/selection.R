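#' Akaike weights
#'
#' \code{w_j = exp(-Delta_j / 2) / sum_k exp(-Delta_k / 2)} with
#' \code{Delta_j = AICc_j - min(AICc)}. Invariant to adding a constant to all
#' values, so printed Delta-AICc columns can be passed directly.
#'
#' @param aicc numeric vector of AICc (or Delta-AICc) values
#' @return numeric weights summing to 1
#' @examples
#' round(akaikeWeights(c(0, 0.19, 2.98)), 3)
#' @export
akaikeWeights <- function(aicc) {
  stopifnot(length(aicc) >= 1L, all(is.finite(aicc)))
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Build an AICc model-comparison table
#'
#' Rows are sorted by AICc. Delta-AICc is relative to the best model in the
#' table; Akaike weights are normalized only over the designated candidate
#' set (the hypothesis-driven models), other rows get \code{NA}.
#'
#' @param fits named list of \linkS4class{MultieventFit} objects on the same
#'   data
#' @param candidates names of the fits forming the candidate set for weights
#'   (default: all)
#' @param hypotheses optional named character vector of hypothesis labels
#' @return a \linkS4class{ModelTable}
#' @export
buildModelTable <- function(fits, candidates = names(fits),
                            hypotheses = NULL) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)),
            all(candidates %in% names(fits)))
  fps <- lapply(fits, function(f) f@details$fingerprint)
  if (length(unique(vapply(fps, paste, "", collapse = "/"))) != 1L)
    stop("fits were not computed on identical data")
  tab <- data.frame(
    model = names(fits),
    mortality = vapply(fits, function(f) f@structure@mortality, ""),
    resight = vapply(fits, function(f) f@structure@resight, ""),
    recovery = vapply(fits, function(f) f@structure@recovery, ""),
    np = vapply(fits, function(f) f@np, 1L),
    deviance = vapply(fits, function(f) f@deviance, 1.0),
    aicc = vapply(fits, function(f) f@aicc, 1.0),
    stringsAsFactors = FALSE)
  tab$dAicc <- tab$aicc - min(tab$aicc)
  tab$weight <- NA_real_
  cand <- tab$model %in% candidates
  tab$weight[cand] <- akaikeWeights(tab$aicc[cand])
  tab$hypothesis <- if (is.null(hypotheses)) NA_character_
                    else unname(hypotheses[tab$model])
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  new("ModelTable", table = tab, candidates = candidates)
}

setMethod("show", "ModelTable", function(object) {
  cat("ModelTable (weights over:", paste(object@candidates, collapse = ", "),
      ")\n")
  tab <- object@table
  tab$deviance <- round(tab$deviance, 2)
  tab$aicc <- round(tab$aicc, 2)
  tab$dAicc <- round(tab$dAicc, 2)
  tab$weight <- round(tab$weight, 3)
  print(tab, row.names = FALSE)
})

#' Model-averaged estimates
#'
#' Weighted average of real-scale estimates across candidate models with the
#' Burnham-Anderson unconditional standard error
#' \code{SE = sum_j w_j sqrt(var_j + (theta_j - thetaBar)^2)}; 95\% CIs by
#' logit-scale Wald on the averaged value. Mortality estimates are always
#' reported per age class of the (shared) partition, so structures with
#' coarser effects average seamlessly.
#'
#' @param fits list of \linkS4class{MultieventFit} objects (the candidate
#'   set)
#' @param weights Akaike weights, same length and order; normalized to sum
#'   to 1
#' @param parameters which parameters to average (default: all shared)
#' @return data.frame: parameter, estimate, se, lcl, ucl
#' @export
modelAverage <- function(fits, weights, parameters = NULL) {
  stopifnot(length(fits) == length(weights), all(weights >= 0))
  weights <- weights / sum(weights)
  tabs <- lapply(fits, estimates)
  shared <- Reduce(intersect, lapply(tabs, function(t) t$parameter))
  if (is.null(parameters)) parameters <- shared
  miss <- setdiff(parameters, shared)
  if (length(miss)) {
    offender <- which(!vapply(tabs, function(t) miss[1L] %in% t$parameter,
                              TRUE))[1L]
    stop("parameter '", miss[1L], "' missing in model ",
         names(fits)[offender] %||% offender)
  }
  out <- lapply(parameters, function(pn) {
    e <- vapply(tabs, function(t) t$estimate[t$parameter == pn], 1.0)
    s <- vapply(tabs, function(t) t$se[t$parameter == pn], 1.0)
    bar <- sum(weights * e)
    s2 <- ifelse(is.finite(s), s^2, 0)  # boundary params: conditional var 0
    use <- sum(weights * sqrt(s2 + (e - bar)^2))
    lcl <- ucl <- NA_real_
    if (use > 0 && bar > 1e-8 && bar < 1 - 1e-8) {
      ci <- waldInterval(logit(bar), use / (bar * (1 - bar)), "logit")
      lcl <- ci[1L]; ucl <- ci[2L]
    }
    data.frame(parameter = pn, estimate = bar, se = use, lcl = lcl,
               ucl = ucl, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Relative poaching mortality
#'
#' The fraction of total annual mortality attributable to poaching,
#' \code{mPoach / (mPoach + mOther)}, per age class, from an averaged (or
#' single-model) estimates table.
#'
#' @param avg data.frame from \code{\link{modelAverage}} or
#'   \code{\link{estimates}}
#' @return data.frame: ageClass, mPoach, mOther, relPoach
#' @export
relativePoachingMortality <- function(avg) {
  mp <- avg[grepl("^mPoach\\[", avg$parameter), ]
  mo <- avg[grepl("^mOther\\[", avg$parameter), ]
  cls <- sub("^mPoach\\[(.*)\\]$", "\\1", mp$parameter)
  stopifnot(identical(cls, sub("^mOther\\[(.*)\\]$", "\\1", mo$parameter)))
  data.frame(ageClass = cls, mPoach = mp$estimate, mOther = mo$estimate,
             relPoach = mp$estimate / (mp$estimate + mo$estimate),
             stringsAsFactors = FALSE)
}
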