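## S4 classes for the multievent poaching-mortality framework.
##
## Latent states (9): four alive states distinguished by mark status, four
## newly-dead states distinguished by cause x GPS status, one absorbing dead
## state. Events (11): the observation codes 0-10 recorded in encounter
## histories.

#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

## state indices -- internal constants
.STATES <- c("A_GPS", "A_GPSoff", "A_COL", "A_TAG",
             "ND_P_GPS", "ND_P_X", "ND_O_GPS", "ND_O_X", "DEAD")
.N_STATES <- 9L
.N_EVENTS <- 11L

## event code semantics (code = column index - 1)
.EVENT_LABELS <- c(
  "0" = "not observed",
  "1" = "alive, working GPS",
  "2" = "alive, optical collar",
  "3" = "alive, ear tags",
  "4" = "alive, inactive GPS collar",
  "5" = "dead, poached, working GPS",
  "6" = "dead, poached, other marks",
  "7" = "dead, other cause, working GPS",
  "8" = "dead, other cause, other marks",
  "9" = "dead, unknown cause, working GPS",
  "10" = "dead, unknown cause, other marks")

.LIVE_CODES <- 1:4
.DEAD_CODES <- 5:10
.POACH_CODES <- 5:6
.OTHER_CODES <- 7:8
.UNKNOWN_CODES <- 9:10
.MARK_TYPES <- c("gps", "collar", "tag")

#' Age partition
#'
#' Ordered, contiguous age classes covering all ages >= 1 year, the last one
#' open-ended, written in the compact form \code{"1,2:7,8+"}.
#'
#' @slot spec character, the compact specification string
#' @slot lower integer, lower bound (years) of each class
#' @slot upper integer, upper bound of each class; \code{NA} for the final
#'   open-ended class
#' @seealso \code{\link{agePartition}}
#' @export
setClass("AgePartition",
  representation(spec = "character", lower = "integer", upper = "integer"))

setValidity("AgePartition", function(object) {
  lo <- object@lower; up <- object@upper
  if (length(lo) == 0L) return("partition has no classes")
  if (length(lo) != length(up)) return("lower/upper length mismatch")
  if (lo[1L] != 1L) return("first class must start at age 1")
  k <- length(lo)
  if (!is.na(up[k])) return("last class must be open-ended")
  if (k > 1L && anyNA(up[-k])) return("only the last class may be open-ended")
  if (k > 1L) {
    if (any(up[-k] < lo[-k])) return("a class has upper < lower")
    if (any(lo[-1L] != up[-k] + 1L)) return("classes must be contiguous")
  }
  TRUE
})

#' Encounter histories of marked individuals
#'
#' A \linkS4class{SummarizedExperiment} with one row per individual and one
#' column per annual occasion. The single assay \code{"events"} holds the
#' observation codes 0-10; occasions before an individual's marking occasion
#' are structurally 0. Row metadata carries \code{sex} ("M"/"F"),
#' \code{ageAtMarking} (years) and \code{markingOccasion} (1-based column
#' index of the release).
#'
#' Per-individual coding rules (enforced by the validity method):
#' the marking-occasion code is a release code in \{1,2,3\}; at most one dead
#' code (5-10) appears and every later code is 0; a working-GPS code (1) never
#' follows a non-GPS live code (2,3,4).
#'
#' @seealso \code{\link{encounterHistories}}, \code{\link{validateHistory}}
#' @export
setClass("EncounterHistories", contains = "SummarizedExperiment")

setValidity("EncounterHistories", function(object) {
  if (!"events" %in% SummarizedExperiment::assayNames(object))
    return("assay 'events' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("sex", "ageAtMarking", "markingOccasion")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain:", paste(need, collapse = ", ")))
  ev <- SummarizedExperiment::assay(object, "events")
  if (!all(ev %in% 0:10)) return("event codes must be integers in 0..10")
  if (!all(rd$sex %in% c("M", "F"))) return("sex must be 'M' or 'F'")
  if (any(rd$ageAtMarking < 1L)) return("ageAtMarking must be >= 1")
  if (any(rd$markingOccasion < 1L | rd$markingOccasion > ncol(ev)))
    return("markingOccasion out of range")
  for (i in seq_len(nrow(ev))) {
    v <- validateHistory(ev[i, ], rd$markingOccasion[i])
    if (length(v))
      return(sprintf("individual %s: %s", rownames(ev)[i] %||% i, v[[1L]]$rule))
  }
  TRUE
})

#' Simulated encounter histories with latent ground truth
#'
#' An \linkS4class{EncounterHistories} whose generating latent process is
#' known. The per-individual truth table (death occasion and cause, recovery
#' and cause-determination outcomes, latent state path) lives in
#' \code{metadata(x)$truth}; \code{metadata(x)$seed} records the generator
#' seed.
#'
#' @seealso \code{\link{simulateHistories}}
#' @export
setClass("SimulatedHistories", contains = "EncounterHistories")

#' Candidate model structure
#'
#' Declarative description of one candidate multievent model: which sex it
#' applies to, the age partition for mortality, and the effect structures for
#' mortality, resighting and recovery. GPS signal loss always has two
#' deployment-age classes; drop-off and the cause-determination probability
#' are always constant; recovery of working-GPS deaths is fixed at
#' \code{rGps}.
#'
#' @slot label character model label
#' @slot sex "M" or "F"
#' @slot agePartition an \linkS4class{AgePartition}
#' @slot mortality one of "interactive" (free age x cause), "additive"
#'   (parallel age profiles on the multinomial-logit scale) or
#'   "constant_poach" (age-constant poaching, free other-cause)
#' @slot resight one of "constant", "by_mark", "by_time", "mark_plus_time",
#'   "mark_by_time"
#' @slot recovery "constant" or "by_time"
#' @slot estimateInit logical; estimate initial mark-type proportions (two
#'   free multinomial-logit parameters) rather than conditioning on the
#'   release event
#' @slot rGps fixed recovery probability for deaths of working-GPS animals
#' @seealso \code{\link{modelStructure}}
#' @export
setClass("ModelStructure",
  representation(label = "character", sex = "character",
    agePartition = "AgePartition", mortality = "character",
    resight = "character", recovery = "character",
    estimateInit = "logical", rGps = "numeric"))

setValidity("ModelStructure", function(object) {
  if (!object@sex %in% c("M", "F")) return("sex must be 'M' or 'F'")
  if (!object@mortality %in% c("interactive", "additive", "constant_poach"))
    return("unknown mortality structure")
  if (!object@resight %in% c("constant", "by_mark", "by_time",
                             "mark_plus_time", "mark_by_time"))
    return("unknown resight structure")
  if (!object@recovery %in% c("constant", "by_time"))
    return("unknown recovery structure")
  if (object@rGps < 0 || object@rGps > 1) return("rGps must be in [0,1]")
  TRUE
})

#' Real-scale parameter set
#'
#' All probabilities of the 9-state/11-event process on the natural scale.
#' Mortality is cause- and age-class-specific; annual survival is the
#' complement \code{1 - mPoach - mOther}. Resighting and recovery are indexed
#' by occasion (entry 1 is unused: no resighting or recovery can precede the
#' earliest release).
#'
#' @slot agePartition the age partition indexing \code{mPoach}/\code{mOther}
#' @slot mPoach annual poaching mortality per age class
#' @slot mOther annual other-cause mortality per age class
#' @slot lambdaGps GPS signal-loss probability, deployment years (1st, 2nd+)
#' @slot dropOff annual GPS collar drop-off probability
#' @slot pCollar resighting probability per occasion, collar-like marks
#'   (optical collars and inactive GPS collars share one probability)
#' @slot pTag resighting probability per occasion, ear tags only
#' @slot recovery carcass recovery probability per occasion, non-GPS deaths
#' @slot rGps recovery probability for working-GPS deaths (default 1:
#'   telemetered deaths are always detected)
#' @slot delta probability the cause of a recovered carcass is determined
#' @slot initProp initial mark-type proportions (gps, collar, tag)
#' @seealso \code{\link{parameterSet}}, \code{\link{inflate}}
#' @export
setClass("ParameterSet",
  representation(agePartition = "AgePartition", mPoach = "numeric",
    mOther = "numeric", lambdaGps = "numeric", dropOff = "numeric",
    pCollar = "numeric", pTag = "numeric", recovery = "numeric",
    rGps = "numeric", delta = "numeric", initProp = "numeric"))

setValidity("ParameterSet", function(object) {
  A <- nClasses(object@agePartition)
  if (length(object@mPoach) != A || length(object@mOther) != A)
    return("mortality vectors must have one entry per age class")
  pr <- c(object@mPoach, object@mOther, object@lambdaGps, object@dropOff,
          object@pCollar, object@pTag, object@recovery, object@rGps,
          object@delta, object@initProp)
  if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
    return("all probabilities must lie in [0,1]")
  if (any(object@mPoach + object@mOther > 1 + 1e-12))
    return("mPoach + mOther must be <= 1 in every age class")
  if (length(object@lambdaGps) != 2L)
    return("lambdaGps needs exactly 2 deployment-age classes")
  n <- length(object@pCollar)
  if (length(object@pTag) != n || length(object@recovery) != n)
    return("pCollar, pTag and recovery must share the occasion span")
  if (length(object@initProp) != 3L ||
      abs(sum(object@initProp) - 1) > 1e-8)
    return("initProp must be 3 proportions summing to 1")
  TRUE
})

#' Maximum-likelihood fit of one candidate model
#'
#' @slot structure the fitted \linkS4class{ModelStructure}
#' @slot theta MLE vector on the link scale (named)
#' @slot logLik maximized log-likelihood
#' @slot deviance -2 logLik
#' @slot np number of identifiable parameters (numerical rank of the
#'   information matrix)
#' @slot ess effective sample size used in the AICc correction
#' @slot aicc small-sample-corrected AIC
#' @slot vcov variance-covariance matrix on the link scale
#' @slot estimates data.frame of real-scale estimates, SE and 95% CI
#' @slot converged logical
#' @slot boundary names of parameters estimated at a boundary
#' @slot nStarts number of random starts used
#' @slot seed RNG seed for the starts
#' @slot details list: per-start optimizer results, data fingerprint
#' @export
setClass("MultieventFit",
  representation(structure = "ModelStructure", theta = "numeric",
    logLik = "numeric", deviance = "numeric", np = "integer",
    ess = "integer", aicc = "numeric", vcov = "matrix",
    estimates = "data.frame", converged = "logical", boundary = "character",
    nStarts = "integer", seed = "integer", details = "list"))

#' AICc model-comparison table
#'
#' @slot table data.frame: model, structure labels, np, deviance, aicc,
#'   dAicc, weight (NA outside the candidate set), hypothesis
#' @slot candidates labels of the hypothesis-driven candidate set over which
#'   Akaike weights are normalized
#' @export
setClass("ModelTable",
  representation(table = "data.frame", candidates = "character"))

#' Goodness-of-fit result for the time-dependent CJS model
#'
#' Component contingency-table chi-square statistics (TEST3.SR, TEST3.SM,
#' TEST2.CT, TEST2.CL) computed per group and pooled.
#'
#' @slot components data.frame: component, group, occasion, chi2, df
#' @slot chi2 pooled statistic
#' @slot df pooled degrees of freedom
#' @slot pValue upper-tail chi-square probability
#' @export
setClass("GofResult",
  representation(components = "data.frame", chi2 = "numeric",
    df = "integer", pValue = "numeric"))

#' Study design for the simulator
#'
#' @slot nOccasions number of annual occasions
#' @slot cohorts data.frame: occasion, sex, mark ("gps"/"collar"/"tag"), n
#' @slot ageProbs named numeric, distribution of age at marking
#' @seealso \code{\link{studyDesign}}, \code{\link{defaultStudyDesign}}
#' @export
setClass("StudyDesign",
  representation(nOccasions = "integer", cohorts = "data.frame",
    ageProbs = "numeric"))

setValidity("StudyDesign", function(object) {
  ch <- object@cohorts
  need <- c("occasion", "sex", "mark", "n")
  if (!all(need %in% colnames(ch)))
    return(paste("cohorts must contain:", paste(need, collapse = ", ")))
  if (any(ch$n < 0)) return("cohort counts must be >= 0")
  if (any(ch$occasion < 1L | ch$occasion > object@nOccasions))
    return("cohort occasions out of range")
  if (!all(ch$mark %in% .MARK_TYPES)) return("unknown mark type in cohorts")
  if (any(object@ageProbs < 0) || abs(sum(object@ageProbs) - 1) > 1e-8)
    return("ageProbs must be a probability distribution")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
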