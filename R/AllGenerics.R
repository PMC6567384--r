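#' @include AllClasses.R
NULL

#' Number of age classes in a partition
#' @param x an \linkS4class{AgePartition}
#' @return integer number of classes
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' Age class membership
#'
#' Maps integer ages (in years, >= 1) to the 1-based index of the age class
#' they fall in.
#'
#' @param x an \linkS4class{AgePartition}
#' @param age integer vector of ages
#' @return integer vector of class indices
#' @export
setGeneric("ageClassOf", function(x, age) standardGeneric("ageClassOf"))

#' Event-code matrix of an encounter set
#' @param x an \linkS4class{EncounterHistories}
#' @return integer matrix, individuals x occasions, codes 0-10
#' @export
setGeneric("eventCodes", function(x) standardGeneric("eventCodes"))

#' Occasion index at which each individual was marked
#' @param x an \linkS4class{EncounterHistories}
#' @return integer vector
#' @export
setGeneric("markingOccasion", function(x) standardGeneric("markingOccasion"))

#' Age (years) of each individual when marked
#' @param x an \linkS4class{EncounterHistories}
#' @return integer vector
#' @export
setGeneric("ageAtMarking", function(x) standardGeneric("ageAtMarking"))

#' Sex of each individual
#' @param x an \linkS4class{EncounterHistories}
#' @return character vector of "M"/"F"
#' @export
setGeneric("sexOf", function(x) standardGeneric("sexOf"))

#' Number of annual occasions
#' @param x an object spanning study occasions
#' @return integer
#' @export
setGeneric("nOccasions", function(x) standardGeneric("nOccasions"))

#' Latent ground truth of a simulated dataset
#' @param x a \linkS4class{SimulatedHistories}
#' @return data.frame with one row per individual (death occasion, cause,
#'   recovery and cause-determination outcomes, mark trajectory)
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' Real-scale estimates table of a fit
#' @param x a \linkS4class{MultieventFit}
#' @return data.frame of back-transformed estimates with SE and 95% CI
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' AICc of a fitted model
#' @param x a \linkS4class{MultieventFit}
#' @return numeric
#' @export
setGeneric("aicc", function(x) standardGeneric("aicc"))

#' Deviance (-2 log L) of a fitted model
#' @param x a \linkS4class{MultieventFit}
#' @return numeric
#' @export
setGeneric("devianceOf", function(x) standardGeneric("devianceOf"))
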