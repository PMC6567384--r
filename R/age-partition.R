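#' Parse an age-partition specification
#'
#' Age classes are written as a comma-separated list of ranges: a single age
#' \code{"a"}, a closed range \code{"a:b"} or the final open-ended class
#' \code{"a+"}. Classes must be contiguous from age 1 and the last must be
#' open-ended, e.g. \code{"1,2:7,8+"} (yearlings, prime-aged, old).
#'
#' @param spec character scalar, e.g. \code{"1:3,4:7,8+"}
#' @return an \linkS4class{AgePartition}
#' @examples
#' ap <- agePartition("1,2:7,8+")
#' ageClassOf(ap, c(1, 5, 12))  # 1 2 3
#' @export
agePartition <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  parts <- strsplit(gsub("[[:space:]]", "", spec), ",", fixed = TRUE)[[1L]]
  if (!length(parts)) stop("empty age-partition specification")
  lower <- integer(length(parts)); upper <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl("^[0-9]+\\+$", p)) {
      lower[i] <- as.integer(sub("\\+$", "", p)); upper[i] <- NA_integer_
    } else if (grepl("^[0-9]+:[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, ":", fixed = TRUE)[[1L]])
      lower[i] <- ab[1L]; upper[i] <- ab[2L]
    } else if (grepl("^[0-9]+$", p)) {
      lower[i] <- upper[i] <- as.integer(p)
    } else {
      stop("malformed age range: '", p, "'")
    }
  }
  new("AgePartition", spec = spec, lower = lower, upper = upper)
}

#' @rdname nClasses
#' @export
setMethod("nClasses", "AgePartition", function(x) length(x@lower))

#' @rdname ageClassOf
#' @export
setMethod("ageClassOf", "AgePartition", function(x, age) {
  age <- as.integer(age)
  if (any(age < 1L)) stop("ages must be >= 1")
  k <- length(x@lower)
  ## findInterval on lower bounds: contiguity guarantees correctness
  idx <- findInterval(age, x@lower)
  stopifnot(all(idx >= 1L & idx <= k))
  idx
})

#' Human-readable labels for the classes of a partition
#' @param x an \linkS4class{AgePartition}
#' @return character vector like \code{c("1", "2-7", "8+")}
#' @export
classLabels <- function(x) {
  stopifnot(is(x, "AgePartition"))
  ifelse(is.na(x@upper), paste0(x@lower, "+"),
         ifelse(x@lower == x@upper, as.character(x@lower),
                paste0(x@lower, "-", x@upper)))
}

setMethod("show", "AgePartition", function(object) {
  cat("AgePartition:", object@spec, "->",
      paste(classLabels(object), collapse = " | "), "\n")
})
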