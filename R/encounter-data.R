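#' Construct encounter histories from an event-code matrix
#'
#' @param events integer matrix (individuals x occasions) of codes 0-10;
#'   column names, if present, label the occasions (e.g. years)
#' @param sex character vector "M"/"F", one per individual
#' @param ageAtMarking integer vector, age in years at marking
#' @param markingOccasion integer vector of 1-based release occasions; by
#'   default the first non-zero column of each row
#' @param id individual identifiers (default: rownames or \code{ind1..n})
#' @param yearMarked optional calendar year of capture, kept as metadata
#' @return an \linkS4class{EncounterHistories}
#' @examples
#' ev <- rbind(c(3, 0, 2, 8, 0), c(1, 1, 5, 0, 0))
#' eh <- encounterHistories(ev, sex = c("F", "M"), ageAtMarking = c(2, 5))
#' summarizeDataset(eh)
#' @export
encounterHistories <- function(events, sex, ageAtMarking,
                               markingOccasion = NULL, id = NULL,
                               yearMarked = NULL) {
  events <- as.matrix(events)
  storage.mode(events) <- "integer"
  n <- nrow(events)
  if (is.null(markingOccasion))
    markingOccasion <- if (n == 0L) integer(0)
      else apply(events != 0L, 1L, function(z) which(z)[1L])
  if (is.null(id)) id <- rownames(events) %||% paste0("ind", seq_len(n))
  if (n > 0L) rownames(events) <- id
  if (is.null(colnames(events)))
    colnames(events) <- paste0("occ", seq_len(ncol(events)))
  rd <- S4Vectors::DataFrame(sex = as.character(sex),
                             ageAtMarking = as.integer(ageAtMarking),
                             markingOccasion = as.integer(markingOccasion),
                             row.names = if (n > 0L) id else NULL)
  if (!is.null(yearMarked)) rd$yearMarked <- as.integer(yearMarked)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(events = events), rowData = rd)
  new("EncounterHistories", se)
}

#' @rdname eventCodes
#' @export
setMethod("eventCodes", "EncounterHistories", function(x)
  SummarizedExperiment::assay(x, "events"))

#' @rdname markingOccasion
#' @export
setMethod("markingOccasion", "EncounterHistories", function(x)
  SummarizedExperiment::rowData(x)$markingOccasion)

#' @rdname ageAtMarking
#' @export
setMethod("ageAtMarking", "EncounterHistories", function(x)
  SummarizedExperiment::rowData(x)$ageAtMarking)

#' @rdname sexOf
#' @export
setMethod("sexOf", "EncounterHistories", function(x)
  SummarizedExperiment::rowData(x)$sex)

#' @rdname nOccasions
#' @export
setMethod("nOccasions", "EncounterHistories", function(x) ncol(x))

setMethod("show", "EncounterHistories", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat(class(object), "with", nrow(object), "individuals x", ncol(object),
      "occasions\n")
  cat("  sex:", paste(sprintf("%s=%d", names(table(rd$sex)),
                              as.integer(table(rd$sex))), collapse = ", "),
      "\n")
  ev <- eventCodes(object)
  nd <- sum(apply(ev, 1L, function(h) any(h %in% .DEAD_CODES)))
  cat("  dead recoveries:", nd, "\n")
})

#' Validate one coded encounter history
#'
#' Checks the per-individual coding rules and returns the violations as data
#' rather than raising errors: each violation is a list with elements
#' \code{rule} and \code{occasion}.
#'
#' @param events integer vector of codes over all occasions (0 before
#'   marking)
#' @param markingOccasion 1-based release occasion; default first non-zero
#'   entry
#' @return list of violations; empty if the history is valid
#' @examples
#' validateHistory(c(1, 1, 5, 0))        # valid -> list()
#' validateHistory(c(3, 6, 2, 0))        # live code after dead code
#' validateHistory(c(2, 1, 0))           # working GPS after non-GPS mark
#' @export
validateHistory <- function(events, markingOccasion = NULL) {
  events <- as.integer(events)
  bad <- list()
  viol <- function(rule, occ)
    list(rule = rule, occasion = occ)
  oob <- which(events < 0L | events > 10L | is.na(events))
  if (length(oob))
    return(list(viol("event code outside 0..10", oob[1L])))
  if (is.null(markingOccasion)) {
    markingOccasion <- which(events != 0L)[1L]
    if (is.na(markingOccasion))
      return(list(viol("history contains no events", 1L)))
  }
  t0 <- as.integer(markingOccasion)
  if (t0 > 1L && any(events[seq_len(t0 - 1L)] != 0L))
    bad <- c(bad, list(viol("non-zero code before marking occasion",
                            which(events[seq_len(t0 - 1L)] != 0L)[1L])))
  if (!events[t0] %in% 1:3)
    bad <- c(bad, list(viol("marking event must be a release code in {1,2,3}",
                            t0)))
  deadAt <- which(events %in% .DEAD_CODES)
  if (length(deadAt) > 1L)
    bad <- c(bad, list(viol("more than one dead code", deadAt[2L])))
  if (length(deadAt)) {
    after <- events[seq_along(events) > deadAt[1L]]
    if (any(after %in% .LIVE_CODES))
      bad <- c(bad, list(viol("live code after dead code",
                              deadAt[1L] + which(after %in% .LIVE_CODES)[1L])))
    else if (any(after != 0L))
      bad <- c(bad, list(viol("non-zero code after dead code",
                              deadAt[1L] + which(after != 0L)[1L])))
  }
  nonGps <- which(events %in% 2:4)
  if (length(nonGps)) {
    lateGps <- which(events == 1L & seq_along(events) > nonGps[1L])
    if (length(lateGps))
      bad <- c(bad, list(viol("working-GPS code after non-GPS live code",
                              lateGps[1L])))
  }
  bad
}

#' Read encounter histories from a delimited file
#'
#' One row per individual. The column layout is configurable because
#' published datasets differ; the default expects \code{id, sex, age,
#' year_marked} followed by one integer event column per study year named
#' \code{y<year>}. The marking occasion is taken as the first non-zero event
#' column, so the release code is part of the history itself.
#'
#' @param file path to a CSV (or other delimited) file
#' @param layout list with entries \code{id}, \code{sex}, \code{age},
#'   \code{yearMarked} (optional) and \code{events} (event column names in
#'   occasion order); \code{NULL} entries are skipped
#' @param sep field separator
#' @return an \linkS4class{EncounterHistories}; rows failing the coding rules
#'   abort with a message locating the individual and the violated rule
#' @export
readEncounterHistories <- function(file,
    layout = list(id = "id", sex = "sex", age = "age",
                  yearMarked = "year_marked", events = NULL),
    sep = ",") {
  cc <- if (!is.null(layout$sex)) stats::setNames(list("character"),
                                                  layout$sex) else NA
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = cc)
  evCols <- layout$events %||% grep("^y[0-9]{4}$", colnames(df), value = TRUE)
  if (!length(evCols))  # fallback: everything that is not metadata
    evCols <- setdiff(colnames(df),
                      unlist(layout[c("id", "sex", "age", "yearMarked")]))
  if (!length(evCols)) stop("no event columns found")
  miss <- setdiff(evCols, colnames(df))
  if (length(miss)) stop("missing event columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    ev <- matrix(integer(0), 0L, length(evCols),
                 dimnames = list(NULL, evCols))
    return(encounterHistories(ev, sex = character(0),
                              ageAtMarking = integer(0)))
  }
  ev <- as.matrix(df[, evCols, drop = FALSE])
  if (!is.numeric(ev) || any(is.na(ev)) || any(ev != round(ev)) ||
      any(ev < 0) || any(ev > 10)) {
    bad <- which(apply(ev, 1L, function(r)
      any(is.na(r) | r != round(r) | r < 0 | r > 10)))[1L]
    stop("malformed event code in row ", bad, " of ", file)
  }
  storage.mode(ev) <- "integer"
  id <- if (!is.null(layout$id)) as.character(df[[layout$id]])
        else paste0("ind", seq_len(nrow(df)))
  x <- encounterHistories(ev, sex = df[[layout$sex]],
    ageAtMarking = df[[layout$age]], id = id,
    yearMarked = if (!is.null(layout$yearMarked) &&
                     layout$yearMarked %in% colnames(df))
      df[[layout$yearMarked]] else NULL)
  for (i in seq_len(nrow(x))) {
    v <- validateHistory(eventCodes(x)[i, ], markingOccasion(x)[i])
    if (length(v))
      stop(sprintf("row %d (id %s), occasion %d: %s",
                   i, id[i], v[[1L]]$occasion, v[[1L]]$rule))
  }
  x
}

#' Write encounter histories to a delimited file
#'
#' Inverse of \code{\link{readEncounterHistories}} under the default layout:
#' columns \code{id, sex, age, year_marked}, then one event column per
#' occasion (named after the occasion labels, prefixed \code{y} when they are
#' bare years).
#'
#' @param x an \linkS4class{EncounterHistories}
#' @param file output path
#' @return \code{file}, invisibly
#' @export
writeEncounterHistories <- function(x, file) {
  stopifnot(is(x, "EncounterHistories"))
  ev <- eventCodes(x)
  cn <- colnames(ev)
  cn <- ifelse(grepl("^[0-9]{4}$", cn), paste0("y", cn), cn)
  rd <- SummarizedExperiment::rowData(x)
  ym <- if ("yearMarked" %in% colnames(rd)) rd$yearMarked
        else markingOccasion(x)
  df <- data.frame(id = rownames(x) %||%
                     paste0("ind", seq_len(nrow(x)), recycle0 = TRUE),
                   sex = rd$sex, age = rd$ageAtMarking, year_marked = ym,
                   stringsAsFactors = FALSE)
  evd <- as.data.frame(ev)
  colnames(evd) <- cn
  utils::write.table(cbind(df, evd), file, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Census of a dataset
#'
#' Counts individuals by sex and initial mark type, and dead recoveries by
#' sex and by cause, purely from the event codes (5/6 poached, 7/8 other
#' cause, 9/10 unknown cause).
#'
#' @param x an \linkS4class{EncounterHistories}
#' @return a named list: \code{nIndividuals}, \code{nBySex},
#'   \code{nByInitialMark}, \code{nRecoveriesBySex}, \code{nRecoveriesByCause}
#' @export
summarizeDataset <- function(x) {
  stopifnot(is(x, "EncounterHistories"))
  ev <- eventCodes(x)
  sx <- sexOf(x)
  t0 <- markingOccasion(x)
  rel <- ev[cbind(seq_len(nrow(ev)), t0)]
  mark <- c("1" = "gps", "2" = "collar", "3" = "tag")[as.character(rel)]
  deadCode <- apply(ev, 1L, function(h) {
    d <- h[h %in% .DEAD_CODES]; if (length(d)) d[1L] else NA_integer_
  })
  cause <- rep(NA_character_, length(deadCode))
  cause[deadCode %in% .POACH_CODES] <- "poached"
  cause[deadCode %in% .OTHER_CODES] <- "other"
  cause[deadCode %in% .UNKNOWN_CODES] <- "unknown"
  cnt <- function(v, lv) {
    out <- table(factor(v, levels = lv))
    stats::setNames(as.integer(out), lv)
  }
  list(nIndividuals = nrow(ev),
       nBySex = cnt(sx, c("M", "F")),
       nByInitialMark = cnt(mark, .MARK_TYPES),
       nRecoveriesBySex = cnt(sx[!is.na(cause)], c("M", "F")),
       nRecoveriesByCause = cnt(cause[!is.na(cause)],
                                c("poached", "other", "unknown")))
}

#' Live-only binary detection histories
#'
#' Reduces coded histories to the binary detections used by the CJS
#' goodness-of-fit test: codes 2, 3 and 4 (optical collar, ear tags, inactive
#' GPS) become 1, everything else (including working-GPS code 1 and all dead
#' codes) becomes 0. Individuals whose binary history has no 1 carry no CJS
#' information and are dropped.
#'
#' @param x an \linkS4class{EncounterHistories}
#' @return list: \code{histories} binary matrix of the retained individuals,
#'   \code{group} their sex, \code{dropped} ids of the excluded individuals
#' @export
liveOnlyBinary <- function(x) {
  stopifnot(is(x, "EncounterHistories"))
  ev <- eventCodes(x)
  bin <- matrix(as.integer(ev %in% 2:4), nrow(ev), ncol(ev),
                dimnames = dimnames(ev))
  keep <- rowSums(bin) > 0L
  list(histories = bin[keep, , drop = FALSE],
       group = sexOf(x)[keep],
       dropped = rownames(ev)[!keep] %||% which(!keep))
}
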