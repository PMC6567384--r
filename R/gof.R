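## Goodness-of-fit of the time-dependent Cormack-Jolly-Seber model on binary
## live-resighting histories, via the classical contingency-table components
## (TEST3.SR, TEST3.SM, TEST2.CT, TEST2.CL). Each component is a set of
## per-occasion tables; sparse columns are pooled (outermost inward) until
## every expected count is >= 2, and tables that cannot support a test
## contribute 0 df.

#' Reduced m-array of binary detection histories
#'
#' Standard CJS sufficient statistic: every detection (re)releases the
#' animal, and \code{m[i, j]} counts first redetections at occasion j of
#' animals released at i.
#'
#' @param bin binary detection matrix (individuals x occasions)
#' @return list: \code{releases} (length K-1), \code{m} ((K-1) x K matrix,
#'   columns 2..K used), \code{neverSeen} (releases never redetected)
#' @export
buildMArray <- function(bin) {
  bin <- as.matrix(bin)
  K <- ncol(bin)
  releases <- integer(K - 1L)
  m <- matrix(0L, K - 1L, K, dimnames = list(paste0("R", seq_len(K - 1L)),
                                             paste0("occ", seq_len(K))))
  for (ind in seq_len(nrow(bin))) {
    det <- which(bin[ind, ] == 1L)
    for (d in seq_along(det)) {
      i <- det[d]
      if (i >= K) next
      releases[i] <- releases[i] + 1L
      if (d < length(det)) {
        j <- det[d + 1L]
        m[i, j] <- m[i, j] + 1L
      }
    }
  }
  list(releases = releases, m = m,
       neverSeen = releases - rowSums(m))
}

## Pearson chi-square of an r x c table after dropping empty rows/columns
## and pooling columns (outermost inward) until all expected counts >= 2.
## Returns chi2 and df (0 if untestable).
.pooledChi2 <- function(tab, minExp = 2) {
  tab <- as.matrix(tab)
  repeat {
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      return(list(chi2 = 0, df = 0L))
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(exp >= minExp)) break
    if (ncol(tab) == 2L) {
      ## cannot pool a 2-column table further: try merging sparse rows,
      ## else the table is untestable
      if (nrow(tab) > 2L) {
        worst <- which.min(rowSums(tab))
        nb <- if (worst == nrow(tab)) worst - 1L else worst + 1L
        tab[nb, ] <- tab[nb, ] + tab[worst, ]
        tab <- tab[-worst, , drop = FALSE]
        next
      }
      return(list(chi2 = 0, df = 0L))
    }
    ## merge the outermost column holding the smallest expected count with
    ## its inward neighbour
    colMin <- apply(exp, 2L, min)
    side <- if (colMin[1L] <= colMin[ncol(tab)]) 1L else ncol(tab)
    inward <- if (side == 1L) 2L else ncol(tab) - 1L
    tab[, inward] <- tab[, inward] + tab[, side]
    tab <- tab[, -side, drop = FALSE]
  }
  chi2 <- sum((tab - exp)^2 / exp)
  list(chi2 = chi2, df = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}

## first detection strictly after occasion i; NA if none
.nextDet <- function(bin, i) {
  apply(bin[, (i + 1L):ncol(bin), drop = FALSE] == 1L, 1L,
        function(z) if (any(z)) i + which(z)[1L] else NA_integer_)
}

#' Component goodness-of-fit tests for one group
#'
#' U-CARE-style contingency-table components on binary histories:
#' \itemize{
#'   \item TEST3.SR(i): among animals detected at i, newly marked vs
#'     previously marked x ever redetected vs not.
#'   \item TEST3.SM(i): among those redetected, newly vs previously marked x
#'     occasion of next detection.
#'   \item TEST2.CT(i): among previously marked animals known alive at i
#'     (detected before and after), detected at i vs not x next detection at
#'     i+1 vs later.
#'   \item TEST2.CL(i): the same contrast among animals whose next detection
#'     is after i+1, split by the occasion of that detection.
#' }
#' The four components split the conditional multinomial sequentially, so
#' their chi-squares pool additively.
#'
#' @param bin binary detection matrix
#' @param group label attached to the output rows
#' @return data.frame: component, group, occasion, chi2, df
#' @export
componentTests <- function(bin, group = "all") {
  bin <- as.matrix(bin)
  K <- ncol(bin)
  if (K < 3L) stop("need at least 3 occasions")
  first <- apply(bin == 1L, 1L, function(z) which(z)[1L])
  rows <- list()
  emit <- function(component, occasion, res)
    rows[[length(rows) + 1L]] <<- data.frame(component = component,
      group = group, occasion = occasion, chi2 = res$chi2, df = res$df)
  for (i in 2:(K - 1L)) {
    atI <- bin[, i] == 1L
    seenAfter <- rowSums(bin[, (i + 1L):K, drop = FALSE]) > 0L
    nxt <- .nextDet(bin, i)
    ## TEST3.SR
    newI <- first == i
    sel <- atI
    if (any(sel)) {
      tab <- table(factor(newI[sel], c(TRUE, FALSE)),
                   factor(seenAfter[sel], c(TRUE, FALSE)))
      emit("TEST3.SR", i, .pooledChi2(tab))
    }
    ## TEST3.SM: column = occasion of next detection
    sel <- atI & seenAfter
    if (any(sel)) {
      tab <- table(factor(newI[sel], c(TRUE, FALSE)),
                   factor(nxt[sel], (i + 1L):K))
      emit("TEST3.SM", i, .pooledChi2(tab))
    }
    ## TEST2: previously marked, known alive across i
    old <- first < i
    known <- old & seenAfter
    if (any(known)) {
      tab <- table(factor(atI[known], c(TRUE, FALSE)),
                   factor(nxt[known] == i + 1L, c(TRUE, FALSE)))
      emit("TEST2.CT", i, .pooledChi2(tab))
      later <- known & nxt > i + 1L
      if (any(later) && i + 2L <= K) {
        tab <- table(factor(atI[later], c(TRUE, FALSE)),
                     factor(nxt[later], (i + 2L):K))
        emit("TEST2.CL", i, .pooledChi2(tab))
      }
    }
  }
  if (!length(rows))
    return(data.frame(component = character(0), group = character(0),
                      occasion = integer(0), chi2 = numeric(0),
                      df = integer(0)))
  do.call(rbind, rows)
}

#' Pooled CJS goodness-of-fit test
#'
#' Runs the component tests on the live-only binary reduction of the coded
#' histories, per group (sex by default), and pools all component
#' chi-squares; the p-value is the upper tail of the chi-square distribution
#' at the pooled df.
#'
#' @param x an \linkS4class{EncounterHistories}, or a binary matrix
#' @param groups optional grouping vector (defaults to sex for
#'   \code{EncounterHistories}, one group for a matrix)
#' @return a \linkS4class{GofResult}
#' @export
overallGof <- function(x, groups = NULL) {
  if (is(x, "EncounterHistories")) {
    lo <- liveOnlyBinary(x)
    bin <- lo$histories
    if (is.null(groups)) groups <- lo$group
  } else {
    bin <- as.matrix(x)
    if (is.null(groups)) groups <- rep("all", nrow(bin))
  }
  comp <- do.call(rbind, lapply(unique(groups), function(g)
    componentTests(bin[groups == g, , drop = FALSE], group = g)))
  chi2 <- sum(comp$chi2)
  df <- as.integer(sum(comp$df))
  p <- if (df > 0L) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  new("GofResult", components = comp, chi2 = chi2, df = df, pValue = p)
}

setMethod("show", "GofResult", function(object) {
  cat(sprintf("CJS goodness-of-fit: chi2 = %.2f, df = %d, p = %.3f\n",
              object@chi2, object@df, object@pValue))
  agg <- stats::aggregate(cbind(chi2, df) ~ component + group,
                          object@components, sum)
  print(agg, row.names = FALSE, digits = 3)
})
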