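test_that("history validation encodes the coding rules as data", {
  expect_length(validateHistory(c(1, 1, 5, 0)), 0L)

  v <- validateHistory(c(3, 6, 2, 0))
  expect_true(any(vapply(v, function(x) grepl("live code after dead", x$rule),
                         TRUE)))

  v <- validateHistory(c(2, 1, 0))
  expect_true(any(vapply(v, function(x)
    grepl("working-GPS code after non-GPS", x$rule), TRUE)))

  v <- validateHistory(c(3, 11, 0))
  expect_match(v[[1L]]$rule, "outside 0..10", fixed = TRUE)

  v <- validateHistory(c(0, 5, 0), markingOccasion = 2)
  expect_match(v[[1L]]$rule, "release code")

  v <- validateHistory(c(2, 8, 0, 10))
  expect_true(any(vapply(v, function(x) grepl("more than one dead", x$rule),
                         TRUE)))
})

test_that("write/read round trip is the identity", {
  ## hand-built 5-record file
  ev <- rbind(c(3, 0, 3, 0, 0),
              c(2, 2, 0, 8, 0),
              c(1, 1, 4, 0, 2),
              c(0, 1, 5, 0, 0),
              c(0, 0, 2, 0, 10))
  colnames(ev) <- paste0("y", 2008:2012)
  x <- encounterHistories(ev, sex = c("F", "F", "M", "M", "F"),
                          ageAtMarking = c(2, 5, 3, 8, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEncounterHistories(x, f)
  y <- readEncounterHistories(f)
  expect_equal(eventCodes(y), eventCodes(x))
  expect_equal(sexOf(y), sexOf(x))
  expect_equal(ageAtMarking(y), ageAtMarking(x))
  expect_equal(markingOccasion(y), markingOccasion(x))

  ## and on simulator output at n = 100
  sim <- simulateHistories(scaledDesign("F", 100), presetParameters("F"),
                           seed = 42)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeEncounterHistories(sim, f2)
  z <- readEncounterHistories(f2)
  expect_equal(unname(eventCodes(z)), unname(eventCodes(sim)))
  expect_equal(markingOccasion(z), markingOccasion(sim))
})

test_that("empty input round-trips to an empty object", {
  ev <- matrix(integer(0), 0, 3, dimnames = list(NULL, paste0("y", 2008:2010)))
  x <- encounterHistories(ev, sex = character(0), ageAtMarking = integer(0),
                          markingOccasion = integer(0))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEncounterHistories(x, f)
  expect_equal(length(readLines(f)), 1L)  # header only
  y <- readEncounterHistories(f)
  expect_equal(nrow(y), 0L)
})

test_that("malformed codes are rejected with a located message", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,age,year_marked,y2008,y2009",
               "a,F,2,2007,3,0",
               "b,M,4,2007,2,12"), f)
  expect_error(readEncounterHistories(f), "row 2")
})

test_that("dataset census counts recoveries by cause from codes alone", {
  ev <- rbind(c(3, 5, 0), c(2, 0, 7), c(2, 10, 0), c(3, 3, 3))
  x <- encounterHistories(ev, sex = c("M", "F", "F", "M"),
                          ageAtMarking = c(1, 2, 3, 4))
  s <- summarizeDataset(x)
  expect_equal(s$nIndividuals, 4L)
  expect_equal(unname(s$nRecoveriesByCause),
               c(1L, 1L, 1L))
  expect_equal(sum(s$nRecoveriesByCause), sum(s$nRecoveriesBySex))

  ## no dead codes -> all recovery counts 0
  x0 <- encounterHistories(rbind(c(2, 2, 0)), sex = "F", ageAtMarking = 2)
  expect_true(all(summarizeDataset(x0)$nRecoveriesByCause == 0L))

  ## permutation invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(summarizeDataset(x[perm, ]), s)
})

test_that("census agrees with simulator ground truth", {
  sim <- smallSimulatedDataset(seed = 5)
  s <- summarizeDataset(sim)
  tr <- simTruth(sim)
  rec <- tr[tr$recovered, ]
  expect_equal(sum(s$nRecoveriesByCause), nrow(rec))
  expect_equal(unname(s$nRecoveriesBySex),
               unname(c(sum(rec$sex == "M"), sum(rec$sex == "F"))))
  expect_equal(unname(s$nRecoveriesByCause["poached"]),
               sum(rec$determined & rec$cause == "poached"))
  expect_equal(unname(s$nRecoveriesByCause["other"]),
               sum(rec$determined & rec$cause == "other"))
  expect_equal(unname(s$nRecoveriesByCause["unknown"]), sum(!rec$determined))
})

test_that("live-only binary reduction keeps exactly codes 2,3,4", {
  ev <- rbind(c(3, 0, 2, 8, 0),
              c(1, 1, 4, 0, 0),
              c(1, 1, 1, 0, 0))
  x <- encounterHistories(ev, sex = c("F", "M", "M"),
                          ageAtMarking = c(2, 3, 4))
  lo <- liveOnlyBinary(x)
  expect_equal(unname(lo$histories[1L, ]), c(1L, 0L, 1L, 0L, 0L))
  expect_equal(unname(lo$histories[2L, ]), c(0L, 0L, 1L, 0L, 0L))
  expect_equal(nrow(lo$histories), 2L)   # all-GPS history dropped
  expect_length(lo$dropped, 1L)

  ## property: never a 1 where the code is outside {2,3,4}
  sim <- smallSimulatedDataset(seed = 9)
  lo2 <- liveOnlyBinary(sim)
  kept <- eventCodes(sim)[rownames(lo2$histories), ]
  expect_true(all(kept[lo2$histories == 1L] %in% 2:4))
})
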