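toyWells <- function(gus, plate = "p1", luc = 100) {
  n <- length(gus)
  data.frame(plate = plate, well = sprintf("w%02d", seq_len(n)),
             construct = "EV", reporter = "ABA", condition = "mock",
             luc = rep_len(luc, n), gus = gus,
             stringsAsFactors = FALSE)
}

test_that("plate QC omits low-transformation wells per plate", {
  # n = 3: top ceiling(0.3) = 1 well (GUS 100), threshold 50
  qc <- qcFilterWells(toyWells(c(100, 90, 10)))
  expect_equal(qc$kept$gus, c(100, 90))
  expect_equal(qc$omitted$gus, 10)

  # all equal -> threshold is half the common value, none omitted
  qcEq <- qcFilterWells(toyWells(rep(70, 5)))
  expect_equal(nrow(qcEq$omitted), 0L)

  # scale invariance of the retained set
  qcScaled <- qcFilterWells(toyWells(7 * c(100, 90, 10)))
  expect_equal(qcScaled$kept$well, qc$kept$well)

  # per-plate computation: each plate judged on its own GUS scale
  two <- rbind(toyWells(c(100, 90, 10), plate = "p1"),
               toyWells(c(10, 9, 1), plate = "p2"))
  qc2 <- qcFilterWells(two)
  expect_equal(nrow(qc2$kept), 4L)

  # plate failure when everything is below threshold is impossible by
  # construction of the rule (top wells always pass); the "max" variant
  # can be stricter
  qcMax <- qcFilterWells(toyWells(c(100, 49, 48)), topStat = "max")
  expect_equal(nrow(qcMax$kept), 1L)
})

test_that("normalisation divides by GUS and averages replicates across plates", {
  w <- rbind(toyWells(gus = c(100, 100), luc = c(200, 400), plate = "p1"),
             toyWells(gus = 100, luc = 300, plate = "p2"))
  agg <- normalizeAndAggregate(w)
  expect_equal(agg$activity, mean(c(2, 4, 3)))
  expect_equal(agg$nWells, 3L)

  wz <- toyWells(gus = c(100, 0), luc = c(200, 500))
  expect_warning(aggz <- normalizeAndAggregate(wz), "zero GUS")
  expect_equal(aggz$activity, 2)
})

test_that("effector ratios and the ranking factor follow the product rule", {
  agg <- data.frame(
    construct = c("EV", "EV", "E1", "E1"),
    reporter = "ABA",
    condition = c("mock", "treated", "mock", "treated"),
    activity = c(2, 4, 8, 2), nWells = 2L, stringsAsFactors = FALSE)
  r <- effectorRatios(agg, "E1", "ABA")
  expect_equal(r$mockRatio, 4)        # 8 / 2
  expect_equal(r$treatmentRatio, 0.5) # 2 / 4
  expect_equal(r$product, 2)
  expect_equal(r$log2Product, 1)
  expect_equal(r$rankFactor, 1)

  # inversion symmetry of the ranking factor
  aggInv <- agg
  aggInv$activity <- c(2, 4, 0.5, 8)  # ratios 1/4 and 2
  rInv <- effectorRatios(aggInv, "E1", "ABA")
  expect_equal(rInv$rankFactor, r$rankFactor)

  expect_error(effectorRatios(agg[-1, ], "E1", "ABA"), "empty-vector")
  aggZero <- agg; aggZero$activity[1] <- 0
  expect_error(effectorRatios(aggZero, "E1", "ABA"), "zero")
})

test_that("modulation calls use strict 2-fold boundaries on the product", {
  rec <- data.frame(effector = paste0("E", 1:5), reporter = "JA",
                    mockRatio = 1, treatmentRatio = 1,
                    product = c(2.1, 1.9, 0.4, 2.0, 0.5))
  rec$log2Product <- log2(rec$product)
  rec$rankFactor <- abs(rec$log2Product)
  called <- callModulation(rec)
  expect_equal(called$call, c("induced", "ns", "suppressed", "ns", "ns"))

  # monotone in the product: increasing product never demotes a call
  prods <- sort(c(rec$product, 3, 0.1))
  rec2 <- data.frame(effector = "E", reporter = "JA", mockRatio = 1,
                     treatmentRatio = 1, product = prods,
                     log2Product = log2(prods),
                     rankFactor = abs(log2(prods)))
  lv <- c(suppressed = -1, ns = 0, induced = 1)
  expect_equal(unname(lv[callModulation(rec2)$call]),
               cummax(unname(lv[callModulation(rec2)$call])))
})

test_that("effector ranking is deterministic with lexicographic tie-breaks", {
  rec <- data.frame(
    effector = c("EB", "EA", "EC", "ED"), reporter = "SA",
    mockRatio = 1, treatmentRatio = 1,
    product = c(4, 4, 2, 1),
    log2Product = log2(c(4, 4, 2, 1)),
    rankFactor = abs(log2(c(4, 4, 2, 1))))
  top <- rankEffectors(rec, n = 3)
  expect_equal(top$effector, c("EA", "EB", "EC"))  # tie EA before EB
  expect_equal(top$rank, 1:3)
  # a null effector (rank factor 0) is ranked last
  expect_false("ED" %in% top$effector)
})

test_that("screen summaries count directions, effectors and specificity", {
  rec <- data.frame(
    effector = c("E1", "E1", "E2", "E3"),
    reporter = c("ABA", "AUX", "ABA", "JA"),
    call = c("induced", "suppressed", "ns", "induced"))
  s <- screenSummary(rec)
  expect_equal(s$nCombinations, 4L)
  expect_equal(s$nSignificant, 3L)
  expect_equal(s$nInduced, 2L)
  expect_equal(s$nSuppressed, 1L)
  expect_equal(s$nModulatingEffectors, 2L)
  expect_equal(s$nSingleHormoneEffectors, 1L)  # E3 only
  aba <- s$perHormone[s$perHormone$reporter == "ABA", ]
  expect_equal(aba$changed, 1L)

  sNone <- screenSummary(transform(rec, call = "ns"))
  expect_equal(sNone$nSignificant, 0L)
  expect_equal(sNone$nModulatingEffectors, 0L)
})

test_that("mutant reporter analysis normalises to wild-type mock per batch", {
  set.seed(42)
  mk <- function(geno, cond, batch, mu, n = 6) {
    data.frame(plate = paste0(batch, geno, cond),
               well = sprintf("w%02d", 1:n), construct = geno,
               reporter = "ABA", condition = cond,
               luc = rnorm(n, mu, mu * 0.05), gus = 100, batch = batch,
               stringsAsFactors = FALSE)
  }
  w <- rbind(mk("Col-0", "mock", "b1", 100), mk("Col-0", "treated", "b1", 500),
             mk("mut-1", "mock", "b1", 100), mk("mut-1", "treated", "b1", 100),
             mk("Col-0", "mock", "b2", 200), mk("Col-0", "treated", "b2", 1000),
             mk("mut-1", "mock", "b2", 200), mk("mut-1", "treated", "b2", 200))
  res <- mutantReporterAnalysis(w)
  wtMock <- res$values$relative[res$values$construct == "Col-0" &
                                  res$values$condition == "mock"]
  expect_equal(mean(wtMock), 1, tolerance = 1e-9)  # self-normalisation
  # the planted genotype x treatment interaction is detected
  pInt <- res$anova[[1]]["construct:condition", "Pr(>F)"]
  expect_lt(pInt, 1e-6)
  # treated wild type differs from treated mutant; mocks share a letter
  expect_true(res$letters[["Col-0:treated"]] !=
                res$letters[["mut-1:treated"]])
  expect_true(any(strsplit(res$letters[["Col-0:mock"]], "")[[1]] %in%
                    strsplit(res$letters[["mut-1:mock"]], "")[[1]]))
  expect_error(mutantReporterAnalysis(w[w$construct != "Col-0", ]),
               "wild-type")
})
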