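toyShipWorld <- function() {
  # E1 -> TA (annotated JA)            : 1st degree
  # E2 -> TU (un-annotated), TU - H1(AUX), TU - H2(ABA), TU - X (un-ann.)
  #                                    : two 2nd-degree records via TU
  # E3 -> TX (un-annotated, no annotated neighbours) : none
  net <- toyNetwork(data.frame(effector = c("E1", "E2", "E3"),
                               target = c("TA", "TU", "TX")))
  ref <- toyReference(rbind(c("TU", "H1"), c("TU", "H2"), c("TU", "X"),
                            c("TX", "X")))
  ann <- hormoneAnnotation(data.frame(
    protein = c("TA", "H1", "H2"),
    hormone = c("JA", "AUX", "ABA")))
  list(net = net, ref = ref, ann = ann)
}

test_that("hormone annotations enforce the controlled vocabulary", {
  expect_error(hormoneAnnotation(data.frame(protein = "P", hormone = "XX")),
               "unknown hormone")
  ann <- hormoneAnnotation(data.frame(protein = c("p1", "p1", "p2"),
                                      hormone = c("JA", "SA", "JA")))
  expect_equal(hormonesOf(ann, "P1")$P1, c("JA", "SA"))  # upper-cased
  expect_equal(hormonesOf(ann, "P3")$P3, character())    # un-annotated
})

test_that("first- and second-degree hormone interaction points are detected", {
  w <- toyShipWorld()
  s <- findShips(w$net, w$ref, w$ann)
  r <- s$records
  expect_equal(sum(r$degree == 1L), 1L)
  d1 <- r[r$degree == 1L, ]
  expect_equal(d1$effector, "E1")
  expect_equal(d1$hormones, "JA")
  # second degree: one record per annotated neighbour reached via TU
  d2 <- r[r$degree == 2L, ]
  expect_equal(nrow(d2), 2L)
  expect_true(all(d2$target == "TU"))
  expect_setequal(d2$reached, c("H1", "H2"))
  expect_setequal(d2$hormones, c("AUX", "ABA"))
  # degree-1 and degree-2 target sets are disjoint by construction
  expect_length(intersect(r$target[r$degree == 1L],
                          r$target[r$degree == 2L]), 0L)
  # effector partition
  expect_equal(unname(s$effectorClass[c("E1", "E2", "E3")]),
               c("has_1st", "only_2nd", "none"))
  expect_equal(s$secondDegreeHormoneProteins, c("H1", "H2"))
})

test_that("an effector with both direct and mediated contacts counts as has_1st", {
  net <- toyNetwork(data.frame(effector = c("E1", "E1"),
                               target = c("TA", "TU")))
  w <- toyShipWorld()
  s <- findShips(net, w$ref, w$ann)
  expect_equal(unname(s$effectorClass["E1"]), "has_1st")
  expect_equal(sort(unique(s$records$degree)), c(1L, 2L))
})

test_that("ship detection is independent of input row order", {
  w <- toyShipWorld()
  e <- networkEdges(w$net)
  netRev <- toyNetwork(e[rev(seq_len(nrow(e))), ])
  s1 <- findShips(w$net, w$ref, w$ann)
  s2 <- findShips(netRev, w$ref, w$ann)
  expect_equal(s1$records, s2$records)
  expect_equal(s1$effectorClass, s2$effectorClass)
})

test_that("the functionally informed network keeps only called effectors with targets", {
  w <- toyShipWorld()
  calls <- data.frame(effector = c("E1", "E2", "E9"),
                      hormone = c("JA", "AUX", "SA"),
                      call = c("induced", "ns", "suppressed"))
  # E1 has a call and targets; E2's call is ns; E9 has no targets
  expect_warning(fs <- buildFispin(w$net, calls, w$ann), "E9")
  expect_equal(effectors(fs), "E1")
  expect_equal(nrow(networkEdges(fs)), 1L)

  # no significant calls at all -> empty network
  nsCalls <- data.frame(effector = "E1", hormone = "JA", call = "ns")
  fsEmpty <- buildFispin(w$net, nsCalls, w$ann)
  expect_equal(nrow(networkEdges(fsEmpty)), 0L)
})

test_that("edge types partition the functionally informed network", {
  net <- toyNetwork(data.frame(effector = c("E1", "E1", "E2"),
                               target = c("TA", "TU", "TB")))
  ann <- hormoneAnnotation(data.frame(protein = c("TA", "TB"),
                                      hormone = c("JA", "SA")))
  calls <- data.frame(effector = c("E1", "E2"), hormone = c("JA", "ABA"),
                      call = c("induced", "suppressed"))
  fs <- buildFispin(net, calls, ann)
  ct <- classifyShipTypes(fs)
  e <- ct$edges
  expect_equal(e$type[e$target == "TA"], "I")    # JA matches JA
  expect_equal(e$type[e$target == "TU"], "II")   # un-annotated target
  expect_equal(e$type[e$target == "TB"], "III")  # ABA vs SA mismatch
  expect_equal(sum(ct$fractions), 100)
  expect_equal(unname(ct$fractions), c(1, 1, 1) / 3 * 100)
})

test_that("annotating a protein can only move edges out of type II", {
  net <- toyNetwork(data.frame(effector = c("E1", "E2"),
                               target = c("TU", "TU")))
  calls <- data.frame(effector = c("E1", "E2"), hormone = c("JA", "SA"),
                      call = "induced")
  annNone <- hormoneAnnotation(data.frame(protein = character(),
                                          hormone = character()))
  before <- classifyShipTypes(buildFispin(net, calls, annNone))
  expect_true(all(before$edges$type == "II"))
  annJA <- hormoneAnnotation(data.frame(protein = "TU", hormone = "JA"))
  after <- classifyShipTypes(buildFispin(net, calls, annJA))
  expect_equal(sum(after$edges$type == "II"), 0L)
  expect_setequal(after$edges$type, c("I", "III"))
})

test_that("ship records round-trip through the TSV writer", {
  w <- toyShipWorld()
  s <- findShips(w$net, w$ref, w$ann)
  f <- tempfile(fileext = ".tsv")
  writeShips(s$records, f)
  back <- read.table(f, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(s$records))
  expect_equal(back$effector, s$records$effector)
})
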