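test_that("intraspecies convergence matches the exact occupancy oracle", {
  # pool of 10, N = 4 edges, 2 unique observed targets: exact lower tail
  # P(unique < 2) = P(all four draws identical) = 10 * (1/10)^4 = 0.001
  net <- toyNetwork(data.frame(effector = c("E1", "E2", "E3", "E4"),
                               target = c("P1", "P1", "P1", "P2")))
  pool <- paste0("X", 1:10)
  exact <- occupancyLowerTail(2, 4, 10)
  expect_equal(exact, 10 * (1 / 10)^4)
  res <- intraspeciesConvergence(net, pool,
                                 rewiringConfig(reps = 10000, seed = 3))
  expect_equal(observedStat(res), 2L)
  expect_lt(abs(pValue(res) - exact), 3 * mcSE(exact, 10000) + 1e-12)

  # a larger case against the DP oracle: pool 12, N 6, observed 4
  net2 <- toyNetwork(data.frame(effector = paste0("E", 1:6),
                                target = c("P1", "P1", "P2", "P3",
                                           "P4", "P4")))
  exact2 <- occupancyLowerTail(4, 6, 12)
  res2 <- intraspeciesConvergence(net2, paste0("X", 1:12),
                                  rewiringConfig(reps = 10000, seed = 5))
  expect_equal(observedStat(res2), 4L)
  expect_lt(abs(pValue(res2) - exact2), 3 * mcSE(exact2, 10000))
})

test_that("degenerate single-protein pool floors the intraspecies p-value", {
  net <- toyNetwork(data.frame(effector = c("E1", "E2", "E3"),
                               target = c("P1", "P1", "P1")))
  res <- intraspeciesConvergence(net, "X",
                                 rewiringConfig(reps = 100, seed = 1))
  expect_equal(pValue(res), 0)
  expect_true(isFloor(res))
  expect_equal(formatPValue(res), "<0.001")
  expect_true(all(nullDraws(res) == 1L))
})

test_that("interspecies convergence matches the 1/pool closed form at N = 1", {
  # two organisms with one unique target each, disjoint: observed common
  # is 0 and P(common > 0) = P(two single draws coincide) = 1/pool
  a <- toyNetwork(data.frame(effector = "A1", target = "P1"),
                  organism = "orgA")
  b <- toyNetwork(data.frame(effector = "B1", target = "P2"),
                  organism = "orgB")
  pool <- paste0("X", 1:100)
  res <- interspeciesConvergence(list(orgA = a, orgB = b), NULL, pool,
                                 rewiringConfig(reps = 10000, seed = 9))
  expect_equal(observedStat(res), 0L)
  expect_lt(abs(pValue(res) - 1 / 100), 3 * mcSE(1 / 100, 10000))
})

test_that("interspecies convergence detects planted sharing and reports the common set", {
  shared <- c("AT1G00010", "AT1G00020", "AT1G00030")
  a <- toyNetwork(data.frame(effector = paste0("A", 1:4),
                             target = c(shared, "AT1G00040")), "orgA")
  b <- toyNetwork(data.frame(effector = paste0("B", 1:4),
                             target = c(shared, "AT1G00050")), "orgB")
  pool <- hostIdsForTest(500)
  res <- interspeciesConvergence(list(orgA = a, orgB = b), NULL, pool,
                                 rewiringConfig(reps = 2000, seed = 2))
  expect_equal(observedStat(res), 3L)
  expect_setequal(attr(res, "commonTargets"), shared)
  expect_true(isFloor(res) || pValue(res) < 0.01)
})

test_that("comparative analyses omit hormone-space-only edges", {
  a <- toyNetwork(data.frame(effector = c("A1", "A2"),
                             target = c("P1", "P2"),
                             hormone_space_only = c(FALSE, TRUE)), "orgA")
  b <- toyNetwork(data.frame(effector = "B1", target = "P2"), "orgB")
  res <- interspeciesConvergence(list(orgA = a, orgB = b), NULL,
                                 paste0("X", 1:50),
                                 rewiringConfig(reps = 100, seed = 1))
  expect_equal(observedStat(res), 0L)  # P2 only reachable via flagged edge
  resKeep <- interspeciesConvergence(list(orgA = a, orgB = b), NULL,
                                     paste0("X", 1:50),
                                     rewiringConfig(reps = 100, seed = 1),
                                     dropHormoneSpaceOnly = FALSE)
  expect_equal(observedStat(resKeep), 1L)
})

test_that("annotated-target excess matches the hypergeometric tail oracle", {
  # pool 10 with 5 annotated, 4 unique targets all annotated:
  # exact P(X >= 4) = C(5,4)/C(10,4) = 5/210
  net <- toyNetwork(data.frame(effector = paste0("E", 1:4),
                               target = paste0("A", 1:4)))
  pool <- c(paste0("A", 1:5), paste0("U", 1:5))
  exact <- hyperUpperTail(4, 5, 10, 4)
  expect_equal(exact, 5 / 210)
  res <- annotatedTargetExcess(net, paste0("A", 1:5), pool,
                               rewiringConfig(reps = 10000, seed = 4))
  expect_equal(observedStat(res), 4L)
  expect_lt(abs(pValue(res) - exact), 3 * mcSE(exact, 10000))

  # saturation: every pool protein annotated -> p = 1
  resSat <- annotatedTargetExcess(net, pool, pool,
                                  rewiringConfig(reps = 500, seed = 4))
  expect_equal(pValue(resSat), 1)
})

test_that("resampling results are bit-identical under the same seed and config", {
  net <- toyNetwork(data.frame(effector = paste0("E", 1:5),
                               target = paste0("P", c(1, 1, 2, 3, 3))))
  pool <- paste0("X", 1:30)
  cfg <- rewiringConfig(reps = 500, seed = 123)
  r1 <- intraspeciesConvergence(net, pool, cfg)
  r2 <- intraspeciesConvergence(net, pool, cfg)
  expect_identical(nullDraws(r1), nullDraws(r2))
  expect_identical(pValue(r1), pValue(r2))
  r3 <- intraspeciesConvergence(net, pool,
                                rewiringConfig(reps = 500, seed = 124))
  expect_false(identical(nullDraws(r1), nullDraws(r3)))
})

test_that("shared/exclusive classification partitions the focal target set", {
  focal <- toyNetwork(data.frame(effector = c("S1", "S2", "S3"),
                                 target = c("PA", "PB", "PC")))
  others <- list(
    orgB = toyNetwork(data.frame(effector = "B1", target = "PB"), "orgB"),
    orgC = toyNetwork(data.frame(effector = c("C1", "C2"),
                                 target = c("PB", "PZ")), "orgC"))
  cls <- classifySharedExclusive(focal, others)
  expect_setequal(cls$protein, c("PA", "PB", "PC"))
  expect_equal(sum(cls$status == "exclusive_to_focal") +
                 sum(cls$status == "shared"), 3L)
  expect_equal(cls$status[cls$protein == "PB"], "shared")
  expect_equal(cls$nSharing[cls$protein == "PB"], 2L)
  expect_equal(cls$sharingOrganisms[cls$protein == "PB"], "orgB,orgC")
  expect_setequal(cls$protein[cls$status == "exclusive_to_focal"],
                  c("PA", "PC"))

  # no competitors: everything exclusive
  clsNone <- classifySharedExclusive(focal, list())
  expect_true(all(clsNone$status == "exclusive_to_focal"))
})

test_that("subset overlaps agree with hand enumeration", {
  a <- toyNetwork(data.frame(effector = paste0("A", 1:3),
                             target = c("P1", "P2", "P3")), "orgA")
  b <- toyNetwork(data.frame(effector = paste0("B", 1:3),
                             target = c("P2", "P3", "P4")), "orgB")
  c_ <- toyNetwork(data.frame(effector = paste0("C", 1:2),
                              target = c("P3", "P5")), "orgC")
  ov <- pairwiseOverlap(list(orgA = a, orgB = b, orgC = c_))
  get <- function(orgs) ov$intersection[ov$organisms == orgs]
  expect_equal(get("orgA,orgB"), 2L)    # P2, P3
  expect_equal(get("orgA,orgC"), 1L)    # P3
  expect_equal(get("orgB,orgC"), 1L)    # P3
  expect_equal(get("orgA,orgB,orgC"), 1L)

  # disjoint sets overlap in nothing
  d <- toyNetwork(data.frame(effector = "D1", target = "P9"), "orgD")
  ovd <- pairwiseOverlap(list(orgA = a, orgD = d))
  expect_equal(ovd$intersection, 0L)
})

test_that("degree-weighted sampling shifts the null toward hub reuse", {
  # a star graph: one hub adjacent to all others; degree weighting makes
  # repeat draws of the hub likely, lowering the null unique count
  hub <- "HUB"
  leaves <- paste0("L", 1:20)
  ref <- toyReference(cbind(rep(hub, 20), leaves))
  net <- toyNetwork(data.frame(effector = paste0("E", 1:6),
                               target = paste0("L", 1:6)))
  uni <- intraspeciesConvergence(net, ref,
                                 rewiringConfig(reps = 2000, seed = 7))
  wei <- intraspeciesConvergence(net, ref,
                                 rewiringConfig(reps = 2000, seed = 7,
                                                sampling = "degree_weighted"))
  expect_lt(mean(nullDraws(wei)), mean(nullDraws(uni)))
})
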