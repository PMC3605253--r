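test_that("benchmark generators satisfy their cross-talk reachability invariants", {
  fct <- generateBenchmark("FCT", seed = 2)
  expect_identical(fct@kind, "FCT")
  for (k in 1:2)
    expect_setequal(dynGRN:::.reachableFrom(fct@truth, k), 1:5)

  lct <- generateBenchmark("LCT", seed = 2)
  r1 <- dynGRN:::.reachableFrom(lct@truth, 1)
  r2 <- dynGRN:::.reachableFrom(lct@truth, 2)
  expect_gt(length(intersect(r1, r2)), 0)              # shared downstream
  expect_lt(length(intersect(r1, r2)), 4)              # but not everything
  # deep no-cross-talk chains cannot always reach the amplitude floor
  # within the coefficient ranges; the generator then warns and returns its
  # best draw
  nct <- suppressWarnings(generateBenchmark("NCT", seed = 2))
  n1 <- dynGRN:::.reachableFrom(nct@truth, 1)
  n2 <- dynGRN:::.reachableFrom(nct@truth, 2)
  expect_length(intersect(n1, n2), 0)
  expect_setequal(c(n1, n2), 1:7)
})

test_that("benchmark coefficients are well-conditioned and reproducible", {
  a <- generateBenchmark("LCT", seed = 9)
  b <- generateBenchmark("LCT", seed = 9)
  expect_identical(interactionMatrix(a@truth), interactionMatrix(b@truth))
  expect_identical(inputMatrix(a@truth), inputMatrix(b@truth))
  expect_false(identical(interactionMatrix(a@truth),
                         interactionMatrix(generateBenchmark("LCT",
                                                             seed = 10)@truth)))
  A <- interactionMatrix(a@truth)
  d <- diag(A)
  expect_true(all(d >= -2 & d <= -0.2))
  expect_gt(min(diff(sort(d))), 0)                     # distinct
  off <- A[row(A) != col(A)]
  off <- off[off != 0]
  expect_true(all(abs(off) >= 0.3 & abs(off) <= 1.5))  # away from zero
  Bc <- inputMatrix(a@truth)
  expect_true(all(abs(Bc[Bc != 0]) >= 0.3))
})

test_that("artificial data follow the scenario, grid and noise specification", {
  bm <- generateBenchmark("LCT", seed = 3)
  dsM <- generateData(bm, "M", noiseSd = 0.05, seed = 3)
  expect_length(dsM@experiments, 2)
  expect_equal(dsM@experiments[[1]]@times, c(0, 1, 2, 4, 8, 16))
  expect_identical(nrow(dsM@experiments[[1]]@exprs), 6L)
  expect_true(dsM@standardised)
  # each experiment applies exactly its own stimulus as a step
  expect_true(all(dsM@experiments[[1]]@stimuli[, 1] == 1))
  expect_true(all(dsM@experiments[[1]]@stimuli[, 2] == 0))
  expect_true(all(dsM@experiments[[2]]@stimuli[, 2] == 1))
  expect_length(generateData(bm, "S2", seed = 3)@experiments, 1)
  expect_error(generateData(bm, "S9", seed = 3), "unknown scenario")

  # without noise the data equal the standardised true trajectories
  ds0 <- generateData(bm, "M", noiseSd = 0, seed = 3)
  tt <- ds0@experiments[[1]]@times
  sim1 <- simulateGRN(bm@truth, c(1, 0), tt)
  sim2 <- simulateGRN(bm@truth, c(0, 1), tt)
  scale <- pmax(apply(abs(sim1), 2, max), apply(abs(sim2), 2, max))
  expect_equal(ds0@experiments[[1]]@exprs,
               sweep(sim1, 2, scale, "/"), tolerance = 1e-6,
               ignore_attr = TRUE)
  # reproducibility of the noise
  expect_identical(generateData(bm, "M", seed = 5)@experiments[[1]]@exprs,
                   generateData(bm, "M", seed = 5)@experiments[[1]]@exprs)
})

test_that("structure evaluation reproduces the printed formulas and worked counts", {
  ev <- structureEvaluation(TP = 18, TN = 15, FPn = 2, FPs = 0, FN = 0)
  expect_equal(ev@SE, 1)
  expect_equal(round(ev@SP, 2), 0.88)
  expect_equal(ev@PR, 0.9)
  expect_equal(ev@FM, 2 * 0.9 * 1 / 1.9)
  # degenerate case: nothing recovered
  empty <- structureEvaluation(TP = 0, TN = 10, FPn = 0, FPs = 0, FN = 5)
  expect_identical(empty@SE, 0)
  expect_identical(empty@FM, 0)

  truth <- generateBenchmark("LCT", seed = 1)@truth
  expect_equal(unname(measures(evaluateStructure(truth, truth))),
               rep(1, 4))
})

test_that("evaluation counts partition all candidate positions and match a brute-force oracle", {
  for (seed in 1:8) {
    inferred <- randomStableModel(4, 2, seed)
    truth <- randomStableModel(4, 2, seed + 100)
    ev <- evaluateStructure(inferred, truth)
    expect_identical(sum(counts(ev)), 4L * 4L + 2L * 4L)
    oracle <- bruteConfusionOracle(interactionMatrix(inferred),
                                   inputMatrix(inferred),
                                   interactionMatrix(truth),
                                   inputMatrix(truth))
    expect_equal(counts(ev), oracle, ignore_attr = TRUE)
  }
  # stimuli missing from the inferred model count as absent columns
  one <- grnModel(matrix(-1, 1, 1), matrix(1, 1, 1), geneNames = "G1",
                  stimulusNames = "Input1")
  two <- grnModel(matrix(-1, 1, 1), matrix(c(1, 1), 1, 2), geneNames = "G1",
                  stimulusNames = c("Input1", "Input2"))
  ev <- evaluateStructure(one, two)
  expect_identical(ev@FN, 1L)
  expect_identical(sum(counts(ev)), 3L)
})

test_that("the allowed-error sweep covers every scenario-value pair and J trends upward", {
  # a full-cross-talk system keeps every series excited in every scenario,
  # which is the regime where the stopping rule makes the model error grow
  # with the allowed error (the greedy inclusion order is path-dependent,
  # so the growth is a trend between the sweep ends, not pointwise)
  bm <- generateBenchmark("FCT", seed = 1)
  vals <- c(0.001, 0.005, 0.01)
  sw <- sweepAllowedError(bm, scenarios = c("M", "S1"), values = vals,
                          seed = 1)
  expect_identical(nrow(sw), 6L)
  expect_setequal(unique(sw$scenario), c("M", "S1"))
  expect_true(all(c("SE", "SP", "PR", "FM", "J", "edges") %in% names(sw)))
  expect_true(all(sw$SE >= 0 & sw$SE <= 1))
  for (s in split(sw, sw$scenario))
    expect_gte(s$J[length(vals)], s$J[1] - 1e-9)
})

test_that("resampling yields frequencies in [0, 1], all one for unperturbed runs", {
  bm <- generateBenchmark("LCT", seed = 1)
  ds <- generateData(bm, "M", noiseSd = 0.05, seed = 1)
  fr0 <- resampleValidate(ds, nRuns = 3, noiseSd = 0, seed = 1)
  expect_true(all(fr0$frequency == 1))
  expect_identical(attr(fr0, "nRuns"), 3L)
  fr <- resampleValidate(ds, nRuns = 5, noiseSd = 0.05, seed = 1)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1))
  # reproducible given the seed
  fr2 <- resampleValidate(ds, nRuns = 5, noiseSd = 0.05, seed = 1)
  expect_identical(fr$frequency, fr2$frequency)
})
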