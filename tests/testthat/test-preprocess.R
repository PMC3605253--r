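test_that("standardisation centres on the first point and scales by the cross-experiment maximum", {
  ex <- grnExperiment(0:2, cbind(g1 = c(2, 3, 4)), cbind(u1 = rep(1, 3)))
  ds <- standardiseDataset(grnDataset(ex))
  expect_equal(ds@experiments[[1]]@exprs[, "g1"], c(0, 0.5, 1))

  exA <- grnExperiment(0:1, cbind(g1 = c(1, 2)), cbind(u1 = rep(1, 2)), "A")
  exB <- grnExperiment(0:1, cbind(g1 = c(1, -3)), cbind(u1 = rep(1, 2)), "B")
  ds2 <- standardiseDataset(grnDataset(list(exA, exB)))
  expect_equal(ds2@experiments[[1]]@exprs[, "g1"], c(0, 0.25))
  expect_equal(ds2@experiments[[2]]@exprs[, "g1"], c(0, -1))
})

test_that("a constant series is rejected as degenerate, not divided by zero", {
  ex <- grnExperiment(0:2, cbind(g1 = c(5, 5, 5)), cbind(u1 = rep(1, 3)))
  expect_error(standardiseDataset(grnDataset(ex)), "degenerate series")
  expect_s3_class(tryCatch(standardiseDataset(grnDataset(ex)),
                           error = identity), "grnDegenerateSeries")
  dropped <- suppressWarnings(
    standardiseDataset(grnDataset(grnExperiment(
      0:2, cbind(g1 = c(5, 5, 5), g2 = c(0, 1, 2)), cbind(u1 = rep(1, 3)))),
      onDegenerate = "drop"))
  expect_identical(geneNames(dropped), "g2")
})

test_that("standardisation is idempotent and attains unit maximum per gene", {
  set.seed(7)
  exs <- lapply(1:2, function(e)
    grnExperiment(c(0, 1, 2, 4), matrix(rnorm(12), 4,
                                        dimnames = list(NULL, paste0("g", 1:3))),
                  cbind(u1 = rep(1, 4)), name = paste0("E", e)))
  ds <- standardiseDataset(grnDataset(exs))
  ds2 <- standardiseDataset(ds)
  expect_equal(ds2@experiments[[1]]@exprs, ds@experiments[[1]]@exprs,
               tolerance = 1e-12)
  maxAbs <- pmax(apply(abs(ds@experiments[[1]]@exprs), 2, max),
                 apply(abs(ds@experiments[[2]]@exprs), 2, max))
  expect_equal(unname(maxAbs), rep(1, 3))
  expect_true(all(abs(ds@experiments[[1]]@exprs) <= 1))
  expect_equal(unname(ds@experiments[[2]]@exprs[1, ]), rep(0, 3))
})

test_that("spline interpolation inserts flagged interior points and preserves measured data", {
  ex <- grnExperiment(0:2, cbind(g1 = c(0, 2, 4)), cbind(u1 = rep(1, 3)))
  ds <- standardiseDataset(grnDataset(ex))
  expect_identical(interpolateDataset(ds, 0), ds)

  # linear data are reproduced exactly by the (linear-fallback) interpolant
  dsi <- suppressMessages(interpolateDataset(ds, 1))
  e <- dsi@experiments[[1]]
  expect_equal(e@times, c(0, 0.5, 1, 1.5, 2))
  expect_equal(e@exprs[, "g1"], c(0, 0.25, 0.5, 0.75, 1))
  expect_identical(e@pointKind,
                   c("measured", "interpolated", "measured", "interpolated",
                     "measured"))
  expect_equal(e@weights, c(1, 0.25, 1, 0.25, 1))

  # six measured points, k = 3: 15 inserted, 21 total; grid stays increasing
  ex6 <- grnExperiment(c(0, 1, 2, 4, 8, 16), cbind(g1 = c(0, .5, .8, 1, .9, .7)),
                       cbind(u1 = rep(1, 6)))
  ds6 <- interpolateDataset(standardiseDataset(grnDataset(ex6)), 3)
  e6 <- ds6@experiments[[1]]
  expect_length(e6@times, 21)
  expect_identical(sum(e6@pointKind == "interpolated"), 15L)
  expect_true(all(diff(e6@times) > 0))
  # measured values bit-exact
  m <- e6@pointKind == "measured"
  expect_identical(e6@exprs[m, "g1"],
                   standardiseDataset(grnDataset(ex6))@experiments[[1]]@exprs[, "g1"])
  # step stimuli stay 0/1
  expect_true(all(e6@stimuli %in% c(0, 1)))
})

test_that("step-input construction follows the applied-stimulus specification", {
  U <- buildStepInputs("TGFb1", 0:9, c("TGFb1", "BMP2"))
  expect_equal(unname(U[, 1]), rep(1, 10))
  expect_equal(unname(U[, 2]), rep(0, 10))
  U2 <- buildStepInputs(c("TGFb1", "BMP2"), 0:9, c("TGFb1", "BMP2"))
  expect_true(all(U2 == 1))
  expect_true(all(buildStepInputs(character(), 0:4, c("a", "b")) == 0))
  expect_error(buildStepInputs("x", 0:4, c("a", "b")), "unknown stimulus")
})

test_that("experiments round-trip through the wide CSV format", {
  ex <- grnExperiment(c(0, 1, 2, 4), cbind(g1 = c(0, .2, .5, 1),
                                           g2 = c(0, -.5, -1, -.8)),
                      cbind(u1 = rep(1, 4), u2 = rep(0, 4)), name = "E1")
  ef <- tempfile(fileext = ".csv")
  sf <- tempfile(fileext = ".csv")
  writeExperiment(ex, ef, sf)
  back <- readExperiment(ef, sf, name = "E1")
  expect_equal(back@times, ex@times)
  expect_equal(back@exprs, ex@exprs)
  expect_equal(back@stimuli, ex@stimuli)
  expect_error(readExperiment(tempfile()), "not found")
})

test_that("experiment subsetting keeps the selected experiments", {
  exs <- lapply(1:3, function(e)
    grnExperiment(0:2, cbind(g1 = c(0, e, 2 * e)), cbind(u1 = rep(1, 3)),
                  name = paste0("E", e)))
  ds <- grnDataset(exs)
  sub <- subsetExperiments(ds, c(1, 3))
  expect_length(sub@experiments, 2)
  expect_identical(sub@experiments[[2]]@name, "E3")
  expect_identical(subsetExperiments(ds, "E2")@experiments[[1]]@name, "E2")
})
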