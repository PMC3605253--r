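test_that("DOT export is well-formed and carries the colour and frequency attributes", {
  A <- matrix(c(-1, 0, 0.8, -1), 2, byrow = TRUE,  # edge a -> b
              dimnames = list(c("a", "b"), c("a", "b")))
  B <- matrix(c(1, 0), 2, dimnames = list(c("a", "b"), "u1"))
  m <- grnModel(A, B)
  p <- grnPrior(c("a", "b"), "u1")
  p@Aflex[2, 1] <- 10
  dot <- exportDOT(m, p)
  expect_match(dot, "^digraph GRN \\{")
  expect_match(dot, "\\}$")
  expect_identical(sum(gregexpr("\\{", dot)[[1]] > 0),
                   sum(gregexpr("\\}", dot)[[1]] > 0))
  expect_match(dot, "\"a\" -> \"b\" \\[color=green")
  expect_match(dot, "\"u1\" -> \"a\" \\[color=black")

  freq <- data.frame(source = "a", target = "b", frequency = 0.76)
  dotF <- exportDOT(m, p, frequencies = freq)
  expect_match(dotF, "label=\"76%\"")
  expect_match(dotF, "penwidth=")

  # an edge-free model still produces a valid graph with all nodes
  lone <- grnModel(matrix(-1, 1, 1, dimnames = list("g", "g")),
                   matrix(0, 1, 1, dimnames = list("g", "u1")))
  dotL <- exportDOT(lone)
  expect_match(dotL, "\"g\" \\[shape=box\\]")
  expect_match(dotL, "\"u1\" \\[shape=ellipse")
  f <- tempfile(fileext = ".dot")
  exportDOT(lone, file = f)
  expect_identical(paste(readLines(f), collapse = "\n"), dotL)
})

test_that("time-course export aligns data and simulation per experiment", {
  truth <- grnModel(matrix(-1, 1, 1), matrix(1, 1, 1), geneNames = "g1",
                    stimulusNames = "u1")
  ds <- makeSimulatedDataset(truth, list(1), noiseSd = 0)
  inf <- inferNetwork(ds, config = grnConfig(kPerInterval = 0L))
  tc <- exportTimecourses(inf)
  T1 <- length(inf@dataset@experiments[[1]]@times)
  expect_identical(nrow(tc), 2L * T1)
  expect_identical(sum(tc$kind == "simulated"), T1)
  # the simulated trajectory starts at the initial state (zero)
  expect_identical(tc$g1[tc$kind == "simulated" & tc$time == 0], 0)
  f <- tempfile(fileext = ".csv")
  exportTimecourses(inf, file = f)
  back <- read.csv(f)
  expect_identical(nrow(back), nrow(tc))
  expect_equal(back$g1, tc$g1, tolerance = 1e-6)
})

test_that("models round-trip through the JSON serialisation", {
  bm <- generateBenchmark("LCT", seed = 4)
  m <- bm@truth
  m@orders <- c(1L, 2L, 1L, 3L)
  m@x0 <- rep(0, sum(m@orders))
  f <- tempfile(fileext = ".json")
  writeGRNModel(m, f)
  back <- readGRNModel(f)
  expect_equal(interactionMatrix(back), interactionMatrix(m))
  expect_equal(inputMatrix(back), inputMatrix(m))
  expect_identical(back@orders, m@orders)
  expect_identical(back@stateOrder, m@stateOrder)
})

test_that("configurations round-trip through YAML and are validated on read", {
  cfg <- grnConfig(allowedError = 0.002, maxConnections = 3L,
                   kPerInterval = 2L, sigmoid = TRUE)
  f <- tempfile(fileext = ".yaml")
  writeConfig(cfg, f)
  back <- readConfig(f)
  for (s in c("allowedError", "maxConnections", "kPerInterval", "sigmoid",
              "weightInterpolated", "maxOrder"))
    expect_identical(slot(back, s), slot(cfg, s))
  writeLines("search:\n  allowed_error: -1\n", f)
  expect_error(readConfig(f), "allowedError")
})

test_that("the command-line driver runs its subcommands reproducibly and fails cleanly", {
  outA <- file.path(tempdir(), "cliA")
  outB <- file.path(tempdir(), "cliB")
  codeA <- suppressMessages(cliMain(c("benchmark", "--kind", "NCT", "--seed",
                                      "1", "--out-dir", outA)))
  codeB <- suppressMessages(cliMain(c("benchmark", "--kind", "NCT", "--seed",
                                      "1", "--out-dir", outB)))
  expect_identical(codeA, 0L)
  expect_identical(readLines(file.path(outA, "model.json")),
                   readLines(file.path(outB, "model.json")))
  ev <- read.csv(file.path(outA, "evaluation.csv"))
  expect_true(all(c("TP", "SE", "FM") %in% names(ev)))

  # infer on the files the benchmark run wrote
  outC <- file.path(tempdir(), "cliC")
  exprs <- list.files(outA, "^expr_", full.names = TRUE)
  stims <- list.files(outA, "^stim_", full.names = TRUE)
  codeC <- suppressMessages(cliMain(c("infer", "--data",
                                      paste(exprs, collapse = ","),
                                      "--inputs",
                                      paste(stims, collapse = ","),
                                      "--out-dir", outC)))
  expect_identical(codeC, 0L)
  expect_true(file.exists(file.path(outC, "network.dot")))
  m <- readGRNModel(file.path(outC, "model.json"))
  expect_identical(sort(geneNames(m)), sort(paste0("G", 1:7)))

  # bad input: nonzero exit, message names the missing path
  expect_message(code <- cliMain(c("infer", "--data", "/nope/missing.csv")),
                 "missing.csv")
  expect_identical(code, 1L)
  expect_identical(suppressMessages(cliMain(c("show-config"))), 0L)
  expect_message(codeBad <- cliMain(character()), "usage")
  expect_identical(codeBad, 1L)
})
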