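#' @include AllClasses.R structure.R
NULL

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Deterministic benchmark topologies. Edges are (target, source) pairs.
.benchmarkTopology <- function(kind, n, m) {
  A <- NULL
  B <- NULL
  addA <- function(i, j) A <<- rbind(A, c(i, j))
  addB <- function(i, k) B <<- rbind(B, c(i, k))
  if (kind == "FCT") {
    ## every stimulus drives gene 1, so the downstream cascade is excited by
    ## all stimuli; stimuli beyond the first also act directly on "their"
    ## gene, giving the single-stimulus scenarios distinct information
    stopifnot(n >= 2L)
    for (k in seq_len(m)) addB(1L, k)
    for (k in seq_len(m)[-1L]) if (k <= n) addB(k, k)
    for (i in seq_len(n - 1L)) addA(i + 1L, i)
    if (n >= 3L) addA(3L, 1L)
  } else if (kind == "LCT") {
    ## each stimulus drives its own entry gene; the cascades converge on a
    ## shared downstream chain (cross-talk limited to that chain)
    stopifnot(n >= m + 1L)
    for (k in seq_len(m)) addB(k, k)
    for (k in seq_len(m)) addA(m + 1L, k)
    if (n > m + 1L) for (i in (m + 1L):(n - 1L)) addA(i + 1L, i)
  } else { # NCT
    stopifnot(n >= m)
    cut <- floor(seq(0L, n, length.out = m + 1L))
    for (k in seq_len(m)) {
      lo <- cut[k] + 1L
      hi <- cut[k + 1L]
      addB(lo, k)
      if (hi > lo) for (i in lo:(hi - 1L)) addA(i + 1L, i)
    }
  }
  list(A = A, B = B)
}

.reachableFrom <- function(model, input) {
  adj <- t(interactionMatrix(model) != 0)
  diag(adj) <- FALSE
  front <- which(inputMatrix(model)[, input] != 0)
  seen <- logical(nrow(adj))
  while (length(front)) {
    seen[front] <- TRUE
    front <- setdiff(which(apply(adj[front, , drop = FALSE], 2L, any)),
                     which(seen))
  }
  which(seen)
}

#' Generate a cross-talk benchmark system
#'
#' Builds a fully parametrised, stable, sparse LTI ground-truth network of
#' the requested cross-talk kind (see [GRNBenchmark-class]). The topology is
#' deterministic per kind; coefficients are drawn from the seeded RNG with
#' magnitudes bounded away from zero (`|c|` in `[0.3, 1.5]`), positive input
#' edges, occasional inhibitory gene-gene edges, and distinct diagonal
#' coefficients in `[-2, -0.2]` (distinct time constants aid
#' identifiability). Draws are rejected until every gene's noise-free
#' response amplitude reaches at least 1, emulating the upstream selection of
#' genes with pronounced temporal dynamics.
#'
#' @param kind `"FCT"`, `"LCT"` or `"NCT"`.
#' @param nGenes number of genes; defaults per kind (FCT 5, LCT 4, NCT 7).
#' @param nInputs number of stimuli, default 2.
#' @param seed integer seed; the same seed reproduces the system exactly.
#' @return a [GRNBenchmark-class].
#' @examples
#' generateBenchmark("NCT", seed = 3)
#' @export
generateBenchmark <- function(kind = c("FCT", "LCT", "NCT"), nGenes = NULL,
                              nInputs = 2L, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(nGenes))
    nGenes <- c(FCT = 5L, LCT = 4L, NCT = 7L)[[kind]]
  n <- as.integer(nGenes)
  m <- as.integer(nInputs)
  topo <- .benchmarkTopology(kind, n, m)
  gn <- paste0("G", seq_len(n))
  sn <- paste0("Input", seq_len(m))
  ampTimes <- seq(0, 16, by = 0.5)
  .withSeed(seed, {
    best <- NULL
    bestAmp <- -Inf
    for (draw in seq_len(200L)) {
      ## distinct, well-separated time constants: jittered centres of equal
      ## bins of the diagonal range, assigned to genes in random order
      width <- 1.8 / n
      centres <- -2 + (seq_len(n) - 0.5) * width
      diagA <- sample(centres + runif(n, -0.25, 0.25) * width)
      Ag <- diag(diagA, n, n)
      if (!is.null(topo$A))
        for (r in seq_len(nrow(topo$A)))
          Ag[topo$A[r, 1L], topo$A[r, 2L]] <-
            runif(1, 0.3, 1.5) * sample(c(1, -1), 1L, prob = c(0.75, 0.25))
      Bg <- matrix(0, n, m)
      if (!is.null(topo$B))
        for (r in seq_len(nrow(topo$B)))
          Bg[topo$B[r, 1L], topo$B[r, 2L]] <- runif(1, 0.3, 1.5)
      model <- grnModel(Ag, Bg, geneNames = gn, stimulusNames = sn)
      amp <- rep(0, n)
      for (k in seq_len(m)) {
        u <- as.numeric(seq_len(m) == k)
        sim <- simulateGRN(model, u, ampTimes)
        amp <- pmax(amp, apply(abs(sim), 2L, max))
      }
      if (min(amp) > bestAmp) {
        bestAmp <- min(amp)
        best <- model
      }
      if (bestAmp >= 1) break
    }
    if (bestAmp < 1)
      warning("benchmark draw did not reach the target response amplitude (",
              sprintf("%.2f", bestAmp), ")")
    new("GRNBenchmark", truth = best, kind = kind, seed = as.integer(seed))
  })
}

#' Generate artificial benchmark data
#'
#' Simulates the benchmark's ground truth under the scenario's step-stimulus
#' experiments on a short grid with exponentially increasing intervals (six
#' time points by default), adds i.i.d. Gaussian measurement noise, and
#' standardises, emulating the characteristics of real microarray time-series
#' data. Scenario `"M"` contains one single-stimulus experiment per input;
#' `"S1"`, `"S2"`, ... keep only the corresponding single experiment.
#'
#' @param benchmark a [GRNBenchmark-class].
#' @param scenario `"M"` or `"S<k>"`.
#' @param noiseSd noise standard deviation on the simulated trajectory scale,
#'   default 0.05.
#' @param seed integer seed for the noise.
#' @param times measurement grid, default `c(0, 1, 2, 4, 8, 16)`.
#' @param standardise centre/scale the noisy series (default); disable to
#'   retain the raw scale, e.g. before subsetting experiments.
#' @return a [GRNDataset-class] of measured points.
#' @export
generateData <- function(benchmark, scenario = "M", noiseSd = 0.05,
                         seed = 1L, times = c(0, 1, 2, 4, 8, 16),
                         standardise = TRUE) {
  truth <- benchmark@truth
  m <- length(stimulusNames(truth))
  expIdx <- if (identical(scenario, "M")) seq_len(m)
            else {
              k <- suppressWarnings(as.integer(sub("^S", "", scenario)))
              if (is.na(k) || k < 1L || k > m)
                stop("unknown scenario: ", scenario)
              k
            }
  exps <- .withSeed(seed, lapply(seq_len(m), function(k) {
    u <- as.numeric(seq_len(m) == k)
    sim <- simulateGRN(truth, u, times)
    noisy <- sim + matrix(rnorm(length(sim), sd = noiseSd), nrow(sim))
    U <- matrix(rep(u, each = length(times)), length(times),
                dimnames = list(NULL, stimulusNames(truth)))
    grnExperiment(times, noisy, U, name = paste0("S", k))
  }))
  ds <- grnDataset(exps[expIdx])
  if (standardise) ds <- standardiseDataset(ds)
  ds
}

#' List the connections of a model
#'
#' All non-zero gene-gene and input-gene coefficients of a model, with their
#' sign codes.
#'
#' @param model a [GRNModel-class] (or [GRNInference-class] /
#'   [GRNBenchmark-class]).
#' @param selfLoops include the diagonal self-regulation entries (default
#'   `TRUE`).
#' @return data.frame with columns `source`, `target`, `type`, `coefficient`,
#'   `code`.
#' @export
edgeList <- function(model, selfLoops = TRUE) {
  model <- .asModel(model)
  gn <- geneNames(model)
  sn <- stimulusNames(model)
  A <- interactionMatrix(model)
  B <- inputMatrix(model)
  rows <- list()
  for (i in seq_along(gn)) {
    for (j in seq_along(gn))
      if (A[i, j] != 0 && (selfLoops || i != j))
        rows[[length(rows) + 1L]] <- data.frame(
          source = gn[j], target = gn[i], type = "gene",
          coefficient = A[i, j], code = encodeEdge(A[i, j]),
          stringsAsFactors = FALSE)
    for (k in seq_along(sn))
      if (B[i, k] != 0)
        rows[[length(rows) + 1L]] <- data.frame(
          source = sn[k], target = gn[i], type = "input",
          coefficient = B[i, k], code = encodeEdge(B[i, k]),
          stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(source = character(), target = character(),
                      type = character(), coefficient = numeric(),
                      code = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.asModel <- function(x) {
  if (is(x, "GRNInference")) x@model
  else if (is(x, "GRNBenchmark")) x@truth
  else x
}

#' Evaluate an inferred structure against the ground truth
#'
#' Classifies every candidate position of the interaction and input matrices
#' (`N^2 + M*N` positions, self-loops included): `TP` present in both with
#' matching sign, `FPs` present in both with the wrong sign, `FPn` inferred
#' but absent from the truth, `FN` true but missing, `TN` absent in both.
#' Genes must agree between the two models; stimuli absent from the inferred
#' model (e.g. after single-stimulus inference) count as all-absent columns.
#'
#' @param inferred a [GRNModel-class] (or [GRNInference-class]).
#' @param truth a [GRNModel-class] (or [GRNBenchmark-class]).
#' @return a [GRNEvaluation-class].
#' @export
evaluateStructure <- function(inferred, truth) {
  inferred <- .asModel(inferred)
  truth <- .asModel(truth)
  gn <- geneNames(truth)
  if (!setequal(gn, geneNames(inferred)))
    stop("inferred and true model must share the gene set")
  gi <- match(gn, geneNames(inferred))
  sn <- stimulusNames(truth)
  if (length(setdiff(stimulusNames(inferred), sn)))
    stop("inferred model has stimuli unknown to the truth")
  At <- interactionMatrix(truth)
  Ai <- interactionMatrix(inferred)[gi, gi, drop = FALSE]
  Bt <- inputMatrix(truth)
  Bi <- matrix(0, length(gn), length(sn), dimnames = list(gn, sn))
  snIn <- stimulusNames(inferred)
  if (length(snIn))
    Bi[, snIn] <- inputMatrix(inferred)[gi, , drop = FALSE]
  ct <- encodeEdge(cbind(At, Bt))
  ci <- encodeEdge(cbind(Ai, Bi))
  TP <- sum(ct != 0 & ci == ct)
  FPs <- sum(ct != 0 & ci != 0 & ci != ct)
  FPn <- sum(ct == 0 & ci != 0)
  FN <- sum(ct != 0 & ci == 0)
  TN <- sum(ct == 0 & ci == 0)
  structureEvaluation(TP = TP, TN = TN, FPn = FPn, FPs = FPs, FN = FN)
}

#' Sweep the allowed-error setting over benchmark scenarios
#'
#' Generates one noisy realisation of the benchmark data (shared across
#' scenarios, so the multi-experiment scenario integrates exactly the
#' single-stimulus experiments), then infers one model per scenario and
#' allowed-error value and evaluates each against the truth. Smaller allowed
#' errors force denser structures; the model error `J` (sum of the accepted
#' sub-model output errors) increases gradually with the setting.
#'
#' @param benchmark a [GRNBenchmark-class].
#' @param scenarios character vector of scenarios (see [generateData()]).
#' @param values allowed-error values, default `0.001, 0.002, ..., 0.01`.
#' @param noiseSd measurement-noise standard deviation.
#' @param seed integer seed for the data realisation.
#' @param config base [GRNConfig-class]; `allowedError` is overridden per
#'   sweep value.
#' @param prior optional [GRNPrior-class].
#' @return data.frame with one row per scenario and value: confusion counts,
#'   `SE`, `SP`, `PR`, `FM`, model error `J` and edge count.
#' @export
sweepAllowedError <- function(benchmark, scenarios = c("M", "S1", "S2"),
                              values = seq(0.001, 0.01, by = 0.001),
                              noiseSd = 0.05, seed = 1L,
                              config = grnConfig(), prior = NULL) {
  raw <- generateData(benchmark, scenario = "M", noiseSd = noiseSd,
                      seed = seed, standardise = FALSE)
  m <- length(stimulusNames(benchmark))
  rows <- list()
  for (sc in scenarios) {
    idx <- if (identical(sc, "M")) seq_len(m)
           else as.integer(sub("^S", "", sc))
    ds <- standardiseDataset(subsetExperiments(raw, idx))
    for (v in values) {
      cfg <- config
      cfg@allowedError <- v
      inf <- inferNetwork(ds, prior = prior, config = cfg)
      ev <- evaluateStructure(inf, benchmark)
      cnt <- counts(ev)
      ms <- measures(ev)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, allowedError = v, t(cnt), t(ms),
        J = sum(modelError(inf)),
        edges = nrow(edgeList(inf@model)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Resampling-based edge-frequency validation
#'
#' Validates an inferred (nominal) model by repeated random perturbation of
#' the time-series data: Gaussian noise is added to the standardised measured
#' series, the perturbed data are re-standardised and the inference is rerun;
#' the relative frequency with which each nominal connection (sign-matched)
#' reappears across runs ranks the connections by reliability.
#'
#' @param dataset the [GRNDataset-class] the nominal model is inferred from
#'   (interpolated points, if any, are dropped before perturbing).
#' @param prior optional [GRNPrior-class].
#' @param config a [GRNConfig-class].
#' @param nRuns number of perturb-and-infer cycles, default 100.
#' @param noiseSd perturbation standard deviation, default 0.05.
#' @param seed integer seed.
#' @return data.frame of the nominal connections with a `frequency` column in
#'   `[0, 1]`; the run count is attached as attribute `nRuns`, the nominal
#'   inference as attribute `nominal`.
#' @export
resampleValidate <- function(dataset, prior = NULL, config = grnConfig(),
                             nRuns = 100L, noiseSd = 0.05, seed = 1L) {
  measuredOnly <- dataset
  measuredOnly@experiments <- lapply(dataset@experiments, function(ex) {
    keep <- ex@pointKind == "measured"
    ex@times <- ex@times[keep]
    ex@exprs <- ex@exprs[keep, , drop = FALSE]
    ex@stimuli <- ex@stimuli[keep, , drop = FALSE]
    ex@pointKind <- ex@pointKind[keep]
    ex@weights <- ex@weights[keep]
    ex
  })
  if (!measuredOnly@standardised)
    measuredOnly <- standardiseDataset(measuredOnly)
  nominal <- inferNetwork(measuredOnly, prior = prior, config = config)
  edges <- edgeList(nominal@model)
  hits <- numeric(nrow(edges))
  .withSeed(seed, for (run in seq_len(nRuns)) {
    perturbed <- measuredOnly
    perturbed@experiments <- lapply(measuredOnly@experiments, function(ex) {
      ex@exprs <- ex@exprs + matrix(rnorm(length(ex@exprs), sd = noiseSd),
                                    nrow(ex@exprs))
      ex
    })
    perturbed@standardised <- FALSE
    perturbed <- standardiseDataset(perturbed)
    runFit <- inferNetwork(perturbed, prior = prior, config = config)
    runEdges <- edgeList(runFit@model)
    key <- function(df) paste(df$source, df$target, df$code)
    hits <- hits + (key(edges) %in% key(runEdges))
  })
  edges$frequency <- if (nRuns > 0) hits / nRuns else rep(0, nrow(edges))
  attr(edges, "nRuns") <- as.integer(nRuns)
  attr(edges, "nominal") <- nominal
  edges
}
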