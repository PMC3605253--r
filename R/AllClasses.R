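#' @import methods
#' @importFrom stats approx approxfun optim rnorm runif setNames spline
#' @importFrom utils read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib dynGRN, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## GRNExperiment: one experiment (one stimulus combination)
## ---------------------------------------------------------------------------

#' One stimulation experiment
#'
#' Holds the time grid, expression matrix and stimulus matrix of a single
#' experiment, together with per-time-point bookkeeping: whether a point was
#' measured or inserted by interpolation, and its weight in the fitting
#' objective.
#'
#' @slot name experiment label.
#' @slot times sampling times (strictly increasing, hours or any consistent
#'   unit).
#' @slot exprs numeric matrix, time points x genes.
#' @slot stimuli numeric matrix, time points x stimuli; typically 0/1 step
#'   profiles constant over the experiment.
#' @slot pointKind `"measured"` or `"interpolated"` per time point.
#' @slot weights non-negative weight per time point; measured points carry at
#'   least the weight of interpolated ones.
#' @export
setClass("GRNExperiment",
  representation(
    name = "character",
    times = "numeric",
    exprs = "matrix",
    stimuli = "matrix",
    pointKind = "character",
    weights = "numeric"
  )
)

setValidity("GRNExperiment", function(object) {
  msg <- character()
  tt <- object@times
  if (length(tt) < 1L) msg <- c(msg, "at least one time point required")
  if (any(diff(tt) <= 0)) msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@exprs) != length(tt))
    msg <- c(msg, "exprs must have one row per time point")
  if (nrow(object@stimuli) != length(tt))
    msg <- c(msg, "stimuli must have one row per time point")
  if (length(object@pointKind) != length(tt) ||
      !all(object@pointKind %in% c("measured", "interpolated")))
    msg <- c(msg, "pointKind must be 'measured'/'interpolated' per time point")
  if (length(object@weights) != length(tt) || any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative, one per time point")
  if (length(msg)) msg else TRUE
})

#' Construct a [GRNExperiment-class]
#'
#' @param times strictly increasing sampling times.
#' @param exprs time points x genes expression matrix (column names are gene
#'   names).
#' @param stimuli time points x stimuli matrix (column names are stimulus
#'   names).
#' @param name experiment label.
#' @param pointKind,weights optional per-point flags and weights; all points
#'   default to measured with unit weight.
#' @return a `GRNExperiment`.
#' @examples
#' ex <- grnExperiment(0:3, cbind(g1 = c(0, .5, .8, 1)), cbind(u1 = rep(1, 4)))
#' @export
grnExperiment <- function(times, exprs, stimuli, name = "experiment",
                          pointKind = NULL, weights = NULL) {
  exprs <- as.matrix(exprs)
  stimuli <- as.matrix(stimuli)
  if (is.null(pointKind)) pointKind <- rep("measured", length(times))
  if (is.null(weights)) weights <- rep(1, length(times))
  new("GRNExperiment", name = name, times = as.numeric(times), exprs = exprs,
      stimuli = stimuli, pointKind = pointKind, weights = as.numeric(weights))
}

## ---------------------------------------------------------------------------
## GRNDataset: ordered collection of experiments over shared genes/stimuli
## ---------------------------------------------------------------------------

#' Multi-experiment time-series dataset
#'
#' An ordered collection of [GRNExperiment-class] objects sharing the same
#' genes and stimuli. All experiments are fitted jointly by one model; the
#' regression stage concatenates their time points.
#'
#' @slot experiments list of `GRNExperiment`.
#' @slot geneNames shared gene labels.
#' @slot stimulusNames shared stimulus labels.
#' @slot standardised whether [standardiseDataset()] has been applied.
#' @export
setClass("GRNDataset",
  representation(
    experiments = "list",
    geneNames = "character",
    stimulusNames = "character",
    standardised = "logical"
  ),
  prototype(standardised = FALSE)
)

setValidity("GRNDataset", function(object) {
  msg <- character()
  if (length(object@experiments) < 1L)
    msg <- c(msg, "at least one experiment required")
  for (ex in object@experiments) {
    if (!is(ex, "GRNExperiment")) {
      msg <- c(msg, "experiments must be GRNExperiment objects")
      break
    }
    if (ncol(ex@exprs) != length(object@geneNames))
      msg <- c(msg, "all experiments must cover the shared genes")
    if (ncol(ex@stimuli) != length(object@stimulusNames))
      msg <- c(msg, "all experiments must cover the shared stimuli")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Construct a [GRNDataset-class]
#'
#' @param experiments list of [GRNExperiment-class] objects with identical
#'   gene and stimulus columns.
#' @param standardised set `TRUE` if the series are already centred at zero
#'   and scaled to `[-1, 1]`.
#' @return a `GRNDataset`.
#' @export
grnDataset <- function(experiments, standardised = FALSE) {
  if (is(experiments, "GRNExperiment")) experiments <- list(experiments)
  ex1 <- experiments[[1L]]
  gn <- colnames(ex1@exprs)
  sn <- colnames(ex1@stimuli)
  if (is.null(gn)) gn <- sprintf("g%d", seq_len(ncol(ex1@exprs)))
  if (is.null(sn) && ncol(ex1@stimuli) > 0)
    sn <- sprintf("u%d", seq_len(ncol(ex1@stimuli)))
  experiments <- lapply(experiments, function(ex) {
    if (ncol(ex@exprs) > 0) colnames(ex@exprs) <- gn
    if (ncol(ex@stimuli) > 0) colnames(ex@stimuli) <- sn
    ex
  })
  new("GRNDataset", experiments = experiments, geneNames = gn,
      stimulusNames = if (is.null(sn)) character() else sn,
      standardised = standardised)
}

## ---------------------------------------------------------------------------
## GRNModel: sparse LTI state-space model with integrator-chain sub-models
## ---------------------------------------------------------------------------

#' Gene-regulatory network model
#'
#' A sparse linear time-invariant state-space model `dx/dt = A x + B u` in
#' which every observed gene is described by a sub-model: an integrator chain
#' of order `r >= 1` whose stages share one diagonal coefficient. The model is
#' stored gene-wise (`interaction` is the genes x genes coefficient matrix,
#' `input` the genes x stimuli matrix, rows are targets); the chain-expanded
#' state-space matrices are derived by [stateMatrices()].
#'
#' @slot interaction genes x genes coefficient matrix (entry `[i, j]` is the
#'   influence of gene `j` on gene `i`; the diagonal holds the self-regulation
#'   / degradation coefficient, constrained negative).
#' @slot input genes x stimuli coefficient matrix.
#' @slot orders sub-model order per gene (chain length).
#' @slot stateOrder genes in the order their sub-models occupy the state
#'   vector (the inclusion order of the inference; forward connections then
#'   sit below the state-space diagonal and global feedbacks above it).
#' @slot x0 initial state (chain-expanded), zero for standardised data.
#' @slot t0 model start time.
#' @slot sigmoid whether the right-hand side is passed through a saturating
#'   sigmoid.
#' @slot sigmoidGain gain of the sigmoid.
#' @export
setClass("GRNModel",
  representation(
    interaction = "matrix",
    input = "matrix",
    orders = "integer",
    stateOrder = "integer",
    x0 = "numeric",
    t0 = "numeric",
    sigmoid = "logical",
    sigmoidGain = "numeric"
  ),
  prototype(t0 = 0, sigmoid = FALSE, sigmoidGain = 1)
)

setValidity("GRNModel", function(object) {
  msg <- character()
  n <- nrow(object@interaction)
  if (ncol(object@interaction) != n)
    msg <- c(msg, "interaction matrix must be square")
  if (nrow(object@input) != n)
    msg <- c(msg, "input matrix must have one row per gene")
  if (length(object@orders) != n || any(object@orders < 1L))
    msg <- c(msg, "one order >= 1 required per gene")
  if (length(object@stateOrder) != n ||
      !setequal(object@stateOrder, seq_len(n)))
    msg <- c(msg, "stateOrder must be a permutation of the genes")
  if (n > 0 && any(diag(object@interaction) >= 0))
    msg <- c(msg, "diagonal (self-regulation) coefficients must be negative")
  if (length(object@x0) != sum(object@orders))
    msg <- c(msg, "x0 must have one entry per chain state")
  if (length(msg)) msg else TRUE
})

#' Construct a [GRNModel-class]
#'
#' @param interaction genes x genes coefficient matrix (targets in rows,
#'   negative diagonal).
#' @param input genes x stimuli coefficient matrix.
#' @param orders integer sub-model orders, default all 1.
#' @param geneNames,stimulusNames labels; taken from the matrices when named.
#' @param stateOrder permutation giving the state layout, default data order.
#' @param x0 initial chain-expanded state, default zero.
#' @param t0 start time.
#' @param sigmoid,sigmoidGain optional saturating nonlinearity, see
#'   [sigmoidTransform()].
#' @return a `GRNModel`.
#' @examples
#' m <- grnModel(matrix(-1, 1, 1), matrix(1, 1, 1),
#'               geneNames = "g1", stimulusNames = "u1")
#' @export
grnModel <- function(interaction, input, orders = NULL, geneNames = NULL,
                     stimulusNames = NULL, stateOrder = NULL, x0 = NULL,
                     t0 = 0, sigmoid = FALSE, sigmoidGain = 1) {
  interaction <- as.matrix(interaction)
  input <- as.matrix(input)
  n <- nrow(interaction)
  if (is.null(geneNames))
    geneNames <- rownames(interaction) %||% sprintf("g%d", seq_len(n))
  if (is.null(stimulusNames))
    stimulusNames <- colnames(input) %||% sprintf("u%d", seq_len(ncol(input)))
  dimnames(interaction) <- list(geneNames, geneNames)
  dimnames(input) <- list(geneNames, stimulusNames)
  if (is.null(orders)) orders <- rep(1L, n)
  if (is.null(stateOrder)) stateOrder <- seq_len(n)
  if (is.null(x0)) x0 <- rep(0, sum(orders))
  new("GRNModel", interaction = interaction, input = input,
      orders = as.integer(orders), stateOrder = as.integer(stateOrder),
      x0 = as.numeric(x0), t0 = t0, sigmoid = sigmoid,
      sigmoidGain = sigmoidGain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## GRNPrior: fix/flexible prior knowledge
## ---------------------------------------------------------------------------

#' Structural prior knowledge
#'
#' Prior knowledge about network connections in the coding convention
#' `1` = connection of unknown sign, `10` = activation, `-10` = inhibition,
#' `0` = no connection, `NA` = unknown. "Fix" entries are rigid requirements:
#' coded edges are always part of the model and fix `0` excludes an edge from
#' the search. "Flexible" entries may be overruled by the data; disagreement
#' is charged to the objective as `lambda * sum(score * distance)`, with the
#' sign distance of [signDistance()].
#'
#' @slot Afix,Aflex genes x genes code matrices (targets in rows).
#' @slot Bfix,Bflex genes x stimuli code matrices.
#' @slot Ascore,Bscore reliability scores in `[0, 1]` for flexible entries.
#' @slot Aorigin,Borigin character matrices tagging the knowledge source
#'   (e.g. `"literature"`, `"binding-site"`), used for graph colouring.
#' @slot lambda penalty weight (>= 0).
#' @export
setClass("GRNPrior",
  representation(
    Afix = "matrix", Bfix = "matrix",
    Aflex = "matrix", Bflex = "matrix",
    Ascore = "matrix", Bscore = "matrix",
    Aorigin = "matrix", Borigin = "matrix",
    lambda = "numeric"
  )
)

.validCodes <- c(0, 1, 10, -10)

setValidity("GRNPrior", function(object) {
  msg <- character()
  okCodes <- function(m) all(m[!is.na(m)] %in% .validCodes)
  if (!okCodes(object@Afix) || !okCodes(object@Bfix) ||
      !okCodes(object@Aflex) || !okCodes(object@Bflex))
    msg <- c(msg, "codes must be NA, 0, 1, 10 or -10")
  if (any(!is.na(object@Afix) & !is.na(object@Aflex)) ||
      any(!is.na(object@Bfix) & !is.na(object@Bflex)))
    msg <- c(msg, "fix and flexible knowledge must not overlap")
  if (any(is.na(object@Ascore[!is.na(object@Aflex)])) ||
      any(is.na(object@Bscore[!is.na(object@Bflex)])))
    msg <- c(msg, "every flexible entry needs a score")
  sc <- c(object@Ascore, object@Bscore)
  if (any(sc < 0 | sc > 1, na.rm = TRUE))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(object@lambda) != 1L || object@lambda < 0)
    msg <- c(msg, "lambda must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a [GRNPrior-class]
#'
#' All matrices default to all-`NA` (no knowledge). Scores default to 1 where
#' flexible knowledge is given.
#'
#' @param geneNames,stimulusNames network labels.
#' @param Afix,Bfix,Aflex,Bflex code matrices (see [GRNPrior-class]); vectors
#'   are recycled, row/column names are matched when present.
#' @param Ascore,Bscore reliability scores for flexible entries.
#' @param Aorigin,Borigin origin tags.
#' @param lambda penalty weight, default 0.1.
#' @return a `GRNPrior`.
#' @export
grnPrior <- function(geneNames, stimulusNames = character(),
                     Afix = NULL, Bfix = NULL, Aflex = NULL, Bflex = NULL,
                     Ascore = NULL, Bscore = NULL,
                     Aorigin = NULL, Borigin = NULL, lambda = 0.1) {
  n <- length(geneNames); m <- length(stimulusNames)
  blank <- function(x, nr, nc, rn, cn, fill = NA_real_) {
    if (is.null(x)) x <- matrix(fill, nr, nc)
    x <- as.matrix(x)
    dimnames(x) <- list(rn, cn)
    x
  }
  Afix <- blank(Afix, n, n, geneNames, geneNames)
  Bfix <- blank(Bfix, n, m, geneNames, stimulusNames)
  Aflex <- blank(Aflex, n, n, geneNames, geneNames)
  Bflex <- blank(Bflex, n, m, geneNames, stimulusNames)
  if (is.null(Ascore)) { Ascore <- Aflex * 0; Ascore[!is.na(Aflex)] <- 1 }
  if (is.null(Bscore)) { Bscore <- Bflex * 0; Bscore[!is.na(Bflex)] <- 1 }
  Ascore <- blank(Ascore, n, n, geneNames, geneNames)
  Bscore <- blank(Bscore, n, m, geneNames, stimulusNames)
  Aorigin <- blank(Aorigin, n, n, geneNames, geneNames, NA_character_)
  Borigin <- blank(Borigin, n, m, geneNames, stimulusNames, NA_character_)
  storage.mode(Aorigin) <- "character"
  storage.mode(Borigin) <- "character"
  new("GRNPrior", Afix = Afix, Bfix = Bfix, Aflex = Aflex, Bflex = Bflex,
      Ascore = Ascore, Bscore = Bscore, Aorigin = Aorigin, Borigin = Borigin,
      lambda = lambda)
}

## ---------------------------------------------------------------------------
## GRNConfig: all heuristic settings
## ---------------------------------------------------------------------------

#' Inference settings
#'
#' All tunable settings of the heuristic. `allowedError` is the per-time-series
#' model-error threshold: a sub-model whose (unpenalised) output error exceeds
#' it is extended by further connections, so smaller values produce denser
#' networks.
#'
#' @slot allowedError per-time-series error threshold (> 0).
#' @slot maxConnections maximal incoming connections per gene beyond the
#'   self-loop.
#' @slot maxOrder maximal sub-model (integrator-chain) order.
#' @slot kPerInterval interpolated points inserted per measured interval.
#' @slot weightMeasured,weightInterpolated objective weights of measured and
#'   interpolated time points.
#' @slot growThreshold relative improvement a structural extension must
#'   achieve to be accepted (new J <= (1 - growThreshold) * old J).
#' @slot pruneThreshold relative worsening tolerated when removing a
#'   connection (new J <= (1 + pruneThreshold) * old J).
#' @slot lowerBound,upperBound box bounds for all coefficients.
#' @slot diagUpper upper bound of the (negative) diagonal coefficient.
#' @slot maxit,pgtol L-BFGS-B iteration cap and projected-gradient tolerance.
#' @slot rtol,atol tolerances of the numerical ODE solver.
#' @slot sigmoid,sigmoidGain optional saturating nonlinearity.
#' @slot seed integer seed; the heuristic itself is deterministic, the seed
#'   feeds benchmark generation and resampling.
#' @export
setClass("GRNConfig",
  representation(
    allowedError = "numeric",
    maxConnections = "integer",
    maxOrder = "integer",
    kPerInterval = "integer",
    weightMeasured = "numeric",
    weightInterpolated = "numeric",
    growThreshold = "numeric",
    pruneThreshold = "numeric",
    lowerBound = "numeric",
    upperBound = "numeric",
    diagUpper = "numeric",
    maxit = "integer",
    pgtol = "numeric",
    rtol = "numeric",
    atol = "numeric",
    sigmoid = "logical",
    sigmoidGain = "numeric",
    seed = "integer"
  )
)

setValidity("GRNConfig", function(object) {
  msg <- character()
  if (object@allowedError <= 0) msg <- c(msg, "allowedError must be > 0")
  if (object@maxOrder < 1L) msg <- c(msg, "maxOrder must be >= 1")
  if (object@maxConnections < 0L) msg <- c(msg, "maxConnections must be >= 0")
  if (object@kPerInterval < 0L) msg <- c(msg, "kPerInterval must be >= 0")
  if (object@weightMeasured < object@weightInterpolated)
    msg <- c(msg, "measured weight must be >= interpolated weight")
  if (object@diagUpper >= 0) msg <- c(msg, "diagUpper must be negative")
  if (object@lowerBound >= object@upperBound)
    msg <- c(msg, "lowerBound must be below upperBound")
  if (length(msg)) msg else TRUE
})

#' Construct a [GRNConfig-class]
#'
#' @param allowedError per-time-series error threshold, default 0.005.
#' @param maxConnections maximal incoming connections beyond the self-loop,
#'   default 4.
#' @param maxOrder maximal sub-model order, default 3.
#' @param kPerInterval interpolated points per measured interval, default 3.
#' @param weightMeasured,weightInterpolated objective weights, defaults 1 and
#'   0.25.
#' @param growThreshold,pruneThreshold structural acceptance thresholds,
#'   default 0.05 each.
#' @param lowerBound,upperBound coefficient box bounds, default `[-50, 50]`.
#' @param diagUpper upper bound of the diagonal coefficient, default `-1e-3`
#'   (sub-models are kept strictly stable).
#' @param maxit,pgtol optimiser settings, defaults 200 and 1e-8.
#' @param rtol,atol solver tolerances, defaults 1e-6 and 1e-8.
#' @param sigmoid,sigmoidGain saturating nonlinearity switch and gain.
#' @param seed integer seed.
#' @return a `GRNConfig`.
#' @export
grnConfig <- function(allowedError = 0.005, maxConnections = 4L,
                      maxOrder = 3L, kPerInterval = 3L, weightMeasured = 1,
                      weightInterpolated = 0.25, growThreshold = 0.05,
                      pruneThreshold = 0.05, lowerBound = -50,
                      upperBound = 50, diagUpper = -1e-3, maxit = 200L,
                      pgtol = 1e-8, rtol = 1e-6, atol = 1e-8,
                      sigmoid = FALSE, sigmoidGain = 1, seed = 1L) {
  new("GRNConfig", allowedError = allowedError,
      maxConnections = as.integer(maxConnections),
      maxOrder = as.integer(maxOrder),
      kPerInterval = as.integer(kPerInterval),
      weightMeasured = weightMeasured,
      weightInterpolated = weightInterpolated,
      growThreshold = growThreshold, pruneThreshold = pruneThreshold,
      lowerBound = lowerBound, upperBound = upperBound,
      diagUpper = diagUpper, maxit = as.integer(maxit), pgtol = pgtol,
      rtol = rtol, atol = atol, sigmoid = sigmoid,
      sigmoidGain = sigmoidGain, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## GRNBenchmark and GRNEvaluation
## ---------------------------------------------------------------------------

#' Benchmark system
#'
#' A ground-truth network for benchmarking, characterised by its degree of
#' cross-talk between the stimuli: `"FCT"` (full cross-talk, every gene is
#' reachable from every stimulus), `"LCT"` (limited cross-talk, some but not
#' all genes respond to more than one stimulus) or `"NCT"` (no cross-talk,
#' the stimuli drive disjoint sub-networks).
#'
#' @slot truth the generating [GRNModel-class].
#' @slot kind `"FCT"`, `"LCT"` or `"NCT"`.
#' @slot seed seed used to draw the coefficients.
#' @export
setClass("GRNBenchmark",
  representation(truth = "GRNModel", kind = "character", seed = "integer")
)

setValidity("GRNBenchmark", function(object) {
  if (!object@kind %in% c("FCT", "LCT", "NCT"))
    "kind must be FCT, LCT or NCT" else TRUE
})

#' Edge-confusion evaluation of an inferred structure
#'
#' Confusion counts over all `N^2 + M*N` candidate positions (including
#' self-loops) of a network with `N` genes and `M` stimuli, with the
#' sign-aware false-positive split: `FPs` are connections recovered with the
#' wrong sign, `FPn` are modelled interactions absent from the true network.
#' Derived measures:
#' \deqn{SE = TP/(TP+FN+FPs), \quad SP = TN/(TN+FPn),}
#' \deqn{PR = TP/(TP+FPn+FPs), \quad FM = 2 \cdot PR \cdot SE/(PR+SE).}
#'
#' @slot TP,TN,FPn,FPs,FN edge confusion counts.
#' @slot SE,SP,PR,FM derived measures in `[0, 1]`.
#' @export
setClass("GRNEvaluation",
  representation(TP = "integer", TN = "integer", FPn = "integer",
                 FPs = "integer", FN = "integer",
                 SE = "numeric", SP = "numeric", PR = "numeric",
                 FM = "numeric")
)

#' Build a [GRNEvaluation-class] from confusion counts
#'
#' Applies the four measure formulas to given counts. Empty denominators
#' yield 0 (an empty inferred model against a non-empty truth scores
#' sensitivity 0).
#'
#' @param TP,TN,FPn,FPs,FN confusion counts.
#' @return a `GRNEvaluation`.
#' @examples
#' structureEvaluation(TP = 18, TN = 15, FPn = 2, FPs = 0, FN = 0)
#' @export
structureEvaluation <- function(TP, TN, FPn, FPs, FN) {
  frac <- function(num, den) if (den > 0) num / den else 0
  SE <- frac(TP, TP + FN + FPs)
  SP <- frac(TN, TN + FPn)
  PR <- frac(TP, TP + FPn + FPs)
  FM <- if (PR + SE > 0) 2 * PR * SE / (PR + SE) else 0
  new("GRNEvaluation", TP = as.integer(TP), TN = as.integer(TN),
      FPn = as.integer(FPn), FPs = as.integer(FPs), FN = as.integer(FN),
      SE = SE, SP = SP, PR = PR, FM = FM)
}

## ---------------------------------------------------------------------------
## GRNInference: result container of inferNetwork()
## ---------------------------------------------------------------------------

#' Result of a network inference run
#'
#' Bundles the final model with the per-gene sub-model errors, the inclusion
#' order, the candidate-acceptance audit trail and the data/config used, so
#' that every reported figure can be reproduced from the object.
#'
#' @slot model the inferred [GRNModel-class].
#' @slot submodelError named per-gene output error (J of the accepted
#'   sub-model fit).
#' @slot coupledError weighted squared error of the final coupled simulation
#'   against the data, summed over genes.
#' @slot inclusionOrder gene names in inclusion order.
#' @slot log audit trail, one line per structural decision.
#' @slot dataset the (standardised, interpolated) data used.
#' @slot config the [GRNConfig-class] used.
#' @export
setClass("GRNInference",
  representation(
    model = "GRNModel",
    submodelError = "numeric",
    coupledError = "numeric",
    inclusionOrder = "character",
    log = "character",
    dataset = "GRNDataset",
    config = "GRNConfig"
  )
)
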