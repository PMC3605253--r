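#' @include AllClasses.R ode.R
NULL

#' Numeric differentiation of one time series
#'
#' Central differences at interior points, one-sided differences at the
#' boundaries. Applied per experiment on the (interpolated) grid; series are
#' never differentiated across experiment boundaries.
#'
#' @param y series values.
#' @param times sampling times (strictly increasing).
#' @return vector of derivative estimates, same length as `y`.
#' @examples
#' numericDerivative(c(0, 1, 4), c(0, 1, 2))  # t^2 -> 1, 2, 3
#' @export
numericDerivative <- function(y, times) {
  n <- length(y)
  stopifnot(length(times) == n, n >= 2L)
  if (any(diff(times) == 0)) stop("duplicate time values")
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (times[2L] - times[1L])
  d[n] <- (y[n] - y[n - 1L]) / (times[n] - times[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (times[i + 1L] - times[i - 1L])
  }
  d
}

#' Weighted linear-regression initialisation
#'
#' Initial sub-model parameters from the regression
#' `theta = ([U X]' W [U X])^-1 [U X]' W dxdt`, where the rows of `U` (input
#' levels) and `X` (state series) are the concatenated time points of all
#' experiments, `W` is the diagonal weight matrix and `dxdt` the numeric
#' derivative of the target series. Concatenation across experiments rests on
#' the dynamic-independence assumption of regression on derivative data.
#'
#' @param U inputs matrix (T x number of input terms), or `NULL`.
#' @param X state-series matrix (T x number of state terms; the target gene's
#'   own series forms the self-regulation column).
#' @param weights per-row weights (length T).
#' @param dxdt numeric derivative of the target series (length T).
#' @return parameter vector, input coefficients first, then state
#'   coefficients.
#' @export
regressInit <- function(U, X, weights, dxdt) {
  H <- cbind(U, X)
  stopifnot(nrow(H) == length(dxdt), nrow(H) == length(weights))
  sw <- sqrt(weights)
  Hs <- H * sw
  if (qr(Hs)$rank < ncol(Hs))
    stop(structure(class = c("grnUnidentifiable", "error", "condition"),
                   list(message = "unidentifiable structure: regressor matrix is rank deficient",
                        call = sys.call(-1))))
  as.numeric(solve(crossprod(Hs), crossprod(Hs, dxdt * sw)))
}

#' Adapt first-order parameters to a higher-order chain
#'
#' Initialises an order-`r` integrator chain from a fitted first-order
#' sub-model such that the total time constant and the static gain of the
#' observed state are unchanged: the diagonal coefficient becomes
#' `a_r = r * a_1` (so `r/(-a_r) = 1/(-a_1)`), and every incoming coefficient
#' is rescaled by `(-a_r)^r / (-a_1)` (so `b_r/(-a_r)^r = b_1/(-a_1)`).
#'
#' @param theta parameter vector with the self-regulation coefficient in the
#'   last position (as used throughout the fitting).
#' @param r target order (>= 1; `r = 1` is the identity).
#' @return adapted parameter vector.
#' @export
higherOrderInit <- function(theta, r) {
  r <- as.integer(r)
  stopifnot(r >= 1L, length(theta) >= 1L)
  if (r == 1L) return(theta)
  p <- length(theta)
  a1 <- theta[p]
  if (a1 >= 0) stop("unstable sub-model: diagonal coefficient must be negative")
  ar <- r * a1
  scale <- (-ar)^r / (-a1)
  c(theta[-p] * scale, ar)
}

## ---------------------------------------------------------------------------
## Internal fitting machinery
## ---------------------------------------------------------------------------

## Per-experiment arrays used by the fitting code: times, Y, U, weights and
## the numeric derivatives of every gene series.
.fitData <- function(dataset) {
  lapply(dataset@experiments, function(ex) {
    N <- ncol(ex@exprs)
    dY <- if (N > 0 && length(ex@times) >= 2L)
      vapply(seq_len(N), function(j) numericDerivative(ex@exprs[, j],
                                                       ex@times),
             numeric(length(ex@times)))
    else matrix(0, length(ex@times), N)
    list(times = ex@times, Y = ex@exprs, U = ex@stimuli, w = ex@weights,
         dY = matrix(dY, nrow = length(ex@times)))
  })
}

## A candidate structure for one gene: incoming stimuli, incoming genes and
## whether each incoming gene is forced by its fitted trajectory (included)
## or by its measured+interpolated data (proxy -> global feedback).
.candidate <- function(gene, inputs = integer(), sources = integer(),
                       proxy = logical(length(sources)), order = 1L) {
  list(gene = gene, inputs = as.integer(inputs),
       sources = as.integer(sources), proxy = as.logical(proxy),
       order = as.integer(order))
}

## Forcing regressors of a candidate, one T x p matrix per experiment.
.forcing <- function(cand, fd, traj) {
  lapply(seq_along(fd), function(e) {
    ex <- fd[[e]]
    cols <- list()
    if (length(cand$inputs))
      cols <- c(cols, list(ex$U[, cand$inputs, drop = FALSE]))
    if (length(cand$sources)) {
      S <- vapply(seq_along(cand$sources), function(s) {
        j <- cand$sources[s]
        if (cand$proxy[s]) ex$Y[, j] else traj[[j]][[e]]
      }, numeric(length(ex$times)))
      cols <- c(cols, list(matrix(S, nrow = length(ex$times))))
    }
    if (length(cols)) do.call(cbind, cols)
    else matrix(0, length(ex$times), 0L)
  })
}

## Sigmoid-wrapped chain integration (optional nonlinear mode): every stage's
## linear combination is passed through tanh(g z)/g.
.chainSigmoid <- function(a, r, times, g, gain, rtol, atol) {
  gf <- approxfun(times, g, rule = 2L)
  deriv <- function(t, x, p) {
    z <- a * x
    z[1L] <- z[1L] + gf(t)
    if (r > 1L) z[2L:r] <- z[2L:r] + x[1L:(r - 1L)]
    list(tanh(gain * z) / gain)
  }
  sol <- deSolve::ode(y = numeric(r), times = times, func = deriv,
                      parms = NULL, method = "impAdams", rtol = rtol,
                      atol = atol)
  as.matrix(sol)[, r + 1L]
}

## Simulated observed series of a candidate sub-model for given parameters.
.candidateSim <- function(theta, cand, Z, fd, config) {
  p <- length(theta)
  a <- theta[p]
  lapply(seq_along(fd), function(e) {
    g <- if (ncol(Z[[e]]) > 0) as.numeric(Z[[e]] %*% theta[-p])
         else numeric(length(fd[[e]]$times))
    if (isTRUE(config@sigmoid))
      .chainSigmoid(a, cand$order, fd[[e]]$times, g, config@sigmoidGain,
                    config@rtol, config@atol)
    else
      chain_response_cpp(a, cand$order, fd[[e]]$times, g,
                         numeric(cand$order))
  })
}

## Coefficient rows (gene-level) implied by a candidate's parameters.
.candidateRows <- function(theta, cand, nGenes, nStim) {
  p <- length(theta)
  aRow <- numeric(nGenes)
  bRow <- numeric(nStim)
  if (length(cand$inputs)) bRow[cand$inputs] <- theta[seq_along(cand$inputs)]
  if (length(cand$sources))
    aRow[cand$sources] <- theta[length(cand$inputs) + seq_along(cand$sources)]
  aRow[cand$gene] <- theta[p]
  list(aRow = aRow, bRow = bRow)
}

.boundsFor <- function(cand, prior, config) {
  nIn <- length(cand$inputs)
  nSrc <- length(cand$sources)
  p <- nIn + nSrc + 1L
  lower <- rep(config@lowerBound, p)
  upper <- rep(config@upperBound, p)
  upper[p] <- config@diagUpper  # stable self-regulation
  fixed <- logical(p)
  if (!is.null(prior)) {
    ## fix knowledge with a stated sign restricts the coefficient's sign and
    ## keeps it away from zero, so the required connection is never silently
    ## optimised out
    if (nIn) for (s in seq_len(nIn)) {
      code <- prior@Bfix[cand$gene, cand$inputs[s]]
      if (is.na(code) || code == 0) next
      fixed[s] <- TRUE
      if (code == 10) lower[s] <- .fixEdgeMin
      if (code == -10) upper[s] <- -.fixEdgeMin
    }
    if (nSrc) for (s in seq_len(nSrc)) {
      code <- prior@Afix[cand$gene, cand$sources[s]]
      if (is.na(code) || code == 0) next
      fixed[nIn + s] <- TRUE
      if (code == 10) lower[nIn + s] <- .fixEdgeMin
      if (code == -10) upper[nIn + s] <- -.fixEdgeMin
    }
  }
  list(lower = lower, upper = upper, fixed = fixed)
}

## minimal magnitude of a fix-prior connection coefficient (dynamically
## negligible, but structurally present)
.fixEdgeMin <- 1e-3

## Full candidate fit: weighted-regression initialisation, optional
## higher-order adaptation, then bounded quasi-Newton refinement.
.fitCandidate <- function(cand, fd, config, prior = NULL, traj = NULL,
                          thetaInit = NULL) {
  gene <- cand$gene
  Z <- .forcing(cand, fd, traj)
  yObs <- lapply(fd, function(ex) ex$Y[, gene])
  w <- lapply(fd, function(ex) ex$w)
  if (is.null(thetaInit)) {
    H <- do.call(rbind, Z)
    Xself <- unlist(lapply(fd, function(ex) ex$Y[, gene]))
    dxdt <- unlist(lapply(fd, function(ex) ex$dY[, gene]))
    thetaInit <- regressInit(H, matrix(Xself, ncol = 1L), unlist(w), dxdt)
    if (cand$order > 1L) {
      if (thetaInit[length(thetaInit)] >= 0)
        thetaInit[length(thetaInit)] <- config@diagUpper
      thetaInit <- higherOrderInit(thetaInit, cand$order)
    }
  }
  bounds <- .boundsFor(cand, prior, config)
  thetaInit <- pmin(pmax(thetaInit, bounds$lower), bounds$upper)
  nGenes <- ncol(fd[[1L]]$Y)
  nStim <- ncol(fd[[1L]]$U)
  lambda <- if (is.null(prior)) 0 else prior@lambda
  penalty <- function(theta) {
    if (lambda == 0) return(0)
    rows <- .candidateRows(theta, cand, nGenes, nStim)
    .priorPenaltyRow(gene, rows$aRow, rows$bRow, prior)
  }
  objective <- function(theta) {
    sims <- .candidateSim(theta, cand, Z, fd, config)
    J <- 0
    for (e in seq_along(fd))
      J <- J + sum(w[[e]] * (yObs[[e]] - sims[[e]])^2)
    J + penalty(theta)
  }
  Jinit <- objective(thetaInit)
  fit <- try(optim(thetaInit, objective, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = config@maxit,
                                  pgtol = config@pgtol)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value) ||
      fit$value > Jinit + 1e-12) {
    theta <- thetaInit
    Jtot <- Jinit
    converged <- FALSE
  } else {
    theta <- fit$par
    Jtot <- fit$value
    converged <- fit$convergence == 0L
  }
  if (any(bounds$fixed)) {
    ## presence-only fix edges (code 1) may sit at zero after optimisation;
    ## pin them to the minimal magnitude so the connection survives
    small <- bounds$fixed & abs(theta) < .fixEdgeMin
    if (any(small)) {
      theta[small] <- ifelse(theta[small] < 0, -.fixEdgeMin, .fixEdgeMin)
      Jtot <- objective(theta)
    }
  }
  pen <- penalty(theta)
  c(cand, list(theta = theta, Joutput = Jtot - pen, Jtotal = Jtot,
               converged = converged, nPar = length(theta)))
}

## Fitted observed trajectories of an accepted sub-model (stored and used as
## forcing for later sub-models).
.fitTrajectories <- function(fit, fd, config, traj) {
  Z <- .forcing(fit, fd, traj)
  .candidateSim(fit$theta, fit, Z, fd, config)
}

#' Fit one sub-model
#'
#' Fits the parameters of a single sub-model with a given structure: weighted
#' linear regression on the numeric derivatives provides the starting point
#' (adapted when the order exceeds one), which is refined by bounded
#' L-BFGS-B minimisation of the weighted output error plus the flexible
#' prior-knowledge penalty. During the fit, incoming genes are represented by
#' their measured+interpolated series (`proxy = TRUE`, the default here) or,
#' inside the search, by the trajectories of already-included sub-models.
#'
#' @param dataset a standardised (and typically interpolated)
#'   [GRNDataset-class].
#' @param gene target gene, by name or index.
#' @param inputs incoming stimuli, by name or index.
#' @param sources incoming genes, by name or index.
#' @param order integrator-chain order.
#' @param config a [GRNConfig-class].
#' @param prior optional [GRNPrior-class].
#' @param thetaInit optional starting parameters (input coefficients, source
#'   coefficients, then the self coefficient); default is the regression
#'   initialisation.
#' @return a list with elements `theta`, `Joutput`, `Jtotal`, `converged`,
#'   `nPar`, and the structure (`gene`, `inputs`, `sources`, `order`).
#' @export
fitSubmodel <- function(dataset, gene, inputs = integer(),
                        sources = integer(), order = 1L,
                        config = grnConfig(), prior = NULL,
                        thetaInit = NULL) {
  gn <- dataset@geneNames
  sn <- dataset@stimulusNames
  if (is.character(gene)) gene <- match(gene, gn)
  if (is.character(inputs)) inputs <- match(inputs, sn)
  if (is.character(sources)) sources <- match(sources, gn)
  cand <- .candidate(gene, inputs, sources,
                     proxy = rep(TRUE, length(sources)), order = order)
  fd <- .fitData(dataset)
  .fitCandidate(cand, fd, config, prior = prior, thetaInit = thetaInit)
}

#' Weighted output error of one sub-model in a model
#'
#' The weighted squared deviation between the simulated and the
#' measured+interpolated series of one gene, summed over all experiments and
#' time points. The model is simulated as a complete coupled system.
#'
#' @param model a [GRNModel-class].
#' @param gene gene, by name or index.
#' @param dataset a [GRNDataset-class].
#' @return scalar error.
#' @export
objectiveOutput <- function(model, gene, dataset) {
  g <- if (is.character(gene)) match(gene, geneNames(model)) else gene
  J <- 0
  for (ex in dataset@experiments) {
    sim <- simulateGRN(model, ex@stimuli, ex@times)
    J <- J + sum(ex@weights * (ex@exprs[, g] - sim[, g])^2)
  }
  J
}

#' Penalised sub-model objective
#'
#' Adds the flexible prior-knowledge penalty of one gene's incoming
#' connections to its output error:
#' `J = J_output + lambda * (sum_j s_ij * d_ij + sum_k s_ik * d_ik)`,
#' where `s` are reliability scores and `d` the sign distances of
#' [signDistance()] between the coded model coefficients and the flexible
#' prior codes.
#'
#' @param Joutput output error of the sub-model.
#' @param gene target gene, by name or index.
#' @param aRow gene-level incoming coefficients (length = genes; the
#'   candidate's row of the interaction matrix).
#' @param bRow incoming input coefficients (length = stimuli).
#' @param prior a [GRNPrior-class], or `NULL` for no penalty.
#' @return the penalised scalar objective.
#' @export
objectiveTotal <- function(Joutput, gene, aRow, bRow, prior = NULL) {
  if (is.null(prior)) return(Joutput)
  g <- if (is.character(gene)) match(gene, rownames(prior@Afix)) else gene
  Joutput + .priorPenaltyRow(g, aRow, bRow, prior)
}

.priorPenaltyRow <- function(gene, aRow, bRow, prior) {
  if (is.null(prior) || prior@lambda == 0) return(0)
  pen <- 0
  score <- function(s) if (is.na(s)) 1 else s
  jA <- which(!is.na(prior@Aflex[gene, ]))
  for (j in jA)
    pen <- pen + score(prior@Ascore[gene, j]) *
      signDistance(encodeEdge(aRow[j]), prior@Aflex[gene, j])
  kB <- which(!is.na(prior@Bflex[gene, ]))
  for (k in kB)
    pen <- pen + score(prior@Bscore[gene, k]) *
      signDistance(encodeEdge(bRow[k]), prior@Bflex[gene, k])
  prior@lambda * pen
}
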