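#' @include AllClasses.R
NULL

#' Chain-expanded state-space matrices
#'
#' Expands the gene-level coefficient matrices of a [GRNModel-class] into the
#' full state-space pair `(A, B)`. A gene of order `r` occupies `r` chain
#' states sharing the diagonal coefficient: incoming connections enter the
#' first stage, each later stage couples to its predecessor with a unit
#' coefficient, and the last stage is the observed one. Sub-models are laid
#' out along the state vector in `stateOrder` (the inclusion order), so
#' below-diagonal entries of `A` are forward connections and above-diagonal
#' entries are global feedbacks.
#'
#' @param model a [GRNModel-class].
#' @return a list with `A` (states x states), `B` (states x stimuli),
#'   `obs` (per gene, index of its observed state), `entry` (per gene, index
#'   of its first chain stage) and `stateGene` (gene index per state).
#' @export
stateMatrices <- function(model) {
  n <- nrow(model@interaction)
  ord <- model@orders
  ns <- sum(ord)
  A <- matrix(0, ns, ns)
  B <- matrix(0, ns, ncol(model@input))
  entry <- obs <- integer(n)
  stateGene <- integer(ns)
  pos <- 1L
  for (g in model@stateOrder) {
    r <- ord[g]
    entry[g] <- pos
    obs[g] <- pos + r - 1L
    stateGene[pos:(pos + r - 1L)] <- g
    pos <- pos + r
  }
  for (g in seq_len(n)) {
    a <- model@interaction[g, g]
    e <- entry[g]
    A[e, e] <- a
    for (j in seq_len(n))
      if (j != g && model@interaction[g, j] != 0)
        A[e, obs[j]] <- model@interaction[g, j]
    if (ncol(B) > 0) B[e, ] <- model@input[g, ]
    if (ord[g] > 1L)
      for (s in (e + 1L):(e + ord[g] - 1L)) {
        A[s, s] <- a
        A[s, s - 1L] <- 1
      }
  }
  colnames(B) <- colnames(model@input)
  list(A = A, B = B, obs = obs, entry = entry, stateGene = stateGene)
}

#' Validate the integrator-chain pattern of a state-space matrix
#'
#' Checks that the intermediate rows of every sub-model chain carry exactly
#' the shared diagonal coefficient, a unit coupling to the predecessor state
#' and nothing else (and no input terms). Used as a structural assertion
#' after any edit of the model.
#'
#' @param A,B state-space matrices.
#' @param orders chain order per gene.
#' @param stateOrder gene layout along the state vector.
#' @return `TRUE`, or a character vector of violations.
#' @export
validateChainStructure <- function(A, B, orders,
                                   stateOrder = seq_along(orders)) {
  bad <- character()
  pos <- 1L
  for (g in stateOrder) {
    r <- orders[g]
    a <- A[pos, pos]
    if (r > 1L) for (s in (pos + 1L):(pos + r - 1L)) {
      row <- A[s, ]
      expect <- rep(0, ncol(A))
      expect[s] <- a
      expect[s - 1L] <- 1
      if (!isTRUE(all.equal(row, expect, tolerance = 1e-12)))
        bad <- c(bad, sprintf("chain row %d violates the chain pattern", s))
      if (ncol(B) > 0 && any(B[s, ] != 0))
        bad <- c(bad, sprintf("chain row %d must have no input terms", s))
    }
    pos <- pos + r
  }
  if (length(bad)) bad else TRUE
}

.stepFun <- function(stimuli, times, M) {
  if (is.function(stimuli)) return(stimuli)
  if (is.null(stimuli)) stimuli <- numeric(M)
  if (is.matrix(stimuli)) {
    if (nrow(stimuli) == 1L) {
      v <- as.numeric(stimuli)
      return(function(t) v)
    }
    stopifnot(!is.null(times), nrow(stimuli) == length(times))
    funs <- lapply(seq_len(ncol(stimuli)), function(j)
      approxfun(times, stimuli[, j], method = "constant", rule = 2L))
    return(function(t) vapply(funs, function(f) f(t), numeric(1L)))
  }
  v <- as.numeric(stimuli)
  stopifnot(length(v) == M)
  function(t) v
}

#' Simulate a model as an initial value problem
#'
#' Numerically integrates `dx/dt = A x + B u(t)` (or its sigmoid-transformed
#' variant) from the model's initial state with the implicit Adams
#' multistep method of \pkg{deSolve} and returns the observed states only.
#'
#' @param model a [GRNModel-class].
#' @param stimuli stimulus specification: a constant vector (one level per
#'   stimulus, step inputs), a `length(times) x M` matrix of piecewise
#'   constant profiles, or a function `u(t)`.
#' @param times output times, starting at the model's `t0`.
#' @param rtol,atol solver tolerances.
#' @return matrix `length(times) x genes` of observed trajectories.
#' @examples
#' m <- grnModel(matrix(-1, 1, 1), matrix(1, 1, 1))
#' x <- simulateGRN(m, 1, seq(0, 5, 0.1))  # approaches 1 - exp(-t)
#' @export
simulateGRN <- function(model, stimuli, times, rtol = 1e-6, atol = 1e-8) {
  sm <- stateMatrices(model)
  ufun <- .stepFun(stimuli, times, ncol(sm$B))
  A <- sm$A
  B <- sm$B
  g <- model@sigmoidGain
  useSig <- isTRUE(model@sigmoid)
  deriv <- function(t, x, parms) {
    z <- as.numeric(A %*% x)
    if (ncol(B) > 0) z <- z + as.numeric(B %*% ufun(t))
    if (useSig) z <- tanh(g * z) / g
    list(z)
  }
  if (length(model@x0) == 0L)
    return(matrix(0, length(times), 0L,
                  dimnames = list(NULL, geneNames(model))))
  sol <- try(deSolve::ode(y = model@x0, times = times, func = deriv,
                          parms = NULL, method = "impAdams", rtol = rtol,
                          atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times))
    stop("integration failure for model with diagonal ",
         paste(sprintf("%.3g", diag(model@interaction)), collapse = ", "))
  out <- unname(as.matrix(sol)[, 1L + sm$obs, drop = FALSE])
  colnames(out) <- geneNames(model)
  out
}

#' Steady-state gain of a sub-model step response
#'
#' Static gain of the observed state of gene `i` for a unit step on stimulus
#' `m`: `b/(-a)` for a first-order sub-model and `b/(-a) * (1/(-a))^(r-1)`
#' for an order-`r` chain (each extra unit-coupled stage contributes a factor
#' `1/(-a)`).
#'
#' @param model a [GRNModel-class].
#' @param gene,input gene and stimulus, by name or index.
#' @return the scalar gain.
#' @export
staticGain <- function(model, gene, input) {
  g <- if (is.character(gene)) match(gene, geneNames(model)) else gene
  m <- if (is.character(input)) match(input, stimulusNames(model)) else input
  a <- model@interaction[g, g]
  if (a >= 0) stop("unstable sub-model: diagonal coefficient must be negative")
  b <- model@input[g, m]
  b / (-a) * (1 / (-a))^(model@orders[g] - 1L)
}

#' Total time constant of a sub-model
#'
#' Sum of the characteristic times of the chain stages, `r * 1/(-a)`.
#' Together with [staticGain()] this is the pair of dynamic characteristics
#' preserved when a sub-model's order is raised during the search.
#'
#' @param model a [GRNModel-class].
#' @param gene gene, by name or index.
#' @return the scalar time constant (time units of the data).
#' @export
totalTimeConstant <- function(model, gene) {
  g <- if (is.character(gene)) match(gene, geneNames(model)) else gene
  a <- model@interaction[g, g]
  if (a >= 0) stop("unstable sub-model: diagonal coefficient must be negative")
  model@orders[g] / (-a)
}

#' Saturating sigmoid transformation
#'
#' The optional nonlinearity applied to the linear combination of a
#' sub-model's right-hand side, modelling saturation of gene expression:
#' `f(z) = tanh(gain * z) / gain`. It is odd, strictly monotone, saturates at
#' `1/gain`, and has unit slope at the origin, so the linear model is
#' recovered for small signals.
#'
#' @param z input value(s).
#' @param gain sigmoid gain (> 0), default 1.
#' @return transformed value(s) in `(-1/gain, 1/gain)`.
#' @export
sigmoidTransform <- function(z, gain = 1) {
  stopifnot(gain > 0)
  tanh(gain * z) / gain
}

#' Exact response of an integrator chain to piecewise-linear forcing
#'
#' Trajectory of the observed (last) state of an order-`r` chain with shared
#' diagonal coefficient `a`, driven by a scalar forcing that is piecewise
#' linear between the grid points. The update is closed-form (matrix
#' exponential of the chain block), so the result is exact for this forcing
#' class; the heuristic uses it to simulate candidate sub-models cheaply,
#' with already-included trajectories or interpolated data as the forcing.
#'
#' @param a diagonal coefficient (nonzero; negative for a stable chain).
#' @param r chain order (>= 1).
#' @param times strictly increasing time grid.
#' @param forcing forcing values on the grid.
#' @param x0 initial chain state (recycled to length `r`, default 0).
#' @return numeric vector: observed state at `times`.
#' @export
chainResponse <- function(a, r, times, forcing, x0 = 0) {
  chain_response_cpp(a, as.integer(r), as.numeric(times),
                     as.numeric(forcing), rep_len(as.numeric(x0), r))
}
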