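#' @include AllClasses.R identification.R
NULL

## Fix-knowledge bookkeeping for one gene: edges that must be present and
## positions that are excluded from the search (fix code 0).
.fixInfo <- function(gene, prior, nGenes, nStim) {
  if (is.null(prior))
    return(list(inputs = integer(), sources = integer(),
                exclIn = logical(nStim), exclSrc = logical(nGenes)))
  bf <- prior@Bfix[gene, ]
  af <- prior@Afix[gene, ]
  list(inputs = which(!is.na(bf) & bf %in% c(1, 10, -10)),
       sources = setdiff(which(!is.na(af) & af %in% c(1, 10, -10)), gene),
       exclIn = !is.na(bf) & bf == 0,
       exclSrc = !is.na(af) & af == 0)
}

.activeInputs <- function(fd) {
  M <- ncol(fd[[1L]]$U)
  if (M == 0L) return(integer())
  active <- logical(M)
  for (ex in fd) active <- active | apply(ex$U != 0, 2L, any)
  which(active)
}

#' Basic candidate structures for one gene
#'
#' The starting structures of the inner loop: self-regulation, one input
#' term, and any connections required by fix prior knowledge. One candidate
#' is generated per applied stimulus (a stimulus that is zero throughout all
#' experiments carries no information and is skipped, as are positions
#' excluded by a fix code 0); when fix knowledge already provides incoming
#' connections, the fix-only structure is offered as well.
#'
#' @param gene target gene, by name or index.
#' @param dataset a [GRNDataset-class].
#' @param prior optional [GRNPrior-class].
#' @return list of candidate structures (lists with `gene`, `inputs`,
#'   `sources`, `order`).
#' @export
basicCandidates <- function(gene, dataset, prior = NULL) {
  if (is.character(gene)) gene <- match(gene, dataset@geneNames)
  fd <- .fitData(dataset)
  .basicCandidates(gene, fd, prior, included = integer())
}

.basicCandidates <- function(gene, fd, prior, included) {
  nGenes <- ncol(fd[[1L]]$Y)
  nStim <- ncol(fd[[1L]]$U)
  fx <- .fixInfo(gene, prior, nGenes, nStim)
  proxy <- !(fx$sources %in% included)
  mk <- function(extraInput = integer())
    .candidate(gene, inputs = sort(unique(c(fx$inputs, extraInput))),
               sources = fx$sources, proxy = proxy)
  free <- setdiff(.activeInputs(fd), fx$inputs)
  free <- free[!fx$exclIn[free]]
  cands <- lapply(free, mk)
  if (length(fx$inputs) || !length(free)) cands <- c(cands, list(mk()))
  cands
}

#' Select the best-reproduced sub-model fit
#'
#' Chooses the candidate with the smallest penalised objective; ties are
#' broken by the smaller parameter count, then by gene order.
#'
#' @param fits list of sub-model fits (as returned by [fitSubmodel()]).
#' @return index of the winning fit within `fits`.
#' @export
selectBest <- function(fits) {
  J <- vapply(fits, `[[`, numeric(1L), "Jtotal")
  nP <- vapply(fits, `[[`, numeric(1L), "nPar")
  g <- vapply(fits, `[[`, numeric(1L), "gene")
  order(J, nP, g)[1L]
}

## ---------------------------------------------------------------------------
## Improvement phases
## ---------------------------------------------------------------------------

.growPhase <- function(fit, fd, config, prior, traj, included, state) {
  nGenes <- ncol(fd[[1L]]$Y)
  fx <- .fixInfo(fit$gene, prior, nGenes, ncol(fd[[1L]]$U))
  repeat {
    if (fit$Joutput <= config@allowedError) break
    if (length(fit$inputs) + length(fit$sources) >= config@maxConnections)
      break
    freeIn <- setdiff(.activeInputs(fd), fit$inputs)
    freeIn <- freeIn[!fx$exclIn[freeIn]]
    freeSrc <- setdiff(seq_len(nGenes), c(fit$gene, fit$sources))
    freeSrc <- freeSrc[!fx$exclSrc[freeSrc]]
    nIn <- length(fit$inputs)
    p <- length(fit$theta)
    cands <- c(
      lapply(freeIn, function(m) list(
        cand = .candidate(fit$gene, c(fit$inputs, m), fit$sources,
                          fit$proxy, fit$order),
        warm = append(fit$theta, 0, after = nIn))),
      lapply(freeSrc, function(j) list(
        cand = .candidate(fit$gene, fit$inputs, c(fit$sources, j),
                          c(fit$proxy, !(j %in% included)), fit$order),
        warm = append(fit$theta, 0, after = p - 1L))))
    if (!length(cands)) break
    ## each extension is fitted twice: from a fresh regression start and
    ## warm-started at the current parameters (new coefficient zero, which
    ## reproduces the current objective exactly); the better fit is kept
    fits <- lapply(cands, function(cd) {
      f1 <- tryCatch(.fitCandidate(cd$cand, fd, config, prior, traj),
                     error = function(e) NULL)
      f2 <- tryCatch(.fitCandidate(cd$cand, fd, config, prior, traj,
                                   thetaInit = cd$warm),
                     error = function(e) NULL)
      if (is.null(f1)) f2
      else if (is.null(f2) || f1$Jtotal <= f2$Jtotal) f1
      else f2
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) break
    best <- fits[[selectBest(fits)]]
    if (best$Jtotal <= (1 - config@growThreshold) * fit$Jtotal) {
      newSrc <- setdiff(best$sources, fit$sources)
      newIn <- setdiff(best$inputs, fit$inputs)
      lab <- if (length(newSrc)) state$gn[newSrc[1L]]
             else state$sn[newIn[1L]]
      state$log <- c(state$log, sprintf(
        "  grow %s: +%s (J %.4g -> %.4g)", state$gn[fit$gene], lab,
        fit$Jtotal, best$Jtotal))
      fit <- best
    } else break
  }
  fit
}

.orderPhase <- function(fit, fd, config, prior, traj, state) {
  ## like growing, the order is only raised while the sub-model is not yet
  ## adequate (output error above the allowed error)
  if (config@maxOrder <= 1L || fit$order != 1L ||
      fit$Joutput <= config@allowedError) return(fit)
  best <- NULL
  for (r in 2L:config@maxOrder) {
    cand <- .candidate(fit$gene, fit$inputs, fit$sources, fit$proxy, r)
    init <- tryCatch(higherOrderInit(fit$theta, r), error = function(e) NULL)
    if (is.null(init)) next
    f <- tryCatch(.fitCandidate(cand, fd, config, prior, traj,
                                thetaInit = init),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$Jtotal < best$Jtotal)) best <- f
  }
  if (!is.null(best) &&
      best$Jtotal <= (1 - config@growThreshold) * fit$Jtotal) {
    state$log <- c(state$log, sprintf(
      "  raise order %s: r=%d (J %.4g -> %.4g)", state$gn[fit$gene],
      best$order, fit$Jtotal, best$Jtotal))
    fit <- best
  }
  fit
}

## a removal is kept if it does not worsen the result significantly, or if
## the reduced sub-model is still adequate (output error within the allowed
## error; the relative criterion is meaningless at near-zero errors)
.pruneOk <- function(f, fit, config) {
  f$Jtotal <= (1 + config@pruneThreshold) * fit$Jtotal ||
    f$Joutput <= config@allowedError
}

## removal refits start both from the remaining current parameters and from
## a fresh regression initialisation; the better fit decides
.refitWithout <- function(cand, idx, fit, fd, config, prior, traj) {
  fWarm <- tryCatch(.fitCandidate(cand, fd, config, prior, traj,
                                  thetaInit = fit$theta[-idx]),
                    error = function(e) NULL)
  fFresh <- tryCatch(.fitCandidate(cand, fd, config, prior, traj),
                     error = function(e) NULL)
  if (is.null(fWarm)) fFresh
  else if (is.null(fFresh) || fWarm$Jtotal <= fFresh$Jtotal) fWarm
  else fFresh
}

.prunePhase <- function(fit, fd, config, prior, traj, state) {
  nGenes <- ncol(fd[[1L]]$Y)
  fx <- .fixInfo(fit$gene, prior, nGenes, ncol(fd[[1L]]$U))
  repeat {
    removed <- FALSE
    for (m in setdiff(fit$inputs, fx$inputs)) {
      keep <- fit$inputs != m
      idx <- which(fit$inputs == m)
      cand <- .candidate(fit$gene, fit$inputs[keep], fit$sources, fit$proxy,
                         fit$order)
      f <- .refitWithout(cand, idx, fit, fd, config, prior, traj)
      if (!is.null(f) && .pruneOk(f, fit, config)) {
        state$log <- c(state$log, sprintf(
          "  prune %s: -%s (J %.4g -> %.4g)", state$gn[fit$gene],
          state$sn[m], fit$Jtotal, f$Jtotal))
        fit <- f
        removed <- TRUE
        break
      }
    }
    if (!removed) for (j in setdiff(fit$sources, fx$sources)) {
      sKeep <- fit$sources != j
      idx <- length(fit$inputs) + which(fit$sources == j)
      cand <- .candidate(fit$gene, fit$inputs, fit$sources[sKeep],
                         fit$proxy[sKeep], fit$order)
      f <- .refitWithout(cand, idx, fit, fd, config, prior, traj)
      if (!is.null(f) && .pruneOk(f, fit, config)) {
        state$log <- c(state$log, sprintf(
          "  prune %s: -%s (J %.4g -> %.4g)", state$gn[fit$gene],
          state$gn[j], fit$Jtotal, f$Jtotal))
        fit <- f
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  fit
}

#' Extend, order-raise or prune one sub-model fit
#'
#' Stand-alone versions of the three structural improvement moves of the
#' heuristic, operating on a fit from [fitSubmodel()] with all incoming
#' genes represented by their data series. `growSubmodel` greedily adds the
#' single best new incoming connection while the output error exceeds
#' `allowedError`, the relative improvement exceeds the growing threshold and
#' the connection cap is not reached. `raiseOrder` tries chain orders
#' `2..maxOrder` (initialised so that static gain and total time constant are
#' preserved) and keeps the best significantly better variant.
#' `pruneSubmodel` removes incoming connections whose removal does not worsen
#' the objective beyond the pruning tolerance; the self-loop and fix-prior
#' connections are never pruned.
#'
#' @param fit a sub-model fit.
#' @param dataset the standardised, interpolated [GRNDataset-class].
#' @param config a [GRNConfig-class].
#' @param prior optional [GRNPrior-class].
#' @return the improved (or unchanged) fit.
#' @export
growSubmodel <- function(fit, dataset, config = grnConfig(), prior = NULL) {
  fd <- .fitData(dataset)
  st <- new.env()
  st$log <- character(); st$gn <- dataset@geneNames
  st$sn <- dataset@stimulusNames
  .growPhase(fit, fd, config, prior, traj = NULL, included = integer(), st)
}

#' @rdname growSubmodel
#' @export
raiseOrder <- function(fit, dataset, config = grnConfig(), prior = NULL) {
  fd <- .fitData(dataset)
  st <- new.env()
  st$log <- character(); st$gn <- dataset@geneNames
  st$sn <- dataset@stimulusNames
  .orderPhase(fit, fd, config, prior, traj = NULL, st)
}

#' @rdname growSubmodel
#' @export
pruneSubmodel <- function(fit, dataset, config = grnConfig(), prior = NULL) {
  fd <- .fitData(dataset)
  st <- new.env()
  st$log <- character(); st$gn <- dataset@geneNames
  st$sn <- dataset@stimulusNames
  .prunePhase(fit, fd, config, prior, traj = NULL, st)
}

## ---------------------------------------------------------------------------
## Main inference loop
## ---------------------------------------------------------------------------

#' Infer a gene-regulatory network
#'
#' The main heuristic: starting from an empty model, the outer loop picks in
#' every round the remaining time series whose best basic sub-model
#' (self-regulation + one input + fix prior connections) reproduces its data
#' best, improves that sub-model structurally (growing further incoming
#' connections, raising the chain order, pruning), and includes it in the
#' model. Incoming connections from genes not yet included are fitted
#' against their measured+interpolated data and become global feedbacks of
#' the final model. The run is deterministic given data, prior and
#' configuration.
#'
#' @param dataset a [GRNDataset-class]; standardisation and interpolation are
#'   applied according to `config` if not already done.
#' @param prior optional [GRNPrior-class]; fix connections are always part of
#'   the model, flexible ones enter the objective.
#' @param config a [GRNConfig-class].
#' @return a [GRNInference-class]; the model is available via
#'   [fittedModel()].
#' @examples
#' bm <- generateBenchmark("LCT", seed = 7)
#' ds <- generateData(bm, scenario = "M", noiseSd = 0, seed = 7)
#' \donttest{fit <- inferNetwork(ds)}
#' @export
inferNetwork <- function(dataset, prior = NULL, config = grnConfig()) {
  if (!dataset@standardised) dataset <- standardiseDataset(dataset)
  anyInterp <- any(vapply(dataset@experiments, function(ex)
    any(ex@pointKind == "interpolated"), logical(1L)))
  if (!anyInterp && config@kPerInterval > 0L)
    dataset <- interpolateDataset(dataset, config@kPerInterval,
                                  config@weightMeasured,
                                  config@weightInterpolated)
  gn <- dataset@geneNames
  sn <- dataset@stimulusNames
  N <- length(gn)
  if (N == 0L) {
    model <- grnModel(matrix(0, 0, 0), matrix(0, 0, length(sn)),
                      geneNames = character(), stimulusNames = sn)
    return(new("GRNInference", model = model,
               submodelError = setNames(numeric(), character()),
               coupledError = 0, inclusionOrder = character(),
               log = "empty gene set: empty model", dataset = dataset,
               config = config))
  }
  fd <- .fitData(dataset)
  st <- new.env()
  st$log <- character(); st$gn <- gn; st$sn <- sn
  traj <- vector("list", N)
  fits <- vector("list", N)
  basicCache <- vector("list", N)
  included <- integer()
  remaining <- seq_len(N)
  inclusion <- integer()
  while (length(remaining)) {
    for (g in remaining) {
      if (!is.null(basicCache[[g]])) next
      cands <- .basicCandidates(g, fd, prior, included)
      cfits <- lapply(cands, function(cd)
        tryCatch(.fitCandidate(cd, fd, config, prior, traj),
                 error = function(e) NULL))
      cfits <- Filter(Negate(is.null), cfits)
      if (!length(cfits)) {
        ## best-effort fallback: self-regulation only, fixed starting point
        fallback <- .candidate(g)
        cfits <- list(.fitCandidate(fallback, fd, config, prior, traj,
                                    thetaInit = -1))
        st$log <- c(st$log, sprintf(
          "  %s: no basic candidate identifiable; best-effort self-model",
          gn[g]))
      }
      basicCache[[g]] <- cfits[[selectBest(cfits)]]
    }
    basics <- basicCache[remaining]
    chosen <- basics[[selectBest(basics)]]
    g <- chosen$gene
    st$log <- c(st$log, sprintf("step %d: include %s (basic J = %.4g)",
                                length(inclusion) + 1L, gn[g],
                                chosen$Jtotal))
    fit <- .growPhase(chosen, fd, config, prior, traj, included, st)
    fit <- .orderPhase(fit, fd, config, prior, traj, st)
    fit <- .prunePhase(fit, fd, config, prior, traj, st)
    fits[[g]] <- fit
    traj[[g]] <- .fitTrajectories(fit, fd, config, traj)
    included <- c(included, g)
    inclusion <- c(inclusion, g)
    remaining <- setdiff(remaining, g)
    ## fits whose fix-prior sources referenced this gene as a data proxy
    ## must be refitted against its now-available trajectory
    if (!is.null(prior))
      for (h in remaining)
        if (!is.null(basicCache[[h]]) && g %in% basicCache[[h]]$sources)
          basicCache[h] <- list(NULL)
  }
  .assembleInference(fits, inclusion, dataset, config, st$log)
}

## Build the final model: collapse accepted sub-model fits into gene-level
## matrices (data-proxy connections to now-included genes become ordinary
## state connections: above-diagonal global feedbacks in inclusion order)
## and simulate the complete coupled system once for reporting.
.assembleInference <- function(fits, inclusion, dataset, config, log) {
  gn <- dataset@geneNames
  sn <- dataset@stimulusNames
  N <- length(gn)
  Ag <- matrix(0, N, N, dimnames = list(gn, gn))
  Bg <- matrix(0, N, length(sn), dimnames = list(gn, sn))
  orders <- rep(1L, N)
  Jout <- setNames(numeric(N), gn)
  for (g in seq_len(N)) {
    f <- fits[[g]]
    rows <- .candidateRows(f$theta, f, N, length(sn))
    Ag[g, ] <- rows$aRow
    Bg[g, ] <- rows$bRow
    orders[g] <- f$order
    Jout[g] <- f$Joutput
  }
  model <- grnModel(Ag, Bg, orders = orders, geneNames = gn,
                    stimulusNames = sn, stateOrder = inclusion,
                    sigmoid = config@sigmoid,
                    sigmoidGain = config@sigmoidGain)
  coupled <- tryCatch({
    J <- 0
    for (ex in dataset@experiments) {
      sim <- simulateGRN(model, ex@stimuli, ex@times, config@rtol,
                         config@atol)
      J <- J + sum(ex@weights * (ex@exprs - sim)^2)
    }
    J
  }, error = function(e) NA_real_)
  new("GRNInference", model = model, submodelError = Jout,
      coupledError = coupled, inclusionOrder = gn[inclusion], log = log,
      dataset = dataset, config = config)
}
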