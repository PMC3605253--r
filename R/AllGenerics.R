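#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics shared by the data, model and result classes.
#'
#' @param object a dynGRN object.
#' @return `geneNames`/`stimulusNames` return character vectors;
#'   `experiments` the list of [GRNExperiment-class]; `interactionMatrix` and
#'   `inputMatrix` gene-level coefficient matrices; `submodelOrders` the
#'   integer chain order per gene; `fittedModel` the [GRNModel-class] inside a
#'   [GRNInference-class]; `modelError` its per-gene sub-model errors;
#'   `runLog` the audit trail; `measures` the named measure vector of a
#'   [GRNEvaluation-class]; `counts` its confusion counts.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("stimulusNames", function(object) standardGeneric("stimulusNames"))
#' @rdname accessors
#' @export
setGeneric("experiments", function(object) standardGeneric("experiments"))
#' @rdname accessors
#' @export
setGeneric("interactionMatrix",
           function(object) standardGeneric("interactionMatrix"))
#' @rdname accessors
#' @export
setGeneric("inputMatrix", function(object) standardGeneric("inputMatrix"))
#' @rdname accessors
#' @export
setGeneric("submodelOrders",
           function(object) standardGeneric("submodelOrders"))
#' @rdname accessors
#' @export
setGeneric("fittedModel", function(object) standardGeneric("fittedModel"))
#' @rdname accessors
#' @export
setGeneric("modelError", function(object) standardGeneric("modelError"))
#' @rdname accessors
#' @export
setGeneric("runLog", function(object) standardGeneric("runLog"))
#' @rdname accessors
#' @export
setGeneric("measures", function(object) standardGeneric("measures"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

## -- GRNExperiment / GRNDataset ---------------------------------------------

#' @rdname accessors
setMethod("geneNames", "GRNExperiment",
          function(object) colnames(object@exprs))
#' @rdname accessors
setMethod("stimulusNames", "GRNExperiment",
          function(object) colnames(object@stimuli))
#' @rdname accessors
setMethod("geneNames", "GRNDataset", function(object) object@geneNames)
#' @rdname accessors
setMethod("stimulusNames", "GRNDataset",
          function(object) object@stimulusNames)
#' @rdname accessors
setMethod("experiments", "GRNDataset", function(object) object@experiments)

## -- GRNModel ----------------------------------------------------------------

#' @rdname accessors
setMethod("geneNames", "GRNModel",
          function(object) rownames(object@interaction))
#' @rdname accessors
setMethod("stimulusNames", "GRNModel",
          function(object) colnames(object@input))
#' @rdname accessors
setMethod("interactionMatrix", "GRNModel",
          function(object) object@interaction)
#' @rdname accessors
setMethod("inputMatrix", "GRNModel", function(object) object@input)
#' @rdname accessors
setMethod("submodelOrders", "GRNModel", function(object)
  setNames(object@orders, geneNames(object)))

## -- GRNBenchmark ------------------------------------------------------------

#' @rdname accessors
setMethod("geneNames", "GRNBenchmark",
          function(object) geneNames(object@truth))
#' @rdname accessors
setMethod("stimulusNames", "GRNBenchmark",
          function(object) stimulusNames(object@truth))
#' @rdname accessors
setMethod("fittedModel", "GRNBenchmark", function(object) object@truth)

## -- GRNInference ------------------------------------------------------------

#' @rdname accessors
setMethod("fittedModel", "GRNInference", function(object) object@model)
#' @rdname accessors
setMethod("modelError", "GRNInference",
          function(object) object@submodelError)
#' @rdname accessors
setMethod("runLog", "GRNInference", function(object) object@log)
#' @rdname accessors
setMethod("geneNames", "GRNInference",
          function(object) geneNames(object@model))
#' @rdname accessors
setMethod("stimulusNames", "GRNInference",
          function(object) stimulusNames(object@model))
#' @rdname accessors
setMethod("interactionMatrix", "GRNInference",
          function(object) interactionMatrix(object@model))
#' @rdname accessors
setMethod("inputMatrix", "GRNInference",
          function(object) inputMatrix(object@model))

## -- GRNEvaluation -----------------------------------------------------------

#' @rdname accessors
setMethod("measures", "GRNEvaluation", function(object)
  c(SE = object@SE, SP = object@SP, PR = object@PR, FM = object@FM))
#' @rdname accessors
setMethod("counts", "GRNEvaluation", function(object)
  c(TP = object@TP, TN = object@TN, FPn = object@FPn, FPs = object@FPs,
    FN = object@FN))

## -- show methods ------------------------------------------------------------

setMethod("show", "GRNExperiment", function(object) {
  cat(sprintf("GRNExperiment '%s': %d time points (%d measured), %d genes, %d stimuli\n",
              object@name, length(object@times),
              sum(object@pointKind == "measured"), ncol(object@exprs),
              ncol(object@stimuli)))
})

setMethod("show", "GRNDataset", function(object) {
  cat(sprintf("GRNDataset: %d experiment(s), %d genes, %d stimuli%s\n",
              length(object@experiments), length(object@geneNames),
              length(object@stimulusNames),
              if (object@standardised) " (standardised)" else ""))
  for (ex in object@experiments) show(ex)
})

setMethod("show", "GRNModel", function(object) {
  n <- nrow(object@interaction)
  off <- sum(object@interaction[row(object@interaction) !=
                                  col(object@interaction)] != 0)
  cat(sprintf(
    "GRNModel: %d genes, %d stimuli, %d states; %d gene-gene and %d input edges%s\n",
    n, ncol(object@input), sum(object@orders), off, sum(object@input != 0),
    if (object@sigmoid) " (sigmoid)" else ""))
})

setMethod("show", "GRNEvaluation", function(object) {
  cnt <- counts(object)
  ms <- measures(object)
  cat("GRNEvaluation\n  counts:  ",
      paste(names(cnt), cnt, sep = "=", collapse = "  "), "\n  measures:",
      paste(names(ms), sprintf("%.3f", ms), sep = "=", collapse = "  "), "\n")
})

setMethod("show", "GRNInference", function(object) {
  cat("GRNInference\n")
  show(object@model)
  cat(sprintf("  inclusion order: %s\n",
              paste(object@inclusionOrder, collapse = " -> ")))
  cat(sprintf("  sub-model errors: %s\n",
              paste(names(object@submodelError),
                    sprintf("%.4g", object@submodelError),
                    sep = "=", collapse = "  ")))
  cat(sprintf("  coupled simulation error: %.4g\n", object@coupledError))
})

setMethod("show", "GRNBenchmark", function(object) {
  cat(sprintf("GRNBenchmark '%s' (seed %d)\n", object@kind, object@seed))
  show(object@truth)
})

setMethod("show", "GRNConfig", function(object) {
  cat("GRNConfig\n")
  for (nm in slotNames(object))
    cat(sprintf("  %s: %s\n", nm, format(slot(object, nm))))
})
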