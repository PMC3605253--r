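#' @include AllClasses.R prior.R benchmark.R
NULL

#' Export a model as a DOT directed graph
#'
#' Writes the network in the DOT graph language: one node per gene (box) and
#' per stimulus (ellipse), one edge per connection, coloured by the
#' prior-knowledge comparison of [classifyEdges()] (black/green/blue/red,
#' grey dashed for prior connections absent from the model). When
#' edge frequencies from [resampleValidate()] are supplied, edge widths and
#' percentage labels display them.
#'
#' @param model a [GRNModel-class] (or [GRNInference-class]).
#' @param prior optional [GRNPrior-class].
#' @param frequencies optional data.frame from [resampleValidate()].
#' @param file optional output path; the DOT text is also returned.
#' @param selfLoops draw self-regulation edges (default `FALSE`; the
#'   diagonal is always present and clutters the graph).
#' @return the DOT source as a character scalar, invisibly when `file` is
#'   given.
#' @export
exportDOT <- function(model, prior = NULL, frequencies = NULL, file = NULL,
                      selfLoops = FALSE) {
  model <- .asModel(model)
  gn <- geneNames(model)
  sn <- stimulusNames(model)
  edges <- classifyEdges(model, prior)
  if (!selfLoops)
    edges <- edges[!(edges$type == "gene" & edges$source == edges$target), ,
                   drop = FALSE]
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph GRN {", "  rankdir=TB;",
             sprintf("  %s [shape=ellipse, style=filled, fillcolor=lightgrey];",
                     vapply(sn, q, "")),
             sprintf("  %s [shape=box];", vapply(gn, q, "")))
  for (r in seq_len(nrow(edges))) {
    e <- edges[r, ]
    attrs <- c(sprintf("color=%s", e$colour))
    if (e$colour == "grey") attrs <- c(attrs, "style=dashed")
    if (e$code == -10) attrs <- c(attrs, "arrowhead=tee")
    if (!is.null(frequencies)) {
      hit <- frequencies$source == e$source & frequencies$target == e$target
      if (any(hit)) {
        f <- frequencies$frequency[which(hit)[1L]]
        attrs <- c(attrs, sprintf('label="%d%%"', round(100 * f)),
                   sprintf("penwidth=%.2f", 0.5 + 3 * f))
      }
    }
    lines <- c(lines, sprintf("  %s -> %s [%s];", q(e$source), q(e$target),
                              paste(attrs, collapse = ", ")))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}

#' Export measured, interpolated and simulated time courses
#'
#' Writes (or returns) a long-by-time, wide-by-gene table comparing the data
#' with the final coupled simulation: one block per experiment with columns
#' `experiment`, `time`, `kind` (`measured`/`interpolated`/`simulated`) and
#' one column per gene.
#'
#' @param inference a [GRNInference-class] (model plus the data it was
#'   fitted to), or a [GRNModel-class] together with `dataset`.
#' @param dataset required when `inference` is a bare model.
#' @param file optional CSV output path.
#' @return the data.frame, invisibly when `file` is given.
#' @export
exportTimecourses <- function(inference, dataset = NULL, file = NULL) {
  if (is(inference, "GRNInference")) {
    model <- inference@model
    dataset <- inference@dataset
  } else model <- .asModel(inference)
  stopifnot(!is.null(dataset))
  out <- list()
  for (ex in dataset@experiments) {
    sim <- simulateGRN(model, ex@stimuli, ex@times)
    dat <- as.data.frame(ex@exprs)
    out[[length(out) + 1L]] <- cbind(
      data.frame(experiment = ex@name, time = ex@times,
                 kind = ex@pointKind, stringsAsFactors = FALSE), dat)
    simdf <- as.data.frame(sim)
    colnames(simdf) <- colnames(dat)
    out[[length(out) + 1L]] <- cbind(
      data.frame(experiment = ex@name, time = ex@times, kind = "simulated",
                 stringsAsFactors = FALSE), simdf)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (!is.null(file)) {
    write.csv(df, file, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Read/write a model as structured text
#'
#' Serialises a [GRNModel-class] (matrices, orders, names, state layout) to a
#' JSON text file and back.
#'
#' @param model a [GRNModel-class].
#' @param file path.
#' @return `writeGRNModel` returns the path invisibly; `readGRNModel` the
#'   model.
#' @export
writeGRNModel <- function(model, file) {
  obj <- list(
    geneNames = geneNames(model),
    stimulusNames = stimulusNames(model),
    interaction = interactionMatrix(model),
    input = inputMatrix(model),
    orders = model@orders,
    stateOrder = model@stateOrder,
    t0 = model@t0,
    sigmoid = model@sigmoid,
    sigmoidGain = model@sigmoidGain)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(file)
}

#' @rdname writeGRNModel
#' @export
readGRNModel <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  gn <- as.character(obj$geneNames)
  sn <- as.character(obj$stimulusNames)
  A <- matrix(as.numeric(obj$interaction), length(gn), length(gn),
              byrow = FALSE)
  B <- matrix(as.numeric(obj$input), length(gn), length(sn), byrow = FALSE)
  grnModel(A, B, orders = as.integer(obj$orders), geneNames = gn,
           stimulusNames = sn, stateOrder = as.integer(obj$stateOrder),
           t0 = as.numeric(obj$t0), sigmoid = isTRUE(obj$sigmoid),
           sigmoidGain = as.numeric(obj$sigmoidGain))
}

## ---------------------------------------------------------------------------
## Configuration files (flat YAML, dotted sections)
## ---------------------------------------------------------------------------

.configKeys <- list(
  list("search", "allowed_error", "allowedError"),
  list("search", "max_connections", "maxConnections"),
  list("search", "max_order", "maxOrder"),
  list("search", "grow_threshold", "growThreshold"),
  list("search", "prune_threshold", "pruneThreshold"),
  list("interpolation", "k_per_interval", "kPerInterval"),
  list("weights", "measured", "weightMeasured"),
  list("weights", "interpolated", "weightInterpolated"),
  list("optimiser", "lower_bound", "lowerBound"),
  list("optimiser", "upper_bound", "upperBound"),
  list("optimiser", "diag_upper", "diagUpper"),
  list("optimiser", "maxit", "maxit"),
  list("optimiser", "pgtol", "pgtol"),
  list("solver", "rtol", "rtol"),
  list("solver", "atol", "atol"),
  list("model", "sigmoid", "sigmoid"),
  list("model", "sigmoid_gain", "sigmoidGain"),
  list("general", "seed", "seed"))

#' Read/write an inference configuration
#'
#' Configurations are stored as a small YAML file with sections
#' (`search`, `interpolation`, `weights`, `optimiser`, `solver`, `model`,
#' `prior`, `general`); every key is optional and defaults to the
#' [grnConfig()] value. `prior: lambda` is returned as attribute `lambda`.
#'
#' @param file path of the YAML configuration.
#' @param config a [GRNConfig-class] to write.
#' @return `readConfig` returns a [GRNConfig-class]; `writeConfig` the path,
#'   invisibly.
#' @export
readConfig <- function(file) {
  y <- yaml::read_yaml(file)
  cfg <- grnConfig()
  for (k in .configKeys) {
    v <- y[[k[[1L]]]][[k[[2L]]]]
    if (!is.null(v)) {
      slotVal <- slot(cfg, k[[3L]])
      slot(cfg, k[[3L]]) <- if (is.integer(slotVal)) as.integer(v)
                            else if (is.logical(slotVal)) as.logical(v)
                            else as.numeric(v)
    }
  }
  validObject(cfg)
  if (!is.null(y$prior$lambda)) attr(cfg, "lambda") <- y$prior$lambda
  cfg
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, file) {
  y <- list()
  for (k in .configKeys) {
    v <- slot(config, k[[3L]])
    y[[k[[1L]]]][[k[[2L]]]] <- v
  }
  yaml::write_yaml(y, file)
  invisible(file)
}
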