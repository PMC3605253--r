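#' @include AllClasses.R
NULL

#' Standardise a dataset gene-wise
#'
#' Centres every gene series on its value at the first time point of each
#' experiment (so every series starts at exactly zero) and then divides the
#' gene's series in *all* experiments by one common scalar, the maximum
#' absolute centred value across experiments. The result lies in `[-1, 1]`
#' and equals 1 in absolute value at its cross-experiment extremum.
#' Standardisation is idempotent.
#'
#' A gene whose centred series is identically zero in every experiment has no
#' dynamics to model and cannot be scaled; depending on `onDegenerate` it
#' either raises an error of class `grnDegenerateSeries` or is dropped with a
#' warning.
#'
#' @param dataset a [GRNDataset-class].
#' @param onDegenerate `"error"` (default) or `"drop"`.
#' @return the standardised [GRNDataset-class].
#' @examples
#' ex <- grnExperiment(0:2, cbind(g1 = c(2, 3, 4)), cbind(u1 = rep(1, 3)))
#' standardiseDataset(grnDataset(list(ex)))  # series becomes 0, 0.5, 1
#' @export
standardiseDataset <- function(dataset, onDegenerate = c("error", "drop")) {
  onDegenerate <- match.arg(onDegenerate)
  gn <- dataset@geneNames
  exps <- dataset@experiments
  centred <- lapply(exps, function(ex)
    sweep(ex@exprs, 2L, ex@exprs[1L, ], "-"))
  scale <- rep(0, length(gn))
  for (ce in centred)
    if (nrow(ce) > 0 && ncol(ce) > 0)
      scale <- pmax(scale, apply(abs(ce), 2L, max))
  degenerate <- scale <= 1e-12
  if (any(degenerate)) {
    bad <- gn[degenerate]
    if (onDegenerate == "error")
      stop(structure(class = c("grnDegenerateSeries", "error", "condition"),
                     list(message = paste0(
                       "degenerate series (constant after centering): ",
                       paste(bad, collapse = ", ")), call = sys.call(-1))))
    warning("dropping degenerate series: ", paste(bad, collapse = ", "))
    keep <- !degenerate
    exps <- lapply(exps, function(ex) {
      ex@exprs <- ex@exprs[, keep, drop = FALSE]
      ex
    })
    centred <- lapply(centred, function(ce) ce[, keep, drop = FALSE])
    scale <- scale[keep]
    gn <- gn[keep]
  }
  out <- mapply(function(ex, ce) {
    ex@exprs <- sweep(ce, 2L, scale, "/")
    ex
  }, exps, centred, SIMPLIFY = FALSE)
  ds <- dataset
  ds@experiments <- out
  ds@geneNames <- gn
  ds@standardised <- TRUE
  validObject(ds)
  ds
}

#' Insert interpolated time points
#'
#' Inserts `k` equally spaced interior points per measured interval using a
#' natural cubic spline fitted per gene and per experiment. Measured values
#' are preserved bit-exactly; inserted points are flagged `"interpolated"`
#' and carry the (lower) interpolated weight, which damps their influence in
#' the fitting objective and so guards against over-fitting the interpolant.
#' Experiments with fewer than four measured points fall back to piecewise
#' linear interpolation (with a message).
#'
#' Stimulus profiles are treated as step functions and carried forward
#' constantly between measured points.
#'
#' @param dataset a [GRNDataset-class] (interpolation is intended to run on
#'   standardised data; interpolated values then inherit the common scale).
#' @param k interior points per interval (>= 0; 0 returns the dataset
#'   unchanged).
#' @param weightMeasured,weightInterpolated weights attached to measured and
#'   inserted points.
#' @return the augmented [GRNDataset-class].
#' @export
interpolateDataset <- function(dataset, k = 3L, weightMeasured = 1,
                               weightInterpolated = 0.25) {
  k <- as.integer(k)
  stopifnot(k >= 0L)
  if (k == 0L) return(dataset)
  ds <- dataset
  ds@experiments <- lapply(dataset@experiments, function(ex) {
    tt <- ex@times
    Tm <- length(tt)
    if (Tm < 2L) return(ex)
    newt <- unlist(lapply(seq_len(Tm - 1L), function(i) {
      seq(tt[i], tt[i + 1L], length.out = k + 2L)[seq_len(k + 1L)]
    }))
    newt <- c(newt, tt[Tm])
    measured <- rep(FALSE, length(newt))
    measured[1L + (seq_len(Tm) - 1L) * (k + 1L)] <- TRUE
    newt[measured] <- tt  # keep measured grid bit-exact
    linearFallback <- Tm < 4L
    if (linearFallback)
      message("fewer than 4 measured points in experiment '", ex@name,
              "': falling back to piecewise-linear interpolation")
    Y <- vapply(seq_len(ncol(ex@exprs)), function(j) {
      y <- if (linearFallback)
        approx(tt, ex@exprs[, j], xout = newt)$y
      else
        spline(tt, ex@exprs[, j], xout = newt, method = "natural")$y
      y[measured] <- ex@exprs[, j]
      y
    }, numeric(length(newt)))
    Y <- matrix(Y, nrow = length(newt),
                dimnames = list(NULL, colnames(ex@exprs)))
    U <- vapply(seq_len(ncol(ex@stimuli)), function(j)
      approx(tt, ex@stimuli[, j], xout = newt, method = "constant",
             rule = 2L)$y, numeric(length(newt)))
    U <- matrix(U, nrow = length(newt),
                dimnames = list(NULL, colnames(ex@stimuli)))
    ex@times <- newt
    ex@exprs <- Y
    ex@stimuli <- U
    ex@pointKind <- ifelse(measured, "measured", "interpolated")
    ex@weights <- ifelse(measured, weightMeasured, weightInterpolated)
    validObject(ex)
    ex
  })
  ds
}

#' Build step-function stimulus profiles
#'
#' Stimuli are described as step functions: a stimulus applied in an
#' experiment contributes a constant column of ones, an absent stimulus a
#' column of zeros.
#'
#' @param applied character vector naming the stimuli applied in the
#'   experiment (subset of `stimulusNames`).
#' @param times the experiment's time grid.
#' @param stimulusNames all stimulus names, fixing the column order.
#' @return a `length(times) x length(stimulusNames)` 0/1 matrix.
#' @examples
#' buildStepInputs("TGFb1", 0:9, c("TGFb1", "BMP2"))
#' @export
buildStepInputs <- function(applied, times, stimulusNames) {
  unknown <- setdiff(applied, stimulusNames)
  if (length(unknown))
    stop("unknown stimulus name(s): ", paste(unknown, collapse = ", "))
  U <- matrix(0, length(times), length(stimulusNames),
              dimnames = list(NULL, stimulusNames))
  U[, applied] <- 1
  U
}

#' Keep a subset of experiments
#'
#' Selects experiments from a dataset (e.g. to infer from a single-stimulus
#' scenario). Standardisation is *not* re-applied automatically; the common
#' gene-wise scale of a subset differs from that of the full dataset, so run
#' [standardiseDataset()] afterwards when the subset is analysed on its own.
#'
#' @param dataset a [GRNDataset-class].
#' @param which integer or character index of the experiments to keep.
#' @return a [GRNDataset-class] with the selected experiments.
#' @export
subsetExperiments <- function(dataset, which) {
  if (is.character(which))
    which <- match(which, vapply(dataset@experiments, slot, "", "name"))
  ds <- dataset
  ds@experiments <- dataset@experiments[which]
  validObject(ds)
  ds
}

## ---------------------------------------------------------------------------
## Tabular input/output (wide CSV: first column = name, then one column per
## time point, header row carries the times)
## ---------------------------------------------------------------------------

.readWide <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  times <- as.numeric(colnames(df)[-1L])
  if (anyNA(times))
    stop("header of ", path, " must contain numeric time points")
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df[[1L]]
  list(names = df[[1L]], times = times, values = M)
}

.writeWide <- function(M, times, path) {
  df <- data.frame(name = rownames(M), M, check.names = FALSE)
  colnames(df) <- c("name", format(times, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one experiment from wide CSV files
#'
#' Expression and stimulus files are wide tables: the first column holds the
#' gene (or stimulus) name, the remaining columns hold one time point each,
#' with the sampling times in the header row.
#'
#' @param exprFile path of the expression table (genes x time points).
#' @param stimulusFile path of the stimulus table (stimuli x time points),
#'   or `NULL` for an unstimulated experiment.
#' @param name experiment label, defaults to the expression file name.
#' @return a [GRNExperiment-class].
#' @export
readExperiment <- function(exprFile, stimulusFile = NULL, name = NULL) {
  e <- .readWide(exprFile)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(exprFile))
  Y <- t(e$values)
  dimnames(Y) <- list(NULL, e$names)
  if (!is.null(stimulusFile)) {
    s <- .readWide(stimulusFile)
    if (!isTRUE(all.equal(e$times, s$times)))
      stop("expression and stimulus files must share the time grid")
    U <- t(s$values)
    dimnames(U) <- list(NULL, s$names)
  } else {
    U <- matrix(0, nrow(Y), 0L)
  }
  grnExperiment(e$times, Y, U, name = name)
}

#' Write one experiment to wide CSV files
#'
#' Writes the measured points of an experiment in the format read by
#' [readExperiment()]. Interpolated points are artefacts of the algorithm and
#' are not part of the on-disk representation.
#'
#' @param experiment a [GRNExperiment-class].
#' @param exprFile,stimulusFile output paths (`stimulusFile = NULL` skips the
#'   stimulus table).
#' @return the expression file path, invisibly.
#' @export
writeExperiment <- function(experiment, exprFile, stimulusFile = NULL) {
  keep <- experiment@pointKind == "measured"
  tt <- experiment@times[keep]
  .writeWide(t(experiment@exprs[keep, , drop = FALSE]), tt, exprFile)
  if (!is.null(stimulusFile))
    .writeWide(t(experiment@stimuli[keep, , drop = FALSE]), tt, stimulusFile)
  invisible(exprFile)
}
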