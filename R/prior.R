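#' @include AllClasses.R
NULL

#' Encode a model coefficient in the prior-knowledge convention
#'
#' Converts a model coefficient into the connection-code notation used for
#' comparing model structure with prior knowledge: `0` (no connection) when
#' the coefficient is inside the zero tolerance, `10` (activation) when
#' positive, `-10` (inhibition) when negative. The code `1` (connection of
#' unknown sign) is an input-side code only and is never produced here.
#'
#' @param coefficient scalar (or vector of) model coefficient(s).
#' @param tol zero tolerance, default `1e-6`.
#' @return integer code(s) in `{0, 10, -10}`.
#' @export
encodeEdge <- function(coefficient, tol = 1e-6) {
  ifelse(abs(coefficient) <= tol, 0L, ifelse(coefficient > 0, 10L, -10L))
}

#' Sign distance between a model edge and a prior code
#'
#' Binary distance used in the penalised objective: `0` when the modelled
#' code is compatible with the prior code (exact match; a presence-only prior
#' `1` satisfied by either sign; unknown prior always compatible), `1`
#' otherwise (edge/no-edge mismatch or sign flip).
#'
#' @param modelCode code of the modelled edge (from [encodeEdge()]).
#' @param priorCode prior code in `{NA, 0, 1, 10, -10}`.
#' @return 0 or 1 (vectorised).
#' @export
signDistance <- function(modelCode, priorCode) {
  d <- ifelse(is.na(priorCode), 0L,
       ifelse(priorCode == modelCode, 0L,
       ifelse(priorCode == 1 & modelCode %in% c(10L, -10L), 0L, 1L)))
  as.integer(d)
}

#' Compare inferred edges with prior knowledge for graph colouring
#'
#' Classifies every inferred edge and every prior-knowledge entry into the
#' colour code used by the DOT export: `black` = inferred, no prior
#' knowledge; `green` = inferred and agreeing with the prior; `blue` =
#' inferred and supported by a binding-site-origin prior; `red` = inferred
#' but contradicting the prior (wrong sign, or a prior "no connection");
#' `grey` (drawn dashed) = prior connection not reproduced by the model.
#'
#' @param model a [GRNModel-class].
#' @param prior a [GRNPrior-class], or `NULL` (all inferred edges black).
#' @return a data.frame with columns `source`, `target`, `type`
#'   (`"gene"`/`"input"`), `coefficient`, `code` and `colour`.
#' @export
classifyEdges <- function(model, prior = NULL) {
  gn <- geneNames(model)
  sn <- stimulusNames(model)
  priorAt <- function(i, j, what) {
    if (is.null(prior)) return(list(code = NA_real_, origin = NA_character_))
    if (what == "gene") {
      code <- prior@Afix[i, j]
      if (is.na(code)) code <- prior@Aflex[i, j]
      list(code = code, origin = prior@Aorigin[i, j])
    } else {
      code <- prior@Bfix[i, j]
      if (is.na(code)) code <- prior@Bflex[i, j]
      list(code = code, origin = prior@Borigin[i, j])
    }
  }
  rows <- list()
  addRow <- function(src, tgt, type, coef, i, j) {
    pk <- priorAt(i, j, type)
    code <- encodeEdge(coef)
    colour <-
      if (code != 0) {
        if (is.na(pk$code)) "black"
        else if (signDistance(code, pk$code) == 0) {
          if (identical(pk$origin, "binding-site")) "blue" else "green"
        } else "red"
      } else if (!is.na(pk$code) && pk$code != 0) "grey"
      else return()
    rows[[length(rows) + 1L]] <<- data.frame(
      source = src, target = tgt, type = type, coefficient = coef,
      code = code, colour = colour, stringsAsFactors = FALSE)
  }
  A <- model@interaction
  B <- model@input
  for (i in seq_along(gn)) {
    for (j in seq_along(gn)) addRow(gn[j], gn[i], "gene", A[i, j], i, j)
    for (m in seq_along(sn)) addRow(sn[m], gn[i], "input", B[i, m], i, m)
  }
  if (!length(rows))
    return(data.frame(source = character(), target = character(),
                      type = character(), coefficient = numeric(),
                      code = integer(), colour = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read prior knowledge from a long-form CSV file
#'
#' One row per known (or excluded) connection with columns `source`, `target`,
#' `mode` (`fix` or `flexible`), `code` (0, 1, 10 or -10), optional `score`
#' (default 1) and optional `origin` (e.g. `literature`, `binding-site`).
#' Sources may be genes or stimuli; targets must be genes.
#'
#' @param path CSV file path.
#' @param geneNames,stimulusNames network labels the entries are validated
#'   against.
#' @param lambda penalty weight of the resulting prior.
#' @return a [GRNPrior-class].
#' @export
readPrior <- function(path, geneNames, stimulusNames = character(),
                      lambda = 0.1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "mode", "code")
  if (!all(need %in% names(df)))
    stop("prior file must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$score)) df$score <- 1
  if (is.null(df$origin)) df$origin <- NA_character_
  pr <- grnPrior(geneNames, stimulusNames, lambda = lambda)
  for (r in seq_len(nrow(df))) {
    src <- df$source[r]; tgt <- df$target[r]
    mode <- df$mode[r]; code <- df$code[r]
    if (!tgt %in% geneNames) stop("unknown target gene: ", tgt)
    if (!code %in% .validCodes) stop("invalid code: ", code)
    if (!mode %in% c("fix", "flexible")) stop("invalid mode: ", mode)
    i <- match(tgt, geneNames)
    if (src %in% geneNames) {
      j <- match(src, geneNames)
      if (mode == "fix") pr@Afix[i, j] <- code else {
        pr@Aflex[i, j] <- code
        pr@Ascore[i, j] <- df$score[r]
      }
      pr@Aorigin[i, j] <- df$origin[r]
    } else if (src %in% stimulusNames) {
      j <- match(src, stimulusNames)
      if (mode == "fix") pr@Bfix[i, j] <- code else {
        pr@Bflex[i, j] <- code
        pr@Bscore[i, j] <- df$score[r]
      }
      pr@Borigin[i, j] <- df$origin[r]
    } else stop("unknown source: ", src)
  }
  validObject(pr)
  pr
}
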