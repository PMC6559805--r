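#' Pairwise parameter-state co-occurrence counts
#'
#' Trajectories are first resampled to a common frame interval (see
#' [resampleAnnotations()]); over the retained observations, cell (i, j)
#' counts how often the row parameter is in state i while the column
#' parameter is in state j (both annotated). The per-column totals count
#' every retained observation whose column parameter is in state j —
#' including those where the row parameter could not be annotated — and
#' are the denominators of the normalisation.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @param rowParam,colParam two distinct parameter names.
#' @param intervalMin resampling interval in minutes (default 15).
#' @return A [CoocMatrix-class] with raw counts and column totals; apply
#'   [normalizeCooccurrence()] for the normalised values.
#' @export
cooccurrenceCounts <- function(ds, rowParam, colParam, intervalMin = 15) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  params <- ds@ontology@parameters
  for (p in c(rowParam, colParam))
    if (!p %in% params) stop("unknown parameter: ", p)
  if (rowParam == colParam)
    stop("row and column parameters must differ")
  rs <- resampleAnnotations(ds, intervalMin)
  d <- rs@data
  nRow <- ds@ontology@nStates[match(rowParam, params)]
  nCol <- ds@ontology@nStates[match(colParam, params)]
  r <- d[[rowParam]]
  c2 <- d[[colParam]]
  colTotals <- tabulate(c2[!is.na(c2)], nbins = nCol)
  both <- !is.na(r) & !is.na(c2)
  counts <- matrix(0L, nRow, nCol,
                   dimnames = list(paste0(rowParam, "_", seq_len(nRow)),
                                   paste0(colParam, "_", seq_len(nCol))))
  if (any(both)) {
    tab <- table(factor(r[both], levels = seq_len(nRow)),
                 factor(c2[both], levels = seq_len(nCol)))
    counts[] <- as.integer(tab)
  }
  new("CoocMatrix", rowParam = rowParam, colParam = colParam,
      counts = counts, colTotals = as.integer(colTotals),
      normalized = matrix(numeric(), 0L, 0L),
      emptyColumns = logical(), intervalMin = intervalMin)
}

#' Column-normalise a co-occurrence matrix
#'
#' Each column is divided by its total number of retained observations in
#' that column state, including observations where the partner parameter
#' was unannotated. Because partner-missing observations contribute to the
#' denominator but never to a numerator, a normalised column sums to 1
#' exactly when the column has no partner-missing observations, and to the
#' non-missing fraction otherwise. Columns with zero total are reported as
#' all-zero and flagged in `emptyColumns`.
#'
#' @param m a [CoocMatrix-class] from [cooccurrenceCounts()].
#' @return The same object with `normalized` and `emptyColumns` filled in.
#' @export
normalizeCooccurrence <- function(m) {
  stopifnot(is(m, "CoocMatrix"))
  empty <- m@colTotals == 0L
  denom <- ifelse(empty, 1L, m@colTotals)
  norm <- sweep(m@counts, 2L, denom, "/")
  norm[, empty] <- 0
  m@normalized <- norm
  m@emptyColumns <- empty
  m
}

setMethod("show", "CoocMatrix", function(object) {
  cat("CoocMatrix: ", object@rowParam, " x ", object@colParam,
      " (", nrow(object@counts), " x ", ncol(object@counts),
      " states), resampled at ", object@intervalMin, " min\n", sep = "")
  cat("  total pair counts: ", sum(object@counts),
      "; column totals incl. partner-missing: ", sum(object@colTotals),
      "\n", sep = "")
  if (!length(object@normalized))
    cat("  (not yet normalised; see normalizeCooccurrence())\n")
})

#' Export a co-occurrence matrix as CSV
#'
#' Writes the raw counts, and the normalised values when present, as CSV
#' tables with a leading column of row-parameter states.
#'
#' @param m a [CoocMatrix-class].
#' @param rawPath path for the raw counts.
#' @param normalizedPath optional path for the normalised matrix.
#' @return Invisibly, the paths written.
#' @export
writeCooccurrence <- function(m, rawPath, normalizedPath = NULL) {
  stopifnot(is(m, "CoocMatrix"))
  utils::write.csv(as.data.frame(m@counts), rawPath, row.names = TRUE,
                   fileEncoding = "UTF-8")
  written <- rawPath
  if (!is.null(normalizedPath)) {
    if (!length(m@normalized)) m <- normalizeCooccurrence(m)
    utils::write.csv(as.data.frame(m@normalized), normalizedPath,
                     row.names = TRUE, fileEncoding = "UTF-8")
    written <- c(written, normalizedPath)
  }
  invisible(written)
}
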