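#' Construct a MeiosisAnnotations object from a data.frame
#'
#' @param data data.frame with columns \code{genotype}, \code{anther_id},
#'   \code{cell_id}, \code{time_min} and one integer column per ontology
#'   parameter (\code{NA} = unannotated). Rows are re-sorted by trajectory
#'   and time.
#' @param ontology a [ParameterOntology-class].
#' @return A [MeiosisAnnotations-class].
#' @export
MeiosisAnnotations <- function(data, ontology) {
  stopifnot(is(ontology, "ParameterOntology"))
  params <- ontology@parameters
  need <- c(ID_COLUMNS, params)
  miss <- setdiff(need, colnames(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[need]
  for (col in c("genotype", "anther_id", "cell_id"))
    data[[col]] <- as.character(data[[col]])
  data$time_min <- as.numeric(data$time_min)
  for (p in params) data[[p]] <- as.integer(data[[p]])
  ord <- order(data$genotype, data$anther_id, data$cell_id, data$time_min)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  new("MeiosisAnnotations", ontology = ontology, data = data)
}

#' Read an annotation CSV
#'
#' The CSV dialect: comma-separated, UTF-8, header row with the columns
#' \code{genotype}, \code{anther_id}, \code{cell_id}, \code{time_min}
#' followed by one column per ontology parameter; an unannotated parameter
#' state is written \code{"n"}.
#'
#' @param path path to the CSV file.
#' @param ontology a [ParameterOntology-class]; the parameter columns of
#'   the file must match its parameters exactly.
#' @return A [MeiosisAnnotations-class] with one observation per row of the
#'   file (row count preserved; trajectories sorted by time).
#' @seealso [writeAnnotations()]
#' @export
readAnnotations <- function(path, ontology) {
  stopifnot(is(ontology, "ParameterOntology"))
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  params <- ontology@parameters
  extra <- setdiff(colnames(raw), c(ID_COLUMNS, params))
  if (length(extra))
    stop("unknown parameter column(s): ", paste(extra, collapse = ", "))
  miss <- setdiff(c(ID_COLUMNS, params), colnames(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (p in params) {
    v <- raw[[p]]
    v[v == "n"] <- NA_character_
    iv <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(iv))
    if (length(bad))
      stop(sprintf("non-integer state for '%s' at data row(s) %s",
                   p, paste(utils::head(bad, 5L), collapse = ", ")))
    k <- ontology@nStates[match(p, params)]
    out <- which(!is.na(iv) & (iv < 1L | iv > k))
    if (length(out))
      stop(sprintf(
        "state value outside ontology range 1..%d for '%s' at data row(s) %s",
        k, p, paste(utils::head(out, 5L), collapse = ", ")))
    raw[[p]] <- iv
  }
  raw$time_min <- as.numeric(raw$time_min)
  MeiosisAnnotations(raw, ontology)
}

#' Write an annotation CSV
#'
#' Inverse of [readAnnotations()]; missing parameter states are written as
#' \code{"n"} so that a parse/write/parse cycle round-trips exactly.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeAnnotations <- function(ds, path) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  d <- ds@data
  for (p in ds@ontology@parameters) {
    v <- as.character(d[[p]])
    v[is.na(v)] <- "n"
    d[[p]] <- v
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Accessors for annotation datasets
#'
#' @param object a [MeiosisAnnotations-class].
#' @return `observations()`: the observation data.frame; `ontology()`: the
#'   [ParameterOntology-class]; `nObservations()`, `nCells()`: integer
#'   scalars; `isComplete()`: logical vector flagging rows with no missing
#'   parameter state.
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))

#' @rdname observations
#' @export
setMethod("observations", "MeiosisAnnotations", function(object) object@data)

#' @rdname observations
#' @export
setGeneric("ontology", function(object) standardGeneric("ontology"))

#' @rdname observations
#' @export
setMethod("ontology", "MeiosisAnnotations", function(object) object@ontology)

#' @rdname observations
#' @export
setGeneric("nObservations", function(object)
  standardGeneric("nObservations"))

#' @rdname observations
#' @export
setMethod("nObservations", "MeiosisAnnotations", function(object)
  nrow(object@data))

#' @rdname observations
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname observations
#' @export
setMethod("nCells", "MeiosisAnnotations", function(object)
  length(unique(trajectoryKey(object@data))))

#' @rdname observations
#' @export
setGeneric("isComplete", function(object) standardGeneric("isComplete"))

#' @rdname observations
#' @export
setMethod("isComplete", "MeiosisAnnotations", function(object) {
  stateMat <- as.matrix(object@data[object@ontology@parameters])
  rowSums(is.na(stateMat)) == 0L
})

trajectoryKey <- function(d)
  paste(d$genotype, d$anther_id, d$cell_id, sep = "\r")

stateMatrix <- function(ds) {
  m <- as.matrix(ds@data[ds@ontology@parameters])
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

setMethod("show", "MeiosisAnnotations", function(object) {
  comp <- sum(isComplete(object))
  cat("MeiosisAnnotations (", object@ontology@genotype, "): ",
      nObservations(object), " observations, ", nCells(object),
      " cells, ", comp, " complete (",
      if (nObservations(object))
        sprintf("%.1f%%", 100 * comp / nObservations(object)) else "-",
      ")\n", sep = "")
})

#' Keep only complete observations
#'
#' Drops every observation with at least one unannotated parameter state;
#' row ordering is preserved.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @return A [MeiosisAnnotations-class] (possibly empty).
#' @export
filterComplete <- function(ds) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  keep <- isComplete(ds)
  out <- ds
  out@data <- ds@data[keep, , drop = FALSE]
  rownames(out@data) <- NULL
  out
}

#' Fractions of incomplete and fully missing observations
#'
#' @param ds a [MeiosisAnnotations-class].
#' @return A list: `n` (rows), `n_incomplete` / `frac_incomplete`
#'   (rows with at least one unannotated parameter) and `n_all_missing` /
#'   `frac_all_missing` (rows with no parameter annotated).
#' @export
missingnessSummary <- function(ds) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  m <- is.na(as.matrix(ds@data[ds@ontology@parameters]))
  n <- nrow(m)
  nInc <- sum(rowSums(m) > 0L)
  nAll <- sum(rowSums(m) == ncol(m))
  list(n = n,
       n_incomplete = nInc,
       frac_incomplete = if (n) nInc / n else 0,
       n_all_missing = nAll,
       frac_all_missing = if (n) nAll / n else 0)
}

resampleIndices <- function(times, intervalMin) {
  n <- length(times)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  t0 <- times[1L]
  span <- times[n] - t0
  grid <- t0 + intervalMin * seq.int(0L, ceiling(span / intervalMin))
  # nearest observation per grid point, ties resolved toward the earlier frame
  idx <- vapply(grid, function(g) which.min(abs(times - g)), integer(1L))
  sort(unique(idx))
}

#' Resample trajectories to a common frame interval
#'
#' Movies were acquired at different frame intervals; before counting
#' co-occurrences all trajectories are put on a common grid. For each
#' trajectory a grid anchored at its first time point is laid out and the
#' original observation nearest to each grid point is retained (ties go to
#' the earlier frame); nothing is interpolated and no states are
#' fabricated, so the result is always a subsequence of the input.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @param intervalMin target frame interval in minutes (default 15, the
#'   coarsest acquisition interval).
#' @return A [MeiosisAnnotations-class] containing the retained subset.
#' @export
resampleAnnotations <- function(ds, intervalMin = 15) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  if (!is.numeric(intervalMin) || length(intervalMin) != 1L ||
      intervalMin <= 0)
    stop("intervalMin must be a single positive number")
  d <- ds@data
  if (!nrow(d)) return(ds)
  key <- trajectoryKey(d)
  keep <- unlist(lapply(split(seq_len(nrow(d)), key), function(rows) {
    rows[resampleIndices(d$time_min[rows], intervalMin)]
  }), use.names = FALSE)
  out <- ds
  out@data <- d[sort(keep), , drop = FALSE]
  rownames(out@data) <- NULL
  out
}

#' Project a dataset onto a subset of parameters
#'
#' Emulates analyses with a single reporter: the new dataset's ontology
#' contains only the requested parameters (in ontology order) and row
#' completeness is re-evaluated on that subset, so observations that were
#' incomplete only in dropped parameters become complete.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @param parameters non-empty character vector of parameter names, in
#'   ontology order.
#' @return A [MeiosisAnnotations-class] over the reduced ontology, with the
#'   same cells and time points.
#' @export
projectParameters <- function(ds, parameters) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  if (!length(parameters)) stop("parameter subset must be non-empty")
  ont <- ds@ontology
  bad <- setdiff(parameters, ont@parameters)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  idx <- match(parameters, ont@parameters)
  if (is.unsorted(idx))
    stop("parameters must be given in ontology order")
  sub <- ParameterOntology(ont@parameters[idx], ont@nStates[idx],
                           ont@genotype)
  MeiosisAnnotations(ds@data[c(ID_COLUMNS, parameters)], sub)
}
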