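#' Enumerate observed complete cellular states
#'
#' Counts every distinct complete cellular state over the complete
#' observations of the dataset (incomplete rows are ignored).
#'
#' @param ds a [MeiosisAnnotations-class].
#' @return A [StateCountTable-class].
#' @export
stateCounts <- function(ds) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  comp <- filterComplete(ds)
  m <- stateMatrix(comp)
  keys <- formatState(m)
  if (!length(keys)) {
    return(new("StateCountTable",
               states = matrix(integer(),
                               ncol = length(ds@ontology@parameters)),
               counts = integer(), total = 0L, ontology = ds@ontology))
  }
  tab <- table(keys)
  states <- parseState(names(tab))
  new("StateCountTable", states = states,
      counts = as.integer(tab), total = as.integer(sum(tab)),
      ontology = ds@ontology)
}

#' Construct a StateCountTable directly
#'
#' @param states integer matrix of complete state tuples (one row per
#'   state) or a character vector of dash tuples.
#' @param counts integer vector of observation counts.
#' @param ontology a [ParameterOntology-class].
#' @return A [StateCountTable-class].
#' @export
StateCountTable <- function(states, counts, ontology) {
  if (!is.matrix(states)) states <- parseState(states)
  if (is.null(rownames(states))) rownames(states) <- formatState(states)
  storage.mode(states) <- "integer"
  new("StateCountTable", states = states, counts = as.integer(counts),
      total = as.integer(sum(counts)), ontology = ontology)
}

setMethod("show", "StateCountTable", function(object) {
  cat("StateCountTable: ", nrow(object@states),
      " distinct complete states over ", object@total,
      " observations\n", sep = "")
})

#' @describeIn StateCountTable-class number of distinct observed states.
#' @param x a `StateCountTable`.
#' @export
setMethod("length", "StateCountTable", function(x) nrow(x@states))

#' @describeIn StateCountTable-class counts as a data.frame (state, count,
#'   frequency in % of complete observations).
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @export
setMethod("as.data.frame", "StateCountTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(state = rownames(x@states),
               count = x@counts,
               frequency_pct = if (x@total) 100 * x@counts / x@total
                               else numeric(length(x@counts)),
               row.names = NULL)
  })

#' Neighbor relation between cellular states
#'
#' Two complete cellular states are neighbors iff they differ in at least
#' one and at most two parameters, and every differing parameter differs by
#' exactly one state (in either direction). The relation is symmetric and
#' irreflexive.
#'
#' @param a,b complete integer state tuples of equal length.
#' @return TRUE or FALSE.
#' @examples
#' areNeighbors(c(2, 4, 2, 3, 4), c(2, 3, 2, 3, 4))  # TRUE
#' areNeighbors(c(2, 4, 2, 3, 4), c(2, 2, 2, 3, 4))  # FALSE: one jump of 2
#' @export
areNeighbors <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("states must have the same number of parameters")
  if (anyNA(a) || anyNA(b))
    stop("neighbor relation is defined for complete states only")
  d <- abs(a - b)
  ndiff <- sum(d > 0L)
  ndiff >= 1L && ndiff <= 2L && all(d <= 1L)
}

# K x K logical adjacency over the rows of a complete-state matrix
neighborAdjacency <- function(states) {
  k <- nrow(states)
  adj <- matrix(FALSE, k, k)
  if (k < 2L) return(adj)
  for (p in seq_len(ncol(states))) {
    dp <- abs(outer(states[, p], states[, p], "-"))
    if (p == 1L) {
      ndiff <- (dp > 0L) * 1L
      okstep <- dp <= 1L
    } else {
      ndiff <- ndiff + (dp > 0L)
      okstep <- okstep & dp <= 1L
    }
  }
  adj <- okstep & ndiff >= 1L & ndiff <= 2L
  diag(adj) <- FALSE
  adj
}

# population (divide-by-n) standard deviation
popSD <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

scoreFromCounts <- function(count, neighborCounts) {
  if (length(neighborCounts) == 0L)
    return(list(score = Inf, basis = "no_neighbors",
                mean = NA_real_, sd = NA_real_))
  m <- mean(neighborCounts)
  s <- popSD(neighborCounts)
  if (s == 0) {
    if (count > m) return(list(score = Inf, basis = "zero_spread",
                               mean = m, sd = s))
    if (count == m) return(list(score = 0, basis = "zero_spread",
                                mean = m, sd = s))
    return(list(score = -Inf, basis = "zero_spread", mean = m, sd = s))
  }
  list(score = (count - m) / s, basis = "finite", mean = m, sd = s)
}

#' Neighboring score of one observed state
#'
#' The score compares how often a state is observed with how often its
#' *observed* neighbors are:
#' \deqn{(count(s) - mean(count(N_s))) / sd_{pop}(count(N_s)).}
#' Only states actually present in the count table enter the neighbor set.
#' When the neighbor spread is zero the formula is undefined; a count above
#' the (common) neighbor count yields the +Inf sentinel, an equal count
#' yields 0. A state without any observed neighbor yields +Inf with a
#' distinct flag.
#'
#' @param state a complete integer state tuple, or its dash notation.
#' @param counts a [StateCountTable-class] containing the state.
#' @return A list: `score`, `basis` ("finite", "zero_spread" or
#'   "no_neighbors"), `count`, `neighbors` (dash notation of the observed
#'   neighbors), `neighbor_mean`, `neighbor_sd`.
#' @export
neighboringScore <- function(state, counts) {
  stopifnot(is(counts, "StateCountTable"))
  if (is.character(state)) state <- drop(parseState(state))
  state <- as.integer(state)
  if (anyNA(state)) stop("score is defined for complete states only")
  key <- formatState(state)
  i <- match(key, rownames(counts@states))
  if (is.na(i)) stop("state ", key, " is not observed in the count table")
  isNb <- vapply(seq_len(nrow(counts@states)), function(j)
    j != i && areNeighbors(state, counts@states[j, ]), logical(1L))
  nb <- which(isNb)
  res <- scoreFromCounts(counts@counts[i], counts@counts[nb])
  list(score = res$score, basis = res$basis,
       count = counts@counts[i],
       neighbors = rownames(counts@states)[nb],
       neighbor_mean = res$mean, neighbor_sd = res$sd)
}

# core scoring over a StateCountTable; adjacency may be precomputed
scoreCountTable <- function(counts, threshold = 1, adjacency = NULL) {
  k <- length(counts@counts)
  if (k == 0L) {
    return(data.frame(state = character(), count = integer(),
                      frequency_pct = numeric(), n_neighbors = integer(),
                      neighbor_mean = numeric(), neighbor_sd = numeric(),
                      score = numeric(), score_basis = character(),
                      is_landmark = logical()))
  }
  if (is.null(adjacency)) adjacency <- neighborAdjacency(counts@states)
  out <- data.frame(state = rownames(counts@states),
                    count = counts@counts,
                    frequency_pct = 100 * counts@counts / counts@total,
                    n_neighbors = integer(k),
                    neighbor_mean = numeric(k),
                    neighbor_sd = numeric(k),
                    score = numeric(k),
                    score_basis = character(k),
                    is_landmark = logical(k),
                    row.names = NULL)
  for (i in seq_len(k)) {
    nb <- counts@counts[adjacency[i, ]]
    res <- scoreFromCounts(counts@counts[i], nb)
    out$n_neighbors[i] <- length(nb)
    out$neighbor_mean[i] <- res$mean
    out$neighbor_sd[i] <- res$sd
    out$score[i] <- res$score
    out$score_basis[i] <- res$basis
  }
  out$is_landmark <- out$score > threshold
  out
}

#' Score every state of a count table
#'
#' Applies the neighboring score to all states of a
#' [StateCountTable-class] (neighbor sets restricted to the states in the
#' table) and flags landmarks at the given strict threshold.
#'
#' @param counts a [StateCountTable-class].
#' @param threshold landmark threshold (default 1).
#' @return data.frame with one row per state: count, frequency (% of the
#'   table total), observed-neighbor summary, score, score basis and
#'   landmark flag.
#' @export
scoreStates <- function(counts, threshold = 1) {
  stopifnot(is(counts, "StateCountTable"))
  scoreCountTable(counts, threshold = threshold)
}

#' Extract landmark states from an annotation dataset
#'
#' Enumerates the observed complete cellular states, scores each against
#' its observed neighbors with the neighboring score, and flags as
#' landmarks the states whose score strictly exceeds the threshold (the
#' +Inf sentinel exceeds any threshold). Landmarks are the convergence
#' points of meiotic progression; the remaining observed states are
#' transition states.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @param threshold landmark threshold (default 1; strict comparison).
#' @return A [LandmarkScores-class]; empty dataset gives an empty table.
#' @export
extractLandmarks <- function(ds, threshold = 1) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  counts <- stateCounts(ds)
  new("LandmarkScores",
      table = scoreCountTable(counts, threshold = threshold),
      threshold = threshold, ontology = ds@ontology)
}

#' Accessors for landmark score tables
#'
#' @param object a [LandmarkScores-class].
#' @param x a [LandmarkScores-class].
#' @return `scores()`: the full score data.frame; `landmarkStates()`: dash
#'   notation of the states flagged as landmarks, ordered by decreasing
#'   count.
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "LandmarkScores", function(object) object@table)

#' @rdname scores
#' @export
setGeneric("landmarkStates", function(object)
  standardGeneric("landmarkStates"))

#' @rdname scores
#' @export
setMethod("landmarkStates", "LandmarkScores", function(object) {
  t <- object@table[object@table$is_landmark, , drop = FALSE]
  t$state[order(-t$count)]
})

#' @rdname scores
#' @param row.names,optional,... S3 compatibility, unused.
#' @export
setMethod("as.data.frame", "LandmarkScores",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "LandmarkScores", function(object) {
  cat("LandmarkScores: ", nrow(object@table), " observed states, ",
      sum(object@table$is_landmark), " landmarks (score > ",
      object@threshold, ")\n", sep = "")
  if (nrow(object@table)) {
    lm <- object@table[object@table$is_landmark, , drop = FALSE]
    lm <- lm[order(-lm$count), , drop = FALSE]
    for (i in seq_len(min(nrow(lm), 15L)))
      cat(sprintf("  %s  count %d  score %s\n", lm$state[i], lm$count[i],
                  ifelse(is.finite(lm$score[i]),
                         sprintf("%.2f", lm$score[i]), "Inf")))
  }
})

#' Export a score table as CSV
#'
#' Columns: state (dash notation), count, frequency (% of complete
#' observations), number of observed neighbors, score, score basis and
#' landmark flag. Infinite sentinel scores are written as "Inf"/"-Inf".
#'
#' @param object a [LandmarkScores-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeScores <- function(object, path) {
  stopifnot(is(object, "LandmarkScores"))
  utils::write.csv(object@table, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
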