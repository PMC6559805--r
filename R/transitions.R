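#' Observed directed network of cellular-state changes
#'
#' For every trajectory, each pair of consecutive complete observations
#' with different cellular states adds one count to the directed edge
#' between them. Pairs separated by one or more incomplete observations
#' contribute no edge (a bridged edge could span several real
#' transitions), and consecutive identical states contribute no edge —
#' persistence is encoded in the node counts.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @return A [TransitionGraph-class].
#' @export
transitionCounts <- function(ds) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  d <- ds@data
  m <- stateMatrix(ds)
  complete <- rowSums(is.na(m)) == 0L
  keys <- rep(NA_character_, nrow(d))
  keys[complete] <- formatState(m[complete, , drop = FALSE])
  key <- trajectoryKey(d)
  from <- character(); to <- character()
  for (rows in split(seq_len(nrow(d)), key)) {
    k <- keys[rows]
    n <- length(k)
    if (n < 2L) next
    a <- k[-n]; b <- k[-1L]
    ok <- !is.na(a) & !is.na(b) & a != b
    from <- c(from, a[ok]); to <- c(to, b[ok])
  }
  counts <- stateCounts(ds)
  nodes <- data.frame(state = rownames(counts@states),
                      count = counts@counts, row.names = NULL)
  if (length(from)) {
    tab <- table(from = from, to = to)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, , drop = FALSE]
    edges <- data.frame(from = df$from, to = df$to,
                        count = as.integer(df$Freq), row.names = NULL)
    edges <- edges[order(-edges$count, edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        count = integer())
  }
  new("TransitionGraph", nodes = nodes, edges = edges,
      scheme = data.frame(), ontology = ds@ontology)
}

setMethod("show", "TransitionGraph", function(object) {
  cat("TransitionGraph: ", nrow(object@nodes), " states, ",
      nrow(object@edges), " directed transitions (",
      sum(object@edges$count), " observed changes)\n", sep = "")
  if (nrow(object@scheme))
    cat("  off-scheme states: ", sum(!object@scheme$scheme_compliant),
        "\n", sep = "")
})

#' Flag states that do not fit a landmark scheme
#'
#' A state is scheme-compliant iff there exists a pair of consecutive
#' landmarks L_k, L_k+1 on the given path such that every parameter value
#' lies within the closed interval between its values at L_k and L_k+1.
#' This is an explicit formalisation of "transitions that do not fit the
#' landmark scheme"; the interpretation is recorded in exported metadata.
#'
#' @param g a [TransitionGraph-class].
#' @param landmarkPath integer matrix of ordered landmark tuples
#'   (coordinate-wise non-decreasing), one row per landmark.
#' @return The graph with its `scheme` slot filled: per-node compliance
#'   flags plus the attribute `offSchemeFraction(g)` — the fraction of
#'   observations sitting in non-compliant states.
#' @export
flagOffScheme <- function(g, landmarkPath) {
  stopifnot(is(g, "TransitionGraph"))
  if (!is.matrix(landmarkPath))
    landmarkPath <- parseState(landmarkPath)
  if (nrow(landmarkPath) > 1L && any(diff(landmarkPath) < 0))
    stop("landmark path must be coordinate-wise non-decreasing")
  states <- parseState(g@nodes$state)
  compliant <- logical(nrow(states))
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    for (k in seq_len(max(nrow(landmarkPath) - 1L, 1L))) {
      lo <- pmin(landmarkPath[k, ],
                 landmarkPath[min(k + 1L, nrow(landmarkPath)), ])
      hi <- pmax(landmarkPath[k, ],
                 landmarkPath[min(k + 1L, nrow(landmarkPath)), ])
      if (all(s >= lo & s <= hi)) { compliant[i] <- TRUE; break }
    }
  }
  g@scheme <- data.frame(state = g@nodes$state,
                         scheme_compliant = compliant, row.names = NULL)
  g
}

#' Fraction of observations in off-scheme states
#'
#' @param g a [TransitionGraph-class] processed by [flagOffScheme()].
#' @return Numeric scalar: observation-weighted fraction of non-compliant
#'   states.
#' @export
offSchemeFraction <- function(g) {
  stopifnot(is(g, "TransitionGraph"))
  if (!nrow(g@scheme)) stop("apply flagOffScheme() first")
  bad <- !g@scheme$scheme_compliant
  total <- sum(g@nodes$count)
  if (!total) return(0)
  sum(g@nodes$count[bad]) / total
}

#' Convert a transition graph to igraph
#'
#' @param g a [TransitionGraph-class].
#' @return An igraph directed graph with node attributes `count` (and
#'   `scheme_compliant` when computed) and edge attribute `count`.
#' @export
asIgraph <- function(g) {
  stopifnot(is(g, "TransitionGraph"))
  vertices <- g@nodes
  colnames(vertices)[1L] <- "name"
  if (nrow(g@scheme))
    vertices$scheme_compliant <- g@scheme$scheme_compliant[
      match(vertices$name, g@scheme$state)]
  igraph::graph_from_data_frame(g@edges, directed = TRUE,
                                vertices = vertices)
}

#' Export a transition graph
#'
#' Writes the edge list as CSV and, optionally, the full graph as GraphML
#' for external viewers.
#'
#' @param g a [TransitionGraph-class].
#' @param edgeCsvPath path for the edge-list CSV.
#' @param graphmlPath optional path for a GraphML export.
#' @return Invisibly, the paths written.
#' @export
writeTransitionGraph <- function(g, edgeCsvPath, graphmlPath = NULL) {
  stopifnot(is(g, "TransitionGraph"))
  utils::write.csv(g@edges, edgeCsvPath, row.names = FALSE,
                   fileEncoding = "UTF-8")
  written <- edgeCsvPath
  if (!is.null(graphmlPath)) {
    igraph::write_graph(asIgraph(g), graphmlPath, format = "graphml")
    written <- c(written, graphmlPath)
  }
  invisible(written)
}
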