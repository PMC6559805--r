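#' Construct a parameter ontology
#'
#' @param parameters character vector of parameter names in fixed order;
#'   the order defines the positions of the dash tuple notation.
#' @param nStates integer vector of per-parameter state counts.
#' @param genotype free-text genotype label.
#' @return A [ParameterOntology-class].
#' @examples
#' ParameterOntology(c("cell_shape", "chromatin"), c(6, 8), "toy")
#' @export
ParameterOntology <- function(parameters, nStates, genotype = "unspecified") {
  new("ParameterOntology",
      parameters = as.character(parameters),
      nStates = as.integer(nStates),
      genotype = as.character(genotype))
}

#' Default wild-type ontology
#'
#' Five parameters in tuple order: cell shape (6 states, rectangular to
#' tetrad), microtubule array (15 states, even cytoplasmic distribution to
#' tetrad), nucleus position (7), nucleolus position (4) and chromatin/REC8
#' pattern (8).
#'
#' @return A [ParameterOntology-class].
#' @export
wtOntology <- function() {
  ParameterOntology(
    parameters = c("cell_shape", "mt_array", "nucleus_position",
                   "nucleolus_position", "chromatin"),
    nStates = c(6L, 15L, 7L, 4L, 8L),
    genotype = "WT")
}

#' Default tam mutant ontology
#'
#' Same five parameters as [wtOntology()]. The mutant exits meiosis after
#' the first division, so cell-shape and nucleus states specific to meiosis
#' II never occur, while the microtubule array gains an ectopic
#' spindle/phragmoplast-like configuration; state ranges are kept as upper
#' bounds so that any annotated value can be represented.
#'
#' @return A [ParameterOntology-class].
#' @export
tamOntology <- function() {
  ParameterOntology(
    parameters = c("cell_shape", "mt_array", "nucleus_position",
                   "nucleolus_position", "chromatin"),
    nStates = c(6L, 16L, 7L, 4L, 8L),
    genotype = "tam")
}

#' Number of possible complete cellular states
#'
#' Product of the per-parameter state counts; for the wild-type ontology
#' (6, 15, 7, 4, 8) this is 20,160 possible states.
#'
#' @param ontology a [ParameterOntology-class].
#' @return A numeric scalar.
#' @examples
#' stateSpaceSize(wtOntology())
#' @export
stateSpaceSize <- function(ontology) {
  stopifnot(is(ontology, "ParameterOntology"))
  prod(as.numeric(ontology@nStates))
}

#' Dash notation for cellular states
#'
#' `formatState()` turns an integer state tuple (possibly with `NA`) into
#' the dash notation `"a-b-c-d-e"` (missing entries printed as `"n"`);
#' `parseState()` inverts it.
#'
#' @param state integer vector (one entry per parameter) or, for
#'   `formatState`, a matrix with one row per state.
#' @param x a character vector of dash-notation states.
#' @return `formatState`: character; `parseState`: an integer matrix with
#'   one row per input string.
#' @examples
#' formatState(c(2, 2, 2, 3, 3))
#' parseState("2-2-2-3-3")
#' @export
formatState <- function(state) {
  if (is.matrix(state)) {
    apply(state, 1L, function(s)
      paste(ifelse(is.na(s), "n", as.character(s)), collapse = "-"))
  } else {
    paste(ifelse(is.na(state), "n", as.character(state)), collapse = "-")
  }
}

#' @rdname formatState
#' @export
parseState <- function(x) {
  parts <- strsplit(as.character(x), "-", fixed = TRUE)
  n <- lengths(parts)
  if (length(unique(n)) > 1L)
    stop("states must all have the same number of parameters")
  out <- matrix(NA_integer_, nrow = length(parts), ncol = n[1L])
  for (i in seq_along(parts)) {
    v <- parts[[i]]
    out[i, ] <- ifelse(v == "n", NA_integer_, suppressWarnings(as.integer(v)))
  }
  rownames(out) <- as.character(x)
  out
}

#' @describeIn ParameterOntology-class parameter names, in order.
#' @param x,object a `ParameterOntology`.
#' @export
setMethod("names", "ParameterOntology", function(x) x@parameters)

#' Accessors for ontology slots
#'
#' @param object a [ParameterOntology-class] or an object carrying one.
#' @return `parameterNames()`: character; `parameterStates()`: named
#'   integer vector; `genotypeLabel()`: character scalar.
#' @export
setGeneric("parameterNames", function(object)
  standardGeneric("parameterNames"))

#' @rdname parameterNames
#' @export
setMethod("parameterNames", "ParameterOntology", function(object)
  object@parameters)

#' @rdname parameterNames
#' @export
setGeneric("parameterStates", function(object)
  standardGeneric("parameterStates"))

#' @rdname parameterNames
#' @export
setMethod("parameterStates", "ParameterOntology", function(object)
  stats::setNames(object@nStates, object@parameters))

#' @rdname parameterNames
#' @export
setGeneric("genotypeLabel", function(object)
  standardGeneric("genotypeLabel"))

#' @rdname parameterNames
#' @export
setMethod("genotypeLabel", "ParameterOntology", function(object)
  object@genotype)

setMethod("show", "ParameterOntology", function(object) {
  cat("ParameterOntology (", object@genotype, "): ",
      length(object@parameters), " parameters, ",
      format(stateSpaceSize(object), big.mark = ","),
      " possible states\n", sep = "")
  for (i in seq_along(object@parameters))
    cat("  ", i, ". ", object@parameters[i], ": 1..",
        object@nStates[i], "\n", sep = "")
})
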