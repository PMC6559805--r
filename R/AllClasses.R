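#' @import methods
NULL

#' ParameterOntology: the ordered state ranges of the morphological parameters
#'
#' An ontology fixes the parameter order (which defines the tuple notation:
#' position 1 = cell shape, ..., position 5 = chromatin for the default
#' wild-type ontology) and the number of ordered states each parameter can
#' adopt. States are integers \code{1..nStates[p]}; a missing annotation is
#' \code{NA} internally and \code{"n"} in the CSV dialect.
#'
#' @slot parameters character vector of parameter names, in fixed order.
#' @slot nStates integer vector, per-parameter count of ordered states.
#' @slot genotype free-text genotype label.
#'
#' @seealso [wtOntology()], [tamOntology()], [stateSpaceSize()]
#' @export
setClass("ParameterOntology",
  representation(
    parameters = "character",
    nStates = "integer",
    genotype = "character"
  )
)

setValidity("ParameterOntology", function(object) {
  msg <- character()
  if (length(object@parameters) < 1L)
    msg <- c(msg, "ontology needs at least one parameter")
  if (anyDuplicated(object@parameters))
    msg <- c(msg, "parameter names must be unique")
  if (length(object@nStates) != length(object@parameters))
    msg <- c(msg, "nStates must have one entry per parameter")
  if (any(is.na(object@nStates)) || any(object@nStates < 1L))
    msg <- c(msg, "every parameter needs nStates >= 1")
  if (length(object@genotype) != 1L)
    msg <- c(msg, "genotype must be a single string")
  if (length(msg)) msg else TRUE
})

#' MeiosisAnnotations: per-cell trajectories of cellular-state observations
#'
#' Long-format container: one row per cell per time point, with the id
#' columns \code{genotype}, \code{anther_id}, \code{cell_id},
#' \code{time_min} followed by one integer column per ontology parameter
#' (\code{NA} = unannotated). Rows are kept sorted by
#' (genotype, anther_id, cell_id, time_min); within a trajectory times
#' strictly increase.
#'
#' @slot ontology a [ParameterOntology-class].
#' @slot data the observation data.frame described above.
#'
#' @seealso [readAnnotations()], [filterComplete()], [resampleAnnotations()]
#' @export
setClass("MeiosisAnnotations",
  representation(
    ontology = "ParameterOntology",
    data = "data.frame"
  )
)

ID_COLUMNS <- c("genotype", "anther_id", "cell_id", "time_min")

setValidity("MeiosisAnnotations", function(object) {
  msg <- character()
  d <- object@data
  params <- object@ontology@parameters
  need <- c(ID_COLUMNS, params)
  if (!all(need %in% colnames(d)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(d)), collapse = ", ")))
  if (nrow(d)) {
    if (!is.numeric(d$time_min) || any(is.na(d$time_min)) ||
        any(d$time_min < 0))
      msg <- c(msg, "time_min must be non-negative and non-missing")
    for (p in params) {
      v <- d[[p]]
      k <- object@ontology@nStates[match(p, params)]
      bad <- which(!is.na(v) & (v < 1L | v > k | v != floor(v)))
      if (length(bad))
        msg <- c(msg, sprintf(
          "parameter '%s' outside 1..%d at row(s) %s", p, k,
          paste(utils::head(bad, 5L), collapse = ", ")))
    }
    ord <- order(d$genotype, d$anther_id, d$cell_id, d$time_min)
    if (!identical(ord, seq_len(nrow(d))))
      msg <- c(msg, "rows must be sorted by trajectory and time")
    key <- paste(d$genotype, d$anther_id, d$cell_id, sep = "\r")
    dup <- tapply(d$time_min, key, function(t) anyDuplicated(t) > 0L)
    if (any(dup))
      msg <- c(msg, "duplicate (cell, time) observation(s)")
  }
  if (length(msg)) msg else TRUE
})

#' StateCountTable: observed complete cellular states and their counts
#'
#' @slot states integer matrix, one row per distinct observed complete
#'   cellular state, one column per ontology parameter; rownames are the
#'   dash notation (e.g. \code{"2-2-2-3-3"}).
#' @slot counts integer vector of observation counts, parallel to the rows.
#' @slot total total number of complete observations (equals sum of counts).
#' @slot ontology the [ParameterOntology-class] the states live in.
#' @export
setClass("StateCountTable",
  representation(
    states = "matrix",
    counts = "integer",
    total = "integer",
    ontology = "ParameterOntology"
  )
)

setValidity("StateCountTable", function(object) {
  msg <- character()
  if (nrow(object@states) != length(object@counts))
    msg <- c(msg, "one count per state row required")
  if (length(object@counts) && any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) != object@total)
    msg <- c(msg, "counts must sum to the total")
  if (ncol(object@states) != length(object@ontology@parameters))
    msg <- c(msg, "state tuples must match ontology arity")
  if (nrow(object@states) && anyNA(object@states))
    msg <- c(msg, "only complete states may appear")
  if (length(msg)) msg else TRUE
})

#' LandmarkScores: neighboring scores and landmark calls per observed state
#'
#' The score of an observed state s is
#' \deqn{(count(s) - mean(count(N_s))) / sd_{pop}(count(N_s))}
#' over the set \eqn{N_s} of *observed* neighbors of s, with the population
#' (divide-by-n) standard deviation. Conventions where the formula is
#' undefined: zero spread with count above the mean gives +Inf ("dominant"),
#' zero spread with count equal to the mean gives 0, a state with no
#' observed neighbor gives +Inf with basis \code{"no_neighbors"}. A state is
#' a landmark iff its score strictly exceeds the threshold (default 1);
#' the +Inf sentinel exceeds any threshold.
#'
#' @slot table data.frame with columns \code{state}, \code{count},
#'   \code{frequency_pct}, \code{n_neighbors}, \code{neighbor_mean},
#'   \code{neighbor_sd}, \code{score}, \code{score_basis}
#'   (\code{"finite"}, \code{"zero_spread"} or \code{"no_neighbors"}) and
#'   \code{is_landmark}.
#' @slot threshold the landmark threshold used (strict comparison).
#' @slot ontology the [ParameterOntology-class].
#' @export
setClass("LandmarkScores",
  representation(
    table = "data.frame",
    threshold = "numeric",
    ontology = "ParameterOntology"
  )
)

#' CoocMatrix: pairwise parameter-state co-occurrence
#'
#' Raw counts: cell (i, j) counts retained observations with row parameter
#' in state i and column parameter in state j (both annotated). Column
#' totals count every retained observation whose column parameter is in
#' state j, *including* those where the row (partner) parameter is
#' unannotated; normalisation divides by these totals, which is why
#' normalised columns sum to less than 1 whenever partner-missing rows
#' exist.
#'
#' @slot rowParam,colParam the two parameter names.
#' @slot counts integer matrix of raw pair counts (rows = row-parameter
#'   states, columns = column-parameter states).
#' @slot colTotals integer vector of per-column totals incl. partner-missing.
#' @slot normalized numeric matrix \code{counts / colTotals} (0x0 until
#'   [normalizeCooccurrence()] is applied).
#' @slot emptyColumns logical flag per column: TRUE where the total is zero
#'   (normalised entries reported as 0).
#' @slot intervalMin the resampling interval applied before counting.
#' @export
setClass("CoocMatrix",
  representation(
    rowParam = "character",
    colParam = "character",
    counts = "matrix",
    colTotals = "integer",
    normalized = "matrix",
    emptyColumns = "logical",
    intervalMin = "numeric"
  )
)

#' BootstrapScores: bootstrap stability of neighboring scores
#'
#' @slot table per-state data.frame: occurrences across replicates, finite
#'   score mean/sd/quantiles, count of +Inf sentinel scores, and the
#'   fraction of replicates (among those where the state occurs) in which
#'   the state is called a landmark.
#' @slot reps,factor,seed,threshold the resampling settings.
#' @slot quantiles the probabilities summarised.
#' @export
setClass("BootstrapScores",
  representation(
    table = "data.frame",
    reps = "integer",
    factor = "numeric",
    seed = "integer",
    threshold = "numeric",
    quantiles = "numeric"
  )
)

#' TransitionGraph: observed directed network of cellular-state changes
#'
#' Edges are direct transitions: consecutive complete observations of one
#' trajectory with different states. Pairs separated by any incomplete
#' observation contribute no edge (a bridged edge could span several real
#' transitions), and state persistence is not an edge.
#'
#' @slot nodes data.frame: \code{state}, \code{count} (observation count).
#' @slot edges data.frame: \code{from}, \code{to}, \code{count}.
#' @slot scheme data.frame of per-node scheme-compliance flags (empty until
#'   [flagOffScheme()] is applied).
#' @slot ontology the [ParameterOntology-class].
#' @export
setClass("TransitionGraph",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    scheme = "data.frame",
    ontology = "ParameterOntology"
  )
)

setValidity("TransitionGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "no self-edges allowed")
    if (any(e$count <= 0L)) msg <- c(msg, "edge counts must be positive")
    if (!all(c(e$from, e$to) %in% object@nodes$state))
      msg <- c(msg, "edge endpoints must be observed states")
  }
  if (length(msg)) msg else TRUE
})

#' LandmarkSeries: landmark-labelled trajectories
#'
#' One row per cell per time point with a \code{landmark} column taking a
#' landmark label, \code{"TRANSITION"} (complete state that is not a
#' landmark) or \code{"MISSING"} (incomplete observation).
#'
#' @slot data data.frame: genotype, anther_id, cell_id, time_min, landmark.
#' @slot landmarkOrder the ordered landmark alphabet.
#' @export
setClass("LandmarkSeries",
  representation(
    data = "data.frame",
    landmarkOrder = "character"
  )
)

setValidity("LandmarkSeries", function(object) {
  d <- object@data
  need <- c(ID_COLUMNS, "landmark")
  if (!all(need %in% colnames(d)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(d)), collapse = ", ")))
  ok <- d$landmark %in% c(object@landmarkOrder, "TRANSITION", "MISSING")
  if (!all(ok))
    return("labels must come from the declared landmark alphabet")
  TRUE
})

#' GeneratorConfig: settings for the synthetic trajectory generator
#'
#' The generator emulates the study design: movies of whole anthers, each
#' with its own frame interval and time window capturing a subsection of
#' meiosis; cells progress through an ordered landmark path with
#' gamma-distributed dwell times, and between consecutive landmarks the
#' differing parameters change one unit step at a time in a uniformly
#' random interleaving, each intermediate state held for a short
#' exponential dwell. Missingness is applied per frame (whole row) and per
#' parameter.
#'
#' @slot ontology a [ParameterOntology-class].
#' @slot landmarkPaths list of integer matrices (rows = ordered landmark
#'   tuples incl. the START row, rownames = labels); coordinate-wise
#'   non-decreasing.
#' @slot routeWeights mixture weights over the paths (sum to 1).
#' @slot dwellMeanMin list of numeric vectors: per path, the mean dwell of
#'   each landmark row, minutes.
#' @slot dwellCV coefficient of variation of the gamma dwell law.
#' @slot transitionDwellMin mean (exponential) dwell of each intermediate
#'   transition state, minutes.
#' @slot nAnthers number of anthers (movies).
#' @slot cellsPerAnther Poisson mean of cells per anther (min 1).
#' @slot frameIntervalChoices,frameIntervalWeights per-movie frame interval
#'   distribution, minutes.
#' @slot windowLengthRange min/max movie length, minutes (uniform).
#' @slot windowStartRange min/max movie start relative to meiosis onset,
#'   minutes (uniform; negative = movie starts before meiosis).
#' @slot cellStartSD per-cell desynchronisation (normal sd, minutes).
#' @slot pParamMissing,pFrameMissing missingness probabilities.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorConfig",
  representation(
    ontology = "ParameterOntology",
    landmarkPaths = "list",
    routeWeights = "numeric",
    dwellMeanMin = "list",
    dwellCV = "numeric",
    transitionDwellMin = "numeric",
    nAnthers = "integer",
    cellsPerAnther = "numeric",
    frameIntervalChoices = "numeric",
    frameIntervalWeights = "numeric",
    windowLengthRange = "numeric",
    windowStartRange = "numeric",
    cellStartSD = "numeric",
    pParamMissing = "numeric",
    pFrameMissing = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  np <- length(object@ontology@parameters)
  if (!length(object@landmarkPaths))
    msg <- c(msg, "at least one landmark path required")
  for (i in seq_along(object@landmarkPaths)) {
    p <- object@landmarkPaths[[i]]
    if (!is.matrix(p) || ncol(p) != np) {
      msg <- c(msg, sprintf("path %d must be a matrix with %d columns", i, np))
      next
    }
    if (nrow(p) > 1L && any(diff(p) < 0))
      msg <- c(msg, sprintf(
        "path %d must be coordinate-wise non-decreasing", i))
    if (any(p < 1L) || any(t(p) > object@ontology@nStates))
      msg <- c(msg, sprintf("path %d leaves the ontology ranges", i))
    if (length(object@dwellMeanMin) >= i &&
        length(object@dwellMeanMin[[i]]) != nrow(p))
      msg <- c(msg, sprintf("path %d needs one dwell mean per landmark", i))
  }
  if (length(object@routeWeights) != length(object@landmarkPaths) ||
      abs(sum(object@routeWeights) - 1) > 1e-8 ||
      any(object@routeWeights < 0))
    msg <- c(msg, "route weights must be non-negative and sum to 1")
  if (object@pParamMissing < 0 || object@pParamMissing > 1 ||
      object@pFrameMissing < 0 || object@pFrameMissing > 1)
    msg <- c(msg, "missingness probabilities must lie in [0, 1]")
  if (length(object@frameIntervalChoices) !=
      length(object@frameIntervalWeights))
    msg <- c(msg, "one weight per frame-interval choice required")
  if (length(msg)) msg else TRUE
})

#' PlantedTruth: ground truth emitted alongside a synthetic dataset
#'
#' @slot paths the landmark paths used (as in [GeneratorConfig-class]).
#' @slot dwellMeanMin the per-path per-landmark mean dwells, minutes.
#' @slot cells data.frame: one row per cell with anther/cell ids, route
#'   index, movie window and frame interval, per-cell start offset.
#' @slot schedule data.frame: one row per landmark visit per cell with the
#'   realised onset (absolute meiosis time, minutes) and dwell.
#' @slot frames data.frame: the emitted observations *before* missingness
#'   was applied (same row order as the dataset).
#' @export
setClass("PlantedTruth",
  representation(
    paths = "list",
    dwellMeanMin = "list",
    cells = "data.frame",
    schedule = "data.frame",
    frames = "data.frame"
  )
)
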