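#' Run the full landmark analysis pipeline
#'
#' One-call orchestration: parse (or accept) an annotation dataset,
#' validate it, compute all pairwise co-occurrence matrices, score the
#' observed cellular states and extract landmarks, bootstrap the scores,
#' build the observed transition network, and — when landmark definitions
#' are supplied — extract per-landmark durations. All tables are written
#' to `outputDir` together with a machine-readable JSON manifest (inputs,
#' parameters, seed, package version and the conventions in force), so
#' every number in the bundle is reproducible from the manifest alone.
#'
#' @param input a [MeiosisAnnotations-class], or the path to an annotation
#'   CSV (then `ontology` is required).
#' @param outputDir output directory (created; must not contain the input
#'   file).
#' @param ontology a [ParameterOntology-class]; required when `input` is a
#'   path.
#' @param resampleIntervalMin co-occurrence resampling interval (minutes).
#' @param threshold landmark score threshold (strict).
#' @param bootstrapReps,bootstrapFactor bootstrap settings; set
#'   `bootstrapReps = 0` to skip the bootstrap stage.
#' @param seed integer seed for the bootstrap.
#' @param landmarkDefs optional named vector (dash tuple -> label) enabling
#'   the duration stage.
#' @param landmarkPath optional landmark-path matrix for off-scheme
#'   flagging of the transition network.
#' @param coocPairs "all" for every ordered parameter pair, or a list of
#'   c(rowParam, colParam) pairs.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the computed objects (`annotations`,
#'   `scores`, `cooccurrence`, `bootstrap`, `graph`, `durations`,
#'   `manifest`).
#' @export
runFullAnalysis <- function(input, outputDir,
                            ontology = NULL,
                            resampleIntervalMin = 15,
                            threshold = 1,
                            bootstrapReps = 1000,
                            bootstrapFactor = 1.5,
                            seed = 1L,
                            landmarkDefs = NULL,
                            landmarkPath = NULL,
                            coocPairs = "all",
                            verbose = FALSE) {
  say <- function(...) if (verbose) message("[", format(Sys.time(),
                                            "%H:%M:%S"), "] ", ...)
  inputPath <- NA_character_
  if (is.character(input)) {
    if (!file.exists(input))
      stop("stage input: annotation file not found: ", input)
    if (is.null(ontology))
      stop("stage input: an ontology is required to parse a CSV input")
    inputPath <- normalizePath(input)
    say("parsing ", input)
    ds <- readAnnotations(input, ontology)
  } else {
    stopifnot(is(input, "MeiosisAnnotations"))
    ds <- input
  }
  validObject(ds)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  outputDir <- normalizePath(outputDir)
  if (!is.na(inputPath) && dirname(inputPath) == outputDir)
    stop("outputs must not overwrite inputs: choose a different outputDir")

  params <- ds@ontology@parameters
  miss <- missingnessSummary(ds)

  say("co-occurrence")
  if (identical(coocPairs, "all")) {
    coocPairs <- list()
    for (i in seq_along(params))
      for (j in seq_along(params))
        if (i != j) coocPairs[[length(coocPairs) + 1L]] <-
            c(params[i], params[j])
  }
  cooc <- lapply(coocPairs, function(pair) {
    m <- normalizeCooccurrence(
      cooccurrenceCounts(ds, pair[1L], pair[2L], resampleIntervalMin))
    base <- file.path(outputDir,
                      paste0("cooc_", pair[1L], "_vs_", pair[2L]))
    writeCooccurrence(m, paste0(base, "_raw.csv"),
                      paste0(base, "_normalized.csv"))
    m
  })

  say("scoring")
  lms <- extractLandmarks(ds, threshold = threshold)
  writeScores(lms, file.path(outputDir, "state_scores.csv"))

  boot <- NULL
  if (bootstrapReps > 0) {
    say("bootstrap (", bootstrapReps, " reps)")
    boot <- bootstrapScores(ds, factor = bootstrapFactor,
                            reps = bootstrapReps, seed = seed,
                            threshold = threshold)
    writeBootstrap(boot, file.path(outputDir, "bootstrap_scores.csv"))
  }

  say("transition network")
  graph <- transitionCounts(ds)
  if (!is.null(landmarkPath)) graph <- flagOffScheme(graph, landmarkPath)
  writeTransitionGraph(graph,
                       file.path(outputDir, "transitions_edges.csv"),
                       file.path(outputDir, "transitions.graphml"))

  durations <- NULL
  durationSummary <- NULL
  if (!is.null(landmarkDefs)) {
    say("durations")
    series <- assignLandmarks(ds, landmarkDefs)
    durations <- extractDurations(series)
    durationSummary <- summarizeDurations(durations,
                                          unname(landmarkDefs))
    utils::write.csv(durations,
                     file.path(outputDir, "duration_records.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(durationSummary,
                     file.path(outputDir, "duration_summary.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }

  manifest <- list(
    package = "meiolandmark",
    version = as.character(utils::packageVersion("meiolandmark")),
    input = if (is.na(inputPath)) "in-memory MeiosisAnnotations"
            else inputPath,
    genotype = ds@ontology@genotype,
    parameters = as.list(parameterStates(ds@ontology)),
    n_observations = nObservations(ds),
    n_cells = nCells(ds),
    missingness = miss,
    settings = list(resample_interval_min = resampleIntervalMin,
                    score_threshold = threshold,
                    bootstrap_reps = bootstrapReps,
                    bootstrap_factor = bootstrapFactor,
                    seed = seed),
    conventions = list(
      std = "population (divide-by-n) standard deviation",
      landmark_rule = "score strictly greater than threshold; +Inf sentinel exceeds any threshold",
      resampling = "nearest-frame subsampling on a grid anchored at each trajectory's first time; ties to the earlier frame",
      cooccurrence_denominator = "column totals include partner-missing observations",
      bootstrap_unit = "individual observation row",
      transition_gaps = "incomplete observations break adjacency",
      duration_rule = "onset-to-onset; transitions folded into the preceding landmark; unbridged missing gaps censor both flanking occurrences",
      off_scheme = "interval interpretation: compliant iff within the closed per-parameter interval of some consecutive landmark pair"),
    results = list(
      n_observed_states = nrow(scores(lms)),
      n_landmarks = sum(scores(lms)$is_landmark),
      landmarks = landmarkStates(lms),
      off_scheme_fraction = if (!is.null(landmarkPath))
        offSchemeFraction(graph) else NULL,
      n_duration_records = if (!is.null(durations))
        sum(durations$complete) else NULL))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done: ", outputDir)
  invisible(list(annotations = ds, scores = lms, cooccurrence = cooc,
                 bootstrap = boot, graph = graph, durations = durations,
                 durationSummary = durationSummary, manifest = manifest))
}
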