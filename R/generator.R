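#' Default wild-type landmark path
#'
#' An ordered set of 12 tuples — the pre-meiotic START state 1-1-1-1-1
#' followed by 11 landmark tuples ending at the tetrad — that is
#' coordinate-wise non-decreasing (parameters only ever advance). Only the
#' zygotene landmark A3 (2-2-2-3-3) and START are fixed by published
#' tuples; the remaining rows are synthetic stand-ins designed so that no
#' two consecutive landmarks are neighbors of each other (at least three
#' differing parameters, or a single parameter advancing by two), which
#' keeps planted landmarks identifiable by the neighboring score.
#'
#' @return Integer matrix, rows named START, A1..A11, columns the
#'   wild-type parameters.
#' @export
wtLandmarkPath <- function() {
  path <- rbind(
    START = c(1L, 1L, 1L, 1L, 1L),
    A1 = c(1L, 1L, 1L, 1L, 3L),
    A2 = c(1L, 1L, 1L, 3L, 3L),
    A3 = c(2L, 2L, 2L, 3L, 3L),
    A4 = c(3L, 4L, 2L, 3L, 4L),
    A5 = c(4L, 5L, 3L, 3L, 4L),
    A6 = c(4L, 6L, 3L, 3L, 6L),
    A7 = c(4L, 7L, 3L, 4L, 7L),
    A8 = c(4L, 9L, 4L, 4L, 8L),
    A9 = c(4L, 11L, 5L, 4L, 8L),
    A10 = c(5L, 13L, 6L, 4L, 8L),
    A11 = c(6L, 15L, 7L, 4L, 8L))
  colnames(path) <- wtOntology()@parameters
  path
}

# wild-type dwell means in minutes (START padding + published timeline:
# A1 8.5 h; A2 1.5 h; zygotene 6 h and pachytene 9.5 h split within pairs;
# A7 3 h; A8, A9 1 h each; meiosis II 4 h split within the pair)
wtDwellMeans <- function() {
  c(START = 120, A1 = 510, A2 = 90, A3 = 180, A4 = 180, A5 = 285,
    A6 = 285, A7 = 180, A8 = 60, A9 = 60, A10 = 120, A11 = 120)
}

#' Default tam-mutant landmark paths
#'
#' Two progression routes through a shared trunk: population A develops
#' ectopic spindle/phragmoplast-like microtubule structures and passes
#' t6 -> t7 -> t9 (skipping t8), population B passes t6 -> t8 -> t9
#' (skipping t7). Meiosis II landmarks never occur; cells exit after the
#' first division. Tuples are synthetic stand-ins built with the same
#' spacing rules as [wtLandmarkPath()].
#'
#' @return List of two integer matrices (routes A and B).
#' @export
tamLandmarkPaths <- function() {
  trunk <- rbind(
    START = c(1L, 1L, 1L, 1L, 1L),
    t1 = c(1L, 1L, 1L, 1L, 3L),
    t2 = c(1L, 1L, 1L, 3L, 3L),
    t3 = c(3L, 4L, 2L, 3L, 4L),
    t4 = c(4L, 5L, 3L, 3L, 4L),
    t5 = c(4L, 6L, 3L, 3L, 6L),
    t6 = c(4L, 7L, 3L, 4L, 7L))
  tail <- rbind(
    t9 = c(4L, 11L, 4L, 4L, 8L),
    t10 = c(4L, 13L, 5L, 4L, 8L),
    t11 = c(4L, 15L, 6L, 4L, 8L))
  routeA <- rbind(trunk, t7 = c(4L, 9L, 3L, 4L, 7L), tail)
  routeB <- rbind(trunk, t8 = c(4L, 8L, 4L, 4L, 8L), tail)
  params <- tamOntology()@parameters
  colnames(routeA) <- params
  colnames(routeB) <- params
  list(A = routeA, B = routeB)
}

tamDwellMeans <- function() {
  shared <- c(START = 120, t1 = 510, t2 = 360, t3 = 180, t4 = 285,
              t5 = 300, t6 = 360)
  tail <- c(t9 = 120, t10 = 180, t11 = 180)
  list(A = c(shared, t7 = 240, tail),
       B = c(shared, t8 = 240, tail))
}

#' Generator configuration with wild-type defaults
#'
#' Defaults reproduce the structure of the study dataset: 169 cells spread
#' over 35 anthers, per-movie frame intervals of
#' 3–15 min (weighted toward 10 and 15 min so that cells carry on the
#' order of a hundred frames), movie windows of 10–30 h capturing
#' subsections of the ~37 h timeline, and missingness rates that give
#' ~42% of rows at least one unannotated parameter and ~32% fully
#' unannotated rows.
#'
#' @param ... named overrides for any [GeneratorConfig-class] slot.
#' @param seed integer RNG seed (default 1).
#' @return A validated [GeneratorConfig-class].
#' @examples
#' cfg <- wtGeneratorConfig(seed = 7, nAnthers = 4)
#' @export
wtGeneratorConfig <- function(..., seed = 1L) {
  defaults <- list(
    ontology = wtOntology(),
    landmarkPaths = list(WT = wtLandmarkPath()),
    routeWeights = 1,
    dwellMeanMin = list(WT = wtDwellMeans()),
    dwellCV = 0.3,
    transitionDwellMin = 2,
    nAnthers = 35L,
    cellsPerAnther = 169 / 35,
    frameIntervalChoices = c(3, 5, 10, 15),
    frameIntervalWeights = c(0.05, 0.15, 0.4, 0.4),
    windowLengthRange = c(600, 1800),
    windowStartRange = c(-300, 1650),
    cellStartSD = 30,
    pParamMissing = 0.033,
    pFrameMissing = 0.32,
    seed = as.integer(seed))
  args <- utils::modifyList(defaults, list(...))
  args$nAnthers <- as.integer(args$nAnthers)
  args$seed <- as.integer(args$seed)
  do.call(new, c(list(Class = "GeneratorConfig"), args))
}

#' Generator configuration with tam-mutant defaults
#'
#' Two-route mixture: population A (weight 0.458) via the ectopic-MT
#' landmark t7, population B (weight 0.542) via t8; extended leptotene and
#' late prophase dwells; no meiosis II landmarks.
#'
#' @param ... named overrides for any [GeneratorConfig-class] slot.
#' @param seed integer RNG seed (default 1).
#' @return A validated [GeneratorConfig-class].
#' @export
tamGeneratorConfig <- function(..., seed = 1L) {
  paths <- tamLandmarkPaths()
  defaults <- list(
    ontology = tamOntology(),
    landmarkPaths = paths,
    routeWeights = c(A = 0.458, B = 0.542),
    dwellMeanMin = tamDwellMeans(),
    dwellCV = 0.3,
    transitionDwellMin = 2,
    nAnthers = 19L,
    cellsPerAnther = 62 / 19,
    frameIntervalChoices = c(3, 5, 10, 15),
    frameIntervalWeights = c(0.05, 0.15, 0.4, 0.4),
    windowLengthRange = c(600, 1800),
    windowStartRange = c(-300, 1900),
    cellStartSD = 30,
    pParamMissing = 0.033,
    pFrameMissing = 0.3,
    seed = as.integer(seed))
  args <- utils::modifyList(defaults, list(...))
  args$nAnthers <- as.integer(args$nAnthers)
  args$seed <- as.integer(args$seed)
  do.call(new, c(list(Class = "GeneratorConfig"), args))
}

# piecewise-constant state timeline of one cell (cell-local clock, t = 0 at
# meiosis onset); intermediate transition states are a uniformly random
# interleaving of single-step parameter changes
buildCellTimeline <- function(path, dwells, transMean, minDwell) {
  nP <- ncol(path)
  segs <- list(); starts <- numeric(); t <- 0
  for (k in seq_len(nrow(path))) {
    segs[[length(segs) + 1L]] <- path[k, ]
    starts <- c(starts, t)
    t <- t + max(dwells[k], minDwell)
    if (k < nrow(path)) {
      delta <- path[k + 1L, ] - path[k, ]
      steps <- rep(seq_len(nP), delta)
      if (length(steps) > 1L) {
        steps <- steps[sample.int(length(steps))]
        cur <- path[k, ]
        for (j in seq_len(length(steps) - 1L)) {
          cur[steps[j]] <- cur[steps[j]] + 1L
          segs[[length(segs) + 1L]] <- cur
          starts <- c(starts, t)
          t <- t + stats::rexp(1L, rate = 1 / transMean)
        }
      }
    }
  }
  list(states = do.call(rbind, segs), starts = starts, end = t)
}

timelineStateAt <- function(timeline, u) {
  # before meiosis: first (START) state; after the end: last state persists
  i <- findInterval(u, timeline$starts)
  i[i < 1L] <- 1L
  i[i > nrow(timeline$states)] <- nrow(timeline$states)
  timeline$states[i, , drop = FALSE]
}

#' Generate a synthetic annotation dataset with planted ground truth
#'
#' Each anther is one movie: it draws a frame interval and a time window;
#' its cells draw a route, per-landmark gamma dwell times (CV
#' `dwellCV`, truncated at one frame) and a small start offset, then
#' progress through the landmark path with uniformly random single-step
#' interleavings between landmarks. The continuous-time path is sampled at
#' the movie's frame grid clipped to the window; missingness is applied
#' per frame and per parameter. Identical seeds give identical output.
#'
#' @param config a [GeneratorConfig-class].
#' @return A list with elements `annotations` (a
#'   [MeiosisAnnotations-class]) and `truth` (a [PlantedTruth-class]).
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  set.seed(config@seed)
  ont <- config@ontology
  params <- ont@parameters
  nP <- length(params)
  shape <- 1 / config@dwellCV^2

  # fixed total cell count (anther sizes as even as possible), mirroring a
  # study design with a known number of annotated cells per genotype
  totalCells <- max(config@nAnthers,
                    round(config@nAnthers * config@cellsPerAnther))
  baseCells <- totalCells %/% config@nAnthers
  extraCells <- totalCells %% config@nAnthers

  rows <- list(); cellRows <- list(); schedRows <- list()
  for (a in seq_len(config@nAnthers)) {
    antherId <- sprintf("a%02d", a)
    interval <- sample(config@frameIntervalChoices, 1L,
                       prob = config@frameIntervalWeights)
    wlen <- stats::runif(1L, config@windowLengthRange[1L],
                         config@windowLengthRange[2L])
    wstart <- stats::runif(1L, config@windowStartRange[1L],
                           config@windowStartRange[2L])
    frameTimes <- seq(0, wlen, by = interval)
    nCellsA <- baseCells + as.integer(a <= extraCells)
    for (ci in seq_len(nCellsA)) {
      cellId <- sprintf("c%02d", ci)
      route <- sample.int(length(config@landmarkPaths), 1L,
                          prob = config@routeWeights)
      path <- config@landmarkPaths[[route]]
      means <- config@dwellMeanMin[[route]]
      dwells <- stats::rgamma(length(means), shape = shape,
                              rate = shape / means)
      offset <- stats::rnorm(1L, 0, config@cellStartSD)
      tl <- buildCellTimeline(path, dwells, config@transitionDwellMin,
                              minDwell = interval)
      st <- timelineStateAt(tl, wstart + frameTimes - offset)
      colnames(st) <- params
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = ont@genotype, anther_id = antherId, cell_id = cellId,
        time_min = frameTimes, st, stringsAsFactors = FALSE)
      cellRows[[length(cellRows) + 1L]] <- data.frame(
        genotype = ont@genotype, anther_id = antherId, cell_id = cellId,
        route = route, frame_interval_min = interval,
        window_start_min = wstart, window_length_min = wlen,
        start_offset_min = offset, stringsAsFactors = FALSE)
      lmStarts <- tl$starts[match(
        formatState(path), formatState(tl$states))]
      schedRows[[length(schedRows) + 1L]] <- data.frame(
        anther_id = antherId, cell_id = cellId,
        landmark = rownames(path),
        onset_min = lmStarts + offset,  # anther (movie-absolute) clock
        dwell_min = pmax(dwells, interval), stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  ord <- order(d$genotype, d$anther_id, d$cell_id, d$time_min)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  truthFrames <- d

  # missingness: whole frames, then independent per-parameter dropout
  n <- nrow(d)
  frameMiss <- stats::runif(n) < config@pFrameMissing
  for (p in params) {
    drop <- frameMiss | (stats::runif(n) < config@pParamMissing)
    d[[p]][drop] <- NA_integer_
  }

  truth <- new("PlantedTruth",
               paths = config@landmarkPaths,
               dwellMeanMin = config@dwellMeanMin,
               cells = {
                 x <- do.call(rbind, cellRows); rownames(x) <- NULL; x
               },
               schedule = {
                 x <- do.call(rbind, schedRows); rownames(x) <- NULL; x
               },
               frames = truthFrames)
  list(annotations = MeiosisAnnotations(d, ont), truth = truth)
}

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth: ", nrow(object@cells), " cells, ",
      length(object@paths), " route(s), ", nrow(object@frames),
      " noiseless frames\n", sep = "")
})

#' Landmark definitions of a planted path
#'
#' Turns a landmark path (or the truth of a generated dataset) into the
#' tuple -> label mapping consumed by [assignLandmarks()]. The START row
#' is not a landmark and is excluded.
#'
#' @param x a [PlantedTruth-class], a [GeneratorConfig-class], or a
#'   landmark path matrix with labelled rows.
#' @param route which route to use when several paths exist (default 1).
#' @return Named character vector: dash tuple -> landmark label.
#' @export
landmarkDefinitions <- function(x, route = 1L) {
  path <- if (is(x, "PlantedTruth")) x@paths[[route]]
          else if (is(x, "GeneratorConfig")) x@landmarkPaths[[route]]
          else x
  stopifnot(is.matrix(path), !is.null(rownames(path)))
  keep <- rownames(path) != "START"
  stats::setNames(rownames(path)[keep],
                  formatState(path[keep, , drop = FALSE]))
}

#' Planted landmark labels across all routes
#'
#' @param truth a [PlantedTruth-class].
#' @return Character vector of unique landmark labels (START excluded),
#'   in path order of the first route they appear on.
#' @export
plantedLandmarkStates <- function(truth) {
  stopifnot(is(truth, "PlantedTruth"))
  out <- character()
  for (p in truth@paths) {
    keep <- rownames(p) != "START"
    tup <- formatState(p[keep, , drop = FALSE])
    out <- c(out, tup[!tup %in% out])
  }
  out
}

#' Write the ground-truth sidecar of a generated dataset
#'
#' JSON file with the planted landmark paths (dash notation), dwell means
#' and per-cell routes — enough to re-derive every planted quantity.
#'
#' @param truth a [PlantedTruth-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "PlantedTruth"))
  payload <- list(
    paths = lapply(truth@paths, function(p)
      stats::setNames(as.list(formatState(p)), rownames(p))),
    dwell_mean_min = lapply(truth@dwellMeanMin, as.list),
    cells = truth@cells,
    schedule = truth@schedule)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
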