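#' Label observations with landmark names
#'
#' Bridges the score table to the duration analysis: each complete
#' observation whose cellular state is a declared landmark receives that
#' landmark's label; other complete observations become
#' \code{"TRANSITION"}; incomplete observations become \code{"MISSING"}.
#'
#' @param ds a [MeiosisAnnotations-class].
#' @param landmarkDefs named character vector mapping dash-notation state
#'   tuples to landmark labels, in landmark order
#'   (e.g. \code{c("2-2-2-3-3" = "A3", ...)}). Each tuple may carry one
#'   label only.
#' @return A [LandmarkSeries-class]; its landmark order is the order of
#'   `landmarkDefs`.
#' @export
assignLandmarks <- function(ds, landmarkDefs) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  if (is.null(names(landmarkDefs)) || any(names(landmarkDefs) == ""))
    stop("landmarkDefs must be a named vector (tuple -> label)")
  if (anyDuplicated(names(landmarkDefs)))
    stop("duplicate labels for one tuple in landmarkDefs")
  if (anyDuplicated(unname(landmarkDefs)))
    stop("each landmark label may be used once")
  keys <- parseState(names(landmarkDefs))  # validates arity & completeness
  if (anyNA(keys)) stop("landmark tuples must be complete states")
  if (ncol(keys) != length(ds@ontology@parameters))
    stop("landmark tuples must match the ontology arity")
  m <- stateMatrix(ds)
  complete <- rowSums(is.na(m)) == 0L
  label <- rep("MISSING", nrow(m))
  obsKeys <- rep(NA_character_, nrow(m))
  obsKeys[complete] <- formatState(m[complete, , drop = FALSE])
  hit <- match(obsKeys, names(landmarkDefs))
  label[complete] <- ifelse(is.na(hit[complete]), "TRANSITION",
                            unname(landmarkDefs)[hit[complete]])
  new("LandmarkSeries",
      data = cbind(ds@data[ID_COLUMNS], landmark = label),
      landmarkOrder = unname(landmarkDefs))
}

#' Read a landmark-labelled trajectory CSV
#'
#' Columns: genotype, anther_id, cell_id, time_min, landmark. Labels other
#' than \code{"TRANSITION"} / \code{"MISSING"} must belong to
#' `landmarkOrder`.
#'
#' @param path path to the CSV file.
#' @param landmarkOrder the ordered landmark alphabet.
#' @return A [LandmarkSeries-class].
#' @export
readLandmarkSeries <- function(path, landmarkOrder) {
  if (!file.exists(path)) stop("landmark series file not found: ", path)
  d <- utils::read.csv(path, colClasses = "character",
                       check.names = FALSE, fileEncoding = "UTF-8")
  need <- c(ID_COLUMNS, "landmark")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  d$time_min <- as.numeric(d$time_min)
  d <- d[order(d$genotype, d$anther_id, d$cell_id, d$time_min), need]
  rownames(d) <- NULL
  new("LandmarkSeries", data = d,
      landmarkOrder = as.character(landmarkOrder))
}

setMethod("show", "LandmarkSeries", function(object) {
  cat("LandmarkSeries: ", nrow(object@data), " labelled frames, ",
      length(unique(trajectoryKey(object@data))), " cells, alphabet ",
      paste(object@landmarkOrder, collapse = " < "), "\n", sep = "")
})

# Per-cell occurrence extraction. Returns a data.frame of landmark
# occurrences with onset times and censoring flags, or NULL when the cell
# must be skipped (landmark regression against the declared order).
cellOccurrences <- function(times, labels, landmarkOrder) {
  n <- length(labels)
  # bridge runs of MISSING flanked by the same landmark
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bridged <- labels
  cut <- logical(n)  # unbridged missing frames act as censoring cuts
  for (j in seq_along(r$values)) {
    if (r$values[j] != "MISSING") next
    prevLab <- if (j > 1L) r$values[j - 1L] else NA_character_
    nextLab <- if (j < length(r$values)) r$values[j + 1L] else NA_character_
    if (!is.na(prevLab) && !is.na(nextLab) && prevLab == nextLab &&
        prevLab %in% landmarkOrder) {
      bridged[starts[j]:ends[j]] <- prevLab
    } else {
      cut[starts[j]:ends[j]] <- TRUE
    }
  }
  isLm <- bridged %in% landmarkOrder
  if (!any(isLm)) return(data.frame())
  r2 <- rle(bridged)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  lmRuns <- which(r2$values %in% landmarkOrder)
  occ <- data.frame(label = r2$values[lmRuns],
                    firstFrame = s2[lmRuns],
                    lastFrame = e2[lmRuns],
                    stringsAsFactors = FALSE)
  # merge repeated runs of the same label (keep the earliest onset)
  keep <- !duplicated(occ$label)
  occ <- occ[keep, , drop = FALSE]
  ord <- match(occ$label, landmarkOrder)
  if (is.unsorted(ord, strictly = TRUE)) return(NULL)  # regression
  occ$onset <- times[occ$firstFrame]
  # onset observed iff the immediately preceding frame exists, is not a
  # censoring cut, and carries a different (non-missing) label
  occ$onset_observed <- vapply(occ$firstFrame, function(f) {
    f > 1L && !cut[f - 1L] && bridged[f - 1L] != "MISSING"
  }, logical(1L))
  # a cut between this occurrence and the next censors both neighbours
  occ$cut_after <- vapply(seq_len(nrow(occ)), function(i) {
    if (i == nrow(occ)) return(any(cut & seq_len(n) > occ$lastFrame[i]))
    any(cut & seq_len(n) > occ$lastFrame[i] &
          seq_len(n) < occ$firstFrame[i + 1L])
  }, logical(1L))
  occ
}

#' Extract per-landmark durations from labelled trajectories
#'
#' The duration of a landmark L in a cell is onset(next landmark) -
#' onset(L), where the onset is the time of the first frame labelled L.
#' Transition frames between L and the next landmark are thereby folded
#' into L. An occurrence yields a complete record only when both onsets
#' are observed inside the movie: a run starting at the first frame of the
#' series (or entered across an unbridged missing gap) is left-censored,
#' and the last landmark of a series is right-censored. Runs of MISSING
#' frames are bridged iff flanked by the same landmark; otherwise both
#' flanking occurrences are censored. A cell whose landmark sequence
#' regresses against `landmarkOrder` is skipped with a warning.
#'
#' @param series a [LandmarkSeries-class].
#' @param landmarkOrder ordered landmark alphabet (defaults to the one
#'   declared in the series).
#' @return data.frame of duration records: genotype, anther_id, cell_id,
#'   landmark, onset_min, duration_min, complete. Censored occurrences are
#'   reported with `complete = FALSE` and `NA` duration.
#' @export
extractDurations <- function(series, landmarkOrder = NULL) {
  stopifnot(is(series, "LandmarkSeries"))
  if (is.null(landmarkOrder)) landmarkOrder <- series@landmarkOrder
  bad <- setdiff(setdiff(unique(series@data$landmark),
                         c("TRANSITION", "MISSING")), landmarkOrder)
  if (length(bad))
    stop("labels outside landmarkOrder: ", paste(bad, collapse = ", "))
  d <- series@data
  out <- list()
  for (rows in split(seq_len(nrow(d)), trajectoryKey(d))) {
    occ <- cellOccurrences(d$time_min[rows], d$landmark[rows],
                           landmarkOrder)
    if (is.null(occ)) {
      warning(sprintf(
        "cell %s/%s: landmark labels regress against the declared order; skipped",
        d$anther_id[rows[1L]], d$cell_id[rows[1L]]))
      next
    }
    if (!nrow(occ)) next
    if (sum(occ$onset_observed) < 2L) next  # need two observed transitions
    nOcc <- nrow(occ)
    complete <- logical(nOcc)
    duration <- rep(NA_real_, nOcc)
    for (i in seq_len(nOcc)) {
      if (!occ$onset_observed[i] || occ$cut_after[i] || i == nOcc) next
      if (!occ$onset_observed[i + 1L]) next
      duration[i] <- occ$onset[i + 1L] - occ$onset[i]
      complete[i] <- TRUE
    }
    out[[length(out) + 1L]] <- data.frame(
      genotype = d$genotype[rows[1L]],
      anther_id = d$anther_id[rows[1L]],
      cell_id = d$cell_id[rows[1L]],
      landmark = occ$label,
      onset_min = occ$onset,
      duration_min = duration,
      complete = complete,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(genotype = character(), anther_id = character(),
                      cell_id = character(), landmark = character(),
                      onset_min = numeric(), duration_min = numeric(),
                      complete = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise landmark durations
#'
#' Per landmark: number of complete records, mean, sd, median, quartiles
#' and the count of outliers by the 1.5 x IQR box-plot rule. Only complete
#' records enter the summaries.
#'
#' @param records duration records from [extractDurations()].
#' @param landmarkOrder optional ordering for the output rows.
#' @return data.frame, one row per landmark with any complete record.
#' @export
summarizeDurations <- function(records, landmarkOrder = NULL) {
  rec <- records[records$complete, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(landmark = character(), n = integer(),
                      mean_min = numeric(), sd_min = numeric(),
                      median_min = numeric(), q1_min = numeric(),
                      q3_min = numeric(), n_outliers = integer()))
  sp <- split(rec$duration_min, rec$landmark)
  summ <- do.call(rbind, lapply(names(sp), function(lm) {
    x <- sp[[lm]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(landmark = lm, n = length(x), mean_min = mean(x),
               sd_min = stats::sd(x), median_min = q[2L],
               q1_min = q[1L], q3_min = q[3L],
               n_outliers = sum(x < q[1L] - 1.5 * iqr |
                                x > q[3L] + 1.5 * iqr),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(landmarkOrder)) {
    summ <- summ[order(match(summ$landmark, landmarkOrder)), , drop = FALSE]
  }
  rownames(summ) <- NULL
  summ
}

#' Timeline total over a landmark range
#'
#' Sum of per-landmark mean durations over the given labels — the headline
#' "length of meiosis" style figure. Landmarks without complete records
#' contribute nothing and are reported in the `missing` attribute.
#'
#' @param records duration records from [extractDurations()].
#' @param landmarks labels to include, in order.
#' @return Numeric scalar, minutes; attribute `missing` lists labels with
#'   no complete record.
#' @export
timelineTotal <- function(records, landmarks) {
  summ <- summarizeDurations(records, landmarks)
  hit <- summ[summ$landmark %in% landmarks, , drop = FALSE]
  total <- sum(hit$mean_min)
  attr(total, "missing") <- setdiff(landmarks, hit$landmark)
  total
}
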