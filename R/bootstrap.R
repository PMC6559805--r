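#' Bootstrap stability of neighboring scores and landmark calls
#'
#' Each replicate draws `round(factor * n)` complete observations with
#' replacement from the dataset (the resampling unit is the individual
#' observation row) and rescores every cellular state observed in the
#' replicate. Per state, statistics are aggregated over the replicates in
#' which the state occurs; +Inf sentinel scores (zero neighbor spread or
#' no observed neighbor) are excluded from the mean/sd/quantile summaries
#' and tallied separately, while the landmark fraction counts them as
#' exceeding the threshold.
#'
#' @param ds a [MeiosisAnnotations-class]; must contain at least one
#'   complete observation.
#' @param factor resample size as a multiple of the number of complete
#'   observations (default 1.5).
#' @param reps number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @param threshold landmark threshold (strict, default 1).
#' @param quantiles probabilities to summarise (default 2.5%, 50%, 97.5%).
#' @return A [BootstrapScores-class].
#' @export
bootstrapScores <- function(ds, factor = 1.5, reps = 1000, seed,
                            threshold = 1,
                            quantiles = c(0.025, 0.5, 0.975)) {
  stopifnot(is(ds, "MeiosisAnnotations"))
  if (reps < 1) stop("reps must be at least 1")
  if (factor <= 0) stop("factor must be positive")
  if (missing(seed)) stop("a seed is required")
  if (any(diff(quantiles) <= 0)) stop("quantiles must be increasing")
  comp <- filterComplete(ds)
  n <- nObservations(comp)
  if (n == 0L) stop("no complete observations to resample")

  counts0 <- stateCounts(comp)
  k <- length(counts0@counts)
  # every replicate's states are a subset of the observed ones, so the
  # neighbor structure can be computed once
  adjacency <- neighborAdjacency(counts0@states)
  stateId <- match(formatState(stateMatrix(comp)), rownames(counts0@states))
  nBoot <- round(factor * n)

  set.seed(as.integer(seed))
  scoresMat <- matrix(NA_real_, nrow = k, ncol = reps)
  presentMat <- matrix(FALSE, nrow = k, ncol = reps)
  for (r in seq_len(reps)) {
    draw <- sample.int(n, nBoot, replace = TRUE)
    cnt <- tabulate(stateId[draw], nbins = k)
    present <- cnt > 0L
    presentMat[, r] <- present
    for (i in which(present)) {
      nb <- cnt[adjacency[i, ] & present]
      scoresMat[i, r] <- scoreFromCounts(cnt[i], nb)$score
    }
  }

  qn <- paste0("q", sub("0\\.", "", formatC(quantiles, format = "g")))
  tab <- data.frame(state = rownames(counts0@states),
                    plugin_score = scoreCountTable(counts0,
                                                   threshold = threshold,
                                                   adjacency = adjacency)$score,
                    n_present = rowSums(presentMat),
                    score_mean = NA_real_, score_sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (q in qn) tab[[q]] <- NA_real_
  tab$n_infinite <- 0L
  tab$landmark_fraction <- NA_real_
  for (i in seq_len(k)) {
    s <- scoresMat[i, presentMat[i, ]]
    if (!length(s)) next
    fin <- s[is.finite(s)]
    tab$n_infinite[i] <- sum(is.infinite(s) & s > 0)
    if (length(fin)) {
      tab$score_mean[i] <- mean(fin)
      tab$score_sd[i] <- stats::sd(fin)
      tab[i, qn] <- stats::quantile(fin, probs = quantiles, names = FALSE)
    }
    tab$landmark_fraction[i] <- mean(s > threshold)
  }
  new("BootstrapScores", table = tab, reps = as.integer(reps),
      factor = factor, seed = as.integer(seed), threshold = threshold,
      quantiles = quantiles)
}

setMethod("show", "BootstrapScores", function(object) {
  stable <- sum(object@table$landmark_fraction >= 0.95, na.rm = TRUE)
  cat("BootstrapScores: ", nrow(object@table), " states, ", object@reps,
      " replicates at ", object@factor, "x resample (seed ", object@seed,
      ")\n  ", stable, " state(s) called landmark in >= 95% of replicates\n",
      sep = "")
})

#' @rdname bootstrapScores
#' @param x a [BootstrapScores-class].
#' @param row.names,optional,... S3 compatibility, unused.
#' @export
setMethod("as.data.frame", "BootstrapScores",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' Export bootstrap results as CSV
#'
#' The header is preceded by comment lines recording the resampling
#' conventions (row-level resampling; per-replicate-occurrence
#' aggregation; sentinel handling) so that the output is self-describing.
#'
#' @param object a [BootstrapScores-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeBootstrap <- function(object, path) {
  stopifnot(is(object, "BootstrapScores"))
  meta <- c(
    "# bootstrap of neighboring scores",
    sprintf("# reps=%d factor=%g seed=%d threshold=%g",
            object@reps, object@factor, object@seed, object@threshold),
    "# resampling unit: individual observation row",
    "# per-state statistics aggregated over replicates containing the state",
    "# +Inf sentinel scores excluded from mean/sd/quantiles, tallied in n_infinite")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(object@table, con, row.names = FALSE)
  invisible(path)
}
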