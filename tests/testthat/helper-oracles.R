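# Independent brute-force oracles and in-code fixtures shared by the suite.
# The oracles deliberately re-derive each quantity by naive enumeration so
# that they share no code path with the implementation they check.

# neighbor relation by explicit difference enumeration
oracleNeighbors <- function(a, b) {
  ndiff <- 0L
  for (i in seq_along(a)) {
    d <- abs(a[i] - b[i])
    if (d > 1L) return(FALSE)
    if (d == 1L) ndiff <- ndiff + 1L
  }
  ndiff == 1L || ndiff == 2L
}

# state-space size by full enumeration (only for small products)
oracleStateSpace <- function(nStates) {
  nrow(do.call(expand.grid, lapply(nStates, seq_len)))
}

# landmark extraction by naive per-state loops over a named count vector
# (names are dash tuples); population sd written out longhand
oracleLandmarks <- function(countVec, threshold = 1) {
  states <- lapply(strsplit(names(countVec), "-", fixed = TRUE), as.integer)
  k <- length(countVec)
  out <- data.frame(state = names(countVec), score = NA_real_,
                    is_landmark = NA)
  for (i in seq_len(k)) {
    nb <- c()
    for (j in seq_len(k))
      if (i != j && oracleNeighbors(states[[i]], states[[j]]))
        nb <- c(nb, countVec[j])
    if (length(nb) == 0L) {
      out$score[i] <- Inf
    } else {
      mu <- sum(nb) / length(nb)
      sd0 <- sqrt(sum((nb - mu)^2) / length(nb))
      out$score[i] <- if (sd0 == 0) {
        if (countVec[i] > mu) Inf else if (countVec[i] == mu) 0 else -Inf
      } else (countVec[i] - mu) / sd0
    }
  }
  out$is_landmark <- out$score > threshold
  out
}

# build a MeiosisAnnotations from a compact frame spec:
# list(cell_id = list(times = c(...), states = matrix or list of tuples))
makeDataset <- function(cells, ontology, genotype = ontology@genotype,
                        anther = "a1") {
  rows <- list()
  for (cid in names(cells)) {
    spec <- cells[[cid]]
    st <- spec$states
    if (is.list(st)) st <- do.call(rbind, st)
    if (!is.matrix(st)) st <- matrix(st, nrow = 1L)
    colnames(st) <- ontology@parameters
    rows[[cid]] <- data.frame(genotype = genotype, anther_id = anther,
                              cell_id = cid, time_min = spec$times, st)
  }
  MeiosisAnnotations(do.call(rbind, rows), ontology)
}

toyOntology2 <- function() ParameterOntology(c("p1", "p2"), c(5L, 5L), "toy")
toyOntology3 <- function() ParameterOntology(c("p1", "p2", "p3"),
                                             c(4L, 4L, 4L), "toy")

# random complete-state count table over a small ontology
randomCountTable <- function(ontology, nStates = 8L, maxCount = 50L) {
  space <- as.matrix(do.call(expand.grid, lapply(ontology@nStates, seq_len)))
  pick <- sample(nrow(space), min(nStates, nrow(space)))
  states <- space[pick, , drop = FALSE]
  dimnames(states) <- NULL
  StateCountTable(states, sample.int(maxCount, length(pick), replace = TRUE),
                  ontology)
}

# small, fast generator settings shared by stochastic tests
smallWTConfig <- function(seed, ...) {
  wtGeneratorConfig(seed = seed, nAnthers = 6L, cellsPerAnther = 3,
                    ...)
}

# duration-annotation variant: emulates the directly landmark-annotated
# movies used for timelines (near-complete labels)
durationConfig <- function(seed, ...) {
  wtGeneratorConfig(seed = seed, pParamMissing = 0, pFrameMissing = 0.05,
                    ...)
}
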