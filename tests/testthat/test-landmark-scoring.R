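test_that("neighbor relation reproduces the worked examples", {
  s <- c(2, 4, 2, 3, 4)
  expect_true(areNeighbors(s, c(2, 3, 2, 3, 4)))   # one step in one param
  expect_true(areNeighbors(s, c(3, 3, 2, 3, 4)))   # one step in two params
  expect_false(areNeighbors(s, c(2, 2, 2, 3, 4)))  # a two-state jump
  expect_false(areNeighbors(s, c(3, 3, 2, 3, 3)))  # three params differ
  expect_false(areNeighbors(s, s))                 # irreflexive
  expect_error(areNeighbors(c(1, NA, 1, 1, 1), s), "complete")
})

test_that("neighbor relation agrees with brute-force enumeration", {
  set.seed(90125)
  for (rep in seq_len(10L)) {
    nP <- sample(2:5, 1L)
    ns <- sample(2:6, nP, replace = TRUE)
    a <- matrix(0L, 1000L, nP)
    b <- matrix(0L, 1000L, nP)
    for (p in seq_len(nP)) {
      a[, p] <- sample.int(ns[p], 1000L, replace = TRUE)
      b[, p] <- sample.int(ns[p], 1000L, replace = TRUE)
    }
    got <- vapply(seq_len(1000L), function(i)
      areNeighbors(a[i, ], b[i, ]), logical(1L))
    want <- vapply(seq_len(1000L), function(i)
      oracleNeighbors(a[i, ], b[i, ]), logical(1L))
    expect_identical(got, want)
    # symmetry
    rev <- vapply(seq_len(1000L), function(i)
      areNeighbors(b[i, ], a[i, ]), logical(1L))
    expect_identical(got, rev)
  }
})

test_that("neighboring score matches hand-computed values and sentinels", {
  ont <- toyOntology2()
  # count(s)=20, observed neighbors {5, 10, 15}: (20-10)/sqrt(50/3)
  tab <- StateCountTable(rbind(c(3, 3), c(2, 3), c(3, 2), c(3, 4)),
                         c(20L, 5L, 10L, 15L), ont)
  r <- neighboringScore(c(3, 3), tab)
  expect_equal(r$score, 10 / sqrt(50 / 3), tolerance = 1e-12)
  expect_equal(round(r$score, 4), 2.4495)
  expect_equal(r$basis, "finite")
  expect_setequal(r$neighbors, c("2-3", "3-2", "3-4"))

  # count(s)=100, neighbors {10, 20}: (100-15)/5 = 17
  tab2 <- StateCountTable(rbind(c(3, 3), c(2, 3), c(4, 3)),
                          c(100L, 10L, 20L), ont)
  expect_equal(neighboringScore(c(3, 3), tab2)$score, 17)

  # count equal to the neighbor mean scores zero
  tab3 <- StateCountTable(rbind(c(3, 3), c(2, 3), c(4, 3)),
                          c(10L, 8L, 12L), ont)
  expect_equal(neighboringScore(c(3, 3), tab3)$score, 0)

  # zero spread: dominant count gives the +Inf sentinel, equal count 0
  tab4 <- StateCountTable(rbind(c(3, 3), c(2, 3), c(4, 3)),
                          c(9L, 4L, 4L), ont)
  r4 <- neighboringScore(c(3, 3), tab4)
  expect_identical(r4$score, Inf)
  expect_equal(r4$basis, "zero_spread")
  tab5 <- StateCountTable(rbind(c(3, 3), c(2, 3), c(4, 3)),
                          c(4L, 4L, 4L), ont)
  expect_equal(neighboringScore(c(3, 3), tab5)$score, 0)

  # no observed neighbor: +Inf with its own flag
  tab6 <- StateCountTable(rbind(c(1, 1), c(5, 5)), c(3L, 4L), ont)
  r6 <- neighboringScore(c(1, 1), tab6)
  expect_identical(r6$score, Inf)
  expect_equal(r6$basis, "no_neighbors")

  expect_error(neighboringScore(c(2, 2), tab6), "not observed")
})

test_that("score is scale invariant, zero at the mean, and monotone", {
  set.seed(2718)
  ont <- toyOntology3()
  for (rep in seq_len(20L)) {
    tab <- randomCountTable(ont, nStates = 10L)
    base <- scoreStates(tab)
    # scaling all counts by a positive constant leaves scores unchanged
    scaled <- StateCountTable(tab@states, tab@counts * 7L, ont)
    expect_equal(scoreStates(scaled)$score, base$score, tolerance = 1e-10)
    # increasing one state's count never decreases its score
    i <- sample(length(tab@counts), 1L)
    bumped <- tab@counts
    bumped[i] <- bumped[i] + 25L
    up <- StateCountTable(tab@states, bumped, ont)
    expect_gte(scoreStates(up)$score[i], base$score[i])
  }
})

test_that("landmark extraction matches an independent brute force", {
  set.seed(314159)
  ont <- toyOntology3()
  for (rep in seq_len(10L)) {
    tab <- randomCountTable(ont, nStates = 12L)
    got <- scoreStates(tab)
    want <- oracleLandmarks(stats::setNames(tab@counts,
                                            rownames(tab@states)))
    ord <- match(want$state, got$state)
    expect_equal(got$score[ord], want$score, tolerance = 1e-10)
    expect_identical(got$is_landmark[ord], want$is_landmark)
  }
})

test_that("state enumeration counts complete observations only", {
  ont <- toyOntology2()
  ds <- makeDataset(list(
    c1 = list(times = c(0, 10, 20, 30),
              states = rbind(c(1, 1), c(1, 1), c(1, 1), c(NA, 2)))), ont)
  tab <- stateCounts(ds)
  expect_equal(length(tab), 1L)
  expect_equal(tab@counts, 3L)
  df <- as.data.frame(tab)
  expect_equal(df$frequency_pct, 100)
  # frequencies always total 100% of the complete observations
  sim <- generateDataset(smallWTConfig(seed = 61))
  expect_equal(sum(as.data.frame(stateCounts(sim$annotations))$frequency_pct),
               100, tolerance = 1e-9)
})

test_that("landmark flags use a strict threshold and Inf passes any", {
  ont <- toyOntology2()
  ds <- makeDataset(list(
    c1 = list(times = 0, states = rbind(c(2, 2)))), ont)
  lms <- extractLandmarks(ds)
  tab <- scores(lms)
  expect_identical(tab$score, Inf)  # single observed state, no neighbors
  expect_true(tab$is_landmark)
  # empty dataset gives an empty, well-formed table
  empty <- filterComplete(makeDataset(list(
    c1 = list(times = 0, states = rbind(c(NA, NA)))), ont))
  expect_equal(nrow(scores(extractLandmarks(empty))), 0L)
})
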