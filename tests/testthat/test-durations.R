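wtDefs <- function() landmarkDefinitions(wtLandmarkPath())

# compact builder for labelled series
makeSeries <- function(cells, order = c("L1", "L2", "L3")) {
  rows <- lapply(names(cells), function(cid) {
    labs <- cells[[cid]]$labels
    data.frame(genotype = "toy", anther_id = "a1", cell_id = cid,
               time_min = cells[[cid]]$times, landmark = labs,
               stringsAsFactors = FALSE)
  })
  new("LandmarkSeries", data = do.call(rbind, rows), landmarkOrder = order)
}

test_that("landmark labelling maps tuples, transitions and missing", {
  sim <- generateDataset(smallWTConfig(seed = 401))
  ds <- sim$annotations
  series <- assignLandmarks(ds, wtDefs())
  d <- observations(ds)
  lab <- series@data$landmark
  m <- as.matrix(d[parameterNames(wtOntology())])
  comp <- rowSums(is.na(m)) == 0L
  expect_true(all(lab[!comp] == "MISSING"))
  # the A3 tuple 2-2-2-3-3 is labelled A3 wherever it occurs complete
  isA3 <- comp & apply(m, 1L, function(r)
    identical(as.integer(r), c(2L, 2L, 2L, 3L, 3L)))
  expect_true(all(lab[isA3] == "A3"))
  # complete non-landmark tuples are transitions
  planted <- names(wtDefs())
  key <- rep(NA_character_, nrow(m))
  key[comp] <- formatState(m[comp, , drop = FALSE])
  expect_true(all(lab[comp & !key %in% planted] == "TRANSITION"))
  expect_error(assignLandmarks(ds, c("2-2-2-3-3" = "X", "2-2-2-3-3" = "Y")),
               "duplicate")
})

test_that("durations are onset differences with transitions folded in", {
  # entry into L1 observed (transition frame precedes it)
  s <- makeSeries(list(c1 = list(
    times = seq(0, 50, by = 10),
    labels = c("TRANSITION", "L1", "L1", "L1", "L1", "L2"))))
  rec <- extractDurations(s)
  r1 <- rec[rec$landmark == "L1", ]
  expect_true(r1$complete)
  expect_equal(r1$duration_min, 40)
  # the movie ends inside L2: right-censored, no complete record
  expect_false(rec$complete[rec$landmark == "L2"])

  # transition frames between landmarks fold into the preceding one
  s2 <- makeSeries(list(c1 = list(
    times = seq(0, 40, by = 10),
    labels = c("TRANSITION", "L1", "TRANSITION", "TRANSITION", "L2"))))
  rec2 <- extractDurations(s2)
  expect_equal(rec2$duration_min[rec2$landmark == "L1"], 30)
})

test_that("a run starting at the movie's first frame is left-censored", {
  s <- makeSeries(list(c1 = list(
    times = seq(0, 40, by = 10),
    labels = c("L1", "L1", "L2", "L2", "L3"))))
  rec <- extractDurations(s)
  expect_false(rec$complete[rec$landmark == "L1"])
  expect_true(rec$complete[rec$landmark == "L2"])
  expect_equal(rec$duration_min[rec$landmark == "L2"], 20)
})

test_that("missing runs bridge within a landmark and censor across labels", {
  # MISSING flanked by the same landmark: bridged, duration unaffected
  s <- makeSeries(list(c1 = list(
    times = seq(0, 50, by = 10),
    labels = c("TRANSITION", "L1", "MISSING", "L1", "L2", "L3"))))
  rec <- extractDurations(s)
  expect_equal(rec$duration_min[rec$landmark == "L1"], 30)
  # MISSING between different landmarks censors both
  s2 <- makeSeries(list(c1 = list(
    times = seq(0, 50, by = 10),
    labels = c("TRANSITION", "L1", "MISSING", "L2", "L3", "L3"))))
  rec2 <- extractDurations(s2)
  expect_false(rec2$complete[rec2$landmark == "L1"])
  expect_false(rec2$complete[rec2$landmark == "L2"])
  expect_true("L2" %in% rec2$landmark[!rec2$complete])
})

test_that("cells need two observed onsets and may not regress", {
  # single landmark onset: no records at all
  s <- makeSeries(list(c1 = list(
    times = c(0, 10, 20), labels = c("TRANSITION", "L1", "L1"))))
  expect_equal(nrow(extractDurations(s)), 0L)
  # regression against the declared order: warn and skip
  s2 <- makeSeries(list(c1 = list(
    times = c(0, 10, 20, 30),
    labels = c("TRANSITION", "L2", "L1", "L3"))))
  expect_warning(rec2 <- extractDurations(s2), "regress")
  expect_equal(nrow(rec2), 0L)
})

test_that("durations conserve total time on fully observed trajectories", {
  cfg <- wtGeneratorConfig(seed = 409, nAnthers = 8L, cellsPerAnther = 3,
                           pParamMissing = 0, pFrameMissing = 0,
                           windowLengthRange = c(3800, 3800),
                           windowStartRange = c(-60, -60))
  sim <- generateDataset(cfg)
  series <- assignLandmarks(sim$annotations, wtDefs())
  rec <- extractDurations(series)
  for (cid in unique(paste(rec$anther_id, rec$cell_id))) {
    rc <- rec[paste(rec$anther_id, rec$cell_id) == cid, ]
    onsets <- rc$onset_min
    # one record per planted landmark, the final one right-censored
    expect_equal(rc$landmark, paste0("A", seq_len(11)))
    expect_equal(sum(rc$complete), 10L)
    expect_equal(sum(rc$duration_min[rc$complete]),
                 max(onsets) - min(onsets))
  }
})

test_that("summaries report quartiles and the 1.5 IQR outlier rule", {
  rec <- data.frame(genotype = "x", anther_id = "a", cell_id = "c",
                    landmark = "L1",
                    onset_min = 0,
                    duration_min = c(40, NA),
                    complete = c(TRUE, FALSE))
  s <- summarizeDurations(rec)
  expect_equal(s$n, 1L)
  expect_equal(s$mean_min, 40)
  expect_equal(s$median_min, 40)
  rec2 <- data.frame(genotype = "x", anther_id = "a",
                     cell_id = paste0("c", 1:9), landmark = "L1",
                     onset_min = 0,
                     duration_min = c(10, 11, 12, 13, 14, 15, 16, 17, 300),
                     complete = TRUE)
  s2 <- summarizeDurations(rec2)
  expect_equal(s2$n_outliers, 1L)
  tot <- timelineTotal(rbind(rec, rec2), c("L1", "L2"))
  expect_equal(attr(tot, "missing"), "L2")
})
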