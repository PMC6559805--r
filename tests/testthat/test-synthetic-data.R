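test_that("generation is deterministic in the seed", {
  a <- generateDataset(smallWTConfig(seed = 21))
  b <- generateDataset(smallWTConfig(seed = 21))
  c <- generateDataset(smallWTConfig(seed = 22))
  expect_identical(observations(a$annotations), observations(b$annotations))
  expect_identical(a$truth@schedule, b$truth@schedule)
  expect_false(identical(observations(a$annotations),
                         observations(c$annotations)))
})

test_that("default config reproduces the study shape", {
  sim <- generateDataset(wtGeneratorConfig(seed = 31))
  ds <- sim$annotations
  expect_equal(nCells(ds), 169L)
  expect_equal(length(unique(observations(ds)$anther_id)), 35L)
  ms <- missingnessSummary(ds)
  # ~42% of rows with >= 1 unannotated parameter, ~32% fully unannotated
  expect_gt(ms$frac_incomplete, 0.35)
  expect_lt(ms$frac_incomplete, 0.50)
  expect_gt(ms$frac_all_missing, 0.26)
  expect_lt(ms$frac_all_missing, 0.38)
})

test_that("without noise every emitted state lies on the planted route", {
  cfg <- smallWTConfig(seed = 41, pParamMissing = 0, pFrameMissing = 0,
                       windowLengthRange = c(3200, 3200),
                       windowStartRange = c(-60, -60))
  sim <- generateDataset(cfg)
  expect_identical(observations(sim$annotations), sim$truth@frames)
  # frame-by-frame: each state is a landmark or sits between consecutive
  # landmarks of the planted path
  g <- flagOffScheme(transitionCounts(sim$annotations), wtLandmarkPath())
  expect_equal(offSchemeFraction(g), 0)
})

test_that("parameter sequences are non-decreasing without missingness", {
  cfg <- smallWTConfig(seed = 43, pParamMissing = 0, pFrameMissing = 0)
  d <- observations(generateDataset(cfg)$annotations)
  for (rows in split(seq_len(nrow(d)),
                     paste(d$anther_id, d$cell_id))) {
    for (p in parameterNames(wtOntology()))
      expect_false(is.unsorted(d[[p]][rows]))
  }
})

test_that("missingness matches its closed form and exact row scans", {
  ont <- toyOntology2()
  noMiss <- makeDataset(list(
    c1 = list(times = c(0, 10), states = rbind(c(1, 1), c(2, 2)))), ont)
  ms0 <- missingnessSummary(noMiss)
  expect_equal(ms0$frac_incomplete, 0)
  expect_equal(ms0$frac_all_missing, 0)

  # independent per-parameter dropout: P(row incomplete) = 1 - (1-p)^5
  cfg <- wtGeneratorConfig(seed = 47, pParamMissing = 0.1,
                           pFrameMissing = 0)
  ms <- missingnessSummary(generateDataset(cfg)$annotations)
  expect_equal(ms$frac_incomplete, 1 - 0.9^5, tolerance = 0.02)
  expect_lt(ms$frac_all_missing, 1e-3)
})

test_that("landmark frames dominate any individual transition state", {
  sim <- generateDataset(wtGeneratorConfig(seed = 53))
  counts <- stateCounts(sim$annotations)
  df <- as.data.frame(counts)
  planted <- formatState(wtLandmarkPath())
  lmCounts <- df$count[df$state %in% planted]
  trCounts <- df$count[!df$state %in% planted]
  expect_equal(length(lmCounts), length(planted))
  expect_gt(min(lmCounts), max(trCounts))
})

test_that("monotonicity of landmark paths is enforced", {
  badPath <- wtLandmarkPath()
  badPath[3L, 2L] <- 9L  # regression relative to the following row
  expect_error(wtGeneratorConfig(landmarkPaths = list(WT = badPath)),
               "non-decreasing")
})

test_that("tam two-route mixture emits both populations", {
  sim <- generateDataset(tamGeneratorConfig(seed = 57))
  routes <- sim$truth@cells$route
  expect_setequal(sort(unique(routes)), c(1L, 2L))
  frac <- mean(routes == 1L)
  expect_gt(frac, 0.25)  # weight 0.458 with 62 cells
  expect_lt(frac, 0.70)
  expect_equal(nCells(sim$annotations), 62L)
})
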