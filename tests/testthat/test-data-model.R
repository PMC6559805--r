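test_that("state space size is the product of per-parameter state counts", {
  expect_identical(stateSpaceSize(wtOntology()), 20160)
  expect_identical(stateSpaceSize(ParameterOntology("p", 4L)), 4)
  withOne <- ParameterOntology(c("a", "b", "c"), c(3L, 1L, 5L))
  expect_identical(stateSpaceSize(withOne), 15)
  # matches brute-force enumeration for small ontologies
  for (ns in list(c(2L, 3L), c(4L, 4L, 4L), c(6L, 15L, 7L)))
    expect_equal(stateSpaceSize(ParameterOntology(paste0("p", seq_along(ns)),
                                                  ns)),
                 oracleStateSpace(ns))
})

test_that("annotation CSV parsing maps 'n' to missing and validates ranges", {
  ont <- wtOntology()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "genotype,anther_id,cell_id,time_min,cell_shape,mt_array,nucleus_position,nucleolus_position,chromatin",
    "WT,a1,c1,0,1,n,1,2,2",
    "WT,a1,c1,15,1,1,1,2,2"), path)
  ds <- readAnnotations(path, ont)
  expect_equal(nObservations(ds), 2L)
  expect_identical(isComplete(ds), c(FALSE, TRUE))
  expect_true(is.na(observations(ds)$mt_array[1]))

  # state outside the ontology range names the offending parameter
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "genotype,anther_id,cell_id,time_min,cell_shape,mt_array,nucleus_position,nucleolus_position,chromatin",
    "WT,a1,c1,0,9,1,1,1,1"), bad)
  expect_error(readAnnotations(bad, ont), "outside ontology range")

  # unknown parameter column is a schema error
  schema <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "genotype,anther_id,cell_id,time_min,cell_shape,mt_array,nucleus_position,nucleolus_position,chromatin,vacuole",
    "WT,a1,c1,0,1,1,1,1,1,1"), schema)
  expect_error(readAnnotations(schema, ont), "unknown parameter")

  # duplicate (cell, time) rejected
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "genotype,anther_id,cell_id,time_min,cell_shape,mt_array,nucleus_position,nucleolus_position,chromatin",
    "WT,a1,c1,0,1,1,1,1,1",
    "WT,a1,c1,0,1,2,1,1,1"), dup)
  expect_error(readAnnotations(dup, ont), "duplicate")
})

test_that("parse -> write -> parse round-trips annotations exactly", {
  sim <- generateDataset(smallWTConfig(seed = 11))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeAnnotations(sim$annotations, p1)
  ds1 <- readAnnotations(p1, wtOntology())
  writeAnnotations(ds1, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(observations(ds1), observations(sim$annotations))
})

test_that("completeness filtering keeps exactly the fully annotated rows", {
  ont <- toyOntology2()
  ds <- makeDataset(list(
    c1 = list(times = c(0, 10, 20),
              states = rbind(c(1, 1), c(NA, 2), c(2, 2))),
    c2 = list(times = c(0, 10),
              states = rbind(c(NA, NA), c(3, NA)))), ont)
  kept <- filterComplete(ds)
  expect_equal(nObservations(kept), 2L)
  expect_true(all(isComplete(kept)))

  # identity on complete data; empty result allowed
  allComplete <- makeDataset(list(
    c1 = list(times = c(0, 10), states = rbind(c(1, 1), c(2, 1)))), ont)
  expect_identical(observations(filterComplete(allComplete)),
                   observations(allComplete))
  allMissing <- makeDataset(list(
    c1 = list(times = 0, states = rbind(c(NA, NA)))), ont)
  expect_equal(nObservations(filterComplete(allMissing)), 0L)

  # row count equals a brute-force row scan on generated data
  sim <- generateDataset(smallWTConfig(seed = 3))
  m <- as.matrix(observations(sim$annotations)[parameterNames(wtOntology())])
  nComplete <- sum(apply(m, 1L, function(r) !anyNA(r)))
  expect_equal(nObservations(filterComplete(sim$annotations)), nComplete)
  ms <- missingnessSummary(sim$annotations)
  expect_equal(ms$n - ms$n_incomplete, nComplete)
})

test_that("nearest-frame resampling follows the anchored grid", {
  ont <- toyOntology2()
  st5 <- function(n) matrix(rep(c(1, 1), n), ncol = 2, byrow = TRUE)
  # exact divisor: every third 5-min frame survives
  ds5 <- makeDataset(list(c1 = list(times = seq(0, 45, by = 5),
                                    states = st5(10))), ont)
  expect_equal(observations(resampleAnnotations(ds5, 15))$time_min,
               c(0, 15, 30, 45))
  # already on the target grid: identity
  ds15 <- makeDataset(list(c1 = list(times = seq(0, 60, by = 15),
                                     states = st5(5))), ont)
  expect_equal(observations(resampleAnnotations(ds15, 15))$time_min,
               seq(0, 60, by = 15))
  # 10-min frames against a 15-min grid: ties go to the earlier frame and
  # the trailing frame is captured by the next grid point
  ds10 <- makeDataset(list(c1 = list(times = seq(0, 40, by = 10),
                                     states = st5(5))), ont)
  expect_equal(observations(resampleAnnotations(ds10, 15))$time_min,
               c(0, 10, 30, 40))
  # output is always a subsequence of the input
  sim <- generateDataset(smallWTConfig(seed = 5))
  res <- resampleAnnotations(sim$annotations, 15)
  orig <- observations(sim$annotations)
  kept <- observations(res)
  keyO <- paste(orig$anther_id, orig$cell_id, orig$time_min)
  keyK <- paste(kept$anther_id, kept$cell_id, kept$time_min)
  expect_true(all(keyK %in% keyO))
  expect_lte(nrow(kept), nrow(orig))
})

test_that("parameter projection re-evaluates completeness on the subset", {
  sim <- generateDataset(smallWTConfig(seed = 8))
  ds <- sim$annotations
  # identity projection
  full <- projectParameters(ds, parameterNames(wtOntology()))
  expect_identical(observations(full), observations(ds))
  # chromatin-reporter view: two parameters survive, completeness relaxes
  sub <- projectParameters(ds, c("nucleolus_position", "chromatin"))
  expect_equal(parameterNames(ontology(sub)),
               c("nucleolus_position", "chromatin"))
  expect_gte(sum(isComplete(sub)), sum(isComplete(ds)))
  expect_equal(nObservations(sub), nObservations(ds))
  expect_error(projectParameters(ds, "unknown_param"), "unknown")
  expect_error(projectParameters(ds, c("chromatin", "cell_shape")),
               "ontology order")
})
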