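test_that("synthetic stimulus tables are deterministic and well-formed", {
  t1 <- synthStimuli(16, 8, seed = 3)
  t2 <- synthStimuli(16, 8, seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 24 * 3)
  expect_false(anyDuplicated(t1$stimulus_id) > 0)
  expect_equal(sort(unique(t1$presentation)), 1:3)
  expect_true(all(t1$concreteness >= 1 & t1$concreteness <= 5))

  tiny <- synthStimuli(2, 2, seed = 9)
  expect_equal(length(unique(tiny$word_id)), 4L)

  # transcriptions parse against the packaged feature table
  feats <- phonemeFeatureTable()
  phon <- unique(unlist(strsplit(t1$transcription, " ")))
  expect_true(all(phon %in% feats$phoneme))
})

test_that("generated word groups differ on concreteness but match elsewhere", {
  hits <- vapply(1:5, function(s) {
    tab <- synthStimuli(128, 64, seed = 100 + s)
    rep_ <- matchingReport(tab, "group",
                           c("concreteness", "frequency", "length"))
    conc <- rep_$t[rep_$property == "concreteness"]
    rest <- rep_$t[rep_$property != "concreteness"]
    conc > 20 && all(rest < 3)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("beta generation is deterministic and honors the null model", {
  tab <- synthStimuli(8, 4, seed = 5)
  dims <- c(8L, 8L, 8L)
  mask <- maskVolume(volumeGrid(dims), array(TRUE, dim = dims))
  cfg <- synthConfig(4, mask, regions = list(), noiseSd = 0.5, seed = 11)
  a <- synthBetas(cfg, tab)
  b <- synthBetas(cfg, tab)
  expect_identical(a$betasets[[1]]@beta, b$betasets[[1]]@beta)
  expect_identical(a$betasets[[2]]@beta, b$betasets[[2]]@beta)

  # no planted regions: group fidelity centered on zero
  repMap <- setNames(tab$word_id, tab$stimulus_id)
  pw <- lapply(a$betasets, averagePresentations, repetitionMap = repMap)
  g <- mapValues(fidelitySearchlight(pw, searchlightSpec(2))$groupMap)
  expect_lt(abs(mean(g)), 2 * sd(g) / sqrt(10))  # conservative SE proxy
})

test_that("a noiseless semantic region reproduces the concreteness geometry", {
  tab <- synthStimuli(12, 6, seed = 21)
  dims <- c(8L, 8L, 8L)
  grid <- volumeGrid(dims)
  mask <- maskVolume(grid, array(TRUE, dim = dims))
  region <- ballVoxels(grid, c(4, 4, 4), 2.5)
  cfg <- synthConfig(1, mask,
                     regions = list(list(name = "sem", voxels = region,
                                         source = "semantic",
                                         effect = 1.0)),
                     noiseSd = 1e-4, nLatent = 0, seed = 31)
  out <- synthBetas(cfg, tab)
  wordTab <- tab[!duplicated(tab$word_id), ]
  pat <- averagePresentations(out$betasets[[1]],
                              setNames(tab$word_id, tab$stimulus_id))
  cols <- match(region, maskIndices(mask))
  pred <- vectorizeLower(propertyRDM(wordTab$concreteness))
  # a 1-D planted property times shared loadings makes pattern distances
  # exactly proportional to the property distance (Euclidean metric) ...
  obsEuc <- vectorizeLower(neuralRDM(pat@beta[, cols],
                                     metric = "euclidean"))
  expect_gt(rdmCorrelation(obsEuc, pred, "spearman"), 0.9)
  # ... while the bounded correlation-distance RDM still tracks it
  obsCor <- vectorizeLower(neuralRDM(pat@beta[, cols]))
  expect_gt(rdmCorrelation(obsCor, pred, "spearman"), 0.75)

  # ground truth bookkeeping
  gt <- out$groundTruth
  expect_equal(sum(gt@regionLabels == 1L), length(region))
  expect_identical(gt@regions$sem$source, "semantic")
  expect_true(validObject(gt@regions$sem$plantedRDM))
})

test_that("config validation rejects malformed regions", {
  dims <- c(6L, 6L, 6L)
  grid <- volumeGrid(dims)
  arr <- array(FALSE, dim = dims); arr[2:5, 2:5, 2:5] <- TRUE
  mask <- maskVolume(grid, arr)
  outside <- list(name = "bad", voxels = 1L, source = "semantic",
                  effect = 1)
  expect_error(synthConfig(3, mask, regions = list(outside), seed = 1),
               "outside the mask")
  inside <- which(arr)[1:5]
  expect_error(synthConfig(3, mask, regions = list(
    list(name = "a", voxels = inside, source = "semantic", effect = 1),
    list(name = "b", voxels = inside[3:5], source = "semantic",
         effect = 1)), seed = 1), "disjoint")
  expect_error(synthConfig(3, mask, regions = list(
    list(name = "a", voxels = inside, source = "astral", effect = 1)),
    seed = 1), "source")
  expect_error(synthConfig(3, mask, seed = 1, noiseSd = 0), "noiseSd")
  expect_error(synthConfig(3, mask), "seed")
})

test_that("expected in-region RSA signal grows with effect and shrinks with noise", {
  tab <- synthStimuli(10, 5, seed = 41)
  dims <- c(7L, 7L, 7L)
  grid <- volumeGrid(dims)
  mask <- maskVolume(grid, array(TRUE, dim = dims))
  region <- ballVoxels(grid, c(4, 4, 4), 2)
  wordTab <- tab[!duplicated(tab$word_id), ]
  pred <- vectorizeLower(propertyRDM(wordTab$concreteness))
  inRegionCoef <- function(w, sigma, seed) {
    cfg <- synthConfig(1, mask, regions = list(
      list(name = "sem", voxels = region, source = "semantic",
           effect = w)), noiseSd = sigma, nLatent = 0, seed = seed)
    out <- synthBetas(cfg, tab)
    pat <- averagePresentations(out$betasets[[1]],
                                setNames(tab$word_id, tab$stimulus_id))
    cols <- match(region, maskIndices(mask))
    obs <- vectorizeLower(neuralRDM(pat@beta[, cols]))
    rdmCorrelation(obs, pred, "spearman")
  }
  seeds <- 1:4
  lowW <- mean(vapply(seeds, function(s) inRegionCoef(0.3, 0.5, s),
                      numeric(1)))
  highW <- mean(vapply(seeds, function(s) inRegionCoef(1.5, 0.5, s),
                       numeric(1)))
  lowNoise <- mean(vapply(seeds, function(s) inRegionCoef(0.8, 0.3, s),
                          numeric(1)))
  highNoise <- mean(vapply(seeds, function(s) inRegionCoef(0.8, 2.0, s),
                           numeric(1)))
  expect_gt(highW, lowW)
  expect_gt(lowNoise, highNoise)
})

test_that("fixture bundles are reproducible and loadable from disk", {
  tmp <- withr::local_tempdir()
  fx <- makeFixture("tiny", dir = file.path(tmp, "a"))
  fx2 <- makeFixture("tiny", dir = file.path(tmp, "b"))
  expect_identical(fx$betasets[[1]]@beta, fx2$betasets[[1]]@beta)
  expect_identical(fx$table, fx2$table)

  back <- readBetaSet(fx$paths$betas[1], fx$paths$mask, fx$paths$table,
                      subjectId = "sub01")
  expect_equal(back@beta, fx$betasets[[1]]@beta, tolerance = 1e-6)
  expect_identical(back@stimulusIds, fx$betasets[[1]]@stimulusIds)
  truth <- yaml::read_yaml(fx$paths$truth)
  expect_equal(truth$regions$semantic$source, "semantic")
  expect_identical(
    sort(unlist(truth$regions$semantic$voxels)),
    sort(fx$groundTruth@regions$semantic$voxels))
})
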