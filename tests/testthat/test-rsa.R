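test_that("partial Spearman reduces, zeroes out and matches the recursive formula", {
  set.seed(10)
  for (k in 1:20) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(partialSpearman(a, b),
                 cor(a, b, method = "spearman"), tolerance = 1e-12)
  }
  # predictor fully explained by a control
  x <- rnorm(30); z <- rnorm(30)
  expect_lt(abs(partialSpearman(x, z, list(z))), 1e-10)

  # closed-form first-order partial correlation oracle, one control
  for (k in 1:10) {
    x <- rnorm(15); y <- rnorm(15); z <- rnorm(15)
    rxy <- cor(x, y, method = "spearman")
    rxz <- cor(x, z, method = "spearman")
    ryz <- cor(y, z, method = "spearman")
    oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(partialSpearman(x, y, list(z)), oracle,
                 tolerance = 1e-10)
  }

  # two controls via iterated recursion
  for (k in 1:10) {
    x <- rnorm(25); y <- rnorm(25); z1 <- rnorm(25); z2 <- rnorm(25)
    pc <- function(a, b, c) (cor(a, b) - cor(a, c) * cor(b, c)) /
      sqrt((1 - cor(a, c)^2) * (1 - cor(b, c)^2))
    rx <- rank(x); ry <- rank(y); r1 <- rank(z1); r2 <- rank(z2)
    rxy1 <- pc(rx, ry, r1); rx21 <- pc(rx, r2, r1); ry21 <- pc(ry, r2, r1)
    oracle <- (rxy1 - rx21 * ry21) / sqrt((1 - rx21^2) * (1 - ry21^2))
    expect_equal(partialSpearman(x, y, list(z1, z2)), oracle,
                 tolerance = 1e-10)
  }

  # invariance under strictly increasing transforms of target/predictor
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  expect_equal(partialSpearman(exp(x), y^3 + 2 * y, list(z)),
               partialSpearman(x, y, list(z)), tolerance = 1e-12)

  expect_error(partialSpearman(x, y, list(c1 = z, c2 = z)), "collinear")
  expect_error(partialSpearman(x, y[1:10]), "equal length")
})

test_that("the RSA model warns on collinear predictors", {
  set.seed(20)
  a <- rnorm(30)
  expect_warning(partialRSAModel(a, list(ctrl = a * 2 + 0.01 * rnorm(30))),
                 "collinearity")
  expect_silent(partialRSAModel(a, list(ctrl = rnorm(30))))
})

test_that("the RSA searchlight recovers planted geometry and matches the R path", {
  # when every neighborhood spans the whole mask, the observed RDM equals
  # the planted geometry exactly and the coefficient saturates at 1
  dims <- c(4L, 4L, 4L)
  mask <- maskVolume(volumeGrid(dims), array(TRUE, dim = dims))
  nW <- 12
  set.seed(31)
  beta <- matrix(rnorm(nW * prod(dims)), nW)
  sets <- lapply(1:3, function(s)
    new("SubjectBetaSet", subjectId = paste0("s", s), mask = mask,
        beta = beta, stimulusIds = paste0("w", 1:nW)))
  z1 <- zscoreAcrossStimuli(sets[[1]])
  planted <- vectorizeLower(neuralRDM(z1@beta))
  model <- partialRSAModel(as.numeric(planted))
  maps <- rsaSearchlight(sets, model, searchlightSpec(10))
  expect_equal(mapValues(maps[[1]]), rep(1, prod(dims)),
               tolerance = 1e-10)
  target <- planted

  # equality with the generic engine + partialSpearman on z-scored betas
  set.seed(32)
  noisy <- lapply(1:3, function(s)
    new("SubjectBetaSet", subjectId = paste0("s", s), mask = mask,
        beta = beta + matrix(rnorm(nW * prod(dims), sd = 0.5), nW),
        stimulusIds = paste0("w", 1:nW)))
  ctrl <- vectorizeLower(randomRDM(nW, seed = 33))
  model2 <- partialRSAModel(target, list(ctrl = as.numeric(ctrl)))
  spec <- searchlightSpec(1.5)
  fast <- rsaSearchlight(noisy, model2, spec)
  zsets <- lapply(noisy, zscoreAcrossStimuli)
  ref <- runSearchlight(zsets, spec, function(mats)
    vapply(mats, function(m) {
      rownames(m) <- paste0("w", seq_len(nrow(m)))
      partialSpearman(as.numeric(vectorizeLower(neuralRDM(m))),
                      as.numeric(target), list(as.numeric(ctrl)))
    }, numeric(1)))
  for (s in 1:3)
    expect_equal(mapValues(fast[[s]]), mapValues(ref[[s]]),
                 tolerance = 1e-10)

  # shuffling the model's stimulus correspondence destroys the effect
  mid <- 22L                              # interior center (2,2,2)
  aligned <- mean(vapply(rsaSearchlight(noisy, partialRSAModel(
    as.numeric(target)), spec, centers = mid),
    function(x) mapValues(x)[mid], numeric(1)))
  expect_gt(aligned, 0.2)
  set.seed(34)
  D <- rdmMatrix(devectorizeLower(target))
  shuffles <- replicate(8, {
    perm <- sample(nW)
    shuffled <- D[perm, perm][lower.tri(D)]
    m <- rsaSearchlight(noisy, partialRSAModel(shuffled), spec,
                        centers = mid)
    mean(vapply(m, function(x) mapValues(x)[mid], numeric(1)))
  })
  expect_lt(abs(mean(shuffles)), 3 * sd(shuffles) / sqrt(8))
})

test_that("group RSA saturates for signal, stays empty for null, and flips sign cleanly", {
  dims <- c(7L, 7L, 7L)
  mask <- maskVolume(volumeGrid(dims), array(TRUE, dim = dims))
  n <- prod(dims)
  # all-zero maps: no suprathreshold voxels at all
  zeros <- mapsFrom(mask, 6, function(s) rep(0, n))
  g0 <- groupRSA(zeros, fwhm = 5, nPerm = 120, seed = 3)
  expect_equal(sum(g0@mask@data), 0L)
  expect_equal(nrow(g0@clusterTable), 0L)

  # constant positive maps with small noise: everything survives
  set.seed(41)
  strong <- mapsFrom(mask, 10, function(s) 0.5 + rnorm(n, sd = 0.05))
  g1 <- groupRSA(strong, fwhm = 5, nPerm = 120, seed = 3)
  expect_equal(sum(g1@mask@data), n)
  expect_equal(min(g1@clusterTable$size_vox), n)

  # equivariance under global sign flip: t negates, mask unchanged
  flipped <- lapply(strong, function(m)
    statMap(mask, -mapValues(m), kind = "rsa_coef"))
  g2 <- groupRSA(flipped, fwhm = 5, nPerm = 120, seed = 3)
  expect_equal(mapValues(g2@tMap), -mapValues(g1@tMap), tolerance = 1e-10)
  expect_identical(g2@mask@data, g1@mask@data)

  expect_warning(groupRSA(strong, nPerm = 50, seed = 1), "coarse")
})
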