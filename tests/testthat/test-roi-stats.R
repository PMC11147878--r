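test_that("top-fraction selection is deterministic and matches a full sort", {
  dims <- c(5L, 5L, 4L)
  grid <- volumeGrid(dims)
  mask <- maskVolume(grid, array(TRUE, dim = dims))
  set.seed(50)
  vals <- rnorm(prod(dims))
  map <- statMap(mask, vals, kind = "z")
  roiIdx <- sort(sample(prod(dims), 10))
  roi <- roiMask(array(seq_len(prod(dims)) %in% roiIdx, dim = dims),
                 grid = grid)
  sel <- topFraction(map, roi, 0.2)
  expect_length(sel, 2L)
  expect_true(all(sel %in% roiIdx))
  # selected minimum beats the unselected maximum
  expect_gte(min(vals[sel]), max(vals[setdiff(roiIdx, sel)]))

  # single best voxel when the fraction rounds to one
  v5 <- rep(-Inf, prod(dims)); v5[roiIdx[1:5]] <- 1:5
  v5[v5 == -Inf] <- 0
  map5 <- statMap(mask, v5, kind = "z")
  roi5 <- roiMask(array(seq_len(prod(dims)) %in% roiIdx[1:5], dim = dims),
                  grid = grid)
  expect_identical(topFraction(map5, roi5, 0.2), roiIdx[5])

  # full-sort oracle at fraction 0.5
  sel <- topFraction(map, roi, 0.5)
  oracle <- roiIdx[order(-vals[roiIdx], roiIdx)][1:5]
  expect_identical(sel, sort(oracle))

  # deterministic tie-break by ascending linear index
  tied <- statMap(mask, rep(1, prod(dims)), kind = "z")
  expect_identical(topFraction(tied, roi, 0.3), roiIdx[1:3])

  expect_error(topFraction(map, roi, 0), "fraction")
})

test_that("ROI mean comparisons run paired t-tests per ROI pair", {
  dims <- c(4L, 4L, 4L)
  mask <- maskVolume(volumeGrid(dims), array(TRUE, dim = dims))
  set.seed(51)
  base <- lapply(1:10, function(s) rnorm(64))
  maps <- mapsFrom(mask, 10, function(s) base[[s]])
  roiA <- 1:20
  # identical ROIs give t = 0
  same <- compareRoiMeans(maps, list(a = roiA, b = roiA))
  expect_equal(same$tests$t, 0)
  expect_equal(same$tests$df, 9)

  # forced separation: ROI-B values exceed ROI-A by 1 for every subject
  shifted <- mapsFrom(mask, 10, function(s) {
    v <- base[[s]]; v[41:60] <- v[1:20] + 1; v
  })
  forced <- compareRoiMeans(shifted, list(a = roiA, b = 41:60))
  expect_lt(forced$tests$p, 1e-6)

  # textbook paired-t oracle on random maps
  res <- compareRoiMeans(maps, list(a = roiA, b = 30:50))
  d <- vapply(1:10, function(s)
    mean(base[[s]][roiA]) - mean(base[[s]][30:50]), numeric(1))
  expect_equal(res$tests$t, mean(d) / (sd(d) / sqrt(10)),
               tolerance = 1e-12)
  expect_equal(res$tests$p,
               2 * pt(abs(res$tests$t), 9, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("overlap accounting reproduces the published ROI arithmetic", {
  # grid large enough to hold the published voxel counts
  dims <- c(40L, 40L, 20L)
  grid <- volumeGrid(dims)
  n <- prod(dims)
  set.seed(52)
  # construct masks with |a| = 5546, |b| = 3338, |a&b| = 449: the mROI,
  # uROI and overlap sizes reported for the two localizers
  inter <- sample(n, 449)
  onlyA <- sample(setdiff(seq_len(n), inter), 5546 - 449)
  onlyB <- sample(setdiff(seq_len(n), c(inter, onlyA)), 3338 - 449)
  a <- roiMask(array(seq_len(n) %in% c(inter, onlyA), dim = dims),
               grid = grid)
  b <- roiMask(array(seq_len(n) %in% c(inter, onlyB), dim = dims),
               grid = grid)
  ov <- overlapStats(a, b)
  expect_equal(ov$nIntersection, 449L)
  expect_equal(ov$pctOfB, 13.5)
  expect_equal(ov$pctOfA, 8.1)
  expect_equal(sum(ov$hemisphere), 449L)
  expect_lte(ov$nIntersection, min(ov$nA, ov$nB))

  disjoint <- overlapStats(
    roiMask(array(seq_len(n) %in% onlyA, dim = dims), grid = grid),
    roiMask(array(seq_len(n) %in% onlyB, dim = dims), grid = grid))
  expect_equal(disjoint$nIntersection, 0L)
  expect_equal(disjoint$pctOfA, 0)

  gridB <- volumeGrid(c(10L, 10L, 10L))
  expect_error(overlapStats(a, roiMask(array(TRUE, dim = c(10, 10, 10)),
                                       grid = gridB)), "grid")
})

test_that("laterality indices follow the voxel-count formula and its symmetries", {
  dims <- c(8L, 6L, 6L)
  grid <- volumeGrid(dims)                 # x < 0 for i <= 4
  left <- array(FALSE, dim = dims); left[1:4, , ] <- TRUE
  li <- lateralityIndex(roiMask(left, grid = grid))
  expect_equal(li$LI, 1)
  balanced <- array(TRUE, dim = dims)
  expect_equal(lateralityIndex(roiMask(balanced, grid = grid))$LI, 0)

  # published overlap hemisphere counts (307 left, 142 right) -> LI ~ 0.367
  g2 <- volumeGrid(c(40L, 4L, 4L))       # x < 0 for i <= 20
  counts <- array(FALSE, dim = c(40L, 4L, 4L))
  allIJK <- as.matrix(expand.grid(i = 1:40, j = 1:4, k = 1:4))
  leftIJK <- allIJK[allIJK[, "i"] <= 20, ][1:307, ]
  rightIJK <- allIJK[allIJK[, "i"] >= 21, ][1:142, ]
  counts[leftIJK] <- TRUE
  counts[rightIJK] <- TRUE
  li307 <- lateralityIndex(roiMask(counts, grid = g2))
  expect_equal(li307$VLeft, 307L)
  expect_equal(li307$VRight, 142L)
  expect_equal(round(li307$LI, 3), 0.367)

  set.seed(53)
  arr <- array(runif(prod(dims)) < 0.3, dim = dims)
  arr[1] <- TRUE
  li1 <- lateralityIndex(roiMask(arr, grid = grid))
  refl <- grid@affine; refl[1, ] <- -refl[1, ]
  li2 <- lateralityIndex(roiMask(arr, grid = volumeGrid(dims,
                                                        affine = refl)))
  expect_equal(li1$LI, -li2$LI)
  expect_true(abs(li1$LI) <= 1)
  expect_equal(li1$VLeft + li1$VRight + li1$midline, sum(arr))
})

test_that("per-subject LI comparison runs a paired t with pairwise dropping", {
  expect_equal(compareLI(c(0.3, 0.4, 0.5, 0.2), c(0.3, 0.4, 0.5, 0.2))$t, 0)
  set.seed(54)
  a <- runif(10, 0, 0.4)
  res <- compareLI(a + 0.3 + rnorm(10, sd = 0.01), a)
  expect_lt(res$p, 1e-4)
  b <- runif(10)
  d <- (a - b)
  oracle <- t.test(a - b)
  got <- compareLI(a, b)
  expect_equal(got$t, unname(oracle$statistic), tolerance = 1e-12)
  suppressMessages(dropped <- compareLI(c(a, NA), c(b, 0.5)))
  expect_equal(dropped$nUsed, 10)
  expect_error(compareLI(c(0.1, NA, NA, NA), c(0.2, 0.3, NA, NA)), ">= 3")
})

test_that("pooled two-sample t reproduces the stimulus-matching statistics", {
  conc <- pooledTwoSampleT(2.45, 0.59, 128, 4.79, 0.19, 64)
  expect_equal(conc$df, 190)
  expect_equal(conc$t, 30.91, tolerance = 0.05)
  expect_equal(pooledTwoSampleT(6.20, 1.87, 128, 6.03, 1.44, 64)$t, 0.63,
               tolerance = 0.05)
  expect_equal(pooledTwoSampleT(7.45, 2.53, 128, 7.59, 1.60, 64)$t, 0.41,
               tolerance = 0.05)
  expect_equal(pooledTwoSampleT(5, 1, 10, 5, 1, 10)$t, 0)

  # textbook formula oracle on random summaries
  set.seed(55)
  for (k in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1); s2 <- runif(1)
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    expect_equal(pooledTwoSampleT(m1, s1, n1, m2, s2, n2)$t,
                 abs(m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2)),
                 tolerance = 1e-12)
  }
})

test_that("matching reports flag only deliberately separated properties", {
  set.seed(56)
  n <- 60
  tab <- data.frame(word_id = paste0("w", 1:n),
                    group = rep(c("abstract", "concrete"), each = n / 2),
                    matched = rnorm(n),
                    target = c(rnorm(n / 2), rnorm(n / 2) + 10))
  rep_ <- matchingReport(tab, "group", c("matched", "target"))
  expect_equal(nrow(rep_), 2L)
  expect_lt(rep_$t[rep_$property == "matched"], 3)
  expect_gt(rep_$t[rep_$property == "target"], 20)
  expect_equal(rep_$df, rep(n - 2, 2))

  one <- matchingReport(tab, "group", "matched")
  expect_equal(nrow(one), 1L)
  tab$group[1] <- "third"
  expect_error(matchingReport(tab, "group", "matched"), "two groups")
})
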