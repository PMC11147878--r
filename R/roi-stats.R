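## ROI-level evaluation: top-fraction voxel queries, ROI mean comparisons,
## overlap accounting, laterality indices, and stimulus-matching tests.

## round half away from zero (so 2.5 -> 3), floor 1
roundHalfAway <- function(x) floor(x + 0.5)

#' Top-fraction voxels of a map within an ROI
#'
#' Selects the k = max(1, round(fraction * |roi|)) highest-valued in-ROI
#' voxels (the "top 20% most active" selection used when querying ROIs);
#' ties are broken by ascending linear voxel index, deterministically.
#'
#' @param map a [StatMap-class].
#' @param roi a [ROIMask-class]/[MaskVolume-class] on the same grid.
#' @param fraction in (0, 1] (default 0.2).
#' @return integer linear voxel indices of the selected set.
#' @export
topFraction <- function(map, roi, fraction = 0.2) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  roiIdx <- maskIndices(roi)
  if (!length(roiIdx)) stop("roi is empty")
  vol <- asVolume(map)
  vals <- vol[roiIdx]
  ok <- !is.na(vals)
  roiIdx <- roiIdx[ok]; vals <- vals[ok]
  if (!length(roiIdx)) stop("roi has no defined map values")
  k <- max(1L, roundHalfAway(fraction * length(roiIdx)))
  ord <- order(-vals, roiIdx)
  sort(roiIdx[ord[seq_len(k)]])
}

#' Compare mean parameter estimates between ROIs
#'
#' For each subject, the mean map value over each ROI's (selected) voxel
#' set; ROI pairs are compared with paired two-tailed t-tests (the same
#' subjects contribute to every ROI).
#'
#' @param subjectMaps list of >= 3 per-subject [StatMap-class]s.
#' @param rois named list of voxel-index vectors (e.g. from
#'   [topFraction()]) or ROI masks.
#' @return list with `means` (subjects x ROIs matrix) and `tests`
#'   (data.frame roi_a, roi_b, t, df, p, mean_diff).
#' @export
compareRoiMeans <- function(subjectMaps, rois) {
  if (length(subjectMaps) < 3L) stop("need >= 3 subjects")
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  idxs <- lapply(rois, function(r)
    if (is(r, "MaskVolume")) maskIndices(r) else as.integer(r))
  means <- vapply(idxs, function(ix) {
    vapply(subjectMaps, function(m) {
      v <- asVolume(m)[ix]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(subjectMaps)))
  if (length(rois) < 2L)
    return(list(means = means,
                tests = data.frame(roi_a = character(),
                                   roi_b = character(), t = numeric(),
                                   df = numeric(), p = numeric(),
                                   mean_diff = numeric())))
  combs <- utils::combn(names(rois), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- means[, combs[1, k]]; b <- means[, combs[2, k]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(!ok))
      message(sum(!ok), " subject(s) dropped pairwise for ",
              combs[1, k], " vs ", combs[2, k])
    d <- a[ok] - b[ok]
    if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
      tt <- if (abs(mean(d)) < 1e-12)
        list(statistic = 0, parameter = length(d) - 1, p.value = 1)
      else
        list(statistic = Inf * sign(mean(d)), parameter = length(d) - 1,
             p.value = 0)
    } else tt <- t.test(d)
    data.frame(roi_a = combs[1, k], roi_b = combs[2, k],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_diff = mean(d))
  }))
  list(means = means, tests = tests)
}

#' Overlap between two ROI masks
#'
#' Voxel counts, per-hemisphere intersection counts, and the intersection
#' as a percentage of each mask (one decimal), e.g. an overlap of 449
#' voxels is 13.5% of a 3338-voxel mask and 8.1% of a 5546-voxel one.
#'
#' @param a,b [ROIMask-class]/[MaskVolume-class] on a shared grid.
#' @return list with `nA`, `nB`, `nIntersection`, `hemisphere` (left/
#'   right/midline intersection counts), `pctOfA`, `pctOfB`.
#' @export
overlapStats <- function(a, b) {
  if (!sameGrid(a@grid, b@grid)) stop("masks are on different grids")
  inter <- a@data & b@data
  hemi <- if (any(inter))
    hemisphereCounts(roiMask(inter, grid = a@grid))
  else c(left = 0L, right = 0L, midline = 0L)
  nA <- sum(a@data); nB <- sum(b@data); nI <- sum(inter)
  list(nA = nA, nB = nB, nIntersection = nI, hemisphere = hemi,
       pctOfA = round(100 * nI / nA, 1),
       pctOfB = round(100 * nI / nB, 1))
}

#' Laterality index of a voxel set
#'
#' LI = (V_left - V_right) / (V_left + V_right) over the in-mask voxel
#' counts per hemisphere (midline voxels excluded); positive values mean
#' left-hemisphere dominance. Undefined (NA, flagged) when no lateralized
#' voxels exist.
#'
#' @param mask a [MaskVolume-class]/[ROIMask-class], or a [StatMap-class]
#'   together with `threshold` to binarize it first.
#' @param threshold optional: voxels with map value >= threshold count.
#' @return list `VLeft`, `VRight`, `midline`, `LI`.
#' @export
lateralityIndex <- function(mask, threshold = NULL) {
  if (is(mask, "StatMap")) {
    if (is.null(threshold))
      stop("a threshold is required to binarize a StatMap")
    vol <- asVolume(mask)
    sel <- !is.na(vol) & vol >= threshold
    if (!any(sel))
      return(list(VLeft = 0L, VRight = 0L, midline = 0L, LI = NA_real_))
    mask <- roiMask(sel, grid = mask@mask@grid)
  }
  h <- hemisphereCounts(mask)
  tot <- h[["left"]] + h[["right"]]
  list(VLeft = h[["left"]], VRight = h[["right"]],
       midline = h[["midline"]],
       LI = if (tot == 0) NA_real_ else (h[["left"]] - h[["right"]]) / tot)
}

#' Per-subject laterality indices and their comparison
#'
#' `subjectLateralityIndices` thresholds each subject's map at its own
#' top-`fraction` within the analysis mask before counting; `compareLI`
#' compares two ROIs' per-subject LI vectors with a paired two-tailed t.
#'
#' @param subjectMaps list of per-subject [StatMap-class]s.
#' @param roi ROI to restrict the count to (default: whole analysis mask).
#' @param fraction top fraction defining each subject's "significant"
#'   voxels (default 0.2).
#' @return numeric vector of per-subject LIs (NA when undefined).
#' @export
subjectLateralityIndices <- function(subjectMaps, roi = NULL,
                                     fraction = 0.2) {
  vapply(subjectMaps, function(m) {
    base <- if (is.null(roi)) m@mask else roi
    sel <- topFraction(m, base, fraction)
    li <- lateralityIndex(roiMask(
      array(seq_len(prod(m@mask@grid@dims)) %in% sel,
            dim = m@mask@grid@dims), grid = m@mask@grid))
    li$LI
  }, numeric(1))
}

#' @rdname subjectLateralityIndices
#' @param liA,liB per-subject LI vectors for the two ROIs.
#' @return `compareLI`: list `t`, `df`, `p`, `meanDiff`, `nUsed`.
#' @export
compareLI <- function(liA, liB) {
  ok <- !is.na(liA) & !is.na(liB)
  if (sum(!ok)) message(sum(!ok), " subject(s) with undefined LI dropped")
  if (sum(ok) < 3L) stop("need >= 3 subjects with defined LIs")
  d <- liA[ok] - liB[ok]
  if (sd(d) <= 1e-10 * max(1, abs(mean(d))))
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1, p = if (mean(d) == 0) 1 else 0,
                meanDiff = mean(d), nUsed = length(d)))
  tt <- t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       meanDiff = mean(d), nUsed = length(d))
}

#' Pooled two-sample t statistic from group summaries
#'
#' Textbook pooled-variance two-sample t from means, SDs and group sizes,
#' reported as a magnitude (the convention of stimulus-matching tables):
#' s2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2),
#' t = |m1-m2| / (s sqrt(1/n1 + 1/n2)), df = n1+n2-2.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group summaries (n >= 2, sd >= 0).
#' @return list `t`, `df`.
#' @export
pooledTwoSampleT <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (s2 == 0)
    return(list(t = if (m1 == m2) 0 else Inf, df = df))
  list(t = abs(m1 - m2) / (sqrt(s2) * sqrt(1 / n1 + 1 / n2)), df = df)
}

#' Stimulus matching report
#'
#' Group means, SDs and pooled two-sample t for each property column,
#' mirroring a stimulus-characteristics table: a well-matched design
#' shows one large t (the target factor) and small t's elsewhere.
#'
#' @param table stimulus table data.frame (one row per word or
#'   presentation; duplicated word_ids are collapsed to their first row).
#' @param groupColumn column with exactly two group labels.
#' @param propertyColumns numeric columns to compare.
#' @return data.frame property, mean/sd per group, t, df, p.
#' @export
matchingReport <- function(table, groupColumn = "group",
                           propertyColumns) {
  if ("word_id" %in% names(table))
    table <- table[!duplicated(table$word_id), , drop = FALSE]
  groups <- unique(table[[groupColumn]])
  if (length(groups) != 2L)
    stop("need exactly two groups, found ", length(groups))
  out <- lapply(propertyColumns, function(p) {
    v <- table[[p]]
    ok <- !is.na(v)
    if (sum(!ok)) message(sum(!ok), " missing value(s) dropped for ", p)
    g1 <- v[ok & table[[groupColumn]] == groups[1]]
    g2 <- v[ok & table[[groupColumn]] == groups[2]]
    tt <- pooledTwoSampleT(mean(g1), sd(g1), length(g1),
                           mean(g2), sd(g2), length(g2))
    data.frame(property = p,
               mean1 = mean(g1), sd1 = sd(g1), n1 = length(g1),
               mean2 = mean(g2), sd2 = sd(g2), n2 = length(g2),
               t = tt$t, df = tt$df,
               p = 2 * pt(tt$t, df = tt$df, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- as.character(groups)
  res
}
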