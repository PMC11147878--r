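## Representational fidelity: leave-one-subject-out RDM reliability, its
## searchlight map, and the multivariate ROI (mROI) definition.

#' Leave-one-out representational fidelity
#'
#' For each subject, the correlation between the subject's vectorized RDM
#' and the elementwise mean of all other subjects' RDMs (correlate RDM_s
#' with mean of the rest). High values mark representational geometry
#' that is reproducible across subjects.
#'
#' @param rdms list of >= 3 [RDM-class] with identical labels.
#' @param method "pearson" (default) or "spearman".
#' @return numeric per-subject fidelity in `[-1, 1]` (NA when a vector is
#'   degenerate).
#' @export
looFidelity <- function(rdms, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(rdms) < 3L) stop("need >= 3 subjects")
  labs <- rdmLabels(rdms[[1]])
  if (!all(vapply(rdms, function(r) identical(rdmLabels(r), labs),
                  logical(1))))
    stop("all RDMs must share labels in the same order")
  V <- vapply(rdms, vectorizeLower,
              numeric(length(labs) * (length(labs) - 1) / 2))
  total <- rowSums(V)
  vapply(seq_along(rdms), function(s) {
    self <- V[, s]
    others <- (total - self) / (length(rdms) - 1)
    if (sd(self) == 0 || sd(others) == 0) return(NA_real_)
    cor(self, others, method = method)
  }, numeric(1))
}

#' Representational fidelity searchlight
#'
#' At every center, builds each subject's neural RDM from the neighborhood
#' patterns (per-word averaged betas) and computes [looFidelity()],
#' yielding one fidelity map per subject plus their mean: a whole-cortex
#' map of areas with consistent multivariate patterns across subjects.
#'
#' @param betasets list of >= 3 [SubjectBetaSet-class] (per-word averages)
#'   on a shared grid+mask, identical stimulus order.
#' @param spec a [SearchlightSpec-class].
#' @param method fidelity correlation: "pearson" or "spearman".
#' @param centers optional in-mask center subset.
#' @return list with `subjectMaps` (list of [StatMap-class]) and
#'   `groupMap` (their voxelwise mean).
#' @export
fidelitySearchlight <- function(betasets, spec = searchlightSpec(),
                                method = c("pearson", "spearman"),
                                centers = NULL) {
  method <- match.arg(method)
  if (length(betasets) < 3L) stop("need >= 3 subjects")
  mask <- betasets[[1]]@mask
  ids <- betasets[[1]]@stimulusIds
  for (b in betasets)
    if (!identical(b@stimulusIds, ids))
      stop("stimulus order must be identical across subjects")
  nh <- searchlightNeighborhoods(mask, spec, centers)
  fid <- cpp_fidelity_map(lapply(betasets, function(b) b@beta),
                          nh$members, method == "spearman")
  n <- nMaskVoxels(mask)
  subjectMaps <- lapply(seq_along(betasets), function(s) {
    v <- rep(NA_real_, n)
    v[nh$centers] <- fid[s, ]
    statMap(mask, v, kind = "fidelity")
  })
  gm <- rep(NA_real_, n)
  gm[nh$centers] <- colMeans(fid)
  list(subjectMaps = subjectMaps,
       groupMap = statMap(mask, gm, kind = "fidelity"))
}

#' Define the multivariate ROI from subject fidelity maps
#'
#' Subject fidelity values are Fisher z-transformed and tested against
#' zero voxelwise (one-sided one-sample t by default: only positive
#' reproducibility defines a localizer; a sign-flip permutation test is
#' available). Voxels with p below `voxelP` are retained and connected
#' components smaller than `extentVox` voxels dropped.
#'
#' @param subjectMaps list of >= 3 per-subject fidelity [StatMap-class].
#' @param voxelP voxel-level threshold (default 0.05, deliberately
#'   inclusive).
#' @param extentVox minimum cluster extent in voxels (default 120).
#' @param connectivity cluster neighborhood: 6, 18 or 26 (default).
#' @param method "t" (one-sided one-sample t on Fisher z) or "signflip"
#'   (sign-flip permutation of the subject z maps).
#' @param nPerm,seed permutation settings for `method = "signflip"`.
#' @return a [ROIMask-class] with threshold provenance.
#' @export
defineMROI <- function(subjectMaps, voxelP = 0.05, extentVox = 120L,
                       connectivity = 26L, method = c("t", "signflip"),
                       nPerm = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (length(subjectMaps) < 3L) stop("need >= 3 subject maps")
  mask <- subjectMaps[[1]]@mask
  V <- vapply(subjectMaps, mapValues, numeric(nMaskVoxels(mask)))
  Z <- atanh(pmin(pmax(t(V), -1 + 1e-12), 1 - 1e-12))  # subjects x voxels
  n <- nrow(Z)
  p <- groupPValues(Z, alternative = "greater", method = method,
                    nPerm = nPerm, seed = seed)
  supra <- !is.na(p) & p < voxelP
  vol <- array(FALSE, dim = mask@grid@dims)
  vol[maskIndices(mask)[supra]] <- TRUE
  cl <- labelClusters(vol, mask@grid, connectivity = connectivity)
  keep <- which(cl$sizes >= extentVox)
  out <- array(FALSE, dim = mask@grid@dims)
  out[cl$labels %in% keep] <- TRUE
  if (!any(out))
    stop("no voxels survive voxelP = ", voxelP,
         " with extent >= ", extentVox, " voxels")
  roiMask(out, grid = mask@grid,
          provenance = list(source = "fidelity", voxelP = voxelP,
                            extentVox = extentVox,
                            connectivity = connectivity, method = method,
                            nSubjects = n))
}

## voxelwise one-sample group p-values from a subjects x voxels matrix
groupPValues <- function(Z, alternative = c("greater", "two.sided"),
                         method = c("t", "signflip"), nPerm = 1000L,
                         seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  n <- nrow(Z)
  tval <- groupTValues(Z)
  if (method == "t") {
    p <- if (alternative == "greater") pt(tval, df = n - 1,
                                          lower.tail = FALSE)
         else 2 * pt(abs(tval), df = n - 1, lower.tail = FALSE)
    return(p)
  }
  set.seed(seed)
  exceed <- rep(1L, ncol(Z))
  for (b in seq_len(nPerm)) {
    tb <- groupTValues(Z * sample(c(-1, 1), n, replace = TRUE))
    exceed <- exceed + if (alternative == "greater") (tb >= tval)
                       else (abs(tb) >= abs(tval))
  }
  exceed / (nPerm + 1)
}

groupTValues <- function(Z) {
  n <- nrow(Z)
  mu <- colMeans(Z)
  s <- sqrt(colSums(sweep(Z, 2, mu)^2) / (n - 1))
  tv <- mu / (s / sqrt(n))
  tv[s == 0 & mu == 0] <- 0
  tv
}

#' Dice coefficient between two masks
#'
#' @param a,b [MaskVolume-class]/[ROIMask-class] on one grid, or logical
#'   arrays.
#' @return 2|A and B| / (|A| + |B|).
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "MaskVolume")) a <- a@data
  if (is(b, "MaskVolume")) b <- b@data
  2 * sum(a & b) / (sum(a) + sum(b))
}
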