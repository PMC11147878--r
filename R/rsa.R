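## Partial-Spearman RSA: rank-based partial correlation between observed
## (neural) and predicted RDM vectors with orthographic/phonological
## controls, its whole-cortex searchlight, and the group-level inference
## with sign-flip cluster-extent correction.

rankAvg <- function(x) rank(x, ties.method = "average")

controlBasis <- function(controls, len) {
  X <- cbind(intercept = rep(1, len))
  if (length(controls)) {
    R <- vapply(controls, function(v) rankAvg(as.numeric(v)), numeric(len))
    colnames(R) <- names(controls) %||% paste0("control", seq_along(controls))
    X <- cbind(X, R)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[1:qrX$rank])]
    stop("collinear control RDM vector(s): ", paste(drop, collapse = ", "))
  }
  qr.Q(qrX)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partial Spearman correlation between RDM vectors
#'
#' All vectors are average-rank transformed; target and predictor ranks
#' are residualized on the control ranks (least squares with intercept)
#' and the residuals Pearson-correlated. With no controls this equals
#' plain Spearman's rho.
#'
#' @param target,predictor numeric vectors (vectorized RDMs) of equal
#'   length >= number of controls + 3.
#' @param controls list of control vectors (possibly empty).
#' @return partial correlation in `[-1, 1]`.
#' @export
partialSpearman <- function(target, predictor, controls = list()) {
  len <- length(target)
  if (length(predictor) != len ||
      any(lengths(controls) != len))
    stop("all vectors must have equal length")
  if (len < length(controls) + 3L)
    stop("need at least ", length(controls) + 3L, " pairs")
  Q <- controlBasis(controls, len)
  rt <- rankAvg(as.numeric(target))
  rp <- rankAvg(as.numeric(predictor))
  et <- rt - Q %*% crossprod(Q, rt)
  ep <- rp - Q %*% crossprod(Q, rp)
  nt <- sqrt(sum(et^2)); np <- sqrt(sum(ep^2))
  ## a vector fully explained by the controls (or constant) leaves no
  ## residual association: the partial correlation is 0 by convention
  if (nt < 1e-8 * length(et) || np < 1e-8 * length(ep)) return(0)
  sum(et * ep) / (nt * np)
}

#' Partial RSA model
#'
#' Bundles the predicted RDM vector of interest with its control vectors
#' and warns when any predictor pair is collinear beyond |r| = 0.7, the
#' conventional multicollinearity bound for linear-model predictors.
#'
#' @param target predicted RDM vector of interest (e.g. concreteness
#'   distance), from [vectorizeLower()].
#' @param controls named list of control RDM vectors (e.g. orthographic
#'   and phonological edit distance).
#' @param warnR collinearity warning threshold (default 0.7).
#' @return list with elements `target`, `controls` (class
#'   "partialRSAModel").
#' @export
partialRSAModel <- function(target, controls = list(), warnR = 0.7) {
  vecs <- c(list(target = as.numeric(target)),
            lapply(controls, as.numeric))
  if (length(unique(lengths(vecs))) != 1L)
    stop("target and controls must have equal length")
  if (length(vecs) > 1L) {
    C <- cor(do.call(cbind, vecs))
    hi <- which(abs(C) >= warnR & upper.tri(C), arr.ind = TRUE)
    for (k in seq_len(nrow(hi)))
      warning(sprintf("predictor collinearity |r| = %.2f between %s and %s",
                      abs(C[hi[k, 1], hi[k, 2]]),
                      rownames(C)[hi[k, 1]] %||% "predictor",
                      colnames(C)[hi[k, 2]] %||% "predictor"))
  }
  structure(list(target = as.numeric(target),
                 controls = lapply(controls, as.numeric)),
            class = "partialRSAModel")
}

#' Partial-Spearman RSA searchlight
#'
#' Z-scores each subject's betas across stimuli within voxel, then at
#' every center computes the neural RDM of the neighborhood patterns and
#' its partial Spearman correlation with the model target, controlling
#' the model's control RDMs; the coefficient is assigned to the center.
#'
#' @param betasets list of [SubjectBetaSet-class] (one row per word, same
#'   order as the model vectors) on a shared grid+mask.
#' @param model a [partialRSAModel()].
#' @param spec a [SearchlightSpec-class].
#' @param centers optional in-mask center subset.
#' @param zscore standardize betas first (the standard preprocessing;
#'   disable only if already standardized).
#' @return list of per-subject coefficient [StatMap-class]s.
#' @export
rsaSearchlight <- function(betasets, model, spec = searchlightSpec(),
                           centers = NULL, zscore = TRUE) {
  mask <- betasets[[1]]@mask
  nWords <- nrow(betasets[[1]]@beta)
  P <- nWords * (nWords - 1) / 2
  if (length(model$target) != P)
    stop(sprintf("model vectors have length %d but %d words give %d pairs",
                 length(model$target), nWords, P))
  if (zscore)
    betasets <- lapply(betasets, function(b)
      suppressWarnings(zscoreAcrossStimuli(b)))
  Q <- controlBasis(model$controls, P)
  rp <- rankAvg(model$target)
  predResid <- rp - Q %*% crossprod(Q, rp)
  nh <- searchlightNeighborhoods(mask, spec, centers)
  coefs <- cpp_rsa_map(lapply(betasets, function(b) b@beta), nh$members,
                       as.numeric(predResid), Q)
  n <- nMaskVoxels(mask)
  lapply(seq_along(betasets), function(s) {
    v <- rep(NA_real_, n)
    v[nh$centers] <- coefs[s, ]
    statMap(mask, v, kind = "rsa_coef")
  })
}

#' Group-level RSA inference
#'
#' Subject coefficient maps are Fisher z-transformed, smoothed
#' (mask-normalized Gaussian, default 5 mm FWHM) and entered into a
#' two-tailed one-sample t-test against zero. The t map is thresholded at
#' `voxelP` and clusters are extent-corrected by a sign-flip permutation
#' of the subject maps (max-cluster-size null over both signs).
#'
#' @param subjectMaps list of >= 3 per-subject coefficient
#'   [StatMap-class]s.
#' @param fwhm smoothing kernel FWHM in mm (default 5).
#' @param voxelP two-tailed voxel threshold (default 0.005).
#' @param clusterAlpha cluster-corrected familywise level (default 0.05).
#' @param nPerm number of sign-flip permutations (default 1000; < 100
#'   warns).
#' @param seed permutation seed.
#' @param connectivity cluster neighborhood (default 26).
#' @param order "zFirst" (default: Fisher z before smoothing and t, the
#'   statistically standard order) or "literal" (smooth raw coefficients,
#'   t-test, then z-transform the t map for thresholding).
#' @return an [RSAGroupResult-class]; an empty suprathreshold mask is a
#'   valid (non-error) outcome.
#' @export
groupRSA <- function(subjectMaps, fwhm = 5, voxelP = 0.005,
                     clusterAlpha = 0.05, nPerm = 1000L, seed = 1L,
                     connectivity = 26L, order = c("zFirst", "literal")) {
  order <- match.arg(order)
  if (length(subjectMaps) < 3L) stop("need >= 3 subject maps")
  if (nPerm < 100L) warning("nPerm < 100 gives a coarse cluster null")
  mask <- subjectMaps[[1]]@mask
  n <- length(subjectMaps)
  prep <- lapply(subjectMaps, function(m) {
    v <- mapValues(m)
    if (order == "zFirst") v <- atanh(pmin(pmax(v, -1 + 1e-12), 1 - 1e-12))
    gaussianSmooth(statMap(mask, v, kind = "z"), fwhm)
  })
  Z <- t(vapply(prep, mapValues, numeric(nMaskVoxels(mask))))
  valid <- colSums(!is.finite(Z)) == 0
  Zv <- Z[, valid, drop = FALSE]
  tcrit <- qt(1 - voxelP / 2, df = n - 1)
  tv <- groupTValues(Zv)
  pv <- 2 * pt(abs(tv), df = n - 1, lower.tail = FALSE)
  zv <- sign(tv) * qnorm(pmin(1 - pv / 2, 1 - 1e-16))

  supraVolume <- function(tvec, sign_) {
    vol <- array(FALSE, dim = mask@grid@dims)
    hit <- if (sign_ > 0) tvec > tcrit else tvec < -tcrit
    vol[maskIndices(mask)[valid][hit]] <- TRUE
    vol
  }
  maxClusterSize <- function(tvec) {
    m <- 0L
    for (sgn in c(1, -1)) {
      vol <- supraVolume(tvec, sgn)
      if (any(vol)) {
        cl <- labelClusters(vol, mask@grid, connectivity = connectivity)
        m <- max(m, max(cl$sizes))
      }
    }
    m
  }
  set.seed(seed)
  nullMax <- vapply(seq_len(nPerm), function(b)
    maxClusterSize(groupTValues(Zv * sample(c(-1, 1), n, replace = TRUE))),
    integer(1))

  outMask <- array(FALSE, dim = mask@grid@dims)
  tab <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    vol <- supraVolume(tv, sgn)
    if (!any(vol)) next
    cl <- labelClusters(vol, mask@grid, connectivity = connectivity)
    for (k in seq_along(cl$sizes)) {
      pCl <- (1 + sum(nullMax >= cl$sizes[k])) / (nPerm + 1)
      cid <- cid + 1L
      vox <- cl$labels == k
      tab[[cid]] <- data.frame(cluster_id = cid, sign = sgn,
                               size_vox = cl$sizes[k],
                               size_mm3 = cl$mm3[k], p_cluster = pCl)
      if (pCl <= clusterAlpha) outMask[vox] <- TRUE
    }
  }
  clusterTable <- if (length(tab)) do.call(rbind, tab)
                  else data.frame(cluster_id = integer(), sign = numeric(),
                                  size_vox = integer(),
                                  size_mm3 = numeric(),
                                  p_cluster = numeric())
  expand <- function(x) {
    v <- rep(NA_real_, nMaskVoxels(mask)); v[valid] <- x; v
  }
  params <- list(fwhm = fwhm, voxelP = voxelP, clusterAlpha = clusterAlpha,
                 nPerm = nPerm, seed = seed, connectivity = connectivity,
                 order = order, nSubjects = n)
  new("RSAGroupResult",
      tMap = statMap(mask, expand(tv), kind = "t"),
      zMap = statMap(mask, expand(zv), kind = "z"),
      pMap = statMap(mask, expand(pv), kind = "p"),
      mask = roiMask(outMask, grid = mask@grid, provenance = params),
      clusterTable = clusterTable, params = params)
}

setMethod("show", "RSAGroupResult", function(object) {
  sig <- sum(object@clusterTable$p_cluster <= object@params$clusterAlpha)
  cat(sprintf(
    "RSAGroupResult: %d subjects, %d cluster(s), %d significant, %d voxels\n",
    object@params$nSubjects, nrow(object@clusterTable), sig,
    sum(object@mask@data)))
})
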