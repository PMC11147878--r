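## Volume-space operations: separable Gaussian smoothing with mask
## renormalization, 3D connected components, and peak extraction.

shiftArray <- function(arr, s, axis) {
  ## zero-padded shift of a 3D array by s voxels along axis
  d <- dim(arr)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (s >= 0) {
    dst[[axis]] <- (1 + s):n
    src[[axis]] <- 1:(n - s)
  } else {
    dst[[axis]] <- 1:(n + s)
    src[[axis]] <- (1 - s):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    arr[src[[1]], src[[2]], src[[3]]]
  out
}

convolveAxis <- function(arr, weights, axis) {
  half <- (length(weights) - 1L) / 2L
  out <- array(0, dim = dim(arr))
  for (s in -half:half)
    out <- out + weights[s + half + 1L] * shiftArray(arr, s, axis)
  out
}

#' Gaussian smoothing of a statistic map
#'
#' Separable Gaussian smoothing with sigma = fwhm / (2 sqrt(2 ln 2)) per
#' axis in mm. By default the kernel is mask-normalized: the smoothed map
#' is divided by the smoothed mask, so zeros outside the mask do not drag
#' down edge voxels and a constant map stays exactly constant.
#'
#' @param map a [StatMap-class].
#' @param fwhmMM full width at half maximum in mm (0 = identity).
#' @param maskNormalize renormalize kernel weights over in-mask voxels.
#' @return a smoothed [StatMap-class] of the same kind.
#' @export
gaussianSmooth <- function(map, fwhmMM, maskNormalize = TRUE) {
  if (fwhmMM < 0) stop("fwhm must be >= 0")
  if (fwhmMM == 0) return(map)
  grid <- map@mask@grid
  sigmaMM <- fwhmMM / (2 * sqrt(2 * log(2)))
  vals <- asVolume(map, fill = 0)
  vals[is.na(vals)] <- 0
  known <- array(0, dim = grid@dims)
  idxKnown <- maskIndices(map@mask)[!is.na(map@values)]
  known[idxKnown] <- 1
  num <- vals * known
  den <- known
  for (axis in 1:3) {
    sigmaVox <- sigmaMM / grid@spacing[axis]
    half <- max(1L, ceiling(3 * sigmaVox))
    w <- dnorm(-half:half, sd = sigmaVox)
    w <- w / sum(w)
    num <- convolveAxis(num, w, axis)
    if (maskNormalize) den <- convolveAxis(den, w, axis)
  }
  if (maskNormalize) {
    sm <- num
    pos <- den > 1e-12
    sm[pos] <- num[pos] / den[pos]
    sm[!pos] <- NA_real_
  } else sm <- num                        # plain zero-padded convolution
  out <- sm[maskIndices(map@mask)]
  out[is.na(map@values)] <- NA_real_
  statMap(map@mask, out, kind = map@kind)
}

connectivityOffsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  n <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = n == 1, "18" = n >= 1 & n <= 2, "26" = n >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components in a binary volume
#'
#' Breadth-first flood fill over the 6/18/26-neighborhood; labels
#' partition the suprathreshold voxels.
#'
#' @param binary logical 3D array (or a [MaskVolume-class]/[ROIMask-class]).
#' @param grid a [VolumeGrid-class] (taken from `binary` when masked).
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners; default).
#' @return list with `labels` (integer array, 0 = background), `sizes`
#'   (voxels per cluster) and `mm3` (sizes times voxel volume).
#' @export
labelClusters <- function(binary, grid = NULL, connectivity = 26L) {
  if (is(binary, "MaskVolume")) {
    grid <- binary@grid
    binary <- binary@data
  }
  if (is.null(grid))
    grid <- volumeGrid(dim(binary))
  dims <- dim(binary)
  offs <- connectivityOffsets(as.integer(connectivity))
  labels <- array(0L, dim = dims)
  idx <- which(binary)
  nextLabel <- 0L
  sizes <- integer()
  queue <- integer(length(idx))
  for (seed in idx) {
    if (labels[seed] != 0L) next
    nextLabel <- nextLabel + 1L
    labels[seed] <- nextLabel
    queue[1] <- seed
    qlen <- 1L
    count <- 0L
    while (qlen > 0L) {
      cur <- queue[qlen]
      qlen <- qlen - 1L
      count <- count + 1L
      ijk <- linearToIJK(dims, cur)
      nb <- offs + matrix(ijk, nrow(offs), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      lin <- ijkToLinear(dims, nb[ok, , drop = FALSE])
      lin <- lin[binary[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- nextLabel
        queue[(qlen + 1L):(qlen + length(lin))] <- lin
        qlen <- qlen + length(lin)
      }
    }
    sizes[nextLabel] <- count
  }
  list(labels = labels, sizes = sizes,
       mm3 = sizes * prod(grid@spacing))
}

#' Local extrema of a statistic map
#'
#' Within each cluster, voxels are visited in descending absolute value
#' and greedily retained as peaks unless within `minSepMM` (world
#' distance) of an already retained peak.
#'
#' @param map a [StatMap-class].
#' @param clusters result of [labelClusters()] on the suprathreshold set.
#' @param minSepMM minimum world-space separation between peaks (mm).
#' @return data.frame `x,y,z,value,cluster_id,cluster_mm3`, world mm.
#' @export
localExtrema <- function(map, clusters, minSepMM = 11) {
  if (minSepMM <= 0) stop("minSepMM must be > 0")
  grid <- map@mask@grid
  vol <- asVolume(map)
  rows <- list()
  for (cl in seq_along(clusters$sizes)) {
    vox <- which(clusters$labels == cl)
    vals <- vol[vox]
    keep <- !is.na(vals)
    vox <- vox[keep]; vals <- vals[keep]
    if (!length(vox)) next
    ord <- order(abs(vals), decreasing = TRUE)
    world <- voxelToWorld(grid, linearToIJK(grid@dims, vox))
    sel <- integer()
    for (cand in ord) {
      if (length(sel)) {
        d <- sqrt(colSums((t(world[sel, , drop = FALSE]) - world[cand, ])^2))
        if (any(d < minSepMM)) next
      }
      sel <- c(sel, cand)
    }
    rows[[cl]] <- data.frame(
      x = world[sel, 1], y = world[sel, 2], z = world[sel, 3],
      value = vals[sel], cluster_id = cl,
      cluster_mm3 = clusters$mm3[cl])
  }
  if (!length(rows))
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      value = numeric(), cluster_id = integer(),
                      cluster_mm3 = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
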