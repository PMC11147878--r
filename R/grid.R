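#' Construct a voxel grid
#'
#' @param dims integer(3) voxel counts.
#' @param spacing numeric(3) voxel size in mm (default 3 mm isotropic).
#' @param affine optional 4x4 voxel-to-world matrix (1-based voxel indices).
#'   When omitted, an RAS affine is built from `spacing` with the world
#'   origin at the grid center, so negative world x is the left hemisphere.
#' @return a [VolumeGrid-class].
#' @examples
#' g <- volumeGrid(c(10, 10, 10))
#' voxelToWorld(g, rbind(c(1, 1, 1)))
#' @export
volumeGrid <- function(dims, spacing = c(3, 3, 3), affine = NULL) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    center <- (dims + 1) / 2               # grid center in 1-based voxels
    affine[1:3, 4] <- -spacing * center
  }
  new("VolumeGrid", dims = dims, spacing = spacing, affine = affine)
}

#' @describeIn volumeGrid map 1-based voxel coordinates (n x 3 matrix) to
#'   world mm coordinates.
#' @param grid a [VolumeGrid-class].
#' @param vox n x 3 matrix of 1-based voxel coordinates.
#' @export
voxelToWorld <- function(grid, vox) {
  vox <- matrix(as.numeric(vox), ncol = 3L)
  h <- cbind(vox, 1)
  w <- h %*% t(grid@affine)
  w[, 1:3, drop = FALSE]
}

#' @describeIn volumeGrid map world mm coordinates back to (fractional)
#'   1-based voxel coordinates.
#' @param world n x 3 matrix of world coordinates in mm.
#' @export
worldToVoxel <- function(grid, world) {
  world <- matrix(as.numeric(world), ncol = 3L)
  h <- cbind(world, 1)
  v <- h %*% t(solve(grid@affine))
  v[, 1:3, drop = FALSE]
}

## linear (column-major) voxel index -> (i,j,k), 1-based
linearToIJK <- function(dims, idx) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijkToLinear <- function(dims, ijk) {
  (ijk[, 3] - 1L) * dims[1] * dims[2] + (ijk[, 2] - 1L) * dims[1] + ijk[, 1]
}

#' Construct a mask volume
#'
#' @param grid a [VolumeGrid-class].
#' @param data logical array of in-mask voxels (or numeric, nonzero = in).
#' @return a [MaskVolume-class].
#' @export
maskVolume <- function(grid, data) {
  if (!is.logical(data)) data <- array(data != 0, dim = dim(data))
  if (!any(data)) stop("mask must contain at least one voxel")
  new("MaskVolume", grid = grid, data = data)
}

#' @rdname maskVolume
#' @param mask a [MaskVolume-class].
#' @return `maskIndices`: linear voxel indices of in-mask voxels, in the
#'   order used by all masked vectors (column-major array order).
#' @export
maskIndices <- function(mask) which(mask@data)

#' @rdname maskVolume
#' @return `nMaskVoxels`: number of in-mask voxels.
#' @export
nMaskVoxels <- function(mask) sum(mask@data)

#' @rdname maskVolume
#' @return `gridOf`: the [VolumeGrid-class] of a masked object.
#' @param x a MaskVolume, SubjectBetaSet or StatMap.
#' @export
gridOf <- function(x) {
  if (is(x, "MaskVolume")) x@grid
  else if (is(x, "SubjectBetaSet")) x@mask@grid
  else if (is(x, "StatMap")) x@mask@grid
  else stop("no grid associated with objects of class ", class(x))
}

sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@dims, b@dims) &&
    max(abs(a@affine - b@affine)) < tol
}

#' Hemisphere voxel counts
#'
#' Assigns each in-mask voxel to a hemisphere by the sign of its world x
#' coordinate (negative = left, positive = right, zero = midline).
#'
#' @param mask a [MaskVolume-class] or [ROIMask-class].
#' @return named integer vector `c(left=, right=, midline=)`; counts sum to
#'   the mask size.
#' @export
hemisphereCounts <- function(mask) {
  idx <- maskIndices(mask)
  ijk <- linearToIJK(mask@grid@dims, idx)
  x <- voxelToWorld(mask@grid, ijk)[, 1]
  c(left = sum(x < 0), right = sum(x > 0), midline = sum(x == 0))
}

#' Values of a StatMap as a 3D array
#'
#' @param map a [StatMap-class].
#' @param fill value for out-of-mask voxels.
#' @return numeric array on the map's grid.
#' @export
asVolume <- function(map, fill = NA_real_) {
  arr <- array(fill, dim = map@mask@grid@dims)
  arr[maskIndices(map@mask)] <- map@values
  arr
}

#' Construct a StatMap
#'
#' @param mask a [MaskVolume-class].
#' @param values numeric per in-mask voxel, or a 3D array to be masked.
#' @param kind statistic tag: "fidelity", "rsa_coef", "t", "z", "p", "other".
#' @export
statMap <- function(mask, values, kind = "other") {
  if (is.array(values)) values <- values[maskIndices(mask)]
  new("StatMap", mask = mask, values = as.numeric(values), kind = kind)
}

#' @rdname statMap
#' @param map a [StatMap-class].
#' @return `mapValues`: the per-voxel values in mask order.
#' @export
mapValues <- function(map) map@values

#' Construct an ROIMask
#'
#' @param mask a [MaskVolume-class] or logical array with a `grid`.
#' @param grid required when `mask` is a bare array.
#' @param provenance named list describing how the region was defined.
#' @export
roiMask <- function(mask, grid = NULL, provenance = list()) {
  if (is(mask, "MaskVolume"))
    new("ROIMask", grid = mask@grid, data = mask@data,
        provenance = provenance)
  else
    new("ROIMask", grid = grid, data = mask, provenance = provenance)
}

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid %s, voxel %s mm\n",
              paste(object@dims, collapse = "x"),
              paste(format(object@spacing), collapse = "x")))
})

setMethod("show", "MaskVolume", function(object) {
  cat(sprintf("%s: %d/%d voxels in mask (%s grid)\n", class(object),
              sum(object@data), prod(object@grid@dims),
              paste(object@grid@dims, collapse = "x")))
})

setMethod("show", "SubjectBetaSet", function(object) {
  cat(sprintf("SubjectBetaSet '%s': %d stimuli x %d voxels\n",
              object@subjectId, nrow(object@beta), ncol(object@beta)))
})

setMethod("show", "StatMap", function(object) {
  v <- object@values
  cat(sprintf("StatMap [%s]: %d voxels, range %.4g..%.4g (%d NA)\n",
              object@kind, length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})
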