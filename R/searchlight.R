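## Spherical searchlight machinery: lattice offsets, per-center
## neighborhoods, and a generic engine mapping an arbitrary function over
## every in-mask center. The fidelity and RSA modules use compiled fast
## paths; this engine is the reference implementation they are tested
## against.

#' Integer lattice offsets of a searchlight sphere
#'
#' All integer triples (dx, dy, dz) with Euclidean norm <= `radiusVox`, in
#' a deterministic sorted order. The default radius of 3.0 voxel units
#' encloses 123 lattice points, the sphere size used throughout the
#' multivariate localizer analyses.
#'
#' @param radiusVox sphere radius in voxel units (>= 0).
#' @return integer matrix (k x 3).
#' @examples
#' nrow(sphereOffsets(3))  # 123
#' @export
sphereOffsets <- function(radiusVox) {
  if (radiusVox < 0) stop("radius must be >= 0")
  r <- floor(radiusVox)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g <- g[rowSums(g^2) <= radiusVox^2 + 1e-9, , drop = FALSE]
  g <- g[order(g[, 3], g[, 2], g[, 1]), , drop = FALSE]
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Searchlight specification
#'
#' @param radiusVox sphere radius in voxel units (default 3.0, a
#'   123-voxel sphere).
#' @param minMembers neighborhoods with fewer in-mask members are flagged
#'   (not dropped).
#' @return a [SearchlightSpec-class].
#' @export
searchlightSpec <- function(radiusVox = 3.0, minMembers = 10L) {
  new("SearchlightSpec", radius = radiusVox,
      minMembers = as.integer(minMembers),
      offsets = sphereOffsets(radiusVox))
}

setMethod("show", "SearchlightSpec", function(object) {
  cat(sprintf("SearchlightSpec: radius %.2f vox, %d offsets, minMembers %d\n",
              object@radius, nrow(object@offsets), object@minMembers))
})

#' Searchlight neighborhoods for every in-mask center
#'
#' One neighborhood per in-mask voxel (each gray-matter voxel serves as a
#' center exactly once); members are clipped to the grid and the mask, so
#' edge neighborhoods are truncated spheres.
#'
#' @param mask a [MaskVolume-class].
#' @param spec a [SearchlightSpec-class].
#' @param centers optional subset of centers, as indices into the in-mask
#'   voxel order (default: all).
#' @return list with `members` (list of integer vectors, indices into the
#'   in-mask voxel order), `centers` (in-mask indices) and `flagged`
#'   (logical: fewer than `minMembers` members).
#' @export
searchlightNeighborhoods <- function(mask, spec = searchlightSpec(),
                                     centers = NULL) {
  dims <- mask@grid@dims
  idx <- maskIndices(mask)
  if (is.null(centers)) centers <- seq_along(idx)
  ## in-mask rank per linear voxel index (0 = out of mask)
  rank <- integer(prod(dims))
  rank[idx] <- seq_along(idx)
  offs <- spec@offsets
  members <- vector("list", length(centers))
  ijkAll <- linearToIJK(dims, idx[centers])
  for (c in seq_along(centers)) {
    nb <- offs + matrix(ijkAll[c, ], nrow(offs), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    r <- rank[ijkToLinear(dims, nb[ok, , drop = FALSE])]
    members[[c]] <- r[r > 0L]
  }
  sizes <- lengths(members)
  list(members = members, centers = centers,
       flagged = sizes < spec@minMembers)
}

#' Generic searchlight engine
#'
#' Evaluates `fn` on the per-subject pattern submatrices of every
#' neighborhood and writes the returned scalar(s) to the center voxel.
#' Deterministic given data and spec; a failing center yields NA and a
#' message with its coordinates.
#'
#' @param betasets list of [SubjectBetaSet-class] on a shared grid+mask.
#' @param spec a [SearchlightSpec-class].
#' @param fn function(list of stimulus x member matrices) returning a
#'   scalar or a named/plain numeric vector (one value per output map).
#' @param centers optional in-mask center subset (see
#'   [searchlightNeighborhoods()]).
#' @return a [StatMap-class], or a list of them when `fn` returns a
#'   vector; non-center voxels are NA when `centers` is a subset.
#' @export
runSearchlight <- function(betasets, spec, fn, centers = NULL) {
  mask <- betasets[[1]]@mask
  for (b in betasets[-1])
    if (!sameGrid(b@mask@grid, mask@grid) ||
        !identical(b@mask@data, mask@data))
      stop("all subjects must share one grid and mask")
  nh <- searchlightNeighborhoods(mask, spec, centers)
  nOut <- NULL
  out <- NULL
  for (c in seq_along(nh$centers)) {
    mem <- nh$members[[c]]
    val <- tryCatch(
      fn(lapply(betasets, function(b) b@beta[, mem, drop = FALSE])),
      error = function(e) {
        ijk <- linearToIJK(mask@grid@dims,
                           maskIndices(mask)[nh$centers[c]])
        message(sprintf("searchlight center (%d,%d,%d) failed: %s",
                        ijk[1], ijk[2], ijk[3], conditionMessage(e)))
        NA_real_
      })
    if (is.null(nOut)) {
      nOut <- length(val)
      out <- matrix(NA_real_, nMaskVoxels(mask), nOut)
    }
    out[nh$centers[c], ] <- as.numeric(val)
  }
  maps <- lapply(seq_len(nOut), function(k)
    statMap(mask, out[, k], kind = "other"))
  if (nOut == 1L) maps[[1]] else maps
}
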