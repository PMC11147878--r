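## Central S4 containers. All voxel data live on a VolumeGrid; masked
## objects carry their MaskVolume so geometry is never separated from values.

#' VolumeGrid: voxel grid geometry
#'
#' Dimensions, voxel size and a 4x4 voxel-to-world affine for a 3D
#' acquisition grid. World coordinates follow the RAS convention with
#' negative x in the left hemisphere, matching stereotaxic peak tables.
#'
#' @slot dims integer(3), number of voxels along each axis (all >= 1).
#' @slot spacing numeric(3), voxel size in mm (all > 0).
#' @slot affine 4x4 matrix mapping 1-based voxel indices to world mm.
#' @export
setClass("VolumeGrid",
  representation(dims = "integer", spacing = "numeric", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be three integers >= 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive voxel sizes (mm)")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else if (abs(det(object@affine)) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    if (length(msg)) msg else TRUE
  })

#' MaskVolume: boolean voxel set on a grid
#'
#' A logical 3D array marking the analysis (e.g. gray-matter) voxels.
#' Provides the bijection between in-mask linear order and (i,j,k).
#'
#' @slot grid a [VolumeGrid-class].
#' @slot data logical array with `dims(grid)` dimensions.
#' @export
setClass("MaskVolume",
  representation(grid = "VolumeGrid", data = "array"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@data))
      msg <- c(msg, "mask data must be logical")
    if (!identical(dim(object@data), object@grid@dims))
      msg <- c(msg, "mask dimensions disagree with grid dims")
    if (length(msg)) msg else TRUE
  })

#' ROIMask: a region of interest with provenance
#'
#' A [MaskVolume-class] subclass recording how the region was defined
#' (thresholds, source map, seeds).
#'
#' @slot provenance named list of defining parameters.
#' @export
setClass("ROIMask", contains = "MaskVolume",
  representation(provenance = "list"))

#' SubjectBetaSet: per-subject stimulus-by-voxel activation estimates
#'
#' Beta estimates for each stimulus presentation restricted to the in-mask
#' voxels, with stimulus ids aligned to the stimulus table. Row order is
#' required to be identical across subjects before any group analysis.
#'
#' @slot subjectId character(1).
#' @slot mask a [MaskVolume-class].
#' @slot beta numeric matrix, stimuli x in-mask voxels.
#' @slot stimulusIds character, one id per beta row.
#' @export
setClass("SubjectBetaSet",
  representation(subjectId = "character", mask = "MaskVolume",
                 beta = "matrix", stimulusIds = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@beta) != sum(object@mask@data))
      msg <- c(msg, sprintf("beta has %d columns but mask has %d voxels",
                            ncol(object@beta), sum(object@mask@data)))
    if (nrow(object@beta) != length(object@stimulusIds))
      msg <- c(msg, "one stimulus id required per beta row")
    if (anyDuplicated(object@stimulusIds))
      msg <- c(msg, "stimulus ids must be unique")
    if (length(msg)) msg else TRUE
  })

#' StatMap: a scalar statistic per in-mask voxel
#'
#' @slot mask a [MaskVolume-class].
#' @slot values numeric, one value per in-mask voxel (NA = undefined center).
#' @slot kind character(1): "fidelity", "rsa_coef", "t", "z", "p" or "other".
#' @export
setClass("StatMap",
  representation(mask = "MaskVolume", values = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) != sum(object@mask@data))
      msg <- c(msg, "values length must equal the number of in-mask voxels")
    if (any(is.infinite(object@values)))
      msg <- c(msg, "in-mask values must be finite or NA")
    if (!object@kind %in% c("fidelity", "rsa_coef", "t", "z", "p", "other"))
      msg <- c(msg, "unknown kind tag")
    if (length(msg)) msg else TRUE
  })

#' RDM: representational dissimilarity matrix
#'
#' Symmetric condition-by-condition dissimilarities with an exactly zero
#' diagonal; the atom of both the fidelity and the RSA analyses.
#'
#' @slot labels character condition ids (rownames of `D`).
#' @slot D numeric n x n matrix.
#' @export
setClass("RDM",
  representation(labels = "character", D = "matrix"),
  validity = function(object) {
    D <- object@D
    msg <- character()
    if (nrow(D) < 2L || nrow(D) != ncol(D))
      msg <- c(msg, "D must be square with n >= 2")
    if (length(object@labels) != nrow(D))
      msg <- c(msg, "one label per condition required")
    if (!all(is.finite(D)))
      msg <- c(msg, "D must be finite")
    else {
      if (any(diag(D) != 0))
        msg <- c(msg, "diagonal must be exactly zero")
      if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
        msg <- c(msg, "D must be symmetric")
    }
    if (length(msg)) msg else TRUE
  })

#' SearchlightSpec: spherical neighborhood specification
#'
#' @slot radius numeric(1), sphere radius in voxel units.
#' @slot minMembers integer(1), neighborhoods smaller than this are flagged.
#' @slot offsets integer matrix (k x 3) of lattice offsets with norm <= radius.
#' @export
setClass("SearchlightSpec",
  representation(radius = "numeric", minMembers = "integer",
                 offsets = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@radius < 0) msg <- c(msg, "radius must be >= 0")
    if (ncol(object@offsets) != 3L)
      msg <- c(msg, "offsets must have three columns")
    n2 <- rowSums(object@offsets^2)
    if (any(n2 > object@radius^2 + 1e-9))
      msg <- c(msg, "offsets must lie within the radius")
    if (!any(n2 == 0)) msg <- c(msg, "center offset (0,0,0) required")
    if (length(msg)) msg else TRUE
  })

#' RSAGroupResult: group-level RSA inference
#'
#' @slot tMap,zMap,pMap [StatMap-class]s of the group statistics.
#' @slot mask a [ROIMask-class] of cluster-corrected suprathreshold voxels.
#' @slot clusterTable data.frame with one row per suprathreshold cluster.
#' @slot params named list of thresholds, smoothing and permutation settings.
#' @export
setClass("RSAGroupResult",
  representation(tMap = "StatMap", zMap = "StatMap", pMap = "StatMap",
                 mask = "ROIMask", clusterTable = "data.frame",
                 params = "list"))

#' SynthGroundTruth: planted structure of a synthetic dataset
#'
#' @slot mask the analysis [MaskVolume-class].
#' @slot regionLabels integer per in-mask voxel; 0 = background, k = region k.
#' @slot regions list of per-region records (indices, source, effect, scores).
#' @slot params generating parameters echoed for provenance.
#' @export
setClass("SynthGroundTruth",
  representation(mask = "MaskVolume", regionLabels = "integer",
                 regions = "list", params = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@regionLabels) != sum(object@mask@data))
      msg <- c(msg, "one region label per in-mask voxel required")
    if (length(msg)) msg else TRUE
  })
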