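## NIfTI-1 and TSV plumbing. Volumes are exchanged as 32-bit float NIfTI,
## masks as 8-bit; affines are honored (sform, code 2).

niftiHeaderFor <- function(grid, datatype = "float") {
  aff <- grid@affine
  ## NIfTI srow maps 0-based voxel indices; ours are 1-based
  shift <- aff[1:3, 1:3] %*% c(1, 1, 1)
  list(pixdim = c(-1, grid@spacing, 1, 0, 0, 0),
       srow_x = c(aff[1, 1:3], aff[1, 4] + shift[1]),
       srow_y = c(aff[2, 1:3], aff[2, 4] + shift[2]),
       srow_z = c(aff[3, 1:3], aff[3, 4] + shift[3]),
       sform_code = 2L, qform_code = 0L)
}

gridFromNifti <- function(img) {
  d <- dim(img)[1:3]
  x <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(x), 4, 4)
  ## convert 0-based srow convention to 1-based voxel indices
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% c(1, 1, 1)
  spacing <- RNifti::pixdim(img)[1:3]
  volumeGrid(as.integer(d), spacing = as.numeric(spacing), affine = aff)
}

#' Write and read volumes on a grid
#'
#' `writeVolume` stores a 3D/4D array as 32-bit float NIfTI (8-bit for
#' logical data) with the grid affine; `readMaskVolume` loads a mask.
#'
#' @param arr numeric or logical array (3D, or 4D for beta sets).
#' @param grid a [VolumeGrid-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
writeVolume <- function(arr, grid, path) {
  dt <- if (is.logical(arr)) "uint8" else "float"
  if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr, niftiHeaderFor(grid), datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @param path input NIfTI path.
#' @export
readMaskVolume <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- gridFromNifti(img)
  maskVolume(grid, array(as.array(img) != 0, dim = grid@dims))
}

#' Read a stimulus table
#'
#' TSV with header; required columns `stimulus_id`, `word`, `transcription`
#' and `word_id`; any numeric property columns (concreteness, frequency,
#' ...) are carried along.
#'
#' @param path TSV path.
#' @return data.frame with one row per stimulus presentation.
#' @export
readStimulusTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("stimulus_id", "word", "transcription", "word_id")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("stimulus table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$stimulus_id))
    stop("stimulus_id values must be unique")
  tab
}

#' @rdname readStimulusTable
#' @param table stimulus table data.frame.
#' @export
writeStimulusTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-subject beta set
#'
#' Loads a 4D beta volume (one 3D frame per stimulus presentation), masks
#' it, and aligns frames with the stimulus table rows.
#'
#' @param volumePath 4D NIfTI of beta images.
#' @param maskPath 3D NIfTI analysis mask on the same grid.
#' @param tablePath stimulus table TSV (see [readStimulusTable()]).
#' @param subjectId subject identifier; defaults to the volume file name.
#' @return a [SubjectBetaSet-class].
#' @export
readBetaSet <- function(volumePath, maskPath, tablePath,
                        subjectId = basename(volumePath)) {
  img <- RNifti::readNifti(volumePath)
  if (length(dim(img)) != 4L)
    stop("expected a 4D beta volume, got dimensions ",
         paste(dim(img), collapse = "x"))
  mask <- readMaskVolume(maskPath)
  if (!identical(dim(img)[1:3], as.integer(mask@grid@dims)))
    stop(sprintf("volume grid %s does not match mask grid %s",
                 paste(dim(img)[1:3], collapse = "x"),
                 paste(mask@grid@dims, collapse = "x")))
  tab <- readStimulusTable(tablePath)
  if (dim(img)[4] != nrow(tab))
    stop(sprintf(
      "4D volume has %d frames but the stimulus table has %d rows",
      dim(img)[4], nrow(tab)))
  arr <- as.array(img)
  nvol <- dim(arr)[4]
  flat <- matrix(arr, ncol = nvol)        # voxels x frames
  beta <- t(flat[maskIndices(mask), , drop = FALSE])
  constCols <- apply(beta, 2, function(v) all(v == v[1]))
  if (any(constCols))
    warning(sum(constCols), " all-constant voxel(s) inside the mask")
  new("SubjectBetaSet", subjectId = subjectId, mask = mask, beta = beta,
      stimulusIds = as.character(tab$stimulus_id))
}

#' @rdname readBetaSet
#' @param betas a [SubjectBetaSet-class] to serialize.
#' @param volumePath output path for the 4D volume.
#' @export
writeBetaSet <- function(betas, volumePath) {
  dims <- betas@mask@grid@dims
  arr <- array(0, dim = c(dims, nrow(betas@beta)))
  idx <- maskIndices(betas@mask)
  nvox <- prod(dims)
  for (s in seq_len(nrow(betas@beta)))
    arr[(s - 1L) * nvox + idx] <- betas@beta[s, ]
  writeVolume(arr, betas@mask@grid, volumePath)
}

#' @rdname writeVolume
#' @param map a [StatMap-class] to serialize (out-of-mask voxels 0).
#' @export
writeStatMap <- function(map, path) {
  writeVolume(asVolume(map, fill = 0), map@mask@grid, path)
}

#' Write a peak table as TSV
#'
#' Columns `x,y,z,value,cluster_id,cluster_mm3` (world mm coordinates).
#'
#' @param peaks data.frame from [localExtrema()].
#' @param path output TSV path.
#' @export
writePeakTable <- function(peaks, path) {
  write.table(peaks[, c("x", "y", "z", "value", "cluster_id", "cluster_mm3")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average presentations into per-word patterns
#'
#' Equal-weight mean of each word's presentations (e.g. three per word);
#' word order follows first appearance among the stimulus ids.
#'
#' @param betas a [SubjectBetaSet-class] with one row per presentation.
#' @param repetitionMap named character: `stimulus_id -> word_id`.
#' @return a [SubjectBetaSet-class] with one row per word.
#' @export
averagePresentations <- function(betas, repetitionMap) {
  ids <- betas@stimulusIds
  unmapped <- setdiff(ids, names(repetitionMap))
  if (length(unmapped))
    stop("stimulus id(s) without a word_id: ",
         paste(head(unmapped, 5), collapse = ", "))
  words <- as.character(repetitionMap[ids])
  order_ <- unique(words)                 # first-appearance order
  out <- matrix(0, length(order_), ncol(betas@beta))
  for (w in seq_along(order_)) {
    rows <- which(words == order_[w])
    if (!length(rows)) stop("empty repetition group for word ", order_[w])
    out[w, ] <- colMeans(betas@beta[rows, , drop = FALSE])
  }
  new("SubjectBetaSet", subjectId = betas@subjectId, mask = betas@mask,
      beta = out, stimulusIds = order_)
}
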