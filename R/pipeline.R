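## Pipeline orchestration: fidelity -> mROI -> partial RSA -> ROI query ->
## laterality, with a JSON manifest of every artifact and parameter.

#' Validate pipeline inputs
#'
#' Report-only checks: shared grid and mask across subjects, identical
#' stimulus order, transcription coverage by the phoneme feature table,
#' and predictor collinearity (warned at |r| >= 0.7).
#'
#' @param betasets list of [SubjectBetaSet-class].
#' @param table stimulus table.
#' @param features phoneme feature table.
#' @return character vector of issues (empty when well-formed).
#' @export
validateInputs <- function(betasets, table,
                           features = phonemeFeatureTable()) {
  issues <- character()
  ref <- betasets[[1]]
  for (b in betasets[-1]) {
    if (!sameGrid(b@mask@grid, ref@mask@grid) ||
        !identical(b@mask@data, ref@mask@data))
      issues <- c(issues, paste0("subject ", b@subjectId,
                                 ": grid or mask differs from ",
                                 ref@subjectId))
    if (!identical(b@stimulusIds, ref@stimulusIds))
      issues <- c(issues, paste0("subject ", b@subjectId,
                                 ": stimulus order differs from ",
                                 ref@subjectId))
  }
  if (!setequal(ref@stimulusIds, table$stimulus_id))
    issues <- c(issues, "stimulus ids of betas and table disagree")
  phon <- unique(unlist(lapply(table$transcription, parseTranscription)))
  unknown <- setdiff(phon, features$phoneme)
  if (length(unknown))
    issues <- c(issues, paste0("transcription phoneme(s) not in feature ",
                               "table: ", paste(unknown, collapse = ", ")))
  wordTab <- table[!duplicated(table$word_id), , drop = FALSE]
  if (nrow(wordTab) >= 3 && !length(unknown)) {
    ortho <- vectorizeLower(pairwiseDistanceMatrix(
      wordTab$word, orthographicEditDistance, labels = wordTab$word_id))
    phono <- vectorizeLower(pairwiseDistanceMatrix(
      wordTab$transcription,
      function(a, b) phonologicalEditDistance(a, b, features),
      labels = wordTab$word_id))
    r <- cor(ortho, phono)
    if (is.finite(r) && abs(r) >= 0.7)
      issues <- c(issues, sprintf(
        "orthographic and phonological RDMs collinear (r = %.2f)", r))
  }
  issues
}

#' Run the full localization + RSA pipeline
#'
#' Averages presentations per word, maps representational fidelity and
#' defines the mROI, runs the partial-Spearman RSA searchlight for the
#' semantic target controlling orthography and phonology, performs group
#' inference, queries the top-fraction voxels of the ROIs, and computes
#' laterality indices. Writes every artifact plus a JSON manifest when
#' `outDir` is given. Idempotent given identical inputs and seed.
#'
#' @param betasets list of [SubjectBetaSet-class] (presentation-level).
#' @param table stimulus table (presentation-level).
#' @param outDir optional output directory.
#' @param radius searchlight radius in voxel units.
#' @param voxelPFidelity,extentVox mROI thresholds.
#' @param fwhm,voxelPRSA,clusterAlpha,nPerm group-RSA settings.
#' @param fraction top-fraction for ROI queries.
#' @param semanticColumn stimulus property defining the semantic RDM.
#' @param externalROI optional [ROIMask-class] (e.g. a distributed
#'   univariate localizer mask) compared against the mROI.
#' @param seed RNG seed for all stochastic steps.
#' @return list with mROI, group maps, query and laterality results, and
#'   the manifest.
#' @export
runPipeline <- function(betasets, table, outDir = NULL, radius = 3.0,
                        voxelPFidelity = 0.05, extentVox = 120L,
                        fwhm = 5, voxelPRSA = 0.005, clusterAlpha = 0.05,
                        nPerm = 1000L, fraction = 0.2,
                        semanticColumn = "concreteness",
                        externalROI = NULL, seed = 1L) {
  issues <- validateInputs(betasets, table)
  if (length(issues))
    stop("invalid inputs:\n  ", paste(issues, collapse = "\n  "))
  spec <- searchlightSpec(radius)
  repMap <- setNames(table$word_id, table$stimulus_id)
  perWord <- lapply(betasets, averagePresentations, repetitionMap = repMap)
  wordTab <- table[!duplicated(table$word_id), , drop = FALSE]

  fid <- fidelitySearchlight(perWord, spec)
  mroi <- defineMROI(fid$subjectMaps, voxelP = voxelPFidelity,
                     extentVox = extentVox)

  semantic <- vectorizeLower(propertyRDM(
    setNames(wordTab[[semanticColumn]], wordTab$word_id)))
  ortho <- vectorizeLower(pairwiseDistanceMatrix(
    wordTab$word, orthographicEditDistance, labels = wordTab$word_id))
  phono <- vectorizeLower(pairwiseDistanceMatrix(
    wordTab$transcription, phonologicalEditDistance,
    labels = wordTab$word_id))
  model <- partialRSAModel(semantic,
                           controls = list(orthographic = ortho,
                                           phonological = phono))
  coefMaps <- rsaSearchlight(perWord, model, spec)
  group <- groupRSA(coefMaps, fwhm = fwhm, voxelP = voxelPRSA,
                    clusterAlpha = clusterAlpha, nPerm = nPerm,
                    seed = seed)

  rois <- list(mROI = mroi)
  if (!is.null(externalROI)) {
    rois$uROI <- externalROI
    overlapArr <- mroi@data & externalROI@data
    if (any(overlapArr))
      rois$overlap <- roiMask(overlapArr, grid = mroi@grid,
                              provenance = list(source = "mROI&uROI"))
  }
  selected <- lapply(rois, function(r)
    topFraction(group@zMap, r, fraction))
  query <- compareRoiMeans(coefMaps, selected)
  laterality <- lapply(rois, lateralityIndex)
  overlap <- if (!is.null(externalROI)) overlapStats(mroi, externalROI)

  result <- list(mroi = mroi, fidelity = fid, group = group,
                 query = query, laterality = laterality,
                 overlap = overlap,
                 params = list(radius = radius,
                               voxelPFidelity = voxelPFidelity,
                               extentVox = extentVox, fwhm = fwhm,
                               voxelPRSA = voxelPRSA,
                               clusterAlpha = clusterAlpha, nPerm = nPerm,
                               fraction = fraction,
                               semanticColumn = semanticColumn,
                               seed = seed))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    artifacts <- list()
    w <- function(name, writer) {
      path <- file.path(outDir, name)
      writer(path)
      artifacts[[name]] <<- path
    }
    w("mroi.nii.gz", function(p) writeVolume(mroi@data, mroi@grid, p))
    w("fidelity_group.nii.gz", function(p) writeStatMap(fid$groupMap, p))
    w("rsa_group_z.nii.gz", function(p) writeStatMap(group@zMap, p))
    w("rsa_group_t.nii.gz", function(p) writeStatMap(group@tMap, p))
    w("rsa_mask.nii.gz", function(p)
      writeVolume(group@mask@data, group@mask@grid, p))
    w("clusters.tsv", function(p)
      write.table(group@clusterTable, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    w("roi_query.tsv", function(p)
      write.table(query$tests, p, sep = "\t", quote = FALSE,
                  row.names = FALSE))
    w("laterality.tsv", function(p)
      write.table(
        data.frame(roi = names(laterality),
                   VLeft = vapply(laterality, `[[`, 0, "VLeft"),
                   VRight = vapply(laterality, `[[`, 0, "VRight"),
                   LI = vapply(laterality, `[[`, 0, "LI")),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
    manifest <- list(artifacts = artifacts, params = result$params,
                     nSubjects = length(betasets),
                     issues = list())
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}
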