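## Synthetic multi-subject data with planted representational geometry.
## The generative model: in each planted region, stimulus scores F
## (standardized property values, multidimensional-scaling coordinates of
## an edit-distance RDM, or a shared random vector) project onto voxel
## loadings shared across subjects, so the regional pattern geometry is
## reproducible across subjects; nuisance latents are subject-specific
## and background voxels carry nuisance + noise only.

consonants <- c("P", "B", "T", "D", "K", "G", "F", "V", "S", "Z", "SH",
                "M", "N", "L", "R", "W")
vowels <- c("IY", "IH", "EH", "AE", "AA", "AO", "OW", "UW", "AH", "ER")

randomWord <- function(len) paste(sample(letters, len, TRUE), collapse = "")

randomTranscription <- function(nSyllables) {
  syll <- replicate(nSyllables,
                    paste(c(sample(consonants, 1), sample(vowels, 1),
                            if (runif(1) < 0.5) sample(consonants, 1)),
                          collapse = " "))
  paste(syll, collapse = " ")
}

#' Synthesize a stimulus table
#'
#' Draws an abstract/concrete word set whose property distributions mimic
#' a matched design: concreteness differs strongly between groups
#' (abstract 2.45 +- 0.59, concrete 4.79 +- 0.19, clipped to 1-5) while
#' log frequency, length and syllable counts are drawn from the same
#' distributions in both groups. Words are random letter strings and
#' transcriptions random pronounceable consonant-vowel sequences.
#'
#' @param nAbstract,nConcrete group sizes (default 128 and 64).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param nPresentations rows per word in the returned presentation-level
#'   table (default 3).
#' @return data.frame with columns stimulus_id, word_id, word,
#'   transcription, group, presentation, concreteness, frequency, length,
#'   syllables.
#' @export
synthStimuli <- function(nAbstract = 128, nConcrete = 64, seed,
                         nPresentations = 3) {
  if (nAbstract + nConcrete < 2) stop("need >= 2 words")
  set.seed(seed)
  n <- nAbstract + nConcrete
  group <- rep(c("abstract", "concrete"), c(nAbstract, nConcrete))
  conc <- ifelse(group == "abstract",
                 rnorm(n, 2.45, 0.59), rnorm(n, 4.79, 0.19))
  conc <- pmin(pmax(conc, 1), 5)
  len <- pmin(pmax(round(rnorm(n, 7.5, 2)), 3), 12)
  freq <- rnorm(n, 6.1, 1.7)
  syll <- pmin(pmax(round(rnorm(n, 2.5, 1)), 1), 4)
  words <- vapply(len, randomWord, character(1))
  while (anyDuplicated(words)) {
    dup <- duplicated(words)
    words[dup] <- vapply(len[dup], randomWord, character(1))
  }
  trans <- vapply(syll, randomTranscription, character(1))
  wordTab <- data.frame(
    word_id = sprintf("w%03d", seq_len(n)), word = words,
    transcription = trans, group = group, concreteness = conc,
    frequency = freq, length = nchar(words), syllables = syll,
    stringsAsFactors = FALSE)
  ## interleave groups so presentation order carries no group structure
  wordTab <- wordTab[sample(n), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nPresentations), function(p)
    transform(wordTab, presentation = p,
              stimulus_id = paste0(word_id, "_p", p))))
  rownames(out) <- NULL
  out[, c("stimulus_id", "word_id", "word", "transcription", "group",
          "presentation", "concreteness", "frequency", "length",
          "syllables")]
}

#' Voxel ball on a grid
#'
#' @param grid a [VolumeGrid-class].
#' @param centerIJK 1-based voxel coordinates of the ball center.
#' @param radiusVox radius in voxel units.
#' @return linear voxel indices.
#' @export
ballVoxels <- function(grid, centerIJK, radiusVox) {
  offs <- sphereOffsets(radiusVox)
  ijk <- offs + matrix(as.integer(centerIJK), nrow(offs), 3, byrow = TRUE)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= grid@dims[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= grid@dims[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= grid@dims[3]
  sort(ijkToLinear(grid@dims, ijk[ok, , drop = FALSE]))
}

#' Synthetic dataset configuration
#'
#' @param nSubjects number of subjects.
#' @param mask analysis [MaskVolume-class].
#' @param regions list of regions, each
#'   `list(name=, voxels=<linear indices>, source=, effect=)` with source
#'   one of "semantic", "phonological", "orthographic", "shared-random"
#'   and effect size w >= 0.
#' @param noiseSd presentation noise SD (> 0).
#' @param nLatent number of subject-specific nuisance latents.
#' @param nuisanceWeight scale of the nuisance latents.
#' @param nPresentations presentations per word.
#' @param seed mandatory RNG seed.
#' @return validated config list (class "synthConfig").
#' @export
synthConfig <- function(nSubjects, mask, regions = list(), noiseSd = 0.5,
                        nLatent = 3, nuisanceWeight = 0.3,
                        nPresentations = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  maskIdx <- maskIndices(mask)
  seen <- integer()
  for (r in regions) {
    if (!all(r$voxels %in% maskIdx))
      stop("region '", r$name, "' has voxels outside the mask")
    if (any(r$voxels %in% seen)) stop("regions must be disjoint")
    if (!is.finite(r$effect) || r$effect < 0)
      stop("region effect must be a finite nonnegative number")
    if (!r$source %in% c("semantic", "phonological", "orthographic",
                         "shared-random"))
      stop("unknown region source '", r$source, "'")
    seen <- c(seen, r$voxels)
  }
  structure(list(nSubjects = nSubjects, mask = mask, regions = regions,
                 noiseSd = noiseSd, nLatent = nLatent,
                 nuisanceWeight = nuisanceWeight,
                 nPresentations = nPresentations, seed = seed),
            class = "synthConfig")
}

regionScores <- function(source, wordTab) {
  switch(source,
    semantic = cbind(as.numeric(scale(wordTab$concreteness))),
    phonological = mdsScores(pairwiseDistanceMatrix(
      wordTab$transcription, phonologicalEditDistance,
      labels = wordTab$word_id)),
    orthographic = mdsScores(pairwiseDistanceMatrix(
      wordTab$word, orthographicEditDistance, labels = wordTab$word_id)),
    `shared-random` = cbind(rnorm(nrow(wordTab))))
}

## classical MDS embedding of an edit-distance RDM, 3 standardized
## components: turns pairwise distances into low-rank stimulus scores
mdsScores <- function(rdm, k = 3) {
  emb <- cmdscale(rdmMatrix(rdm), k = k)
  apply(emb, 2, function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v)
}

#' Generate synthetic multi-subject beta sets
#'
#' See the module header: planted regions carry stimulus scores times
#' voxel loadings shared across subjects (weight = effect size), all
#' voxels carry subject-specific low-rank nuisance structure, and each of
#' the presentations of a word is an independent noisy replicate of the
#' word's mean pattern.
#'
#' @param config a [synthConfig()].
#' @param table presentation-level stimulus table from [synthStimuli()].
#' @return list with `betasets` (list of [SubjectBetaSet-class]) and
#'   `groundTruth` (a [SynthGroundTruth-class]).
#' @export
synthBetas <- function(config, table) {
  stopifnot(inherits(config, "synthConfig"))
  set.seed(config$seed)
  mask <- config$mask
  maskIdx <- maskIndices(mask)
  V <- length(maskIdx)
  wordTab <- table[!duplicated(table$word_id), , drop = FALSE]
  nWords <- nrow(wordTab)
  ## shared (across-subject) components, drawn first so subject count
  ## does not perturb the planted geometry
  labels <- rep(0L, V)
  regions <- list()
  signal <- matrix(0, nWords, V)
  for (k in seq_along(config$regions)) {
    r <- config$regions[[k]]
    cols <- match(r$voxels, maskIdx)
    scores <- regionScores(r$source, wordTab)
    L <- matrix(rnorm(length(cols) * ncol(scores)), length(cols))
    signal[, cols] <- signal[, cols] + r$effect * scores %*% t(L)
    labels[cols] <- k
    planted <- switch(r$source,
      semantic = propertyRDM(wordTab$concreteness,
                             labels = wordTab$word_id),
      phonological = pairwiseDistanceMatrix(
        wordTab$transcription, phonologicalEditDistance,
        labels = wordTab$word_id),
      orthographic = pairwiseDistanceMatrix(
        wordTab$word, orthographicEditDistance,
        labels = wordTab$word_id),
      `shared-random` = propertyRDM(as.numeric(scores[, 1]),
                                    labels = wordTab$word_id))
    regions[[r$name %||% paste0("region", k)]] <-
      list(name = r$name %||% paste0("region", k), voxels = r$voxels,
           source = r$source, effect = r$effect, scores = scores,
           plantedRDM = planted)
  }
  presWords <- match(table$word_id, wordTab$word_id)
  betasets <- lapply(seq_len(config$nSubjects), function(s) {
    wordMean <- signal
    if (config$nLatent > 0) {
      G <- matrix(rnorm(nWords * config$nLatent), nWords)
      M <- matrix(rnorm(config$nLatent * V), config$nLatent)
      wordMean <- wordMean + config$nuisanceWeight * G %*% M
    }
    beta <- wordMean[presWords, , drop = FALSE] +
      matrix(rnorm(nrow(table) * V, sd = config$noiseSd), nrow(table))
    new("SubjectBetaSet", subjectId = sprintf("sub%02d", s), mask = mask,
        beta = beta, stimulusIds = as.character(table$stimulus_id))
  })
  gt <- new("SynthGroundTruth", mask = mask, regionLabels = labels,
            regions = regions,
            params = config[setdiff(names(config), "mask")])
  list(betasets = betasets, groundTruth = gt)
}

#' Searchlight-detectable extent of a planted region
#'
#' A center-assigned searchlight map attributes signal to every center
#' whose sphere overlaps informative voxels, so the recoverable footprint
#' of a planted region is its dilation by the searchlight radius
#' (restricted to the analysis mask). This is the appropriate
#' ground-truth target when scoring recovery of a center-indexed map.
#'
#' @param groundTruth a [SynthGroundTruth-class].
#' @param region region name or index.
#' @param radiusVox dilation radius (the searchlight radius; default 3).
#' @return a [ROIMask-class].
#' @export
detectableRegion <- function(groundTruth, region, radiusVox = 3.0) {
  reg <- groundTruth@regions[[region]]
  grid <- groundTruth@mask@grid
  offs <- sphereOffsets(radiusVox)
  ijk <- linearToIJK(grid@dims, reg$voxels)
  vol <- array(FALSE, dim = grid@dims)
  for (k in seq_len(nrow(offs))) {
    nb <- ijk + matrix(offs[k, ], nrow(ijk), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid@dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= grid@dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= grid@dims[3]
    vol[ijkToLinear(grid@dims, nb[ok, , drop = FALSE])] <- TRUE
  }
  vol <- vol & groundTruth@mask@data
  roiMask(vol, grid = grid,
          provenance = list(source = "detectableRegion", region = reg$name,
                            radiusVox = radiusVox))
}

setMethod("show", "SynthGroundTruth", function(object) {
  cat(sprintf("SynthGroundTruth: %d region(s) in %d mask voxels\n",
              length(object@regions), length(object@regionLabels)))
  for (r in object@regions)
    cat(sprintf("  %s: %d voxels, source %s, effect %.2f\n",
                r$name, length(r$voxels), r$source, r$effect))
})

fixtureDesigns <- list(
  tiny = list(nSubjects = 4, dims = c(12L, 12L, 12L), maskRadius = 4.5,
              nAbstract = 16, nConcrete = 8, seed = 101,
              regions = list(
                list(name = "semantic", center = c(5, 6, 6),
                     radius = 2.0, source = "semantic", effect = 1.0))),
  demo = list(nSubjects = 12, dims = c(24L, 24L, 24L), maskRadius = 9.5,
              nAbstract = 64, nConcrete = 32, seed = 202,
              regions = list(
                list(name = "semantic", center = c(7, 12, 12),
                     radius = 3.3, source = "semantic", effect = 1.0),
                list(name = "phonological", center = c(18, 13, 13),
                     radius = 3.3, source = "phonological",
                     effect = 1.0))))

#' Build a synthetic fixture bundle
#'
#' `tiny` (4 subjects, 12^3 grid, 24 words) is sized for unit tests;
#' `demo` (12 subjects, 24^3 grid, 96 words, planted semantic and
#' phonological regions of ~150 voxels each, effect 1.0, noise 0.5) for
#' end-to-end parameter-recovery runs. Deterministic given the built-in
#' seeds; pass `seed` to draw an independent replicate of the same
#' design.
#'
#' @param size "tiny" or "demo".
#' @param dir optional directory: when given, volumes (NIfTI), the
#'   stimulus table (TSV) and a ground-truth/config sidecar (YAML) are
#'   written there.
#' @param seed overrides the built-in seed.
#' @return list `betasets`, `table`, `mask`, `groundTruth`, `config`
#'   (plus `paths` when `dir` is given).
#' @export
makeFixture <- function(size = c("tiny", "demo"), dir = NULL, seed = NULL) {
  size <- match.arg(size)
  d <- fixtureDesigns[[size]]
  if (!is.null(seed)) d$seed <- seed
  grid <- volumeGrid(d$dims)
  center <- (d$dims + 1) / 2
  offs <- sphereOffsets(d$maskRadius)
  maskArr <- array(FALSE, dim = d$dims)
  ijk <- offs + matrix(as.integer(round(center)), nrow(offs), 3,
                       byrow = TRUE)
  maskArr[ijkToLinear(d$dims, ijk)] <- TRUE
  mask <- maskVolume(grid, maskArr)
  table <- synthStimuli(d$nAbstract, d$nConcrete, seed = d$seed)
  regions <- lapply(d$regions, function(r)
    list(name = r$name, voxels = ballVoxels(grid, r$center, r$radius),
         source = r$source, effect = r$effect))
  config <- synthConfig(d$nSubjects, mask, regions = regions,
                        noiseSd = 0.5, seed = d$seed + 1)
  sim <- synthBetas(config, table)
  out <- list(betasets = sim$betasets, table = table, mask = mask,
              groundTruth = sim$groundTruth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(mask = file.path(dir, "mask.nii.gz"),
                  table = file.path(dir, "stimuli.tsv"),
                  truth = file.path(dir, "ground_truth.yaml"))
    writeVolume(mask@data, grid, paths$mask)
    writeStimulusTable(table, paths$table)
    paths$betas <- vapply(sim$betasets, function(b) {
      p <- file.path(dir, paste0(b@subjectId, "_betas.nii.gz"))
      writeBetaSet(b, p)
      p
    }, character(1))
    gt <- sim$groundTruth
    yaml::write_yaml(list(
      size = size, seed = d$seed,
      regions = lapply(gt@regions, function(r)
        list(name = r$name, source = r$source, effect = r$effect,
             voxels = as.integer(r$voxels))),
      params = gt@params[c("nSubjects", "noiseSd", "nLatent",
                           "nuisanceWeight", "nPresentations", "seed")]),
      paths$truth)
    out$paths <- paths
  }
  out
}
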