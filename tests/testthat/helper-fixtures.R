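# shared generators for small in-code fixtures

randomRDM <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- runif(n * (n - 1) / 2)
  rdm(D + t(D))
}

# betasets with independent noise on a small full grid
noiseBetaSets <- function(nSubjects, nStim, dims = c(6L, 6L, 6L),
                          seed = 1) {
  set.seed(seed)
  grid <- volumeGrid(dims)
  mask <- maskVolume(grid, array(TRUE, dim = dims))
  lapply(seq_len(nSubjects), function(s)
    new("SubjectBetaSet", subjectId = paste0("s", s), mask = mask,
        beta = matrix(rnorm(nStim * prod(dims)), nStim),
        stimulusIds = paste0("stim", seq_len(nStim))))
}

# subject statistic maps filled from a function(subject) -> values
mapsFrom <- function(mask, n, fn, kind = "rsa_coef") {
  lapply(seq_len(n), function(s) statMap(mask, fn(s), kind = kind))
}

# random pseudo-lexicon over letters that map one-to-one onto phonemes,
# so orthographic and phonological sequences are structurally identical
pseudoLexicon <- function(nWords, seed) {
  set.seed(seed)
  letter2phoneme <- c(p = "P", b = "B", t = "T", d = "D", k = "K",
                      g = "G", m = "M", n = "N", s = "S", z = "Z")
  words <- replicate(nWords, paste(
    sample(names(letter2phoneme), sample(3:7, 1), TRUE), collapse = ""))
  words <- make.unique(words, sep = "")
  trans <- vapply(strsplit(words, ""), function(ch)
    paste(letter2phoneme[ch], collapse = " "), character(1))
  list(words = words, transcriptions = trans)
}

# feature table in which every consonant differs from every other on both
# place and manner, forcing all substitution costs to 1
unitCostFeatures <- function() {
  p <- c("P", "B", "T", "D", "K", "G", "M", "N", "S", "Z")
  data.frame(phoneme = p,
             class = "consonant",
             place = paste0("pl", seq_along(p)),
             manner = paste0("mn", seq_along(p)),
             voicing = "voiced", height = NA, backness = NA,
             row.names = p, stringsAsFactors = FALSE)
}
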