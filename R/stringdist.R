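## Orthographic and phonological edit distances. Both run through the same
## dynamic-programming core; the phonological variant weights substitutions
## by phonetic-feature mismatch (place/manner for consonants,
## height/backness for vowels), which attenuates the correlation between
## orthographic and phonological dissimilarity structure.

editDistanceDP <- function(a, b, subCost) {
  n <- length(a); m <- length(b)
  prev <- as.numeric(0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1,       # deletion
                         cur[j] + 1,             # insertion
                         prev[j] + subCost(a[i], b[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Orthographic edit distance
#'
#' Standard Levenshtein distance between case-folded letter strings with
#' unit insertion, deletion and substitution costs: the number of edits
#' needed to make the pair identical (e.g. "bullet" vs "wallet" is 2).
#'
#' @param s1,s2 character strings (empty allowed).
#' @return nonnegative integer edit distance.
#' @examples
#' orthographicEditDistance("bullet", "wallet")  # 2
#' orthographicEditDistance("wallet", "jacket")  # 3
#' @export
orthographicEditDistance <- function(s1, s2) {
  a <- strsplit(tolower(s1), "")[[1]]
  b <- strsplit(tolower(s2), "")[[1]]
  as.integer(editDistanceDP(a, b, function(x, y) if (x == y) 0 else 1))
}

#' Phoneme feature table
#'
#' Loads the packaged phoneme feature table (ARPABET-style symbols with
#' class, place, manner, voicing, height and backness), or a user table
#' with the same columns.
#'
#' @param path optional TSV path overriding the packaged table.
#' @return data.frame keyed by `phoneme`.
#' @export
phonemeFeatureTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phoneme_features.tsv",
                        package = "replocal")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("phoneme", "class", "place", "manner", "voicing",
           "height", "backness")
  if (!all(req %in% names(tab)))
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(tab$phoneme)) stop("duplicate phoneme symbols")
  rownames(tab) <- tab$phoneme
  tab
}

## full phoneme-pair substitution cost matrix; memoized on the feature
## table so pairwise RDM construction pays the table scan only once
phonemeCostMatrix <- local({
  cacheKey <- NULL
  cacheVal <- NULL
  function(features, includeVoicing = FALSE) {
    key <- list(features, includeVoicing)
    if (identical(key, cacheKey)) return(cacheVal)
    p <- features$phoneme
    n <- length(p)
    mismatch <- function(col) outer(features[[col]], features[[col]], "!=")
    consPair <- outer(features$class == "consonant",
                      features$class == "consonant", "&")
    vowPair <- outer(features$class == "vowel", features$class == "vowel",
                     "&")
    nFeat <- if (includeVoicing) 3 else 2
    cost <- matrix(1, n, n, dimnames = list(p, p))
    consCost <- mismatch("place") + mismatch("manner")
    vowCost <- mismatch("height") + mismatch("backness")
    if (includeVoicing) {
      consCost <- consCost + mismatch("voicing")
      vowCost <- vowCost + mismatch("voicing")
    }
    cost[consPair] <- consCost[consPair] / nFeat
    cost[vowPair] <- vowCost[vowPair] / nFeat
    diag(cost) <- 0
    cacheKey <<- key
    cacheVal <<- cost
    cost
  }
})

#' Phonological edit distance
#'
#' Edit distance over phoneme sequences where substituting one phoneme for
#' another costs the fraction of mismatching phonetic features: place and
#' manner of articulation for consonant pairs, height and backness for
#' vowel pairs (0, 0.5 or 1), and 1 across classes. Insertions and
#' deletions cost 1, so the distance reduces to plain phoneme-level
#' Levenshtein when all substitution costs are forced to 1.
#'
#' @param t1,t2 transcriptions: character vectors of phoneme symbols, or
#'   single space-separated strings.
#' @param features feature table from [phonemeFeatureTable()].
#' @param includeVoicing also count voicing as a feature (default FALSE).
#' @return nonnegative real distance.
#' @export
phonologicalEditDistance <- function(t1, t2,
                                     features = phonemeFeatureTable(),
                                     includeVoicing = FALSE) {
  a <- parseTranscription(t1)
  b <- parseTranscription(t2)
  unknown <- setdiff(c(a, b), features$phoneme)
  if (length(unknown))
    stop("unknown phoneme symbol(s): ", paste(unknown, collapse = ", "))
  cost <- phonemeCostMatrix(features, includeVoicing)
  ai <- match(a, features$phoneme)
  bi <- match(b, features$phoneme)
  n <- length(ai); m <- length(bi)
  prev <- as.numeric(0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i
    costRow <- cost[ai[i], ]
    for (j in seq_len(m))
      cur[j + 1L] <- min(prev[j + 1L] + 1, cur[j] + 1,
                         prev[j] + costRow[bi[j]])
    prev <- cur
  }
  prev[m + 1L]
}

parseTranscription <- function(t) {
  if (length(t) == 1L && is.character(t)) {
    out <- strsplit(trimws(t), "[ .]+")[[1]]
    out[nzchar(out)]
  } else as.character(t)
}

#' Pairwise distance matrix
#'
#' Applies a symmetric distance function to every item pair, yielding a
#' predicted [RDM-class] (zero diagonal, symmetric).
#'
#' @param items list or vector of items.
#' @param distanceFn function of two items returning a nonnegative scalar.
#' @param labels condition labels (default: the items themselves).
#' @return an [RDM-class].
#' @export
pairwiseDistanceMatrix <- function(items, distanceFn, labels = NULL) {
  n <- length(items)
  if (n < 2L) stop("need at least 2 items")
  if (is.null(labels))
    labels <- if (is.character(items)) items else paste0("item", seq_len(n))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(distanceFn(items[[i]], items[[j]]),
                    error = function(e)
                      stop(sprintf("distance failed for pair (%s, %s): %s",
                                   labels[i], labels[j], conditionMessage(e)),
                           call. = FALSE))
      D[i, j] <- D[j, i] <- d
    }
  }
  rdm(D, labels = as.character(labels))
}
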