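## Construction, vectorization and comparison of representational
## dissimilarity matrices (RDMs), observed (neural) and predicted.

#' Construct an RDM
#'
#' @param D symmetric numeric matrix with zero diagonal.
#' @param labels condition ids (default from dimnames or cond1..condN).
#' @return an [RDM-class].
#' @export
rdm <- function(D, labels = NULL) {
  if (is.null(labels))
    labels <- if (!is.null(rownames(D))) rownames(D)
              else paste0("cond", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  new("RDM", labels = as.character(labels), D = D)
}

#' @rdname rdm
#' @param x an [RDM-class].
#' @return `rdmMatrix`: the dissimilarity matrix; `rdmLabels`: its labels.
#' @export
rdmMatrix <- function(x) x@D

#' @rdname rdm
#' @export
rdmLabels <- function(x) x@labels

setMethod("show", "RDM", function(object) {
  cat(sprintf("RDM: %d conditions, dissimilarity range %.4g..%.4g\n",
              nrow(object@D), min(object@D[lower.tri(object@D)]),
              max(object@D)))
})

#' Z-score betas across stimuli
#'
#' Standardizes each voxel column to mean 0 and sample SD 1 across
#' stimuli, the normalization applied before the RSA searchlight.
#' Zero-variance voxels cannot be standardized; they are set to NA and
#' reported via a warning so downstream searchlights can skip them.
#'
#' @param betas a [SubjectBetaSet-class] (>= 2 stimuli).
#' @return a [SubjectBetaSet-class] with standardized columns.
#' @export
zscoreAcrossStimuli <- function(betas) {
  X <- betas@beta
  if (nrow(X) < 2L) stop("need >= 2 stimuli to z-score")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  bad <- s == 0 | !is.finite(s)
  if (any(bad)) {
    warning(sum(bad), " zero-variance voxel(s) set to NA for subject ",
            betas@subjectId)
    s[bad] <- NA_real_
  }
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  methods::initialize(betas, beta = Xs)
}

#' Neural RDM from activation patterns
#'
#' Dissimilarity between stimulus patterns is 1 - Pearson correlation of
#' their voxel vectors (correlation distance); squared Euclidean distance
#' is available as an alternative metric.
#'
#' @param patterns stimulus x voxel matrix (>= 2 rows, >= 2 columns).
#' @param labels condition ids (default rownames).
#' @param metric "correlation" (default) or "euclidean".
#' @return an [RDM-class].
#' @export
neuralRDM <- function(patterns, labels = rownames(patterns),
                      metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(patterns) < 2L || ncol(patterns) < 2L)
    stop("patterns must be at least 2 stimuli x 2 voxels")
  if (is.null(labels)) labels <- paste0("stim", seq_len(nrow(patterns)))
  if (metric == "correlation") {
    s <- apply(patterns, 1, sd)
    if (any(s == 0))
      stop("zero-variance pattern for stimulus ",
           paste(labels[s == 0], collapse = ", "))
    D <- 1 - cor(t(patterns))
  } else {
    D <- as.matrix(stats::dist(patterns))
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2                     # exact symmetry
  rdm(D, labels = labels)
}

#' Predicted RDM from a scalar stimulus property
#'
#' Dissimilarity is the absolute difference of the property values, e.g.
#' pairwise differences in rated concreteness.
#'
#' @param values named numeric, one value per stimulus.
#' @param labels condition ids (default names of `values`).
#' @return an [RDM-class].
#' @export
propertyRDM <- function(values, labels = names(values)) {
  if (length(values) < 2L) stop("need >= 2 values")
  if (is.null(labels)) labels <- paste0("stim", seq_along(values))
  if (any(is.na(values)))
    stop("missing property value for stimulus ",
         paste(labels[is.na(values)], collapse = ", "))
  D <- abs(outer(values, values, "-"))
  dimnames(D) <- NULL
  rdm(D, labels = labels)
}

#' Per-subject familiarity RDM from binary responses
#'
#' Each word's 0/1 familiarity responses are averaged over its available
#' presentations; dissimilarity is the absolute difference of the means.
#' Words with no valid response are dropped with a warning, shrinking the
#' label set.
#'
#' @param responses word x presentation matrix of 0/1 (NA = no response).
#' @param labels word ids (default rownames).
#' @return an [RDM-class].
#' @export
familiarityRDM <- function(responses, labels = rownames(responses)) {
  if (is.null(labels)) labels <- paste0("word", seq_len(nrow(responses)))
  means <- rowMeans(responses, na.rm = TRUE)
  valid <- rowSums(!is.na(responses)) > 0
  if (!all(valid)) {
    warning("dropping word(s) with no valid response: ",
            paste(labels[!valid], collapse = ", "))
    means <- means[valid]
    labels <- labels[valid]
  }
  propertyRDM(means, labels = labels)
}

#' Vectorize the lower triangle of an RDM
#'
#' Strictly-lower-triangle entries in column order (pairs (2,1), (3,1),
#' ..., (n,1), (3,2), ...), the fixed convention used by every RDM
#' comparison in the package. `devectorizeLower` reconstructs the RDM.
#'
#' @param x an [RDM-class].
#' @return numeric vector of length n(n-1)/2 with attributes `labels`, `n`.
#' @export
vectorizeLower <- function(x) {
  D <- x@D
  v <- D[lower.tri(D)]
  attr(v, "labels") <- x@labels
  attr(v, "n") <- nrow(D)
  v
}

#' @rdname vectorizeLower
#' @param v vector produced by `vectorizeLower`.
#' @export
devectorizeLower <- function(v) {
  n <- attr(v, "n")
  if (is.null(n)) n <- (1 + sqrt(1 + 8 * length(v))) / 2
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- as.numeric(v)
  D <- D + t(D)
  labels <- attr(v, "labels")
  rdm(D, labels = if (is.null(labels)) paste0("cond", 1:n) else labels)
}

#' Elementwise mean of RDMs
#'
#' @param rdms list of [RDM-class] with identical labels in the same order.
#' @return an [RDM-class].
#' @export
averageRDMs <- function(rdms) {
  labs <- rdmLabels(rdms[[1]])
  bad <- which(!vapply(rdms, function(r) identical(rdmLabels(r), labs),
                       logical(1)))
  if (length(bad))
    stop("RDM label mismatch at position(s): ", paste(bad, collapse = ", "))
  D <- Reduce(`+`, lapply(rdms, rdmMatrix)) / length(rdms)
  rdm(D, labels = labs)
}

#' Correlation between two vectorized RDMs
#'
#' @param a,b numeric vectors of equal length >= 3 (e.g. from
#'   [vectorizeLower()]).
#' @param method "pearson" or "spearman" (average ranks for ties).
#' @return correlation in `[-1, 1]`, or NA when either vector has zero
#'   variance.
#' @export
rdmCorrelation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b) || length(a) < 3L)
    stop("vectors must have equal length >= 3")
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(as.numeric(a), as.numeric(b), method = method)
}
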