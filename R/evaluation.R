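#' Jaccard index of two protein sets
#'
#' \eqn{J(x, k) = |x \cap k| / |x \cup k|}.
#'
#' @param x,k non-empty character vectors.
#' @return Numeric in [0, 1].
#' @examples
#' jaccard(c("A", "B"), c("A", "C"))  # 1/3
#' @export
jaccard <- function(x, k) {
  inter <- length(intersect(x, k))
  inter / (length(unique(x)) + length(unique(k)) - inter)
}

#' Geometric-mean overlap ratio of two protein sets
#'
#' \eqn{|x \cap k| / \sqrt{|x| |k|}}; the other common matching score
#' besides the Jaccard index. For two size-2 sets sharing one protein it
#' is 1/2 while the Jaccard index is 1/3, which is why small clusters are
#' matched exactly rather than by a low threshold.
#'
#' @inheritParams jaccard
#' @return Numeric in [0, 1].
#' @export
overlapRatio <- function(x, k) {
  x <- unique(x); k <- unique(k)
  length(intersect(x, k)) / sqrt(length(x) * length(k))
}

#' Predicted clusters matching a complex set
#'
#' The clusters in \code{Xs} whose Jaccard index with at least one
#' complex in \code{Ks} reaches the threshold \code{eta}.
#'
#' @param Xs list of character vectors (predicted clusters) or a
#'   [ClusterSet-class].
#' @param Ks list of character vectors (known complexes) or a
#'   [ClusterSet-class].
#' @param eta matching threshold in (0, 1].
#' @return The matching subset of \code{Xs}, as a list.
#' @export
matchedPredictions <- function(Xs, Ks, eta) {
  if (is(Xs, "ClusterSet")) Xs <- clusters(Xs)
  if (is(Ks, "ClusterSet")) Ks <- clusters(Ks)
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  Filter(function(x) any(vapply(Ks, jaccard, 0, x = x) >= eta), Xs)
}

#' Known complexes matched by a prediction set
#'
#' Mirror of [matchedPredictions()]: the complexes in \code{Ks} whose
#' Jaccard index with at least one cluster in \code{Xs} reaches
#' \code{eta}.
#'
#' @inheritParams matchedPredictions
#' @return The matched subset of \code{Ks}, as a list.
#' @export
matchedComplexes <- function(Xs, Ks, eta) {
  if (is(Xs, "ClusterSet")) Xs <- clusters(Xs)
  if (is(Ks, "ClusterSet")) Ks <- clusters(Ks)
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  Filter(function(k) any(vapply(Xs, jaccard, 0, k = k) >= eta), Ks)
}

#' Size-stratified evaluation against a complex catalogue
#'
#' Matches predictions and complexes within three hard size strata:
#' size-2 against size-2 and size-3 against size-3 require an exact match
#' (Jaccard threshold 1), while size >= 4 against size >= 4 requires
#' Jaccard >= 0.5. Cross-stratum matches are impossible by construction.
#' Precision is the fraction of predictions matched in their stratum,
#' recall the fraction of complexes matched, and the F-measure their
#' harmonic mean. An empty prediction set (or catalogue) yields
#' precision (recall) 0.
#'
#' @param X predicted [ClusterSet-class].
#' @param K known-complex [ClusterSet-class].
#' @return An [EvalReport-class].
#' @examples
#' X <- clusterSet(list(c("A", "B")))
#' K <- clusterSet(list(c("A", "B"), c("C", "D", "E")))
#' evaluateClusters(X, K)  # precision 1, recall 0.5, F 2/3
#' @export
evaluateClusters <- function(X, K) {
  xs <- clusters(X)
  ks <- clusters(K)
  strat <- function(cl) {
    sz <- lengths(cl)
    list(cl[sz == 2L], cl[sz == 3L], cl[sz >= 4L])
  }
  sx <- strat(xs)
  sk <- strat(ks)
  eta <- c(1, 1, 0.5)
  mp <- integer(3L)
  mk <- integer(3L)
  for (i in 1:3) {
    mp[i] <- length(matchedPredictions(sx[[i]], sk[[i]], eta[i]))
    mk[i] <- length(matchedComplexes(sx[[i]], sk[[i]], eta[i]))
  }
  precision <- if (length(xs)) sum(mp) / length(xs) else 0
  recall <- if (length(ks)) sum(mk) / length(ks) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  new("EvalReport",
      precision = precision, recall = recall, fMeasure = f,
      matchedPredictionsByStratum = structure(mp,
        names = c("size2", "size3", "size4plus")),
      matchedComplexesByStratum = structure(mk,
        names = c("size2", "size3", "size4plus")),
      nPredicted = length(xs), nKnown = length(ks))
}

#' @describeIn EvalReport-class precision of the report.
#' @param object an \code{EvalReport}.
#' @export
setGeneric("precision", function(object) standardGeneric("precision"))

#' @rdname EvalReport-class
#' @export
setMethod("precision", "EvalReport", function(object) object@precision)

#' @describeIn EvalReport-class recall of the report.
#' @export
setGeneric("recall", function(object) standardGeneric("recall"))

#' @rdname EvalReport-class
#' @export
setMethod("recall", "EvalReport", function(object) object@recall)

#' @describeIn EvalReport-class F-measure of the report.
#' @export
setGeneric("fMeasure", function(object) standardGeneric("fMeasure"))

#' @rdname EvalReport-class
#' @export
setMethod("fMeasure", "EvalReport", function(object) object@fMeasure)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", object@nPredicted, "predictions vs",
      object@nKnown, "known complexes\n")
  cat(sprintf("  precision %.4f | recall %.4f | F %.4f\n",
              object@precision, object@recall, object@fMeasure))
  cat("  matched predictions (2 / 3 / >=4):",
      paste(object@matchedPredictionsByStratum, collapse = " / "), "\n")
  cat("  matched complexes   (2 / 3 / >=4):",
      paste(object@matchedComplexesByStratum, collapse = " / "), "\n")
})

#' Overlap statistics of a complex catalogue
#'
#' Tallies, over every unordered pair of distinct complexes with a
#' non-empty intersection, the size of the intersection. Also reports the
#' number of overlapping pairs and the number of distinct complexes
#' involved in at least one overlapping pair.
#'
#' @param K a [ClusterSet-class] catalogue.
#' @return A list with \code{histogram} (integer counts named by overlap
#'   size), \code{nPairs} and \code{nComplexesInvolved}.
#' @examples
#' K <- clusterSet(list(c("A", "B"), c("B", "C"), c("C", "D")))
#' overlapHistogram(K)  # two pairs of overlap size 1, 3 complexes
#' @export
overlapHistogram <- function(K) {
  cl <- clusters(K)
  n <- length(cl)
  sizes <- integer(0)
  involved <- logical(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- length(intersect(cl[[i]], cl[[j]]))
        if (ov > 0L) {
          sizes <- c(sizes, ov)
          involved[i] <- TRUE
          involved[j] <- TRUE
        }
      }
    }
  }
  hist <- integer(0)
  if (length(sizes)) {
    tb <- table(sizes)
    hist <- structure(as.integer(tb), names = names(tb))
  }
  list(histogram = hist, nPairs = length(sizes),
       nComplexesInvolved = sum(involved))
}
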