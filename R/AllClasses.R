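#' @import methods
NULL

#' Weighted protein-protein interaction network
#'
#' An undirected, edge-weighted graph whose nodes are proteins and whose
#' edges are interactions. Weights are interaction reliabilities in
#' \eqn{(0, 1]}; a non-edge has weight 0 by convention. Self-loops are
#' forbidden and every edge is stored once with its endpoints ordered by
#' node index.
#'
#' @slot nodes character vector of protein identifiers (opaque strings).
#' @slot edgeMat integer matrix with two columns; each row holds the node
#'   indices of one edge, first index smaller than the second.
#' @slot weights numeric vector of edge weights, parallel to the rows of
#'   \code{edgeMat}.
#'
#' @seealso [ppiNetwork()], [loadPPINetwork()]
#' @export
setClass("PPINetwork",
  representation(
    nodes = "character",
    edgeMat = "matrix",
    weights = "numeric"
  )
)

setValidity("PPINetwork", function(object) {
  msgs <- character(0)
  n <- length(object@nodes)
  em <- object@edgeMat
  w <- object@weights
  if (anyDuplicated(object@nodes)) {
    msgs <- c(msgs, "duplicated node identifiers")
  }
  if (!is.integer(em) || ncol(em) != 2L) {
    msgs <- c(msgs, "edgeMat must be a two-column integer matrix")
  } else {
    if (nrow(em) != length(w)) {
      msgs <- c(msgs, "weights must be parallel to edgeMat rows")
    }
    if (nrow(em) > 0L) {
      if (any(em < 1L) || any(em > n)) {
        msgs <- c(msgs, "edge endpoint index out of range")
      } else {
        if (any(em[, 1L] == em[, 2L])) {
          msgs <- c(msgs, "self-loops are not allowed")
        }
        if (any(em[, 1L] > em[, 2L])) {
          msgs <- c(msgs, "edge endpoints must be ordered (i < j)")
        }
        if (anyDuplicated(em) > 0L) {
          msgs <- c(msgs, "duplicate edges are not allowed")
        }
      }
      if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
        msgs <- c(msgs, "edge weights must lie in (0, 1]")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of predicted clusters or known complexes
#'
#' A collection of protein sets, each of size at least two. Clusters may
#' overlap (share proteins) but no two stored clusters may have identical
#' member sets. The same container represents predicted cluster sets and
#' gold-standard complex catalogues.
#'
#' @slot clusters list of character vectors; each vector holds the sorted,
#'   unique member identifiers of one cluster.
#'
#' @seealso [clusterSet()], [readClusterSet()]
#' @export
setClass("ClusterSet", representation(clusters = "list"))

setValidity("ClusterSet", function(object) {
  cl <- object@clusters
  msgs <- character(0)
  for (x in cl) {
    if (!is.character(x)) {
      msgs <- c(msgs, "every cluster must be a character vector")
      break
    }
    if (length(x) < 2L) {
      msgs <- c(msgs, "every cluster must have at least two members")
      break
    }
    if (anyDuplicated(x)) {
      msgs <- c(msgs, "cluster members must be distinct")
      break
    }
    if (is.unsorted(x)) {
      msgs <- c(msgs, "cluster members must be stored sorted")
      break
    }
  }
  if (!length(msgs) && length(cl) > 1L) {
    keys <- vapply(cl, paste, "", collapse = "\t")
    if (anyDuplicated(keys)) {
      msgs <- c(msgs, "duplicate clusters (identical member sets) are not allowed")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Coefficients and constants of the cluster-set score
#'
#' Holds every tunable of the regularized score \eqn{f(X, \gamma)}: the
#' cluster-size cap, the overlap-ratio cap \eqn{\beta}, the coefficients of
#' the overlap, size-distribution, exponent-prior and protein-count
#' regularizers, and the prior center \eqn{\gamma_0} of the power-law
#' scaling exponent. Defaults are the values selected for the largest
#' published yeast compendium analysis.
#'
#' @slot sMax integer; maximum allowed cluster size (default 100).
#' @slot beta numeric in (0,1); maximum tolerated overlap-to-minimum-size
#'   ratio for two clusters of size >= 4 (default 0.2).
#' @slot cCluDis numeric >= 0; coefficient of the pairwise overlap
#'   penalty (default 110).
#' @slot cCluSize numeric >= 0; coefficient of the size-distribution
#'   penalty (default 500).
#' @slot cHy numeric >= 0; coefficient of the quadratic prior on the
#'   scaling exponent (default 10).
#' @slot cProNum numeric >= 0; coefficient of the squared clustered-protein
#'   count (default 5e-5).
#' @slot gamma0 numeric; prior center of the scaling exponent
#'   (default 2.5, the median of the typical power-law range (2,3)).
#'
#' @seealso [scoreParams()], [totalScore()]
#' @export
setClass("ScoreParams",
  representation(
    sMax = "integer", beta = "numeric",
    cCluDis = "numeric", cCluSize = "numeric",
    cHy = "numeric", cProNum = "numeric",
    gamma0 = "numeric"
  )
)

setValidity("ScoreParams", function(object) {
  msgs <- character(0)
  if (length(object@sMax) != 1L || object@sMax < 2L) {
    msgs <- c(msgs, "sMax must be a single integer >= 2")
  }
  if (length(object@beta) != 1L || object@beta <= 0 || object@beta >= 1) {
    msgs <- c(msgs, "beta must lie strictly between 0 and 1")
  }
  for (nm in c("cCluDis", "cCluSize", "cHy", "cProNum")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      msgs <- c(msgs, paste(nm, "must be a single finite value >= 0"))
    }
  }
  if (length(object@gamma0) != 1L || !is.finite(object@gamma0)) {
    msgs <- c(msgs, "gamma0 must be a single finite value")
  }
  if (length(msgs)) msgs else TRUE
})

#' Additive breakdown of the cluster-set score
#'
#' The six components of \eqn{f(X, \gamma)} together with the
#' coefficient-weighted total. \code{b} (feasibility) and \code{dis}
#' (overlap penalty) may be \code{Inf}; the total is \code{Inf} exactly
#' when one of them is.
#'
#' @slot b numeric; 0 if every cluster is connected and within the size
#'   cap, \code{Inf} otherwise.
#' @slot den numeric; negative sum of generalized cluster densities.
#' @slot dis numeric; sum of pairwise overlap penalties (may be \code{Inf}).
#' @slot size numeric; squared-error between the empirical and power-law
#'   cluster-size distributions.
#' @slot hy numeric; squared deviation of the scaling exponent from its
#'   prior center.
#' @slot pro numeric; squared count of distinct clustered proteins.
#' @slot total numeric; \code{b + den + cCluDis*dis + cCluSize*size +
#'   cHy*hy + cProNum*pro}.
#'
#' @seealso [totalScore()]
#' @export
setClass("ScoreBreakdown",
  representation(
    b = "numeric", den = "numeric", dis = "numeric",
    size = "numeric", hy = "numeric", pro = "numeric",
    total = "numeric"
  )
)

#' Tunables of the annealed Metropolis-Hastings sampler
#'
#' @slot moveProbs numeric vector of four probabilities, in order:
#'   add-cluster, add-protein, remove-cluster, remove-protein. Must sum
#'   to 1 (default 0.25 each; the move mix is not prescribed elsewhere).
#' @slot L integer; number of iterations (published runs use 5e6; desk
#'   runs use 1e4--2e5).
#' @slot T0 numeric; initial temperature (default 1).
#' @slot coolingFactor numeric in (0,1]; geometric cooling multiplier per
#'   iteration (default 0.999999). 1 gives a fixed-temperature chain.
#' @slot gammaStepSd numeric; standard deviation of the Gaussian proposal
#'   for the scaling exponent (default \code{sqrt(0.001)}).
#' @slot gammaFloor numeric; lower clamp for the proposed exponent
#'   (default 1e-10).
#' @slot seed integer RNG seed; the run is fully reproducible from it.
#' @slot hastings logical; apply the proposal-ratio (Hastings) correction
#'   in the acceptance probability (default TRUE).
#' @slot sampleGamma logical; propose exponent updates (default TRUE;
#'   FALSE freezes the exponent at its initial value).
#' @slot traceEvery integer; record the score trace every this many
#'   iterations (default 1000).
#' @slot recomputeEvery integer; cross-check the incrementally maintained
#'   score against a full recomputation every this many iterations
#'   (default 10000); disagreement beyond 1e-8 aborts the run.
#' @slot recordStates logical; tally the visit count of every distinct
#'   cluster-set state (default FALSE; intended for small exactly
#'   enumerable networks).
#'
#' @seealso [samplerParams()], [runSampler()]
#' @export
setClass("SamplerParams",
  representation(
    moveProbs = "numeric", L = "integer", T0 = "numeric",
    coolingFactor = "numeric", gammaStepSd = "numeric",
    gammaFloor = "numeric", seed = "integer",
    hastings = "logical", sampleGamma = "logical",
    traceEvery = "integer", recomputeEvery = "integer",
    recordStates = "logical"
  )
)

setValidity("SamplerParams", function(object) {
  msgs <- character(0)
  mp <- object@moveProbs
  if (length(mp) != 4L || any(mp < 0) || abs(sum(mp) - 1) > 1e-12) {
    msgs <- c(msgs, "moveProbs must be four nonnegative values summing to 1")
  }
  if (object@L < 1L) msgs <- c(msgs, "L must be >= 1")
  if (!(object@coolingFactor > 0 && object@coolingFactor <= 1)) {
    msgs <- c(msgs, "coolingFactor must lie in (0, 1]")
  }
  if (object@T0 <= 0) msgs <- c(msgs, "T0 must be positive")
  if (object@gammaStepSd <= 0) msgs <- c(msgs, "gammaStepSd must be positive")
  if (object@gammaFloor <= 0) msgs <- c(msgs, "gammaFloor must be positive")
  if (object@traceEvery < 1L) msgs <- c(msgs, "traceEvery must be >= 1")
  if (object@recomputeEvery < 1L) msgs <- c(msgs, "recomputeEvery must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Result of one annealed sampling run
#'
#' @slot bestClusters [ClusterSet-class]; lowest-scoring cluster set
#'   visited by the chain.
#' @slot bestGamma numeric; scaling exponent at the best state.
#' @slot bestScore numeric; total score of the best state.
#' @slot trace data.frame with columns \code{iteration}, \code{score},
#'   \code{temperature}; the subsampled score trace.
#' @slot acceptanceRate numeric; fraction of iterations whose joint
#'   candidate was accepted.
#' @slot maxScoreDrift numeric; largest discrepancy observed between the
#'   incrementally maintained score and a full recomputation.
#' @slot stateCounts integer vector named by canonical state keys; visit
#'   counts when \code{recordStates} was on, empty otherwise.
#'
#' @seealso [runSampler()]
#' @export
setClass("SamplerResult",
  representation(
    bestClusters = "ClusterSet", bestGamma = "numeric",
    bestScore = "numeric", trace = "data.frame",
    acceptanceRate = "numeric", maxScoreDrift = "numeric",
    stateCounts = "integer"
  )
)

#' Size-stratified match evaluation report
#'
#' Precision, recall and F-measure of a predicted cluster set against a
#' catalogue of known complexes, under the size-stratified matching rule:
#' predictions and complexes of size 2 or 3 must match exactly, while
#' size >= 4 pairs match when their Jaccard index is at least 0.5.
#'
#' @slot precision numeric in [0,1].
#' @slot recall numeric in [0,1].
#' @slot fMeasure numeric in [0,1]; harmonic mean of precision and recall
#'   (0 when both are 0).
#' @slot matchedPredictionsByStratum integer vector (size2, size3, size4plus).
#' @slot matchedComplexesByStratum integer vector (size2, size3, size4plus).
#' @slot nPredicted integer; number of predicted clusters.
#' @slot nKnown integer; number of known complexes.
#'
#' @seealso [evaluateClusters()]
#' @export
setClass("EvalReport",
  representation(
    precision = "numeric", recall = "numeric", fMeasure = "numeric",
    matchedPredictionsByStratum = "integer",
    matchedComplexesByStratum = "integer",
    nPredicted = "integer", nKnown = "integer"
  )
)

#' Synthetic planted-complex benchmark
#'
#' A generated PPI network together with the ground-truth catalogue of
#' complexes planted in it and the generating configuration.
#'
#' @slot network [PPINetwork-class]; the generated network.
#' @slot truth [ClusterSet-class]; the planted complexes.
#' @slot config list; the full generating configuration, including the seed.
#'
#' @seealso [generateBenchmark()]
#' @export
setClass("SyntheticBenchmark",
  representation(
    network = "PPINetwork",
    truth = "ClusterSet",
    config = "list"
  )
)
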