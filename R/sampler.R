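#' Sampler parameters
#'
#' Constructor for [SamplerParams-class]. Defaults follow the published
#' configuration where one exists (initial temperature 1, cooling factor
#' 0.999999 per iteration, Gaussian exponent proposal with variance 0.001
#' clamped at 1e-10); the four move probabilities are symmetric 0.25 each
#' and the iteration count defaults to a desk-scale 1e5 (published runs
#' use 5e6).
#'
#' @param moveProbs numeric vector of four move probabilities, in order
#'   add-cluster, add-protein, remove-cluster, remove-protein.
#' @param L number of iterations.
#' @param T0 initial temperature.
#' @param coolingFactor geometric cooling multiplier; 1 fixes the
#'   temperature.
#' @param gammaStepSd standard deviation of the exponent proposal.
#' @param gammaFloor lower clamp of the proposed exponent.
#' @param seed RNG seed (integer).
#' @param hastings apply the proposal-ratio correction (default TRUE).
#' @param sampleGamma propose exponent updates (default TRUE).
#' @param traceEvery score-trace subsampling cadence.
#' @param recomputeEvery full-recompute cross-check cadence.
#' @param recordStates tally per-state visit counts (small networks only).
#' @return A [SamplerParams-class].
#' @export
samplerParams <- function(moveProbs = rep(0.25, 4), L = 1e5, T0 = 1,
                          coolingFactor = 0.999999,
                          gammaStepSd = sqrt(0.001), gammaFloor = 1e-10,
                          seed = 1L, hastings = TRUE, sampleGamma = TRUE,
                          traceEvery = 1000L, recomputeEvery = 10000L,
                          recordStates = FALSE) {
  new("SamplerParams", moveProbs = as.numeric(moveProbs),
      L = as.integer(L), T0 = T0, coolingFactor = coolingFactor,
      gammaStepSd = gammaStepSd, gammaFloor = gammaFloor,
      seed = as.integer(seed), hastings = hastings,
      sampleGamma = sampleGamma, traceEvery = as.integer(traceEvery),
      recomputeEvery = as.integer(recomputeEvery),
      recordStates = recordStates)
}

setMethod("show", "SamplerParams", function(object) {
  cat("SamplerParams: L =", object@L,
      "| T0 =", object@T0,
      "| cooling =", object@coolingFactor,
      "| moveProbs =", paste(object@moveProbs, collapse = "/"),
      "| seed =", object@seed, "\n")
})

#' Metropolis-Hastings acceptance probability
#'
#' \code{min(1, exp((fCurrent - fCandidate)/temperature) *
#' qReverse/qForward)} with the Hastings proposal-ratio correction on
#' (the default), or the plain Metropolis ratio with it off. An infinite
#' candidate score gives 0; an impossible reverse move
#' (\code{qReverse = 0}) forces rejection under the correction.
#'
#' @param fCurrent current total score (finite).
#' @param fCandidate candidate total score (may be \code{Inf}).
#' @param temperature positive temperature.
#' @param qForward forward proposal probability (> 0).
#' @param qReverse reverse proposal probability (>= 0).
#' @param hastings logical; apply the proposal-ratio correction.
#' @return Probability in [0, 1].
#' @export
acceptanceProbability <- function(fCurrent, fCandidate, temperature,
                                  qForward = 1, qReverse = 1,
                                  hastings = TRUE) {
  if (temperature <= 0) stop("temperature must be positive")
  if (is.infinite(fCandidate)) return(0)
  ratio <- exp((fCurrent - fCandidate) / temperature)
  if (hastings) ratio <- ratio * qReverse / qForward
  min(1, ratio)
}

#' Geometric cooling step
#'
#' @param temperature current temperature (> 0).
#' @param coolingFactor multiplier in (0, 1].
#' @return The cooled temperature.
#' @export
cool <- function(temperature, coolingFactor = 0.999999) {
  if (temperature <= 0) stop("temperature must be positive")
  temperature * coolingFactor
}

#' Gaussian proposal for the scaling exponent
#'
#' Returns \code{max(gammaFloor, gamma + eps)} with
#' \code{eps ~ N(0, gammaStepSd^2)}; the floor keeps the exponent
#' positive.
#'
#' @param gamma current exponent.
#' @param gammaStepSd proposal standard deviation (default
#'   \code{sqrt(0.001)}).
#' @param gammaFloor lower clamp (default 1e-10).
#' @return The proposed exponent.
#' @export
proposeGamma <- function(gamma, gammaStepSd = sqrt(0.001),
                         gammaFloor = 1e-10) {
  max(gammaFloor, gamma + stats::rnorm(1L, 0, gammaStepSd))
}

# Shared driver for the exported one-shot proposal wrappers: rebuild the
# chain state from a ClusterSet, draw one proposal with the global RNG,
# and translate it to user-facing names.
oneShotProposal <- function(net, X, scoreParams, samplerParams, fun) {
  st <- stateFromClusterSet(net, X, scoreParams)
  p <- fun(st, samplerParams@moveProbs)
  nm <- st$idx$names
  out <- list(
    kind = p$kind,
    noop = isTRUE(p$noop),
    infeasible = isTRUE(p$infeasible),
    qForward = p$qf,
    qReverse = p$qr
  )
  if (!is.null(p$pick)) out$pick <- nm[p$pick]
  if (!is.null(p$cluster)) {
    out$clusterIndex <- match(p$cluster, st$activeIds)
  }
  if (!out$noop && !out$infeasible) {
    commitProposal(st, p)
    out$candidate <- stateClusterSet(st)
  } else {
    out$candidate <- X
  }
  out
}

#' Single proposal moves
#'
#' One-shot versions of the four cluster-editing moves of the sampler,
#' drawn with the current global RNG from the state \code{(net, X)}.
#' Useful for inspecting and testing the proposal distributions:
#' \describe{
#'   \item{add-cluster}{pick an edge with probability proportional to its
#'     weight and add the corresponding two-protein cluster; proposing a
#'     cluster already present leaves the state unchanged.}
#'   \item{add-protein}{pick a cluster uniformly, then a neighboring
#'     protein with probability proportional to its connection weight to
#'     the cluster, and add it.}
#'   \item{remove-cluster}{pick a size-2 cluster with probability
#'     proportional to the inverse of its edge weight and remove it.}
#'   \item{remove-protein}{pick a cluster of size >= 3 uniformly, then a
#'     member with probability proportional to the inverse of its
#'     attachment weight, and remove it.}
#' }
#' Each returns the candidate cluster set, the forward and reverse
#' proposal probabilities (including the move-choice probability), the
#' picked edge/protein, and flags for no-op and infeasible outcomes.
#'
#' @param net a [PPINetwork-class].
#' @param X the current [ClusterSet-class] (must be feasible).
#' @param scoreParams a [ScoreParams-class] (supplies the size cap and
#'   overlap rule).
#' @param samplerParams a [SamplerParams-class] (supplies the move
#'   probabilities).
#' @return A list with elements \code{kind}, \code{noop},
#'   \code{infeasible}, \code{qForward}, \code{qReverse}, \code{pick},
#'   \code{clusterIndex} (when a cluster was selected) and
#'   \code{candidate}.
#' @name proposals
NULL

#' @rdname proposals
#' @export
proposeAddCluster <- function(net, X, scoreParams = NULL,
                              samplerParams = NULL) {
  scoreParams <- scoreParams %||% ComplexSampler::scoreParams()
  samplerParams <- samplerParams %||% ComplexSampler::samplerParams()
  oneShotProposal(net, X, scoreParams, samplerParams,
                  proposeAddClusterInternal)
}

#' @rdname proposals
#' @export
proposeAddProtein <- function(net, X, scoreParams = NULL,
                              samplerParams = NULL) {
  scoreParams <- scoreParams %||% ComplexSampler::scoreParams()
  samplerParams <- samplerParams %||% ComplexSampler::samplerParams()
  oneShotProposal(net, X, scoreParams, samplerParams,
                  proposeAddProteinInternal)
}

#' @rdname proposals
#' @export
proposeRemoveCluster <- function(net, X, scoreParams = NULL,
                                 samplerParams = NULL) {
  scoreParams <- scoreParams %||% ComplexSampler::scoreParams()
  samplerParams <- samplerParams %||% ComplexSampler::samplerParams()
  oneShotProposal(net, X, scoreParams, samplerParams,
                  proposeRemoveClusterInternal)
}

#' @rdname proposals
#' @export
proposeRemoveProtein <- function(net, X, scoreParams = NULL,
                                 samplerParams = NULL) {
  scoreParams <- scoreParams %||% ComplexSampler::scoreParams()
  samplerParams <- samplerParams %||% ComplexSampler::samplerParams()
  oneShotProposal(net, X, scoreParams, samplerParams,
                  proposeRemoveProteinInternal)
}

#' Run the annealed complex sampler
#'
#' Simulated annealing over cluster-set states: starting from the empty
#' set with the exponent at its prior center and temperature \code{T0},
#' each iteration draws one of the four cluster-editing moves, proposes a
#' Gaussian update of the scaling exponent, accepts or rejects the joint
#' candidate by the Metropolis-Hastings rule on the regularized score,
#' and cools the temperature geometrically. The lowest-scoring state ever
#' visited is returned.
#'
#' The RNG draw order per iteration is fixed (move choice, move-specific
#' selections, exponent noise, acceptance uniform), so a run is fully
#' reproducible from the seed.
#'
#' @param net a [PPINetwork-class] with at least one edge.
#' @param scoreParams a [ScoreParams-class].
#' @param samplerParams a [SamplerParams-class].
#' @return A [SamplerResult-class].
#' @examples
#' net <- ppiNetwork(data.frame(a = "A", b = "B", w = 1))
#' res <- runSampler(net, scoreParams(sMax = 3L),
#'                   samplerParams(L = 2000, seed = 7))
#' bestClusters(res)
#' @export
runSampler <- function(net, scoreParams = NULL,
                       samplerParams = NULL) {
  scoreParams <- scoreParams %||% ComplexSampler::scoreParams()
  samplerParams <- samplerParams %||% ComplexSampler::samplerParams()
  if (numEdges(net) == 0L) stop("network has no edges")
  sp <- scoreParams
  pp <- samplerParams
  set.seed(pp@seed)
  idx <- netIndex(net)
  st <- newSamplerState(idx, sp)
  alpha <- pp@moveProbs
  cumAlpha <- cumsum(alpha)
  gamma <- sp@gamma0
  psi <- powerLawPmfVec(gamma, sp@sMax)
  temp <- pp@T0
  fCur <- currentScore(st, gamma, psi)
  bestScore <- fCur
  bestGamma <- gamma
  bestClusters <- list()
  nAccept <- 0L
  maxDrift <- 0
  L <- pp@L
  nTrace <- L %/% pp@traceEvery
  traceIter <- integer(nTrace)
  traceScore <- numeric(nTrace)
  traceTemp <- numeric(nTrace)
  ti <- 0L
  counts <- if (pp@recordStates) new.env(parent = emptyenv()) else NULL
  curKey <- if (pp@recordStates) clusterSetKey(list()) else NULL
  sampleG <- pp@sampleGamma
  hastings <- pp@hastings

  for (l in seq_len(L)) {
    k <- findInterval(stats::runif(1), cumAlpha) + 1L
    p <- switch(k,
      proposeAddClusterInternal(st, alpha),
      proposeAddProteinInternal(st, alpha),
      proposeRemoveClusterInternal(st, alpha),
      proposeRemoveProteinInternal(st, alpha)
    )
    if (sampleG) {
      gNew <- max(pp@gammaFloor, gamma + stats::rnorm(1L, 0, pp@gammaStepSd))
      psiNew <- powerLawPmfVec(gNew, sp@sMax)
    } else {
      gNew <- gamma
      psiNew <- psi
    }
    accept <- FALSE
    if (isTRUE(p$infeasible)) {
      # candidate has zero probability; the joint move is rejected
    } else if (isTRUE(p$noop)) {
      if (sampleG) {
        fCand <- currentScore(st, gNew, psiNew)
        if (stats::runif(1) < exp((fCur - fCand) / temp)) {
          accept <- TRUE
          gamma <- gNew; psi <- psiNew; fCur <- fCand
        }
      } else {
        accept <- TRUE
      }
    } else {
      disNew <- st$disSum + p$dDis
      counts2 <- st$sizeCounts
      nX2 <- st$nX
      if (!is.na(p$sizeFrom)) {
        counts2[p$sizeFrom] <- counts2[p$sizeFrom] - 1L
        nX2 <- nX2 - 1L
      }
      if (!is.na(p$sizeTo)) {
        counts2[p$sizeTo] <- counts2[p$sizeTo] + 1L
        nX2 <- nX2 + 1L
      }
      fCand <- stateScore(st, st$densSum + p$dDens, disNew, counts2, nX2,
                          st$nUnion + p$dU, gNew, psiNew)
      ratio <- exp((fCur - fCand) / temp)
      if (hastings) ratio <- ratio * p$qr / p$qf
      if (stats::runif(1) < ratio) {
        accept <- TRUE
        commitProposal(st, p)
        gamma <- gNew; psi <- psiNew; fCur <- fCand
        if (!is.null(counts)) {
          curKey <- clusterSetKey(lapply(st$clist[st$activeIds],
                                         function(m) idx$names[m]))
        }
      }
    }
    if (accept) {
      nAccept <- nAccept + 1L
      if (fCur < bestScore) {
        bestScore <- fCur
        bestGamma <- gamma
        bestClusters <- st$clist[st$activeIds]
      }
    }
    if (l %% pp@traceEvery == 0L) {
      ti <- ti + 1L
      traceIter[ti] <- l
      traceScore[ti] <- fCur
      traceTemp[ti] <- temp
    }
    if (l %% pp@recomputeEvery == 0L) {
      full <- totalScore(net, stateClusterSet(st), gamma, sp)@total
      drift <- abs(full - fCur)
      if (drift > maxDrift) maxDrift <- drift
      if (drift > 1e-8 * max(1, abs(fCur))) {
        stop("incremental score drifted from full recomputation by ", drift)
      }
    }
    if (!is.null(counts)) {
      cur <- counts[[curKey]]
      counts[[curKey]] <- if (is.null(cur)) 1L else cur + 1L
    }
    temp <- temp * pp@coolingFactor
  }

  stateCounts <- integer(0)
  if (!is.null(counts)) {
    keys <- ls(counts, all.names = TRUE, sorted = TRUE)
    stateCounts <- vapply(keys, function(k) counts[[k]], 0L)
  }
  new("SamplerResult",
      bestClusters = clusterSet(lapply(bestClusters,
                                       function(m) idx$names[m])),
      bestGamma = bestGamma,
      bestScore = bestScore,
      trace = data.frame(iteration = traceIter[seq_len(ti)],
                         score = traceScore[seq_len(ti)],
                         temperature = traceTemp[seq_len(ti)]),
      acceptanceRate = nAccept / L,
      maxScoreDrift = maxDrift,
      stateCounts = stateCounts)
}

#' @describeIn SamplerResult-class the lowest-scoring cluster set visited.
#' @param object a \code{SamplerResult}.
#' @export
setGeneric("bestClusters", function(object) standardGeneric("bestClusters"))

#' @rdname SamplerResult-class
#' @export
setMethod("bestClusters", "SamplerResult",
          function(object) object@bestClusters)

#' @describeIn SamplerResult-class scaling exponent at the best state.
#' @export
setGeneric("bestGamma", function(object) standardGeneric("bestGamma"))

#' @rdname SamplerResult-class
#' @export
setMethod("bestGamma", "SamplerResult", function(object) object@bestGamma)

#' @describeIn SamplerResult-class total score of the best state.
#' @export
setGeneric("bestScore", function(object) standardGeneric("bestScore"))

#' @rdname SamplerResult-class
#' @export
setMethod("bestScore", "SamplerResult", function(object) object@bestScore)

#' @describeIn SamplerResult-class subsampled score trace.
#' @export
setGeneric("scoreTrace", function(object) standardGeneric("scoreTrace"))

#' @rdname SamplerResult-class
#' @export
setMethod("scoreTrace", "SamplerResult", function(object) object@trace)

setMethod("show", "SamplerResult", function(object) {
  cat("SamplerResult\n")
  cat("  best score     :", object@bestScore, "\n")
  cat("  best exponent  :", format(object@bestGamma, digits = 4), "\n")
  cat("  best clusters  :", length(object@bestClusters), "\n")
  cat("  acceptance rate:", format(object@acceptanceRate, digits = 4), "\n")
})
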