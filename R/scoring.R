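#' Score parameters with published defaults
#'
#' Constructor for [ScoreParams-class]. Defaults are the coefficient set
#' selected for the large weighted yeast compendium: overlap coefficient
#' 110, overlap-ratio cap 0.2, size-distribution coefficient 500,
#' exponent-prior coefficient 10, protein-count coefficient 5e-5, size cap
#' 100, and prior center 2.5 for the scaling exponent.
#'
#' @param sMax integer cluster-size cap.
#' @param beta overlap-ratio cap for clusters of size >= 4.
#' @param cCluDis coefficient of the overlap penalty.
#' @param cCluSize coefficient of the size-distribution penalty.
#' @param cHy coefficient of the exponent prior.
#' @param cProNum coefficient of the squared clustered-protein count.
#' @param gamma0 prior center of the scaling exponent.
#' @return A [ScoreParams-class].
#' @export
scoreParams <- function(sMax = 100L, beta = 0.2, cCluDis = 110,
                        cCluSize = 500, cHy = 10, cProNum = 5e-5,
                        gamma0 = 2.5) {
  new("ScoreParams", sMax = as.integer(sMax), beta = beta,
      cCluDis = cCluDis, cCluSize = cCluSize, cHy = cHy,
      cProNum = cProNum, gamma0 = gamma0)
}

setMethod("show", "ScoreParams", function(object) {
  cat("ScoreParams: sMax =", object@sMax,
      "| beta =", object@beta,
      "| cCluDis =", object@cCluDis,
      "| cCluSize =", object@cCluSize,
      "| cHy =", object@cHy,
      "| cProNum =", format(object@cProNum),
      "| gamma0 =", object@gamma0, "\n")
})

#' Feasibility term of the score
#'
#' Returns 0 when every cluster has at most \code{sMax} members and is
#' connected in its induced subgraph, and \code{Inf} otherwise. An
#' infinite value gives the state zero probability.
#'
#' @param net a [PPINetwork-class].
#' @param X a [ClusterSet-class].
#' @param sMax integer cluster-size cap.
#' @return 0 or \code{Inf}.
#' @export
booleanTerm <- function(net, X, sMax = 100L) {
  idx <- netIndex(net)
  for (x in clusters(X)) {
    xi <- memberIdx(idx, x)
    if (length(xi) > sMax || !inducedConnected(idx, xi)) return(Inf)
  }
  0
}

#' Generalized density of a cluster
#'
#' Internal edge-weight sum divided by the square root of the cluster
#' size: \eqn{w(x)/\sqrt{|x|}}. The square-root denominator softens the
#' penalty on large clusters relative to the standard density
#' \eqn{w(x)/(|x|(|x|-1)/2)}, since not every protein pair inside a large
#' complex interacts physically.
#'
#' @inheritParams clusterWeight
#' @return Numeric density.
#' @export
clusterDensity <- function(net, members) {
  clusterWeight(net, members) / sqrt(length(members))
}

#' Density term of the score
#'
#' Negative sum of the generalized densities of all clusters; the only
#' reward in the score (all other terms are penalties).
#'
#' @inheritParams booleanTerm
#' @return Numeric (0 for an empty cluster set).
#' @export
densityTerm <- function(net, X) {
  cl <- clusters(X)
  if (!length(cl)) return(0)
  -sum(vapply(cl, clusterDensity, 0, net = net))
}

#' Overlap penalty between two clusters
#'
#' For clusters \code{x}, \code{y} with \eqn{m = \min(|x|, |y|)}: if
#' \eqn{m \le 3} the pair may share at most one protein; if \eqn{m \ge 4}
#' the shared fraction \eqn{|x \cap y|/m} may not exceed \code{beta}.
#' Within those bounds the penalty is the Jaccard index of the pair;
#' beyond them it is \code{Inf} (the overlap is forbidden). Disjoint
#' clusters score 0.
#'
#' @param x,y character vectors of cluster members (size >= 2).
#' @param beta overlap-ratio cap for the large-cluster branch.
#' @return Numeric penalty, possibly \code{Inf}.
#' @examples
#' pairDissimilarity(c("A", "B"), c("B", "C"))          # 1/3
#' pairDissimilarity(c("A", "B", "C"), c("A", "B", "D")) # Inf
#' @export
pairDissimilarity <- function(x, y, beta = 0.2) {
  inter <- length(intersect(x, y))
  m <- min(length(x), length(y))
  ok <- if (m <= 3L) inter <= 1L else inter / m <= beta
  if (!ok) return(Inf)
  inter / (length(x) + length(y) - inter)
}

#' Overlap term of the score
#'
#' Sum of [pairDissimilarity()] over all unordered pairs of distinct
#' clusters. 0 when the set has at most one cluster or all clusters are
#' pairwise disjoint.
#'
#' @param X a [ClusterSet-class].
#' @param beta overlap-ratio cap.
#' @return Numeric penalty, possibly \code{Inf}.
#' @export
overlapTerm <- function(X, beta = 0.2) {
  cl <- clusters(X)
  n <- length(cl)
  if (n <= 1L) return(0)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pairDissimilarity(cl[[i]], cl[[j]], beta)
      if (is.infinite(d)) return(Inf)
      tot <- tot + d
    }
  }
  tot
}

#' Truncated power-law size distribution
#'
#' Probability of cluster size \code{s} under the two-sided truncated
#' power law \eqn{\psi_\gamma(s) = s^{-\gamma} / \sum_{t=2}^{S_{max}}
#' t^{-\gamma}} on \eqn{[2, S_{max}]}. \code{gamma = 0} gives the uniform
#' distribution.
#'
#' @param s integer vector of sizes in \code{[2, sMax]}.
#' @param gamma scaling exponent (>= 0).
#' @param sMax upper truncation point.
#' @return Numeric vector of probabilities.
#' @examples
#' powerLawPmf(2:3, gamma = 1, sMax = 3)  # 0.6, 0.4
#' @export
powerLawPmf <- function(s, gamma, sMax = 100L) {
  if (any(s < 2L | s > sMax)) {
    stop("size outside [2, sMax]")
  }
  if (gamma < 0) stop("gamma must be nonnegative")
  t <- 2:sMax
  s^(-gamma) / sum(t^(-gamma))
}

# Full pmf vector over sizes 2..sMax (position i holds size i+1).
powerLawPmfVec <- function(gamma, sMax) {
  t <- 2:sMax
  p <- t^(-gamma)
  p / sum(p)
}

#' Empirical cluster-size fraction
#'
#' Fraction of clusters in \code{X} with exactly \code{s} members; 0 for
#' every size when \code{X} is empty.
#'
#' @param X a [ClusterSet-class].
#' @param s integer vector of sizes (>= 2).
#' @return Numeric vector of fractions.
#' @export
sizeFraction <- function(X, s) {
  if (any(s < 2L)) stop("size must be >= 2")
  n <- length(X)
  if (n == 0L) return(rep(0, length(s)))
  sz <- clusterSizes(X)
  vapply(s, function(si) sum(sz == si), 0) / n
}

#' Size-distribution term of the score
#'
#' Squared-error between the empirical size distribution of \code{X} and
#' the truncated power law with exponent \code{gamma}:
#' \eqn{\sum_{s=2}^{S_{max}} (\psi_X(s) - \psi_\gamma(s))^2}. For an
#' empty set the empirical distribution is identically 0, leaving the
#' finite penalty \eqn{\sum_s \psi_\gamma(s)^2} that pushes the sampler
#' away from the empty state.
#'
#' @inheritParams sizeFraction
#' @param gamma scaling exponent.
#' @param sMax size cap / truncation point.
#' @return Numeric in \code{[0, 2]}.
#' @export
sizeTerm <- function(X, gamma, sMax = 100L) {
  psiG <- powerLawPmfVec(gamma, sMax)
  n <- length(X)
  psiX <- if (n == 0L) {
    numeric(sMax - 1L)
  } else {
    tabulate(clusterSizes(X), nbins = sMax)[-1L] / n
  }
  sum((psiX - psiG)^2)
}

#' Prior term on the scaling exponent
#'
#' Quadratic loss \eqn{(\gamma - \gamma_0)^2} centering the power-law
#' exponent on \code{gamma0} (default 2.5, the midpoint of the range
#' (2, 3) typical of empirical power laws).
#'
#' @param gamma scaling exponent.
#' @param gamma0 prior center.
#' @return Numeric penalty.
#' @export
hyperPriorTerm <- function(gamma, gamma0 = 2.5) {
  (gamma - gamma0)^2
}

#' Clustered-protein-count term of the score
#'
#' Square of the number of distinct proteins appearing in any cluster,
#' restraining the total coverage of the prediction.
#'
#' @param X a [ClusterSet-class].
#' @return Numeric penalty.
#' @export
proteinCountTerm <- function(X) {
  length(unique(unlist(clusters(X))))^2
}

#' Total regularized score of a cluster-set state
#'
#' Evaluates every component of \eqn{f(X, \gamma)} and the
#' coefficient-weighted total:
#' \deqn{f(X,\gamma) = b(X) + h_{den}(X) + c_{dis} h_{dis}(X) +
#'   c_{size} \sum_s (\psi_X(s)-\psi_\gamma(s))^2 +
#'   c_{hy} (\gamma-\gamma_0)^2 + c_{pro} |\cup_x x|^2.}
#' The total is \code{Inf} exactly when the feasibility term or the
#' overlap term is.
#'
#' @param net a [PPINetwork-class].
#' @param X a [ClusterSet-class].
#' @param gamma scaling exponent of the candidate power law.
#' @param params a [ScoreParams-class].
#' @return A [ScoreBreakdown-class].
#' @export
totalScore <- function(net, X, gamma, params = scoreParams()) {
  b <- booleanTerm(net, X, params@sMax)
  den <- densityTerm(net, X)
  dis <- overlapTerm(X, params@beta)
  size <- sizeTerm(X, gamma, params@sMax)
  hy <- hyperPriorTerm(gamma, params@gamma0)
  pro <- proteinCountTerm(X)
  total <- if (is.infinite(b) || is.infinite(dis)) {
    Inf
  } else {
    b + den + params@cCluDis * dis + params@cCluSize * size +
      params@cHy * hy + params@cProNum * pro
  }
  new("ScoreBreakdown", b = b, den = den, dis = dis, size = size,
      hy = hy, pro = pro, total = total)
}

#' @describeIn ScoreBreakdown-class the weighted total score.
#' @param object a \code{ScoreBreakdown}.
#' @export
setGeneric("scoreTotal", function(object) standardGeneric("scoreTotal"))

#' @rdname ScoreBreakdown-class
#' @export
setMethod("scoreTotal", "ScoreBreakdown", function(object) object@total)

setMethod("show", "ScoreBreakdown", function(object) {
  cat("ScoreBreakdown\n")
  cat("  feasibility b :", object@b, "\n")
  cat("  density       :", object@den, "\n")
  cat("  overlap       :", object@dis, "\n")
  cat("  size dist.    :", object@size, "\n")
  cat("  exponent prior:", object@hy, "\n")
  cat("  protein count :", object@pro, "\n")
  cat("  total         :", object@total, "\n")
})
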